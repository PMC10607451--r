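#' Square image grids
#'
#' An `image_grid` is a square numeric matrix carrying the number of allowed
#' gray levels as an attribute. It holds both ground-truth phantoms (integer
#' values in `0:(levels - 1)`) and reconstructions, which may be continuous
#' before the final discretization step. Wherever an image is treated as a
#' vector (system matrices, QUBO variables) the order is row-major from the
#' top-left pixel.
#'
#' @param values square numeric matrix of non-negative gray levels.
#' @param levels number of allowed gray levels (2 for binary, 16 for 4-bit).
#' @return an `image_grid`: the matrix with class and `levels` attribute.
#' @export
image_grid <- function(values, levels = 2L) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("image_grid values must be a square matrix", call. = FALSE)
  }
  if (nrow(values) < 1L) stop("image_grid must have at least one pixel", call. = FALSE)
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L) stop("levels must be an integer >= 2", call. = FALSE)
  structure(values, class = c("image_grid", class(values)), levels = levels)
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid %dx%d, %d gray levels>\n",
              nrow(x), ncol(x), img_levels(x)))
  print(unclass_image(x), ...)
  invisible(x)
}

#' @rdname image_grid
#' @param image an `image_grid` or plain square matrix.
#' @export
img_size <- function(image) nrow(image)

#' @rdname image_grid
#' @export
img_levels <- function(image) {
  lv <- attr(image, "levels")
  if (is.null(lv)) 2L else as.integer(lv)
}

unclass_image <- function(image) {
  attr(image, "levels") <- NULL
  class(image) <- setdiff(class(image), "image_grid")
  as.matrix(image)
}

#' Row-major vectorization of an image
#'
#' `vec_image` flattens row by row from the top-left pixel; `unvec_image`
#' inverts it. This is the pixel order used by system-matrix columns and
#' QUBO variables throughout the package.
#'
#' @param image square matrix.
#' @return numeric vector of length `N^2`.
#' @export
vec_image <- function(image) as.vector(t(unclass_image(image)))

#' @rdname vec_image
#' @param x numeric vector of length `size^2`.
#' @param size image side length.
#' @export
unvec_image <- function(x, size) {
  if (length(x) != size * size) {
    stop("vector length does not match size^2", call. = FALSE)
  }
  matrix(x, nrow = size, ncol = size, byrow = TRUE)
}

assert_square_image <- function(image, what = "image") {
  if (!is.matrix(image) || nrow(image) != ncol(image)) {
    stop(sprintf("%s must be a square matrix", what), call. = FALSE)
  }
  invisible(image)
}
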