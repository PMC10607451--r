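#' Parallel-beam projection geometry
#'
#' Fixes the meaning of every sinogram row: `n_views` angles equally spaced
#' on \[0, 180) degrees (`angle_k = 180 k / V`), with the 0-degree view taken
#' from the top of the image (rays travel vertically) and increasing angles
#' rotating clockwise. Detector bins run left to right within a view.
#'
#' @param image_size side length N of the image the geometry addresses.
#' @param n_views number of projection views V.
#' @param n_bins detector bins per view; defaults to N.
#' @return a `tomo_geometry` object.
#' @export
tomo_geometry <- function(image_size, n_views, n_bins = image_size) {
  image_size <- as.integer(image_size)
  n_views <- as.integer(n_views)
  n_bins <- as.integer(n_bins)
  if (image_size < 2L) stop("image_size must be >= 2", call. = FALSE)
  if (n_views < 1L) stop("n_views must be >= 1", call. = FALSE)
  if (n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  structure(list(
    image_size = image_size,
    n_views = n_views,
    n_bins = n_bins,
    angles = 180 * (seq_len(n_views) - 1L) / n_views
  ), class = "tomo_geometry")
}

#' @export
print.tomo_geometry <- function(x, ...) {
  cat(sprintf("<tomo_geometry N=%d, %d views x %d bins, angles %s%s>\n",
              x$image_size, x$n_views, x$n_bins,
              paste(utils::head(round(x$angles, 2), 4), collapse = ", "),
              if (x$n_views > 4) ", ..." else ""))
  invisible(x)
}

#' Sinogram container
#'
#' A `V x B` matrix of line-integral measurements plus the geometry that
#' fixes its interpretation. When a sinogram appears as a vector `y`, the
#' order is row-major: views in angle order, bins left to right.
#'
#' @param values `n_views x n_bins` numeric matrix.
#' @param geometry a [tomo_geometry].
#' @return a `sinogram` object.
#' @export
sinogram <- function(values, geometry) {
  values <- as.matrix(values)
  if (nrow(values) != geometry$n_views || ncol(values) != geometry$n_bins) {
    stop("sinogram values must be n_views x n_bins", call. = FALSE)
  }
  structure(list(values = values, geometry = geometry), class = "sinogram")
}

#' @rdname sinogram
#' @param sino a `sinogram`.
#' @export
vec_sinogram <- function(sino) as.vector(t(sino$values))

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram %d views x %d bins (N=%d)>\n",
              x$geometry$n_views, x$geometry$n_bins, x$geometry$image_size))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Per-view projection operators.
#
# A view at angle theta is computed by rotating the image about its center
# ((N-1)/2, 0-based) with bilinear interpolation and zero padding, then
# summing the rotated image along the vertical axis into B = N bins. The
# rotation is a fixed sparse linear map, so the whole view is one sparse
# matrix P_theta (N x N^2, row-major pixel order). project() and
# build_system_matrix() share these operators, which makes the
# matrix/operator consistency exact by construction.
# ---------------------------------------------------------------------------

projection_cache <- new.env(parent = emptyenv())

view_operator <- function(n, angle_deg) {
  key <- sprintf("%d_%.10f", n, angle_deg)
  cached <- projection_cache[[key]]
  if (!is.null(cached)) return(cached)

  theta <- angle_deg * pi / 180
  cc <- (n - 1) / 2
  # output pixel grid, 0-based, row-major order
  out_r <- rep(0:(n - 1), each = n)
  out_c <- rep(0:(n - 1), times = n)
  dx <- out_c - cc
  dy <- out_r - cc
  # inverse map: source coordinates of each rotated pixel
  sx <- cos(theta) * dx - sin(theta) * dy + cc
  sy <- sin(theta) * dx + cos(theta) * dy + cc

  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0;   fy <- sy - y0
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (corner in 1:4) {
    xi <- x0 + (corner == 2L || corner == 4L)
    yi <- y0 + (corner >= 3L)
    w <- (ifelse(xi == x0, 1 - fx, fx)) * (ifelse(yi == y0, 1 - fy, fy))
    keep <- xi >= 0 & xi <= n - 1 & yi >= 0 & yi <= n - 1 & w > 0
    rows <- c(rows, which(keep))
    cols <- c(cols, (yi[keep] * n + xi[keep]) + 1L)
    vals <- c(vals, w[keep])
  }
  rot <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                              dims = c(n * n, n * n))
  # bin b sums rotated pixels in column b: row-major pixel p = r*n + c + 1
  # has column index (p - 1) %% n
  sel <- Matrix::sparseMatrix(i = (seq_len(n * n) - 1L) %% n + 1L,
                              j = seq_len(n * n), x = 1,
                              dims = c(n, n * n))
  op <- sel %*% rot
  projection_cache[[key]] <- op
  op
}

#' Forward-project an image into a sinogram
#'
#' Rotate-then-sum parallel-beam projector: for each view the image is
#' rotated about its center by the view angle (bilinear interpolation, zero
#' padding outside the grid) and summed vertically into `N` bins. The
#' operator is linear in the image and agrees with [build_system_matrix()]
#' to machine precision.
#'
#' @param image an [image_grid] or square matrix.
#' @param geometry a [tomo_geometry] with `image_size` equal to the image's.
#' @return a [sinogram].
#' @export
project <- function(image, geometry) {
  assert_square_image(image)
  n <- img_size(image)
  if (n != geometry$image_size) {
    stop("image size does not match geometry image_size", call. = FALSE)
  }
  if (geometry$n_bins != n) {
    stop("projector requires n_bins = image_size; rebin afterwards instead",
         call. = FALSE)
  }
  x <- vec_image(image)
  values <- matrix(0, geometry$n_views, geometry$n_bins)
  for (v in seq_len(geometry$n_views)) {
    values[v, ] <- as.numeric(view_operator(n, geometry$angles[v]) %*% x)
  }
  sinogram(values, geometry)
}

#' Assemble the explicit system matrix
#'
#' Returns the dense `m x n` matrix `M` (m = views x bins, n = N^2) whose
#' column j is the vectorized sinogram of the unit image with a single 1 at
#' pixel j (row-major order). By construction `M %*% vec_image(x)` equals
#' `vec_sinogram(project(x, geometry))` exactly for every image.
#'
#' @param geometry a [tomo_geometry].
#' @return a `system_matrix` object wrapping the dense matrix.
#' @export
build_system_matrix <- function(geometry) {
  n <- geometry$image_size
  if (geometry$n_bins != n) {
    stop("system matrix requires n_bins = image_size", call. = FALSE)
  }
  blocks <- lapply(geometry$angles, function(a) view_operator(n, a))
  m <- as.matrix(do.call(rbind, blocks))
  dimnames(m) <- NULL
  structure(list(values = m, geometry = geometry), class = "system_matrix")
}

#' @export
print.system_matrix <- function(x, ...) {
  cat(sprintf("<system_matrix %d x %d (N=%d, %d views)>\n",
              nrow(x$values), ncol(x$values),
              x$geometry$image_size, x$geometry$n_views))
  invisible(x)
}

system_values <- function(M) {
  if (inherits(M, "system_matrix")) M$values else as.matrix(M)
}

#' Rebin a sinogram to a coarser detector
#'
#' Groups of `factor` adjacent bins are averaged and multiplied by `scale`
#' (default `1/factor`), which expresses the fine-grid line integrals in the
#' coarse grid's pixel units: a ray through a grid refined by `factor`
#' accumulates about `factor` times more samples. The view count and angles
#' are unchanged; the output geometry addresses the coarse grid
#' (`image_size = n_bins / factor`).
#'
#' @param sino a [sinogram].
#' @param factor integer dividing the bin count.
#' @param scale multiplier applied after averaging; default `1/factor`.
#' @return a [sinogram] on the coarse geometry.
#' @export
rebin_sinogram <- function(sino, factor, scale = 1 / factor) {
  factor <- as.integer(factor)
  b <- sino$geometry$n_bins
  if (factor < 1L || b %% factor != 0L) {
    stop("factor must divide the number of detector bins", call. = FALSE)
  }
  b_out <- b %/% factor
  group <- rep(seq_len(b_out), each = factor)
  values <- t(apply(sino$values, 1L, function(row) {
    tapply(row, group, mean) * scale
  }))
  if (sino$geometry$n_views == 1L) values <- matrix(values, nrow = 1L)
  geom_out <- tomo_geometry(b_out, sino$geometry$n_views, b_out)
  sinogram(values, geom_out)
}

#' Sample a per-view noise field
#'
#' Signal-dependent integer offsets imitating low-count emission statistics:
#' at pixels where the image is zero the offset is drawn uniformly from
#' \{0, 1\}; elsewhere uniformly from \{-1, 0, 1\}. The perturbed image
#' `x + n` is therefore always non-negative. Draws from the current RNG
#' state; seed externally (e.g. [withr::with_seed()]) for reproducibility.
#'
#' @param image integer-valued non-negative image.
#' @return integer matrix of offsets, same shape as `image`.
#' @export
sample_noise_field <- function(image) {
  values <- unclass_image(image)
  if (any(values < 0) || any(values != round(values))) {
    stop("noise model requires a non-negative integer-valued image",
         call. = FALSE)
  }
  n <- length(values)
  field <- matrix(0L, nrow(values), ncol(values))
  zero <- values == 0
  field[zero] <- sample(c(0L, 1L), sum(zero), replace = TRUE)
  field[!zero] <- sample(c(-1L, 0L, 1L), sum(!zero), replace = TRUE)
  field
}

#' Project with per-view additive image noise
#'
#' For each view an independent noise field is drawn and added to the
#' ground-truth image before projecting that single view, creating
#' independent noise realizations across views (the acquisition sees a
#' slightly different object at every angle).
#'
#' @param image integer-valued non-negative [image_grid].
#' @param geometry a [tomo_geometry].
#' @param seed integer seed; the whole noisy sinogram is bitwise
#'   reproducible per seed.
#' @return a [sinogram].
#' @export
project_with_noise <- function(image, geometry, seed) {
  assert_square_image(image)
  n <- img_size(image)
  if (n != geometry$image_size) {
    stop("image size does not match geometry image_size", call. = FALSE)
  }
  values <- withr::with_seed(as.integer(seed), {
    out <- matrix(0, geometry$n_views, geometry$n_bins)
    for (v in seq_len(geometry$n_views)) {
      field <- sample_noise_field(image)
      noisy <- unclass_image(image) + field
      out[v, ] <- as.numeric(view_operator(n, geometry$angles[v]) %*%
                               as.vector(t(noisy)))
    }
    out
  })
  sinogram(values, geometry)
}

#' Sinogram and system-matrix CSV interchange
#'
#' Sinograms are written as CSV (one row per view) with a JSON sidecar
#' (`<path>.json`) carrying the geometry. System matrices are written as
#' plain CSV; sizes above N = 64 are refused unless `force = TRUE`, since
#' the dense matrix grows as N^4.
#'
#' @param sino a [sinogram].
#' @param path output file path.
#' @name sinogram_io
#' @export
write_sinogram_csv <- function(sino, path) {
  utils::write.table(sino$values, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  g <- sino$geometry
  jsonlite::write_json(
    list(image_size = g$image_size, n_views = g$n_views, n_bins = g$n_bins),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname sinogram_io
#' @export
read_sinogram_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  values <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(values) <- NULL
  sinogram(values, tomo_geometry(meta$image_size, meta$n_views, meta$n_bins))
}

#' @rdname sinogram_io
#' @param M a `system_matrix`.
#' @param force write even for N > 64.
#' @export
write_system_matrix_csv <- function(M, path, force = FALSE) {
  if (M$geometry$image_size > 64L && !force) {
    stop("refusing to write a dense system matrix for N > 64; ",
         "pass force = TRUE to override", call. = FALSE)
  }
  utils::write.table(M$values, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
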