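#' Generate a synthetic ground-truth phantom
#'
#' Produces the test images used throughout the package's experiments:
#' four procedural binary structures of deliberately different frequency
#' content, a quantized Shepp-Logan head phantom, and small digit-like
#' integer blob images.
#'
#' * `foam`: thresholded smoothed Gaussian noise, giving irregular blobs.
#' * `tree`: recursive branching strokes growing upward from the base.
#' * `snowflake`: random radial rays mirrored with 6-fold dihedral symmetry.
#' * `molecule`: a handful of disjoint filled disks.
#' * `shepp_logan`: the standard (modified) Shepp-Logan ellipse phantom,
#'   scaled to `[0, levels - 1]` and rounded half up.
#' * `digit`: an 8x8-style stroke blob with integer values in
#'   `[0, levels - 1]`.
#'
#' Binary structures are drawn on a 4x finer grid and reduced by local block
#' means, then thresholded at 0.5 (ties to 1), so the same seed yields a
#' consistent object across image sizes. Output is bitwise deterministic per
#' `(kind, size, levels, seed)`.
#'
#' @param kind one of `"foam"`, `"tree"`, `"snowflake"`, `"molecule"`,
#'   `"shepp_logan"`, `"digit"`.
#' @param size image side length N (N >= 3; N >= 4 for `shepp_logan`).
#' @param levels number of gray levels; must be 2 for the binary kinds.
#' @param seed integer seed for the phantom's private random stream.
#' @return an [image_grid] with integer values in `0:(levels - 1)`; binary
#'   kinds contain both classes.
#' @export
make_phantom <- function(kind, size, levels = 2L, seed = 1L) {
  kind <- match.arg(kind, c("foam", "tree", "snowflake", "molecule",
                            "shepp_logan", "digit"))
  size <- as.integer(size)
  levels <- as.integer(levels)
  seed <- as.integer(seed)
  binary_kinds <- c("foam", "tree", "snowflake", "molecule")
  if (is.na(size) || size < 3L) {
    stop("size too small to host the structure (need size >= 3)", call. = FALSE)
  }
  if (kind %in% c("shepp_logan", "digit") && size < 4L) {
    stop("size too small to host the structure (need size >= 4)", call. = FALSE)
  }
  if (levels < 2L) stop("levels must be >= 2", call. = FALSE)
  if (kind %in% binary_kinds && levels != 2L) {
    stop("binary phantom kinds require levels = 2", call. = FALSE)
  }

  values <- withr::with_seed(seed, {
    switch(kind,
      foam      = gen_binary_structure(size, gen_foam_fine),
      tree      = gen_binary_structure(size, gen_tree_fine),
      snowflake = gen_binary_structure(size, gen_snowflake_fine),
      molecule  = gen_binary_structure(size, gen_molecule_fine),
      shepp_logan = gen_shepp_logan(size, levels),
      digit     = gen_digit(size, levels)
    )
  })
  image_grid(values, levels)
}

# Draw a binary structure on a 4x finer grid, local-mean downsample, and
# binarize at 0.5 (ties to 1). Falls back to a median split if the midpoint
# threshold collapses to a single class (possible at very small sizes).
gen_binary_structure <- function(size, generator) {
  fine <- generator(4L * size)
  coarse <- block_mean(fine, 4L)
  out <- (coarse >= 0.5) * 1
  if (length(unique(as.vector(out))) < 2L) {
    med <- stats::median(coarse)
    out <- (coarse >= med) * 1
    if (length(unique(as.vector(out))) < 2L) {
      # all block means identical: keep a single bright pixel
      out[] <- 0
      out[1L, 1L] <- 1
    }
  }
  out
}

gen_foam_fine <- function(f) {
  noise <- matrix(stats::rnorm(f * f), f, f)
  s <- gaussian_smoother(f, sigma = f / 10)
  smooth <- s %*% noise %*% t(s)
  (smooth >= stats::quantile(smooth, 0.55)) * 1
}

# One-dimensional Gaussian smoothing operator with renormalized edge rows.
gaussian_smoother <- function(n, sigma) {
  idx <- seq_len(n)
  d <- outer(idx, idx, function(a, b) a - b)
  k <- exp(-d^2 / (2 * sigma^2))
  k / rowSums(k)
}

draw_disk <- function(canvas, row, col, radius) {
  n <- nrow(canvas)
  r0 <- max(1L, floor(row - radius)); r1 <- min(n, ceiling(row + radius))
  c0 <- max(1L, floor(col - radius)); c1 <- min(n, ceiling(col + radius))
  if (r0 > r1 || c0 > c1) return(canvas)
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - row)^2, (cc - col)^2, `+`)
  canvas[rr, cc][d2 <= radius^2] <- 1
  canvas
}

draw_segment <- function(canvas, r0, c0, r1, c1, thickness) {
  len <- sqrt((r1 - r0)^2 + (c1 - c0)^2)
  steps <- max(2L, ceiling(len / 0.4))
  t <- seq(0, 1, length.out = steps)
  for (i in seq_along(t)) {
    canvas <- draw_disk(canvas, r0 + t[i] * (r1 - r0), c0 + t[i] * (c1 - c0),
                        thickness)
  }
  canvas
}

gen_tree_fine <- function(f) {
  canvas <- matrix(0, f, f)
  # angle 0 points up (decreasing row); recursion thins and shortens branches
  grow <- function(canvas, row, col, angle, len, depth, thickness) {
    r1 <- row - len * cos(angle)
    c1 <- col + len * sin(angle)
    canvas <- draw_segment(canvas, row, col, r1, c1, thickness)
    if (depth > 0L) {
      for (sgn in c(-1, 1)) {
        branch_angle <- angle + sgn * (stats::runif(1, 0.35, 0.8))
        canvas <- grow(canvas, r1, c1, branch_angle, len * 0.68, depth - 1L,
                       max(0.6, thickness * 0.7))
      }
    }
    canvas
  }
  grow(canvas, f, f / 2 + stats::runif(1, -f / 16, f / 16),
       stats::runif(1, -0.15, 0.15), f * 0.3, 3L, f / 28)
}

gen_snowflake_fine <- function(f) {
  canvas <- matrix(0, f, f)
  cc <- (f + 1) / 2
  n_rays <- 4L + stats::rpois(1, 2)
  base_angles <- stats::runif(n_rays, 0, pi / 6)
  lengths <- stats::runif(n_rays, 0.35, 0.95) * (f / 2 - 1)
  thickness <- f / 40
  for (i in seq_len(n_rays)) {
    for (k in 0:5) {
      for (sgn in c(-1, 1)) {             # 6-fold rotation + mirror
        a <- sgn * base_angles[i] + k * pi / 3
        canvas <- draw_segment(canvas, cc, cc,
                               cc - lengths[i] * cos(a),
                               cc + lengths[i] * sin(a), thickness)
      }
    }
  }
  canvas
}

gen_molecule_fine <- function(f) {
  canvas <- matrix(0, f, f)
  n_atoms <- sample(3:6, 1)
  centers <- matrix(NA_real_, 0, 3)        # row, col, radius
  tries <- 0L
  while (nrow(centers) < n_atoms && tries < 200L) {
    tries <- tries + 1L
    radius <- stats::runif(1, f / 12, f / 7)
    row <- stats::runif(1, radius + 1, f - radius)
    col <- stats::runif(1, radius + 1, f - radius)
    ok <- TRUE
    if (nrow(centers) > 0L) {
      d <- sqrt((centers[, 1] - row)^2 + (centers[, 2] - col)^2)
      ok <- all(d > centers[, 3] + radius + f / 40)   # keep disks disjoint
    }
    if (ok) centers <- rbind(centers, c(row, col, radius))
  }
  for (i in seq_len(nrow(centers))) {
    canvas <- draw_disk(canvas, centers[i, 1], centers[i, 2], centers[i, 3])
  }
  canvas
}

# Modified Shepp-Logan ellipse table: intensity, semi-axes a, b,
# center x0, y0, rotation phi (degrees), on the [-1, 1]^2 square.
shepp_logan_ellipses <- function() {
  matrix(c(
     1.0, 0.6900, 0.9200,  0.00,  0.0000,   0,
    -0.8, 0.6624, 0.8740,  0.00, -0.0184,   0,
    -0.2, 0.1100, 0.3100,  0.22,  0.0000, -18,
    -0.2, 0.1600, 0.4100, -0.22,  0.0000,  18,
     0.1, 0.2100, 0.2500,  0.00,  0.3500,   0,
     0.1, 0.0460, 0.0460,  0.00,  0.1000,   0,
     0.1, 0.0460, 0.0460,  0.00, -0.1000,   0,
     0.1, 0.0460, 0.0230, -0.08, -0.6050,   0,
     0.1, 0.0230, 0.0230,  0.00, -0.6060,   0,
     0.1, 0.0230, 0.0460,  0.06, -0.6050,   0
  ), ncol = 6, byrow = TRUE)
}

gen_shepp_logan <- function(size, levels) {
  e <- shepp_logan_ellipses()
  coord <- (seq_len(size) - (size + 1) / 2) / (size / 2)
  x <- matrix(coord, size, size, byrow = TRUE)       # columns left to right
  y <- matrix(rev(coord), size, size)                # rows top to bottom
  img <- matrix(0, size, size)
  for (i in seq_len(nrow(e))) {
    phi <- e[i, 6] * pi / 180
    xr <- cos(phi) * (x - e[i, 3]) + sin(phi) * (y - e[i, 4])
    yr <- -sin(phi) * (x - e[i, 3]) + cos(phi) * (y - e[i, 4])
    inside <- (xr / e[i, 2])^2 + (yr / e[i, 5])^2 <= 1
    img[inside] <- img[inside] + e[i, 1]
  }
  img <- pmin(pmax(img, 0), 1)
  floor(img * (levels - 1) + 0.5)
}

gen_digit <- function(size, levels) {
  # a couple of soft strokes, as in small handwritten-digit rasters
  n_strokes <- sample(2:3, 1)
  field <- matrix(0, size, size)
  grid_r <- matrix(seq_len(size), size, size)
  grid_c <- matrix(seq_len(size), size, size, byrow = TRUE)
  sigma <- size / 7
  for (s in seq_len(n_strokes)) {
    p0 <- stats::runif(2, size * 0.2, size * 0.8)
    p1 <- stats::runif(2, size * 0.2, size * 0.8)
    ctrl <- stats::runif(2, size * 0.1, size * 0.9)
    t <- seq(0, 1, length.out = 12)
    for (ti in t) {     # quadratic Bezier through a random control point
      pr <- (1 - ti)^2 * p0[1] + 2 * (1 - ti) * ti * ctrl[1] + ti^2 * p1[1]
      pc <- (1 - ti)^2 * p0[2] + 2 * (1 - ti) * ti * ctrl[2] + ti^2 * p1[2]
      field <- field + exp(-((grid_r - pr)^2 + (grid_c - pc)^2) / (2 * sigma^2))
    }
  }
  field <- field / max(field)
  floor(field * (levels - 1) + 0.5)
}

#' Downsample an image by local block means
#'
#' Each output pixel is the arithmetic mean of its `factor x factor` block,
#' so the global mean is preserved exactly. The result is continuous;
#' re-discretize explicitly with [discretize()] when an integer image is
#' needed.
#'
#' @param image an [image_grid] or square matrix.
#' @param factor integer block size; must divide the image size.
#' @return an [image_grid] of side `size / factor` (continuous values).
#' @export
downsample_local_mean <- function(image, factor) {
  assert_square_image(image)
  factor <- as.integer(factor)
  n <- img_size(image)
  if (factor < 1L || n %% factor != 0L) {
    stop("factor must divide the image size", call. = FALSE)
  }
  image_grid(block_mean(unclass_image(image), factor), img_levels(image))
}

block_mean <- function(values, factor) {
  n <- nrow(values)
  m <- n %/% factor
  agg <- matrix(0, m, n)
  for (i in seq_len(m)) agg[i, ((i - 1L) * factor + 1L):(i * factor)] <- 1
  (agg %*% values %*% t(agg)) / factor^2
}

#' Upsample an image by pixel replication
#'
#' Nearest-neighbour upscaling: every pixel becomes a `factor x factor`
#' block of its value. Used to place a coarse phantom on a finer simulation
#' grid when avoiding the inverse crime.
#'
#' @inheritParams downsample_local_mean
#' @return an [image_grid] of side `size * factor`.
#' @export
upsample_nearest <- function(image, factor) {
  assert_square_image(image)
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1", call. = FALSE)
  image_grid(kronecker(unclass_image(image), matrix(1, factor, factor)),
             img_levels(image))
}

#' Read and write phantoms as CSV or PNG
#'
#' CSV is the lossless interchange format (exact numeric values, one image
#' row per line, no header). PNG stores gray levels scaled to 8-bit, which
#' quantizes: round-trips are exact only when `levels <= 256` and the image
#' is integer-valued.
#'
#' @param image an [image_grid].
#' @param path file path.
#' @param levels gray-level count to attach on read.
#' @name phantom_io
#' @export
write_image_csv <- function(image, path) {
  utils::write.table(unclass_image(image), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname phantom_io
#' @export
read_image_csv <- function(path, levels = 2L) {
  values <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(values) <- NULL
  image_grid(values, levels)
}

#' @rdname phantom_io
#' @export
write_image_png <- function(image, path) {
  lv <- img_levels(image)
  png::writePNG(pmin(pmax(unclass_image(image) / (lv - 1), 0), 1), path)
  invisible(path)
}

#' @rdname phantom_io
#' @export
read_image_png <- function(path, levels = 2L) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
  image_grid(round(raw * (levels - 1)), levels)
}
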