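#' Discretize a continuous reconstruction
#'
#' Clips to `[0, levels - 1]` and rounds to the nearest integer level,
#' halves up. Continuous reconstructions (FBP, SART, pseudoinverse) pass
#' through this step before being compared with discrete ground truth.
#'
#' @param image continuous [image_grid] or matrix.
#' @param levels number of allowed gray levels.
#' @return an [image_grid] with integer values.
#' @export
discretize <- function(image, levels = img_levels(image)) {
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2", call. = FALSE)
  v <- pmin(pmax(unclass_image(image), 0), levels - 1)
  image_grid(floor(v + 0.5), levels)
}

# Ram-Lak (ramp) filter response, built from the band-limited real-space
# kernel rather than a bare |f| ramp so the DC component is handled
# correctly on short detectors.
ramp_filter <- function(size) {
  n <- c(seq(1, size / 2, by = 2), seq(size / 2 - 1, 1, by = -2))
  f <- numeric(size)
  f[1] <- 0.25
  f[seq(2, size, by = 2)] <- -1 / (pi * n)^2
  2 * Re(stats::fft(f))
}

#' Filtered backprojection reconstruction
#'
#' Each view is convolved with the ramp (Ram-Lak) filter in the frequency
#' domain (zero-padded to a power of two) and backprojected with bilinear
#' detector interpolation, using the same rotation-center and angle
#' conventions as [project()]. Matrix-free and linear in the sinogram.
#'
#' @param sino a [sinogram].
#' @return a continuous [image_grid] of side `n_bins`.
#' @export
reconstruct_fbp <- function(sino) {
  g <- sino$geometry
  if (g$n_views < 1L) stop("need at least one view", call. = FALSE)
  b <- g$n_bins
  pad <- max(64L, 2^ceiling(log2(2 * b)))
  filt <- ramp_filter(pad)

  filtered <- matrix(0, g$n_views, b)
  for (v in seq_len(g$n_views)) {
    row <- c(sino$values[v, ], numeric(pad - b))
    row_f <- Re(stats::fft(stats::fft(row) * filt, inverse = TRUE)) / pad
    filtered[v, ] <- row_f[seq_len(b)]
  }

  cc <- (b - 1) / 2
  coord <- (0:(b - 1)) - cc
  dxs <- matrix(coord, b, b, byrow = TRUE)   # x: column offset from center
  dys <- matrix(coord, b, b)                 # y: row offset from center
  recon <- matrix(0, b, b)
  for (v in seq_len(g$n_views)) {
    theta <- g$angles[v] * pi / 180
    # detector coordinate a pixel projects to at this view (0-based bin)
    t <- cos(theta) * dxs + sin(theta) * dys + cc
    t0 <- floor(t)
    frac <- t - t0
    val <- matrix(0, b, b)
    in0 <- t0 >= 0 & t0 <= b - 1
    in1 <- t0 + 1 >= 0 & t0 + 1 <= b - 1
    val[in0] <- (1 - frac[in0]) * filtered[v, t0[in0] + 1L]
    val[in1] <- val[in1] + frac[in1] * filtered[v, t0[in1] + 2L]
    recon <- recon + val
  }
  image_grid(recon * pi / (2 * g$n_views), 2L)
}

#' Simultaneous algebraic reconstruction (SART)
#'
#' Additive per-view updates `x <- x + lambda * C_v^-1 A_v' R_v^-1 (y_v -
#' A_v x)` with `R_v`, `C_v` the view block's row and column sums, sweeping
#' the views in angle order; one iteration is one full sweep. Rows or
#' columns with zero sum are skipped.
#'
#' @param sino a [sinogram].
#' @param M a `system_matrix` consistent with the sinogram's geometry.
#' @param iterations number of full sweeps (>= 1).
#' @param relaxation update step `lambda` in (0, 2); default 0.5.
#' @param x0 optional starting image vector (row-major); default zeros.
#' @return a continuous [image_grid].
#' @export
reconstruct_sart <- function(sino, M, iterations = 10L, relaxation = 0.5,
                             x0 = NULL) {
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  mv <- system_values(M)
  g <- sino$geometry
  n <- ncol(mv)
  x <- if (is.null(x0)) numeric(n) else as.numeric(x0)
  y <- vec_sinogram(sino)
  b <- g$n_bins
  blocks <- lapply(seq_len(g$n_views), function(v) {
    rows <- ((v - 1L) * b + 1L):(v * b)
    A <- mv[rows, , drop = FALSE]
    rs <- rowSums(A)
    cs <- colSums(A)
    list(A = A, yv = y[rows],
         rinv = ifelse(rs > 1e-12, 1 / rs, 0),
         cinv = ifelse(cs > 1e-12, 1 / cs, 0))
  })
  for (it in seq_len(iterations)) {
    for (blk in blocks) {
      resid <- (blk$yv - as.numeric(blk$A %*% x)) * blk$rinv
      x <- x + relaxation * blk$cinv * as.numeric(crossprod(blk$A, resid))
    }
  }
  image_grid(unvec_image(x, g$image_size), 2L)
}

#' Discrete algebraic reconstruction (DART)
#'
#' Seeds from SART, then alternates segmentation with boundary re-solving:
#' each DART iteration discretizes the current image, marks as free every
#' pixel with a 4-neighbor of a different level, fixes all other pixels at
#' their discrete value, subtracts the fixed pixels' forward projection
#' from the data, and runs SART on the free pixels only. The final image
#' is discretized. All steps are deterministic (no random free fraction,
#' no smoothing), so paired comparisons against plain discretized SART are
#' exactly reproducible.
#'
#' @inheritParams reconstruct_sart
#' @param levels number of gray levels for segmentation.
#' @param dart_iterations segmentation/re-solve cycles (0 reduces to
#'   discretized SART); default 2.
#' @param sart_iterations SART sweeps for the initial solve; default 10.
#' @param sub_iterations SART sweeps inside each DART cycle; default 1.
#' @return a discrete [image_grid].
#' @export
reconstruct_dart <- function(sino, M, levels = 2L, dart_iterations = 2L,
                             sart_iterations = 10L, sub_iterations = 1L,
                             relaxation = 0.5) {
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2", call. = FALSE)
  mv <- system_values(M)
  g <- sino$geometry
  size <- g$image_size
  x <- vec_image(reconstruct_sart(sino, M, iterations = sart_iterations,
                                  relaxation = relaxation))
  y <- vec_sinogram(sino)

  for (it in seq_len(max(0L, as.integer(dart_iterations)))) {
    disc <- discretize(unvec_image(x, size), levels)
    free <- boundary_pixels(unclass_image(disc))
    if (!any(free)) return(disc)
    fixed_vec <- vec_image(disc)
    fixed_vec[vec_image(free) == 1] <- 0       # keep only fixed pixels
    y_res <- y - as.numeric(mv %*% fixed_vec)
    free_idx <- which(vec_image(free) == 1)
    m_free <- mv[, free_idx, drop = FALSE]
    sino_res <- sinogram(matrix(y_res, g$n_views, g$n_bins, byrow = TRUE), g)
    sub <- sart_on_columns(sino_res, m_free, sub_iterations, relaxation,
                           x0 = x[free_idx])
    x <- vec_image(disc)
    x[free_idx] <- sub
  }
  discretize(unvec_image(x, size), levels)
}

# free pixels: any pixel whose 4-neighborhood contains a different level
boundary_pixels <- function(disc) {
  n <- nrow(disc)
  free <- matrix(FALSE, n, n)
  shift_differs <- function(dr, dc) {
    out <- matrix(FALSE, n, n)
    r_src <- max(1, 1 + dr):min(n, n + dr)
    c_src <- max(1, 1 + dc):min(n, n + dc)
    out[r_src - dr, c_src - dc] <-
      disc[r_src - dr, c_src - dc] != disc[r_src, c_src]
    out
  }
  free | shift_differs(1, 0) | shift_differs(-1, 0) |
    shift_differs(0, 1) | shift_differs(0, -1)
}

# SART restricted to a column subset of the system matrix
sart_on_columns <- function(sino, m_free, iterations, relaxation, x0) {
  g <- sino$geometry
  b <- g$n_bins
  y <- vec_sinogram(sino)
  x <- as.numeric(x0)
  for (it in seq_len(max(1L, as.integer(iterations)))) {
    for (v in seq_len(g$n_views)) {
      rows <- ((v - 1L) * b + 1L):(v * b)
      A <- m_free[rows, , drop = FALSE]
      rs <- rowSums(A)
      cs <- colSums(A)
      rinv <- ifelse(rs > 1e-12, 1 / rs, 0)
      cinv <- ifelse(cs > 1e-12, 1 / cs, 0)
      resid <- (y[rows] - as.numeric(A %*% x)) * rinv
      x <- x + relaxation * cinv * as.numeric(crossprod(A, resid))
    }
  }
  x
}

#' Truncated Moore-Penrose pseudoinverse reconstruction
#'
#' Computes the SVD of the system matrix, zeroes singular values below
#' `cutoff` times the largest (always suppressing numerically-zero values
#' below `1e-12` relative, since the tomographic system matrix is
#' singular), and applies the resulting pseudoinverse to the measurement
#' vector. Larger cutoffs trade resolution for noise robustness.
#'
#' @param M a `system_matrix` or plain matrix.
#' @param y measurement vector or [sinogram].
#' @param cutoff relative singular-value threshold (>= 0); 0.001 is a
#'   typical noise-robust choice.
#' @return a continuous [image_grid] (row-major reshape of `M^+ y`).
#' @export
reconstruct_pinv <- function(M, y, cutoff = 0) {
  if (cutoff < 0) stop("cutoff must be >= 0", call. = FALSE)
  mv <- system_values(M)
  y <- as_measurement_vector(y)
  sv <- svd(mv)
  thresh <- max(cutoff, 1e-12) * sv$d[1]
  dinv <- ifelse(sv$d >= thresh & sv$d > 0, 1 / sv$d, 0)
  x <- sv$v %*% (dinv * crossprod(sv$u, y))
  size <- as.integer(sqrt(length(x)))
  image_grid(unvec_image(as.numeric(x), size), 2L)
}
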