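#' Root-mean-square error between reconstruction and ground truth
#'
#' @param recon,truth images of equal shape.
#' @return `sqrt(mean((recon - truth)^2))` over all pixels.
#' @export
rmse <- function(recon, truth) {
  a <- unclass_image(recon); b <- unclass_image(truth)
  if (!all(dim(a) == dim(b))) stop("image shapes differ", call. = FALSE)
  sqrt(mean((a - b)^2))
}

#' Structural similarity index (SSIM)
#'
#' Mean over all fully-contained uniform `window x window` neighbourhoods
#' of the luminance/contrast/structure product
#' `((2 mu_a mu_b + c1)(2 cov_ab + c2)) / ((mu_a^2 + mu_b^2 + c1)(var_a +
#' var_b + c2))`, with stabilizers `c1 = (k1 L)^2`, `c2 = (k2 L)^2` on data
#' range `L = levels - 1` and sample (unbiased) variances, matching the
#' reference scikit-image implementation. The window defaults to 7x7,
#' dropping to 3x3 when the image is smaller than 7.
#'
#' @param recon,truth images of equal square shape.
#' @param levels gray-level count fixing the data range `L`.
#' @param window odd window size `<= N`; `NULL` picks 7 (or 3 for small
#'   images).
#' @param k1,k2 stabilizer constants.
#' @return SSIM in `[-1, 1]`; 1 for identical images.
#' @export
ssim <- function(recon, truth, levels = img_levels(truth), window = NULL,
                 k1 = 0.01, k2 = 0.03) {
  a <- unclass_image(recon); b <- unclass_image(truth)
  if (!all(dim(a) == dim(b))) stop("image shapes differ", call. = FALSE)
  n <- nrow(a)
  if (is.null(window)) window <- if (n >= 7L) 7L else 3L
  window <- as.integer(window)
  if (window %% 2L == 0L || window > n) {
    stop("window must be odd and no larger than the image", call. = FALSE)
  }
  L <- levels - 1
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  np <- window^2
  cov_norm <- np / (np - 1)     # sample covariance

  ux <- valid_mean(a, window);  uy <- valid_mean(b, window)
  uxx <- valid_mean(a * a, window)
  uyy <- valid_mean(b * b, window)
  uxy <- valid_mean(a * b, window)
  vx <- cov_norm * (uxx - ux^2)
  vy <- cov_norm * (uyy - uy^2)
  vxy <- cov_norm * (uxy - ux * uy)

  s <- ((2 * ux * uy + c1) * (2 * vxy + c2)) /
    ((ux^2 + uy^2 + c1) * (vx + vy + c2))
  mean(s)
}

# mean over all fully-contained w x w windows, via an integral image
valid_mean <- function(m, w) {
  n <- nrow(m)
  ii <- rbind(0, cbind(0, apply(apply(m, 2, cumsum), 1, cumsum)))
  # ii is now the transposed integral image; index carefully
  ii <- t(ii)
  k <- n - w + 1L
  out <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    out[i, j] <- ii[i + w, j + w] - ii[i, j + w] - ii[i + w, j] + ii[i, j]
  }
  out / w^2
}

#' Quantum-annealing-style reconstruction via quadratic binary optimization
#'
#' The package's core reconstruction route: builds the least-squares QUBO
#' (binary images) or the binary-encoded bounded-integer model (gray-level
#' images), solves it with the requested sampler, and returns the
#' lowest-energy sample as the image together with the sample set and the
#' pixel-wise uncertainty map.
#'
#' @param M a `system_matrix`.
#' @param y measurement vector or [sinogram].
#' @param levels gray levels of the sought image (2 = binary).
#' @param sampler `"sa"`, `"exact"`, or `"qpu-stub"`.
#' @param reads,sweeps,seed simulated-annealing parameters (ignored by the
#'   exact solver).
#' @param bits bits per pixel for integer problems; default
#'   `ceiling(log2(levels))`.
#' @return list with `image` ([image_grid]), `energy` (squared residual of
#'   the best sample), `samples` (`sample_set`), `uncertainty`
#'   ([image_grid]), `encoding` (`binary_encoding` or NULL).
#' @export
reconstruct_qa <- function(M, y, levels = 2L, sampler = "sa",
                           reads = 50L, sweeps = 1000L, seed = 1L,
                           bits = NULL) {
  g <- M$geometry
  size <- g$image_size
  if (levels == 2L) {
    model <- build_binary_qubo(M, y)
    encoding <- NULL
    qubo <- model
  } else {
    if (is.null(bits)) bits <- ceiling(log2(levels))
    enc <- encode_integer_as_binary(
      build_integer_model(M, y, upper_bound = levels - 1L), bits)
    qubo <- enc$qubo
    encoding <- enc$encoding
  }
  samples <- switch(sampler,
    exact = solve_exact(qubo),
    sa = solve_simulated_annealing(qubo, reads = reads, sweeps = sweeps,
                                   seed = seed),
    `qpu-stub` = solve_qpu_stub(qubo),
    stop("unknown sampler", call. = FALSE))
  img <- best_sample(samples, encoding, size)
  img <- image_grid(pmin(unclass_image(img), levels - 1), levels)
  list(image = img,
       energy = samples$energies[1],
       samples = samples,
       uncertainty = uncertainty_map(samples, encoding, size),
       encoding = encoding)
}

#' Run a named benchmark experiment
#'
#' Executes the full pipeline (phantom, sinogram with optional noise or
#' rebinning, all four reconstruction methods, metrics) and returns a tidy
#' results table. The presets mirror the package's standard study designs:
#'
#' * `size_sweep`: binary phantoms at sizes 4-32, fully determined (V = N),
#'   noiseless.
#' * `integer_sweep`: quantized Shepp-Logan at 4-bit gray levels.
#' * `noise`: digit-like 8x8 integer images with per-view additive
#'   signal-dependent noise.
#' * `few_view`: 32x32 binary phantoms from 2, 4, and 32 views.
#' * `inverse_crime`: acquisition simulated on a 4x finer grid and the
#'   sinogram rebinned before reconstruction, with a truncated
#'   pseudoinverse (cutoff 0.001).
#'
#' Rows that cannot run (e.g. the exact solver above its variable cap) are
#' kept with `status` recording the reason.
#'
#' @param experiment preset name.
#' @param sizes image sizes (preset default if NULL).
#' @param kinds phantom kinds (preset default if NULL).
#' @param seeds integer seeds; one pipeline run per (phantom, size, views,
#'   seed).
#' @param views view counts (default fully determined V = N).
#' @param methods reconstruction methods to run.
#' @param sampler QA sampler backend.
#' @param reads,sweeps simulated-annealing effort per QA solve.
#' @param cutoff pseudoinverse truncation (preset default if NULL).
#' @param noise add per-view noise to the acquisition.
#' @param levels gray levels (preset default if NULL).
#' @param dart_iterations DART segmentation cycles.
#' @param verbose print per-row progress to stderr.
#' @return data.frame with one row per (phantom, size, views, seed,
#'   method): `rmse`, `ssim`, `energy` (QA only), `runtime`, `status`.
#' @export
run_experiment <- function(experiment = c("size_sweep", "integer_sweep",
                                          "noise", "few_view",
                                          "inverse_crime"),
                           sizes = NULL, kinds = NULL, seeds = 1:2,
                           views = NULL,
                           methods = c("fbp", "dart", "pinv", "qa"),
                           sampler = "sa", reads = 20L, sweeps = 500L,
                           cutoff = NULL, noise = NULL, levels = NULL,
                           dart_iterations = 2L, verbose = FALSE) {
  experiment <- match.arg(experiment)
  preset <- switch(experiment,
    size_sweep = list(sizes = c(4L, 8L, 16L, 32L),
                      kinds = c("foam", "tree", "snowflake", "molecule"),
                      levels = 2L, cutoff = 0, noise = FALSE),
    integer_sweep = list(sizes = c(4L, 8L),
                         kinds = "shepp_logan",
                         levels = 16L, cutoff = 0, noise = FALSE),
    noise = list(sizes = 8L, kinds = "digit",
                 levels = 17L, cutoff = 0.001, noise = TRUE),
    few_view = list(sizes = 32L,
                    kinds = c("foam", "tree", "snowflake", "molecule"),
                    levels = 2L, cutoff = 0, noise = FALSE,
                    views = c(2L, 4L, 32L)),
    inverse_crime = list(sizes = 32L,
                         kinds = c("foam", "tree", "snowflake", "molecule"),
                         levels = 2L, cutoff = 0.001, noise = FALSE))
  if (is.null(sizes)) sizes <- preset$sizes
  if (is.null(kinds)) kinds <- preset$kinds
  if (is.null(levels)) levels <- preset$levels
  if (is.null(cutoff)) cutoff <- preset$cutoff
  if (is.null(noise)) noise <- preset$noise

  rows <- list()
  for (size in sizes) {
    view_list <- if (!is.null(views)) views
                 else if (!is.null(preset$views)) preset$views
                 else size
    for (n_views in view_list) {
      geom <- tomo_geometry(size, n_views)
      M <- build_system_matrix(geom)
      for (kind in kinds) {
        for (seed in seeds) {
          truth <- make_phantom(kind, size, levels, seed)
          sino <- acquire_sinogram(truth, geom, experiment, noise, seed)
          for (method in methods) {
            if (verbose) {
              message(sprintf("[%s] %s N=%d V=%d seed=%d %s",
                              experiment, kind, size, n_views, seed, method))
            }
            rows[[length(rows) + 1L]] <- run_one_method(
              method, truth, sino, M, levels, cutoff, sampler,
              reads, sweeps, seed, dart_iterations,
              kind, size, n_views, experiment)
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

# acquisition step: plain projection, noisy projection, or fine-grid
# simulation with rebinning (inverse-crime avoidance)
acquire_sinogram <- function(truth, geom, experiment, noise, seed) {
  if (experiment == "inverse_crime") {
    fine <- upsample_nearest(truth, 4L)
    fine_geom <- tomo_geometry(img_size(fine), geom$n_views,
                               n_bins = img_size(fine))
    rebin_sinogram(project(fine, fine_geom), 4L)
  } else if (isTRUE(noise)) {
    project_with_noise(truth, geom, seed = seed + 10000L)
  } else {
    project(truth, geom)
  }
}

run_one_method <- function(method, truth, sino, M, levels, cutoff, sampler,
                           reads, sweeps, seed, dart_iterations,
                           kind, size, n_views, experiment) {
  t0 <- proc.time()[["elapsed"]]
  row <- data.frame(experiment = experiment, phantom = kind, size = size,
                    views = n_views, levels = levels, seed = seed,
                    method = method, rmse = NA_real_, ssim = NA_real_,
                    energy = NA_real_, runtime = NA_real_,
                    status = "ok", stringsAsFactors = FALSE)
  recon <- tryCatch({
    switch(method,
      fbp = discretize(reconstruct_fbp(sino), levels),
      dart = reconstruct_dart(sino, M, levels,
                              dart_iterations = dart_iterations),
      pinv = discretize(reconstruct_pinv(M, sino, cutoff), levels),
      qa = {
        qa <- reconstruct_qa(M, sino, levels, sampler = sampler,
                             reads = reads, sweeps = sweeps,
                             seed = seed + 20000L)
        row$energy <- qa$energy
        qa$image
      },
      stop("unknown method: ", method))
  }, error = function(e) {
    row$status <<- conditionMessage(e)
    NULL
  })
  if (!is.null(recon)) {
    row$rmse <- rmse(recon, truth)
    row$ssim <- ssim(recon, truth, levels = levels)
  }
  row$runtime <- proc.time()[["elapsed"]] - t0
  row
}

#' Write an experiment result table with its configuration sidecar
#'
#' @param result data.frame from [run_experiment()].
#' @param path CSV output path; a JSON sidecar `<path>.json` records the
#'   configuration columns.
#' @export
write_experiment_csv <- function(result, path) {
  utils::write.csv(result, path, row.names = FALSE)
  cfg <- unique(result[, c("experiment", "size", "views", "levels")])
  jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
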