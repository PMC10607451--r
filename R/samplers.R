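#' Sample sets
#'
#' Solver output container: binary assignments with their energies and
#' occurrence counts, sorted ascending by energy with lexicographic
#' tie-breaking on the bit tuple (0 before 1, first variable most
#' significant). Every stored energy is recomputed from the model, so it
#' can be audited against [model_energy()].
#'
#' @param assignments integer 0/1 matrix, one row per distinct assignment.
#' @param energies numeric vector of energies per row.
#' @param num_occurrences integer counts per row.
#' @param metadata list of sampler details (name, reads, seed, ...).
#' @return a `sample_set`.
#' @export
sample_set <- function(assignments, energies, num_occurrences, metadata = list()) {
  assignments <- as.matrix(assignments)
  if (nrow(assignments) == 0L) stop("empty sample set", call. = FALSE)
  ord <- do.call(order, c(list(energies),
                          lapply(seq_len(ncol(assignments)),
                                 function(j) assignments[, j])))
  structure(list(assignments = assignments[ord, , drop = FALSE],
                 energies = energies[ord],
                 num_occurrences = as.integer(num_occurrences)[ord],
                 metadata = metadata),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set %d distinct states over %d variables (%s), best energy %.6g>\n",
              nrow(x$assignments), ncol(x$assignments),
              if (is.null(x$metadata$sampler)) "?" else x$metadata$sampler,
              x$energies[1]))
  invisible(x)
}

#' Solve a QUBO exactly by full enumeration
#'
#' Enumerates all `2^n` binary assignments (chunked to bound memory) and
#' returns every global minimizer found plus up to 100 next-best states, in
#' deterministic (energy, then lexicographic) order. This is the classical
#' oracle used to audit the stochastic samplers; it refuses models above
#' `max_vars` variables.
#'
#' @param model a `qubo_model`.
#' @param max_vars refusal threshold (default 22).
#' @return a `sample_set` with `num_occurrences = 1` per state.
#' @export
solve_exact <- function(model, max_vars = 22L) {
  n <- model$n_vars
  if (n > max_vars) {
    stop(sprintf(paste0("model has %d variables; exact enumeration is capped ",
                        "at %d. Use solve_simulated_annealing() instead."),
                 n, max_vars), call. = FALSE)
  }
  total <- 2^n
  chunk <- 2^min(n, 16L)
  keep_cap <- 512L
  pow <- 2^((n - 1L):0)          # first variable is the most significant bit

  kept_X <- NULL; kept_E <- numeric(0); kept_k <- numeric(0)
  k0 <- 0
  while (k0 < total) {
    ks <- k0 + seq_len(min(chunk, total - k0)) - 1
    X <- (outer(ks, pow, `%/%`)) %% 2
    E <- qubo_energies(model, X)
    sel <- order(E)[seq_len(min(length(E), keep_cap))]
    kept_X <- rbind(kept_X, X[sel, , drop = FALSE])
    kept_E <- c(kept_E, E[sel])
    kept_k <- c(kept_k, ks[sel])
    if (nrow(kept_X) > keep_cap) {
      ord <- order(kept_E, kept_k)[seq_len(keep_cap)]
      kept_X <- kept_X[ord, , drop = FALSE]
      kept_E <- kept_E[ord]
      kept_k <- kept_k[ord]
    }
    k0 <- k0 + chunk
  }
  ord <- order(kept_E, kept_k)
  kept_X <- kept_X[ord, , drop = FALSE]
  kept_E <- kept_E[ord]
  n_min <- sum(kept_E == kept_E[1])
  n_keep <- min(nrow(kept_X), n_min + 100L)
  sample_set(kept_X[seq_len(n_keep), , drop = FALSE],
             kept_E[seq_len(n_keep)],
             rep(1L, n_keep),
             metadata = list(sampler = "exact", n_enumerated = total))
}

#' Solve a QUBO by classical simulated annealing
#'
#' `reads` independent single-spin-flip Metropolis runs, each over a
#' geometric inverse-temperature ladder from `1 / dE_max` to
#' `1000 / dE_max` (with `dE_max` the largest possible single-flip energy
#' change) followed by zero-temperature sweeps until no flip improves.
#' Identical assignments are aggregated with occurrence counts; energies
#' are re-evaluated against the model in R. Deterministic per `seed`,
#' independent of R's global RNG state. This sampler is the package's
#' classical stand-in for quantum-annealing hardware: it is audited by
#' energy, the same criterion the hardware is scored on.
#'
#' @param model a `qubo_model`.
#' @param reads number of independent annealing repetitions.
#' @param sweeps Metropolis sweeps per read.
#' @param seed integer seed.
#' @param beta_range optional length-2 numeric overriding the inverse
#'   temperature schedule endpoints.
#' @param time_limit accepted and recorded for interface compatibility with
#'   remote solvers; it does not alter the schedule.
#' @return a `sample_set` whose occurrence counts sum to `reads`.
#' @export
solve_simulated_annealing <- function(model, reads = 50L, sweeps = 1000L,
                                      seed = 1L, beta_range = NULL,
                                      time_limit = NULL) {
  reads <- as.integer(reads); sweeps <- as.integer(sweeps)
  if (reads < 1L || sweeps < 1L) stop("reads and sweeps must be >= 1", call. = FALSE)
  n <- model$n_vars
  cp <- model$couplers
  if (is.null(beta_range)) {
    abs_w <- numeric(n)
    if (nrow(cp) > 0L) {
      for (k in seq_len(nrow(cp))) {
        abs_w[cp[k, "i"]] <- abs_w[cp[k, "i"]] + abs(cp[k, "value"])
        abs_w[cp[k, "j"]] <- abs_w[cp[k, "j"]] + abs(cp[k, "value"])
      }
    }
    de_max <- max(abs(model$linear) + abs_w, 1e-12)
    beta_range <- c(1 / de_max, 1000 / de_max)
  }
  res <- .sa_sample_cpp(model$linear,
                        as.integer(cp[, "i"]), as.integer(cp[, "j"]),
                        as.numeric(cp[, "value"]),
                        reads, sweeps, beta_range[1], beta_range[2],
                        as.double(as.integer(seed)))
  states <- res$states
  keys <- apply(states, 1L, paste, collapse = "")
  first <- !duplicated(keys)
  occ <- as.integer(table(factor(keys, levels = keys[first])))
  uniq <- states[first, , drop = FALSE]
  energies <- qubo_energies(model, uniq)
  sample_set(uniq, energies, occ,
             metadata = list(sampler = "sa", reads = reads, sweeps = sweeps,
                             seed = as.integer(seed),
                             beta_range = beta_range,
                             time_limit = time_limit))
}

#' Dispatch a QUBO to a named sampler backend
#'
#' @param model a `qubo_model`.
#' @param sampler `"sa"` (simulated annealing), `"exact"` (enumeration), or
#'   `"qpu-stub"` (remote-hardware interface stub, disabled by default).
#' @param ... passed to the backend.
#' @return a `sample_set`.
#' @export
solve_qubo <- function(model, sampler = c("sa", "exact", "qpu-stub"), ...) {
  sampler <- match.arg(sampler)
  switch(sampler,
         sa = solve_simulated_annealing(model, ...),
         exact = solve_exact(model, ...),
         `qpu-stub` = solve_qpu_stub(model, ...))
}

#' Remote quantum-annealer interface stub
#'
#' Placeholder for physical annealing hardware behind the same
#' `sample_set` contract. No network access is performed: a user-supplied
#' handler can be registered via `options(annealtomo.qpu_handler = fn)`
#' (receiving the model and `...`, returning a `sample_set`); without one,
#' the call fails with guidance. The model's [scale_chain_strength()] value
#' is passed along to the handler.
#'
#' @inheritParams solve_qubo
#' @export
solve_qpu_stub <- function(model, ...) {
  handler <- getOption("annealtomo.qpu_handler")
  if (is.null(handler)) {
    stop(paste0("no QPU backend configured; the qpu-stub sampler requires ",
                "options(annealtomo.qpu_handler = <function>). Use the 'sa' ",
                "or 'exact' sampler for local solving."), call. = FALSE)
  }
  handler(model, chain_strength = scale_chain_strength(model), ...)
}

#' Chain-strength scale for hardware embedding
#'
#' Largest absolute bias or coupler magnitude in the model, the usual
#' relative-chain-strength convention for minor-embedded annealers.
#' Consumed only by the QPU stub; inert for the classical backends.
#'
#' @param model a `qubo_model`.
#' @return non-negative scalar (0 for an empty model).
#' @export
scale_chain_strength <- function(model) {
  vals <- c(abs(model$linear),
            if (nrow(model$couplers) > 0L) abs(model$couplers[, "value"]))
  if (length(vals) == 0L) 0 else max(vals)
}

#' Extract the best (lowest-energy) sample as an image
#'
#' Takes the lowest-energy assignment (ties resolved lexicographically on
#' the bit tuple), decodes it through the binary encoding if one is given,
#' and reshapes row-major into a square image.
#'
#' @param samples a `sample_set`.
#' @param encoding optional `binary_encoding` for integer problems.
#' @param image_size side length of the output image.
#' @return an [image_grid].
#' @export
best_sample <- function(samples, encoding = NULL, image_size) {
  if (!inherits(samples, "sample_set") || nrow(samples$assignments) == 0L) {
    stop("non-empty sample_set required", call. = FALSE)
  }
  values <- decode_binary(samples$assignments[1L, ], encoding)
  levels <- if (is.null(encoding)) 2L else as.integer(2^encoding$bits)
  image_grid(unvec_image(values, image_size), levels)
}

#' Pixel-wise uncertainty map of a sample set
#'
#' Population variance of the decoded pixel values across all returned
#' samples, weighted by occurrence counts and independent of the samples'
#' energies. An interpretability by-product of stochastic solving: pixels
#' the sampler keeps flipping are the uncertain ones.
#'
#' @inheritParams best_sample
#' @return an [image_grid] of per-pixel variances (continuous).
#' @export
uncertainty_map <- function(samples, encoding = NULL, image_size) {
  if (!inherits(samples, "sample_set") || nrow(samples$assignments) == 0L) {
    stop("non-empty sample_set required", call. = FALSE)
  }
  decoded <- t(apply(samples$assignments, 1L, decode_binary, encoding = encoding))
  if (nrow(samples$assignments) == 1L) decoded <- matrix(decoded, nrow = 1L)
  w <- samples$num_occurrences
  mu <- colSums(decoded * w) / sum(w)
  second <- colSums(decoded^2 * w) / sum(w)
  image_grid(unvec_image(second - mu^2, image_size), 2L)
}

#' Serialize a sample set to JSON
#'
#' Assignments are stored as bit strings together with energies,
#' occurrence counts and sampler metadata.
#'
#' @param samples a `sample_set`.
#' @param path file path.
#' @name sample_set_json
#' @export
write_sample_set_json <- function(samples, path) {
  jsonlite::write_json(
    list(assignments = apply(samples$assignments, 1L, paste, collapse = ""),
         energies = samples$energies,
         num_occurrences = samples$num_occurrences,
         metadata = samples$metadata),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname sample_set_json
#' @export
read_sample_set_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  X <- do.call(rbind, lapply(strsplit(obj$assignments, ""), as.integer))
  sample_set(X, obj$energies, obj$num_occurrences, as.list(obj$metadata))
}
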