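# Small randomized least-squares problems and brute-force oracles shared
# across test files.

# random (M, y) pair and the QUBO built from it
rand_lsq_qubo <- function(n_vars, n_meas = n_vars + 2L, seed = 1L) {
  withr::with_seed(seed, {
    M <- matrix(stats::rnorm(n_meas * n_vars), n_meas, n_vars)
    y <- stats::rnorm(n_meas)
    list(M = M, y = y, model = build_binary_qubo(M, y))
  })
}

# all binary assignments of n variables, lexicographic order (first
# variable most significant), one row each
all_assignments <- function(n) {
  ks <- 0:(2^n - 1)
  (outer(ks, 2^((n - 1):0), `%/%`)) %% 2
}

# independent residual oracle: ||M x - y||^2 for each assignment row
residual_energies <- function(M, y, X) {
  colSums((M %*% t(X) - y)^2)
}

# batch QUBO energies from the model's stored coefficients (the documented
# energy contract), vectorized for full enumerations
batch_model_energies <- function(model, X) {
  q <- matrix(0, model$n_vars, model$n_vars)
  diag(q) <- model$linear
  if (nrow(model$couplers) > 0L) {
    for (k in seq_len(nrow(model$couplers))) {
      i <- model$couplers[k, "i"]; j <- model$couplers[k, "j"]
      v <- model$couplers[k, "value"]
      q[i, j] <- q[i, j] + v / 2
      q[j, i] <- q[j, i] + v / 2
    }
  }
  rowSums((X %*% q) * X) + model$offset
}

# all integer assignments of n variables over 0..cap, one row each
all_integer_assignments <- function(n, cap) {
  grids <- rep(list(0:cap), n)
  as.matrix(rev(expand.grid(rev(grids))))
}

tiny_recon_problem <- function(kind = "molecule", size = 3L, seed = 1L) {
  truth <- make_phantom(kind, size, 2L, seed)
  geom <- tomo_geometry(size, size)
  M <- build_system_matrix(geom)
  sino <- project(truth, geom)
  list(truth = truth, geom = geom, M = M, sino = sino,
       model = build_binary_qubo(M, sino))
}
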