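test_that("exact solver enumerates, preserves ties, and orders deterministically", {
  # two tied zero-energy minimizers; lexicographic order puts (0,1) first
  q <- build_binary_qubo(matrix(c(1, 1), 1, 2), 1)
  ss <- solve_exact(q)
  expect_equal(ss$energies[1], 0)
  expect_equal(ss$energies[2], 0)
  expect_equal(ss$assignments[1, ], c(0, 1), ignore_attr = TRUE)
  expect_equal(ss$assignments[2, ], c(1, 0), ignore_attr = TRUE)

  # 3x3 phantom, fully determined noiseless: unique minimizer is the truth
  prob <- tiny_recon_problem("molecule", 3L, seed = 1L)
  ss3 <- solve_exact(prob$model)
  expect_lt(abs(ss3$energies[1]), 1e-9)
  expect_gt(ss3$energies[2], 1e-6)
  expect_equal(unclass(best_sample(ss3, NULL, 3L)), unclass(prob$truth),
               ignore_attr = TRUE)

  one <- structure(list(n_vars = 1L, linear = -1,
                        couplers = matrix(numeric(0), ncol = 3,
                                          dimnames = list(NULL, c("i", "j", "value"))),
                        offset = 2), class = "qubo_model")
  s1 <- solve_exact(one)
  expect_equal(s1$assignments[1, ], 1, ignore_attr = TRUE)
  expect_equal(s1$energies[1], 1)   # -1 + offset 2

  big <- rand_lsq_qubo(n_vars = 12L, seed = 1L)$model
  big$n_vars <- 30L
  expect_error(solve_exact(big), "solve_simulated_annealing")
})

test_that("simulated annealing is seeded, audited, and never beats the oracle", {
  prob <- rand_lsq_qubo(n_vars = 10L, seed = 42L)
  a <- solve_simulated_annealing(prob$model, reads = 20L, sweeps = 200L, seed = 3L)
  b <- solve_simulated_annealing(prob$model, reads = 20L, sweeps = 200L, seed = 3L)
  expect_identical(a$assignments, b$assignments)
  expect_identical(a$energies, b$energies)
  expect_identical(a$num_occurrences, b$num_occurrences)
  expect_equal(sum(a$num_occurrences), 20L)

  # stored energies re-verify against the model
  audit <- apply(a$assignments, 1L, function(x) model_energy(prob$model, x))
  expect_lt(max(abs(audit - a$energies)), 1e-9)

  # oracle bound across random models
  for (seed in 1:10) {
    p <- rand_lsq_qubo(n_vars = sample(4:12, 1), seed = seed + 100L)
    exact_min <- solve_exact(p$model)$energies[1]
    sa_min <- solve_simulated_annealing(p$model, reads = 10L, sweeps = 200L,
                                        seed = seed)$energies[1]
    expect_gte(sa_min, exact_min - 1e-9)
  }

  single <- solve_simulated_annealing(prob$model, reads = 1L, sweeps = 50L,
                                      seed = 1L)
  expect_equal(nrow(single$assignments), 1L)
  expect_equal(single$num_occurrences, 1L)
})

test_that("annealing recovers an 8x8 binary phantom from complete data", {
  prob <- tiny_recon_problem("foam", 8L, seed = 2L)
  hits <- 0L
  for (seed in 1:10) {
    ss <- solve_simulated_annealing(prob$model, reads = 10L, sweeps = 300L,
                                    seed = seed)
    if (abs(ss$energies[1]) < 1e-6 &&
        all(best_sample(ss, NULL, 8L) == prob$truth)) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 8L)
})

test_that("best_sample reshapes row-major and breaks ties lexicographically", {
  single <- sample_set(matrix(c(1, 0, 1, 1), 1), 0.5, 1L)
  img <- best_sample(single, NULL, 2L)
  expect_equal(unclass(img), rbind(c(1, 0), c(1, 1)), ignore_attr = TRUE)

  # tied minimizers: the lexicographically smaller bit tuple (0,1) wins
  tied <- sample_set(rbind(c(1, 0), c(0, 1)), c(0, 0), c(1L, 1L))
  expect_equal(tied$assignments[1, ], c(0, 1), ignore_attr = TRUE)
  expect_error(best_sample(list(), NULL, 2L), "sample_set")
})

test_that("decoded best samples map bit weights to pixel values", {
  enc <- structure(list(n_pixels = 2L, bits = 2L, weights = c(1, 2)),
                   class = "binary_encoding")
  ss <- sample_set(matrix(c(1, 0, 1, 1), 1), 0, 1L)
  expect_equal(decode_binary(ss$assignments[1, ], enc), c(1, 3))
})

test_that("uncertainty map is the occurrence-weighted population variance", {
  same <- sample_set(rbind(c(1, 0, 1, 1), c(1, 0, 1, 1)), c(0, 1), c(3L, 2L))
  expect_equal(unclass(uncertainty_map(same, NULL, 2L)), matrix(0, 2, 2),
               ignore_attr = TRUE)

  two <- sample_set(rbind(c(1, 0, 0, 0), c(0, 0, 0, 0)), c(0, 1), c(1L, 1L))
  um <- uncertainty_map(two, NULL, 2L)
  expect_equal(um[1, 1], 0.25)
  expect_equal(sum(um), 0.25)

  weighted <- sample_set(rbind(c(0, 0, 0, 0), c(1, 0, 0, 0)), c(0, 1), c(3L, 1L))
  expect_equal(uncertainty_map(weighted, NULL, 2L)[1, 1], 3 / 16)
})

test_that("chain strength is the largest absolute coefficient", {
  zero <- structure(list(n_vars = 2L, linear = c(0, 0),
                         couplers = matrix(numeric(0), ncol = 3,
                                           dimnames = list(NULL, c("i", "j", "value"))),
                         offset = 0), class = "qubo_model")
  expect_equal(scale_chain_strength(zero), 0)

  q <- build_binary_qubo(matrix(c(1, 1), 1, 2), 1)
  expect_equal(scale_chain_strength(q), 2)

  q_scaled <- q
  q_scaled$linear <- -3 * q$linear
  q_scaled$couplers[, "value"] <- -3 * q$couplers[, "value"]
  expect_equal(scale_chain_strength(q_scaled), 3 * scale_chain_strength(q))
})

test_that("the QPU stub is inert unless a handler is registered", {
  q <- build_binary_qubo(diag(2), c(1, 0))
  expect_error(solve_qpu_stub(q), "qpu_handler")
  withr::local_options(annealtomo.qpu_handler = function(model, chain_strength, ...) {
    expect_equal(chain_strength, scale_chain_strength(model))
    solve_exact(model)
  })
  ss <- solve_qubo(q, sampler = "qpu-stub")
  expect_equal(ss$energies[1], 0)
})

test_that("integer problems routed through the encoding keep all contracts", {
  prob <- withr::with_seed(13, {
    m <- matrix(rnorm(24), 6, 4)
    x_true <- sample(0:3, 4, replace = TRUE)
    list(m = m, y = as.numeric(m %*% x_true), x_true = x_true)
  })
  enc <- encode_integer_as_binary(
    build_integer_model(prob$m, prob$y, upper_bound = 3L), 2L)
  exact <- solve_exact(enc$qubo)
  expect_lt(abs(exact$energies[1]), 1e-9)
  expect_equal(decode_binary(exact$assignments[1, ], enc$encoding), prob$x_true)
  sa <- solve_simulated_annealing(enc$qubo, reads = 20L, sweeps = 500L, seed = 2L)
  expect_gte(sa$energies[1], exact$energies[1] - 1e-9)
})

test_that("sample sets survive a JSON round-trip", {
  prob <- rand_lsq_qubo(n_vars = 6L, seed = 8L)
  ss <- solve_simulated_annealing(prob$model, reads = 5L, sweeps = 100L, seed = 1L)
  path <- withr::local_tempfile(fileext = ".json")
  write_sample_set_json(ss, path)
  got <- read_sample_set_json(path)
  expect_equal(got$assignments, ss$assignments, ignore_attr = TRUE)
  expect_equal(got$energies, ss$energies)
  expect_equal(got$num_occurrences, ss$num_occurrences)
})
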