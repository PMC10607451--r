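test_that("binary QUBO coefficients match the expanded residual", {
  # identity system: expanding ||x - (1,0)||^2 over all 4 assignments
  q <- build_binary_qubo(diag(2), c(1, 0))
  expect_equal(q$linear, c(-1, 1))
  expect_equal(nrow(q$couplers), 0L)
  expect_equal(q$offset, 1)
  expect_equal(model_energy(q, c(1, 0)), 0)

  # rank-one system with tied minimizers
  q2 <- build_binary_qubo(matrix(c(1, 1), 1, 2), 1)
  expect_equal(q2$linear, c(-1, -1))
  expect_equal(q2$couplers[, "value"], 2, ignore_attr = TRUE)
  expect_equal(q2$offset, 1)
  expect_equal(model_energy(q2, c(1, 0)), 0)
  expect_equal(model_energy(q2, c(0, 1)), 0)

  # zero measurements: non-negative biases, minimum at x = 0
  m <- withr::with_seed(1, matrix(rnorm(12), 4, 3))
  q3 <- build_binary_qubo(m, numeric(4))
  expect_equal(q3$linear, colSums(m^2))
  expect_equal(q3$offset, 0)
  expect_equal(model_energy(q3, c(0, 0, 0)), 0)
  expect_error(build_binary_qubo(m, numeric(3)), "dimension")
})

test_that("QUBO energy equals the squared residual for every assignment", {
  for (seed in 1:5) {
    prob <- rand_lsq_qubo(n_vars = 8L, seed = seed)
    X <- all_assignments(8L)
    want <- residual_energies(prob$M, prob$y, X)
    got <- apply(X, 1L, function(x) model_energy(prob$model, x))
    expect_lt(max(abs(got - want)), 1e-9)
  }
})

test_that("model_energy validates its domain and handles random triples", {
  for (seed in 1:20) {
    prob <- withr::with_seed(seed, {
      m <- matrix(rnorm(35), 7, 5)
      y <- rnorm(7)
      x <- rbinom(5, 1, 0.5)
      list(m = m, y = y, x = x)
    })
    q <- build_binary_qubo(prob$m, prob$y)
    expect_lt(abs(model_energy(q, prob$x) -
                    sum((prob$m %*% prob$x - prob$y)^2)), 1e-9)
  }
  q <- build_binary_qubo(diag(2), c(1, 0))
  expect_equal(model_energy(q, c(0, 0)), 1)   # ||y||^2 at x = 0
  expect_error(model_energy(q, c(2, 0)), "binary")
  expect_error(model_energy(q, c(1, 0, 1)), "length")
})

test_that("Ising conversion preserves energies over all assignments", {
  z <- build_binary_qubo(matrix(0, 1, 1), 0)
  iz <- qubo_to_ising(z)
  expect_equal(iz$h, 0)
  expect_equal(iz$offset, 0)

  # single variable, linear 1: states 0/1 have energies 0/1; spins -1/+1
  single <- structure(list(n_vars = 1L, linear = 1, couplers = matrix(
    numeric(0), ncol = 3, dimnames = list(NULL, c("i", "j", "value"))),
    offset = 0), class = "qubo_model")
  is1 <- qubo_to_ising(single)
  expect_equal(is1$h, 0.5)
  expect_equal(is1$offset, 0.5)
  expect_equal(model_energy(is1, -1), model_energy(single, 0))
  expect_equal(model_energy(is1, 1), model_energy(single, 1))

  for (seed in 1:3) {
    prob <- rand_lsq_qubo(n_vars = 6L, seed = seed + 30L)
    ising <- qubo_to_ising(prob$model)
    X <- all_assignments(6L)
    for (k in seq_len(nrow(X))) {
      x <- X[k, ]
      expect_lt(abs(model_energy(ising, 2 * x - 1) -
                      model_energy(prob$model, x)), 1e-12)
    }
  }
})

test_that("integer model matches the residual objective on its domain", {
  m1 <- build_integer_model(matrix(1), 3, upper_bound = 15L)
  objs <- sapply(0:15, function(v) model_energy(m1, v))
  expect_equal(which.min(objs) - 1L, 3L)
  expect_equal(min(objs), 0)

  m0 <- build_integer_model(matrix(1), 0, upper_bound = 15L)
  expect_equal(model_energy(m0, 0), 0)
  expect_true(all(sapply(1:15, function(v) model_energy(m0, v)) > 0))

  # bound 1 reduces to the binary QUBO argmin set on a 6-pixel problem
  prob <- withr::with_seed(77, {
    m <- matrix(rnorm(48), 8, 6)
    x_true <- rbinom(6, 1, 0.5)
    list(m = m, y = as.numeric(m %*% x_true))
  })
  mi <- build_integer_model(prob$m, prob$y, upper_bound = 1L)
  q <- build_binary_qubo(prob$m, prob$y)
  X <- all_assignments(6L)
  e_int <- apply(X, 1L, function(x) model_energy(mi, x))
  e_bin <- apply(X, 1L, function(x) model_energy(q, x))
  expect_lt(max(abs(e_int - e_bin)), 1e-9)
  expect_equal(which(e_int == min(e_int)), which(e_bin == min(e_bin)))
  expect_error(model_energy(mi, c(0, 2, 0, 0, 0, 0)), "domain")
})

test_that("binary encoding is energy-identical to the integer model", {
  expect_equal(decode_binary(c(1, 0, 1),
                             structure(list(n_pixels = 1L, bits = 3L,
                                            weights = c(1, 2, 4)),
                                       class = "binary_encoding")), 5)

  mi4 <- withr::with_seed(5, build_integer_model(matrix(rnorm(20), 5, 4),
                                                 rnorm(5), upper_bound = 15L))
  enc4 <- encode_integer_as_binary(mi4, 4L)
  expect_equal(enc4$qubo$n_vars, 16L)

  # full-domain enumeration for 3 pixels at 2 bits
  mi <- withr::with_seed(6, build_integer_model(matrix(rnorm(15), 5, 3),
                                                rnorm(5), upper_bound = 3L))
  enc <- encode_integer_as_binary(mi, 2L)
  V <- all_integer_assignments(3L, 3L)
  for (k in seq_len(nrow(V))) {
    v <- V[k, ]
    bits <- as.integer(intToBits(v[1]))[1:2]
    bits <- c(bits, as.integer(intToBits(v[2]))[1:2],
              as.integer(intToBits(v[3]))[1:2])
    expect_lt(abs(model_energy(enc$qubo, bits) - model_energy(mi, v)), 1e-9)
  }
  expect_error(encode_integer_as_binary(mi4, 2L), "upper_bound")
})

test_that("QUBO JSON round-trip is lossless", {
  prob <- rand_lsq_qubo(n_vars = 5L, seed = 99L)
  path <- withr::local_tempfile(fileext = ".json")
  write_qubo_json(prob$model, path)
  got <- read_qubo_json(path)
  expect_identical(got$n_vars, prob$model$n_vars)
  expect_identical(got$linear, prob$model$linear)
  expect_identical(got$offset, prob$model$offset)
  expect_equal(got$couplers, prob$model$couplers)
})
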