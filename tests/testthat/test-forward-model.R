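test_that("geometry spaces angles evenly on [0, 180)", {
  g <- tomo_geometry(8L, 4L)
  expect_equal(g$angles, c(0, 45, 90, 135))
  expect_equal(g$n_bins, 8L)
  expect_error(tomo_geometry(1L, 4L))
})

test_that("projector is linear, zero-preserving, and axis-exact at 0 degrees", {
  g <- tomo_geometry(4L, 4L)
  expect_equal(project(matrix(0, 4, 4), g)$values, matrix(0, 4, 4))

  img <- withr::with_seed(1, matrix(runif(16), 4, 4))
  expect_equal(project(img, g)$values[1L, ], colSums(img))

  a <- withr::with_seed(2, matrix(runif(16), 4, 4))
  b <- withr::with_seed(3, matrix(runif(16), 4, 4))
  expect_lt(max(abs(project(a, g)$values + project(b, g)$values -
                      project(a + b, g)$values)), 1e-9)
  expect_true(all(project(a, g)$values >= -1e-12))
  expect_error(project(matrix(0, 5, 5), g), "size")
})

test_that("system matrix reproduces the projector exactly", {
  g <- tomo_geometry(4L, 4L)
  M <- build_system_matrix(g)
  expect_equal(dim(M$values), c(16L, 16L))

  g8 <- tomo_geometry(8L, 8L)
  M8 <- build_system_matrix(g8)
  x <- make_phantom("tree", 8L, 2L, seed = 4L)
  expect_equal(max(abs(M8$values %*% vec_image(x) -
                         vec_sinogram(project(x, g8)))), 0)

  # single 0-degree view: row for bin b selects exactly column-b pixels
  g1 <- tomo_geometry(4L, 1L)
  M1 <- build_system_matrix(g1)
  selector <- matrix(0, 4, 16)
  for (b in 1:4) selector[b, seq(b, 16, by = 4)] <- 1   # row-major pixels
  expect_equal(M1$values, selector)
})

test_that("per-view mass is consistent for content inside the inscribed circle", {
  n <- 16L
  cc <- (n + 1) / 2
  img <- matrix(0, n, n)
  d2 <- outer((1:n - cc)^2, (1:n - cc)^2, `+`)
  img[d2 <= (n / 3)^2] <- 1
  s <- project(img, tomo_geometry(n, 8L))
  sums <- rowSums(s$values)
  expect_lt(max(abs(sums - mean(sums))) / mean(sums), 0.01)
})

test_that("rebinning averages bin groups with the pixel-unit scale", {
  g <- tomo_geometry(4L, 1L)
  s <- sinogram(matrix(c(2, 2, 4, 4), 1, 4), g)
  expect_equal(rebin_sinogram(s, 1L, scale = 1)$values, s$values)
  expect_equal(rebin_sinogram(s, 2L, scale = 0.5)$values,
               matrix(c(1, 2), 1, 2))
  expect_equal(rebin_sinogram(s, 2L)$values, matrix(c(1, 2), 1, 2))
  expect_error(rebin_sinogram(s, 3L), "divide")
})

test_that("rebinned fine-grid sinogram approximates the coarse projection", {
  coarse <- make_phantom("foam", 16L, 2L, seed = 6L)
  fine <- upsample_nearest(coarse, 4L)
  s_fine <- project(fine, tomo_geometry(64L, 16L))
  s_reb <- rebin_sinogram(s_fine, 4L)
  s_coarse <- project(coarse, tomo_geometry(16L, 16L))
  mae <- mean(abs(s_reb$values - s_coarse$values))
  expect_lt(mae, 0.05 * max(s_coarse$values))
  expect_gt(mae, 0)    # small but nonzero model mismatch, by design
})

test_that("noise fields obey the signal-dependent support", {
  img <- image_grid(rbind(c(0, 2), c(1, 0)), 4L)
  fields <- withr::with_seed(11, replicate(200, sample_noise_field(img),
                                           simplify = FALSE))
  for (f in fields) {
    expect_true(all(f %in% c(-1L, 0L, 1L)))
    expect_true(all(f[unclass(img) == 0] %in% c(0L, 1L)))
  }
  expect_error(sample_noise_field(matrix(0.5, 2, 2)), "integer")
})

test_that("noisy projection is seeded, per-view independent, and in-model", {
  img <- make_phantom("molecule", 8L, 2L, seed = 1L)
  g <- tomo_geometry(8L, 8L)
  a <- project_with_noise(img, g, seed = 5L)
  b <- project_with_noise(img, g, seed = 5L)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values,
                         project_with_noise(img, g, seed = 6L)$values))
  # the all-zero image only ever gains counts: sinogram stays non-negative
  z <- project_with_noise(image_grid(matrix(0, 4, 4), 2L),
                          tomo_geometry(4L, 4L), seed = 1L)
  expect_true(all(z$values >= -1e-12))
  # views see independent noise draws: rows differ from the clean sinogram
  clean <- project(img, g)
  expect_false(all(a$values == clean$values))
})

test_that("sinogram CSV round-trips with its geometry sidecar", {
  s <- project(make_phantom("foam", 8L, 2L, seed = 2L), tomo_geometry(8L, 8L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sinogram_csv(s, path)
  got <- read_sinogram_csv(path)
  expect_equal(got$values, s$values)
  expect_equal(got$geometry$angles, s$geometry$angles)
})

test_that("dense system matrices above N = 64 are refused without force", {
  fake <- structure(list(values = matrix(0, 2, 2),
                         geometry = tomo_geometry(128L, 2L, 128L)),
                    class = "system_matrix")
  expect_error(write_system_matrix_csv(fake, tempfile()), "refusing")
})
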