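test_that("hand-checkable 2x2 geometry produces axis-sum projections", {
  fx <- generate_fixture("toy-projector")
  G <- as.matrix(fx$G$weights)
  # rows are column/row indicators with unit weights
  expect_equal(G, rbind(c(1, 1, 0, 0), c(0, 0, 1, 1),
                        c(1, 0, 1, 0), c(0, 1, 0, 1)),
               ignore_attr = TRUE)
  s <- forward_project(fx$G, fx$frame)
  expect_equal(as.vector(s$expected), c(4, 6, 3, 7))
})

test_that("single-angle unit-spacing geometry is a column-sum operator", {
  G <- build_system_matrix(1, 6, c(6, 6), detector_spacing = 1)
  img <- matrix(seq_len(36), 6, 6)
  s <- forward_project(G, img)
  expect_equal(as.vector(s$expected), colSums(img))
})

test_that("system matrix entries are finite, nonnegative, FOV fully covered", {
  G <- build_system_matrix(24, 32, c(32, 32))
  expect_true(all(G$weights@x >= 0))
  expect_true(all(is.finite(G$weights@x)))
  sens <- as.vector(Matrix::colSums(G$weights))
  fov <- as.vector(dynpet:::fov_mask(G))
  expect_true(all(sens[fov] > 0))
  expect_error(build_system_matrix(4, 4, c(0, 4)), "degenerate")
})

test_that("projector agrees with the analytic per-pixel clipping oracle", {
  # even radial-bin counts: no zero-offset ray, which for even grids would
  # lie exactly on the central gridline (a convention-dependent case)
  cases <- expand.grid(n = c(3, 5, 8), a = c(1, 4, 7), r = c(4, 8))
  for (i in seq_len(nrow(cases))) {
    n <- cases$n[i]; a <- cases$a[i]; r <- cases$r[i]
    # irrational-ish spacing keeps rays off pixel boundaries, where the
    # closed-box oracle and the half-open traversal differ by convention
    sp <- 0.937 * n / r
    img <- withr::with_seed(100 + i, matrix(runif(n * n), n, n))
    G <- build_system_matrix(a, r, c(n, n), detector_spacing = sp)
    got <- as.vector(forward_project(G, img)$expected)
    want <- oracle_project(img, a, r, spacing = sp)
    expect_equal(got, want, tolerance = 1e-10)
  }
  # non-square grid
  img <- withr::with_seed(55, matrix(runif(5 * 7), 5, 7))
  G <- build_system_matrix(6, 6, c(5, 7))
  expect_equal(as.vector(forward_project(G, img)$expected),
               oracle_project(img, 6, 6, spacing = 5 / 6), tolerance = 1e-10)
})

test_that("forward/back projection satisfy the adjoint identity", {
  G <- build_system_matrix(12, 16, c(16, 16))
  withr::with_seed(3, {
    x <- runif(256); y <- runif(nrow(G$weights))
  })
  lhs <- sum(as.vector(G$weights %*% x) * y)
  rhs <- sum(x * as.vector(Matrix::t(G$weights) %*% y))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("forward projection is linear and rejects shape mismatches", {
  G <- build_system_matrix(4, 8, c(8, 8))
  expect_equal(max(abs(forward_project(G, matrix(0, 8, 8))$expected)), 0)
  # unit voxel reproduces a column of G
  e <- matrix(0, 8, 8); e[3, 5] <- 1
  p <- (5 - 1) * 8 + 3
  expect_equal(as.vector(forward_project(G, e)$expected),
               as.vector(G$weights[, p]))
  expect_error(forward_project(G, matrix(1, 4, 4)), "does not match")
})

test_that("scale_to_counts hits the budget exactly and scales linearly", {
  G <- build_system_matrix(8, 8, c(16, 16))
  ph <- make_dynamic_phantom("disks", c(16, 16), 3, 1, seed = 4)
  s <- forward_project(G, ph)
  s1 <- scale_to_counts(s, 5e4)
  expect_equal(sum(s1$expected), 5e4, tolerance = 1e-9)
  expect_equal(scale_to_counts(s1, 5e4)$expected, s1$expected,
               tolerance = 1e-12)
  s2 <- scale_to_counts(s, 1e5)
  expect_equal(s2$expected, 2 * s1$expected, tolerance = 1e-12)
  s$expected[] <- 0
  expect_error(scale_to_counts(s, 1e4), "all-zero")
})

test_that("phantom calibration puts truth and data in common units", {
  G <- build_system_matrix(16, 16, c(16, 16))
  ph <- make_dynamic_phantom("disks", c(16, 16), 3, 1, seed = 4)
  cal <- calibrate_phantom(G, ph, 2e4)
  expect_equal(sum(forward_project(G, cal)$expected), 2e4, tolerance = 1e-8)
  per <- calibrate_phantom(G, ph, 2e4, per_frame = TRUE)
  ex <- forward_project(G, per)$expected
  expect_equal(rowSums(ex), rep(2e4, 3), tolerance = 1e-8)
})

test_that("Poisson sampling is seeded, exact at zero, centred on the mean", {
  G <- build_system_matrix(8, 8, c(16, 16))
  ph <- make_dynamic_phantom("disks", c(16, 16), 3, 1, seed = 4)
  s <- scale_to_counts(forward_project(G, ph), 1e4)
  a <- sample_poisson(s, seed = 11)
  b <- sample_poisson(s, seed = 11)
  expect_identical(a$counts, b$counts)
  expect_true(all(a$counts >= 0 & a$counts == round(a$counts)))

  z <- s; z$expected[] <- 0
  expect_equal(max(sample_poisson(z, seed = 1)$counts), 0)

  totals <- vapply(1:200, function(k) sum(sample_poisson(s, seed = k)$counts),
                   0)
  se <- sqrt(sum(s$expected) / 200)    # var of a Poisson sum = its mean
  expect_lt(abs(mean(totals) - sum(s$expected)), 3 * se)

  s$expected[1] <- -1
  expect_error(sample_poisson(s, seed = 1), ">= 0")
})
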