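test_that("encode/decode are elementwise sigmoids of affine maps", {
  p <- ae_params(4, 3, seed = 1)
  x <- c(0.2, 0.9, 0.1, 0.5)
  expect_equal(ae_encode(x, p), plogis(as.vector(t(p$W_enc) %*% x + p$b_enc)))
  h <- ae_encode(x, p)
  expect_equal(ae_decode(h, p), plogis(as.vector(t(p$W_dec) %*% h + p$b_dec)))

  pz <- p; pz$W_enc[] <- 0; pz$b_enc[] <- 0
  expect_equal(ae_encode(x, pz), rep(0.5, 3))
  expect_error(ae_encode(c(1, 2), p), "width")
  # batch evaluation matches row-by-row
  X <- matrix(runif(12), 3, 4)
  expect_equal(ae_encode(X, p), t(apply(X, 1, ae_encode, params = p)))
})

test_that("KL sparsity penalty has its closed form and identity at rho0", {
  expect_equal(kl_sparsity(0.25, 0.25), 0)
  expect_equal(kl_sparsity(0.5, 0.25), 0.5 * log(2) + 0.5 * log(2 / 3))
  expect_equal(kl_sparsity(rep(0.25, 7), 0.25), 0)
  expect_gt(kl_sparsity(0.3, 0.25), 0)
  expect_gt(kl_sparsity(0.2, 0.25), 0)
  expect_error(kl_sparsity(0.5, 1.2), "rho0")
})

test_that("objective combines reconstruction, weight and sparsity terms", {
  p <- ae_params(4, 3, seed = 2)
  X <- matrix(0.5, 6, 4)
  pz <- p; pz$W_enc[] <- 0; pz$b_enc[] <- 0; pz$W_dec[] <- 0; pz$b_dec[] <- 0
  cfg <- sparsity_config(alpha1 = 0, alpha2 = 2, rho0 = 0.2)
  # zero params on 0.5-inputs: perfect reconstruction, KL at rho_hat = 0.5
  expect_equal(ae_objective(pz, X, cfg), 2 * 3 * kl_sparsity(0.5, 0.2))
  cfg2 <- sparsity_config(alpha1 = 0.3, alpha2 = 0, rho0 = 0.2)
  expect_equal(ae_objective(p, X, cfg2),
               mean(rowSums((ae_decode(ae_encode(X, p), p) - X)^2)) +
                 0.3 * (sqrt(sum(p$W_enc^2)) + sqrt(sum(p$W_dec^2))))
  expect_error(ae_objective(p, X[0, ], cfg), "empty")
})

test_that("analytic gradients match central finite differences per term", {
  fx <- generate_fixture("gradcheck-net")
  combos <- list(c(0, 0), c(1e-3, 0), c(0, 0.5), c(1e-3, 0.5))
  for (al in combos) {
    cfg <- sparsity_config(alpha1 = al[1], alpha2 = al[2], rho0 = 0.05)
    g <- ae_gradients(fx$params, fx$batch, cfg)
    for (f in c("W_enc", "b_enc", "W_dec", "b_dec")) {
      idx <- withr::with_seed(7, sample(length(fx$params[[f]]), 4))
      for (i in idx) {
        eps <- 1e-6
        p1 <- fx$params; p1[[f]][i] <- p1[[f]][i] + eps
        p2 <- fx$params; p2[[f]][i] <- p2[[f]][i] - eps
        num <- (ae_objective(p1, fx$batch, cfg) -
                  ae_objective(p2, fx$batch, cfg)) / (2 * eps)
        expect_equal(g[[f]][i], num, tolerance = 1e-6)
      }
    }
  }
})

test_that("objective is invariant to permuting hidden units", {
  p <- ae_params(6, 4, seed = 3)
  X <- withr::with_seed(4, matrix(runif(30), 5, 6))
  cfg <- sparsity_config(alpha1 = 1e-2, alpha2 = 0.3, rho0 = 0.1)
  perm <- c(3, 1, 4, 2)
  q <- p
  q$W_enc <- p$W_enc[, perm]; q$b_enc <- p$b_enc[perm]
  q$W_dec <- p$W_dec[perm, ]
  expect_equal(ae_objective(q, X, cfg), ae_objective(p, X, cfg),
               tolerance = 1e-12)
})

test_that("training approximates the identity on a repeated patch", {
  patch <- withr::with_seed(4, runif(16, 0.2, 0.8))
  X <- matrix(rep(patch, 200), 200, 16, byrow = TRUE)
  fit <- train_autoencoder(X, 12, sparsity_config(0, 0, 0.05),
                           learning_rate = 0.5, epochs = 300,
                           rbm_init = FALSE, seed = 2, track = 100)
  o <- ae_decode(ae_encode(patch, fit$params), fit$params)
  expect_lt(sum((o - patch)^2), 1e-2)
  expect_true(all(diff(fit$history$objective) <= 0))
})

test_that("training is deterministic for a fixed seed", {
  X <- withr::with_seed(8, matrix(runif(50 * 9), 50, 9))
  a <- train_autoencoder(X, 5, sparsity_config(), epochs = 10,
                         rbm_init = FALSE, seed = 3)
  b <- train_autoencoder(X, 5, sparsity_config(), epochs = 10,
                         rbm_init = FALSE, seed = 3)
  expect_identical(a$params, b$params)
  c2 <- train_autoencoder(X, 5, sparsity_config(), epochs = 10,
                          rbm_init = TRUE, seed = 3)
  d <- train_autoencoder(X, 5, sparsity_config(), epochs = 10,
                         rbm_init = TRUE, seed = 3)
  expect_identical(c2$params, d$params)
})

test_that("strong sparsity penalty drives mean activations toward rho0", {
  G <- build_system_matrix(16, 16, c(16, 16))
  ph <- calibrate_phantom(G, make_dynamic_phantom("disks", c(16, 16), 3, 1,
                                                  seed = 3), 2e4)
  rec <- mlem_reconstruct(G, sample_poisson(forward_project(G, ph), seed = 3),
                          20)
  X <- extract_patches(rec, truth = ph, frame_index = 2,
                       patch_size = c(3, 3), stride = 1)$inputs
  fit <- train_autoencoder(X, 20, sparsity_config(0, 1, 0.05),
                           learning_rate = 0.3, epochs = 80, batch_size = 64,
                           rbm_init = FALSE, seed = 9)
  expect_lt(mean(ae_encode(X, fit$params)), 0.2)
})

test_that("filters reshape weight rows; smooth inputs train sparser codes", {
  W <- matrix(seq_len(2 * 4 * 3), 8, 3)
  f <- ae_filters(W, c(2, 2))
  expect_length(f, 3)
  expect_length(f[[1]], 2)
  expect_equal(f[[1]][[1]], matrix(W[1:4, 1], 2, 2, byrow = TRUE))
  expect_error(ae_filters(W, c(3, 2)), "multiple")

  # Smooth patches sit at the code's rest state; structure-rich (edge)
  # patches recruit the learned features, so their codes deviate strongly.
  ph <- make_dynamic_phantom("disks", c(32, 32), 3, 2, seed = 31)
  img <- ph$frames[[2]] / max(ph$frames[[2]])
  ds <- extract_patches(list(img, img, img), truth = NULL, frame_index = 2,
                        patch_size = c(5, 5), stride = 1)
  mid <- ds$inputs[, 26:50]
  smooth_idx <- apply(mid, 1, stats::var) < 1e-12
  fit <- train_autoencoder(ds$inputs, 30, sparsity_config(0, 0.5, 0.05),
                           learning_rate = 0.3, epochs = 100, batch_size = 64,
                           rbm_init = FALSE, seed = 3)
  H <- ae_encode(ds$inputs, fit$params)
  rest <- colMeans(H[smooth_idx, ])
  dev <- sqrt(rowSums(sweep(H, 2, rest)^2))
  expect_gt(mean(dev[!smooth_idx]), 3 * mean(dev[smooth_idx]))
})
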