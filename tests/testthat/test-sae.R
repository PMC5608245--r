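test_that("patch extraction: position count, row length, ordering", {
  frames <- lapply(1:5, function(i) matrix(i * seq_len(64 * 64) / 4096, 64, 64))
  ds <- extract_patches(frames, truth = NULL, frame_index = 3,
                        patch_size = c(7, 7), stride = 1)
  expect_equal(nrow(ds$inputs), 58 * 58)       # (64 - 7 + 1)^2 positions
  expect_equal(ncol(ds$inputs), 3 * 49)
  # first row is frames 2,3,4 at top-left corner, row-major pixels
  pr <- function(img) as.vector(t(img[1:7, 1:7])) * ds$norm$scale
  expect_equal(ds$inputs[1, ], c(pr(frames[[2]]), pr(frames[[3]]),
                                 pr(frames[[4]])))
})

test_that("edge frames are replicated at the temporal boundary", {
  frames <- lapply(1:4, function(i) matrix(i, 8, 8))
  ds <- extract_patches(frames, truth = NULL, frame_index = 1,
                        patch_size = c(3, 3), stride = 1)
  row <- ds$inputs[1, ]
  expect_equal(unique(row[1:9]), unique(row[10:18]))    # frame 1 twice
  expect_equal(row[19:27] / ds$norm$scale, rep(2, 9))
})

test_that("constant images give identical input rows; stride subsamples", {
  frames <- lapply(1:3, function(i) matrix(0.7, 16, 16))
  ds <- extract_patches(frames, truth = NULL, frame_index = 2,
                        patch_size = c(5, 5), stride = 1)
  expect_equal(max(apply(ds$inputs, 2, function(col) diff(range(col)))), 0)
  ds2 <- extract_patches(frames, truth = NULL, frame_index = 2,
                         patch_size = c(5, 5), stride = 3)
  expect_equal(nrow(ds2$inputs), length(seq(1, 12, 3))^2)
  expect_error(extract_patches(frames, truth = NULL, frame_index = 2,
                               patch_size = c(17, 5)), "larger")
  expect_error(extract_patches(frames, truth = NULL, frame_index = 9,
                               patch_size = c(5, 5)), "out of range")
})

test_that("labels are the truth patches under the truth-anchored norm", {
  ph <- make_dynamic_phantom("disks", c(16, 16), 3, 1, seed = 2)
  ds <- extract_patches(ph$frames, truth = ph, frame_index = 2,
                        patch_size = c(3, 3), stride = 1)
  expect_equal(ds$norm$scale, 1 / max(ph$frames[[2]]))
  expect_true(all(ds$labels >= 0 & ds$labels <= 1))
  expect_equal(ds$labels[1, ],
               as.vector(t(ph$frames[[2]][1:3, 1:3])) * ds$norm$scale)
})

test_that("a single-layer stack equals a plain sparse autoencoder", {
  X <- withr::with_seed(5, matrix(runif(60 * 12), 60, 12))
  cfg <- sparsity_config()
  st <- greedy_pretrain(X, 6L, cfg, epochs = 15, batch_size = 32,
                        rbm_init = TRUE, seed = 21)
  direct <- train_autoencoder(X, 6L, cfg, epochs = 15, batch_size = 32,
                              rbm_init = TRUE,
                              seed = derive_seed(21, "layer-1"))
  expect_identical(st[[1]]$W, direct$params$W_enc)
  expect_identical(st[[1]]$b, direct$params$b_enc)
})

test_that("stacked layers chain dimensionally", {
  X <- withr::with_seed(5, matrix(runif(40 * 12), 40, 12))
  st <- greedy_pretrain(X, c(8L, 4L), sparsity_config(), epochs = 5,
                        rbm_init = FALSE, seed = 1)
  expect_equal(dim(st[[1]]$W), c(12L, 8L))
  expect_equal(dim(st[[2]]$W), c(8L, 4L))
})

test_that("fine-tuning learns the identity on a noiseless oracle dataset", {
  ds <- identity_patch_dataset(n = 800)
  stack <- greedy_pretrain(ds, c(40L, 20L), sparsity_config(0, 0, 0.05),
                           epochs = 50, batch_size = 128, rbm_init = FALSE,
                           seed = 5)
  m <- sae_finetune(stack, ds, epochs = 300, learning_rate = 1,
                    batch_size = 64, seed = 5, track = 50)
  m <- sae_finetune(m, ds, epochs = 200, learning_rate = 0.3,
                    batch_size = 64, seed = 6, track = 50)
  O <- sae_predict(m, ds$inputs)
  expect_lt(mean((O - ds$labels)^2), 1e-3)    # per-element MSE
})

test_that("fine-tuning loss trends down and training is deterministic", {
  ds <- identity_patch_dataset(n = 200, seed = 9)
  stack <- greedy_pretrain(ds, 15L, sparsity_config(), epochs = 10,
                           rbm_init = FALSE, seed = 2)
  m1 <- sae_finetune(stack, ds, epochs = 60, learning_rate = 0.5,
                     batch_size = 50, seed = 3, track = 10)
  m2 <- sae_finetune(stack, ds, epochs = 60, learning_rate = 0.5,
                     batch_size = 50, seed = 3, track = 10)
  expect_identical(m1$layers, m2$layers)
  expect_identical(m1$output, m2$output)
  h <- m1$history$loss
  expect_lt(tail(h, 1), h[1])
  # loose monotone trend: each tracked loss below the running max so far
  expect_true(all(h <= cummax(c(h[1], h))[-1] + 1e-8))

  # output-only mode freezes the encoders
  m3 <- sae_finetune(stack, ds, epochs = 5, learning_rate = 0.5,
                     output_only = TRUE, seed = 3)
  expect_identical(m3$layers, stack)
})

test_that("prediction composes the encoders and output layer statelessly", {
  ds <- identity_patch_dataset(n = 50, seed = 4)
  stack <- greedy_pretrain(ds, c(10L, 6L), sparsity_config(), epochs = 3,
                           rbm_init = FALSE, seed = 1)
  m <- sae_finetune(stack, ds, epochs = 3, learning_rate = 0.2, seed = 1)
  X <- ds$inputs[1:7, ]
  # step-by-step compositional oracle
  H <- X
  for (l in m$layers) H <- plogis(sweep(H %*% l$W, 2, l$b, `+`))
  O <- plogis(sweep(H %*% m$output$W, 2, m$output$b, `+`))
  expect_equal(sae_predict(m, X), O, tolerance = 1e-14)
  # batch equals row-by-row
  expect_equal(sae_predict(m, X),
               t(vapply(seq_len(7), function(i) sae_predict(m, X[i, ]),
                        numeric(9))))
  # all-zero parameters: sigmoid cascade lands at 0.5
  mz <- m
  for (l in seq_along(mz$layers)) {
    mz$layers[[l]]$W[] <- 0; mz$layers[[l]]$b[] <- 0
  }
  mz$output$W[] <- 0; mz$output$b[] <- 0
  expect_equal(sae_predict(mz, X[1, ]), rep(0.5, 9))
})

test_that("save / load / predict round trip is bit-identical", {
  ds <- identity_patch_dataset(n = 50, seed = 4)
  stack <- greedy_pretrain(ds, 8L, sparsity_config(), epochs = 3,
                           rbm_init = FALSE, seed = 1)
  m <- sae_finetune(stack, ds, epochs = 3, learning_rate = 0.2, seed = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  save_sae_model(m, path)
  back <- load_sae_model(path)
  expect_identical(sae_predict(back, ds$inputs), sae_predict(m, ds$inputs))
})
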