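#' Default end-to-end experiment configuration
#'
#' One list holding every tunable of the pipeline, validated against the
#' module preconditions before any stage runs.  The model defaults follow
#' the reference architecture: a 3-frame window of 7x7 patches (147
#' inputs), two hidden layers of 200 and 100 units, and a 49-unit patch
#' output.  Simulation defaults are desk-scale: 64x64 grids, 9 frames,
#' a 5e4-count budget per scan, 12 training and 4 test phantoms.
#'
#' @param seed master seed; every stage derives named sub-streams from it.
#' @param ... overrides for any configuration entry.
#' @return a `run_config` list.
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # phantom / simulation
    kind = "disks", grid = c(64L, 64L), n_frames = 9L, n_regions = 4L,
    n_train = 12L, n_test = 4L,
    n_angles = 64L, n_radial = 64L,
    total_counts = 5e4, counts_per_frame = FALSE,
    # MLEM
    mlem_iters = 50L,
    # SAE
    frame_index = 5L, patch = c(7L, 7L), n_window = 3L, stride = 1L,
    hidden = c(200L, 100L),
    alpha1 = 1e-4, alpha2 = 0.1, rho0 = 0.05,
    batch_size = 128L,
    rbm_epochs = 3L, rbm_lr = 0.05,
    pretrain_lr = 0.1, pretrain_epochs = 20L,
    finetune_lr = 1.0, finetune_epochs = 150L,
    anneal_lr = 0.3, anneal_epochs = 50L,
    # patch sweep
    sigma = 1.0, aggregate = "overlap")
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(all(cfg$grid >= 16L), cfg$n_frames >= 3L, cfg$n_regions >= 1L,
            cfg$n_train >= 1L, cfg$n_test >= 1L,
            cfg$n_angles >= 1L, cfg$n_radial >= 1L,
            cfg$total_counts > 0, cfg$mlem_iters >= 1L,
            cfg$frame_index >= 1L, cfg$frame_index <= cfg$n_frames,
            all(cfg$patch >= 1L), cfg$n_window %% 2L == 1L,
            cfg$stride >= 1L, length(cfg$hidden) >= 1L,
            cfg$alpha1 >= 0, cfg$alpha2 >= 0,
            cfg$rho0 > 0, cfg$rho0 < 1)
  cfg
}

# content hash of any R object (serialized to a temp file, md5)
hash_obj <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, compress = FALSE)
  unname(tools::md5sum(f))
}

# run `fun()` unless a cached result with the same key exists in run_dir
cached_stage <- function(run_dir, name, key, fun, cache = TRUE) {
  if (is.null(run_dir)) return(fun())
  h <- hash_obj(key)
  rds <- file.path(run_dir, paste0("stage_", name, ".rds"))
  meta <- file.path(run_dir, paste0("stage_", name, ".hash"))
  if (cache && file.exists(rds) && file.exists(meta) &&
      identical(readLines(meta, warn = FALSE)[1], h))
    return(readRDS(rds))
  out <- fun()
  saveRDS(out, rds)
  writeLines(h, meta)
  out
}

simulate_one <- function(G, phantom, cfg, stream) {
  phantom <- calibrate_phantom(G, phantom, cfg$total_counts,
                               per_frame = isTRUE(cfg$counts_per_frame))
  sino <- forward_project(G, phantom)
  sino$total_counts <- sum(sino$expected)
  list(phantom = phantom,
       sinogram = sample_poisson(sino, seed = derive_seed(cfg$seed, stream)))
}

#' Run the full simulate / reconstruct / train / fuse / evaluate pipeline
#'
#' Executes the five stages in order -- phantom generation, sinogram
#' simulation, per-frame MLEM, SAE training on the training sets, patch
#' reconstruction and ROI metrics on the held-out test sets.  When
#' `run_dir` is given, each completed stage is cached on disk keyed by a
#' content hash of the configuration entries it depends on, and a manifest
#' of seeds and stage hashes is written.
#'
#' @param config a `run_config` from [default_config()].
#' @param run_dir optional directory for caches, the model, metrics CSV
#'   and manifest; `NULL` keeps everything in memory.
#' @param cache reuse cached stages when their keys match.
#' @param verbose print stage progress.
#' @return list with `model`, `metrics` (per set/method/ROI data frame),
#'   `summary` (Total-ROI means per method), `test_images`, `config`.
#' @export
run_experiment <- function(config = default_config(), run_dir = NULL,
                           cache = TRUE, verbose = FALSE) {
  cfg <- validate_config(config)
  if (!is.null(run_dir) && !dir.exists(run_dir))
    dir.create(run_dir, recursive = TRUE)
  say <- function(...) if (verbose) message(...)

  sim_key <- cfg[c("seed", "kind", "grid", "n_frames", "n_regions", "n_train",
                   "n_test", "n_angles", "n_radial", "total_counts",
                   "counts_per_frame")]

  say("stage 1/5: phantoms")
  phantoms <- cached_stage(run_dir, "phantoms", sim_key[1:7], function() {
    mk <- function(stream, i)
      make_dynamic_phantom(cfg$kind, cfg$grid, cfg$n_frames, cfg$n_regions,
                           seed = derive_seed(cfg$seed, paste0(stream, i)))
    list(train = lapply(seq_len(cfg$n_train), function(i) mk("train-", i)),
         test = lapply(seq_len(cfg$n_test), function(i) mk("test-", i)))
  }, cache)

  say("stage 2/5: simulation")
  G <- build_system_matrix(cfg$n_angles, cfg$n_radial, cfg$grid)
  sims <- cached_stage(run_dir, "sinograms", sim_key, function() {
    list(train = lapply(seq_len(cfg$n_train), function(i)
           simulate_one(G, phantoms$train[[i]], cfg, paste0("sino-train-", i))),
         test = lapply(seq_len(cfg$n_test), function(i)
           simulate_one(G, phantoms$test[[i]], cfg, paste0("sino-test-", i))))
  }, cache)
  # phantoms calibrated to the count budget: the common activity unit
  phantoms <- list(train = lapply(sims$train, `[[`, "phantom"),
                   test = lapply(sims$test, `[[`, "phantom"))
  sinos <- list(train = lapply(sims$train, `[[`, "sinogram"),
                test = lapply(sims$test, `[[`, "sinogram"))

  say("stage 3/5: MLEM")
  mlem_key <- c(sim_key, cfg["mlem_iters"])
  recons <- cached_stage(run_dir, "mlem", mlem_key, function() {
    list(train = lapply(sinos$train, function(s)
           mlem_reconstruct(G, s, n_iterations = cfg$mlem_iters)),
         test = lapply(sinos$test, function(s)
           mlem_reconstruct(G, s, n_iterations = cfg$mlem_iters)))
  }, cache)

  say("stage 4/5: SAE training")
  train_key <- c(mlem_key, cfg[c("frame_index", "patch", "n_window", "stride",
                                 "hidden", "alpha1", "alpha2", "rho0",
                                 "batch_size", "rbm_epochs", "rbm_lr",
                                 "pretrain_lr", "pretrain_epochs",
                                 "finetune_lr", "finetune_epochs",
                                 "anneal_lr", "anneal_epochs")])
  model <- cached_stage(run_dir, "model", train_key, function() {
    sets <- lapply(seq_len(cfg$n_train), function(i)
      extract_patches(recons$train[[i]], truth = phantoms$train[[i]],
                      frame_index = cfg$frame_index, patch_size = cfg$patch,
                      stride = cfg$stride, n_window = cfg$n_window))
    ds <- rbind_patches(sets)
    scfg <- sparsity_config(cfg$alpha1, cfg$alpha2, cfg$rho0)
    stack <- greedy_pretrain(ds, cfg$hidden, scfg,
                             learning_rate = cfg$pretrain_lr,
                             epochs = cfg$pretrain_epochs,
                             batch_size = cfg$batch_size,
                             rbm_epochs = cfg$rbm_epochs, rbm_lr = cfg$rbm_lr,
                             seed = derive_seed(cfg$seed, "pretrain"))
    fit <- sae_finetune(stack, ds, epochs = cfg$finetune_epochs,
                        learning_rate = cfg$finetune_lr,
                        batch_size = cfg$batch_size,
                        seed = derive_seed(cfg$seed, "finetune"))
    if (cfg$anneal_epochs > 0L)
      fit <- sae_finetune(fit, ds, epochs = cfg$anneal_epochs,
                          learning_rate = cfg$anneal_lr,
                          batch_size = cfg$batch_size,
                          seed = derive_seed(cfg$seed, "anneal"))
    fit
  }, cache)
  if (!is.null(run_dir)) save_sae_model(model, file.path(run_dir, "model.rds"))

  say("stage 5/5: reconstruction + evaluation")
  kernel <- gaussian_kernel(cfg$patch, cfg$sigma)
  rows <- list(); test_images <- list()
  for (i in seq_len(cfg$n_test)) {
    truth <- phantoms$test[[i]]
    masks <- roi_masks(truth)
    mlem_img <- recons$test[[i]]$images[[cfg$frame_index]]
    sae_img <- reconstruct_frame(model, recons$test[[i]],
                                 frame_index = cfg$frame_index,
                                 kernel = kernel, aggregate = cfg$aggregate)
    test_images[[i]] <- list(truth = truth$frames[[cfg$frame_index]],
                             mlem = mlem_img, sae = sae_img)
    for (method in c("MLEM", "MLEM+SAE")) {
      img <- if (method == "MLEM") mlem_img else sae_img
      rep_i <- roi_report(list(img), list(truth$frames[[cfg$frame_index]]),
                          masks)
      rep_i$frame <- cfg$frame_index
      rep_i <- cbind(set = i, method = method, rep_i)
      rows[[length(rows) + 1L]] <- rep_i
    }
  }
  metrics <- do.call(rbind, rows)
  tot <- metrics[metrics$roi == "Total", ]
  summary <- do.call(rbind, lapply(split(tot, tot$method), function(d)
    data.frame(method = d$method[1], mean_snr_db = mean(d$snr_db),
               mean_abs_bias = mean(abs(d$bias)),
               mean_variance = mean(d$variance))))
  rownames(summary) <- NULL

  if (!is.null(run_dir)) {
    write_metrics_csv(metrics, file.path(run_dir, "metrics.csv"))
    manifest <- list(package_version = as.character(utils::packageVersion("dynpet")),
                     seed = cfg$seed, config = cfg[names(cfg) != "seed"],
                     stage_hashes = list(
                       phantoms = hash_obj(sim_key[1:7]),
                       sinograms = hash_obj(sim_key),
                       mlem = hash_obj(mlem_key),
                       model = hash_obj(train_key)))
    jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  list(model = model, metrics = metrics, summary = summary,
       test_images = test_images, config = cfg)
}

#' MLEM image quality across counting rates
#'
#' For each seed, simulates one dynamic phantom and scans it at every
#' counting rate (total coincidence events per scan), reconstructs with
#' MLEM, and scores the Total-ROI SNR of the target frame.  Reconstruction
#' quality is expected to improve (SNR non-decreasing) with the counting
#' rate; low rates are where frame-by-frame MLEM degrades most.
#'
#' @param rates numeric vector of total-count budgets,
#'   e.g. `c(5e4, 1e5, 5e5, 1e6)`.
#' @param seeds integer vector; one phantom + noise realization per seed.
#' @param config a `run_config` supplying geometry/phantom/MLEM settings.
#' @return data frame with columns `rate`, `seed`, `snr_db`, `bias`,
#'   `variance`.
#' @export
counting_rate_sweep <- function(rates = c(5e4, 1e5, 5e5, 1e6),
                                seeds = 1:3, config = default_config()) {
  cfg <- validate_config(config)
  G <- build_system_matrix(cfg$n_angles, cfg$n_radial, cfg$grid)
  rows <- list()
  for (s in seeds) {
    ph0 <- make_dynamic_phantom(cfg$kind, cfg$grid, cfg$n_frames,
                                cfg$n_regions,
                                seed = derive_seed(s, "sweep-phantom"))
    for (rate in rates) {
      ph <- calibrate_phantom(G, ph0, rate)
      sino <- sample_poisson(forward_project(G, ph),
                             seed = derive_seed(s, paste0("sweep-", rate)))
      rec <- mlem_reconstruct(G, sino, n_iterations = cfg$mlem_iters)
      i <- cfg$frame_index
      rep_i <- roi_report(list(rec$images[[i]]), list(ph$frames[[i]]),
                          roi_masks(ph)["Total"])
      rows[[length(rows) + 1L]] <- data.frame(
        rate = rate, seed = s, snr_db = rep_i$snr_db, bias = rep_i$bias,
        variance = rep_i$variance)
    }
  }
  do.call(rbind, rows)
}

#' Deterministic test fixtures
#'
#' Emits the tiny problems used throughout the test suite: the
#' hand-checkable 2x2 projector toy, a 4-visible/2-hidden RBM with a
#' two-pattern dataset, a 12-8-12 gradient-check net with a 5-row batch,
#' and a 32x32 dynamic phantom with its system matrix and noisy sinogram.
#'
#' @param name one of `"toy-projector"`, `"toy-rbm"`, `"gradcheck-net"`,
#'   `"phantom-32"`.
#' @param seed integer seed.
#' @return a named list; contents depend on the fixture.
#' @export
generate_fixture <- function(name = c("toy-projector", "toy-rbm",
                                      "gradcheck-net", "phantom-32"),
                             seed = 1L) {
  name <- match.arg(name)
  switch(name,
    "toy-projector" = {
      G <- build_system_matrix(2, 2, c(2L, 2L), detector_spacing = 1)
      frame <- matrix(c(1, 3, 2, 4), 2, 2)   # [[1,2],[3,4]] by row
      list(G = G, frame = frame,
           expected = c(4, 6, 3, 7))         # 0deg column sums, 90deg row sums
    },
    "toy-rbm" = {
      data <- matrix(rep(c(1, 1, 0, 0, 0, 0, 1, 1), 10), ncol = 4,
                     byrow = TRUE)
      list(params = rbm_params(4, 2, lambda = 0, seed = seed), data = data)
    },
    "gradcheck-net" = {
      batch <- withr::with_seed(derive_seed(seed, "gradcheck"),
                                matrix(stats::runif(5 * 12), 5, 12))
      list(params = ae_params(12, 8, 12, seed = seed), batch = batch)
    },
    "phantom-32" = {
      ph <- make_dynamic_phantom("disks", c(32L, 32L), n_frames = 5L,
                                 n_regions = 2L, seed = seed)
      G <- build_system_matrix(32, 32, c(32L, 32L))
      sino <- sample_poisson(scale_to_counts(forward_project(G, ph), 2e4),
                             seed = seed)
      list(phantom = ph, G = G, sinogram = sino)
    })
}
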