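#' Scaled-down block-design benchmark corpus
#'
#' The package's standard synthetic testbed: a counterbalanced three-class
#' block design (two sessions of six blocks of six trials per subject, 2 s
#' windows at 10 Hz, 12 spatial channels x HbO/HbR), sized so that a full
#' cross-validated comparison runs on one CPU in minutes while still showing
#' the phenomena of interest (within-corpus splits easier than cross-block /
#' cross-subject splits; discrepancy penalties improving cross-subject
#' generalization).
#'
#' @param n_subjects Number of subjects (default 12).
#' @param n_spatial_channels Spatial channels (default 12).
#' @return An [experiment_design()].
#' @export
benchmark_design <- function(n_subjects = 12L, n_spatial_channels = 12L) {
  experiment_design(
    "custom", n_subjects = n_subjects, sessions_per_subject = 2L,
    blocks_per_session = 6L, trials_per_block = 6L,
    block_condition_order = c(0L, 1L, 2L, 2L, 0L, 1L),
    window_seconds = 2, sampling_rate = 10,
    n_spatial_channels = n_spatial_channels, n_hemoglobin_types = 2L,
    n_optical_types = 1L, class_set = 0:2
  )
}

benchmark_mixer_config <- function(design) {
  mixer_config(
    n_timesteps = design$n_timesteps, features_per_group = n_features(design),
    hidden_dim = 16L, n_layers = 2L, temporal_hidden = 64L,
    channel_hidden = 32L, n_classes = length(design$class_set)
  )
}

benchmark_train_config <- function(da_mode = "none", alpha = 1, seed = 1L,
                                   max_epochs = 60L, patience = 20L) {
  train_config(
    learning_rate = 1e-3, dropout_ratio = 0.25, alpha = alpha,
    da_mode = da_mode, batch_size = 32L, n_domain_pairs = 8L,
    patience_epochs = patience, max_epochs = max_epochs, seed = seed
  )
}

bench_fold_sets <- function(set, scenario, seed) {
  sp <- split_spec(scenario, k_folds = 4L, seed = seed)
  fold <- make_split(set, sp, 1L)
  list(train = subset_epochs(set, fold$train),
       val = subset_epochs(set, fold$val),
       test = subset_epochs(set, fold$test))
}

#' Cross-subject benchmark: plain cross-entropy vs domain-adaptive training
#'
#' For each seed, generates a fresh benchmark corpus, holds out whole
#' subjects, and trains one model per DA mode on identical splits. Reports
#' held-out-subject accuracy and macro F1 per (seed, mode), plus a paired
#' t-test of F1 between the first two modes.
#'
#' @param seeds Integer vector of seeds (one corpus + split + run per seed).
#' @param da_modes Modes to compare (first is the reference), subset of
#'   `"none"`, `"subject"`, `"session"`, `"block"`.
#' @param n_subjects Subjects per corpus.
#' @param alpha Discrepancy weight for the DA modes.
#' @param max_epochs Epoch cap per run.
#' @return List: `results` (tibble seed x mode), `summary` (per-mode means),
#'   `ttest` (paired F1 test of mode 2 vs mode 1, when both present).
#' @export
run_da_benchmark <- function(seeds = 1:5, da_modes = c("none", "block"),
                             n_subjects = 12L, alpha = 1,
                             max_epochs = 60L) {
  rows <- list()
  for (seed in seeds) {
    config <- generator_config(benchmark_design(n_subjects),
                               seed = seed * 1009L + 17L)
    set <- generate_dataset(config)
    sets <- bench_fold_sets(set, "subject", seed)
    mc <- benchmark_mixer_config(set$design)
    for (mode in da_modes) {
      fit <- train_model(sets$train, sets$val, mc,
                         benchmark_train_config(mode, alpha, seed, max_epochs))
      pred <- predict(fit, sets$test)
      metrics <- evaluate_metrics(pred, sets$test$meta$label,
                                  class_set = set$design$class_set)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        seed = seed, da_mode = mode, accuracy = metrics$accuracy,
        macro_f1 = metrics$macro_f1, n_test = metrics$n_test
      )
    }
  }
  results <- dplyr::bind_rows(rows)
  summary <- results |>
    dplyr::group_by(da_mode) |>
    dplyr::summarise(mean_accuracy = mean(accuracy),
                     mean_macro_f1 = mean(macro_f1), .groups = "drop")
  ttest <- NULL
  if (length(da_modes) >= 2L && length(seeds) >= 2L) {
    a <- results$macro_f1[results$da_mode == da_modes[2]]
    b <- results$macro_f1[results$da_mode == da_modes[1]]
    ttest <- paired_ttest(a, b)
  }
  list(results = results, summary = summary, ttest = ttest)
}

#' Split-scenario benchmark with Wasserstein shift diagnostic
#'
#' For each seed and scenario (trial / block / session / subject), trains a
#' cross-entropy model on that scenario's split of a fresh benchmark corpus,
#' measures test accuracy, and computes the mean mini-batch Wasserstein
#' distance between the encoder features of the training and test sides. A
#' larger diagnostic means the split exposes the model to a larger
#' distribution shift; accuracy is expected to be highest (and the diagnostic
#' smallest) for the trial split, which mixes every subject, session and
#' block into training.
#'
#' The diagnostic is measured through one fixed reference encoder per seed
#' (the trial-split model, which sees every domain during training): holding
#' the feature map constant is what makes the shift numbers comparable
#' across scenarios -- features from four differently trained encoders live
#' on four different scales.
#'
#' @param seeds Integer vector of seeds.
#' @param scenarios Scenarios to evaluate.
#' @param n_subjects Subjects per corpus.
#' @param max_epochs Epoch cap per run.
#' @param wd_pairs,wd_batch Mini-batch pairs and batch size of the
#'   Wasserstein diagnostic.
#' @return List: `results` (tibble seed x scenario with accuracy and
#'   `wasserstein`), `summary` (per-scenario means).
#' @export
run_split_benchmark <- function(seeds = 1:5,
                                scenarios = c("trial", "block", "session", "subject"),
                                n_subjects = 12L, max_epochs = 35L,
                                wd_pairs = 50L, wd_batch = 64L) {
  rows <- list()
  for (seed in seeds) {
    config <- generator_config(benchmark_design(n_subjects),
                               seed = seed * 2003L + 29L)
    set <- generate_dataset(config)
    mc <- benchmark_mixer_config(set$design)
    cfg <- benchmark_train_config("none", 0, seed, max_epochs, patience = 12L)
    ref_sets <- bench_fold_sets(set, "trial", seed)
    ref <- train_model(ref_sets$train, ref_sets$val, mc, cfg)
    for (scenario in scenarios) {
      sets <- if (scenario == "trial") ref_sets else bench_fold_sets(set, scenario, seed)
      fit <- if (scenario == "trial") ref else train_model(sets$train, sets$val, mc, cfg)
      pred <- predict(fit, sets$test)
      metrics <- evaluate_metrics(pred, sets$test$meta$label,
                                  class_set = set$design$class_set)
      wd <- wasserstein_diagnostic(
        predict(ref, sets$train, type = "feature"),
        predict(ref, sets$test, type = "feature"),
        n_pairs = wd_pairs,
        batch_size = min(wd_batch, n_epochs(sets$train), n_epochs(sets$test)),
        seed = seed
      )
      rows[[length(rows) + 1L]] <- tibble::tibble(
        seed = seed, scenario = scenario, accuracy = metrics$accuracy,
        macro_f1 = metrics$macro_f1, wasserstein = wd
      )
    }
  }
  results <- dplyr::bind_rows(rows)
  summary <- results |>
    dplyr::group_by(scenario) |>
    dplyr::summarise(mean_accuracy = mean(accuracy),
                     mean_wasserstein = mean(wasserstein), .groups = "drop")
  list(results = results, summary = summary)
}

#' Planted-signal channel-mask recovery benchmark
#'
#' Generates corpora in which only spatial channels 1-4 carry class signal,
#' trains a cross-entropy model per seed, and runs [channel_mask_scan()] with
#' disjoint 4-channel masks on held-out subjects. Reports how often the mask
#' covering the informative channels -- and only that mask -- is flagged
#' critical.
#'
#' @param seeds Integer vector of seeds.
#' @param n_subjects Subjects per corpus.
#' @param n_spatial_channels Spatial channels (6 masks at the default 24).
#' @param max_epochs Epoch cap per run.
#' @return List: `results` (tibble seed x mask), `recovery_rate` (fraction of
#'   seeds whose only critical mask is the informative one),
#'   `hit_rate` (fraction of seeds flagging the informative mask at all).
#' @export
run_mask_benchmark <- function(seeds = 1:5, n_subjects = 12L,
                               n_spatial_channels = 24L, max_epochs = 35L) {
  rows <- list()
  for (seed in seeds) {
    design <- benchmark_design(n_subjects, n_spatial_channels)
    # planted-signal recovery needs a decodable plant: the class contrast is
    # doubled relative to the standard benchmark so the fitted model
    # measurably relies on the informative channels
    config <- generator_config(design, seed = seed * 3001L + 41L,
                               class_amplitudes = c(0.6, 1.7, 2.8),
                               informative_channels = 1:4)
    set <- generate_dataset(config)
    sets <- bench_fold_sets(set, "subject", seed)
    mc <- benchmark_mixer_config(design)
    fit <- train_model(sets$train, sets$val, mc,
                       benchmark_train_config("none", 0, seed, max_epochs,
                                              patience = 12L))
    scan <- channel_mask_scan(fit, sets$test, make_channel_masks(design, 4L))
    rows[[length(rows) + 1L]] <- dplyr::mutate(
      tibble::as_tibble(scan), seed = seed,
      unmasked_accuracy = attr(scan, "unmasked_accuracy"),
      ci_lower = attr(scan, "ci_lower")
    )
  }
  results <- dplyr::bind_rows(rows)
  per_seed <- results |>
    dplyr::group_by(seed) |>
    dplyr::summarise(
      informative_flagged = critical[mask_id == "mask1"],
      n_false = sum(critical[mask_id != "mask1"]),
      .groups = "drop"
    )
  list(results = results,
       recovery_rate = mean(per_seed$informative_flagged & per_seed$n_false == 0L),
       hit_rate = mean(per_seed$informative_flagged),
       per_seed = per_seed)
}
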