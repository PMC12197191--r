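test_that("subject folds reproduce the published 18/5/3 layout", {
  config <- generator_config(experiment_design(
    "tuberlin", n_spatial_channels = 2L), seed = 1L)
  design <- config$design
  design$trials_per_block <- 1L # one epoch per block keeps this light
  set <- generate_dataset(generator_config(design, seed = 1L))
  spec <- split_spec("subject", k_folds = 10L, n_train = 18L, n_val = 5L,
                     n_test = 3L, seed = 4L)
  seen_test <- character(0)
  for (fold in 1:10) {
    idx <- make_split(set, spec, fold)
    count_subjects <- function(i) length(unique(set$meta$subject_id[i]))
    expect_equal(count_subjects(idx$train), 18L)
    expect_equal(count_subjects(idx$val), 5L)
    expect_equal(count_subjects(idx$test), 3L)
    expect_equal(length(intersect(idx$train, idx$test)), 0L)
    expect_equal(length(intersect(idx$val, idx$test)), 0L)
    expect_equal(length(intersect(idx$train, idx$val)), 0L)
    expect_equal(sort(c(idx$train, idx$val, idx$test)), seq_len(n_epochs(set)))
    seen_test <- c(seen_test, unique(set$meta$subject_id[idx$test]))
  }
  # test subjects rotate across folds
  expect_gte(length(unique(seen_test)), 24L)
})

test_that("splits are atomic in their scenario's unit", {
  set <- tiny_set(tiny_design(n_subjects = 4L, blocks = 4L))
  for (scenario in c("block", "session", "subject")) {
    idx <- make_split(set, split_spec(scenario, k_folds = 4L, seed = 7L), 2L)
    unit <- switch(scenario,
      block = paste(set$meta$subject_id, set$meta$session_idx, set$meta$block_idx),
      session = paste(set$meta$subject_id, set$meta$session_idx),
      subject = set$meta$subject_id)
    expect_equal(length(intersect(unit[idx$train], unit[idx$test])), 0L)
    expect_equal(length(intersect(unit[idx$val], unit[idx$test])), 0L)
    expect_equal(sort(c(idx$train, idx$val, idx$test)), seq_len(n_epochs(set)))
  }
  # session scenario holds out one whole session of every subject
  idx <- make_split(set, split_spec("session", k_folds = 2L, seed = 1L), 1L)
  expect_equal(unique(set$meta$session_idx[idx$test]), 0L)
  idx2 <- make_split(set, split_spec("session", k_folds = 2L, seed = 1L), 2L)
  expect_equal(unique(set$meta$session_idx[idx2$test]), 1L)
})

test_that("metrics match a hand-computed confusion matrix", {
  # binary confusion with TP=3, FP=1, FN=1, TN=5
  labels <- c(rep(1, 4), rep(0, 6))
  preds <- c(1, 1, 1, 0, 1, rep(0, 5))
  m <- evaluate_metrics(preds, labels)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$per_class$f1[m$per_class$class == 1], 0.75)
  expect_equal(m$macro_f1,
               mean(c(0.75, 2 * (5 / 6) * (5 / 6) / (5 / 6 + 5 / 6))))

  perfect <- evaluate_metrics(c(0, 1, 2), c(0, 1, 2))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_f1, 1)

  # invariance under consistent relabeling
  relabeled <- evaluate_metrics(5 - preds, 5 - labels)
  expect_equal(relabeled$accuracy, m$accuracy)
  expect_equal(relabeled$macro_f1, m$macro_f1)

  # a class absent from the labels scores 0 and is flagged
  m2 <- evaluate_metrics(c(0, 0, 1), c(0, 0, 0), class_set = 0:1)
  expect_equal(m2$flagged_classes, 1)
  expect_equal(m2$per_class$f1[2], 0)
})

test_that("wasserstein diagnostic has its closed-form values", {
  # identically paired batches -> 0
  a <- matrix(rnorm(20), 10, 2)
  expect_lt(wasserstein_diagnostic(a, a, n_pairs = 5, batch_size = 10), 1e-6)
  # two 1-point batches at 0 and 1 in 1-D -> 1
  expect_equal(wasserstein_diagnostic(matrix(0), matrix(1), n_pairs = 1,
                                      batch_size = 1), 1)
  # shift monotonicity
  set.seed(12)
  base <- matrix(rnorm(200), 100, 2)
  vals <- vapply(c(0, 1, 2), function(delta) {
    wasserstein_diagnostic(base, base + delta, n_pairs = 10, batch_size = 32,
                           seed = 3)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(wasserstein_diagnostic(a, a, batch_size = 99), "exceeds")
})

test_that("exact assignment beats a greedy transport plan", {
  # the LSAP solution must be no worse than identity pairing on any draw
  set.seed(13)
  a <- matrix(rnorm(60), 30, 2)
  b <- matrix(rnorm(60) + 0.5, 30, 2)
  d <- wasserstein_diagnostic(a, b, n_pairs = 1, batch_size = 30, seed = 1)
  set.seed(1)
  ia <- sample.int(30, 30); ib <- sample.int(30, 30)
  cost <- sqrt(outer(rowSums(a[ia, ]^2), rowSums(b[ib, ]^2), `+`) -
                 2 * tcrossprod(a[ia, ], b[ib, ]))
  expect_lte(d, mean(diag(cost)) + 1e-12)
})

test_that("paired t-test matches the closed form", {
  # differences (1, 2, 3): t = mean / (sd / sqrt(n)) = 2 / (1 / sqrt(3))
  out <- paired_ttest(c(2, 4, 6), c(1, 2, 3))
  expect_equal(out$t_statistic, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(out$t_statistic, 3.4641016, tolerance = 1e-6)
  expect_equal(out$df, 2)
  # two-sided p from the t distribution at df = 2
  expect_equal(out$p_value, 2 * (1 - pt(2 * sqrt(3), df = 2)), tolerance = 1e-9)
  # identical scores -> degenerate signal, not an error
  deg <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$t_statistic))
  expect_error(paired_ttest(1, 1), "length")
})

test_that("mask construction and the scan's bookkeeping are sound", {
  design <- tiny_design(channels = 8L)
  masks <- make_channel_masks(design, 4L)
  expect_equal(length(masks), 2L)
  expect_equal(masks$mask1, 1:4)
  expect_equal(anyDuplicated(unlist(masks)), 0L)

  set <- tiny_set(design)
  mc <- tiny_mixer_config(design)
  fit <- structure(list(params = mixer_init(mc, 3), model_config = mc,
                        train_config = NULL, class_set = design$class_set,
                        history = tibble::tibble(), best_epoch = 1L,
                        best_val_loss = NA_real_, stop_reason = "max_epochs"),
                   class = "mixer_fit")
  scan <- channel_mask_scan(fit, set, masks)
  expect_equal(nrow(scan), 2L)
  expect_true(all(c("mask_id", "accuracy", "critical") %in% names(scan)))

  # an empty mask leaves the accuracy unchanged
  scan0 <- channel_mask_scan(fit, set, list(none = integer(0)))
  expect_equal(scan0$accuracy[1], attr(scan0, "unmasked_accuracy"))

  # overlapping masks are rejected
  expect_error(channel_mask_scan(fit, set, list(a = 1:4, b = 4:6)), "disjoint")
  p <- autoplot(scan)
  expect_s3_class(p, "ggplot")
})

test_that("masking everything reduces a trained model to chance", {
  design <- tiny_design(n_subjects = 2L, channels = 4L, window = 2)
  config <- generator_config(design, seed = 31L,
                             class_amplitudes = c(0, 2, 4),
                             informative_channels = 1:4)
  set <- generate_dataset(config)
  idx <- make_split(set, split_spec("trial", k_folds = 4L, seed = 1L), 1L)
  mc <- tiny_mixer_config(design)
  fit <- train_model(subset_epochs(set, idx$train), subset_epochs(set, idx$val),
                     mc, train_config(da_mode = "none", max_epochs = 30L,
                                      patience_epochs = 30L, seed = 32L))
  test_set <- subset_epochs(set, idx$test)
  scan <- channel_mask_scan(fit, test_set, list(all = 1:4))
  # balanced three-class data: chance is 1/3
  expect_lt(abs(scan$accuracy[1] - 1 / 3), 0.2)
  expect_gt(attr(scan, "unmasked_accuracy"), scan$accuracy[1])
})
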