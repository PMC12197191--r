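#' Split specification for cross-validation
#'
#' The scenario decides the atomic unit of splitting: `"trial"` splits on
#' individual epochs, `"block"` on (subject, session, block) units, `"session"`
#' holds out one session of every subject per fold (rotating), `"subject"`
#' holds out whole subjects. No trial of a held-out unit ever appears on the
#' training side.
#'
#' For the subject scenario the per-fold unit counts can be pinned (e.g., 18
#' train / 5 val / 3 test subjects); by default the test share is
#' `n_units / k_folds` rounded, validation is `val_fraction` of the rest.
#'
#' @param scenario `"trial"`, `"block"`, `"session"` or `"subject"`.
#' @param k_folds Number of folds (test units rotate across folds).
#' @param n_train,n_val,n_test Optional explicit unit counts (subject
#'   scenario); must sum to the number of available units.
#' @param val_fraction Fraction of remaining epochs used for validation when
#'   counts are not pinned.
#' @param seed Seed for the unit permutation.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(scenario = c("trial", "block", "session", "subject"),
                       k_folds = 10L, n_train = NULL, n_val = NULL,
                       n_test = NULL, val_fraction = 0.2, seed = 1L) {
  scenario <- match.arg(scenario)
  structure(list(scenario = scenario, k_folds = as.integer(k_folds),
                 n_train = n_train, n_val = n_val, n_test = n_test,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "split_spec")
}

#' Build one fold's train/val/test epoch indices
#'
#' Deterministic given the spec's seed: units are permuted once, then the test
#' slice rotates with the fold number. Units are atomic -- all epochs of a
#' held-out block/session/subject land on the same side.
#'
#' @param set An `epoch_set`.
#' @param spec A [split_spec()].
#' @param fold Fold number in `1..k_folds`.
#' @return List of integer vectors `train`, `val`, `test` (1-based epoch
#'   indices).
#' @export
make_split <- function(set, spec, fold = 1L) {
  stopifnot(inherits(set, "epoch_set"), inherits(spec, "split_spec"))
  if (fold < 1L || fold > spec$k_folds) stop("fold out of range", call. = FALSE)
  meta <- set$meta
  n <- n_epochs(set)
  with_seed <- function(s, expr) {
    saved <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(saved)) assign(".Random.seed", saved, globalenv()))
    set.seed(s)
    expr
  }
  if (spec$scenario == "session") {
    sessions <- sort(unique(meta$session_idx))
    if (length(sessions) < 2L) {
      stop("session scenario needs at least two sessions", call. = FALSE)
    }
    held <- sessions[((fold - 1L) %% length(sessions)) + 1L]
    test <- which(meta$session_idx == held)
    rest <- setdiff(seq_len(n), test)
    val <- with_seed(spec$seed + fold, {
      sample(rest, max(1L, round(spec$val_fraction * length(rest))))
    })
    return(list(train = setdiff(rest, val), val = sort(val), test = sort(test)))
  }

  unit_of <- switch(spec$scenario,
    trial = paste(meta$subject_id, meta$session_idx, meta$block_idx, meta$trial_idx),
    block = paste(meta$subject_id, meta$session_idx, meta$block_idx),
    subject = meta$subject_id
  )
  units <- unique(unit_of)
  n_units <- length(units)
  perm <- with_seed(spec$seed, sample(units))
  n_test <- if (!is.null(spec$n_test)) spec$n_test else max(1L, round(n_units / spec$k_folds))
  if (!is.null(spec$n_train) && !is.null(spec$n_val) && !is.null(spec$n_test)) {
    if (spec$n_train + spec$n_val + spec$n_test != n_units) {
      stop("per-fold counts (", spec$n_train, "+", spec$n_val, "+", spec$n_test,
           ") must sum to the available units (", n_units, ")", call. = FALSE)
    }
  }
  if (n_test >= n_units) stop("not enough units for the requested test size", call. = FALSE)
  # contiguous rotation of the seeded permutation
  start <- ((fold - 1L) * n_test) %% n_units
  pick <- function(from, count) perm[((from + seq_len(count) - 1L) %% n_units) + 1L]
  test_units <- pick(start, n_test)
  if (!is.null(spec$n_val)) {
    val_units <- pick(start + n_test, spec$n_val)
    train_units <- setdiff(perm, c(test_units, val_units))
    test <- which(unit_of %in% test_units)
    val <- which(unit_of %in% val_units)
    train <- which(unit_of %in% train_units)
  } else {
    test <- which(unit_of %in% test_units)
    rest <- setdiff(seq_len(n), test)
    if (spec$scenario == "subject") {
      rest_units <- setdiff(perm, test_units)
      n_val_units <- max(1L, round(spec$val_fraction * length(rest_units)))
      val_units <- pick(start + n_test, n_val_units)
      val <- which(unit_of %in% val_units)
      train <- setdiff(rest, val)
    } else {
      val <- with_seed(spec$seed + fold, {
        sort(sample(rest, max(1L, round(spec$val_fraction * length(rest)))))
      })
      train <- setdiff(rest, val)
    }
  }
  list(train = sort(train), val = sort(val), test = sort(test))
}

#' Accuracy, macro F1 and per-class precision/recall
#'
#' Macro F1 is the unweighted mean of per-class F1 scores over the label
#' classes; a class absent from `labels` contributes an F1 of 0 and is
#' flagged.
#'
#' @param predictions,labels Equal-length vectors of class labels (any common
#'   coding).
#' @param class_set Classes to score over (default: classes observed in
#'   `labels`).
#' @return A list of class `metrics_report`: `accuracy`, `macro_f1`,
#'   `per_class` tibble, `n_test`, `flagged_classes`.
#' @export
evaluate_metrics <- function(predictions, labels, class_set = NULL) {
  if (length(predictions) != length(labels) || length(labels) == 0L) {
    stop("predictions and labels must be aligned and nonempty", call. = FALSE)
  }
  if (is.null(class_set)) class_set <- sort(unique(labels))
  per <- lapply(class_set, function(cl) {
    tp <- sum(predictions == cl & labels == cl)
    fp <- sum(predictions == cl & labels != cl)
    fn <- sum(predictions != cl & labels == cl)
    support <- sum(labels == cl)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    tibble::tibble(class = cl, precision = precision, recall = recall,
                   f1 = f1, support = support)
  })
  per <- dplyr::bind_rows(per)
  flagged <- per$class[per$support == 0L]
  structure(list(
    accuracy = mean(predictions == labels),
    macro_f1 = mean(per$f1),
    per_class = per,
    n_test = length(labels),
    flagged_classes = flagged
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("accuracy ", sprintf("%.4f", x$accuracy), ", macro F1 ",
      sprintf("%.4f", x$macro_f1), " (n = ", x$n_test, ")\n", sep = "")
  invisible(x)
}

#' Mean mini-batch Wasserstein distance between two feature sets
#'
#' Draws `n_pairs` seeded mini-batch pairs (one batch from each set, equal
#' size, uniform weights) and averages the exact optimal-transport cost under
#' the Euclidean ground metric. With equal-size uniform batches exact OT is an
#' assignment problem, solved exactly. Used as a train/test distribution-shift
#' diagnostic: larger values mean the classifier faces a larger shift.
#'
#' @param train_feats,test_feats Feature matrices or [feature_batch()]s.
#' @param n_pairs Number of mini-batch pairs to average over.
#' @param batch_size Samples per mini-batch (must not exceed either set).
#' @param seed Seed for the batch draws.
#' @return Scalar mean Wasserstein-1 distance (mean per-sample transport
#'   cost).
#' @export
wasserstein_diagnostic <- function(train_feats, test_feats, n_pairs = 50L,
                                   batch_size = 64L, seed = 1L) {
  a <- as_feature_batch(train_feats)$features
  b <- as_feature_batch(test_feats)$features
  if (batch_size > nrow(a) || batch_size > nrow(b)) {
    stop("batch_size exceeds the available samples", call. = FALSE)
  }
  set.seed(as.integer(seed))
  total <- 0
  for (p in seq_len(n_pairs)) {
    ia <- sample.int(nrow(a), batch_size)
    ib <- sample.int(nrow(b), batch_size)
    cost <- sqrt(cross_sqdist(a[ia, , drop = FALSE], b[ib, , drop = FALSE]))
    if (batch_size == 1L) {
      total <- total + cost[1, 1]
    } else {
      assignment <- clue::solve_LSAP(cost)
      total <- total + mean(cost[cbind(seq_len(batch_size), assignment)])
    }
  }
  total / n_pairs
}

#' Classical paired t-test on per-fold scores
#'
#' @param scores_a,scores_b Equal-length numeric vectors (length >= 2), e.g.
#'   per-fold F1 of two training regimes.
#' @return Tibble: `t_statistic`, `p_value` (two-sided, df = k - 1),
#'   `mean_diff`, `df`, `degenerate` (TRUE when the differences have zero
#'   variance, in which case t and p are NA).
#' @export
paired_ttest <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b) || length(scores_a) < 2L) {
    stop("need equal-length score vectors of length >= 2", call. = FALSE)
  }
  d <- scores_a - scores_b
  if (stats::sd(d) == 0) {
    return(tibble::tibble(t_statistic = NA_real_, p_value = NA_real_,
                          mean_diff = mean(d), df = length(d) - 1L,
                          degenerate = TRUE))
  }
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE)
  tibble::tibble(t_statistic = unname(tt$statistic),
                 p_value = tt$p.value, mean_diff = mean(d),
                 df = unname(tt$parameter), degenerate = FALSE)
}

#' Disjoint channel masks for the importance scan
#'
#' Consecutive groups of `channels_per_mask` spatial channels; trailing
#' channels that do not fill a mask are left uncovered.
#'
#' @param design An [experiment_design()].
#' @param channels_per_mask Spatial channels per mask (default 4).
#' @return Named list of 1-based channel index vectors.
#' @export
make_channel_masks <- function(design, channels_per_mask = 4L) {
  n_masks <- design$n_spatial_channels %/% channels_per_mask
  if (n_masks < 1L) stop("fewer channels than one mask", call. = FALSE)
  masks <- lapply(seq_len(n_masks), function(i) {
    ((i - 1L) * channels_per_mask + 1L):(i * channels_per_mask)
  })
  names(masks) <- paste0("mask", seq_len(n_masks))
  masks
}

#' Channel-masking importance scan
#'
#' Applies one mask at a time -- zeroing every feature column of the masked
#' spatial channels -- and measures test accuracy. A mask is flagged critical
#' when its masked accuracy falls below the lower bound of the 95% t-interval
#' for the mean of the per-mask accuracies: those channels carry information
#' the classifier cannot do without.
#'
#' @param fit A `mixer_fit`.
#' @param test_set An `epoch_set`.
#' @param masks List of disjoint 1-based spatial channel index vectors (see
#'   [make_channel_masks()]).
#' @return An object of class `mask_scan`: tibble of per-mask accuracies with
#'   attributes `unmasked_accuracy`, `ci_lower`, `ci_upper`, `mask_mean`,
#'   `critical_masks`.
#' @export
channel_mask_scan <- function(fit, test_set, masks) {
  stopifnot(inherits(fit, "mixer_fit"), inherits(test_set, "epoch_set"))
  design <- test_set$design
  flat <- unlist(masks)
  if (anyDuplicated(flat)) stop("masks must cover disjoint channels", call. = FALSE)
  if (length(flat) > 0 && (min(flat) < 1L || max(flat) > design$n_spatial_channels)) {
    stop("mask channel index out of range", call. = FALSE)
  }
  labels <- test_set$meta$label
  acc_of <- function(data) {
    pred <- predict(fit, data)
    mean(pred == labels)
  }
  unmasked <- acc_of(test_set$data)
  rows <- lapply(seq_along(masks), function(i) {
    cols <- channel_feature_columns(design, masks[[i]])
    data <- test_set$data
    if (length(cols) > 0) data[, , cols] <- 0
    tibble::tibble(
      mask_id = if (!is.null(names(masks))) names(masks)[i] else paste0("mask", i),
      channels = list(masks[[i]]),
      accuracy = acc_of(data)
    )
  })
  res <- dplyr::bind_rows(rows)
  m <- nrow(res)
  mask_mean <- mean(res$accuracy)
  half <- if (m >= 2L) {
    stats::qt(0.975, df = m - 1L) * stats::sd(res$accuracy) / sqrt(m)
  } else {
    Inf
  }
  ci <- c(mask_mean - half, mask_mean + half)
  res$critical <- res$accuracy < ci[1]
  structure(res, class = c("mask_scan", class(res)),
            unmasked_accuracy = unmasked, mask_mean = mask_mean,
            ci_lower = ci[1], ci_upper = ci[2],
            critical_masks = res$mask_id[res$critical])
}

#' @export
print.mask_scan <- function(x, ...) {
  cat("<mask_scan> unmasked accuracy ",
      sprintf("%.4f", attr(x, "unmasked_accuracy")),
      "; 95% CI of masked accuracies [",
      sprintf("%.4f", attr(x, "ci_lower")), ", ",
      sprintf("%.4f", attr(x, "ci_upper")), "]\n", sep = "")
  critical <- attr(x, "critical_masks")
  cat("critical masks: ",
      if (length(critical)) paste(critical, collapse = ", ") else "none",
      "\n", sep = "")
  NextMethod()
}
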