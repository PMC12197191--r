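#' Training configuration
#'
#' @param learning_rate Adam step size (Adam is used with its default moment
#'   parameters beta1 = 0.9, beta2 = 0.999).
#' @param dropout_ratio Dropout applied to MLP block outputs during training
#'   (overrides the model config when not `NULL`).
#' @param alpha Weight of the discrepancy penalty in the objective
#'   `l = l_ce + alpha (D_cdd + D_BWise)`.
#' @param da_mode `"none"` for plain cross-entropy training, else the domain
#'   axis (`"subject"`, `"session"`, `"block"`) used for paired sampling.
#' @param batch_size Nominal epochs per step (sets steps per epoch).
#' @param n_domain_pairs,samples_per_class_per_side Paired-batch composition
#'   for DA modes.
#' @param patience_epochs Early stopping: stop when the evaluation loss has
#'   not improved for this many consecutive epochs.
#' @param max_epochs Hard cap on epochs.
#' @param kernel A [kernel_spec()] for the discrepancy terms.
#' @param seed Seed controlling initialization, batch order and dropout.
#' @param cdd_weight,bwise_weight Term-ablation weights inside the penalty:
#'   the objective becomes `l_ce + alpha (w_cdd D_cdd + w_bw D_BWise)`. The
#'   standard objective uses 1 for both; setting one to 0 isolates the other
#'   term's contribution.
#' @param force_zero_discrepancy Debug switch: run the DA pipeline but force
#'   `D_cdd = D_BWise = 0` (their gradients vanish); the trajectory must then
#'   match `alpha = 0` exactly.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, dropout_ratio = NULL,
                         alpha = 1, da_mode = c("none", "subject", "session", "block"),
                         batch_size = 32L, n_domain_pairs = 4L,
                         samples_per_class_per_side = 4L,
                         patience_epochs = 50L, max_epochs = 500L,
                         kernel = kernel_spec(), seed = 1L,
                         cdd_weight = 1, bwise_weight = 1,
                         force_zero_discrepancy = FALSE) {
  da_mode <- match.arg(da_mode)
  stopifnot(learning_rate > 0, patience_epochs >= 1, max_epochs >= 1)
  structure(list(
    learning_rate = learning_rate, dropout_ratio = dropout_ratio,
    alpha = alpha, da_mode = da_mode, batch_size = as.integer(batch_size),
    n_domain_pairs = as.integer(n_domain_pairs),
    samples_per_class_per_side = as.integer(samples_per_class_per_side),
    patience_epochs = as.integer(patience_epochs),
    max_epochs = as.integer(max_epochs), kernel = kernel,
    seed = as.integer(seed), cdd_weight = cdd_weight,
    bwise_weight = bwise_weight,
    force_zero_discrepancy = force_zero_discrepancy
  ), class = "train_config")
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# D_cdd and (for block/session modes) D_BWise of one paired batch, with
# gradients w.r.t. the feature rows of `feats` (rows indexed by all_idx).
#
# D_cdd is computed once over the union of the source halves vs the union of
# the target halves: with single-condition blocks any one pair holds a single
# shared class, so only the pooled domains expose both the intra-class and
# the inter-class terms of the contrastive discrepancy. D_BWise stays
# per-pair (same-class MMD between the two paired domains), averaged.
paired_batch_losses <- function(pb, feats, all_idx, da_mode, kernel) {
  d_feat_cdd <- matrix(0, nrow(feats), ncol(feats))
  d_feat_bw <- matrix(0, nrow(feats), ncol(feats))
  bw_sum <- 0; bw_n <- 0L
  src_pos_all <- integer(0); tgt_pos_all <- integer(0)
  src_lab_all <- integer(0); tgt_lab_all <- integer(0)
  for (pair in pb$pairs) {
    src_pos <- match(pair$source_idx, all_idx)
    tgt_pos <- match(pair$target_idx, all_idx)
    src_pos_all <- c(src_pos_all, src_pos)
    tgt_pos_all <- c(tgt_pos_all, tgt_pos)
    src_lab_all <- c(src_lab_all, pair$source_labels)
    tgt_lab_all <- c(tgt_lab_all, pair$target_labels)
    if (da_mode %in% c("block", "session")) {
      fs <- feats[src_pos, , drop = FALSE]
      ft <- feats[tgt_pos, , drop = FALSE]
      bw <- bwise_batch_with_grad(fs, pair$source_labels, ft,
                                  pair$target_labels, spec = kernel)
      if (!is.na(bw$value)) {
        bw_sum <- bw_sum + bw$value; bw_n <- bw_n + 1L
        d_feat_bw[src_pos, ] <- d_feat_bw[src_pos, ] + bw$d_a
        d_feat_bw[tgt_pos, ] <- d_feat_bw[tgt_pos, ] + bw$d_b
      }
    }
  }
  d_cdd <- 0
  term <- tryCatch(
    cdd_with_grad(feature_batch(feats[src_pos_all, , drop = FALSE], src_lab_all),
                  feature_batch(feats[tgt_pos_all, , drop = FALSE], tgt_lab_all),
                  spec = kernel),
    error = function(e) NULL # batch without both term kinds: skip
  )
  if (!is.null(term)) {
    d_cdd <- term$value
    # scatter-add union grads back to the (possibly repeated) feature rows
    for (r in seq_along(src_pos_all)) {
      d_feat_cdd[src_pos_all[r], ] <- d_feat_cdd[src_pos_all[r], ] +
        term$d_source[r, ]
    }
    for (r in seq_along(tgt_pos_all)) {
      d_feat_cdd[tgt_pos_all[r], ] <- d_feat_cdd[tgt_pos_all[r], ] +
        term$d_target[r, ]
    }
  }
  list(d_cdd = d_cdd,
       d_bwise = if (bw_n > 0L) bw_sum / bw_n else 0,
       d_feat_cdd = d_feat_cdd,
       d_feat_bwise = if (bw_n > 0L) d_feat_bw / bw_n else d_feat_bw)
}

#' Fit the mixer, optionally with domain-adaptive discrepancy penalties
#'
#' Minimizes `l = l_ce + alpha (D_cdd + D_BWise)` by Adam over mini-batches.
#' In DA modes every step draws a paired batch ([build_paired_batch()]);
#' cross-entropy is computed on both halves, the contrastive domain
#' discrepancy between the halves, and (block/session modes) the block-wise
#' term between same-class samples of the two domains. Gradients flow through
#' the encoder features for all discrepancy terms; kernel bandwidths are
#' treated as data-dependent constants.
#'
#' Early stopping monitors the full objective on the validation split (same
#' pairing scheme, evaluated on a deterministic per-epoch draw; plain
#' cross-entropy when pairing is impossible) and restores the best-epoch
#' parameters.
#'
#' @param train_set,val_set `epoch_set` objects; `val_set` must be nonempty.
#' @param model_config A [mixer_config()] (see [mixer_config_for()]).
#' @param config A [train_config()].
#' @return An object of class `mixer_fit`.
#' @export
train_model <- function(train_set, val_set, model_config, config = train_config()) {
  stopifnot(inherits(train_set, "epoch_set"), inherits(val_set, "epoch_set"))
  if (n_epochs(val_set) == 0L) stop("val set must be nonempty", call. = FALSE)
  class_set <- train_set$design$class_set
  if (!is.null(config$dropout_ratio)) {
    model_config$dropout_ratio <- config$dropout_ratio
  }
  y_train <- encode_labels(train_set$meta$label, class_set)
  y_val <- encode_labels(val_set$meta$label, class_set)
  n_train <- n_epochs(train_set)

  params <- mixer_init(model_config, seed = config$seed)
  state <- adam_state(params)
  partition <- NULL
  val_partition <- NULL
  if (config$da_mode != "none") {
    partition <- partition_domains(train_set, config$da_mode)
    val_partition <- tryCatch(partition_domains(val_set, config$da_mode),
                              error = function(e) NULL)
  }
  use_da_loss <- config$da_mode != "none" && config$alpha > 0 &&
    !config$force_zero_discrepancy
  steps_per_epoch <- max(1L, ceiling(n_train / config$batch_size))
  objective <- objective_config(config$alpha, config$kernel,
                                if (config$da_mode == "none") "none" else config$da_mode)

  set.seed(config$seed + 1L)
  history <- vector("list", config$max_epochs)
  best <- list(loss = Inf, epoch = 0L, params = params)
  stop_reason <- "max_epochs"

  for (epoch in seq_len(config$max_epochs)) {
    tr_ce <- 0; tr_cdd <- 0; tr_bw <- 0
    if (config$da_mode == "none") perm <- sample.int(n_train)
    for (step in seq_len(steps_per_epoch)) {
      if (config$da_mode == "none") {
        lo <- (step - 1L) * config$batch_size + 1L
        hi <- min(step * config$batch_size, n_train)
        all_idx <- perm[lo:hi]
        pb <- NULL
      } else {
        pb <- build_paired_batch(partition, train_set, config$n_domain_pairs,
                                 config$samples_per_class_per_side)
        all_idx <- unique(unlist(lapply(pb$pairs, function(p) {
          c(p$source_idx, p$target_idx)
        })))
      }
      x <- train_set$data[all_idx, , , drop = FALSE]
      fwd <- mixer_forward(x, model_config, params, mode = "both",
                           training = TRUE, keep_cache = TRUE)
      ce <- cross_entropy(fwd$logits, y_train[all_idx], want_grad = TRUE)
      d_feat <- NULL
      d_cdd <- 0; d_bw <- 0
      if (use_da_loss) {
        losses <- paired_batch_losses(pb, fwd$features, all_idx,
                                      config$da_mode, config$kernel)
        d_cdd <- config$cdd_weight * losses$d_cdd
        d_bw <- if (config$da_mode == "subject") 0 else
          config$bwise_weight * losses$d_bwise
        d_feat <- config$alpha * (config$cdd_weight * losses$d_feat_cdd +
                                    config$bwise_weight * losses$d_feat_bwise)
      }
      total <- ce$value + config$alpha * (d_cdd + d_bw)
      if (!is.finite(total)) {
        stop("training diverged at epoch ", epoch, " (ce=", signif(ce$value, 4),
             ", d_cdd=", signif(d_cdd, 4), ", d_bwise=", signif(d_bw, 4), ")",
             call. = FALSE)
      }
      grads <- mixer_backward(model_config, params, fwd$cache,
                              d_logits = ce$grad, d_features = d_feat)
      upd <- adam_step(params, grads, state, config$learning_rate)
      params <- upd$params; state <- upd$state
      tr_ce <- tr_ce + ce$value; tr_cdd <- tr_cdd + d_cdd; tr_bw <- tr_bw + d_bw
    }

    val <- local({ # evaluate without consuming the training RNG stream
      saved <- .Random.seed
      on.exit(assign(".Random.seed", saved, envir = globalenv()))
      set.seed((config$seed + 97L * epoch) %% 2147483647L)
      evaluate_epoch(val_set, y_val, model_config, params, config,
                     val_partition, use_da_loss)
    })
    history[[epoch]] <- tibble::tibble(
      epoch = epoch,
      train_ce = tr_ce / steps_per_epoch,
      train_d_cdd = tr_cdd / steps_per_epoch,
      train_d_bwise = tr_bw / steps_per_epoch,
      train_loss = (tr_ce + config$alpha * (tr_cdd + tr_bw)) / steps_per_epoch,
      val_ce = val$ce, val_d_cdd = val$d_cdd, val_d_bwise = val$d_bwise,
      val_loss = val$loss, val_accuracy = val$accuracy, val_macro_f1 = val$macro_f1
    )
    if (val$loss < best$loss - 1e-12) {
      best <- list(loss = val$loss, epoch = epoch, params = params)
    }
    if (epoch - best$epoch >= config$patience_epochs) {
      stop_reason <- "early_stop"
      history <- history[seq_len(epoch)]
      break
    }
  }
  history <- dplyr::bind_rows(history)
  structure(list(
    params = best$params, model_config = model_config, train_config = config,
    class_set = class_set, history = history, best_epoch = best$epoch,
    best_val_loss = best$loss, stop_reason = stop_reason
  ), class = "mixer_fit")
}

# Validation objective + metrics for one epoch.
evaluate_epoch <- function(val_set, y_val, model_config, params, config,
                           val_partition, use_da_loss) {
  logits <- predict_logits(val_set$data, model_config, params)
  ce <- cross_entropy(logits, y_val)$value
  d_cdd <- 0; d_bw <- 0
  pb <- NULL
  if (use_da_loss && !is.null(val_partition)) {
    pb <- tryCatch(
      build_paired_batch(val_partition, val_set, config$n_domain_pairs,
                         config$samples_per_class_per_side),
      error = function(e) NULL) # pairing impossible on val: plain CE
  }
  if (!is.null(pb)) {
    all_idx <- unique(unlist(lapply(pb$pairs, function(p) {
      c(p$source_idx, p$target_idx)
    })))
    feats <- mixer_forward(val_set$data[all_idx, , , drop = FALSE],
                           model_config, params, mode = "features")
    losses <- paired_batch_losses(pb, feats, all_idx, config$da_mode,
                                  config$kernel)
    d_cdd <- config$cdd_weight * losses$d_cdd
    d_bw <- if (config$da_mode == "subject") 0 else
      config$bwise_weight * losses$d_bwise
  }
  pred <- max.col(logits, ties.method = "first")
  metrics <- evaluate_metrics(pred, y_val)
  list(ce = ce, d_cdd = d_cdd, d_bwise = d_bw,
       loss = ce + config$alpha * (d_cdd + d_bw),
       accuracy = metrics$accuracy, macro_f1 = metrics$macro_f1)
}

predict_logits <- function(data, model_config, params, chunk = 1024L) {
  n <- dim(data)[1]
  out <- NULL
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    block <- mixer_forward(data[lo:hi, , , drop = FALSE], model_config, params)
    out <- rbind(out, block)
  }
  out
}

#' Predict classes, probabilities or features from a fitted mixer
#'
#' @param object A `mixer_fit`.
#' @param newdata An `epoch_set` or `[n x T x F]` array.
#' @param type `"class"` (labels from the training class set), `"prob"`
#'   (softmax matrix) or `"feature"` (pooled encoder features).
#' @param ... Unused.
#' @return Vector, matrix, or feature matrix accordingly.
#' @export
predict.mixer_fit <- function(object, newdata, type = c("class", "prob", "feature"),
                              ...) {
  type <- match.arg(type)
  data <- if (inherits(newdata, "epoch_set")) newdata$data else newdata
  if (type == "feature") {
    return(mixer_forward(data, object$model_config, object$params,
                         mode = "features"))
  }
  logits <- predict_logits(data, object$model_config, object$params)
  if (type == "prob") {
    z <- logits - apply(logits, 1, max)
    p <- exp(z) / rowSums(exp(z))
    colnames(p) <- object$class_set
    return(p)
  }
  object$class_set[max.col(logits, ties.method = "first")]
}

#' @export
print.mixer_fit <- function(x, ...) {
  counts <- count_parameters_and_macs(x$model_config)
  cat("<mixer_fit> ", counts$parameters, " parameters, da_mode=",
      x$train_config$da_mode, ", alpha=", x$train_config$alpha, "\n", sep = "")
  cat("  stopped after ", nrow(x$history), " epochs (", x$stop_reason,
      "), best epoch ", x$best_epoch, " (val loss ",
      signif(x$best_val_loss, 5), ")\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fitted mixer
#' @param x A `mixer_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch (losses, discrepancies, val metrics).
#' @method tidy mixer_fit
#' @export
tidy.mixer_fit <- function(x, ...) x$history

#' One-row summary of a fitted mixer
#' @param x A `mixer_fit`.
#' @param ... Unused.
#' @return Tibble: epochs run, best epoch, best val loss/accuracy/F1,
#'   parameter count.
#' @method glance mixer_fit
#' @export
glance.mixer_fit <- function(x, ...) {
  counts <- count_parameters_and_macs(x$model_config)
  best_row <- x$history[x$history$epoch == x$best_epoch, ]
  tibble::tibble(
    epochs = nrow(x$history), best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    val_accuracy = if (nrow(best_row)) best_row$val_accuracy else NA_real_,
    val_macro_f1 = if (nrow(best_row)) best_row$val_macro_f1 else NA_real_,
    parameters = counts$parameters, stop_reason = x$stop_reason
  )
}

#' Grid search over learning rate, dropout and alpha
#'
#' Trains every grid combination on every fold and selects the configuration
#' with the highest mean validation accuracy. Ties break toward the lower
#' learning rate, then lower dropout, then lower alpha.
#'
#' @param model_config A [mixer_config()].
#' @param folds List of folds, each a list with `train` and `val` epoch sets.
#' @param grids List with numeric vectors `learning_rate`, `dropout_ratio`,
#'   `alpha` (defaults: the standard 4 x 4 rate/dropout grid and alpha fixed
#'   at 1).
#' @param base_config A [train_config()] supplying all other settings.
#' @return List with `best` (a `train_config`) and `results` (tibble of
#'   config x fold accuracies plus per-config means).
#' @export
grid_search <- function(model_config, folds,
                        grids = list(learning_rate = c(1e-4, 1e-3, 1e-2, 1e-1),
                                     dropout_ratio = c(0, 0.25, 0.5, 0.75),
                                     alpha = 1),
                        base_config = train_config()) {
  stopifnot(length(folds) >= 1, length(grids) >= 1)
  grid <- expand.grid(learning_rate = grids$learning_rate,
                      dropout_ratio = grids$dropout_ratio,
                      alpha = grids$alpha, KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    for (f in seq_along(folds)) {
      cfg <- base_config
      cfg$learning_rate <- grid$learning_rate[i]
      cfg$dropout_ratio <- grid$dropout_ratio[i]
      cfg$alpha <- grid$alpha[i]
      fit <- train_model(folds[[f]]$train, folds[[f]]$val, model_config, cfg)
      g <- glance(fit)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        learning_rate = cfg$learning_rate, dropout_ratio = cfg$dropout_ratio,
        alpha = cfg$alpha, fold = f, val_accuracy = g$val_accuracy,
        val_macro_f1 = g$val_macro_f1
      )
    }
  }
  results <- dplyr::bind_rows(rows)
  summary <- results |>
    dplyr::group_by(learning_rate, dropout_ratio, alpha) |>
    dplyr::summarise(mean_val_accuracy = mean(val_accuracy), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(mean_val_accuracy), learning_rate,
                   dropout_ratio, alpha)
  best_cfg <- base_config
  best_cfg$learning_rate <- summary$learning_rate[1]
  best_cfg$dropout_ratio <- summary$dropout_ratio[1]
  best_cfg$alpha <- summary$alpha[1]
  list(best = best_cfg, results = results, summary = summary)
}
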