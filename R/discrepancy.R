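#' Bundle encoder features with labels and domain keys
#'
#' The operand of every discrepancy: a matrix of encoder outputs (one row per
#' epoch) plus the epoch labels and the subject/session/block keys needed to
#' check domain constraints.
#'
#' @param features Numeric matrix `[n x C]`.
#' @param labels Integer vector of class labels (length `n`), or `NULL`.
#' @param subject_id,session_idx,block_idx Optional domain keys (length `n` or
#'   scalar, recycled).
#' @return An object of class `feature_batch`.
#' @export
feature_batch <- function(features, labels = NULL, subject_id = NULL,
                          session_idx = NULL, block_idx = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 1L) stop("feature_batch needs at least one sample", call. = FALSE)
  recycle <- function(v) {
    if (is.null(v)) return(NULL)
    if (length(v) == 1L) v <- rep(v, n)
    if (length(v) != n) stop("key length must match feature rows", call. = FALSE)
    v
  }
  structure(list(features = features,
                 labels = if (!is.null(labels)) as.integer(recycle(labels)) else NULL,
                 subject_id = recycle(subject_id),
                 session_idx = recycle(session_idx),
                 block_idx = recycle(block_idx)),
            class = "feature_batch")
}

as_feature_batch <- function(x) {
  if (inherits(x, "feature_batch")) return(x)
  feature_batch(x)
}

#' Biased maximum mean discrepancy between two feature batches
#'
#' The V-statistic (self-pairs included) estimate of the squared RKHS distance
#' between the mean embeddings of two samples:
#' `1/ns^2 sum k(s,s') + 1/nt^2 sum k(t,t') - 2/(ns nt) sum k(s,t)`.
#' The standard `2/(ns nt)` cross-term normalization is used by default;
#' `cross_term = "ns2nt2"` divides the cross term by `ns^2 nt^2` instead, which
#' is not scale-consistent with the first two terms and is provided only for
#' comparison.
#'
#' @param source,target Feature matrices or [feature_batch()] objects.
#' @param spec A [kernel_spec()]; median-heuristic bandwidths are resolved on
#'   the pooled rows of both batches.
#' @param cross_term `"standard"` or `"ns2nt2"`.
#' @return Scalar discrepancy, `>= 0` up to float tolerance (standard form).
#' @export
mmd <- function(source, target, spec = kernel_spec(),
                cross_term = c("standard", "ns2nt2")) {
  mmd_with_grad(source, target, spec, match.arg(cross_term),
                want_grad = FALSE)$value
}

# MMD plus d(value)/d(features) of both batches (used by training).
mmd_with_grad <- function(source, target, spec = kernel_spec(),
                          cross_term = "standard", want_grad = TRUE,
                          bandwidths = NULL) {
  fs <- as_feature_batch(source)$features
  ft <- as_feature_batch(target)$features
  ns <- nrow(fs); nt <- nrow(ft)
  if (ns < 1L || nt < 1L) stop("mmd needs nonempty batches", call. = FALSE)
  if (is.null(bandwidths)) bandwidths <- resolve_bandwidths(spec, rbind(fs, ft))
  kss <- gaussian_kernel_pair(fs, fs, bandwidths)
  ktt <- gaussian_kernel_pair(ft, ft, bandwidths)
  kst <- gaussian_kernel_pair(fs, ft, bandwidths)
  c_st <- if (identical(cross_term, "standard")) 2 / (ns * nt) else 2 / (ns^2 * nt^2)
  value <- sum(kss$k) / ns^2 + sum(ktt$k) / nt^2 - c_st * sum(kst$k)
  if (!want_grad) return(list(value = value))
  # within-set terms: symmetric, so gradient doubles
  gs <- weighted_kernel_grad(kss$g / ns^2, fs, fs)
  gt <- weighted_kernel_grad(ktt$g / nt^2, ft, ft)
  gc <- weighted_kernel_grad(kst$g * c_st, fs, ft)
  list(value = value,
       d_source = gs$dx + gs$dy - gc$dx,
       d_target = gt$dx + gt$dy - gc$dy)
}

#' Class-aware discrepancy between two domains
#'
#' The class-conditional two-sample discrepancy
#' `D_{c1,c2} = e1 + e2 - 2 e3`, where `e1` is the mask-normalized mean kernel
#' over source pairs of class `c1`, `e2` over target pairs of class `c2`, and
#' `e3` the cross-domain mean kernel over `(c1, c2)` pairs. With `c1 == c2` it
#' measures intra-class cross-domain discrepancy; with `c1 != c2` it measures
#' how close together the two different classes sit across domains.
#'
#' @param source,target [feature_batch()] objects with labels.
#' @param c1,c2 Class labels selecting the source and target masks.
#' @param spec A [kernel_spec()].
#' @param bandwidths Optional pre-resolved bandwidths.
#' @return A list with `value` and a `report` tibble holding `e1`, `e2`, `e3`
#'   and the per-domain class counts.
#' @export
class_aware_discrepancy <- function(source, target, c1, c2,
                                    spec = kernel_spec(), bandwidths = NULL) {
  out <- cad_with_grad(source, target, c1, c2, spec, bandwidths,
                       want_grad = FALSE)
  list(value = out$value, report = out$report)
}

cad_with_grad <- function(source, target, c1, c2, spec = kernel_spec(),
                          bandwidths = NULL, want_grad = TRUE) {
  source <- as_feature_batch(source); target <- as_feature_batch(target)
  if (is.null(source$labels) || is.null(target$labels)) {
    stop("class-aware discrepancy needs labeled batches", call. = FALSE)
  }
  is1 <- which(source$labels == c1)
  is2 <- which(target$labels == c2)
  if (length(is1) == 0L || length(is2) == 0L) {
    stop("undefined class term: class ", c1, " has ", length(is1),
         " source samples and class ", c2, " has ", length(is2),
         " target samples", call. = FALSE)
  }
  fs <- source$features; ft <- target$features
  if (is.null(bandwidths)) bandwidths <- resolve_bandwidths(spec, rbind(fs, ft))
  x1 <- fs[is1, , drop = FALSE]
  x2 <- ft[is2, , drop = FALSE]
  k11 <- gaussian_kernel_pair(x1, x1, bandwidths)
  k22 <- gaussian_kernel_pair(x2, x2, bandwidths)
  k12 <- gaussian_kernel_pair(x1, x2, bandwidths)
  n1 <- length(is1); n2 <- length(is2)
  e1 <- sum(k11$k) / n1^2
  e2 <- sum(k22$k) / n2^2
  e3 <- sum(k12$k) / (n1 * n2)
  value <- e1 + e2 - 2 * e3
  report <- tibble::tibble(c1 = c1, c2 = c2, e1 = e1, e2 = e2, e3 = e3,
                           n_source = n1, n_target = n2, value = value)
  if (!want_grad) return(list(value = value, report = report))
  d_source <- matrix(0, nrow(fs), ncol(fs))
  d_target <- matrix(0, nrow(ft), ncol(ft))
  g1 <- weighted_kernel_grad(k11$g / n1^2, x1, x1)
  g2 <- weighted_kernel_grad(k22$g / n2^2, x2, x2)
  g3 <- weighted_kernel_grad(k12$g * 2 / (n1 * n2), x1, x2)
  d_source[is1, ] <- g1$dx + g1$dy - g3$dx
  d_target[is2, ] <- g2$dx + g2$dy - g3$dy
  list(value = value, report = report,
       d_source = d_source, d_target = d_target)
}

#' Contrastive domain discrepancy between two labeled domains
#'
#' Averages the intra-class terms and subtracts the average of the inter-class
#' terms of [class_aware_discrepancy()]:
#' `D_cdd = mean_c D_cc - mean_{c != c'} D_cc'`. Minimizing it pulls same-class
#' samples of the two domains together while pushing different classes apart.
#'
#' Class terms whose mask is empty in either domain are skipped and the
#' normalizing counts reduced to the number of computed terms (mini-batches
#' routinely miss a class); at least one intra- and one inter-class term must
#' be computable.
#'
#' @param source,target [feature_batch()] objects with labels.
#' @param class_set Integer vector of classes to consider (default: union of
#'   observed labels). Must contain at least two classes.
#' @param spec A [kernel_spec()]; bandwidths are resolved once on the pooled
#'   batches and shared by every class term.
#' @return A list with `value`, the per-term `report` tibble, and the counts
#'   of intra/inter terms used.
#' @export
cdd <- function(source, target, class_set = NULL, spec = kernel_spec()) {
  out <- cdd_with_grad(source, target, class_set, spec, want_grad = FALSE)
  out[c("value", "report", "n_intra", "n_inter")]
}

cdd_with_grad <- function(source, target, class_set = NULL,
                          spec = kernel_spec(), want_grad = TRUE) {
  source <- as_feature_batch(source); target <- as_feature_batch(target)
  if (is.null(class_set)) {
    class_set <- sort(union(source$labels, target$labels))
  }
  m <- length(class_set)
  if (m < 2L) stop("cdd needs at least two classes", call. = FALSE)
  bandwidths <- resolve_bandwidths(spec, rbind(source$features, target$features))
  src_classes <- class_set[class_set %in% source$labels]
  tgt_classes <- class_set[class_set %in% target$labels]

  reports <- list()
  intra_sum <- 0; n_intra <- 0L
  inter_sum <- 0; n_inter <- 0L
  zeros_s <- matrix(0, nrow(source$features), ncol(source$features))
  zeros_t <- matrix(0, nrow(target$features), ncol(target$features))
  d_src_intra <- zeros_s; d_tgt_intra <- zeros_t
  d_src_inter <- zeros_s; d_tgt_inter <- zeros_t
  for (c1 in src_classes) {
    for (c2 in tgt_classes) {
      term <- cad_with_grad(source, target, c1, c2, bandwidths = bandwidths,
                            want_grad = want_grad)
      kind <- if (c1 == c2) "intra" else "inter"
      reports[[length(reports) + 1L]] <-
        dplyr::mutate(term$report, kind = kind)
      if (c1 == c2) {
        intra_sum <- intra_sum + term$value; n_intra <- n_intra + 1L
        if (want_grad) {
          d_src_intra <- d_src_intra + term$d_source
          d_tgt_intra <- d_tgt_intra + term$d_target
        }
      } else {
        inter_sum <- inter_sum + term$value; n_inter <- n_inter + 1L
        if (want_grad) {
          d_src_inter <- d_src_inter + term$d_source
          d_tgt_inter <- d_tgt_inter + term$d_target
        }
      }
    }
  }
  if (n_intra == 0L || n_inter == 0L) {
    stop("cdd undefined: needs at least one intra-class and one inter-class ",
         "term with support in both domains", call. = FALSE)
  }
  value <- intra_sum / n_intra - inter_sum / n_inter
  out <- list(value = value, report = dplyr::bind_rows(reports),
              n_intra = n_intra, n_inter = n_inter)
  if (want_grad) {
    out$d_source <- d_src_intra / n_intra - d_src_inter / n_inter
    out$d_target <- d_tgt_intra / n_intra - d_tgt_inter / n_inter
  }
  out
}

#' Block-wise discrepancy between two blocks for one class
#'
#' The biased MMD of [mmd()] restricted to the class-`c` samples of two blocks
#' recorded in the same session of the same subject. Minimizing it during
#' training aligns the conditional distributions of the two blocks.
#'
#' @param block_a,block_b [feature_batch()] objects with labels and domain
#'   keys. Both must share subject and session and differ in block; violations
#'   raise an error. If class `c` is absent from either block the function
#'   returns `NA_real_` (a skip signal, not an error).
#' @param class_c The class label to condition on.
#' @param spec A [kernel_spec()].
#' @return Scalar MMD, or `NA_real_` when the class is absent.
#' @export
bwise_discrepancy <- function(block_a, block_b, class_c, spec = kernel_spec()) {
  block_a <- as_feature_batch(block_a); block_b <- as_feature_batch(block_b)
  check_block_pair_keys(block_a, block_b)
  ia <- which(block_a$labels == class_c)
  ib <- which(block_b$labels == class_c)
  if (length(ia) == 0L || length(ib) == 0L) return(NA_real_)
  mmd(block_a$features[ia, , drop = FALSE],
      block_b$features[ib, , drop = FALSE], spec)
}

check_block_pair_keys <- function(a, b) {
  if (is.null(a$labels) || is.null(b$labels)) {
    stop("block-wise discrepancy needs labeled batches", call. = FALSE)
  }
  if (!is.null(a$subject_id) && !is.null(b$subject_id)) {
    if (length(unique(c(a$subject_id, b$subject_id))) != 1L) {
      stop("domain mismatch: blocks must come from the same subject", call. = FALSE)
    }
    if (!is.null(a$session_idx) && !is.null(b$session_idx) &&
        length(unique(c(a$session_idx, b$session_idx))) != 1L) {
      stop("domain mismatch: blocks must come from the same session", call. = FALSE)
    }
    if (!is.null(a$block_idx) && !is.null(b$block_idx) &&
        length(intersect(unique(a$block_idx), unique(b$block_idx))) > 0L) {
      stop("domain mismatch: the two batches must come from different blocks",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Mean class-conditional MMD over the classes shared by two paired batches,
# with feature gradients (the per-pair D_BWise term used in training).
bwise_batch_with_grad <- function(feats_a, labels_a, feats_b, labels_b,
                                  spec = kernel_spec(), bandwidths = NULL,
                                  want_grad = TRUE) {
  shared <- intersect(unique(labels_a), unique(labels_b))
  if (length(shared) == 0L) {
    return(list(value = NA_real_,
                d_a = matrix(0, nrow(feats_a), ncol(feats_a)),
                d_b = matrix(0, nrow(feats_b), ncol(feats_b))))
  }
  if (is.null(bandwidths)) {
    bandwidths <- resolve_bandwidths(spec, rbind(feats_a, feats_b))
  }
  total <- 0
  d_a <- matrix(0, nrow(feats_a), ncol(feats_a))
  d_b <- matrix(0, nrow(feats_b), ncol(feats_b))
  for (cl in shared) {
    ia <- which(labels_a == cl); ib <- which(labels_b == cl)
    part <- mmd_with_grad(feats_a[ia, , drop = FALSE],
                          feats_b[ib, , drop = FALSE],
                          bandwidths = bandwidths, want_grad = want_grad)
    total <- total + part$value
    if (want_grad) {
      d_a[ia, ] <- d_a[ia, ] + part$d_source / length(shared)
      d_b[ib, ] <- d_b[ib, ] + part$d_target / length(shared)
    }
  }
  list(value = total / length(shared), d_a = d_a, d_b = d_b)
}

#' Objective weights for domain-adaptive training
#'
#' @param alpha Nonnegative weight of the discrepancy penalty.
#' @param kernel A [kernel_spec()].
#' @param da_mode One of `"none"`, `"subject"`, `"session"`, `"block"`: which
#'   hierarchy level is treated as the domain axis. In `"subject"` mode the
#'   block-wise term is identically zero (there is no within-subject pair).
#' @return An object of class `objective_config`.
#' @export
objective_config <- function(alpha = 1, kernel = kernel_spec(),
                             da_mode = c("none", "subject", "session", "block")) {
  da_mode <- match.arg(da_mode)
  if (!is.finite(alpha) || alpha < 0) stop("alpha must be finite and >= 0", call. = FALSE)
  structure(list(alpha = alpha, kernel = kernel, da_mode = da_mode),
            class = "objective_config")
}

#' Combine cross-entropy with the discrepancy penalty
#'
#' Evaluates `l = l_ce + alpha * (D_cdd + D_BWise)` where `l_ce` is the mean
#' softmax cross-entropy of `logits` against `labels`. In `da_mode = "subject"`
#' the block-wise term contributes zero regardless of the value passed.
#'
#' @param logits Numeric matrix `[n x M]`.
#' @param labels Integer vector of 1-based class column indices (length `n`).
#' @param d_cdd,d_bwise Scalar discrepancy values (`NA` treated as 0).
#' @param config An [objective_config()].
#' @return A `loss_breakdown` list: `total`, `cross_entropy`, `d_cdd`,
#'   `d_bwise`, `alpha`.
#' @export
total_objective <- function(logits, labels, d_cdd = 0, d_bwise = 0,
                            config = objective_config()) {
  stopifnot(inherits(config, "objective_config"))
  lce <- cross_entropy(logits, labels)$value
  if (is.na(d_cdd)) d_cdd <- 0
  if (is.na(d_bwise) || config$da_mode == "subject") d_bwise <- 0
  total <- lce + config$alpha * (d_cdd + d_bwise)
  structure(list(total = total, cross_entropy = lce,
                 d_cdd = d_cdd, d_bwise = d_bwise, alpha = config$alpha),
            class = "loss_breakdown")
}

# Mean softmax cross-entropy and its logits gradient. labels are 1-based
# column indices.
cross_entropy <- function(logits, labels, want_grad = FALSE) {
  logits <- as.matrix(logits)
  n <- nrow(logits)
  if (length(labels) != n) stop("logits/labels misaligned", call. = FALSE)
  z <- logits - apply(logits, 1, max)
  p <- exp(z) / rowSums(exp(z))
  picked <- p[cbind(seq_len(n), labels)]
  value <- -mean(log(pmax(picked, 1e-300)))
  if (!want_grad) return(list(value = value, probs = p))
  grad <- p
  grad[cbind(seq_len(n), labels)] <- grad[cbind(seq_len(n), labels)] - 1
  list(value = value, probs = p, grad = grad / n)
}

# Map raw class labels to 1-based column indices of the classifier head.
encode_labels <- function(labels, class_set) {
  idx <- match(labels, class_set)
  if (anyNA(idx)) stop("label outside class_set", call. = FALSE)
  idx
}
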