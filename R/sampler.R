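#' Partition training epochs into domains
#'
#' Groups epoch indices by the domain key of the chosen mode: `"subject"` keys
#' on subject only, `"session"` on (subject, session), `"block"` on (subject,
#' session, block). The groups partition the input indices; each group also
#' carries per-class index lists for class-matched pairing.
#'
#' @param set An `epoch_set` (typically the training split).
#' @param mode `"subject"`, `"session"` or `"block"`.
#' @return An object of class `domain_partition`: a tibble of groups plus the
#'   mode.
#' @export
partition_domains <- function(set, mode = c("block", "session", "subject")) {
  mode <- match.arg(mode)
  stopifnot(inherits(set, "epoch_set"))
  if (n_epochs(set) == 0L) stop("cannot partition an empty epoch set", call. = FALSE)
  meta <- set$meta
  if (mode == "block" && length(unique(meta$block_idx)) < 2L) {
    stop("block mode needs at least two blocks per session; ",
         "this design has one block -- use session or subject mode", call. = FALSE)
  }
  if (mode == "session" && length(unique(meta$session_idx)) < 2L) {
    stop("session mode needs at least two sessions per subject; ",
         "use subject mode", call. = FALSE)
  }
  key_cols <- switch(mode,
    subject = "subject_id",
    session = c("subject_id", "session_idx"),
    block = c("subject_id", "session_idx", "block_idx")
  )
  groups <- meta |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key_cols))) |>
    dplyr::summarise(
      idx = list(.row),
      by_class = list(split(.row, label)),
      classes = list(sort(unique(label))),
      .groups = "drop"
    ) |>
    dplyr::mutate(group_id = dplyr::row_number(), .before = 1)
  partition <- structure(
    list(mode = mode, groups = groups, n_epochs = n_epochs(set)),
    class = "domain_partition")
  # valid pairs are a pure function of the partition: compute once
  partition$valid_pairs <- if (nrow(groups) >= 2L) {
    compute_valid_pairs(partition)
  } else {
    matrix(integer(0), 0, 2)
  }
  partition
}

#' @export
print.domain_partition <- function(x, ...) {
  cat("<domain_partition> mode=", x$mode, ", ", nrow(x$groups), " groups over ",
      x$n_epochs, " epochs\n", sep = "")
  invisible(x)
}

# All unordered group pairs that satisfy the mode's key constraints and share
# at least one class. Returns a two-column matrix of group ids.
valid_domain_pairs <- function(partition) {
  pairs <- partition$valid_pairs
  if (is.null(pairs)) pairs <- compute_valid_pairs(partition)
  if (nrow(pairs) == 0L) {
    stop("no valid ", partition$mode, "-mode domain pair with a shared class ",
         "among subjects: ",
         paste(unique(partition$groups$subject_id), collapse = ", "),
         call. = FALSE)
  }
  pairs
}

compute_valid_pairs <- function(partition) {
  g <- partition$groups
  mode <- partition$mode
  if (nrow(g) < 2L) return(matrix(integer(0), 0, 2))
  pairs <- list()
  idx_pairs <- utils::combn(nrow(g), 2)
  classes <- g$classes
  subj <- g$subject_id
  sess <- if ("session_idx" %in% names(g)) g$session_idx else NULL
  blk <- if ("block_idx" %in% names(g)) g$block_idx else NULL
  for (j in seq_len(ncol(idx_pairs))) {
    a <- idx_pairs[1, j]; b <- idx_pairs[2, j]
    ok <- switch(mode,
      subject = subj[a] != subj[b],
      session = subj[a] == subj[b] && sess[a] != sess[b],
      block = subj[a] == subj[b] && sess[a] == sess[b] && blk[a] != blk[b]
    )
    if (ok && length(intersect(classes[[a]], classes[[b]])) > 0L) {
      pairs[[length(pairs) + 1L]] <- c(a, b)
    }
  }
  if (length(pairs) == 0L) return(matrix(integer(0), 0, 2))
  do.call(rbind, pairs)
}

#' Draw a paired mini-batch for domain-adaptive training
#'
#' Draws `n_domain_pairs` domain pairs uniformly from all pairs valid under
#' the partition's mode (block pairs share subject and session; session pairs
#' share subject; subject pairs differ in subject), then samples up to
#' `samples_per_class_per_side` epochs per shared class from each side,
#' without replacement within the batch. Reproducible from the current RNG
#' state (seed it with [set.seed()]).
#'
#' @param partition A [partition_domains()] result.
#' @param set The `epoch_set` the partition was built from.
#' @param n_domain_pairs Number of domain pairs per batch.
#' @param samples_per_class_per_side Cap on epochs per class per side
#'   (availability-limited).
#' @return An object of class `paired_batch`: a list of pairs, each holding
#'   `source_idx`, `target_idx` (1-based epoch indices), their labels, and the
#'   two group rows.
#' @export
build_paired_batch <- function(partition, set, n_domain_pairs = 4L,
                               samples_per_class_per_side = 4L) {
  stopifnot(inherits(partition, "domain_partition"))
  cand <- valid_domain_pairs(partition)
  draw <- cand[sample.int(nrow(cand), n_domain_pairs, replace = TRUE), ,
               drop = FALSE]
  g <- partition$groups
  labels <- set$meta$label
  pairs <- vector("list", nrow(draw))
  for (j in seq_len(nrow(draw))) {
    ia <- draw[j, 1]; ib <- draw[j, 2]
    shared <- intersect(g$classes[[ia]], g$classes[[ib]])
    take <- function(gi, cl) {
      pool <- g$by_class[[gi]][[as.character(cl)]]
      pool[sample.int(length(pool), min(length(pool), samples_per_class_per_side))]
    }
    src <- unlist(lapply(shared, function(cl) take(ia, cl)))
    tgt <- unlist(lapply(shared, function(cl) take(ib, cl)))
    pairs[[j]] <- list(
      source_idx = src, target_idx = tgt,
      source_labels = labels[src], target_labels = labels[tgt],
      source_group = g[ia, ], target_group = g[ib, ]
    )
  }
  structure(list(pairs = pairs, mode = partition$mode), class = "paired_batch")
}
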