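#' Bundle epoched fNIRS data with its hierarchy metadata
#'
#' An `epoch_set` holds all epochs of a study as one numeric array
#' `[n_epochs x n_timesteps x n_features]` together with a metadata tibble
#' (one row per epoch: `epoch_idx`, `subject_id`, `session_idx`, `block_idx`,
#' `trial_idx`, `label`) and the `experiment_design` the epochs follow.
#' Session, block and trial indices are 0-based; `epoch_idx` is the 0-based
#' storage row.
#'
#' Values are truncated to IEEE float32 precision on construction so that the
#' on-disk container (which stores float32) round-trips bit-exactly.
#'
#' @param data Numeric array `[n x T x F]`, all values finite.
#' @param meta Data frame with columns `subject_id`, `session_idx`,
#'   `block_idx`, `trial_idx`, `label` (and optionally `epoch_idx`).
#' @param design An [experiment_design()].
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, meta, design) {
  validate_design(design)
  if (length(dim(data)) != 3L) stop("data must be a 3-D array [n x T x F]", call. = FALSE)
  meta <- tibble::as_tibble(meta)
  n <- dim(data)[1]
  if (nrow(meta) != n) stop("meta must have one row per epoch", call. = FALSE)
  need <- c("subject_id", "session_idx", "block_idx", "trial_idx", "label")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0L) {
    stop("meta is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  meta$subject_id <- as.character(meta$subject_id)
  for (col in c("session_idx", "block_idx", "trial_idx", "label")) {
    meta[[col]] <- as.integer(meta[[col]])
  }
  meta$epoch_idx <- seq_len(n) - 1L
  meta <- meta[, c("epoch_idx", need)]

  if (n > 0L) {
    if (dim(data)[2] != design$n_timesteps) {
      stop("epoch length ", dim(data)[2], " does not match design n_timesteps ",
           design$n_timesteps, call. = FALSE)
    }
    if (dim(data)[3] != n_features(design)) {
      stop("feature count ", dim(data)[3], " does not match design layout ",
           n_features(design), call. = FALSE)
    }
    if (!all(is.finite(data))) {
      bad <- which(!apply(is.finite(data), 1, all))[1]
      stop("non-finite values in epoch ", bad - 1L, call. = FALSE)
    }
    if (!all(meta$label %in% design$class_set)) {
      bad <- which(!(meta$label %in% design$class_set))[1]
      stop("epoch ", bad - 1L, " has label ", meta$label[bad],
           " outside the design class_set", call. = FALSE)
    }
    key <- paste(meta$subject_id, meta$session_idx, meta$block_idx, meta$trial_idx)
    if (anyDuplicated(key)) {
      stop("duplicate (subject, session, block, trial) tuple: ",
           key[anyDuplicated(key)], call. = FALSE)
    }
  }
  storage.mode(data) <- "double"
  set <- structure(
    list(data = float32_truncate(data), meta = meta, design = design),
    class = "epoch_set"
  )
  set
}

# Truncate doubles to the nearest IEEE float32 value (round trip through a
# 4-byte binary representation), so float32 storage is lossless afterwards.
float32_truncate <- function(x) {
  if (length(x) == 0L) return(x)
  d <- dim(x)
  out <- readBin(writeBin(as.numeric(x), raw(), size = 4L),
                 what = "numeric", n = length(x), size = 4L)
  dim(out) <- d
  out
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> ", n_epochs(x), " epochs [",
      x$design$n_timesteps, " x ", n_features(x$design), "], design '",
      x$design$name, "'\n", sep = "")
  if (n_epochs(x) > 0L) {
    cat("  subjects: ", length(unique(x$meta$subject_id)),
        "; labels: ", paste(sort(unique(x$meta$label)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param set An `epoch_set`.
#' @return Integer count.
#' @export
n_epochs <- function(set) {
  stopifnot(inherits(set, "epoch_set"))
  dim(set$data)[1]
}

#' Subset an epoch set by epoch index
#'
#' @param set An `epoch_set`.
#' @param idx Integer vector of 1-based epoch positions.
#' @return A new `epoch_set` containing the selected epochs, in `idx` order.
#' @export
subset_epochs <- function(set, idx) {
  stopifnot(inherits(set, "epoch_set"))
  idx <- as.integer(idx)
  if (length(idx) > 0 && (min(idx) < 1L || max(idx) > n_epochs(set))) {
    stop("epoch index out of range", call. = FALSE)
  }
  epoch_set(set$data[idx, , , drop = FALSE], set$meta[idx, ], set$design)
}

#' Write an epoch set to its on-disk container
#'
#' The container is a directory holding `epochs.h5` (one float32 HDF5 dataset
#' named `"epochs"`, shape `[n x T x F]`), `meta.csv` (UTF-8, comma-delimited,
#' header row) and `design.json`. [load_epochs()] restores it bit-exactly.
#'
#' @param set An `epoch_set`.
#' @param path Directory to write into (created if absent).
#' @return `path`, invisibly.
#' @export
save_epochs <- function(set, path) {
  stopifnot(inherits(set, "epoch_set"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  h5 <- file.path(path, "epochs.h5")
  if (file.exists(h5)) file.remove(h5)
  rhdf5::h5createFile(h5)
  dims <- dim(set$data)
  rhdf5::h5createDataset(h5, "epochs", dims = dims, H5type = "H5T_IEEE_F32LE",
                         chunk = NULL, level = 0)
  if (n_epochs(set) > 0L) {
    rhdf5::h5write(set$data, h5, "epochs")
  }
  rhdf5::h5closeAll()
  readr::write_csv(set$meta, file.path(path, "meta.csv"))
  design <- set$design
  class(design) <- NULL
  jsonlite::write_json(design, file.path(path, "design.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an epoch set back from its on-disk container
#'
#' Validates the files written by [save_epochs()]: the metadata must reference
#' in-range epoch rows and every label must belong to the design's class set.
#' Epochs are returned in `meta.csv` row order.
#'
#' @param path Directory containing `epochs.h5`, `meta.csv`, `design.json`.
#' @return An `epoch_set`.
#' @export
load_epochs <- function(path) {
  for (f in c("epochs.h5", "meta.csv", "design.json")) {
    if (!file.exists(file.path(path, f))) {
      stop("epoch container is missing ", f, call. = FALSE)
    }
  }
  dj <- jsonlite::read_json(file.path(path, "design.json"), simplifyVector = TRUE)
  design <- experiment_design(
    name = dj$name, n_subjects = dj$n_subjects,
    sessions_per_subject = dj$sessions_per_subject,
    blocks_per_session = dj$blocks_per_session,
    trials_per_block = dj$trials_per_block,
    block_condition_order = dj$block_condition_order,
    window_seconds = dj$window_seconds, sampling_rate = dj$sampling_rate,
    n_spatial_channels = dj$n_spatial_channels,
    n_hemoglobin_types = dj$n_hemoglobin_types,
    n_optical_types = dj$n_optical_types,
    class_set = dj$class_set, n_timesteps = dj$n_timesteps
  )
  meta <- readr::read_csv(file.path(path, "meta.csv"), show_col_types = FALSE)
  need <- c("epoch_idx", "subject_id", "session_idx", "block_idx", "trial_idx", "label")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0L) {
    stop("meta.csv is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- rhdf5::h5read(file.path(path, "epochs.h5"), "epochs")
  rhdf5::h5closeAll()
  if (is.null(dim(data))) dim(data) <- c(length(data), 1L, 1L)
  n <- dim(data)[1]
  if (nrow(meta) > 0L) {
    if (any(meta$epoch_idx < 0L | meta$epoch_idx >= n)) {
      bad <- meta$epoch_idx[which(meta$epoch_idx < 0L | meta$epoch_idx >= n)[1]]
      stop("meta.csv references out-of-range epoch_idx ", bad, call. = FALSE)
    }
    data <- data[meta$epoch_idx + 1L, , , drop = FALSE]
  } else {
    data <- array(numeric(0), dim = c(0L, design$n_timesteps, n_features(design)))
  }
  epoch_set(data, meta[, setdiff(need, "epoch_idx")], design)
}

#' Cut sliding-window epochs out of a continuous recording
#'
#' Each annotated task period is sliced into windows of
#' `round(window_seconds * sampling_rate)` samples, advanced by
#' `stride_seconds`, using half-open sample ranges `[start, start + T)`.
#' Windows never extend past the end of their own task period, so no window
#' crosses a block boundary. Trial indices restart at 0 within each block.
#'
#' @param recording Numeric matrix `[T_total x F]` of continuous samples.
#' @param sampling_rate Hz.
#' @param window_seconds Window length in seconds.
#' @param stride_seconds Hop between consecutive window onsets; defaults to the
#'   window length (non-overlapping windows).
#' @param annotations Data frame with one row per task period and columns
#'   `onset_seconds`, `duration_seconds`, `label`, `session_idx`, `block_idx`.
#' @param subject_id Subject identifier attached to every produced epoch.
#' @param design Optional `experiment_design` for the output set; inferred from
#'   the recording when omitted (each feature column treated as one spatial
#'   channel).
#' @return An `epoch_set` of the windows, in annotation order.
#' @export
slide_windows <- function(recording, sampling_rate, window_seconds,
                          stride_seconds = window_seconds, annotations,
                          subject_id = "S01", design = NULL) {
  recording <- as.matrix(recording)
  t_win <- as.integer(round(window_seconds * sampling_rate))
  stride <- as.integer(round(stride_seconds * sampling_rate))
  if (t_win < 1L) stop("window must span at least one sample", call. = FALSE)
  if (stride < 1L) stop("stride must span at least one sample", call. = FALSE)
  annotations <- tibble::as_tibble(annotations)
  need <- c("onset_seconds", "duration_seconds", "label", "session_idx", "block_idx")
  missing_cols <- setdiff(need, names(annotations))
  if (length(missing_cols) > 0L) {
    stop("annotations missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(design)) {
    design <- experiment_design(
      "custom", n_subjects = 1L, sessions_per_subject = max(annotations$session_idx) + 1L,
      blocks_per_session = max(annotations$block_idx) + 1L,
      trials_per_block = 1L, block_condition_order = NULL,
      window_seconds = window_seconds, sampling_rate = sampling_rate,
      n_spatial_channels = ncol(recording), n_hemoglobin_types = 1L,
      n_optical_types = 1L, class_set = sort(unique(as.integer(annotations$label))),
      n_timesteps = t_win
    )
  }

  slabs <- list()
  meta <- list()
  for (i in seq_len(nrow(annotations))) {
    ann <- annotations[i, ]
    onset <- as.integer(round(ann$onset_seconds * sampling_rate))
    period <- as.integer(round(ann$duration_seconds * sampling_rate))
    if (t_win > period) {
      stop("window (", t_win, " samples) longer than task period (", period,
           " samples) at annotation ", i, call. = FALSE)
    }
    starts <- seq.int(onset, onset + period - t_win, by = stride) # 0-based
    if (max(starts) + t_win > nrow(recording)) {
      stop("annotation ", i, " extends past the end of the recording", call. = FALSE)
    }
    for (k in seq_along(starts)) {
      slabs[[length(slabs) + 1L]] <-
        recording[(starts[k] + 1L):(starts[k] + t_win), , drop = FALSE]
      meta[[length(meta) + 1L]] <- tibble::tibble(
        subject_id = subject_id,
        session_idx = as.integer(ann$session_idx),
        block_idx = as.integer(ann$block_idx),
        trial_idx = k - 1L,
        label = as.integer(ann$label)
      )
    }
  }
  n <- length(slabs)
  data <- array(0, dim = c(n, t_win, ncol(recording)))
  for (k in seq_len(n)) data[k, , ] <- slabs[[k]]
  epoch_set(data, dplyr::bind_rows(meta), design)
}
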