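#' Describe the structure of an epoched fNIRS experiment
#'
#' An experiment design records the hierarchy (subjects > sessions > blocks >
#' trials) of a block-design fNIRS study, the windowing used to cut epochs, and
#' the feature layout of each epoch. Three presets mirror widely used public
#' n-back / finger-tapping corpora; `"custom"` designs can take any shape.
#'
#' Feature columns are laid out channel-major: for spatial channel `s`,
#' hemoglobin type `h` (1 = HbO, 2 = HbR) and optical type `o`, the column index
#' is `(s - 1) * H * O + (h - 1) * O + o`, with `H = n_hemoglobin_types` and
#' `O = n_optical_types`. The per-epoch time length `n_timesteps` defaults to
#' `round(window_seconds * sampling_rate)` but may be pinned explicitly (the
#' `"fft"` preset uses 134 samples for a 10 s window at 13.33 Hz).
#'
#' `block_condition_order` gives the class label of each block in a session, in
#' presentation order. When it is `NULL` the design is trial-randomized: each
#' session presents a seeded random order of trials balanced across classes and
#' consecutive trials are grouped into nominal blocks of `trials_per_block`.
#'
#' @param name One of `"tuberlin"`, `"fft"`, `"tufts"`, `"custom"`.
#' @param n_subjects Number of subjects.
#' @param sessions_per_subject Sessions recorded per subject.
#' @param blocks_per_session Blocks per session.
#' @param trials_per_block Trials (epochs) per block.
#' @param block_condition_order Integer vector of class labels, one per block,
#'   or `NULL` for trial-randomized designs.
#' @param window_seconds Epoch window length in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @param n_spatial_channels,n_hemoglobin_types,n_optical_types Feature layout.
#' @param class_set Integer vector of the class labels used in the design.
#' @param n_timesteps Optional explicit per-epoch time length; defaults to
#'   `round(window_seconds * sampling_rate)`.
#' @return An object of class `experiment_design`.
#' @examples
#' d <- experiment_design("tuberlin")
#' c(d$n_timesteps, n_features(d)) # 20 x 72 epochs
#' @export
experiment_design <- function(name = c("tuberlin", "fft", "tufts", "custom"),
                              n_subjects = NULL,
                              sessions_per_subject = NULL,
                              blocks_per_session = NULL,
                              trials_per_block = NULL,
                              block_condition_order = NULL,
                              window_seconds = NULL,
                              sampling_rate = NULL,
                              n_spatial_channels = NULL,
                              n_hemoglobin_types = NULL,
                              n_optical_types = NULL,
                              class_set = NULL,
                              n_timesteps = NULL) {
  name <- match.arg(name)
  preset <- switch(name,
    tuberlin = list(
      n_subjects = 26L, sessions_per_subject = 3L, blocks_per_session = 9L,
      trials_per_block = 20L,
      block_condition_order = c(0L, 2L, 3L, 2L, 3L, 0L, 3L, 0L, 2L),
      window_seconds = 2, sampling_rate = 10,
      n_spatial_channels = 36L, n_hemoglobin_types = 2L, n_optical_types = 1L,
      class_set = c(0L, 2L, 3L), n_timesteps = 20L
    ),
    fft = list(
      n_subjects = 30L, sessions_per_subject = 3L, blocks_per_session = 25L,
      trials_per_block = 3L,
      block_condition_order = NULL, # trial-randomized, 25 trials per class
      window_seconds = 10, sampling_rate = 13.33,
      n_spatial_channels = 20L, n_hemoglobin_types = 2L, n_optical_types = 1L,
      class_set = c(0L, 1L, 2L), n_timesteps = 134L
    ),
    tufts = list(
      n_subjects = 68L, sessions_per_subject = 1L, blocks_per_session = 16L,
      trials_per_block = 40L,
      block_condition_order = c(0L, 1L, 2L, 3L, 1L, 2L, 3L, 0L,
                                2L, 3L, 0L, 1L, 3L, 0L, 1L, 2L),
      window_seconds = 15, sampling_rate = 10,
      n_spatial_channels = 2L, n_hemoglobin_types = 2L, n_optical_types = 2L,
      class_set = c(0L, 1L, 2L, 3L), n_timesteps = 150L
    ),
    custom = list()
  )
  take <- function(user, key, default = NULL) {
    if (!is.null(user)) user else if (!is.null(preset[[key]])) preset[[key]] else default
  }
  design <- list(
    name = name,
    n_subjects = as.integer(take(n_subjects, "n_subjects")),
    sessions_per_subject = as.integer(take(sessions_per_subject, "sessions_per_subject")),
    blocks_per_session = as.integer(take(blocks_per_session, "blocks_per_session")),
    trials_per_block = as.integer(take(trials_per_block, "trials_per_block")),
    block_condition_order = {
      bco <- if (!is.null(block_condition_order) || name == "custom") {
        block_condition_order
      } else {
        preset$block_condition_order
      }
      if (!is.null(bco)) as.integer(bco) else NULL
    },
    window_seconds = as.numeric(take(window_seconds, "window_seconds")),
    sampling_rate = as.numeric(take(sampling_rate, "sampling_rate")),
    n_spatial_channels = as.integer(take(n_spatial_channels, "n_spatial_channels")),
    n_hemoglobin_types = as.integer(take(n_hemoglobin_types, "n_hemoglobin_types", 2L)),
    n_optical_types = as.integer(take(n_optical_types, "n_optical_types", 1L)),
    class_set = as.integer(take(class_set, "class_set"))
  )
  design$n_timesteps <- as.integer(
    take(n_timesteps, "n_timesteps",
         round(design$window_seconds * design$sampling_rate))
  )
  class(design) <- "experiment_design"
  validate_design(design)
  design
}

validate_design <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  need <- c("n_subjects", "sessions_per_subject", "blocks_per_session",
            "trials_per_block", "window_seconds", "sampling_rate",
            "n_spatial_channels", "n_hemoglobin_types", "n_optical_types",
            "class_set", "n_timesteps")
  for (key in need) {
    if (is.null(design[[key]]) || anyNA(design[[key]])) {
      stop("experiment_design: field '", key, "' is missing", call. = FALSE)
    }
  }
  if (!is.null(design$block_condition_order)) {
    if (length(design$block_condition_order) != design$blocks_per_session) {
      stop("block_condition_order must have one label per block (",
           design$blocks_per_session, ")", call. = FALSE)
    }
    if (!all(design$block_condition_order %in% design$class_set)) {
      stop("block_condition_order contains labels outside class_set", call. = FALSE)
    }
  } else {
    n_trials <- design$blocks_per_session * design$trials_per_block
    if (n_trials %% length(design$class_set) != 0L) {
      stop("trial-randomized design: trials per session (", n_trials,
           ") must be divisible by the number of classes", call. = FALSE)
    }
  }
  if (design$n_timesteps < 1L) stop("n_timesteps must be >= 1", call. = FALSE)
  invisible(design)
}

#' Number of feature columns per epoch for a design
#'
#' @param design An `experiment_design`.
#' @return Integer: spatial channels x hemoglobin types x optical types.
#' @export
n_features <- function(design) {
  design$n_spatial_channels * design$n_hemoglobin_types * design$n_optical_types
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design '", x$name, "'>\n", sep = "")
  cat("  ", x$n_subjects, " subjects x ", x$sessions_per_subject, " sessions x ",
      x$blocks_per_session, " blocks x ", x$trials_per_block, " trials\n", sep = "")
  cat("  epochs: ", x$n_timesteps, " timesteps x ", n_features(x),
      " features (", x$window_seconds, " s @ ", x$sampling_rate, " Hz)\n", sep = "")
  cat("  classes: {", paste(x$class_set, collapse = ", "), "}\n", sep = "")
  if (is.null(x$block_condition_order)) {
    cat("  block order: trial-randomized\n")
  } else {
    cat("  block order: ", paste(x$block_condition_order, collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Feature columns belonging to given spatial channels
#'
#' Maps 1-based spatial channel indices to the 1-based feature-column indices
#' they occupy under the channel-major layout.
#'
#' @param design An `experiment_design`.
#' @param channels Integer vector of spatial channel indices (1-based).
#' @return Sorted integer vector of feature column indices.
#' @export
channel_feature_columns <- function(design, channels) {
  channels <- as.integer(channels)
  if (length(channels) == 0L) return(integer(0))
  if (any(channels < 1L | channels > design$n_spatial_channels)) {
    stop("channel index out of range 1..", design$n_spatial_channels, call. = FALSE)
  }
  per <- design$n_hemoglobin_types * design$n_optical_types
  sort(as.integer(outer(seq_len(per), (channels - 1L) * per, `+`)))
}
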