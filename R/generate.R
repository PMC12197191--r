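#' Configuration for the hierarchical synthetic fNIRS generator
#'
#' The generator emulates block-design workload studies: every epoch carries a
#' class-dependent hemodynamic response on a subset of informative spatial
#' channels, modulated by subject-, session- and block-level nuisance effects
#' (the dominant variance sources in real multi-session fNIRS: anatomy and
#' coupling differences between subjects, sensor re-placement between sessions,
#' slow drifts within a sitting), plus temporally correlated measurement noise
#' and a global physiological oscillation.
#'
#' Per-epoch data for subject `s`, session `e`, block `b` is
#' `gain_s * gain_b * signal + offset_s + offset_se + drift_b(t) + AR1 noise
#' + physiological sinusoid`, where `signal` puts
#' `amplitude[class] * hemodynamic response` on the HbO columns of informative
#' channels and the negated, `hbr_ratio`-scaled response on their HbR columns.
#' In counterbalanced designs (block order given) the response is the
#' sustained-task curve evaluated at time since block onset; in
#' trial-randomized designs each trial's response restarts at its own onset.
#'
#' Default magnitudes are fixed package-wide study conditions; see the methods
#' vignette for how they were chosen.
#'
#' @param design An [experiment_design()].
#' @param class_amplitudes Named or ordered numeric vector of response gains,
#'   one per class in `design$class_set`, monotone in workload level. Default:
#'   `0.6 + 0.45 * rank` across the class set.
#' @param hrf An [hrf_model()].
#' @param subject_gain_sd SD of the multiplicative subject gain (around 1).
#' @param subject_offset_sd SD of the per-feature additive subject offset.
#' @param session_offset_sd SD of the per-feature additive session offset
#'   (sensor re-placement).
#' @param block_drift_sd SD of the per-feature additive block offset and of the
#'   slow within-block ramp.
#' @param block_gain_sd SD of the small multiplicative block gain jitter.
#' @param ar1_coefficient Temporal AR(1) coefficient of the measurement noise,
#'   `|phi| < 1`.
#' @param physio_oscillation_amplitude,physio_oscillation_frequency Amplitude
#'   and frequency (Hz) of a global sinusoidal physiological component with a
#'   random phase per (subject, session).
#' @param measurement_noise_sd Marginal SD of the AR(1) measurement noise.
#' @param informative_channel_fraction Fraction of spatial channels carrying
#'   class signal (the leading channels), in `(0, 1]`.
#' @param common_mode_fraction Share of each domain offset's variance that is
#'   channel-common, in `[0, 1)`. Systemic physiology (blood pressure, heart
#'   rate) and cap shifts move all channels together, so real session/block
#'   nuisance is spatially coherent rather than independent per channel; the
#'   remaining variance share is independent per feature.
#' @param informative_channels Optional explicit 1-based spatial channel
#'   indices overriding the fraction.
#' @param seed Integer seed; all draws derive from it via fixed per-subject
#'   substreams, so generation is reproducible and per-subject draws do not
#'   depend on how many subjects precede them.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(design,
                             class_amplitudes = NULL,
                             hrf = hrf_model(),
                             subject_gain_sd = 0.2,
                             subject_offset_sd = 0.25,
                             session_offset_sd = 0.3,
                             block_drift_sd = 0.3,
                             block_gain_sd = 0.05,
                             ar1_coefficient = 0.5,
                             physio_oscillation_amplitude = 0.25,
                             physio_oscillation_frequency = 0.1,
                             measurement_noise_sd = 0.45,
                             informative_channel_fraction = 1 / 3,
                             common_mode_fraction = 0.7,
                             informative_channels = NULL,
                             seed = 1L) {
  validate_design(design)
  m <- length(design$class_set)
  if (is.null(class_amplitudes)) {
    class_amplitudes <- 0.6 + 0.45 * (seq_len(m) - 1L)
  }
  if (length(class_amplitudes) != m) {
    stop("class_amplitudes must have one value per class", call. = FALSE)
  }
  sds <- c(subject_gain_sd, subject_offset_sd, session_offset_sd,
           block_drift_sd, block_gain_sd, measurement_noise_sd,
           physio_oscillation_amplitude)
  if (any(sds < 0)) stop("all SDs/amplitudes must be >= 0", call. = FALSE)
  if (abs(ar1_coefficient) >= 1) stop("|ar1_coefficient| must be < 1", call. = FALSE)
  if (common_mode_fraction < 0 || common_mode_fraction >= 1) {
    stop("common_mode_fraction must be in [0, 1)", call. = FALSE)
  }
  if (is.null(informative_channels)) {
    if (informative_channel_fraction <= 0 || informative_channel_fraction > 1) {
      stop("informative_channel_fraction must be in (0, 1]", call. = FALSE)
    }
    k <- max(1L, ceiling(informative_channel_fraction * design$n_spatial_channels))
    informative_channels <- seq_len(k)
  } else {
    informative_channels <- as.integer(informative_channels)
    if (any(informative_channels < 1L |
            informative_channels > design$n_spatial_channels)) {
      stop("informative_channels out of range", call. = FALSE)
    }
  }
  config <- list(
    design = design,
    class_amplitudes = as.numeric(class_amplitudes),
    hrf = hrf,
    subject_gain_sd = subject_gain_sd,
    subject_offset_sd = subject_offset_sd,
    session_offset_sd = session_offset_sd,
    block_drift_sd = block_drift_sd,
    block_gain_sd = block_gain_sd,
    ar1_coefficient = ar1_coefficient,
    physio_oscillation_amplitude = physio_oscillation_amplitude,
    physio_oscillation_frequency = physio_oscillation_frequency,
    measurement_noise_sd = measurement_noise_sd,
    informative_channels = informative_channels,
    common_mode_fraction = common_mode_fraction,
    seed = as.integer(seed)
  )
  class(config) <- "generator_config"
  config
}

# Deterministic per-subject substream seed (Lehmer-style mix, < 2^31).
subject_stream_seed <- function(seed, subject_index) {
  ((as.double(seed) %% 2147483647) * 48271 +
     as.double(subject_index) * 104729) %% 2147483629 + 1
}

# Draw the subject/session/block effects for one subject. The draw order is
# fixed (subject, then sessions, then blocks) so generate_dataset() and
# sample_domain_effects() produce identical tables from the same config.
draw_subject_effects <- function(config, subject_index) {
  design <- config$design
  nf <- n_features(design)
  set.seed(as.integer(subject_stream_seed(config$seed, subject_index)))
  # spatially coherent offsets: a channel-common draw carries
  # common_mode_fraction of the variance, the rest is per-feature
  coherent <- function(sd) {
    frac <- config$common_mode_fraction
    sd * (sqrt(frac) * stats::rnorm(1) + sqrt(1 - frac) * stats::rnorm(nf))
  }
  subject <- list(
    gain = 1 + stats::rnorm(1, 0, config$subject_gain_sd),
    offset = coherent(config$subject_offset_sd)
  )
  sessions <- lapply(seq_len(design$sessions_per_subject), function(e) {
    list(offset = coherent(config$session_offset_sd),
         physio_phase = stats::runif(1, 0, 2 * pi))
  })
  blocks <- lapply(seq_len(design$sessions_per_subject), function(e) {
    lapply(seq_len(design$blocks_per_session), function(b) {
      list(offset = coherent(config$block_drift_sd),
           ramp = coherent(config$block_drift_sd),
           gain = 1 + stats::rnorm(1, 0, config$block_gain_sd))
    })
  })
  trial_orders <- NULL
  if (is.null(design$block_condition_order)) {
    n_trials <- design$blocks_per_session * design$trials_per_block
    per_class <- n_trials %/% length(design$class_set)
    trial_orders <- lapply(seq_len(design$sessions_per_subject), function(e) {
      sample(rep(design$class_set, per_class))
    })
  }
  list(subject = subject, sessions = sessions, blocks = blocks,
       trial_orders = trial_orders)
}

#' Tabulate the domain effects the generator would apply
#'
#' Draws (from the configured seed) the per-subject, per-session and per-block
#' nuisance effects, returned as tibbles keyed by the domain hierarchy. The
#' tables match exactly what [generate_dataset()] applies for the same config.
#'
#' @param config A [generator_config()].
#' @param n_subjects Number of subjects to draw (defaults to the design's).
#' @return A list of three tibbles: `subjects` (`subject_id`, `gain`,
#'   `offset` list-column), `sessions` (`subject_id`, `session_idx`, `offset`),
#'   `blocks` (`subject_id`, `session_idx`, `block_idx`, `offset`, `ramp`,
#'   `gain`).
#' @export
sample_domain_effects <- function(config, n_subjects = config$design$n_subjects) {
  stopifnot(inherits(config, "generator_config"))
  if (n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  subjects <- list(); sessions <- list(); blocks <- list()
  for (s in seq_len(n_subjects)) {
    sid <- subject_label(s)
    eff <- draw_subject_effects(config, s)
    subjects[[s]] <- tibble::tibble(
      subject_id = sid, gain = eff$subject$gain, offset = list(eff$subject$offset)
    )
    for (e in seq_len(config$design$sessions_per_subject)) {
      sessions[[length(sessions) + 1L]] <- tibble::tibble(
        subject_id = sid, session_idx = e - 1L,
        offset = list(eff$sessions[[e]]$offset)
      )
      for (b in seq_len(config$design$blocks_per_session)) {
        blk <- eff$blocks[[e]][[b]]
        blocks[[length(blocks) + 1L]] <- tibble::tibble(
          subject_id = sid, session_idx = e - 1L, block_idx = b - 1L,
          offset = list(blk$offset), ramp = list(blk$ramp), gain = blk$gain
        )
      }
    }
  }
  list(subjects = dplyr::bind_rows(subjects),
       sessions = dplyr::bind_rows(sessions),
       blocks = dplyr::bind_rows(blocks))
}

subject_label <- function(i) sprintf("S%02d", i)

#' Generate a synthetic epoched fNIRS corpus
#'
#' Realizes the full hierarchy of `config$design`: every subject, session,
#' block and trial, with epoch data assembled as described in
#' [generator_config()]. Fully reproducible from `config$seed`; per-subject
#' substreams make each subject's data independent of generation order.
#'
#' @param config A [generator_config()].
#' @param n_subjects Number of subjects to generate (defaults to the design's).
#' @return An `epoch_set`.
#' @export
generate_dataset <- function(config, n_subjects = config$design$n_subjects) {
  stopifnot(inherits(config, "generator_config"))
  design <- config$design
  if (design$trials_per_block < 1L || design$blocks_per_session < 1L) {
    stop("design must have at least one block and one trial", call. = FALSE)
  }
  t_len <- design$n_timesteps
  nf <- n_features(design)
  rate <- design$sampling_rate
  win <- design$window_seconds
  t_in_win <- (seq_len(t_len) - 1L) / rate
  counterbalanced <- !is.null(design$block_condition_order)
  sustained <- hrf_sustained_fun(config$hrf,
                                 horizon = design$trials_per_block * win)
  # response template per trial position within a block: [T x trials]
  resp_by_trial <- vapply(seq_len(design$trials_per_block), function(k) {
    t_onset <- if (counterbalanced) (k - 1L) * win else 0
    sustained(t_onset + t_in_win)
  }, numeric(t_len))

  # class response template per (class, trial position): [T x n_classes]
  m <- length(design$class_set)
  amp <- config$class_amplitudes
  hbo_cols <- informative_cols(design, config$informative_channels, hemo = 1L)
  hbr_cols <- if (design$n_hemoglobin_types >= 2L) {
    informative_cols(design, config$informative_channels, hemo = 2L)
  } else {
    integer(0)
  }

  n_per_subject <- design$sessions_per_subject * design$blocks_per_session *
    design$trials_per_block
  n_total <- n_per_subject * n_subjects
  data <- array(0, dim = c(n_total, t_len, nf))
  meta <- vector("list", n_subjects)
  row <- 0L

  for (s in seq_len(n_subjects)) {
    eff <- draw_subject_effects(config, s)
    sid <- subject_label(s)
    sub_meta <- vector("list", n_per_subject)
    j <- 0L
    for (e in seq_len(design$sessions_per_subject)) {
      sess <- eff$sessions[[e]]
      for (b in seq_len(design$blocks_per_session)) {
        blk <- eff$blocks[[e]][[b]]
        block_span <- design$trials_per_block * win
        for (k in seq_len(design$trials_per_block)) {
          t_onset <- (k - 1L) * win
          if (counterbalanced) {
            label <- design$block_condition_order[b]
          } else {
            pos <- (b - 1L) * design$trials_per_block + k
            label <- eff$trial_orders[[e]][pos]
          }
          resp <- resp_by_trial[, k]
          a <- amp[match(label, design$class_set)]
          signal <- matrix(0, t_len, nf)
          signal[, hbo_cols] <- a * resp
          if (length(hbr_cols) > 0L) {
            signal[, hbr_cols] <- -config$hrf$hbr_ratio * a * resp
          }
          # AR(1) noise with marginal SD = measurement_noise_sd, per feature
          innov_sd <- config$measurement_noise_sd *
            sqrt(1 - config$ar1_coefficient^2)
          noise <- matrix(stats::rnorm(t_len * nf, 0, innov_sd), t_len, nf)
          if (config$ar1_coefficient != 0 && t_len > 1L) {
            for (tt in 2:t_len) { # vectorized over features
              noise[tt, ] <- config$ar1_coefficient * noise[tt - 1L, ] + noise[tt, ]
            }
          }
          ramp_t <- (t_onset + t_in_win) / block_span - 0.5 # slow drift over block
          physio <- config$physio_oscillation_amplitude *
            sin(2 * pi * config$physio_oscillation_frequency *
                  (t_onset + t_in_win) + sess$physio_phase)
          x <- eff$subject$gain * blk$gain * signal +
            matrix(eff$subject$offset, t_len, nf, byrow = TRUE) +
            matrix(sess$offset, t_len, nf, byrow = TRUE) +
            matrix(blk$offset, t_len, nf, byrow = TRUE) +
            outer(ramp_t, blk$ramp) +
            noise + physio
          row <- row + 1L
          j <- j + 1L
          data[row, , ] <- x
          sub_meta[[j]] <- tibble::tibble(
            subject_id = sid, session_idx = e - 1L, block_idx = b - 1L,
            trial_idx = k - 1L, label = as.integer(label)
          )
        }
      }
    }
    meta[[s]] <- dplyr::bind_rows(sub_meta)
  }
  epoch_set(data, dplyr::bind_rows(meta), design)
}

# feature columns of given spatial channels for one hemoglobin type (all
# optical types)
informative_cols <- function(design, channels, hemo) {
  per <- design$n_hemoglobin_types * design$n_optical_types
  off <- (hemo - 1L) * design$n_optical_types
  sort(as.integer(outer(seq_len(design$n_optical_types) + off,
                        (channels - 1L) * per, `+`)))
}
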