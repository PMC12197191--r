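# Shared fixtures and independent oracles for the test suite.

tiny_design <- function(n_subjects = 2L, sessions = 2L, blocks = 3L,
                        trials = 4L, channels = 3L, window = 1,
                        rate = 5, classes = 0:2) {
  experiment_design(
    "custom", n_subjects = n_subjects, sessions_per_subject = sessions,
    blocks_per_session = blocks, trials_per_block = trials,
    block_condition_order = rep(classes, length.out = blocks),
    window_seconds = window, sampling_rate = rate,
    n_spatial_channels = channels, n_hemoglobin_types = 2L,
    n_optical_types = 1L, class_set = classes
  )
}

tiny_set <- function(design = tiny_design(), seed = 7L, ...) {
  generate_dataset(generator_config(design, seed = seed, ...))
}

tiny_mixer_config <- function(design, ...) {
  args <- list(n_timesteps = design$n_timesteps,
               features_per_group = n_features(design),
               hidden_dim = 4L, n_layers = 1L, temporal_hidden = 6L,
               channel_hidden = 5L, n_classes = length(design$class_set))
  override <- list(...)
  args[names(override)] <- override
  do.call(mixer_config, args)
}

random_features <- function(n, d, labels = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  feature_batch(matrix(rnorm(n * d), n, d), labels = labels)
}

# --- literal nested-loop oracles (kept deliberately naive) ------------------

oracle_kernel <- function(x, y, sigmas) {
  mean(sapply(sigmas, function(s) exp(-sum((x - y)^2) / (2 * s^2))))
}

oracle_mmd <- function(fs, ft, sigmas) {
  ns <- nrow(fs); nt <- nrow(ft)
  t1 <- 0; t2 <- 0; t3 <- 0
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    t1 <- t1 + oracle_kernel(fs[i, ], fs[j, ], sigmas)
  }
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    t2 <- t2 + oracle_kernel(ft[i, ], ft[j, ], sigmas)
  }
  for (i in seq_len(ns)) for (j in seq_len(nt)) {
    t3 <- t3 + oracle_kernel(fs[i, ], ft[j, ], sigmas)
  }
  t1 / ns^2 + t2 / nt^2 - 2 * t3 / (ns * nt)
}

# the indicator-weighted class-conditional discrepancy, summed literally
oracle_cad <- function(fs, ls, ft, lt, c1, c2, sigmas) {
  mu <- function(y, yp, ca, cb) as.numeric(y == ca && yp == cb)
  masked_mean <- function(X, lx, Y, ly, ca, cb) {
    num <- 0; den <- 0
    for (i in seq_len(nrow(X))) for (j in seq_len(nrow(Y))) {
      w <- mu(lx[i], ly[j], ca, cb)
      num <- num + w * oracle_kernel(X[i, ], Y[j, ], sigmas)
      den <- den + w
    }
    num / den
  }
  masked_mean(fs, ls, fs, ls, c1, c1) +
    masked_mean(ft, lt, ft, lt, c2, c2) -
    2 * masked_mean(fs, ls, ft, lt, c1, c2)
}

oracle_cdd <- function(fs, ls, ft, lt, classes, sigmas) {
  intra <- c(); inter <- c()
  for (c1 in classes) {
    for (c2 in classes) {
      if (!(c1 %in% ls) || !(c2 %in% lt)) next
      v <- oracle_cad(fs, ls, ft, lt, c1, c2, sigmas)
      if (c1 == c2) intra <- c(intra, v) else inter <- c(inter, v)
    }
  }
  mean(intra) - mean(inter)
}

# brute-force sliding-window start enumeration (0-based starts, in samples)
oracle_window_starts <- function(period_samples, window_samples, stride_samples) {
  starts <- c()
  s <- 0L
  while (s + window_samples <= period_samples) {
    starts <- c(starts, s)
    s <- s + stride_samples
  }
  starts
}
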