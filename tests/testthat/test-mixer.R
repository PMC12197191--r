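test_that("mlp_block matches a direct two-matrix-product computation", {
  expect_equal(gelu(0), 0)
  set.seed(91)
  d_in <- 4L; h <- 8L
  params <- list(W1 = matrix(rnorm(d_in * h), d_in, h), b1 = rnorm(h),
                 W2 = matrix(rnorm(h * d_in), h, d_in), b2 = rnorm(d_in))
  x <- matrix(rnorm(3 * d_in), 3, d_in)
  got <- mlp_block(x, params)
  # independent matrix-math oracle with the exact Gaussian-CDF GELU
  manual <- t(apply(x, 1, function(row) {
    a <- as.numeric(row %*% params$W1) + params$b1
    g <- a * pnorm(a)
    as.numeric(g %*% params$W2) + params$b2
  }))
  expect_equal(got, manual, tolerance = 1e-12)

  # zero weights -> zero output; output dim equals input dim
  zero <- list(W1 = matrix(0, d_in, h), b1 = numeric(h),
               W2 = matrix(0, h, d_in), b2 = numeric(d_in))
  expect_equal(mlp_block(x, zero), x * 0)
  expect_equal(dim(got), dim(x))
  expect_error(mlp_block(matrix(0, 2, 5), params), "shapes")
})

test_that("mixer_forward satisfies its shape contract and determinism", {
  design <- experiment_design("tufts", n_subjects = 1L)
  cfg <- mixer_config_for(design, n_classes = 2L)
  expect_equal(cfg$n_probe_groups, 2L)
  expect_equal(cfg$features_per_group, 4L)
  params <- mixer_init(cfg, seed = 5)
  x <- array(rnorm(3 * 150 * 8), c(3, 150, 8))
  logits <- mixer_forward(x, cfg, params)
  expect_equal(dim(logits), c(3L, 2L))
  feats <- mixer_forward(x, cfg, params, mode = "features")
  expect_equal(dim(feats), c(3L, cfg$hidden_dim))
  # bit-reproducible with dropout disabled
  expect_identical(logits, mixer_forward(x, cfg, params))
  expect_error(mixer_forward(array(NaN, c(1, 150, 8)), cfg, params),
               "non-finite")
})

test_that("zeroed parameters yield the head bias for every input", {
  cfg <- mixer_config(n_timesteps = 6, features_per_group = 3, hidden_dim = 4,
                      n_layers = 2, temporal_hidden = 5, channel_hidden = 5,
                      n_classes = 3)
  params <- mixer_init(cfg, seed = 1)
  for (nm in names(params)) params[[nm]] <- params[[nm]] * 0
  params$head_b <- c(0.3, -0.1, 0.5)
  x <- array(rnorm(4 * 6 * 3), c(4, 6, 3))
  logits <- mixer_forward(x, cfg, params)
  expect_equal(logits, matrix(params$head_b, 4, 3, byrow = TRUE))
})

test_that("a single-layer toy forward matches a hand-unrolled computation", {
  cfg <- mixer_config(n_timesteps = 4, features_per_group = 1, hidden_dim = 2,
                      n_layers = 1, temporal_hidden = 3, channel_hidden = 3,
                      n_classes = 2)
  params <- mixer_init(cfg, seed = 13)
  x <- array(rnorm(4), c(1, 4, 1))
  got <- mixer_forward(x, cfg, params, mode = "both")

  # hand-unrolled: encoder -> pre-norm temporal MLP + residual ->
  # pre-norm channel MLP + residual -> mean-pool -> head
  ln <- function(v, g, b) {
    mu <- mean(v); s <- sqrt(mean((v - mu)^2) + 1e-5)
    (v - mu) / s * g + b
  }
  h <- matrix(0, 4, 2)
  for (t in 1:4) h[t, ] <- x[1, t, 1] * params$enc_W[1, ] + params$enc_b
  y <- t(apply(h, 1, ln, g = params$l1_ln1_g, b = params$l1_ln1_b))
  for (c in 1:2) {
    col <- y[, c]
    a <- as.numeric(col %*% params$l1_t_W1) + params$l1_t_b1
    z <- (a * pnorm(a)) %*% params$l1_t_W2 + params$l1_t_b2
    h[, c] <- h[, c] + as.numeric(z)
  }
  y2 <- t(apply(h, 1, ln, g = params$l1_ln2_g, b = params$l1_ln2_b))
  for (t in 1:4) {
    a <- as.numeric(y2[t, ] %*% params$l1_c_W1) + params$l1_c_b1
    z <- (a * pnorm(a)) %*% params$l1_c_W2 + params$l1_c_b2
    h[t, ] <- h[t, ] + as.numeric(z)
  }
  feats <- colMeans(h)
  logits <- as.numeric(feats %*% params$head_W) + params$head_b
  expect_equal(as.numeric(got$features), feats, tolerance = 1e-9)
  expect_equal(as.numeric(got$logits), logits, tolerance = 1e-9)
})

test_that("zeroing both MLPs makes mixer layers the identity", {
  cfg <- mixer_config(n_timesteps = 8, features_per_group = 5, hidden_dim = 6,
                      n_layers = 3, temporal_hidden = 4, channel_hidden = 4,
                      n_classes = 2)
  params <- mixer_init(cfg, seed = 3)
  for (l in 1:3) {
    for (part in c("t_W1", "t_b1", "t_W2", "t_b2",
                   "c_W1", "c_b1", "c_W2", "c_b2")) {
      nm <- paste0("l", l, "_", part)
      params[[nm]] <- params[[nm]] * 0
    }
  }
  bare <- mixer_config(n_timesteps = 8, features_per_group = 5, hidden_dim = 6,
                       n_layers = 0, temporal_hidden = 4, channel_hidden = 4,
                       n_classes = 2)
  bare_params <- list(enc_W = params$enc_W, enc_b = params$enc_b,
                      head_W = params$head_W, head_b = params$head_b)
  x <- array(rnorm(3 * 8 * 5), c(3, 8, 5))
  expect_equal(mixer_forward(x, cfg, params),
               mixer_forward(x, bare, bare_params), tolerance = 1e-12)
})

test_that("forward output is per-sample (batch-order invariant)", {
  cfg <- mixer_config(n_timesteps = 6, features_per_group = 4, hidden_dim = 5,
                      n_layers = 2, temporal_hidden = 6, channel_hidden = 6,
                      n_classes = 3)
  params <- mixer_init(cfg, seed = 8)
  x <- array(rnorm(5 * 6 * 4), c(5, 6, 4))
  logits <- mixer_forward(x, cfg, params)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(mixer_forward(x[perm, , , drop = FALSE], cfg, params),
               logits[perm, ], tolerance = 1e-12)
})

test_that("analytic gradients match central differences", {
  cfg <- mixer_config(n_timesteps = 4, features_per_group = 3, hidden_dim = 4,
                      n_layers = 1, temporal_hidden = 5, channel_hidden = 5,
                      n_classes = 2)
  params <- mixer_init(cfg, seed = 17)
  set.seed(18)
  x <- array(rnorm(3 * 4 * 3), c(3, 4, 3))
  y <- c(1L, 2L, 1L)
  loss_of <- function(p) {
    out <- mixer_forward(x, cfg, p, mode = "both")
    cross_entropy(out$logits, y)$value + 0.25 * sum(out$features^2)
  }
  fwd <- mixer_forward(x, cfg, params, mode = "both", keep_cache = TRUE)
  ce <- cross_entropy(fwd$logits, y, want_grad = TRUE)
  grads <- mixer_backward(cfg, params, fwd$cache, d_logits = ce$grad,
                          d_features = 0.5 * fwd$features)
  eps <- 1e-5
  for (nm in c("enc_W", "l1_ln1_g", "l1_t_W1", "l1_t_b2", "l1_ln2_b",
               "l1_c_W2", "head_W", "head_b")) {
    idx <- seq_len(min(6L, length(params[[nm]])))
    for (i in idx) {
      up <- params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (loss_of(up) - loss_of(dn)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-5,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("parameter and MAC counts match a layer-by-layer tally", {
  # degenerate single-unit architecture: encoder 1 MAC + head 1 MAC
  cfg0 <- mixer_config(n_timesteps = 1, features_per_group = 1, hidden_dim = 1,
                       n_layers = 0, temporal_hidden = 1, channel_hidden = 1,
                       n_classes = 1)
  expect_equal(count_parameters_and_macs(cfg0)$macs, 2)

  cfg <- mixer_config_for(experiment_design("tufts"), n_classes = 2L)
  counts <- count_parameters_and_macs(cfg)
  # parameters: every array in an initialized parameter set
  params <- mixer_init(cfg, seed = 1)
  expect_equal(counts$parameters, sum(vapply(params, length, 1L)))
  # MACs: explicit enumeration of the linear maps, layer by layer
  layer_list <- list(c(8, 16, 150)) # encoder: in, out, applications
  for (l in seq_len(cfg$n_layers)) {
    layer_list <- c(layer_list,
                    list(c(150, 64, 16), c(64, 150, 16), # temporal MLP per channel
                         c(16, 32, 150), c(32, 16, 150))) # channel MLP per step
  }
  layer_list <- c(layer_list, list(c(16, 2, 1))) # head
  tally <- sum(vapply(layer_list, function(v) v[1] * v[2] * v[3], numeric(1)))
  expect_equal(counts$macs, tally)

  # doubling N exactly doubles the mixer-layer MAC term
  cfg2 <- mixer_config_for(experiment_design("tufts"), n_classes = 2L,
                           n_layers = 8L)
  enc_head <- 150 * 8 * 16 + 16 * 2
  expect_equal(count_parameters_and_macs(cfg2)$macs - enc_head,
               2 * (counts$macs - enc_head))
})

test_that("checkpoints round-trip through the JSON archive", {
  design <- tiny_design()
  cfg <- tiny_mixer_config(design)
  fit <- structure(list(params = mixer_init(cfg, 2), model_config = cfg,
                        train_config = NULL, class_set = design$class_set,
                        history = tibble::tibble(), best_epoch = 1L,
                        best_val_loss = 0.5, stop_reason = "max_epochs"),
                   class = "mixer_fit")
  path <- withr::local_tempfile(fileext = ".json")
  save_mixer_fit(fit, path)
  back <- load_mixer_fit(path)
  x <- tiny_set(design)$data[1:3, , , drop = FALSE]
  expect_equal(mixer_forward(x, back$model_config, back$params),
               mixer_forward(x, cfg, fit$params), tolerance = 1e-12)
})
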