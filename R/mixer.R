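#' Configuration of the fNIRS MLP-Mixer classifier
#'
#' A per-timestep fully connected encoder maps the flattened spatial features
#' (`n_probe_groups * features_per_group` per timestep) to a token of width
#' `hidden_dim`. `n_layers` mixer layers follow, each applying a pre-norm
#' temporal-mixing MLP along the time axis (T -> T, hidden `temporal_hidden`)
#' and a pre-norm channel-mixing MLP along the token axis (C -> C, hidden
#' `channel_hidden`), both with residual skip connections. Global average
#' pooling over time yields the feature vector used by the linear classifier
#' head and by all discrepancy losses.
#'
#' @param n_timesteps Sequence length T.
#' @param features_per_group Features per probe group per timestep (D).
#' @param n_probe_groups Number of probe groups (2 for a left/right forehead
#'   montage whose groups are flattened together, else 1).
#' @param hidden_dim Token width C.
#' @param n_layers Number of mixer layers N.
#' @param temporal_hidden,channel_hidden Hidden widths of the two MLPs.
#' @param n_classes Number of output classes M.
#' @param dropout_ratio Dropout probability applied to each MLP block output
#'   during training.
#' @return An object of class `mixer_config`.
#' @examples
#' cfg <- mixer_config_for(experiment_design("tufts"))
#' count_parameters_and_macs(cfg)
#' @export
mixer_config <- function(n_timesteps, features_per_group, n_probe_groups = 1L,
                         hidden_dim = 16L, n_layers = 4L,
                         temporal_hidden = 64L, channel_hidden = 32L,
                         n_classes = 2L, dropout_ratio = 0) {
  stopifnot(n_timesteps >= 1, features_per_group >= 1, n_probe_groups >= 1,
            hidden_dim >= 1, n_layers >= 0, n_classes >= 1,
            dropout_ratio >= 0, dropout_ratio < 1)
  structure(list(
    n_timesteps = as.integer(n_timesteps),
    features_per_group = as.integer(features_per_group),
    n_probe_groups = as.integer(n_probe_groups),
    hidden_dim = as.integer(hidden_dim),
    n_layers = as.integer(n_layers),
    temporal_hidden = as.integer(temporal_hidden),
    channel_hidden = as.integer(channel_hidden),
    n_classes = as.integer(n_classes),
    dropout_ratio = dropout_ratio
  ), class = "mixer_config")
}

#' Default mixer configuration for an experiment design
#'
#' Uses the probe-group split only for two-probe forehead montages (the
#' `"tufts"` preset); otherwise the whole feature vector is one group.
#'
#' @param design An [experiment_design()].
#' @param ... Overrides passed to [mixer_config()].
#' @return A `mixer_config`.
#' @export
mixer_config_for <- function(design, ...) {
  groups <- if (design$name == "tufts") 2L else 1L
  args <- list(
    n_timesteps = design$n_timesteps,
    features_per_group = n_features(design) %/% groups,
    n_probe_groups = groups,
    n_classes = length(design$class_set)
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(mixer_config, args)
}

encoder_width <- function(config) config$n_probe_groups * config$features_per_group

#' Initialize mixer parameters
#'
#' Glorot-uniform weights, zero biases, unit layer-norm gains.
#'
#' @param config A [mixer_config()].
#' @param seed Integer seed for the draws.
#' @return Named list of parameter arrays (class `mixer_params`).
#' @export
mixer_init <- function(config, seed = 1L) {
  stopifnot(inherits(config, "mixer_config"))
  set.seed(as.integer(seed))
  glorot <- function(n_in, n_out) {
    lim <- sqrt(6 / (n_in + n_out))
    matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
  }
  p <- list()
  f_in <- encoder_width(config)
  c_dim <- config$hidden_dim
  t_len <- config$n_timesteps
  p$enc_W <- glorot(f_in, c_dim); p$enc_b <- numeric(c_dim)
  for (l in seq_len(config$n_layers)) {
    pre <- paste0("l", l, "_")
    p[[paste0(pre, "ln1_g")]] <- rep(1, c_dim)
    p[[paste0(pre, "ln1_b")]] <- numeric(c_dim)
    p[[paste0(pre, "t_W1")]] <- glorot(t_len, config$temporal_hidden)
    p[[paste0(pre, "t_b1")]] <- numeric(config$temporal_hidden)
    p[[paste0(pre, "t_W2")]] <- glorot(config$temporal_hidden, t_len)
    p[[paste0(pre, "t_b2")]] <- numeric(t_len)
    p[[paste0(pre, "ln2_g")]] <- rep(1, c_dim)
    p[[paste0(pre, "ln2_b")]] <- numeric(c_dim)
    p[[paste0(pre, "c_W1")]] <- glorot(c_dim, config$channel_hidden)
    p[[paste0(pre, "c_b1")]] <- numeric(config$channel_hidden)
    p[[paste0(pre, "c_W2")]] <- glorot(config$channel_hidden, c_dim)
    p[[paste0(pre, "c_b2")]] <- numeric(c_dim)
  }
  p$head_W <- glorot(c_dim, config$n_classes)
  p$head_b <- numeric(config$n_classes)
  class(p) <- "mixer_params"
  p
}

#' Exact Gaussian-error linear unit
#'
#' `gelu(x) = x * Phi(x)` with the exact Gaussian CDF (not the tanh
#' approximation).
#'
#' @param x Numeric vector/matrix.
#' @return Same shape as `x`.
#' @export
gelu <- function(x) x * stats::pnorm(x)

gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

add_rows <- function(m, b) m + matrix(b, nrow(m), length(b), byrow = TRUE)

#' Two-layer MLP block with GELU
#'
#' `F = W2 gelu(W1 x + b1) + b2`, applied along the last axis of `x`. The
#' output has the same trailing dimension as the input so the block fits a
#' residual skip connection.
#'
#' @param x Numeric matrix or array whose last dimension equals `nrow(W1)`.
#' @param params List with `W1 [d_in x h]`, `b1 [h]`, `W2 [h x d_in]`,
#'   `b2 [d_in]`.
#' @return Same shape as `x`.
#' @export
mlp_block <- function(x, params) {
  d <- dim(x)
  if (is.null(d)) d <- c(1L, length(x))
  d_in <- d[length(d)]
  if (nrow(params$W1) != d_in || ncol(params$W2) != d_in) {
    stop("mlp_block: weight shapes do not match input width ", d_in, call. = FALSE)
  }
  m <- matrix(x, prod(d) / d_in, d_in)
  out <- add_rows(gelu(add_rows(m %*% params$W1, params$b1)) %*% params$W2,
                  params$b2)
  array(out, d)
}

# ---- forward / backward ----------------------------------------------------

layernorm_fwd <- function(m, g, b, eps = 1e-5) {
  mu <- rowMeans(m)
  xc <- m - mu
  v <- rowMeans(xc^2)
  inv_std <- 1 / sqrt(v + eps)
  xhat <- xc * inv_std
  list(y = xhat * matrix(g, nrow(m), length(g), byrow = TRUE) +
         matrix(b, nrow(m), length(b), byrow = TRUE),
       xhat = xhat, inv_std = inv_std)
}

layernorm_bwd <- function(dy, cache, g) {
  dxhat <- dy * matrix(g, nrow(dy), length(g), byrow = TRUE)
  dg <- colSums(dy * cache$xhat)
  db <- colSums(dy)
  dx <- cache$inv_std *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx, dg = dg, db = db)
}

mlp_fwd <- function(m, w1, b1, w2, b2) {
  a1 <- add_rows(m %*% w1, b1)
  z1 <- gelu(a1)
  list(y = add_rows(z1 %*% w2, b2), a1 = a1, z1 = z1, x = m)
}

mlp_bwd <- function(dy, cache, w1, w2) {
  dw2 <- crossprod(cache$z1, dy)
  db2 <- colSums(dy)
  da1 <- (dy %*% t(w2)) * gelu_grad(cache$a1)
  dw1 <- crossprod(cache$x, da1)
  db1 <- colSums(da1)
  list(dx = da1 %*% t(w1), dw1 = dw1, db1 = db1, dw2 = dw2, db2 = db2)
}

# [n,T,C] <-> matrix views
as_tc_matrix <- function(a) matrix(a, dim(a)[1] * dim(a)[2], dim(a)[3]) # rows (i,t), cols C
from_tc_matrix <- function(m, d) array(m, d)
as_ct_matrix <- function(a) { # rows (i,c), cols T
  p <- aperm(a, c(1, 3, 2))
  matrix(p, dim(a)[1] * dim(a)[3], dim(a)[2])
}
from_ct_matrix <- function(m, d) aperm(array(m, c(d[1], d[3], d[2])), c(1, 3, 2))

#' Run the mixer forward
#'
#' @param x Numeric array `[n x T x F]` with `F = n_probe_groups *
#'   features_per_group`, or an `epoch_set` (its data array is used).
#' @param config A [mixer_config()].
#' @param params A [mixer_init()] parameter list.
#' @param mode `"logits"` (default), `"features"` (pooled pre-head C-vector,
#'   the tap every discrepancy uses) or `"both"`.
#' @param training Apply dropout (draws from the current RNG stream)?
#' @param keep_cache Keep intermediates for [mixer_backward()]?
#' @return For `"logits"`: matrix `[n x M]`. For `"features"`: matrix
#'   `[n x C]`. For `"both"`: list with `logits`, `features` and (optionally)
#'   `cache`.
#' @export
mixer_forward <- function(x, config, params,
                          mode = c("logits", "features", "both"),
                          training = FALSE, keep_cache = FALSE) {
  mode <- match.arg(mode)
  if (inherits(x, "epoch_set")) x <- x$data
  if (length(dim(x)) == 4L) { # [n, groups, T, D] -> [n, T, groups*D]
    n <- dim(x)[1]; g <- dim(x)[2]; t_len <- dim(x)[3]; d_f <- dim(x)[4]
    x <- aperm(x, c(1, 3, 4, 2)) # n, T, D, G
    dim(x) <- c(n, t_len, d_f * g)
  }
  if (!all(is.finite(x))) stop("non-finite values in model input", call. = FALSE)
  n <- dim(x)[1]; t_len <- dim(x)[2]; f_in <- dim(x)[3]
  if (t_len != config$n_timesteps || f_in != encoder_width(config)) {
    stop("input shape [", t_len, " x ", f_in, "] does not match config [",
         config$n_timesteps, " x ", encoder_width(config), "]", call. = FALSE)
  }
  c_dim <- config$hidden_dim
  p_drop <- if (training) config$dropout_ratio else 0
  cache <- list(x_mat = matrix(x, n * t_len, f_in), n = n, t_len = t_len,
                layers = vector("list", config$n_layers), p_drop = p_drop)

  h <- from_tc_matrix(add_rows(cache$x_mat %*% params$enc_W, params$enc_b),
                      c(n, t_len, c_dim))
  for (l in seq_len(config$n_layers)) {
    pre <- paste0("l", l, "_")
    lc <- list()
    # temporal mixing (pre-norm over tokens, MLP along T, residual)
    lc$ln1_in <- as_tc_matrix(h)
    ln1 <- layernorm_fwd(lc$ln1_in, params[[paste0(pre, "ln1_g")]],
                         params[[paste0(pre, "ln1_b")]])
    lc$ln1 <- ln1
    y_ct <- as_ct_matrix(from_tc_matrix(ln1$y, dim(h)))
    tm <- mlp_fwd(y_ct, params[[paste0(pre, "t_W1")]], params[[paste0(pre, "t_b1")]],
                  params[[paste0(pre, "t_W2")]], params[[paste0(pre, "t_b2")]])
    lc$tm <- tm
    z <- tm$y
    if (p_drop > 0) {
      lc$t_mask <- matrix(stats::rbinom(length(z), 1, 1 - p_drop), nrow(z)) /
        (1 - p_drop)
      z <- z * lc$t_mask
    }
    h <- h + from_ct_matrix(z, dim(h))
    # channel mixing
    lc$ln2_in <- as_tc_matrix(h)
    ln2 <- layernorm_fwd(lc$ln2_in, params[[paste0(pre, "ln2_g")]],
                         params[[paste0(pre, "ln2_b")]])
    lc$ln2 <- ln2
    cm <- mlp_fwd(ln2$y, params[[paste0(pre, "c_W1")]], params[[paste0(pre, "c_b1")]],
                  params[[paste0(pre, "c_W2")]], params[[paste0(pre, "c_b2")]])
    lc$cm <- cm
    z2 <- cm$y
    if (p_drop > 0) {
      lc$c_mask <- matrix(stats::rbinom(length(z2), 1, 1 - p_drop), nrow(z2)) /
        (1 - p_drop)
      z2 <- z2 * lc$c_mask
    }
    h <- h + from_tc_matrix(z2, dim(h))
    cache$layers[[l]] <- lc
  }
  # global average pooling over T
  h_perm <- matrix(aperm(h, c(2, 1, 3)), t_len, n * c_dim)
  features <- matrix(colMeans(h_perm), n, c_dim)
  cache$features <- features
  logits <- add_rows(features %*% params$head_W, params$head_b)
  if (mode == "logits" && !keep_cache) return(logits)
  if (mode == "features" && !keep_cache) return(features)
  out <- list(logits = logits, features = features)
  if (keep_cache) out$cache <- cache
  out
}

# Backpropagate gradients given at the logits and/or at the pooled features.
# Returns a named list of parameter gradients matching mixer_init() layout.
mixer_backward <- function(config, params, cache, d_logits = NULL,
                           d_features = NULL) {
  n <- cache$n; t_len <- cache$t_len; c_dim <- config$hidden_dim
  grads <- list()
  d_feat <- if (is.null(d_features)) matrix(0, n, c_dim) else d_features
  if (!is.null(d_logits)) {
    grads$head_W <- crossprod(cache$features, d_logits)
    grads$head_b <- colSums(d_logits)
    d_feat <- d_feat + d_logits %*% t(params$head_W)
  } else {
    grads$head_W <- matrix(0, c_dim, config$n_classes)
    grads$head_b <- numeric(config$n_classes)
  }
  # pooling backward: spread over T
  dh_perm <- matrix(rep(as.numeric(d_feat) / t_len, each = t_len),
                    t_len, n * c_dim)
  dh <- aperm(array(dh_perm, c(t_len, n, c_dim)), c(2, 1, 3))
  for (l in rev(seq_len(config$n_layers))) {
    pre <- paste0("l", l, "_")
    lc <- cache$layers[[l]]
    # channel mixing backward
    dz2 <- as_tc_matrix(dh)
    if (!is.null(lc$c_mask)) dz2 <- dz2 * lc$c_mask
    cmb <- mlp_bwd(dz2, lc$cm, params[[paste0(pre, "c_W1")]],
                   params[[paste0(pre, "c_W2")]])
    grads[[paste0(pre, "c_W1")]] <- cmb$dw1
    grads[[paste0(pre, "c_b1")]] <- cmb$db1
    grads[[paste0(pre, "c_W2")]] <- cmb$dw2
    grads[[paste0(pre, "c_b2")]] <- cmb$db2
    lnb2 <- layernorm_bwd(cmb$dx, lc$ln2, params[[paste0(pre, "ln2_g")]])
    grads[[paste0(pre, "ln2_g")]] <- lnb2$dg
    grads[[paste0(pre, "ln2_b")]] <- lnb2$db
    dh <- dh + from_tc_matrix(lnb2$dx, dim(dh))
    # temporal mixing backward
    dz_ct <- as_ct_matrix(dh)
    if (!is.null(lc$t_mask)) dz_ct <- dz_ct * lc$t_mask
    tmb <- mlp_bwd(dz_ct, lc$tm, params[[paste0(pre, "t_W1")]],
                   params[[paste0(pre, "t_W2")]])
    grads[[paste0(pre, "t_W1")]] <- tmb$dw1
    grads[[paste0(pre, "t_b1")]] <- tmb$db1
    grads[[paste0(pre, "t_W2")]] <- tmb$dw2
    grads[[paste0(pre, "t_b2")]] <- tmb$db2
    d_ln1_y <- as_tc_matrix(from_ct_matrix(tmb$dx, dim(dh)))
    lnb1 <- layernorm_bwd(d_ln1_y, lc$ln1, params[[paste0(pre, "ln1_g")]])
    grads[[paste0(pre, "ln1_g")]] <- lnb1$dg
    grads[[paste0(pre, "ln1_b")]] <- lnb1$db
    dh <- dh + from_tc_matrix(lnb1$dx, dim(dh))
  }
  dh_mat <- as_tc_matrix(dh)
  grads$enc_W <- crossprod(cache$x_mat, dh_mat)
  grads$enc_b <- colSums(dh_mat)
  grads
}

#' Closed-form parameter and multiply-accumulate counts
#'
#' Parameters count every weight, bias and layer-norm gain/shift. MACs count
#' the multiply-accumulates of the linear maps only (encoder, the two MLPs of
#' each layer, head), for one forward pass of one sample; layer-norm, GELU and
#' bias additions are excluded.
#'
#' @param config A [mixer_config()].
#' @return A tibble with `parameters` and `macs`.
#' @export
count_parameters_and_macs <- function(config) {
  stopifnot(inherits(config, "mixer_config"))
  f_in <- encoder_width(config)
  t_len <- config$n_timesteps; c_dim <- config$hidden_dim
  t_h <- config$temporal_hidden; c_h <- config$channel_hidden
  m <- config$n_classes; n_l <- config$n_layers
  params <- f_in * c_dim + c_dim +
    n_l * (4 * c_dim + # two layernorm gain/shift pairs
             t_len * t_h + t_h + t_h * t_len + t_len +
             c_dim * c_h + c_h + c_h * c_dim + c_dim) +
    c_dim * m + m
  macs <- t_len * f_in * c_dim +
    n_l * (c_dim * (t_len * t_h + t_h * t_len) +
             t_len * (c_dim * c_h + c_h * c_dim)) +
    c_dim * m
  tibble::tibble(parameters = params, macs = macs)
}
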