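#' Configuration of a generative stochastic network
#'
#' A GSN is a stacked denoising auto-encoder (DAE) whose
#' corrupt-encode-decode cycle is the transition operator of a Markov
#' chain over samples X = (J, G, R); the chain's stationary distribution
#' estimates the data distribution.  Hidden-layer widths are drawn
#' uniformly from `[2d, 5d]` (d = sample dimension) under the recorded
#' seed unless given explicitly, in which case they must lie in that
#' range relative to each layer's input dimension.
#'
#' @param d sample dimension.
#' @param r number of stacked DAE layers (>= 1).
#' @param widths optional integer vector of r hidden widths.
#' @param corruption_sd corruption noise scale theta1, on the
#'   standardized (unit-variance) scale; >= 0.
#' @param corruption_family `"gaussian"` (default) or `"t"`
#'   (heavy-tailed, 3 df scaled to `corruption_sd`).
#' @param recon_family reconstruction sampling family, `"gaussian"`
#'   (default) or `"t"`.
#' @param alpha damping factor on the reconstruction step of the
#'   transition operator (default 1 = full step).
#' @param epochs training epochs per layer.
#' @param learning_rate,momentum,batch_size minibatch SGD parameters.
#' @param walkback logical; interleave Gibbs-resampled points with the
#'   original training set during training (walkback training).
#' @param walkback_mix fraction of each epoch's pool drawn by Gibbs
#'   resampling (default 0.5, i.e. resampled and original points 1:1).
#' @param chain_steps,burn_in sampling-chain defaults; `chain_steps >
#'   burn_in >= 0`.
#' @param calibration_rounds fixed-point refinement rounds of the
#'   post-training moment calibration (0 disables the chain-based
#'   refinement).
#' @param calibration_chains,calibration_keep parallel chains and
#'   retained steps per chain used to estimate the stationary mean
#'   drift in each refinement round.
#' @param seed integer seed controlling width draws, initialization,
#'   corruption and minibatch order.
#' @return an object of class `"gsn_config"`.
#' @export
gsn_config <- function(d, r = 1L, widths = NULL,
                       corruption_sd = 0.5,
                       corruption_family = c("gaussian", "t"),
                       recon_family = c("gaussian", "t"),
                       alpha = 1,
                       epochs = 80L, learning_rate = 0.05,
                       momentum = 0.9, batch_size = 32L,
                       walkback = TRUE, walkback_mix = 0.5,
                       chain_steps = 60L, burn_in = 20L,
                       calibration_rounds = 2L,
                       calibration_chains = 64L,
                       calibration_keep = 120L,
                       seed = 1L) {
  corruption_family <- match.arg(corruption_family)
  recon_family <- match.arg(recon_family)
  if (r < 1L) bad_field("r", "need at least one layer")
  if (corruption_sd < 0) bad_field("corruption_sd", "must be >= 0")
  if (!(chain_steps > burn_in && burn_in >= 0))
    bad_field("chain_steps", "need chain_steps > burn_in >= 0")
  # input dimension of each layer: d, then the previous widths
  if (is.null(widths)) {
    set.seed(sub_seed(seed, "widths"))
    widths <- integer(r)
    din <- d
    for (l in seq_len(r)) {
      widths[l] <- sample(seq.int(2L * din, 5L * din), 1L)
      din <- widths[l]
    }
  } else {
    if (length(widths) != r) bad_field("widths", "must have length r")
    din <- d
    for (l in seq_len(r)) {
      if (widths[l] < 2L * din || widths[l] > 5L * din)
        bad_field("widths",
                  sprintf("layer %d width %d outside [2d, 5d] = [%d, %d]",
                          l, widths[l], 2L * din, 5L * din))
      din <- widths[l]
    }
  }
  structure(list(d = as.integer(d), r = as.integer(r),
                 widths = as.integer(widths),
                 corruption_sd = corruption_sd,
                 corruption_family = corruption_family,
                 recon_family = recon_family, alpha = alpha,
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 walkback = isTRUE(walkback), walkback_mix = walkback_mix,
                 chain_steps = as.integer(chain_steps),
                 burn_in = as.integer(burn_in),
                 calibration_rounds = as.integer(calibration_rounds),
                 calibration_chains = as.integer(calibration_chains),
                 calibration_keep = as.integer(calibration_keep),
                 seed = as.integer(seed)),
            class = "gsn_config")
}

#' Corrupt samples with the configured noise family
#'
#' The corruption distribution P0(x^- | x): additive Gaussian noise by
#' default, or scaled Student-t (3 df) as the heavy-tailed alternative.
#' Scale 0 returns the input unchanged.  Uses the current RNG stream.
#'
#' @param x numeric vector or matrix of samples (rows).
#' @param scale noise scale (>= 0).
#' @param family `"gaussian"` or `"t"`.
#' @return corrupted copy of `x`.
#' @export
corrupt <- function(x, scale, family = c("gaussian", "t")) {
  family <- match.arg(family)
  if (scale < 0) bad_field("scale", "must be >= 0")
  if (scale == 0) return(x)
  m <- length(x)
  noise <- if (family == "gaussian") stats::rnorm(m, sd = scale) else
    stats::rt(m, df = 3) * scale / sqrt(3)  # unit-variance t3, rescaled
  x + noise
}

#' Training-set summary statistics and initial hidden state
#'
#' Computes the sample mean `x_star` and sample covariance `M_star`
#' (divisor n - 1) of the dataset, and the initial hidden state `H0`
#' used to launch the hidden Markov chain: the deterministic first-layer
#' encoding of `x_star`.  Before training (no `model`), the encoding of
#' the standardized mean is `tanh(b1) = 0`, so `H0` is the zero vector
#' of the first hidden width.
#'
#' @param data an `adr_dataset` or numeric sample matrix (rows =
#'   samples); needs at least 2 rows.
#' @param model optional fitted [gsn()] model providing the trained
#'   first-layer encoder.
#' @return list with `x_star`, `M_star`, `H0`.
#' @export
init_hidden_state <- function(data, model = NULL) {
  X <- if (inherits(data, "adr_dataset")) data$X else as.matrix(data)
  if (nrow(X) < 2L)
    bad_field("data", "need at least 2 samples for a sample covariance")
  x_star <- colMeans(X)
  M_star <- stats::cov(X)
  H0 <- if (is.null(model)) NULL else
    drop(layer_encode(model$layers[[1L]],
                      matrix(standardize(model, x_star), 1L)))
  list(x_star = x_star, M_star = M_star, H0 = H0)
}

## ---- internal DAE machinery -------------------------------------------

layer_init <- function(p, w, seed) {
  set.seed(seed)
  s <- sqrt(6 / (p + w))
  list(W1 = matrix(stats::runif(p * w, -s, s), p, w), b1 = numeric(w),
       W2 = matrix(stats::runif(w * p, -s, s), w, p), b2 = numeric(p))
}

layer_encode <- function(layer, X) {
  tanh(X %*% layer$W1 + rep(layer$b1, each = nrow(X)))
}

layer_decode <- function(layer, H) {
  H %*% layer$W2 + rep(layer$b2, each = nrow(H))
}

encode_stack <- function(layers, X) {
  for (l in layers) X <- layer_encode(l, X)
  X
}

decode_stack <- function(layers, H) {
  for (l in rev(layers)) H <- layer_decode(l, H)
  H
}

# one SGD minibatch update (squared reconstruction loss, momentum)
layer_sgd_step <- function(layer, vel, Xclean, Xcorrupt, lr, mom) {
  b <- nrow(Xclean)
  H <- layer_encode(layer, Xcorrupt)
  Xhat <- layer_decode(layer, H)
  dXhat <- 2 * (Xhat - Xclean) / (b * ncol(Xclean))
  gW2 <- crossprod(H, dXhat)
  gb2 <- colSums(dXhat)
  dH <- (dXhat %*% t(layer$W2)) * (1 - H * H)
  gW1 <- crossprod(Xcorrupt, dH)
  gb1 <- colSums(dH)
  vel$W1 <- mom * vel$W1 - lr * gW1
  vel$b1 <- mom * vel$b1 - lr * gb1
  vel$W2 <- mom * vel$W2 - lr * gW2
  vel$b2 <- mom * vel$b2 - lr * gb2
  layer$W1 <- layer$W1 + vel$W1
  layer$b1 <- layer$b1 + vel$b1
  layer$W2 <- layer$W2 + vel$W2
  layer$b2 <- layer$b2 + vel$b2
  list(layer = layer, vel = vel)
}

#' Train one denoising auto-encoder layer
#'
#' Minimizes the squared reconstruction loss of clean inputs from
#' corrupted inputs by minibatch SGD with momentum, optionally
#' interleaving Gibbs-resampled points (walkback) with the originals in
#' each epoch's training pool.  Exposed for inspection; [gsn()] calls it
#' layerwise.
#'
#' @param inputs numeric matrix (rows = samples), already on the scale
#'   the layer sees.
#' @param width hidden width.
#' @param corruption_sd,corruption_family corruption parameters.
#' @param epochs,learning_rate,momentum,batch_size SGD parameters.
#' @param walkback,walkback_mix see [gsn_config()].
#' @param seed integer seed (initialization, corruption, batch order).
#' @return list with the trained `layer` (weights W1, b1, W2, b2) and
#'   `loss`, the per-epoch clean-reconstruction MSE.
#' @export
dae_train_layer <- function(inputs, width, corruption_sd = 0.3,
                            corruption_family = "gaussian",
                            epochs = 80L, learning_rate = 0.05,
                            momentum = 0.9, batch_size = 32L,
                            walkback = FALSE, walkback_mix = 0.5,
                            seed = 1L) {
  X <- as.matrix(inputs)
  n <- nrow(X); p <- ncol(X)
  layer <- layer_init(p, width, sub_seed(seed, "init"))
  vel <- lapply(layer, function(m) m * 0)
  set.seed(sub_seed(seed, "sgd"))
  loss <- numeric(epochs)
  for (e in seq_len(epochs)) {
    # stepped learning-rate decay for a clean final fit
    lr_e <- learning_rate * if (e > 0.85 * epochs) 0.1 else
      if (e > 0.6 * epochs) 0.3 else 1
    target <- X
    input <- corrupt(X, corruption_sd, corruption_family)
    if (walkback && walkback_mix > 0) {
      # walkback pairs: Gibbs-resampled inputs several corruption/
      # reconstruction steps away, still trained to reconstruct the
      # ORIGINAL clean point
      nw <- max(1L, round(walkback_mix * n))
      idx <- sample.int(n, nw, replace = TRUE)
      walk <- corrupt(X[idx, , drop = FALSE], corruption_sd,
                      corruption_family)
      Xhat <- layer_decode(layer, layer_encode(layer, walk))
      resid_s <- sqrt(mean((Xhat - X[idx, , drop = FALSE])^2))
      walk <- Xhat + matrix(stats::rnorm(nw * p, sd = resid_s), nw, p)
      walk <- corrupt(walk, corruption_sd, corruption_family)
      target <- rbind(X, X[idx, , drop = FALSE])
      input <- rbind(input, walk)
    }
    ord <- sample.int(nrow(target))
    for (start in seq(1L, nrow(target), by = batch_size)) {
      rows <- ord[start:min(start + batch_size - 1L, nrow(target))]
      upd <- layer_sgd_step(layer, vel, target[rows, , drop = FALSE],
                            input[rows, , drop = FALSE],
                            lr_e, momentum)
      layer <- upd$layer; vel <- upd$vel
    }
    recon <- layer_decode(layer, layer_encode(layer, X))
    loss[e] <- mean((recon - X)^2)
    if (!is.finite(loss[e]))
      stop("DAE training diverged (non-finite loss at epoch ", e,
           "); reduce learning_rate", call. = FALSE)
  }
  list(layer = layer, loss = loss)
}

standardize <- function(model, x) {
  if (is.matrix(x))
    sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  else (x - model$center) / model$scale
}

unstandardize <- function(model, z) {
  if (is.matrix(z))
    sweep(sweep(z, 2, model$scale, "*"), 2, model$center, "+")
  else z * model$scale + model$center
}

#' Fit a generative stochastic network
#'
#' Trains the stacked DAE layer by layer on the (internally
#' standardized) sample matrix, each layer on the previous layer's
#' clean encodings, with per-epoch walkback pools mixing Gibbs-resampled
#' points with the originals.  After training, the per-coordinate
#' reconstruction-residual scale under corruption is estimated; it is
#' the scale of the Gaussian reconstruction draw in the sampling chain
#' (for linear-Gaussian data this equals the posterior sd of the clean
#' sample given its corrupted version, which makes the chain's
#' stationary moments match the training moments).
#'
#' @param data an `adr_dataset` or numeric sample matrix (rows =
#'   samples).
#' @param config a [gsn_config()]; default configuration derived from
#'   the data dimension.
#' @param ... passed to [gsn_config()] when `config` is NULL.
#' @return an object of class `"gsn"`: layers, per-layer loss curves,
#'   training summary statistics `x_star` / `M_star`, initial hidden
#'   state `H0`, standardization, reconstruction scale, and block
#'   metadata when fitted to an `adr_dataset`.
#' @export
gsn <- function(data, config = NULL, ...) {
  X <- if (inherits(data, "adr_dataset")) data$X else as.matrix(data)
  if (nrow(X) < 2L) bad_field("data", "need at least 2 samples")
  if (is.null(config)) config <- gsn_config(d = ncol(X), ...)
  if (config$d != ncol(X))
    bad_field("config", sprintf("config d = %d but data has d = %d",
                                config$d, ncol(X)))
  center <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scl, "/")
  layers <- vector("list", config$r)
  losses <- vector("list", config$r)
  inputs <- Z
  for (l in seq_len(config$r)) {
    fit <- dae_train_layer(inputs, config$widths[l],
                           corruption_sd = config$corruption_sd,
                           corruption_family = config$corruption_family,
                           epochs = config$epochs,
                           learning_rate = config$learning_rate,
                           momentum = config$momentum,
                           batch_size = config$batch_size,
                           walkback = config$walkback,
                           walkback_mix = config$walkback_mix,
                           seed = sub_seed(config$seed, paste0("layer", l)))
    layers[[l]] <- fit$layer
    losses[[l]] <- fit$loss
    inputs <- layer_encode(fit$layer, inputs)
  }
  # Moment calibration of the Gaussian reconstruction conditional
  # (whose parameters are a mean map and a covariance) so that the
  # training distribution is a fixed point of the chain in first and
  # second moments: (i) recentre the top decoder so the one-step mean
  # displacement vanishes (a residual bias would be amplified by
  # 1/(1 - slope) under iteration); (ii) set the reconstruction draw
  # covariance to the second-moment deficit of the reconstruction under
  # corruption.  For an L2-optimal linear map this is exactly the
  # posterior covariance of the clean sample given its corrupted
  # version.  Calibrated first against the training set, then refined
  # against the chain's own marginal (a fixed-point iteration), because
  # the nonlinear map's displacement under the chain marginal is what
  # stationarity actually involves.
  set.seed(sub_seed(config$seed, "calibrate"))
  mu_z <- colMeans(Z)
  cov_z <- stats::cov(Z)
  one_step <- function(Zin, passes = 2L) {
    # reconstruction-mean outputs over a few corruption draws
    out <- vector("list", passes)
    for (k in seq_len(passes)) {
      Zc <- corrupt(Zin, config$corruption_sd, config$corruption_family)
      out[[k]] <- decode_stack(layers, encode_stack(layers, Zc))
    }
    do.call(rbind, out)
  }
  psd_chol <- function(C) {
    C <- (C + t(C)) / 2
    e <- eigen(C, symmetric = TRUE)
    chol(e$vectors %*% diag(pmax(e$values, 1e-8),
                            length(e$values)) %*% t(e$vectors))
  }
  passes <- 3L
  Yhat <- one_step(Z, passes = passes)
  # linear response A of the reconstruction-mean map to the clean input
  Zrep <- Z[rep(seq_len(nrow(Z)), passes), , drop = FALSE]
  A <- t(solve(cov_z + diag(1e-8, ncol(Z)),
               stats::cov(Zrep, Yhat)))
  layers[[1L]]$b2 <- layers[[1L]]$b2 - (colMeans(Yhat) - mu_z)
  recon_chol <- psd_chol(cov_z - stats::cov(Yhat))
  # fixed-point refinement: cancel the stationary mean drift of the
  # chain, whose linear gain with respect to a decoder-bias shift is
  # (I - A)^{-1}
  for (round in seq_len(config$calibration_rounds %||% 2L)) {
    tmp <- structure(list(layers = layers, recon_chol = recon_chol,
                          config = config,
                          center = rep(0, ncol(Z)),
                          scale = rep(1, ncol(Z))), class = "gsn")
    m <- config$calibration_chains %||% 64L
    Zchain <- run_chain(tmp, matrix(rep(mu_z, each = m), m),
                        steps = config$burn_in +
                          (config$calibration_keep %||% 120L),
                        burn_in = config$burn_in)
    drift <- colMeans(Zchain) - mu_z
    layers[[1L]]$b2 <- layers[[1L]]$b2 -
      drop((diag(ncol(Z)) - A) %*% drift)
  }
  recon_sd <- sqrt(diag(crossprod(recon_chol)))
  model <- structure(list(
    config = config, layers = layers, loss = losses,
    center = center, scale = scl, recon_sd = recon_sd,
    recon_chol = recon_chol,
    x_star = colMeans(X), M_star = stats::cov(X),
    blocks = if (inherits(data, "adr_dataset")) data$blocks else NULL,
    group_levels = if (inherits(data, "adr_dataset")) data$group_levels
      else NULL,
    var_names = colnames(X),
    n_train = nrow(X)), class = "gsn")
  model$H0 <- drop(layer_encode(layers[[1L]],
                                matrix(standardize(model, model$x_star),
                                       1L)))
  model
}

#' One application of the chain's transition operator
#'
#' Maps a chain state (H_i, x_i) to (H_\{i+1\}, x_\{i+1\}): corrupt the
#' visible sample, encode through the stack to the new hidden state,
#' decode to the reconstruction mean, and draw the new visible sample
#' from the reconstruction conditional (Gaussian with the model's
#' per-coordinate residual scale), damped by `alpha`.  Uses the current
#' RNG stream.
#'
#' @param state list with element `x` (visible sample, original scale;
#'   vector or matrix of parallel chains) and optional `step`.
#' @param model a fitted [gsn()].
#' @return list with `H` (new hidden state, top layer), `x`, `step`.
#' @export
transition_step <- function(state, model) {
  x <- state$x
  vec <- !is.matrix(x)
  Z <- standardize(model, if (vec) matrix(x, 1L) else x)
  if (ncol(Z) != model$config$d) bad_field("state$x", "dimension mismatch")
  cfg <- model$config
  Zc <- corrupt(Z, cfg$corruption_sd, cfg$corruption_family)
  H <- encode_stack(model$layers, Zc)
  Zhat <- decode_stack(model$layers, H)
  m <- nrow(Z); p <- ncol(Z)
  eps <- if (cfg$recon_family == "gaussian")
    matrix(stats::rnorm(m * p), m, p) else
      matrix(stats::rt(m * p, df = 3) / sqrt(3), m, p)
  draw <- Zhat + eps %*% model$recon_chol
  Znew <- Z + cfg$alpha * (draw - Z)
  xnew <- unstandardize(model, Znew)
  if (vec) xnew <- drop(xnew)
  list(H = if (vec) drop(H) else H, x = xnew,
       step = (state$step %||% 0L) + 1L)
}

# run n parallel chains, optionally clamping columns to observed values;
# returns retained (post-burn-in) visible states, averaged if `average`
run_chain <- function(model, x0, steps, burn_in, clamp_idx = NULL,
                      clamp_values = NULL, average = FALSE,
                      thin_collect = TRUE) {
  state <- list(x = x0, step = 0L)
  m <- nrow(x0)
  keep <- NULL
  acc <- matrix(0, m, ncol(x0))
  nacc <- 0L
  for (s in seq_len(steps)) {
    state <- transition_step(state, model)
    if (!is.null(clamp_idx))
      state$x[, clamp_idx] <- clamp_values
    if (s > burn_in) {
      if (average) {
        acc <- acc + state$x
        nacc <- nacc + 1L
      } else keep <- rbind(keep, state$x)
    }
  }
  if (average) acc / nacc else keep
}
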