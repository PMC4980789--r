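#' @export
print.gsn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Generative stochastic network (stacked DAE, %d layer%s)\n",
              cfg$r, if (cfg$r > 1) "s" else ""))
  cat(sprintf("  d = %d, widths = [%s], trained on %d samples\n",
              cfg$d, paste(cfg$widths, collapse = ", "), x$n_train))
  cat(sprintf("  corruption: %s(sd = %g); reconstruction: %s; alpha = %g\n",
              cfg$corruption_family, cfg$corruption_sd, cfg$recon_family,
              cfg$alpha))
  cat(sprintf("  final reconstruction MSE: %s\n",
              paste(signif(vapply(x$loss, function(l) l[length(l)],
                                  numeric(1)), 3), collapse = ", ")))
  invisible(x)
}

#' @export
summary.gsn <- function(object, ...) {
  out <- list(config = object$config,
              n_train = object$n_train,
              final_loss = vapply(object$loss, function(l) l[length(l)],
                                  numeric(1)),
              recon_sd = summary(object$recon_sd),
              H0_norm = sqrt(sum(object$H0^2)))
  class(out) <- "summary.gsn"
  out
}

#' @export
print.summary.gsn <- function(x, ...) {
  cat(sprintf("GSN summary: %d layers, d = %d, n_train = %d\n",
              x$config$r, x$config$d, x$n_train))
  cat("per-layer final reconstruction MSE:",
      paste(signif(x$final_loss, 4), collapse = ", "), "\n")
  cat("reconstruction draw scale (standardized):\n")
  print(x$recon_sd)
  cat(sprintf("|H0| = %.3f\n", x$H0_norm))
  invisible(x)
}

#' Model parameters of a fitted GSN
#'
#' Returns the reconstruction parameters theta2: the encoder/decoder
#' weights and biases of every DAE layer.
#'
#' @param object a fitted [gsn()].
#' @param ... unused.
#' @return list of per-layer lists (W1, b1, W2, b2).
#' @export
coef.gsn <- function(object, ...) object$layers

#' Plot per-layer training loss curves
#'
#' @param x a fitted [gsn()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.gsn <- function(x, ...) {
  L <- do.call(cbind, x$loss)
  graphics::matplot(L, type = "l", lty = 1, xlab = "epoch",
                    ylab = "reconstruction MSE",
                    main = "DAE training loss by layer", ...)
  graphics::legend("topright", legend = paste("layer", seq_len(ncol(L))),
                   col = seq_len(ncol(L)), lty = 1, bty = "n")
  invisible(x)
}

#' Reconstruction residuals of a fitted GSN
#'
#' Clean-pass residuals `x - decode(encode(x))` on the supplied samples
#' (original scale).
#'
#' @param object a fitted [gsn()].
#' @param data an `adr_dataset` or sample matrix; required (the model
#'   does not retain its training data).
#' @param ... unused.
#' @return residual matrix with the dimensions of the input.
#' @export
residuals.gsn <- function(object, data, ...) {
  if (missing(data)) bad_field("data", "supply the samples to reconstruct")
  X <- if (inherits(data, "adr_dataset")) data$X else as.matrix(data)
  Z <- standardize(object, X)
  Zhat <- decode_stack(object$layers, encode_stack(object$layers, Z))
  X - unstandardize(object, Zhat)
}

#' Draw samples from the GSN's stationary distribution
#'
#' Runs parallel sampling chains (initialized at the training mean) and
#' returns post-burn-in visible states; with enough steps these are
#' draws from the chain's stationary distribution, the model's estimate
#' of the data distribution.
#'
#' @param object a fitted [gsn()].
#' @param nsim number of samples to return.
#' @param seed integer seed.
#' @param n_chains number of parallel chains (default 32).
#' @param burn_in burn-in steps per chain (default from config).
#' @param ... unused.
#' @return numeric matrix `nsim x d` on the original data scale.
#' @export
simulate.gsn <- function(object, nsim = 1000L, seed = 1L,
                         n_chains = 32L, burn_in = NULL, ...) {
  burn_in <- burn_in %||% object$config$burn_in
  set.seed(sub_seed(seed, "simulate"))
  m <- min(n_chains, nsim)
  steps <- burn_in + ceiling(nsim / m)
  x0 <- matrix(rep(object$x_star, each = m), m)
  colnames(x0) <- object$var_names
  out <- run_chain(object, x0, steps, burn_in)
  out[seq_len(nsim), , drop = FALSE]
}

#' Predict ADR outcomes by clamped conditional sampling
#'
#' For each query subject the sampling chain is run with the observed
#' covariate and genotype coordinates (J, G) clamped back to their
#' observed values after every transition, so the chain explores the
#' conditional distribution of the ADR block R given (J, G).  The
#' prediction is the post-burn-in chain mean of R (continuous), or its
#' ordinal rounding onto \{-2..2\} for classification output.
#'
#' @param object a fitted [gsn()] (must have been fitted to an
#'   `adr_dataset`, so block metadata is available).
#' @param newdata an `adr_dataset` (its R block is ignored) or a matrix
#'   of d columns in training order.
#' @param type `"numeric"` (default; chain mean) or `"ordinal"`
#'   (rounded and clipped to -2..2).
#' @param chain_steps,burn_in chain length; retained samples number
#'   `chain_steps - burn_in`.
#' @param seed integer seed; fixed seed gives deterministic output.
#' @param ... unused.
#' @return numeric matrix `n x 14` of per-category predictions.
#' @export
predict.gsn <- function(object, newdata, type = c("numeric", "ordinal"),
                        chain_steps = NULL, burn_in = NULL, seed = 1L,
                        ...) {
  type <- match.arg(type)
  if (is.null(object$blocks))
    bad_field("object", "model was not fitted to an adr_dataset; no (J, G, R) blocks to clamp")
  X <- if (inherits(newdata, "adr_dataset")) newdata$X else
    as.matrix(newdata)
  if (ncol(X) != object$config$d)
    bad_field("newdata", "column dimension does not match the model")
  chain_steps <- chain_steps %||% object$config$chain_steps
  burn_in <- burn_in %||% object$config$burn_in
  obs_idx <- c(object$blocks$J, object$blocks$G)
  r_idx <- object$blocks$R
  x0 <- X
  x0[, r_idx] <- rep(object$x_star[r_idx], each = nrow(X))
  set.seed(sub_seed(seed, "predict"))
  avg <- run_chain(object, x0, chain_steps, burn_in,
                   clamp_idx = obs_idx,
                   clamp_values = X[, obs_idx, drop = FALSE],
                   average = TRUE)
  pred <- avg[, r_idx, drop = FALSE]
  colnames(pred) <- adr_categories()
  if (type == "ordinal") pred <- pmax(pmin(round(pred), 2), -2)
  pred
}

#' Serialize a fitted GSN to versioned JSON
#'
#' All weights are stored as plain JSON arrays (text only).
#'
#' @param model a fitted [gsn()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gsn <- function(model, path) {
  payload <- list(format = "gsnadr-model/1",
                  config = unclass(model$config),
                  layers = lapply(model$layers, function(l)
                    lapply(l, function(m) unname(as.matrix(m)))),
                  center = unname(model$center),
                  scale = unname(model$scale),
                  recon_sd = unname(model$recon_sd),
                  recon_chol = unname(as.matrix(model$recon_chol)),
                  x_star = unname(model$x_star),
                  M_star = unname(model$M_star),
                  H0 = unname(model$H0),
                  loss = model$loss,
                  blocks = model$blocks,
                  group_levels = model$group_levels,
                  var_names = model$var_names,
                  n_train = model$n_train)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized GSN model
#' @param path path written by [write_gsn()].
#' @return a `"gsn"` object.
#' @export
read_gsn <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "gsnadr-model/1"))
    bad_field("path", "not a gsnadr-model/1 file")
  cfg <- p$config
  class(cfg) <- "gsn_config"
  # jsonlite stores the list of layers column-wise (one list per field)
  r <- length(p$layers$W1)
  layers <- lapply(seq_len(r), function(l)
    list(W1 = as.matrix(p$layers$W1[[l]]),
         b1 = as.numeric(p$layers$b1[[l]]),
         W2 = as.matrix(p$layers$W2[[l]]),
         b2 = as.numeric(p$layers$b2[[l]])))
  blocks <- if (length(p$blocks)) lapply(p$blocks, as.integer) else NULL
  model <- structure(list(
    config = cfg, layers = layers, loss = p$loss,
    center = stats::setNames(p$center, p$var_names),
    scale = stats::setNames(p$scale, p$var_names),
    recon_sd = p$recon_sd,
    recon_chol = as.matrix(p$recon_chol),
    x_star = stats::setNames(p$x_star, p$var_names),
    M_star = as.matrix(p$M_star),
    blocks = blocks, group_levels = p$group_levels,
    var_names = p$var_names, H0 = p$H0,
    n_train = p$n_train), class = "gsn")
  model
}
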