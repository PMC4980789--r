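#' Fit the penalized least-squares (LASSO) baseline
#'
#' Per-category lasso regressions of the 14 ADR ordinals on the (J, G)
#' feature block: squared loss with an L1 penalty.  `lambda = NULL`
#' (default) selects each category's penalty by 5-fold cross-validation;
#' `lambda = 0` is solved exactly by ordinary least squares (with a rank
#' check), the OLS limit of the penalty path.
#'
#' @param train an `adr_dataset`.
#' @param lambda penalty weight: NULL (cross-validated), 0 (exact OLS),
#'   or a positive scalar shared across categories.
#' @param features `"JG"` (default) or `"G"`: which blocks enter the
#'   design.
#' @param nfolds cross-validation folds (default 5).
#' @param seed integer seed for fold assignment.
#' @return object of class `"adr_lasso"`: intercepts (length 14),
#'   coefficient matrix (p x 14), lambdas used.
#' @export
lasso_fit <- function(train, lambda = NULL, features = c("JG", "G"),
                      nfolds = 5L, seed = 1L) {
  features <- match.arg(features)
  if (n_samples(train) == 0L) bad_field("train", "empty training set")
  xy <- ds_xy(train, features)
  x <- xy$x; y <- xy$y
  p <- ncol(x)
  coefs <- matrix(0, p, 14L, dimnames = list(colnames(x),
                                             adr_categories()))
  icpt <- numeric(14L)
  lambdas <- numeric(14L)
  if (!is.null(lambda) && length(lambda) == 1L && lambda == 0) {
    X1 <- cbind(1, x)
    qx <- qr(X1)
    if (qx$rank < ncol(X1))
      warning("design is rank-deficient at lambda = 0; ",
              "dropped directions get zero coefficients", call. = FALSE)
    for (j in seq_len(14L)) {
      b <- qr.coef(qx, y[, j])
      b[is.na(b)] <- 0
      icpt[j] <- b[1L]
      coefs[, j] <- b[-1L]
    }
  } else {
    for (j in seq_len(14L)) {
      if (stats::var(y[, j]) == 0) {
        # constant target (e.g. a category absent from a small split):
        # the penalized solution is the constant itself
        icpt[j] <- y[1L, j]
        lambdas[j] <- NA_real_
        next
      }
      if (is.null(lambda)) {
        set.seed(sub_seed(seed, paste0("cv", j)))
        nf <- max(3L, min(nfolds, nrow(x) %/% 3L))
        cv <- tryCatch(
          suppressWarnings(
            glmnet::cv.glmnet(x, y[, j], alpha = 1, nfolds = nf,
                              nlambda = 30L, standardize = TRUE)),
          error = function(e) NULL)
        if (is.null(cv)) {
          # near-degenerate response (constant within folds): the
          # cross-validated penalty collapses the fit to the mean
          icpt[j] <- mean(y[, j])
          lambdas[j] <- NA_real_
          next
        }
        lam <- cv$lambda.min
        fit <- cv$glmnet.fit
      } else {
        lam <- lambda
        fit <- glmnet::glmnet(x, y[, j], alpha = 1, standardize = TRUE)
      }
      cf <- as.numeric(glmnet::coef.glmnet(fit, s = lam, exact = FALSE))
      icpt[j] <- cf[1L]
      coefs[, j] <- cf[-1L]
      lambdas[j] <- lam
    }
  }
  structure(list(intercepts = icpt, coefficients = coefs,
                 lambda = lambdas, features = features),
            class = "adr_lasso")
}

#' @export
print.adr_lasso <- function(x, ...) {
  cat(sprintf("LASSO baseline: %d features -> 14 ADR categories\n",
              nrow(x$coefficients)))
  cat(sprintf("nonzero coefficients: %d; lambda: %s\n",
              sum(x$coefficients != 0),
              paste(signif(unique(x$lambda), 3), collapse = ", ")))
  invisible(x)
}

#' @export
coef.adr_lasso <- function(object, ...)
  rbind("(Intercept)" = object$intercepts, object$coefficients)

#' Predict from the LASSO baseline
#'
#' Affine in the features for a fixed model.
#'
#' @param object an `"adr_lasso"`.
#' @param newdata an `adr_dataset` or feature matrix matching the
#'   training design.
#' @param ... unused.
#' @return numeric matrix `n x 14`.
#' @export
predict.adr_lasso <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "adr_dataset"))
    ds_xy(newdata, object$features)$x else as.matrix(newdata)
  out <- x %*% object$coefficients +
    rep(object$intercepts, each = nrow(x))
  colnames(out) <- adr_categories()
  out
}

#' Alias: lasso prediction operation
#' @inheritParams predict.adr_lasso
#' @param model an `"adr_lasso"`.
#' @return numeric matrix `n x 14`.
#' @export
lasso_predict <- function(model, newdata) predict(model, newdata)

#' Transductive k-nearest-neighbour multi-target regression
#'
#' Predicts each query's 14 ADR values as the unweighted mean of the R
#' blocks of its k nearest training subjects under Euclidean distance on
#' the (J, G) feature block.  No function is fitted: prediction reads
#' the training instances directly (transductive learning).  Distance
#' ties are broken by stable (ascending) training-row index.
#'
#' @param train an `adr_dataset`.
#' @param queries an `adr_dataset` or feature matrix.
#' @param k neighbourhood size, `1 <= k <= n_train`.
#' @param features `"JG"` (default) or `"G"`.
#' @return numeric matrix `n_query x 14`.
#' @export
knn_predict <- function(train, queries, k = 5L,
                        features = c("JG", "G")) {
  features <- match.arg(features)
  n <- n_samples(train)
  if (n == 0L) bad_field("train", "empty training set")
  if (k < 1L || k > n)
    bad_field("k", sprintf("must be in [1, %d]", n))
  xy <- ds_xy(train, features)
  q <- if (inherits(queries, "adr_dataset"))
    ds_xy(queries, features)$x else as.matrix(queries)
  tx <- xy$x
  # squared Euclidean distances, queries x train
  d2 <- outer(rowSums(q^2), rowSums(tx^2), "+") - 2 * q %*% t(tx)
  out <- matrix(0, nrow(q), 14L, dimnames = list(NULL, adr_categories()))
  for (i in seq_len(nrow(q))) {
    nb <- order(d2[i, ])[seq_len(k)]   # order() is stable: index ties
    out[i, ] <- colMeans(xy$y[nb, , drop = FALSE])
  }
  out
}

## ---- uniform model interface for the evaluation protocols -------------

#' Model specifications for the evaluation protocols
#'
#' Each constructor returns a `fit`/`predict` pair with a label, so the
#' ratio and noise sweeps can train and evaluate the LASSO (M1), kNN
#' (M2), GSN (M3) and global-mean null models uniformly.  `fit(train,
#' seed)` returns a fitted object; `predict(fit, test)` an `n x 14`
#' matrix.
#'
#' @param lambda,features see [lasso_fit()].
#' @return an object of class `"adr_model"`.
#' @export
model_lasso <- function(lambda = NULL, features = "JG") {
  structure(list(
    label = "lasso",
    fit = function(train, seed = 1L)
      lasso_fit(train, lambda = lambda, features = features, seed = seed),
    predict = function(fit, test) predict(fit, test)),
    class = "adr_model")
}

#' @rdname model_lasso
#' @param k neighbourhood size.
#' @export
model_knn <- function(k = 5L, features = "JG") {
  structure(list(
    label = "knn",
    fit = function(train, seed = 1L)
      list(train = train, k = k, features = features),
    predict = function(fit, test)
      knn_predict(fit$train, test, k = min(fit$k, n_samples(fit$train)),
                  features = fit$features)),
    class = "adr_model")
}

#' @rdname model_lasso
#' @param ... arguments passed to [gsn_config()] (except `d` and
#'   `seed`, supplied at fit time).
#' @export
model_gsn <- function(...) {
  dots <- list(...)
  structure(list(
    label = "gsn",
    fit = function(train, seed = 1L) {
      cfg <- do.call(gsn_config,
                     c(list(d = ncol(train$X), seed = seed), dots))
      gsn(train, cfg)
    },
    predict = function(fit, test) predict(fit, test)),
    class = "adr_model")
}

#' @rdname model_lasso
#' @export
model_null <- function() {
  structure(list(
    label = "null",
    fit = function(train, seed = 1L)
      colMeans(train$X[, train$blocks$R, drop = FALSE]),
    predict = function(fit, test)
      matrix(fit, n_samples(test), 14L, byrow = TRUE,
             dimnames = list(NULL, adr_categories()))),
    class = "adr_model")
}

#' @export
print.adr_model <- function(x, ...) {
  cat(sprintf("<adr_model> %s\n", x$label))
  invisible(x)
}
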