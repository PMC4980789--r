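#' Average accuracy loss (mean relative error)
#'
#' The accuracy-loss statistic `l_a = (1/n) sum_i |(h(x_i) - y_i*) /
#' y_i*|`, the mean relative error of predictions against ground truth,
#' reported in percent.  Most ADR coordinates are 0, where the relative
#' error is undefined; the default policy replaces a zero denominator by
#' 1, i.e. falls back to absolute error on the -2..2 ordinal scale.  The
#' strict alternative skips zero-truth terms.
#'
#' @param predictions,truths equal-length numeric vectors (or matrices,
#'   compared elementwise).
#' @param zero_policy `"unit"` (default: denominator 1 where truth is 0)
#'   or `"skip"` (drop zero-truth terms).
#' @param percent report in percent (default TRUE).
#' @return scalar l_a (`NA` if `"skip"` leaves no terms).
#' @export
accuracy_loss <- function(predictions, truths,
                          zero_policy = c("unit", "skip"),
                          percent = TRUE) {
  zero_policy <- match.arg(zero_policy)
  h <- as.numeric(predictions); y <- as.numeric(truths)
  if (length(h) != length(y))
    bad_field("predictions", "length differs from truths")
  if (length(h) == 0L) bad_field("predictions", "need at least one term")
  denom <- abs(y)
  keep <- rep(TRUE, length(y))
  if (zero_policy == "unit") denom[y == 0] <- 1 else keep <- y != 0
  if (!any(keep)) return(NA_real_)
  la <- mean(abs(h[keep] - y[keep]) / denom[keep])
  if (percent) 100 * la else la
}

#' Per-category accuracy-loss report
#'
#' Applies [accuracy_loss()] to each of the 14 ADR coordinates across
#' the test subjects, plus the overall loss pooled over all coordinates.
#'
#' @param predictions numeric matrix `n x 14` of model predictions.
#' @param test an `adr_dataset` (truths taken from its R block) or a
#'   truth matrix `n x 14`.
#' @param condition label of the protocol condition (ratio, noise
#'   level, ...).
#' @param seed seed used to produce the condition (metadata).
#' @inheritParams accuracy_loss
#' @return object of class `"loss_report"`: named `per_category` vector
#'   (percent), `overall`, `n_test`, `condition`, `seed`.
#' @export
per_category_loss <- function(predictions, test, condition = NA,
                              seed = NA,
                              zero_policy = c("unit", "skip")) {
  zero_policy <- match.arg(zero_policy)
  y <- if (inherits(test, "adr_dataset"))
    test$X[, test$blocks$R, drop = FALSE] else as.matrix(test)
  predictions <- as.matrix(predictions)
  if (!all(dim(predictions) == dim(y)))
    bad_field("predictions", "dimensions do not match the test targets")
  if (nrow(y) == 0L) bad_field("test", "empty test set")
  percat <- vapply(seq_len(14L), function(j)
    accuracy_loss(predictions[, j], y[, j], zero_policy), numeric(1L))
  names(percat) <- adr_categories()
  structure(list(per_category = percat,
                 overall = accuracy_loss(predictions, y, zero_policy),
                 n_test = nrow(y), condition = condition, seed = seed),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, digits = 1, ...) {
  cat(sprintf("Accuracy loss l_a (%%), condition = %s, n_test = %d\n",
              format(x$condition), x$n_test))
  print(round(x$per_category, digits))
  cat(sprintf("overall: %.*f%%\n", digits, x$overall))
  invisible(x)
}

#' Convert a loss report (or list of them) to a data frame
#'
#' Long format with one row per (condition, model, category) cell,
#' `category = "overall"` included — the tabular mirror of the
#' per-category report layout.
#'
#' @param x a `loss_report`, or a named list of them (names = models).
#' @param ... unused.
#' @return data frame with columns condition, model, category, l_a,
#'   n_test.
#' @export
as.data.frame.loss_report <- function(x, ...) {
  data.frame(condition = x$condition,
             category = c(names(x$per_category), "overall"),
             l_a = c(unname(x$per_category), x$overall),
             n_test = x$n_test, row.names = NULL)
}

# split a dataset into train/test at a training fraction
split_dataset <- function(ds, train_frac, seed) {
  n <- n_samples(ds)
  ntr <- round(train_frac * n)
  if (ntr < 1L || ntr > n - 1L)
    bad_field("train_frac",
              sprintf("fraction %g leaves an empty train or test set",
                      train_frac))
  set.seed(seed)
  idx <- sample.int(n, ntr)
  list(train = ds_subset(ds, idx), test = ds_subset(ds, -idx))
}

fit_and_score <- function(models, train, test, cond_seed, condition,
                          zero_policy = "unit") {
  out <- list()
  for (m in models) {
    fit <- m$fit(train, seed = sub_seed(cond_seed, m$label))
    pred <- m$predict(fit, test)
    rep_ <- per_category_loss(pred, test, condition = condition,
                              seed = cond_seed,
                              zero_policy = zero_policy)
    df <- as.data.frame(rep_)
    df$model <- m$label
    out[[m$label]] <- df
  }
  do.call(rbind, out)
}

#' Train/test ratio sweep
#'
#' For each training fraction, draws a random split, trains every model
#' on the training part and reports the accuracy loss on the held-out
#' part.  One split per condition by default; replicate seeds supported
#' for variance control.
#'
#' @param dataset an `adr_dataset`.
#' @param models list of [model_lasso()] / [model_knn()] / [model_gsn()]
#'   / [model_null()] specifications.
#' @param ratios training fractions, a subset of 0.1..0.9 (0.1 = 1:9
#'   train:test, 0.9 = 9:1).
#' @param seed master seed; split and fit seeds are derived from it.
#' @param replicates number of independent replicate splits per ratio.
#' @param zero_policy passed to [accuracy_loss()].
#' @return object of class `"sweep_result"`: a long data frame (ratio,
#'   replicate, model, category, l_a, n_test) with a `condition_var`
#'   attribute.
#' @export
ratio_sweep <- function(dataset, models,
                        ratios = seq(0.1, 0.9, by = 0.1),
                        seed = 1L, replicates = 1L,
                        zero_policy = "unit") {
  if (any(ratios <= 0 | ratios >= 1))
    bad_field("ratios", "training fractions must be inside (0, 1)")
  rows <- list()
  for (rep_i in seq_len(replicates)) {
    rep_seed <- sub_seed(seed, paste0("replicate", rep_i))
    for (rat in ratios) {
      cond_seed <- sub_seed(rep_seed, paste0("ratio", rat))
      sp <- split_dataset(dataset, rat, cond_seed)
      df <- fit_and_score(models, sp$train, sp$test, cond_seed,
                          condition = rat, zero_policy = zero_policy)
      df$replicate <- rep_i
      names(df)[names(df) == "condition"] <- "ratio"
      rows[[length(rows) + 1L]] <- df
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("sweep_result", "data.frame"),
            condition_var = "ratio")
}

#' Scale of the training-noise protocol at one level
#'
#' Level m in 0..5 perturbs every training feature with Gaussian noise
#' whose mean is `m * 0.1 * a` (a = the feature's training average) and
#' whose variance is half that mean (level 0 = no noise).
#'
#' @param level integer 0..5.
#' @param feature_means vector a of per-feature training averages.
#' @return list with per-feature `mean` and `sd` of the noise.
#' @export
noise_spec <- function(level, feature_means) {
  if (!(level %in% 0:5)) bad_field("level", "must be an integer in 0..5")
  mu <- level * 0.1 * feature_means
  list(mean = mu, sd = sqrt(pmax(mu, 0) / 2))
}

#' Gaussian-noise robustness sweep
#'
#' Splits the data evenly in half (5:5 train:test), then for each noise
#' level perturbs every training feature (J and G blocks only — targets
#' and test data are untouched) per [noise_spec()], trains every model
#' on the noisy training set and evaluates on the clean held-out half.
#' Perturbed dummy variables are not re-binarized.
#'
#' @param dataset an `adr_dataset`.
#' @param models list of model specifications.
#' @param levels noise levels, subset of 0..5.
#' @param seed master seed.
#' @param replicates replicate splits per level.
#' @param zero_policy passed to [accuracy_loss()].
#' @return a `"sweep_result"` long data frame (level, replicate, model,
#'   category, l_a, n_test).
#' @export
noise_sweep <- function(dataset, models, levels = 0:5, seed = 1L,
                        replicates = 1L, zero_policy = "unit") {
  rows <- list()
  feat_idx <- c(dataset$blocks$J, dataset$blocks$G)
  for (rep_i in seq_len(replicates)) {
    rep_seed <- sub_seed(seed, paste0("replicate", rep_i))
    sp <- split_dataset(dataset, 0.5, sub_seed(rep_seed, "split"))
    a <- colMeans(sp$train$X[, feat_idx, drop = FALSE])
    for (lv in levels) {
      cond_seed <- sub_seed(rep_seed, paste0("level", lv))
      train <- sp$train
      if (lv > 0L) {
        ns <- noise_spec(lv, a)
        set.seed(sub_seed(cond_seed, "noise"))
        ntr <- n_samples(train)
        noise <- matrix(stats::rnorm(ntr * length(feat_idx)),
                        ntr, length(feat_idx))
        noise <- sweep(noise, 2, ns$sd, "*")
        noise <- sweep(noise, 2, ns$mean, "+")
        train$X[, feat_idx] <- train$X[, feat_idx] + noise
      }
      df <- fit_and_score(models, train, sp$test, cond_seed,
                          condition = lv, zero_policy = zero_policy)
      df$replicate <- rep_i
      names(df)[names(df) == "condition"] <- "level"
      rows[[length(rows) + 1L]] <- df
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("sweep_result", "data.frame"),
            condition_var = "level")
}

#' Median overall accuracy loss per condition and model
#'
#' Summarizes a sweep result: the across-replicate median (and its
#' standard error, 1.2533 * sd / sqrt(n), the large-sample normal-theory
#' scaling) of the overall l_a for each model at each condition.
#'
#' @param sweep a `"sweep_result"`.
#' @return data frame (condition, model, median_la, se_median, n).
#' @export
sweep_summary <- function(sweep) {
  cv <- attr(sweep, "condition_var")
  ov <- sweep[sweep$category == "overall", ]
  agg <- function(f) stats::aggregate(ov$l_a,
                                      by = list(condition = ov[[cv]],
                                                model = ov$model),
                                      FUN = f)
  med <- agg(stats::median)
  sdv <- agg(stats::sd)
  nn <- agg(length)
  out <- data.frame(condition = med$condition, model = med$model,
                    median_la = med$x,
                    se_median = 1.2533 * sdv$x / sqrt(nn$x),
                    n = nn$x)
  out[order(out$model, out$condition), ]
}

#' Plot a sweep result
#'
#' Median overall l_a per model against the sweep condition.
#'
#' @param x a `"sweep_result"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.sweep_result <- function(x, ...) {
  sm <- sweep_summary(x)
  models <- unique(sm$model)
  conds <- sort(unique(sm$condition))
  M <- sapply(models, function(m)
    sm$median_la[sm$model == m][order(sm$condition[sm$model == m])])
  graphics::matplot(conds, M, type = "b", pch = 19, lty = 1,
                    xlab = attr(x, "condition_var"),
                    ylab = "median overall l_a (%)", ...)
  graphics::legend("topright", legend = models, col = seq_along(models),
                   lty = 1, pch = 19, bty = "n")
  invisible(x)
}

#' Write a loss report as a TSV table
#'
#' Rows = ADR categories (plus overall), columns = models — the shape
#' of a per-category accuracy table.
#'
#' @param reports named list of `loss_report`s (names = model labels).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_loss_table <- function(reports, path) {
  tab <- data.frame(`ADR category` = c(adr_categories(), "overall"),
                    check.names = FALSE)
  for (nm in names(reports))
    tab[[nm]] <- round(c(reports[[nm]]$per_category,
                         reports[[nm]]$overall), 1)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
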