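#' Build a numeric dataset from a cohort table
#'
#' Converts a cohort data frame (one row per subject: `subject_id`,
#' `group_id`, `dose`, five genotype columns with base-pair labels, 14
#' ADR columns with ordinal grades) into the numeric sample matrix used
#' by all models, with every row an X = (J, G, R) vector sharing the
#' same block metadata.
#'
#' @param cohort data frame in the cohort schema (see [read_cohort()]).
#' @param covariates which covariates enter the J block: any subset of
#'   `c("dose", "group")`.  Default both.
#' @return an object of class `"adr_dataset"`: a list with the `n x d`
#'   matrix `X`, the `blocks` index list, `group_levels`, and
#'   `subject_id`.
#' @export
as_dataset <- function(cohort, covariates = c("dose", "group")) {
  covariates <- match.arg(covariates, several.ok = TRUE)
  check_cohort(cohort)
  n <- nrow(cohort)
  group_levels <- sort(unique(as.character(cohort$group_id)))
  jcols <- list()
  if ("dose" %in% covariates) jcols$dose <- as.numeric(cohort$dose)
  if ("group" %in% covariates)
    for (gl in group_levels)
      jcols[[paste0("group.", gl)]] <- as.numeric(cohort$group_id == gl)
  J <- if (length(jcols)) do.call(cbind, jcols) else
    matrix(numeric(0), nrow = n, ncol = 0)
  G <- genotype_dummies(cohort)
  R <- as.matrix(cohort[, adr_categories(), drop = FALSE])
  storage.mode(R) <- "double"
  X <- cbind(J, G, R)
  if (n == 0L) X <- matrix(numeric(0), 0L,
                           ncol(J) + 29L,
                           dimnames = list(NULL, c(colnames(J), dummy_names(),
                                                   adr_categories())))
  colnames(X) <- c(colnames(J), dummy_names(), adr_categories())
  structure(list(
    X = X,
    blocks = list(J = seq_len(ncol(J)),
                  G = ncol(J) + 1:15,
                  R = ncol(J) + 15L + 1:14),
    group_levels = group_levels,
    subject_id = as.character(cohort$subject_id)),
    class = "adr_dataset")
}

# vectorized 15-dummy coding of the genotype columns of a cohort table
genotype_dummies <- function(cohort) {
  n <- nrow(cohort)
  labs <- genotype_labels()
  G <- matrix(0, n, 15L, dimnames = list(NULL, dummy_names()))
  for (i in seq_len(5L)) {
    lc <- cyp_loci()[i]
    v <- as.character(cohort[[lc]])
    v[is.na(v)] <- ""
    s <- match(v, labs[[lc]])
    bad <- is.na(s) & v != ""
    if (any(bad))
      bad_field(lc, sprintf("row %d: unknown genotype '%s'",
                            which(bad)[1L], v[which(bad)[1L]]))
    ok <- which(!is.na(s))
    G[cbind(ok, (i - 1L) * 3L + s[ok])] <- 1
  }
  G
}

# one cohort row -> genotype_record
cohort_row_record <- function(cohort, i) {
  labs <- genotype_labels()
  calls <- vapply(cyp_loci(), function(lc) {
    v <- as.character(cohort[[lc]][i])
    if (is.na(v) || v == "") return("MISSING")
    s <- match(v, labs[[lc]])
    if (is.na(s))
      bad_field(lc, sprintf("row %d: unknown genotype '%s'", i, v))
    .call_states[s]
  }, character(1L))
  genotype_record(cohort$subject_id[i], cohort$group_id[i],
                  cohort$dose[i], calls)
}

check_cohort <- function(cohort) {
  need <- c("subject_id", "group_id", "dose", cyp_loci(), adr_categories())
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    bad_field("cohort", paste("missing required columns:",
                              paste(miss, collapse = ", ")))
  if (nrow(cohort)) {
    if (!is.numeric(cohort$dose) || anyNA(cohort$dose))
      bad_field("dose", "must be numeric and non-missing")
    for (cat in adr_categories()) {
      v <- cohort[[cat]]
      if (!all(v %in% -2:2))
        bad_field(cat, sprintf("row %d: grade outside [-2, 2]",
                               which(!(v %in% -2:2))[1L]))
    }
  }
  invisible(cohort)
}

#' @export
print.adr_dataset <- function(x, ...) {
  cat(sprintf("<adr_dataset> %d samples, d = %d (J: %d, G: 15, R: 14)\n",
              nrow(x$X), ncol(x$X), length(x$blocks$J)))
  cat("groups:", paste(x$group_levels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.adr_dataset <- function(x) dim(x$X)

#' Number of samples in a dataset
#' @param ds an `adr_dataset`.
#' @return integer.
#' @export
n_samples <- function(ds) nrow(ds$X)

#' Subset the rows of a dataset
#' @param ds an `adr_dataset`.
#' @param idx integer or logical row index.
#' @return an `adr_dataset` with the selected samples.
#' @export
ds_subset <- function(ds, idx) {
  stopifnot(inherits(ds, "adr_dataset"))
  out <- ds
  out$X <- ds$X[idx, , drop = FALSE]
  out$subject_id <- ds$subject_id[idx]
  out
}

#' Extract the feature (J, G) and target (R) matrices of a dataset
#' @param ds an `adr_dataset`.
#' @param features which blocks form the feature matrix: `"JG"`
#'   (default) or `"G"`.
#' @return list with matrices `x` (features) and `y` (ADR targets).
#' @export
ds_xy <- function(ds, features = c("JG", "G")) {
  features <- match.arg(features)
  fidx <- if (features == "JG") c(ds$blocks$J, ds$blocks$G) else ds$blocks$G
  list(x = ds$X[, fidx, drop = FALSE],
       y = ds$X[, ds$blocks$R, drop = FALSE])
}
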