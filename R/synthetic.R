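#' Default per-locus genotype frequencies
#'
#' Count-ratio frequencies of the typed cohort (e.g. 59/74 wild-type
#' homozygotes at CYP2D6*2), which sum to 1 exactly; the undetected
#' CYP2D6*14 locus defaults to all wild-type.
#'
#' @return named list of length-3 probability triples
#'   (wild-hom, het, var-hom).
#' @export
table1_freqs <- function() {
  cnt <- table1_counts()
  out <- lapply(cnt, function(x) {
    tot <- sum(x)
    p <- if (tot == 0L) c(1, 0, 0) else as.numeric(x) / tot
    stats::setNames(p, c("wt", "het", "hom"))
  })
  out
}

#' Specification of a synthetic cohort
#'
#' Collects every generator parameter: cohort size, per-locus genotype
#' frequencies, the planted 15 x 14 genotype-to-ADR effect matrix W,
#' per-category intercepts, the latent-to-ordinal thresholds, latent
#' noise, and genotype missingness.  ADR grades are generated by an
#' ordinal latent-threshold model: per subject and category,
#' `L = g' W[, j] + intercept[j] + Normal(0, noise_sd)` is cut at the
#' four thresholds into \{-2, -1, 0, 1, 2\}.
#'
#' @param n subject count.
#' @param genotype_freqs named list of 5 probability triples (each sums
#'   to 1 within 1e-9); default [table1_freqs()].
#' @param effect_matrix 15 x 14 real matrix of planted effects (rows =
#'   genotype dummies, columns = ADR categories); default all zero.
#' @param intercepts length-14 reals; default calibrated with
#'   [prevalence_to_intercept()] so that, under a null effect matrix,
#'   each category's nonzero rate matches the reported category counts
#'   among 83 subjects.
#' @param thresholds strictly increasing length-4 cut-points; default
#'   `c(-3.4, -2.6, 2.6, 3.4)`, a central no-ADR band of +/- 2.6 latent
#'   noise units, wide enough that the baseline nonzero rate (0.9%)
#'   sits below the rarest reported category so every published rate is
#'   reachable by the intercept calibration.
#' @param noise_sd non-negative latent noise sd; default 1.
#' @param missing_rate_genotype per-locus genotype missingness
#'   probability in `[0, 1]`; default 0.
#' @param seed integer seed; the generator is a pure function of
#'   (spec, seed).
#' @return an object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n,
                        genotype_freqs = table1_freqs(),
                        effect_matrix = matrix(0, 15, 14),
                        intercepts = NULL,
                        thresholds = c(-3.4, -2.6, 2.6, 3.4) *
                          max(noise_sd, 1e-12),
                        noise_sd = 1,
                        missing_rate_genotype = 0,
                        seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n))
    bad_field("n", "must be a single non-negative integer")
  if (!setequal(names(genotype_freqs), cyp_loci()))
    bad_field("genotype_freqs", "must be named by the 5 loci")
  genotype_freqs <- genotype_freqs[cyp_loci()]
  for (lc in cyp_loci()) {
    p <- genotype_freqs[[lc]]
    if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      bad_field(paste0("genotype_freqs[", lc, "]"),
                "must be 3 non-negative probabilities summing to 1")
  }
  if (!is.matrix(effect_matrix) || !all(dim(effect_matrix) == c(15L, 14L)))
    bad_field("effect_matrix", "must be a 15 x 14 matrix")
  if (length(thresholds) != 4L || any(diff(thresholds) <= 0))
    bad_field("thresholds", "must be 4 strictly increasing cut-points")
  if (noise_sd < 0) bad_field("noise_sd", "must be non-negative")
  if (missing_rate_genotype < 0 || missing_rate_genotype > 1)
    bad_field("missing_rate_genotype", "must be in [0, 1]")
  if (is.null(intercepts)) {
    intercepts <- if (noise_sd > 0) {
      target <- as.numeric(table2_counts()) / 83
      vapply(target, prevalence_to_intercept, numeric(1L),
             thresholds = thresholds, noise_sd = noise_sd)
    } else rep(0, 14L)
  }
  if (length(intercepts) != 14L)
    bad_field("intercepts", "must have length 14")
  structure(list(n = as.integer(n), genotype_freqs = genotype_freqs,
                 effect_matrix = effect_matrix,
                 intercepts = as.numeric(intercepts),
                 thresholds = as.numeric(thresholds),
                 noise_sd = noise_sd,
                 missing_rate_genotype = missing_rate_genotype,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Nonzero-ADR probability of the latent-threshold model
#'
#' Closed-form Gaussian probability that a category's ordinal grade is
#' nonzero given its latent intercept: `1 - (pnorm((t3 - b)/sd) -
#' pnorm((t2 - b)/sd))` with `(t2, t3)` the central cut-points.
#'
#' @param intercept latent intercept b.
#' @param thresholds length-4 cut-points.
#' @param noise_sd latent noise sd (> 0).
#' @return probability in (0, 1).
#' @export
nonzero_prevalence <- function(intercept, thresholds, noise_sd = 1) {
  1 - (stats::pnorm((thresholds[3L] - intercept) / noise_sd) -
         stats::pnorm((thresholds[2L] - intercept) / noise_sd))
}

#' Intercept achieving a target nonzero-ADR prevalence
#'
#' Inverts [nonzero_prevalence()] in the intercept (restricted to
#' non-negative intercepts, i.e. excess ADRs on the increased side).
#'
#' @param target desired nonzero probability.
#' @param thresholds length-4 cut-points.
#' @param noise_sd latent noise sd (> 0).
#' @return the intercept b >= 0.
#' @export
prevalence_to_intercept <- function(target, thresholds, noise_sd = 1) {
  stopifnot(noise_sd > 0, target > 0, target < 1)
  base <- nonzero_prevalence(0, thresholds, noise_sd)
  if (target <= base) return(0)
  stats::uniroot(function(b)
    nonzero_prevalence(b, thresholds, noise_sd) - target,
    lower = 0, upper = thresholds[4L] + 10 * noise_sd,
    tol = 1e-10)$root
}

#' A deterministic planted effect matrix for benchmark cohorts
#'
#' Assigns each ADR category one strong primary effect and one weaker
#' opposite-sign secondary effect from the 12 informative genotype
#' dummies (the CYP2D6*14 dummies are structurally zero under the
#' default frequencies and carry no effect).
#'
#' @param strength magnitude of the primary planted effect (latent
#'   units); secondary effects have magnitude `strength / 2`.
#' @return a 15 x 14 matrix.
#' @export
example_effect_matrix <- function(strength = 2) {
  W <- matrix(0, 15L, 14L, dimnames = list(dummy_names(), adr_categories()))
  informative <- c(1:6, 10:15)
  for (j in seq_len(14L)) {
    i1 <- informative[(j - 1L) %% 12L + 1L]
    i2 <- informative[(j + 4L) %% 12L + 1L]
    W[i1, j] <- strength * if (j %% 2L == 1L) 1 else -1
    W[i2, j] <- -strength / 2
  }
  W
}

#' Sample subject genotypes from a cohort specification
#'
#' Each locus is drawn independently from its frequency triple (no
#' linkage disequilibrium); missingness is applied independently per
#' locus at `missing_rate_genotype`.  Subjects are assigned to the
#' trial/blank groups with equal probability; dose is 1 in the trial
#' group and 0 in the blank group.
#'
#' @param spec a [cohort_spec()].
#' @return a cohort data frame without ADR columns.
#' @export
sample_genotypes <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  set.seed(sub_seed(spec$seed, "genotypes"))
  group <- if (n) sample(c("trial", "blank"), n, replace = TRUE) else
    character(0)
  out <- data.frame(subject_id = sprintf("P%05d", seq_len(n)),
                    group_id = group,
                    dose = as.numeric(group == "trial"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  labs <- genotype_labels()
  for (lc in cyp_loci()) {
    g <- if (n) sample(labs[[lc]], n, replace = TRUE,
                       prob = spec$genotype_freqs[[lc]]) else character(0)
    if (spec$missing_rate_genotype > 0 && n)
      g[stats::runif(n) < spec$missing_rate_genotype] <- ""
    out[[lc]] <- g
  }
  out
}

#' Sample graded ADR outcomes given genotypes
#'
#' Applies the ordinal latent-threshold model of the spec to the 15
#' genotype dummies of each subject.
#'
#' @param genotypes cohort data frame from [sample_genotypes()] (ADR
#'   columns, if present, are ignored).
#' @param spec the [cohort_spec()].
#' @return integer matrix `n x 14` of grades in \{-2..2\}.
#' @export
sample_adrs <- function(genotypes, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- nrow(genotypes)
  if (n == 0L)
    return(matrix(integer(0), 0L, 14L,
                  dimnames = list(NULL, adr_categories())))
  G <- genotype_dummies(genotypes)
  set.seed(sub_seed(spec$seed, "adrs"))
  L <- G %*% spec$effect_matrix +
    matrix(spec$intercepts, n, 14L, byrow = TRUE) +
    matrix(stats::rnorm(n * 14L, sd = spec$noise_sd), n, 14L)
  grade <- matrix(findInterval(L, spec$thresholds) - 2L, n, 14L,
                  dimnames = list(NULL, adr_categories()))
  storage.mode(grade) <- "integer"
  grade
}

empty_adr_frame <- function(n) {
  as.data.frame(matrix(0L, n, 14L, dimnames = list(NULL, adr_categories())),
                check.names = FALSE)
}

#' Generate a full synthetic cohort
#'
#' Composition of [sample_genotypes()] and [sample_adrs()]; pure
#' function of (spec, seed).
#'
#' @param spec a [cohort_spec()].
#' @param as return an `"adr_dataset"` (default) or the raw `"cohort"`
#'   data frame.
#' @return dataset or cohort data frame per `as`.
#' @export
make_cohort <- function(spec, as = c("dataset", "cohort")) {
  as <- match.arg(as)
  geno <- sample_genotypes(spec)
  adr <- sample_adrs(geno, spec)
  cohort <- cbind(geno, as.data.frame(adr, check.names = FALSE))
  if (as == "cohort") cohort else as_dataset(cohort)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> n = %d, noise_sd = %g, ",
                     "missing rate = %g, seed = %d\n"),
              x$n, x$noise_sd, x$missing_rate_genotype, x$seed))
  cat(sprintf("planted effects: %d nonzero entries (max |W| = %g)\n",
              sum(x$effect_matrix != 0), max(abs(x$effect_matrix))))
  invisible(x)
}
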