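#' Genotype frequency counts of the 83-subject cohort
#'
#' Per-locus diploid genotype counts among successfully typed subjects.
#' CYP2D6*14 was not detected (genotyping failed at that locus), so its
#' counts are all zero; per-locus typed totals are (74, 83, 0, 66, 77).
#'
#' @return named list of length-3 integer count vectors, one per locus.
#' @export
table1_counts <- function() {
  list(
    "CYP2D6*2"  = c(CC = 59L, CT = 9L,  TT = 6L),
    "CYP2D6*10" = c(CC = 16L, CT = 8L,  TT = 59L),
    "CYP2D6*14" = c(GG = 0L,  GA = 0L,  AA = 0L),
    "CYP1A2*1C" = c(GG = 38L, GA = 21L, AA = 7L),
    "CYP1A2*1F" = c(CC = 33L, CA = 11L, AA = 33L)
  )
}

#' ADR report counts by category
#'
#' Counts of the 53 adverse reactions reported in the cohort, by the 14
#' categories in canonical order.
#'
#' @return named integer vector of length 14 summing to 53.
#' @export
table2_counts <- function() {
  stats::setNames(
    c(3L, 8L, 4L, 6L, 7L, 5L, 4L, 6L, 3L, 2L, 2L, 1L, 1L, 1L),
    adr_categories())
}

#' Percentage of a count within a total, printed-precision style
#' @param count,total non-negative numbers.
#' @param digits decimal places (default 1).
#' @return numeric percentage.
#' @export
pct <- function(count, total, digits = 1) round(100 * count / total, digits)

#' Deterministic fixture cohort with the printed marginal counts
#'
#' Builds an 83-subject cohort whose per-locus genotype counts equal
#' [table1_counts()] exactly (untyped subjects blank at that locus) and
#' whose per-category nonzero ADR counts equal [table2_counts()] exactly
#' (each report a single +/-1 grade).  The joint assignment of genotypes
#' to subjects and of reports to subjects is an arbitrary but fixed
#' deterministic shuffle: this is a synthetic stand-in reproducing only
#' the published margins, NOT the real joint clinical data, which was
#' never deposited.
#'
#' @return a cohort data frame of 83 rows.
#' @export
fixture_cohort <- function() {
  n <- 83L
  cohort <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group_id = rep(c("trial", "blank"), length.out = n),
    dose = rep(c(1, 0), length.out = n),
    stringsAsFactors = FALSE, check.names = FALSE)
  counts <- table1_counts()
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  for (i in seq_along(cyp_loci())) {
    lc <- cyp_loci()[i]
    cnt <- counts[[lc]]
    col <- c(rep(names(cnt), cnt), rep("", n - sum(cnt)))
    set.seed(8300L + i)
    cohort[[lc]] <- sample(col)
  }
  adr <- matrix(0L, n, 14L, dimnames = list(NULL, adr_categories()))
  set.seed(5300L)
  subj <- sample(n)
  pos <- 1L
  t2 <- table2_counts()
  for (j in seq_len(14L)) {
    k <- t2[j]
    if (k == 0L) next
    rows <- subj[pos:(pos + k - 1L)]
    adr[rows, j] <- rep(c(1L, -1L), length.out = k)
    pos <- pos + k
  }
  cbind(cohort, as.data.frame(adr, check.names = FALSE))
}
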