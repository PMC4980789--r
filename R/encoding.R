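#' Canonical pharmacogene loci
#'
#' The five star-allele loci typed in the cohort, in the package's fixed
#' canonical order (the order used for the 15 genotype dummy variables).
#'
#' @return character vector of length 5.
#' @export
cyp_loci <- function() {
  c("CYP2D6*2", "CYP2D6*10", "CYP2D6*14", "CYP1A2*1C", "CYP1A2*1F")
}

#' Diploid genotype labels per locus
#'
#' Base-pair genotype labels for each locus in the order
#' (wild-type homozygous, heterozygous, variant homozygous).  The first
#' listed genotype of each locus is taken as the wild-type homozygote.
#'
#' @return named list of length-3 character vectors.
#' @export
genotype_labels <- function() {
  list(
    "CYP2D6*2"  = c("CC", "CT", "TT"),
    "CYP2D6*10" = c("CC", "CT", "TT"),
    "CYP2D6*14" = c("GG", "GA", "AA"),
    "CYP1A2*1C" = c("GG", "GA", "AA"),
    "CYP1A2*1F" = c("CC", "CA", "AA")
  )
}

#' The 14 adverse-drug-reaction categories
#'
#' Graded laboratory/clinical abnormality categories, in the package's
#' fixed canonical order.
#'
#' @return character vector of length 14.
#' @export
adr_categories <- function() {
  c("Abnormal platelet counting", "Abnormal protein counting",
    "Abnormal TBIL", "Abnormal neutrophil ratio",
    "Abnormal lymphocyte ratio", "Fecal occult blood",
    "Abnormal fibrinogen", "Prolonged PT", "Abnormal blood chlorine",
    "Abnormal hemoglobin", "Abnormal RBC", "Abnormal urobilinogen",
    "Urine protein", "Abnormal APTT")
}

.call_states <- c("WILD_HOM", "HET", "VAR_HOM", "MISSING")

#' Construct a per-subject genotype record
#'
#' @param subject_id opaque subject identifier.
#' @param group_id group label (e.g. "trial" / "blank").
#' @param dose non-negative dose (arbitrary units).
#' @param calls named character vector mapping each of the five loci
#'   ([cyp_loci()]) to one of `"WILD_HOM"`, `"HET"`, `"VAR_HOM"`,
#'   `"MISSING"`.
#' @return an object of class `"genotype_record"`.
#' @export
genotype_record <- function(subject_id, group_id, dose, calls) {
  if (!is.numeric(dose) || length(dose) != 1L || is.na(dose) || dose < 0)
    bad_field("dose", "must be a single non-negative number")
  loci <- cyp_loci()
  if (is.null(names(calls)) || !setequal(names(calls), loci))
    bad_field("calls", paste("must be named with exactly the loci:",
                             paste(loci, collapse = ", ")))
  calls <- calls[loci]
  bad <- !(calls %in% .call_states)
  if (any(bad))
    bad_field(paste0("calls[", loci[which(bad)[1L]], "]"),
              paste("unknown call state", calls[which(bad)[1L]]))
  structure(list(subject_id = as.character(subject_id),
                 group_id = as.character(group_id),
                 dose = as.numeric(dose),
                 calls = calls),
            class = "genotype_record")
}

#' Names of the 15 genotype dummy variables
#' @return character vector of length 15.
#' @export
dummy_names <- function() {
  as.vector(t(outer(cyp_loci(), c("wt", "het", "hom"), paste, sep = ".")))
}

#' Encode a genotype record as 15 dummy variables
#'
#' Each locus contributes three 0/1 indicators (wild-type homozygous,
#' heterozygous, variant homozygous); a `MISSING` locus maps to three
#' zeros, the zero-fill missing-data policy.
#'
#' @param record a [genotype_record()].
#' @return named integer vector of length 15.
#' @export
encode_genotype <- function(record) {
  stopifnot(inherits(record, "genotype_record"))
  g <- integer(15L)
  names(g) <- dummy_names()
  for (i in seq_len(5L)) {
    s <- match(record$calls[[i]], .call_states)
    if (s <= 3L) g[(i - 1L) * 3L + s] <- 1L
  }
  g
}

#' Decode 15 genotype dummies back to call states
#'
#' Inverse of [encode_genotype()]; an all-zero triple decodes to
#' `MISSING` (the zero-fill collapse).
#'
#' @param g length-15 0/1 vector.
#' @return named character vector of 5 call states.
#' @export
decode_genotype <- function(g) {
  if (length(g) != 15L || !all(g %in% c(0, 1)))
    bad_field("g", "must be a length-15 binary vector")
  loci <- cyp_loci()
  out <- character(5L)
  names(out) <- loci
  for (i in seq_len(5L)) {
    tri <- g[(i - 1L) * 3L + 1:3]
    if (sum(tri) > 1L)
      bad_field(paste0("g[", loci[i], "]"), "dummy triple sums to more than 1")
    out[i] <- if (sum(tri) == 0L) "MISSING" else .call_states[which(tri == 1)]
  }
  out
}

#' Encode graded ADR reports as a length-14 ordinal vector
#'
#' Levels are ordinal on \{-2, -1, 0, 1, 2\}: 2 extremely increased, 1
#' increased, 0 no ADR, -1 decreased, -2 extremely decreased.  Unreported
#' categories (including missing outcomes) are coded 0; by design a
#' missing outcome is indistinguishable from "no ADR".
#'
#' @param reports named numeric vector or list mapping category names
#'   (subset of [adr_categories()]) to grades in \{-2..2\}; may be empty.
#' @return named integer vector of length 14.
#' @export
encode_adr <- function(reports = numeric()) {
  cats <- adr_categories()
  r <- integer(14L)
  names(r) <- cats
  if (length(reports)) {
    reports <- unlist(reports)
    unknown <- setdiff(names(reports), cats)
    if (length(unknown))
      bad_field("reports", paste("unknown ADR category:", unknown[1L]))
    if (any(!(reports %in% -2:2)))
      bad_field("reports", "grades must be integers in [-2, 2]")
    r[names(reports)] <- as.integer(reports)
  }
  r
}

#' Assemble a numeric sample vector X = (J, G, R)
#'
#' Concatenates the covariate block J (dose plus a one-hot group
#' indicator), the 15 genotype dummies G and the 14 ADR ordinals R into
#' one numeric vector with block boundaries recorded as an attribute.
#'
#' @param record a [genotype_record()].
#' @param adr length-14 ADR vector (from [encode_adr()]).
#' @param group_levels character vector of all group levels in the cohort
#'   (defines the one-hot width); default is the record's own group.
#' @return numeric vector of length `d = length(J) + 15 + 14` with a
#'   `blocks` attribute listing the index ranges of J, G and R.
#' @export
assemble_sample <- function(record, adr, group_levels = record$group_id) {
  stopifnot(inherits(record, "genotype_record"))
  if (length(adr) != 14L || any(abs(adr) > 2))
    bad_field("adr", "must be a length-14 vector with entries in [-2, 2]")
  grp <- as.integer(group_levels == record$group_id)
  names(grp) <- paste0("group.", group_levels)
  j <- c(dose = record$dose, grp)
  g <- encode_genotype(record)
  x <- c(j, g, as.numeric(adr))
  names(x) <- c(names(j), names(g), adr_categories())
  attr(x, "blocks") <- list(
    J = seq_along(j),
    G = length(j) + 1:15,
    R = length(j) + 15L + 1:14)
  x
}

#' Split a sample vector into its (J, G, R) blocks
#'
#' @param x a vector produced by [assemble_sample()] (carries a `blocks`
#'   attribute), or any numeric vector plus an explicit `blocks` list.
#' @param blocks optional blocks list overriding the attribute.
#' @return list with components `J`, `G`, `R`.
#' @export
split_blocks <- function(x, blocks = attr(x, "blocks")) {
  if (is.null(blocks)) bad_field("blocks", "no block metadata available")
  if (length(x) != length(blocks$J) + length(blocks$G) + length(blocks$R))
    bad_field("x", "length does not match block metadata")
  list(J = x[blocks$J], G = x[blocks$G], R = x[blocks$R])
}
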