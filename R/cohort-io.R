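#' Read a cohort table from CSV/TSV
#'
#' Expected schema (UTF-8, header required): `subject_id`, `group_id`,
#' `dose`, one column per locus in [cyp_loci()] holding base-pair
#' genotypes (e.g. CC/CT/TT; blank = missing), and one column per ADR
#' category in [adr_categories()] holding integer grades in -2..2
#' (blank = 0, the zero-fill policy).  Malformed cells are reported with
#' their row and column.
#'
#' @param path file path; `sep` inferred from the extension (.tsv ->
#'   tab) unless given.
#' @param sep field separator.
#' @return a cohort data frame (validated).
#' @export
read_cohort <- function(path, sep = if (grepl("\\.tsv$", path)) "\t" else ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#",
                           quote = "\"")
  need <- c("subject_id", "group_id", "dose", cyp_loci(), adr_categories())
  miss <- setdiff(need, names(raw))
  if (length(miss))
    bad_field("header", paste("missing required columns:",
                              paste(miss, collapse = ", ")))
  raw <- raw[, need, drop = FALSE]
  dose <- suppressWarnings(as.numeric(raw$dose))
  if (nrow(raw) && anyNA(dose))
    bad_field("dose", sprintf("row %d: non-numeric dose '%s'",
                              which(is.na(dose))[1L],
                              raw$dose[which(is.na(dose))[1L]]))
  raw$dose <- dose
  for (cat in adr_categories()) {
    v <- trimws(raw[[cat]])
    v[v == "" | is.na(v)] <- "0"
    g <- suppressWarnings(as.integer(v))
    bad <- is.na(g) | !(g %in% -2:2)
    if (any(bad))
      bad_field(cat, sprintf("row %d: unparseable grade '%s'",
                             which(bad)[1L], v[which(bad)[1L]]))
    raw[[cat]] <- g
  }
  for (lc in cyp_loci()) {
    v <- trimws(raw[[lc]])
    v[is.na(v)] <- ""
    ok <- v == "" | v %in% genotype_labels()[[lc]]
    if (any(!ok))
      bad_field(lc, sprintf("row %d: unknown genotype '%s'",
                            which(!ok)[1L], v[which(!ok)[1L]]))
    raw[[lc]] <- v
  }
  check_cohort(raw)
}

#' Write a cohort table to CSV/TSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, p))` is the
#' identity on valid cohorts.  A JSON sidecar `<path>.json` documenting
#' the block metadata (schema version, locus and category order) is
#' written alongside.
#'
#' @param cohort cohort data frame.
#' @param path output path; separator inferred from extension.
#' @param sidecar write the JSON block-metadata sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path,
                         sidecar = TRUE) {
  check_cohort(cohort)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  out <- cohort[, c("subject_id", "group_id", "dose", cyp_loci(),
                    adr_categories()), drop = FALSE]
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
  if (sidecar) {
    meta <- list(schema = "gsnadr-cohort/1",
                 loci = cyp_loci(),
                 genotype_labels = genotype_labels(),
                 adr_categories = adr_categories(),
                 blocks = list(J = c("dose", "group one-hot"),
                               G = "15 genotype dummies",
                               R = "14 ADR ordinals"))
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
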