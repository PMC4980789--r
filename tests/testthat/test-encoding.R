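test_that("dummy coding places single indicators and zero-fills missing loci", {
  all_missing <- genotype_record("S1", "trial", 0,
                                 stats::setNames(rep("MISSING", 5),
                                                 cyp_loci()))
  expect_identical(unname(encode_genotype(all_missing)), rep(0L, 15))

  one <- genotype_record("S2", "trial", 0,
                         stats::setNames(c("WILD_HOM", rep("MISSING", 4)),
                                         cyp_loci()))
  g <- encode_genotype(one)
  expect_identical(sum(g), 1L)
  expect_identical(unname(g[1]), 1L)  # CYP2D6*2 wild-hom is position 1

  # per-locus triples sum to <= 1, 0 iff missing
  r <- toy_record()
  g2 <- encode_genotype(r)
  sums <- vapply(1:5, function(i) sum(g2[(i - 1) * 3 + 1:3]), integer(1))
  expect_true(all(sums == 1L))
})

test_that("genotype encoding round-trips and is injective off the missing collapse", {
  states <- c("WILD_HOM", "HET", "VAR_HOM")
  grid <- expand.grid(rep(list(states), 5), stringsAsFactors = FALSE)
  seen <- character(0)
  for (i in seq_len(nrow(grid))) {
    calls <- stats::setNames(unlist(grid[i, ]), cyp_loci())
    g <- encode_genotype(genotype_record("X", "g", 0, calls))
    expect_identical(decode_genotype(g), calls)
    key <- paste(g, collapse = "")
    expect_false(key %in% seen)
    seen <- c(seen, key)
  }
})

test_that("invalid genotype records are rejected with the offending field named", {
  expect_error(genotype_record("S", "g", -1,
                               stats::setNames(rep("HET", 5), cyp_loci())),
               "dose")
  expect_error(genotype_record("S", "g", 0,
                               stats::setNames(rep("HET", 4),
                                               cyp_loci()[1:4])),
               "calls")
  bad <- stats::setNames(c("HET", "HETERO", "HET", "HET", "HET"),
                         cyp_loci())
  expect_error(genotype_record("S", "g", 0, bad), "CYP2D6\\*10")
})

test_that("ADR coding zero-fills unreported categories and validates grades", {
  expect_identical(unname(encode_adr()), rep(0L, 14))
  r <- encode_adr(c("Abnormal hemoglobin" = -1))
  expect_identical(unname(r[match("Abnormal hemoglobin",
                                  adr_categories())]), -1L)
  expect_identical(sum(r != 0), 1L)
  expect_error(encode_adr(c("No such ADR" = 1)), "unknown ADR")
  expect_error(encode_adr(c("Abnormal RBC" = 3)), "-2, 2")
})

test_that("sample assembly and block splitting are exact inverses", {
  rec <- toy_record()
  adr <- encode_adr(c("Prolonged PT" = 2, "Abnormal RBC" = -2))
  x <- assemble_sample(rec, adr, group_levels = c("blank", "trial"))
  expect_length(x, 3 + 15 + 14)  # dose + 2 groups, G, R
  parts <- split_blocks(x)
  expect_identical(unname(parts$G), as.numeric(encode_genotype(rec)))
  expect_identical(unname(parts$R), as.numeric(adr))
  expect_identical(unname(parts$J[1]), rec$dose)
  # single covariate column: d = 1 + 15 + 14 = 30
  x1 <- assemble_sample(rec, adr, group_levels = rec$group_id)
  expect_length(x1, 31)  # dose + 1 group indicator
})

test_that("fixture dummy column sums equal the published genotype counts", {
  ds <- as_dataset(fixture_cohort())
  cs <- colSums(ds$X[, ds$blocks$G])
  expect_identical(unname(cs[1:3]), c(59, 9, 6))      # CYP2D6*2
  expect_identical(unname(cs[4:6]), c(16, 8, 59))     # CYP2D6*10
  expect_identical(unname(cs[7:9]), c(0, 0, 0))       # CYP2D6*14 undetected
  expect_identical(unname(cs[10:12]), c(38, 21, 7))   # CYP1A2*1C
  expect_identical(unname(cs[13:15]), c(33, 11, 33))  # CYP1A2*1F
  # ADR entries bounded, dimension constant
  expect_true(all(abs(ds$X[, ds$blocks$R]) <= 2))
})

test_that("cohort CSV writing and reading is the identity on valid files", {
  fx <- fixture_cohort()
  p <- withr::local_tempfile(fileext = ".csv")
  write_cohort(fx, p)
  back <- read_cohort(p)
  expect_identical(dim(back), dim(fx))
  for (col in names(fx)) expect_equal(back[[col]], fx[[col]])
  expect_true(file.exists(paste0(p, ".json")))

  # empty file with valid header -> empty cohort
  empty <- fx[0, ]
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(empty, p2)
  expect_identical(nrow(read_cohort(p2)), 0L)

  # blank genotype cell -> MISSING without error; blank grade -> 0
  one <- fx[1, ]
  one[["CYP1A2*1C"]] <- ""
  one[["Abnormal TBIL"]] <- 0L
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(one, p3)
  again <- read_cohort(p3)
  expect_identical(again[["CYP1A2*1C"]], "")
  g <- genotype_dummies(again)
  expect_identical(unname(g[1, 10:12]), c(0, 0, 0))
})

test_that("malformed cohort files are reported with row and column", {
  fx <- fixture_cohort()[1:3, ]
  p <- withr::local_tempfile(fileext = ".csv")
  fx$dose <- as.character(fx$dose)
  fx$dose[2] <- "high"
  utils::write.table(fx, p, sep = ",", row.names = FALSE, quote = TRUE)
  expect_error(read_cohort(p), "row 2.*high")

  fx2 <- fixture_cohort()[1:3, ]
  fx2[["Abnormal RBC"]] <- c(0L, 0L, 7L)
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(fx2, p2, sep = ",", row.names = FALSE, quote = TRUE)
  expect_error(read_cohort(p2), "row 3")

  expect_error(read_cohort({
    p3 <- withr::local_tempfile(fileext = ".csv")
    writeLines("subject_id,group_id", p3); p3
  }), "missing required columns")
})
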