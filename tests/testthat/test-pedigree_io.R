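test_that("a minimal trio PED with one tumor row parses into one pedigree", {
  ped_file <- withr::local_tempfile(fileext = ".ped")
  tum_file <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("FAM1\tF\t0\t0\t1\t1",
               "FAM1\tM\t0\t0\t2\t1",
               "FAM1\tC\tF\tM\t2\t2"), ped_file)
  writeLines(c("individual_id\tsite\tage_at_diagnosis\ttumor_index",
               "C\tcolorectal\t45\t1"), tum_file)
  peds <- read_pedigrees(ped_file, tum_file)
  expect_length(peds, 1)
  p <- peds[["FAM1"]]
  expect_equal(nrow(p$individuals), 3)
  expect_equal(p$proband_id, "C")
  expect_equal(nrow(tumors_of(p, "C")), 1)
  expect_equal(p$individuals$sex, c("male", "female", "female"))
  expect_true(is.na(p$individuals$father[1]))
})

test_that("space-delimited PED and '0'/'' missing-parent codes are accepted", {
  ped_file <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("FAM1 F 0 0 1 1", "FAM1 M 0 0 2 1", "FAM1 C F M 0 2"),
             ped_file)
  peds <- read_pedigrees(ped_file)
  expect_equal(peds[["FAM1"]]$individuals$sex[3], "unknown")
  ped_file2 <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("FAM1\tF\t\t\t1\t1", "FAM1\tM\t\t\t2\t1",
               "FAM1\tC\tF\tM\t2\t2"), ped_file2)
  peds2 <- read_pedigrees(ped_file2)
  expect_true(all(is.na(peds2[["FAM1"]]$individuals$father[1:2])))
})

test_that("structural violations are rejected with informative errors", {
  # self-parentage is a cycle
  expect_error(
    ped_build(list(list("A", "A", NA, "male")), proband = "A"),
    "cyclic parentage")
  # dangling parent reference
  expect_error(
    ped_build(list(list("A", "X", NA, "male")), proband = "A"),
    "dangling father")
  # duplicate (individual, tumor_index)
  expect_error(
    ped_build(list(list("A", NA, NA, "male")),
              list(list("A", "colorectal", 50L, 1L),
                   list("A", "gastric", 60L, 1L)),
              proband = "A"),
    "duplicate \\(individual_id, tumor_index\\)")
  # two probands in one family
  ped_file <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("FAM1\tA\t0\t0\t1\t2", "FAM1\tB\t0\t0\t2\t2"), ped_file)
  expect_error(read_pedigrees(ped_file), "exactly one proband")
  # tumor referencing an individual absent from the PED
  ped_file2 <- withr::local_tempfile(fileext = ".ped")
  tum_file <- withr::local_tempfile(fileext = ".tsv")
  writeLines("FAM1\tA\t0\t0\t1\t2", ped_file2)
  writeLines(c("individual_id\tsite\tage_at_diagnosis\ttumor_index",
               "Z\tcolorectal\t45\t1"), tum_file)
  expect_error(read_pedigrees(ped_file2, tum_file), "absent from the PED")
})

test_that("unknown tumor sites map to 'other' with a warning and never count
           as LS-associated", {
  ped_file <- withr::local_tempfile(fileext = ".ped")
  tum_file <- withr::local_tempfile(fileext = ".tsv")
  writeLines("FAM1\tA\t0\t0\t1\t2", ped_file)
  writeLines(c("individual_id\tsite\tage_at_diagnosis\ttumor_index",
               "A\tpancreatic\t55\t1", "A\tcolorectal\t50\t2"), tum_file)
  expect_warning(peds <- read_pedigrees(ped_file, tum_file), "pancreatic")
  p <- peds[["FAM1"]]
  expect_equal(sort(p$tumors$site), c("colorectal", "other"))
  # the downstream count ignores the remapped tumor
  r <- select_cfdr(p)
  expect_equal(r$tumor_count, 1L)
  expect_equal(r$lad, 50L)
})

test_that("write -> read round-trips pedigrees and is row-order independent", {
  set.seed(42)
  co <- generate_cohort(cohort_params(n_probands = 12), seed = 42)
  dir <- withr::local_tempdir()
  write_pedigrees(co$pedigrees, file.path(dir, "c.ped"),
                  file.path(dir, "t.tsv"))
  back <- read_pedigrees(file.path(dir, "c.ped"), file.path(dir, "t.tsv"))
  expect_equal(length(back), length(co$pedigrees))
  for (fid in names(co$pedigrees)) {
    a <- co$pedigrees[[fid]]; b <- back[[fid]]
    expect_equal(b$proband_id, a$proband_id)
    key <- function(df) df[order(df$id), , drop = FALSE]
    expect_equal(unname(key(b$individuals)), unname(key(a$individuals)),
                 ignore_attr = TRUE)
    tkey <- function(df) {
      df <- df[order(df$individual_id, df$tumor_index), , drop = FALSE]
      rownames(df) <- NULL
      df
    }
    expect_equal(tkey(b$tumors), tkey(a$tumors))
  }
  # shuffle rows in the files: parsed pedigrees must be identical
  lines <- readLines(file.path(dir, "c.ped"))
  set.seed(1); writeLines(sample(lines), file.path(dir, "shuffled.ped"))
  tl <- readLines(file.path(dir, "t.tsv"))
  writeLines(c(tl[1], sample(tl[-1])), file.path(dir, "shuffled.tsv"))
  shuf <- read_pedigrees(file.path(dir, "shuffled.ped"),
                         file.path(dir, "shuffled.tsv"))
  for (fid in names(back)) {
    expect_equal(select_cfdr(shuf[[fid]])[c("member_ids", "tumor_count",
                                            "lad", "branch")],
                 select_cfdr(back[[fid]])[c("member_ids", "tumor_count",
                                            "lad", "branch")])
  }
})

test_that("lab results parse, validate their invariants, and round-trip", {
  lab_file <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste("proband_id", "mmr_functional", "ihc_pattern", "braf_v600e",
               "screened_genes", "mutation_gene", "variant_class", sep = "\t")
  writeLines(c(hdr, "P1\tdeficient\tMLH1;PMS2\tnot_done\t\t\t"), lab_file)
  lab <- read_lab_results(lab_file)
  expect_equal(lab$mmr_functional, "deficient")
  expect_equal(split_multi(lab$ihc_pattern), c("MLH1", "PMS2"))

  # pathogenic class without a mutation gene passes; gene without class fails
  writeLines(c(hdr, "P1\tdeficient\t\tnot_done\tMLH1;PMS2\tMLH1\tVUS"),
             lab_file)
  expect_error(read_lab_results(lab_file), "variant_class not 'pathogenic'")
  # variant_class set but nothing screened
  writeLines(c(hdr, "P1\tdeficient\t\tnot_done\t\t\tnone"), lab_file)
  expect_error(read_lab_results(lab_file), "screened_genes empty")
  # illegal enumeration token names the row
  writeLines(c(hdr, "P1\tmaybe\t\tnot_done\t\t\t"), lab_file)
  expect_error(read_lab_results(lab_file), "illegal mmr_functional.*row 1")

  # synthetic cohort lab frame round-trips with field equality
  co <- generate_cohort(cohort_params(n_probands = 372), seed = 11)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_lab_results(co$lab, out)
  back <- read_lab_results(out)
  rownames(back) <- rownames(co$lab) <- NULL
  expect_equal(back, co$lab)
})
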