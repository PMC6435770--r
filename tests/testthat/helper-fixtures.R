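# Fixture cohorts built from published marginal counts. No per-patient
# microdata exist, so the fixtures realise the marginals exactly:
# 372 probands, 368 MMR-tested of whom 92 deficient, 114 screened of whom 48
# carry a pathogenic mutation (15 MLH1, 22 MSH2, 10 MSH6, 1 PMS2).

fixture_lab_372 <- function() {
  n <- 372L
  lab <- data.frame(
    proband_id = sprintf("P%03d", seq_len(n)),
    mmr_functional = "proficient",
    ihc_pattern = "", braf_v600e = "not_done",
    screened_genes = "", mutation_gene = "", variant_class = "",
    stringsAsFactors = FALSE
  )
  lab$mmr_functional[1:4] <- "not_done"      # direct-sequencing referrals
  lab$mmr_functional[5:96] <- "deficient"    # 92 deficient among 368 tested
  screened <- 1:114
  lab$screened_genes[screened] <- "MLH1;PMS2;MSH2;MSH6"
  lab$variant_class[screened] <- "none"
  genes <- c(rep("MLH1", 15), rep("MSH2", 22), rep("MSH6", 10), "PMS2")
  mut <- 5:52                                # 48 mutations, all screened
  lab$mutation_gene[mut] <- genes
  lab$variant_class[mut] <- "pathogenic"
  validate_lab_results(lab)
  lab
}

# CFDR rows for the same probands. Values only need to be structurally
# plausible: the published per-patient tumor counts and ages are not
# recoverable, and no test asserts them from this fixture.
fixture_cfdr_for_lab <- function(lab, seed = 404) {
  n <- nrow(lab)
  withr::with_seed(seed, data.frame(
    proband_id = lab$proband_id,
    family_id = sub("^P", "F", lab$proband_id),
    tumor_count = sample(1:6, n, replace = TRUE,
                         prob = c(0.35, 0.25, 0.2, 0.1, 0.06, 0.04)),
    lad = sample(25:70, n, replace = TRUE),
    branch = "maternal",
    member_ids = lab$proband_id,
    stringsAsFactors = FALSE
  ))
}

# (tumor_count, LAD) values realising the published triage partition:
# 31 single-tumor clusters under 40, 77 two-tumor clusters under 50,
# 129 clusters with >= 3 tumors under 60, 40 single-tumor clusters at 40-49,
# and 95 probands outside every criterion.
fixture_triage_grid <- function(seed = 405) {
  rows <- withr::with_seed(seed, rbind(
    data.frame(tumor_count = 1L,
               lad = sample(22:39, 31, replace = TRUE)),
    data.frame(tumor_count = 2L,
               lad = sample(22:49, 77, replace = TRUE)),
    data.frame(tumor_count = sample(3:6, 129, replace = TRUE),
               lad = sample(22:59, 129, replace = TRUE)),
    data.frame(tumor_count = 1L,
               lad = sample(40:49, 40, replace = TRUE)),
    # outside every criterion: old single/double clusters and very old large
    data.frame(tumor_count = sample(1:2, 60, replace = TRUE),
               lad = sample(50:75, 60, replace = TRUE)),
    data.frame(tumor_count = sample(3:5, 35, replace = TRUE),
               lad = sample(60:75, 35, replace = TRUE))
  ))
  rows$proband_id <- sprintf("P%03d", seq_len(nrow(rows)))
  rows
}
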