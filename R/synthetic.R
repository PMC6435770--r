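# Synthetic referral-cohort generator.
#
# Emulates a clinical-genetics referral cohort for suspected Lynch syndrome:
# three-generation pedigrees, an autosomal-dominant carrier fraction with a
# gene-specific onset and tumor-burden model, and a sporadic background in
# which some colorectal tumors are MMR-deficient through MLH1 promoter
# methylation (partly BRAF V600E positive). Every proband is affected — the
# referral condition.

#' Parameters of the synthetic referral cohort
#'
#' Defaults describe the emulated referral cohort: 13% of probands carry a
#' pathogenic MMR-gene mutation with gene mix MSH2 > MLH1 > MSH6 > PMS2;
#' carriers' onset ages are gene-specific (means 37/39/42/44 years, spread a
#' quarter of the observed range) and their family branch carries a
#' gene-specific expected tumor burden (4.3/3.4/3.2/2). Sporadic tumors onset
#' later; 15% of sporadic colorectal tumors are MMR-deficient via MLH1
#' methylation, of which 60% carry BRAF V600E. The MMR assay detects a
#' carrier's deficiency with sensitivity 47/48; a small fraction of probands
#' skip tumor testing and go straight to sequencing.
#'
#' @param n_probands Number of referred probands.
#' @param ls_fraction Probability a proband is a Lynch carrier.
#' @param gene_mix Named probabilities over MLH1/MSH2/MSH6/PMS2 (sum 1).
#' @param onset_mean,onset_sd Named per-gene onset age mean and SD (years).
#' @param carrier_tumor_intensity Named per-gene expected LS tumor count in
#'   the proband's branch.
#' @param sporadic_onset_mean,sporadic_onset_sd Sporadic onset model (years).
#' @param relative_tumor_rate Probability a non-carrier relative has a
#'   sporadic tumor.
#' @param other_site_rate Probability a relative's sporadic tumor is at a
#'   non-LS (`"other"`) site.
#' @param second_tumor_rate Probability a sporadic proband has a second
#'   primary.
#' @param sporadic_mmr_deficiency_rate P(MMR-deficient | sporadic colorectal
#'   tumor).
#' @param braf_positive_given_methylation P(BRAF V600E | sporadic
#'   MLH1-methylated deficiency).
#' @param assay_sensitivity P(tumor shows MMR deficiency | carrier).
#' @param mutation_detection_rate P(mutation found | carrier screened for the
#'   right gene).
#' @param mmr_not_done_rate Probability a proband bypasses tumor testing
#'   (direct germline sequencing).
#' @param braf_assay_rate Probability the BRAF reflex assay is actually run
#'   on an MLH1/PMS2-deficient tumor (era coverage).
#' @param screen_proficient_rate Probability a proficient-tumor proband is
#'   screened anyway on clinical grounds.
#' @param max_sibs,max_aunts_uncles Upper bounds of the uniform sibship-size
#'   draws.
#' @return List of class `"cohort_params"`.
#' @export
cohort_params <- function(
    n_probands = 372L,
    ls_fraction = 0.13,
    gene_mix = c(MLH1 = 0.31, MSH2 = 0.46, MSH6 = 0.21, PMS2 = 0.02),
    onset_mean = c(MLH1 = 37, MSH2 = 39, MSH6 = 42, PMS2 = 44),
    onset_sd = c(MLH1 = 6.25, MSH2 = 8.75, MSH6 = 4.25, PMS2 = 5),
    carrier_tumor_intensity = c(MLH1 = 4.3, MSH2 = 3.4, MSH6 = 3.2,
                                PMS2 = 2),
    sporadic_onset_mean = 52, sporadic_onset_sd = 10,
    relative_tumor_rate = 0.12,
    other_site_rate = 0.05,
    second_tumor_rate = 0.08,
    sporadic_mmr_deficiency_rate = 0.15,
    braf_positive_given_methylation = 0.6,
    assay_sensitivity = 47 / 48,
    mutation_detection_rate = 1,
    mmr_not_done_rate = 4 / 372,
    braf_assay_rate = 0.16,
    screen_proficient_rate = 0.08,
    max_sibs = 3L, max_aunts_uncles = 3L) {
  p <- list(n_probands = as.integer(n_probands), ls_fraction = ls_fraction,
            gene_mix = gene_mix, onset_mean = onset_mean, onset_sd = onset_sd,
            carrier_tumor_intensity = carrier_tumor_intensity,
            sporadic_onset_mean = sporadic_onset_mean,
            sporadic_onset_sd = sporadic_onset_sd,
            relative_tumor_rate = relative_tumor_rate,
            other_site_rate = other_site_rate,
            second_tumor_rate = second_tumor_rate,
            sporadic_mmr_deficiency_rate = sporadic_mmr_deficiency_rate,
            braf_positive_given_methylation = braf_positive_given_methylation,
            assay_sensitivity = assay_sensitivity,
            mutation_detection_rate = mutation_detection_rate,
            mmr_not_done_rate = mmr_not_done_rate,
            braf_assay_rate = braf_assay_rate,
            screen_proficient_rate = screen_proficient_rate,
            max_sibs = as.integer(max_sibs),
            max_aunts_uncles = as.integer(max_aunts_uncles))
  probs <- unlist(p[c("ls_fraction", "relative_tumor_rate", "other_site_rate",
                      "second_tumor_rate", "sporadic_mmr_deficiency_rate",
                      "braf_positive_given_methylation", "assay_sensitivity",
                      "mutation_detection_rate", "mmr_not_done_rate",
                      "braf_assay_rate", "screen_proficient_rate")])
  if (any(probs < 0 | probs > 1)) {
    stop("probability parameters must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(gene_mix) - 1) > 1e-8) {
    stop("gene_mix must sum to 1", call. = FALSE)
  }
  if (p$n_probands < 1L) stop("n_probands must be >= 1", call. = FALSE)
  structure(p, class = "cohort_params")
}

# truncated-normal draw via inverse CDF (exact, loop-free)
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# LS tumor-site draws; sex-aware (gynaecological sites female-only)
draw_ls_site <- function(n, sex, crc_weight = 0.55) {
  sites <- c("colorectal", "rectal", "endometrial", "ovarian", "gastric",
             "small_bowel", "upper_urinary_tract")
  w <- c(crc_weight, 0.12, 0.12, 0.05, 0.08, 0.04, 0.04)
  if (sex != "female") {
    w[3:4] <- 0
  }
  sample(sites, n, replace = TRUE, prob = w / sum(w))
}

heterodimer_pattern <- function(gene) {
  switch(gene,
         MLH1 = c("MLH1", "PMS2"), PMS2 = "PMS2",
         MSH2 = c("MSH2", "MSH6"), MSH6 = "MSH6")
}

#' Generate one synthetic pedigree
#'
#' Builds a three-generation pedigree (four grandparents, the parents with
#' optional aunts/uncles on each side, the proband with optional siblings).
#' When `carrier_gene` is set, carrier status enters through one grandparent
#' on a random side and segregates dominantly (transmission 1/2), with the
#' connecting parent and the proband forced carriers so the referral is a
#' carrier; the branch's LS tumor burden is `1 + Poisson(intensity - 1)`
#' tumors spread over carriers (the proband always keeps one), with onset
#' ages from the gene's truncated-normal model on `[18, 90]`. Non-carrier
#' relatives acquire sporadic tumors at a low rate; a non-carrier proband
#' gets one (occasionally two) sporadic LS-site tumors so the referral
#' condition holds. Uses the current RNG state; seed outside.
#'
#' @param params A [cohort_params()] object.
#' @param carrier_gene `NULL` (sporadic pedigree) or one of MLH1/MSH2/MSH6/
#'   PMS2.
#' @param family_id Family identifier, also the id prefix.
#' @return `list(pedigree, truth)` where `truth` is a data frame of latent
#'   per-individual carrier assignments.
#' @export
generate_pedigree <- function(params, carrier_gene = NULL,
                              family_id = "FAM1") {
  pre <- function(x) paste0(family_id, "_", x)
  n_sibs <- sample.int(params$max_sibs + 1L, 1L) - 1L
  n_pau <- sample.int(params$max_aunts_uncles + 1L, 1L) - 1L
  n_mau <- sample.int(params$max_aunts_uncles + 1L, 1L) - 1L
  rand_sex <- function(n) sample(c("male", "female"), n, replace = TRUE)

  ids <- c("pgf", "pgm", "mgf", "mgm", "fa", "mo", "pb",
           if (n_sibs > 0) paste0("sib", seq_len(n_sibs)),
           if (n_pau > 0) paste0("pau", seq_len(n_pau)),
           if (n_mau > 0) paste0("mau", seq_len(n_mau)))
  father <- c(NA, NA, NA, NA, "pgf", NA, "fa",
              rep("fa", n_sibs), rep("pgf", n_pau), rep("mgf", n_mau))
  mother <- c(NA, NA, NA, NA, "pgm", NA, "mo",
              rep("mo", n_sibs), rep("pgm", n_pau), rep("mgm", n_mau))
  sex <- c("male", "female", "male", "female", "male", "female",
           rand_sex(1L + n_sibs), rand_sex(n_pau), rand_sex(n_mau))
  # the mother descends from the maternal grandparents
  father[ids == "mo"] <- "mgf"; mother[ids == "mo"] <- "mgm"
  ind <- data.frame(
    id = pre(ids),
    father = ifelse(is.na(father), NA_character_, pre(father)),
    mother = ifelse(is.na(mother), NA_character_, pre(mother)),
    sex = sex, stringsAsFactors = FALSE
  )

  carrier <- stats::setNames(rep(FALSE, length(ids)), ids)
  if (!is.null(carrier_gene)) {
    side <- sample(c("maternal", "paternal"), 1L)
    founder <- if (side == "maternal") sample(c("mgf", "mgm"), 1L)
               else sample(c("pgf", "pgm"), 1L)
    parent <- if (side == "maternal") "mo" else "fa"
    carrier[c(founder, parent, "pb")] <- TRUE
    au <- if (side == "maternal") grep("^mau", ids, value = TRUE)
          else grep("^pau", ids, value = TRUE)
    for (a in au) carrier[a] <- stats::runif(1) < 0.5
    for (s in grep("^sib", ids, value = TRUE)) {
      carrier[s] <- stats::runif(1) < 0.5
    }
  }

  tumors <- list()
  add_tumor <- function(id, site, age) {
    idx <- sum(vapply(tumors, function(t) t$individual_id == pre(id),
                      logical(1))) + 1L
    tumors[[length(tumors) + 1L]] <<- data.frame(
      individual_id = pre(id), site = site,
      age_at_diagnosis = as.integer(round(age)), tumor_index = idx,
      stringsAsFactors = FALSE)
  }

  if (!is.null(carrier_gene)) {
    g <- carrier_gene
    intensity <- params$carrier_tumor_intensity[[g]]
    n_tum <- 1L + stats::rpois(1L, max(intensity - 1, 0))
    carriers <- ids[carrier[ids]]
    bearers <- c("pb", if (n_tum > 1L)
      sample(carriers, n_tum - 1L, replace = TRUE))
    ages <- rtrunc_norm(n_tum, params$onset_mean[[g]], params$onset_sd[[g]],
                        18, 90)
    for (i in seq_len(n_tum)) {
      s <- draw_ls_site(1L, sex[ids == bearers[i]])
      add_tumor(bearers[i], s, ages[i])
    }
  } else {
    n_tum <- 1L + (stats::runif(1) < params$second_tumor_rate)
    ages <- rtrunc_norm(n_tum, params$sporadic_onset_mean,
                        params$sporadic_onset_sd, 25, 90)
    for (i in seq_len(n_tum)) {
      s <- draw_ls_site(1L, sex[ids == "pb"], crc_weight = 0.7)
      add_tumor("pb", s, ages[i])
    }
  }

  # sporadic background among non-carrier relatives
  for (id in setdiff(ids, "pb")) {
    if (carrier[id]) next
    if (stats::runif(1) < params$relative_tumor_rate) {
      site <- if (stats::runif(1) < params$other_site_rate) "other"
              else draw_ls_site(1L, sex[ids == id])
      age <- rtrunc_norm(1L, params$sporadic_onset_mean,
                         params$sporadic_onset_sd, 25, 90)
      add_tumor(id, site, age)
    }
  }

  ped <- new_pedigree(family_id, ind, do.call(rbind, tumors), pre("pb"))
  truth <- data.frame(
    family_id = family_id, individual_id = pre(ids),
    is_proband = ids == "pb", carrier = unname(carrier[ids]),
    gene = ifelse(carrier[ids], carrier_gene %||% "", ""),
    stringsAsFactors = FALSE
  )
  list(pedigree = ped, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate laboratory results for one proband
#'
#' Simulates the historical laboratory record: MMR functional analysis
#' (skipped for the rare direct-sequencing referrals), IHC staining following
#' the carrier gene's heterodimer (MLH1 loss drags PMS2; MSH2 drags MSH6),
#' BRAF V600E reflex testing of MLH1/PMS2-deficient tumors at the era's
#' coverage, and germline screening of deficient (non-BRAF-positive) cases —
#' plus an occasional proficient case screened on clinical suspicion.
#' Sporadic MLH1-methylated deficiency only arises from colorectal tumors.
#'
#' @param ped The pedigree (for the proband's tumor sites).
#' @param truth Truth frame from [generate_pedigree()].
#' @param params A [cohort_params()].
#' @return One-row lab-results data frame.
#' @export
generate_lab_results <- function(ped, truth, params) {
  pid <- ped$proband_id
  trow <- truth[truth$individual_id == pid, ]
  is_carrier <- trow$carrier
  gene <- if (is_carrier) trow$gene else NA_character_
  mmr <- "not_done"; ihc <- character(0); braf <- "not_done"
  screened <- character(0); mut_gene <- ""; vclass <- ""

  if (stats::runif(1) < params$mmr_not_done_rate) {
    # direct germline sequencing without tumor testing
    screened <- mmr_genes()
  } else {
    if (is_carrier) {
      if (stats::runif(1) < params$assay_sensitivity) {
        mmr <- "deficient"
        ihc <- heterodimer_pattern(gene)
      } else {
        mmr <- "proficient"
      }
    } else {
      has_crc <- any(tumors_of(ped, pid)$site == "colorectal")
      if (has_crc &&
          stats::runif(1) < params$sporadic_mmr_deficiency_rate) {
        mmr <- "deficient"
        ihc <- c("MLH1", "PMS2")
      } else {
        mmr <- "proficient"
      }
    }
    if (mmr == "deficient" && "MLH1" %in% ihc &&
        stats::runif(1) < params$braf_assay_rate) {
      sporadic_methylation <- !is_carrier
      braf <- if (sporadic_methylation &&
                  stats::runif(1) < params$braf_positive_given_methylation) {
        "positive"
      } else {
        "negative"
      }
    }
    if (mmr == "deficient" && braf != "positive") {
      screened <- if (length(ihc) > 0L) {
        if (setequal(ihc, c("MLH1", "PMS2"))) c("MLH1", "PMS2")
        else if (setequal(ihc, c("MSH2", "MSH6"))) c("MSH2", "MSH6")
        else ihc
      } else {
        mmr_genes()
      }
    } else if (mmr == "proficient" &&
               stats::runif(1) < params$screen_proficient_rate) {
      screened <- mmr_genes()
    }
  }

  if (length(screened) > 0L) {
    if (is_carrier && gene %in% screened &&
        stats::runif(1) < params$mutation_detection_rate) {
      mut_gene <- gene
      vclass <- "pathogenic"
    } else {
      vclass <- "none"
    }
  }
  data.frame(proband_id = pid, mmr_functional = mmr,
             ihc_pattern = join_multi(ihc), braf_v600e = braf,
             screened_genes = join_multi(screened),
             mutation_gene = mut_gene, variant_class = vclass,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic referral cohort
#'
#' Draws carrier status and gene for each proband, then generates pedigrees
#' and laboratory results. Fully deterministic under `seed`.
#'
#' @param params A [cohort_params()].
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @return List: `pedigrees` (named list), `lab` (data frame), `truth`
#'   (per-individual latent assignments, data frame).
#' @export
generate_cohort <- function(params = cohort_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- names(params$gene_mix)
  peds <- vector("list", params$n_probands)
  labs <- vector("list", params$n_probands)
  truths <- vector("list", params$n_probands)
  for (i in seq_len(params$n_probands)) {
    fid <- sprintf("F%05d", i)
    cg <- if (stats::runif(1) < params$ls_fraction) {
      sample(genes, 1L, prob = params$gene_mix)
    } else NULL
    gp <- generate_pedigree(params, cg, fid)
    peds[[i]] <- gp$pedigree
    truths[[i]] <- gp$truth
    labs[[i]] <- generate_lab_results(gp$pedigree, gp$truth, params)
  }
  names(peds) <- vapply(peds, `[[`, character(1), "family_id")
  list(pedigrees = peds, lab = do.call(rbind, labs),
       truth = do.call(rbind, truths))
}

#' Write a synthetic cohort to the standard exchange formats
#'
#' Emits the PED + tumor TSV consumed by [read_pedigrees()], the lab TSV for
#' [read_lab_results()], and the latent truth table.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the four file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ped = file.path(dir, "cohort.ped"),
             tumors = file.path(dir, "tumors.tsv"),
             lab = file.path(dir, "lab.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_pedigrees(cohort$pedigrees, paths["ped"], paths["tumors"])
  write_lab_results(cohort$lab, paths["lab"])
  utils::write.table(cohort$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
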