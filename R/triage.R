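# Triage of probands between direct gene-panel screening and the stepwise
# MMR work-up, plus a reconstruction of the historical decision tree.
#
# Direct-panel criteria (CFDR tumor count / LAD in whole years):
#   (a) 1 tumor,  LAD < 40     -> gene panel
#   (b) 2 tumors, LAD < 50     -> gene panel
#   (c) >= 3 tumors, LAD < 60  -> gene panel
#   1 tumor, LAD 40-49         -> MMR functional analysis first (national
#                                 guideline: test all CRC diagnosed < 50)
#   anything else              -> no testing
# Criterion (b) as a rule reads ">= 2 tumors"; eligibility is the union of
# (a)-(c) but reporting categories use exact counts (1, 2, >= 3) so category
# histograms partition the cohort.

TRIAGE_CATEGORIES <- c("panel_a", "panel_b", "panel_c", "mmr_first", "none")

#' Classify a CFDR result into a triage category
#'
#' Age boundaries are strict `<` for 40/50/60 and the MMR-first band is the
#' closed integer range 40–49, so LAD 49 is `mmr_first` and LAD 50 is `none`.
#' Two-tumor clusters with LAD in 50–59 are `none`: the two-tumor rule stops
#' at 50 and the three-tumor rule requires a third tumor.
#'
#' @param tumor_count Integer >= 1: LS-associated tumors in the CFDR.
#' @param lad Integer years: lowest age at diagnosis.
#' @return One of `"panel_a"`, `"panel_b"`, `"panel_c"`, `"mmr_first"`,
#'   `"none"`.
#' @export
classify_cfdr <- function(tumor_count, lad) {
  stopifnot(length(tumor_count) == 1L, length(lad) == 1L, tumor_count >= 1)
  if (tumor_count == 1) {
    if (lad < 40) "panel_a" else if (lad <= 49) "mmr_first" else "none"
  } else if (tumor_count == 2) {
    if (lad < 50) "panel_b" else "none"
  } else {
    if (lad < 60) "panel_c" else "none"
  }
}

#' Triage decision for one proband
#'
#' @param r A `"cfdr_result"` (or any list with `proband_id`, `tumor_count`,
#'   `lad`).
#' @return Object of class `"triage_decision"`: `proband_id`, `category`,
#'   `analyses_planned` (ordered character vector; panel categories plan
#'   `gene_panel`, `mmr_first` plans `mmr_functional` pending
#'   [resolve_mmr_first()], `none` plans nothing).
#' @export
classify <- function(r) {
  category <- classify_cfdr(r$tumor_count, r$lad)
  analyses <- switch(category,
    panel_a = , panel_b = , panel_c = "gene_panel",
    mmr_first = "mmr_functional",
    none = character(0)
  )
  structure(list(proband_id = r$proband_id, category = category,
                 analyses_planned = analyses),
            class = "triage_decision")
}

#' @export
print.triage_decision <- function(x, ...) {
  cat("<triage_decision>", x$proband_id, "->", x$category, "[",
      paste(x$analyses_planned, collapse = " -> "), "]\n")
  invisible(x)
}

ihc_gene_count <- function(ihc_lost, msi_only_gene_count = 4L) {
  if (length(ihc_lost) == 0L) return(as.integer(msi_only_gene_count))
  if (setequal(ihc_lost, c("MLH1", "PMS2")) ||
      setequal(ihc_lost, c("MSH2", "MSH6"))) return(2L)
  if (length(ihc_lost) == 1L) return(1L)
  min(length(ihc_lost), 4L)
}

sequencing_analysis <- function(n_genes) {
  paste0("sequencing_", n_genes, "_gene", if (n_genes > 1) "s" else "")
}

#' Resolve an MMR-first triage decision against laboratory results
#'
#' Under the simulated strategy, single-tumor probands with LAD 40–49 get MMR
#' functional analysis first; a deficient tumor triggers targeted germline
#' sequencing. The number of genes follows the IHC staining pattern: a lost
#' heterodimer pair (MLH1/PMS2 or MSH2/MSH6) means 2 genes, a single lost
#' protein 1 gene, and MSI positivity without informative IHC all 4 MMR genes.
#'
#' @param d A `"triage_decision"` with category `"mmr_first"`.
#' @param lab One row of the lab-results frame for the same proband.
#' @param config Work-up configuration, see [workup_config()].
#' @return The decision with `analyses_planned` extended.
#' @export
resolve_mmr_first <- function(d, lab, config = workup_config()) {
  stopifnot(inherits(d, "triage_decision"), d$category == "mmr_first")
  mmr <- lab$mmr_functional
  if (!mmr %in% c("deficient", "proficient")) {
    stop("unresolved MMR-first case for proband ", d$proband_id,
         ": mmr_functional is '", mmr, "'", call. = FALSE)
  }
  if (mmr == "deficient") {
    k <- ihc_gene_count(split_multi(lab$ihc_pattern),
                        config$msi_only_gene_count)
    d$analyses_planned <- c(d$analyses_planned, sequencing_analysis(k))
  }
  d
}

#' Work-up configuration
#'
#' Options for the historical stepwise decision tree. `braf_available`
#' reflects the assay era (tumor BRAF V600E testing entered routine use late
#' in the study period); `direct_sequencing_overrides` is a named list of
#' per-proband analysis vectors for the rare referrals that went straight to
#' germline sequencing without tumor testing.
#'
#' @param braf_available Logical; offer BRAF V600E reflex testing for
#'   MLH1/PMS2-deficient tumors.
#' @param msi_only_gene_count Genes sequenced when MSI is the only MMR
#'   readout (default all 4).
#' @param direct_sequencing_overrides Named list: proband id -> character
#'   vector of analyses replacing the tree.
#' @return A list of class `"workup_config"`.
#' @export
workup_config <- function(braf_available = TRUE, msi_only_gene_count = 4L,
                          direct_sequencing_overrides = list()) {
  structure(list(braf_available = isTRUE(braf_available),
                 msi_only_gene_count = as.integer(msi_only_gene_count),
                 direct_sequencing_overrides = direct_sequencing_overrides),
            class = "workup_config")
}

#' Historical stepwise work-up path for one proband
#'
#' Reconstruction of the standard Lynch-syndrome laboratory cascade:
#' MMR functional analysis first; for a deficient tumor with the MLH1/PMS2
#' staining pattern and BRAF testing available, BRAF V600E next — a positive
#' result indicates sporadic MLH1 promoter methylation and stops the cascade;
#' otherwise deficiency leads to germline sequencing of 1–4 MMR genes guided
#' by the IHC pattern. MSH2/MSH6 loss never triggers BRAF (the mutation only
#' discriminates MLH1-methylated sporadic tumors). Probands listed in
#' `config$direct_sequencing_overrides` bypass the tree.
#'
#' @param r The proband's `"cfdr_result"` (used for its id; the historical
#'   path is driven by laboratory findings, not family history).
#' @param lab One row of the lab-results frame.
#' @param config A [workup_config()].
#' @return Ordered character vector of analysis names (possibly empty).
#' @export
standard_workup_path <- function(r, lab, config = workup_config()) {
  ov <- config$direct_sequencing_overrides[[r$proband_id]]
  if (!is.null(ov)) return(ov)
  if (lab$mmr_functional == "not_done") return(character(0))
  path <- "mmr_functional"
  if (lab$mmr_functional == "proficient") return(path)
  ihc <- split_multi(lab$ihc_pattern)
  mlh1_pattern <- length(ihc) == 0L || "MLH1" %in% ihc
  if (mlh1_pattern && config$braf_available &&
      lab$braf_v600e %in% c("positive", "negative")) {
    path <- c(path, "braf_v600e")
    if (lab$braf_v600e == "positive") return(path)  # somatic origin
  }
  k <- ihc_gene_count(ihc, config$msi_only_gene_count)
  c(path, sequencing_analysis(k))
}

#' Triage a cohort under the direct-panel strategy
#'
#' Classifies every CFDR row, resolves MMR-first cases against the lab
#' results, and returns the per-proband decisions.
#'
#' @param cfdr Data frame from [cfdr_cohort()].
#' @param lab Lab-results frame (needed for `mmr_first` resolution; rows are
#'   matched by `proband_id`).
#' @param config A [workup_config()].
#' @return Data frame: `proband_id`, `category`, `analyses_planned`
#'   (semicolon-joined).
#' @export
triage_cohort <- function(cfdr, lab = NULL, config = workup_config()) {
  rows <- lapply(seq_len(nrow(cfdr)), function(i) {
    d <- classify(as.list(cfdr[i, ]))
    if (d$category == "mmr_first" && !is.null(lab)) {
      lrow <- lab[lab$proband_id == d$proband_id, , drop = FALSE]
      if (nrow(lrow) == 1L && lrow$mmr_functional != "not_done") {
        d <- resolve_mmr_first(d, as.list(lrow), config)
      }
    }
    data.frame(proband_id = d$proband_id, category = d$category,
               analyses_planned = join_multi(d$analyses_planned),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Analysis paths of a cohort under the historical stepwise strategy
#'
#' @param cfdr Data frame from [cfdr_cohort()].
#' @param lab Lab-results frame.
#' @param config A [workup_config()].
#' @return Named list: proband id -> ordered character vector of analyses.
#' @export
standard_cohort_paths <- function(cfdr, lab, config = workup_config()) {
  paths <- lapply(seq_len(nrow(cfdr)), function(i) {
    r <- as.list(cfdr[i, ])
    lrow <- lab[lab$proband_id == r$proband_id, , drop = FALSE]
    if (nrow(lrow) != 1L) {
      stop("no lab result for proband ", r$proband_id, call. = FALSE)
    }
    standard_workup_path(r, as.list(lrow), config)
  })
  names(paths) <- cfdr$proband_id
  paths
}

#' Pool per-patient analysis paths into analysis counts
#' @param paths List of character vectors (or a triage frame's
#'   semicolon-joined `analyses_planned` column).
#' @return Named integer vector of counts per analysis name.
#' @export
count_analyses <- function(paths) {
  if (is.character(paths)) paths <- lapply(paths, split_multi)
  tab <- table(unlist(paths, use.names = FALSE))
  stats::setNames(as.integer(tab), names(tab))
}
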