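# End-to-end pipeline: pedigrees + lab results -> CFDR statistics, triage,
# strategy costs, cohort summary and figure-data exports.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the full diagnostic-evaluation pipeline
#'
#' Chains every stage: parse (or accept in-memory) pedigrees and lab results,
#' compute per-proband CFDR statistics, triage under the direct-panel
#' criteria, price both diagnostic strategies, summarise the cohort, compare
#' CFDR metrics by MMR status, and write the report artifacts:
#' `cfdr.tsv`, `triage.tsv`, `costs_standard.{tsv,json}`,
#' `costs_panel.{tsv,json}`, `comparison.json`, `summary.json`,
#' `scatter.tsv` (with the cutoff polyline in `cutoff.tsv`).
#'
#' @param peds List of pedigrees, or a path to a PED file.
#' @param lab Lab-results data frame, or a path to the lab TSV.
#' @param out_dir Output directory (created if missing).
#' @param tumors_path Tumor TSV path (required when `peds` is a PED path).
#' @param cost_table Cost table (named integer vector or [read_cost_table()]
#'   path).
#' @param config A [workup_config()] for the historical cascade.
#' @return Invisibly, a list with every computed object and the artifact
#'   paths.
#' @export
run_pipeline <- function(peds, lab, out_dir, tumors_path = NULL,
                         cost_table = default_cost_table(),
                         config = workup_config()) {
  if (is.character(peds)) peds <- read_pedigrees(peds, tumors_path)
  if (is.character(lab)) lab <- read_lab_results(lab)
  if (is.character(cost_table)) cost_table <- read_cost_table(cost_table)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  message("stage cfdr: ", length(peds), " pedigrees")
  cfdr <- cfdr_cohort(peds)
  excl <- attr(cfdr, "excluded")
  if (length(excl) > 0L) {
    message("  excluded ", length(excl),
            " pedigree(s) with unaffected proband")
  }

  message("stage triage: ", nrow(cfdr), " probands")
  triage <- triage_cohort(cfdr, lab, config)

  message("stage cost")
  std_paths <- standard_cohort_paths(cfdr, lab, config)
  panel_paths <- lapply(triage$analyses_planned, split_multi)
  std <- aggregate_costs(count_analyses(std_paths), cost_table,
                         "standard work-up")
  pan <- aggregate_costs(count_analyses(panel_paths), cost_table,
                         "direct panel")
  cmp <- compare_strategies(std, pan)

  message("stage stats")
  summary <- summarize_cohort(cfdr, lab, n_probands = nrow(lab))
  mmr_cmp <- tryCatch(compare_by_mmr_status(cfdr, lab), error = function(e) {
    message("  MMR-status comparison skipped: ", conditionMessage(e))
    NULL
  })

  scatter <- merge(cfdr[c("proband_id", "tumor_count", "lad")],
                   lab[c("proband_id", "mmr_functional", "variant_class")],
                   by = "proband_id", all.x = TRUE, sort = TRUE)

  paths <- list(
    cfdr = write_tsv(cfdr, file.path(out_dir, "cfdr.tsv")),
    triage = write_tsv(triage, file.path(out_dir, "triage.tsv")),
    costs_standard_tsv = write_tsv(std$line_items,
                                   file.path(out_dir, "costs_standard.tsv")),
    costs_standard_json = write_json(
      list(strategy = std$strategy, line_items = std$line_items,
           total = std$total),
      file.path(out_dir, "costs_standard.json")),
    costs_panel_tsv = write_tsv(pan$line_items,
                                file.path(out_dir, "costs_panel.tsv")),
    costs_panel_json = write_json(
      list(strategy = pan$strategy, line_items = pan$line_items,
           total = pan$total),
      file.path(out_dir, "costs_panel.json")),
    comparison = write_json(cmp, file.path(out_dir, "comparison.json")),
    summary = write_json(summary_to_list(summary, triage, mmr_cmp),
                         file.path(out_dir, "summary.json")),
    scatter = write_tsv(scatter, file.path(out_dir, "scatter.tsv")),
    cutoff = write_tsv(cutoff_polyline(), file.path(out_dir, "cutoff.tsv"))
  )
  invisible(list(cfdr = cfdr, triage = triage, costs_standard = std,
                 costs_panel = pan, comparison = cmp, summary = summary,
                 mmr_comparison = mmr_cmp, paths = paths))
}

summary_to_list <- function(s, triage, mmr_cmp) {
  cat_counts <- as.list(table(factor(triage$category,
                                     levels = TRIAGE_CATEGORIES)))
  out <- unclass(s)
  out$triage_categories <- cat_counts
  if (!is.null(mmr_cmp)) {
    out$mmr_comparison <- list(
      tumor_count = list(p_value = mmr_cmp$tumor_count$test$p_value,
                         direction = mmr_cmp$tumor_count$direction),
      lad = list(p_value = mmr_cmp$lad$test$p_value,
                 direction = mmr_cmp$lad$direction)
    )
  }
  out
}
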