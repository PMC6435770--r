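# Laboratory cost model. All prices are whole euros at 2012 charge levels;
# money stays in integer arithmetic end to end so totals are reproducible
# bit-for-bit.

COST_ITEM_ORDER <- c("mmr_functional", "braf_v600e", "sequencing_1_gene",
                     "sequencing_2_genes", "sequencing_3_genes",
                     "sequencing_4_genes", "gene_panel")

#' Default laboratory cost table
#'
#' Unit prices in euros: MMR functional analysis (MSI and/or IHC) 356,
#' tumor BRAF V600E 640, germline Sanger sequencing of 1/2/3/4 MMR genes
#' 556/1022/1422/1689, and massively parallel gene-panel sequencing covering
#' the major hereditary-CRC genes 1648.
#'
#' @return Named integer vector of prices.
#' @export
default_cost_table <- function() {
  c(mmr_functional = 356L, braf_v600e = 640L,
    sequencing_1_gene = 556L, sequencing_2_genes = 1022L,
    sequencing_3_genes = 1422L, sequencing_4_genes = 1689L,
    gene_panel = 1648L)
}

#' Read a cost table from YAML or JSON
#'
#' Entries override the defaults; unknown analysis names are allowed (custom
#' assays) but negative prices are not.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file mapping analysis
#'   names to euro prices; `NULL` returns the defaults.
#' @return Named integer vector of prices.
#' @export
read_cost_table <- function(path = NULL) {
  tab <- default_cost_table()
  if (is.null(path)) return(tab)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  raw <- unlist(raw)
  if (any(raw < 0)) stop("negative price in cost table", call. = FALSE)
  tab[names(raw)] <- as.integer(raw)
  tab
}

#' Price a per-patient analysis path
#' @param path Character vector of analysis names (order irrelevant to cost).
#' @param table Cost table, see [default_cost_table()].
#' @return Integer euros; an empty path costs 0.
#' @export
price_path <- function(path, table = default_cost_table()) {
  if (length(path) == 0L) return(0L)
  miss <- setdiff(path, names(table))
  if (length(miss) > 0L) {
    stop("unpriced analysis name(s): ", paste(unique(miss), collapse = ", "),
         call. = FALSE)
  }
  sum(table[path])
}

#' Aggregate analysis counts into a strategy cost report
#'
#' @param counts Named non-negative integer vector: analysis name -> number
#'   of analyses performed under the strategy.
#' @param table Cost table.
#' @param strategy Label for printing.
#' @return Object of class `"cost_report"`: `line_items` data frame
#'   (`analysis`, `count`, `unit_price`, `subtotal`) in a fixed declared
#'   order, and integer `total`.
#' @export
aggregate_costs <- function(counts, table = default_cost_table(),
                            strategy = "strategy") {
  counts <- counts[counts > 0]
  if (any(counts != as.integer(counts)) || any(counts < 0)) {
    stop("analysis counts must be non-negative integers", call. = FALSE)
  }
  miss <- setdiff(names(counts), names(table))
  if (length(miss) > 0L) {
    stop("unpriced analysis name(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ord <- c(intersect(COST_ITEM_ORDER, names(counts)),
           sort(setdiff(names(counts), COST_ITEM_ORDER)))
  li <- data.frame(
    analysis = ord,
    count = as.integer(counts[ord]),
    unit_price = as.integer(table[ord]),
    stringsAsFactors = FALSE
  )
  li$subtotal <- li$count * li$unit_price
  structure(list(strategy = strategy, line_items = li,
                 total = as.integer(sum(li$subtotal))),
            class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat("<cost_report>", x$strategy, "\n")
  if (nrow(x$line_items) > 0L) {
    print(x$line_items, row.names = FALSE)
  }
  cat("  total:", format(x$total, big.mark = ","), "€\n")
  invisible(x)
}

#' Compare two strategy cost reports
#'
#' The excess fraction of strategy B over strategy A is
#' `total_B / total_A - 1`, also reported as an integer percent (rounded half
#' away from zero).
#'
#' @param a Baseline `"cost_report"` (total must be positive).
#' @param b Comparator `"cost_report"`.
#' @return List: `total_a`, `total_b`, `excess_fraction`, `excess_percent`.
#' @export
compare_strategies <- function(a, b) {
  if (a$total <= 0L) {
    stop("excess fraction undefined: baseline total is not positive",
         call. = FALSE)
  }
  excess <- b$total / a$total - 1
  list(strategy_a = a$strategy, strategy_b = b$strategy,
       total_a = a$total, total_b = b$total,
       excess_fraction = excess,
       excess_percent = as.integer(round_half_away(100 * excess)))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Side-by-side cost comparison table
#'
#' Renders the two strategies' line items and totals in one frame, the
#' stepwise work-up on the left and the simulated panel strategy on the
#' right, with footnote markers on the panel rows: (a) probands meeting a
#' direct-panel criterion, (b) single-tumor CFDR with LAD 40-49 sent to MMR
#' functional analysis first, (c) the subset of (b) with a deficient tumor
#' continuing to targeted sequencing.
#'
#' @param counts_standard,counts_panel Named integer vectors of analysis
#'   counts for the two strategies.
#' @param table Cost table.
#' @return List: `standard` and `panel` cost reports (panel line items carry
#'   a `footnote` column), and the [compare_strategies()] record.
#' @export
make_table2 <- function(counts_standard, counts_panel,
                        table = default_cost_table()) {
  std <- aggregate_costs(counts_standard, table, "standard work-up")
  pan <- aggregate_costs(counts_panel, table, "direct panel")
  fn <- c(gene_panel = "a", mmr_functional = "b")
  seq_items <- grep("^sequencing_", pan$line_items$analysis, value = TRUE)
  fn <- c(fn, stats::setNames(rep("c", length(seq_items)), seq_items))
  pan$line_items$footnote <- unname(fn[pan$line_items$analysis])
  pan$line_items$footnote[is.na(pan$line_items$footnote)] <- ""
  list(standard = std, panel = pan,
       comparison = if (std$total > 0L) compare_strategies(std, pan))
}
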