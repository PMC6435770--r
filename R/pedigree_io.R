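# PED / TSV readers and writers.
#
# PED dialect: >= 6 whitespace- or tab-delimited columns
#   family_id individual_id father_id mother_id sex phenotype
# "0" or "" denote a missing parent; sex is 1/2/0 (male/female/unknown);
# phenotype 2 marks the proband (exactly one per family), anything else is
# ignored.  Tumor phenotypes travel in a separate TSV because PED's single
# phenotype column cannot carry multiple dated primaries.

SEX_CODES <- c("1" = "male", "2" = "female", "0" = "unknown")

split_ped_line <- function(line) {
  # prefer pure-tab splitting (preserves empty fields), else any whitespace
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) >= 6L) return(f)
  strsplit(trimws(line), "[ \t]+")[[1]]
}

#' Read pedigrees from PED + tumor TSV files
#'
#' Parses a standard 6-column PED file together with a tumor-phenotype table
#' and returns validated [new_pedigree()] objects. The PED phenotype column
#' marks the proband (value 2); "0" and "" both denote a missing parent; both
#' tab- and space-delimited files are accepted. The tumor TSV must have a
#' header `individual_id, site, age_at_diagnosis, tumor_index`. Sites outside
#' the recognised enumeration are mapped to `"other"` with a warning and are
#' excluded from all LS-associated counting downstream.
#'
#' @param ped_path Path to the PED file.
#' @param tumors_path Path to the tumor TSV (optional; `NULL` for none).
#' @return Named list of `"pedigree"` objects (names = family ids).
#' @export
read_pedigrees <- function(ped_path, tumors_path = NULL) {
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty PED file: ", ped_path, call. = FALSE)
  rows <- lapply(lines, split_ped_line)
  nf <- vapply(rows, length, integer(1))
  if (any(nf < 6L)) {
    stop("PED line(s) with fewer than 6 columns: ",
         paste(which(nf < 6L), collapse = ", "), call. = FALSE)
  }
  ped_df <- data.frame(
    family_id = vapply(rows, `[[`, character(1), 1L),
    id        = vapply(rows, `[[`, character(1), 2L),
    father    = vapply(rows, `[[`, character(1), 3L),
    mother    = vapply(rows, `[[`, character(1), 4L),
    sex       = vapply(rows, `[[`, character(1), 5L),
    phenotype = vapply(rows, `[[`, character(1), 6L),
    stringsAsFactors = FALSE
  )
  ped_df$father[ped_df$father %in% c("0", "")] <- NA_character_
  ped_df$mother[ped_df$mother %in% c("0", "")] <- NA_character_
  ped_df$sex <- ifelse(ped_df$sex %in% names(SEX_CODES),
                       SEX_CODES[ped_df$sex], "unknown")

  tumors <- read_tumors(tumors_path)
  if (nrow(tumors) > 0L) {
    unknown <- setdiff(tumors$individual_id, ped_df$id)
    if (length(unknown) > 0L) {
      stop("tumor records reference individuals absent from the PED file: ",
           paste(sort(unknown), collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(ped_df$id)) {
      dup <- unique(ped_df$id[duplicated(ped_df$id)])
      amb <- intersect(tumors$individual_id, dup)
      if (length(amb) > 0L) {
        stop("individual id(s) occur in multiple families, tumor assignment ",
             "ambiguous: ", paste(amb, collapse = ", "), call. = FALSE)
      }
    }
  }

  fams <- unique(ped_df$family_id)
  peds <- lapply(fams, function(fid) {
    sub <- ped_df[ped_df$family_id == fid, , drop = FALSE]
    pro <- sub$id[sub$phenotype == "2"]
    if (length(pro) != 1L) {
      stop("family ", fid, " must have exactly one proband (phenotype 2); ",
           "found ", length(pro), call. = FALSE)
    }
    tum <- tumors[tumors$individual_id %in% sub$id, , drop = FALSE]
    new_pedigree(fid, sub[c("id", "father", "mother", "sex")], tum, pro)
  })
  names(peds) <- fams
  peds
}

read_tumors <- function(path) {
  empty <- data.frame(individual_id = character(0), site = character(0),
                      age_at_diagnosis = integer(0), tumor_index = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(path)) return(empty)
  tum <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("individual_id", "site", "age_at_diagnosis", "tumor_index")
  miss <- setdiff(need, names(tum))
  if (length(miss) > 0L) {
    stop("tumor TSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tum) == 0L) return(empty)
  odd <- !(tum$site %in% tumor_sites())
  if (any(odd)) {
    warning("tumor site(s) outside the LS-associated enumeration mapped to ",
            "'other': ", paste(unique(tum$site[odd]), collapse = ", "),
            call. = FALSE)
    tum$site[odd] <- "other"
  }
  tum$age_at_diagnosis <- as.integer(tum$age_at_diagnosis)
  tum$tumor_index <- as.integer(tum$tumor_index)
  tum[need]
}

#' Write pedigrees to PED + tumor TSV files
#'
#' Inverse of [read_pedigrees()]: emits tab-delimited 6-column PED (missing
#' parents as "0", sexes as 1/2/0, proband flagged with phenotype 2) and the
#' tumor TSV. `read_pedigrees(write_pedigrees(...))` round-trips up to row
#' order.
#'
#' @param peds List of pedigrees.
#' @param ped_path,tumors_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_pedigrees <- function(peds, ped_path, tumors_path) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  sex_back <- c(male = "1", female = "2", unknown = "0")
  ped_rows <- do.call(rbind, lapply(peds, function(p) {
    ind <- p$individuals
    data.frame(
      family_id = p$family_id, id = ind$id,
      father = ifelse(is.na(ind$father), "0", ind$father),
      mother = ifelse(is.na(ind$mother), "0", ind$mother),
      sex = sex_back[ind$sex],
      phenotype = ifelse(ind$id == p$proband_id, "2", "1"),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(ped_rows, ped_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  tum_rows <- do.call(rbind, lapply(peds, `[[`, "tumors"))
  utils::write.table(tum_rows, tumors_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(ped_path, tumors_path))
}

LAB_ENUMS <- list(
  mmr_functional = c("deficient", "proficient", "not_done"),
  braf_v600e = c("positive", "negative", "not_done"),
  variant_class = c("pathogenic", "VUS", "none", "")
)

#' Read per-proband laboratory results
#'
#' Parses the lab TSV (one row per proband) into a validated data frame.
#' Multi-valued fields (`ihc_pattern`, `screened_genes`) are semicolon-joined
#' in the file and kept that way in the returned frame; use
#' [split_multi()] to expand them. Enumeration tokens are validated with the
#' offending row number reported; a non-empty `mutation_gene` requires
#' `variant_class = "pathogenic"`, and any non-empty `variant_class` requires
#' non-empty `screened_genes`.
#'
#' @param path Path to the TSV with header `proband_id, mmr_functional,
#'   ihc_pattern, braf_v600e, screened_genes, mutation_gene, variant_class`.
#' @return Data frame keyed by unique `proband_id`.
#' @export
read_lab_results <- function(path) {
  lab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  need <- c("proband_id", "mmr_functional", "ihc_pattern", "braf_v600e",
            "screened_genes", "mutation_gene", "variant_class")
  miss <- setdiff(need, names(lab))
  if (length(miss) > 0L) {
    stop("lab TSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lab <- lab[need]
  validate_lab_results(lab)
  lab
}

validate_lab_results <- function(lab) {
  if (anyDuplicated(lab$proband_id)) {
    stop("duplicate proband_id in lab results: ",
         paste(unique(lab$proband_id[duplicated(lab$proband_id)]),
               collapse = ", "), call. = FALSE)
  }
  for (col in names(LAB_ENUMS)) {
    ok <- lab[[col]] %in% LAB_ENUMS[[col]]
    if (any(!ok)) {
      stop("illegal ", col, " token '", lab[[col]][which(!ok)[1]],
           "' at row ", which(!ok)[1], call. = FALSE)
    }
  }
  genes_ok <- function(x) all(split_multi(x) %in% mmr_genes())
  bad_ihc <- !vapply(lab$ihc_pattern, genes_ok, logical(1))
  if (any(bad_ihc)) {
    stop("illegal ihc_pattern token at row ", which(bad_ihc)[1], call. = FALSE)
  }
  has_gene <- nzchar(lab$mutation_gene)
  if (any(has_gene & lab$variant_class != "pathogenic")) {
    stop("mutation_gene set but variant_class not 'pathogenic' at row ",
         which(has_gene & lab$variant_class != "pathogenic")[1], call. = FALSE)
  }
  if (any(has_gene & !(lab$mutation_gene %in% mmr_genes()))) {
    stop("illegal mutation_gene at row ",
         which(has_gene & !(lab$mutation_gene %in% mmr_genes()))[1],
         call. = FALSE)
  }
  classed <- nzchar(lab$variant_class)
  no_screen <- classed & !nzchar(lab$screened_genes)
  if (any(no_screen)) {
    stop("variant_class set but screened_genes empty at row ",
         which(no_screen)[1], call. = FALSE)
  }
  invisible(lab)
}

#' Write laboratory results
#' @param lab Data frame as returned by [read_lab_results()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_lab_results <- function(lab, path) {
  validate_lab_results(lab)
  utils::write.table(lab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split a semicolon-joined multi-value field
#' @param x Character scalar such as `"MLH1;PMS2"`; `""` gives `character(0)`.
#' @return Character vector of tokens.
#' @export
split_multi <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, ";", fixed = TRUE)[[1]]
}

join_multi <- function(x) paste(x, collapse = ";")
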