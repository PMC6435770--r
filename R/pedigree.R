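#' Lynch-syndrome-associated tumor sites
#'
#' The fixed list of tumor sites counted towards CFDR tumor burden.
#' Rectal cancer is kept distinct from colorectal because MMR deficiency in
#' rectal tumors is rare in sporadic disease and therefore a Lynch indicator;
#' both count as LS-associated. Any other site is coded `"other"` and never
#' contributes to tumor counts or affected status.
#'
#' @return Character vector of LS-associated site codes.
#' @export
ls_sites <- function() {
  c("colorectal", "rectal", "endometrial", "ovarian", "gastric",
    "small_bowel", "upper_urinary_tract")
}

#' All recognised tumor site codes
#' @return Character vector: the LS-associated sites plus `"other"`.
#' @export
tumor_sites <- function() c(ls_sites(), "other")

mmr_genes <- function() c("MLH1", "MSH2", "MSH6", "PMS2")

#' Construct a pedigree
#'
#' Builds the internal pedigree object used throughout the package: a family
#' of individuals with parent links, per-individual tumor records and a single
#' proband (the referred index patient).
#'
#' @param family_id Family identifier.
#' @param individuals Data frame with columns `id`, `father`, `mother`
#'   (`NA` for founders), and `sex` (`"male"`, `"female"` or `"unknown"`).
#' @param tumors Data frame with columns `individual_id`, `site`,
#'   `age_at_diagnosis` and `tumor_index` (which distinguishes metachronous /
#'   synchronous primaries in one individual); may be `NULL` for no tumors.
#' @param proband_id Identifier of the proband; must appear in `individuals`.
#' @param validate Run [validate_pedigree()] before returning (default `TRUE`).
#' @return An object of class `"pedigree"`.
#' @export
new_pedigree <- function(family_id, individuals, tumors = NULL, proband_id,
                         validate = TRUE) {
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  for (col in c("id", "father", "mother", "sex")) {
    if (!col %in% names(individuals)) {
      stop("individuals must have column '", col, "'", call. = FALSE)
    }
  }
  individuals$id <- as.character(individuals$id)
  individuals$father <- as.character(individuals$father)
  individuals$mother <- as.character(individuals$mother)
  individuals$sex <- as.character(individuals$sex)
  if (is.null(tumors) || nrow(as.data.frame(tumors)) == 0L) {
    tumors <- data.frame(individual_id = character(0), site = character(0),
                         age_at_diagnosis = integer(0), tumor_index = integer(0),
                         stringsAsFactors = FALSE)
  } else {
    tumors <- as.data.frame(tumors, stringsAsFactors = FALSE)
    tumors$individual_id <- as.character(tumors$individual_id)
    tumors$site <- as.character(tumors$site)
    tumors$age_at_diagnosis <- as.integer(tumors$age_at_diagnosis)
    tumors$tumor_index <- as.integer(tumors$tumor_index)
  }
  ped <- structure(
    list(family_id = as.character(family_id), individuals = individuals,
         tumors = tumors, proband_id = as.character(proband_id)),
    class = "pedigree"
  )
  if (validate) validate_pedigree(ped)
  ped
}

#' Validate a pedigree
#'
#' Checks the structural invariants: parent references resolve within the
#' family, parentage is acyclic, exactly one proband, tumor records reference
#' known individuals, `(individual_id, tumor_index)` pairs are unique, ages lie
#' in `[0, 120]` and sites are recognised codes.
#'
#' @param ped A `"pedigree"` object.
#' @return `ped`, invisibly; errors describe every offending identifier.
#' @export
validate_pedigree <- function(ped) {
  ind <- ped$individuals
  if (anyDuplicated(ind$id)) {
    stop("duplicate individual ids in family ", ped$family_id, ": ",
         paste(unique(ind$id[duplicated(ind$id)]), collapse = ", "),
         call. = FALSE)
  }
  for (side in c("father", "mother")) {
    ref <- ind[[side]]
    bad <- !is.na(ref) & !(ref %in% ind$id)
    if (any(bad)) {
      stop("dangling ", side, " reference in family ", ped$family_id, ": ",
           paste(ind$id[bad], "->", ref[bad], collapse = ", "), call. = FALSE)
    }
  }
  # acyclicity by iterated founder stripping (topological peel)
  remaining <- ind$id
  repeat {
    keep <- ind$id %in% remaining
    fa <- ind$father[keep]; mo <- ind$mother[keep]
    founders <- ind$id[keep][(is.na(fa) | !(fa %in% remaining)) &
                             (is.na(mo) | !(mo %in% remaining))]
    if (length(founders) == 0L) break
    remaining <- setdiff(remaining, founders)
  }
  if (length(remaining) > 0L) {
    stop("cyclic parentage in family ", ped$family_id, " involving: ",
         paste(sort(remaining), collapse = ", "), call. = FALSE)
  }
  if (!ped$proband_id %in% ind$id) {
    stop("proband ", ped$proband_id, " not found in family ", ped$family_id,
         call. = FALSE)
  }
  tum <- ped$tumors
  if (nrow(tum) > 0L) {
    unknown <- setdiff(tum$individual_id, ind$id)
    if (length(unknown) > 0L) {
      stop("tumor records reference unknown individuals in family ",
           ped$family_id, ": ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    key <- paste(tum$individual_id, tum$tumor_index, sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate (individual_id, tumor_index) in family ", ped$family_id,
           ": ", paste(unique(key[duplicated(key)]), collapse = "; "),
           call. = FALSE)
    }
    if (any(tum$age_at_diagnosis < 0L | tum$age_at_diagnosis > 120L)) {
      stop("age_at_diagnosis outside [0, 120] in family ", ped$family_id,
           call. = FALSE)
    }
    bad_site <- setdiff(tum$site, tumor_sites())
    if (length(bad_site) > 0L) {
      stop("unrecognised tumor site(s): ", paste(bad_site, collapse = ", "),
           call. = FALSE)
    }
    if (any(tum$tumor_index < 1L)) {
      stop("tumor_index must be >= 1", call. = FALSE)
    }
  }
  invisible(ped)
}

#' @export
print.pedigree <- function(x, ...) {
  n_aff <- length(affected_ids(x))
  cat("<pedigree> family", x$family_id, "-", nrow(x$individuals),
      "individuals,", nrow(x$tumors), "tumor records,", n_aff,
      "affected; proband", x$proband_id, "\n")
  invisible(x)
}

#' Tumors of one individual
#' @param ped A pedigree.
#' @param id Individual identifier.
#' @param ls_only Keep only LS-associated sites (default `TRUE`).
#' @return Data frame of tumor records.
#' @export
tumors_of <- function(ped, id, ls_only = TRUE) {
  tum <- ped$tumors[ped$tumors$individual_id == id, , drop = FALSE]
  if (ls_only) tum <- tum[tum$site %in% ls_sites(), , drop = FALSE]
  tum
}

#' Affected individuals
#'
#' An individual is affected iff it carries at least one LS-associated tumor;
#' tumors at `"other"` sites never confer affected status.
#'
#' @param ped A pedigree.
#' @return Character vector of ids, sorted.
#' @export
affected_ids <- function(ped) {
  tum <- ped$tumors
  sort(unique(tum$individual_id[tum$site %in% ls_sites()]))
}

#' Is the proband affected?
#' @param ped A pedigree.
#' @return `TRUE` iff the proband has at least one LS-associated tumor.
#' @export
proband_affected <- function(ped) ped$proband_id %in% affected_ids(ped)
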