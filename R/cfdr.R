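# CFDR / LAD statistics.
#
# The per-pedigree statistic is the cluster of first-degree relatives (CFDR)
# carrying the largest number of LS-associated tumors, where metachronous and
# synchronous primaries count independently, and its lowest age at diagnosis
# (LAD), which affected second-degree relatives in the same family branch may
# lower but never raise.

#' First-degree relative edges of a pedigree
#'
#' First-degree = parent, child, or full sibling (both parents shared and
#' known). Spouses are never edges; half-siblings share no sibling edge but
#' remain linked to the shared parent.
#'
#' @param ped A pedigree.
#' @return Data frame with columns `a`, `b` (unordered pairs, `a < b`).
#' @export
first_degree_edges <- function(ped) {
  ind <- ped$individuals
  pairs <- list()
  pc <- rbind(
    data.frame(a = ind$id, b = ind$father, stringsAsFactors = FALSE),
    data.frame(a = ind$id, b = ind$mother, stringsAsFactors = FALSE)
  )
  pairs[[1]] <- pc[!is.na(pc$b), , drop = FALSE]
  both <- !is.na(ind$father) & !is.na(ind$mother)
  key <- paste(ind$father, ind$mother, sep = "\r")
  for (k in unique(key[both])) {
    sibs <- sort(ind$id[both & key == k])
    if (length(sibs) >= 2L) {
      cmb <- utils::combn(sibs, 2L)
      pairs[[length(pairs) + 1L]] <-
        data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
    }
  }
  e <- do.call(rbind, pairs)
  if (is.null(e) || nrow(e) == 0L) {
    return(data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE))
  }
  swap <- e$a > e$b
  tmp <- e$a[swap]; e$a[swap] <- e$b[swap]; e$b[swap] <- tmp
  e <- unique(e)
  rownames(e) <- NULL
  e[order(e$a, e$b), , drop = FALSE]
}

ancestor_ids <- function(ped, id, include_self = TRUE) {
  ind <- ped$individuals
  seen <- character(0)
  frontier <- id
  while (length(frontier) > 0L) {
    rows <- match(frontier, ind$id)
    parents <- c(ind$father[rows], ind$mother[rows])
    parents <- setdiff(parents[!is.na(parents)], seen)
    seen <- c(seen, parents)
    frontier <- parents
  }
  if (include_self) unique(c(id, seen)) else unique(seen)
}

#' Family branch of an individual relative to the proband
#'
#' Partitions blood relatives of the proband into `"maternal"` (common
#' ancestry only through the proband's mother), `"paternal"` (only through
#' the father), and `"nuclear"` (the proband, its descendants, and relatives
#' whose shared ancestry spans both parents: full siblings and their
#' descendants). Individuals with no common ancestor — spouses marrying in —
#' are `"unrelated"`. Blood relationship is decided by a non-empty
#' intersection of ancestor sets (self included), so spouses connected only
#' through shared children are correctly excluded.
#'
#' @param ped A pedigree.
#' @param id Individual identifier.
#' @return One of `"maternal"`, `"paternal"`, `"nuclear"`, `"unrelated"`.
#' @export
branch_of <- function(ped, id) {
  pro <- ped$proband_id
  if (id == pro) return("nuclear")
  anc_id <- ancestor_ids(ped, id)
  if (pro %in% anc_id) return("nuclear")     # descendant of the proband
  anc_pro <- ancestor_ids(ped, pro)
  common <- intersect(anc_id, anc_pro)
  if (length(common) == 0L) return("unrelated")
  row <- match(pro, ped$individuals$id)
  fa <- ped$individuals$father[row]
  mo <- ped$individuals$mother[row]
  mat_side <- if (!is.na(mo)) ancestor_ids(ped, mo) else character(0)
  pat_side <- if (!is.na(fa)) ancestor_ids(ped, fa) else character(0)
  m <- any(common %in% mat_side)
  p <- any(common %in% pat_side)
  if (m && p) "nuclear" else if (m) "maternal" else if (p) "paternal"
  else "unrelated"
}

#' Second-degree relatives of the proband
#'
#' Grandparents, grandchildren, aunts/uncles (full siblings of a parent),
#' nieces/nephews (children of full siblings) and half-siblings.
#'
#' @param ped A pedigree.
#' @return Character vector of ids, sorted.
#' @export
second_degree_ids <- function(ped) {
  ind <- ped$individuals
  pro <- ped$proband_id
  row <- function(id) match(id, ind$id)
  parents_of <- function(id) {
    r <- row(id)
    c(ind$father[r], ind$mother[r])
  }
  children_of <- function(ids) {
    ind$id[(!is.na(ind$father) & ind$father %in% ids) |
           (!is.na(ind$mother) & ind$mother %in% ids)]
  }
  full_sibs_of <- function(id) {
    pp <- parents_of(id)
    if (any(is.na(pp))) return(character(0))
    setdiff(ind$id[!is.na(ind$father) & !is.na(ind$mother) &
                   ind$father == pp[1] & ind$mother == pp[2]], id)
  }
  pp <- parents_of(pro)
  pp <- pp[!is.na(pp)]
  grandparents <- unlist(lapply(pp, function(p) parents_of(p)))
  grandparents <- grandparents[!is.na(grandparents)]
  children <- children_of(pro)
  grandchildren <- children_of(children)
  aunts_uncles <- unlist(lapply(pp, full_sibs_of))
  full_sibs <- full_sibs_of(pro)
  nieces <- children_of(full_sibs)
  r <- row(pro)
  half_sibs <- setdiff(
    ind$id[(!is.na(ind$father) & !is.na(ind$father[r]) &
              ind$father == ind$father[r]) |
           (!is.na(ind$mother) & !is.na(ind$mother[r]) &
              ind$mother == ind$mother[r])],
    c(pro, full_sibs)
  )
  sort(unique(c(grandparents, grandchildren, aunts_uncles, nieces, half_sibs)))
}

#' Enumerate candidate CFDR clusters
#'
#' For each family branch, takes the subgraph of first-degree edges restricted
#' to affected individuals whose branch is that side or nuclear; the connected
#' components (including isolated affected singletons) are the candidates.
#' Purely nuclear components arise identically on both sides and are
#' deduplicated with branch label `"nuclear"`; nuclear members may otherwise
#' appear in candidates of both branches.
#'
#' @param ped A pedigree.
#' @return List of candidates, each `list(members = <sorted ids>, branch)`.
#' @export
enumerate_clusters <- function(ped) {
  aff <- affected_ids(ped)
  if (length(aff) == 0L) {
    stop("no LS-associated tumor in pedigree ", ped$family_id, call. = FALSE)
  }
  br <- vapply(aff, function(id) branch_of(ped, id), character(1))
  aff <- aff[br != "unrelated"]
  br <- br[br != "unrelated"]
  if (length(aff) == 0L) {
    stop("no LS-associated tumor among blood relatives of the proband in ",
         "pedigree ", ped$family_id, call. = FALSE)
  }
  edges <- first_degree_edges(ped)
  out <- list()
  seen <- character(0)
  for (side in c("maternal", "paternal")) {
    nodes <- aff[br %in% c(side, "nuclear")]
    if (length(nodes) == 0L) next
    for (comp in connected_components(nodes, edges)) {
      pure_nuclear <- all(br[match(comp, aff)] == "nuclear")
      label <- if (pure_nuclear) "nuclear" else side
      key <- paste(label, paste(comp, collapse = ";"))
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- list(members = comp, branch = label)
    }
  }
  out
}

connected_components <- function(nodes, edges) {
  keep <- edges$a %in% nodes & edges$b %in% nodes
  adj <- split(c(edges$b[keep], edges$a[keep]),
               c(edges$a[keep], edges$b[keep]))
  comps <- list()
  left <- nodes
  while (length(left) > 0L) {
    comp <- left[1]
    frontier <- comp
    while (length(frontier) > 0L) {
      nb <- setdiff(intersect(unlist(adj[frontier], use.names = FALSE), left),
                    comp)
      comp <- c(comp, nb)
      frontier <- nb
    }
    comps[[length(comps) + 1L]] <- sort(comp)
    left <- setdiff(left, comp)
  }
  comps
}

#' Score a cluster: LS tumor count and internal minimum age
#'
#' Metachronous and synchronous LS-associated tumors count independently, so
#' one member can contribute several tumors; `"other"`-site tumors contribute
#' nothing.
#'
#' @param ped A pedigree.
#' @param members Character vector of cluster member ids.
#' @return `list(tumor_count, internal_min_age)`.
#' @export
score_cluster <- function(ped, members) {
  tum <- ped$tumors
  keep <- tum$individual_id %in% members & tum$site %in% ls_sites()
  list(tumor_count = sum(keep),
       internal_min_age = if (any(keep)) min(tum$age_at_diagnosis[keep])
                          else NA_integer_)
}

#' Lowest age at diagnosis (LAD) of a cluster
#'
#' The cluster's own minimum age, possibly lowered (never raised) by
#' LS-associated tumors of affected second-degree relatives of the proband
#' whose branch matches the cluster's branch or is nuclear. A cluster labelled
#' `"nuclear"` belongs to both candidate branches, so second-degree relatives
#' of either side may lower its LAD.
#'
#' @param ped A pedigree.
#' @param members Cluster member ids.
#' @param branch Cluster branch (`"maternal"`, `"paternal"`, `"nuclear"`).
#' @return Integer LAD in years.
#' @export
compute_lad <- function(ped, members, branch) {
  sc <- score_cluster(ped, members)
  allowed <- if (branch == "nuclear") c("maternal", "paternal", "nuclear")
             else c(branch, "nuclear")
  sdr <- second_degree_ids(ped)
  sdr <- sdr[vapply(sdr, function(id) branch_of(ped, id) %in% allowed,
                    logical(1))]
  tum <- ped$tumors
  keep <- tum$individual_id %in% sdr & tum$site %in% ls_sites()
  ages <- c(sc$internal_min_age, tum$age_at_diagnosis[keep])
  as.integer(min(ages, na.rm = TRUE))
}

#' Select the CFDR of a pedigree
#'
#' Returns the candidate cluster maximising the LS-associated tumor count;
#' ties are broken by lower LAD, then smaller member count, then lexicographic
#' member ids, making the selection deterministic.
#'
#' @param ped A pedigree.
#' @return Object of class `"cfdr_result"`: `proband_id`, `member_ids`,
#'   `tumor_count`, `lad`, `branch`.
#' @export
select_cfdr <- function(ped) {
  cands <- enumerate_clusters(ped)
  scored <- lapply(cands, function(cl) {
    sc <- score_cluster(ped, cl$members)
    list(members = cl$members, branch = cl$branch,
         tumor_count = sc$tumor_count,
         lad = compute_lad(ped, cl$members, cl$branch))
  })
  ord <- order(-vapply(scored, `[[`, numeric(1), "tumor_count"),
               vapply(scored, `[[`, numeric(1), "lad"),
               vapply(scored, function(s) length(s$members), integer(1)),
               vapply(scored, function(s) paste(s$members, collapse = ";"),
                      character(1)))
  best <- scored[[ord[1]]]
  structure(
    list(proband_id = ped$proband_id, member_ids = best$members,
         tumor_count = as.integer(best$tumor_count),
         lad = as.integer(best$lad), branch = best$branch),
    class = "cfdr_result"
  )
}

#' @export
print.cfdr_result <- function(x, ...) {
  cat("<cfdr_result> proband", x$proband_id, "-", x$tumor_count,
      "LS tumor(s), LAD", x$lad, "(", x$branch, "branch );",
      "members:", paste(x$member_ids, collapse = ", "), "\n")
  invisible(x)
}

#' CFDR statistics for a cohort of pedigrees
#'
#' Applies [select_cfdr()] to every pedigree with an affected proband;
#' pedigrees whose proband carries no LS-associated tumor are excluded
#' (mirroring the exclusion of referrals without a symptomatic individual)
#' and reported in the `excluded` attribute.
#'
#' @param peds List of pedigrees.
#' @return Data frame: `proband_id`, `family_id`, `tumor_count`, `lad`,
#'   `branch`, `member_ids` (semicolon-joined); attribute `excluded` holds
#'   the skipped family ids.
#' @export
cfdr_cohort <- function(peds) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  ok <- vapply(peds, proband_affected, logical(1))
  rows <- lapply(peds[ok], function(p) {
    r <- select_cfdr(p)
    data.frame(proband_id = r$proband_id, family_id = p$family_id,
               tumor_count = r$tumor_count, lad = r$lad, branch = r$branch,
               member_ids = join_multi(r$member_ids),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(proband_id = character(0), family_id = character(0),
               tumor_count = integer(0), lad = integer(0),
               branch = character(0), member_ids = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- vapply(peds[!ok], `[[`, character(1), "family_id")
  out
}
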