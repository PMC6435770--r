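# Hand-built pedigrees and independent brute-force oracles used across the
# suite. Oracle code deliberately re-derives relationships from first
# principles (pairwise predicates, exhaustive subset enumeration) rather than
# calling the package's graph machinery.

ped_build <- function(rows, tumors = NULL, proband, family_id = "FAM") {
  ind <- do.call(rbind, lapply(rows, function(r) {
    data.frame(id = r[[1]],
               father = if (is.na(r[[2]])) NA_character_ else r[[2]],
               mother = if (is.na(r[[3]])) NA_character_ else r[[3]],
               sex = r[[4]], stringsAsFactors = FALSE)
  }))
  tum <- if (is.null(tumors)) NULL else do.call(rbind, lapply(tumors,
    function(t) data.frame(individual_id = t[[1]], site = t[[2]],
                           age_at_diagnosis = t[[3]], tumor_index = t[[4]],
                           stringsAsFactors = FALSE)))
  new_pedigree(family_id, ind, tum, proband)
}

# trio: father, mother, affected child proband (CRC at 45)
trio_pedigree <- function() {
  ped_build(
    list(list("F", NA, NA, "male"), list("M", NA, NA, "female"),
         list("C", "F", "M", "female")),
    list(list("C", "colorectal", 45L, 1L)),
    proband = "C")
}

# three generations on the maternal side plus paternal relatives; used by
# branch / LAD cases
three_gen_pedigree <- function(tumors) {
  ped_build(
    list(list("mgf", NA, NA, "male"), list("mgm", NA, NA, "female"),
         list("pgf", NA, NA, "male"), list("pgm", NA, NA, "female"),
         list("mo", "mgf", "mgm", "female"), list("fa", "pgf", "pgm", "male"),
         list("aunt_m", "mgf", "mgm", "female"),
         list("uncle_p", "pgf", "pgm", "male"),
         list("pb", "fa", "mo", "female"), list("sib", "fa", "mo", "male")),
    tumors, proband = "pb")
}

# ---- independent first-degree predicate -----------------------------------

oracle_first_degree_pair <- function(ped, a, b) {
  ind <- ped$individuals
  ra <- ind[ind$id == a, ]; rb <- ind[ind$id == b, ]
  parent <- identical(ra$father, b) || identical(ra$mother, b) ||
    identical(rb$father, a) || identical(rb$mother, a)
  fullsib <- !is.na(ra$father) && !is.na(ra$mother) &&
    identical(ra$father, rb$father) && identical(ra$mother, rb$mother)
  parent || fullsib
}

oracle_edges <- function(ped) {
  ids <- ped$individuals$id
  out <- list()
  if (length(ids) >= 2L) {
    cmb <- utils::combn(sort(ids), 2L)
    for (k in seq_len(ncol(cmb))) {
      if (oracle_first_degree_pair(ped, cmb[1, k], cmb[2, k])) {
        out[[length(out) + 1L]] <- cmb[, k]
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(a = character(0), b = character(0)))
  }
  m <- do.call(rbind, out)
  data.frame(a = m[, 1], b = m[, 2], stringsAsFactors = FALSE)
}

# ---- independent second-degree set (explicit roles) -----------------------

oracle_second_degree <- function(ped) {
  ind <- ped$individuals
  get <- function(id) ind[ind$id == id, ]
  pro <- ped$proband_id
  pr <- get(pro)
  parents <- c(pr$father, pr$mother)
  parents <- parents[!is.na(parents)]
  gp <- unlist(lapply(parents, function(p) {
    r <- get(p); c(r$father, r$mother)
  }))
  kids <- ind$id[(!is.na(ind$father) & ind$father == pro) |
                 (!is.na(ind$mother) & ind$mother == pro)]
  gkids <- ind$id[(!is.na(ind$father) & ind$father %in% kids) |
                  (!is.na(ind$mother) & ind$mother %in% kids)]
  fullsib <- function(a, b) {
    ra <- get(a); rb <- get(b)
    !is.na(ra$father) && !is.na(ra$mother) &&
      identical(ra$father, rb$father) && identical(ra$mother, rb$mother)
  }
  others <- setdiff(ind$id, pro)
  aunts <- unlist(lapply(parents, function(p) {
    Filter(function(x) x != p && fullsib(x, p), others)
  }))
  sibs <- Filter(function(x) fullsib(x, pro), others)
  nieces <- ind$id[(!is.na(ind$father) & ind$father %in% sibs) |
                   (!is.na(ind$mother) & ind$mother %in% sibs)]
  halfsibs <- Filter(function(x) {
    rx <- get(x)
    shares <- (!is.na(rx$father) && !is.na(pr$father) &&
                 rx$father == pr$father) ||
      (!is.na(rx$mother) && !is.na(pr$mother) && rx$mother == pr$mother)
    shares && !fullsib(x, pro)
  }, others)
  sort(unique(c(gp[!is.na(gp)], gkids, unlist(aunts), nieces,
                unlist(halfsibs))))
}

# ---- exhaustive CFDR oracle -----------------------------------------------

# enumerate every non-empty subset of affected blood relatives that is
# single-branch and connected under the first-degree predicate, then pick the
# max-tumor subset with the package's tie-break chain (lower LAD, smaller,
# lexicographic). LAD is recomputed here from the explicit second-degree
# role set.
oracle_select_cfdr <- function(ped) {
  aff <- affected_ids(ped)
  br <- vapply(aff, function(id) branch_of(ped, id), character(1))
  aff <- aff[br != "unrelated"]
  br <- br[br != "unrelated"]
  stopifnot(length(aff) > 0L)
  n <- length(aff)
  sdr <- oracle_second_degree(ped)
  sdr_br <- vapply(sdr, function(id) branch_of(ped, id), character(1))
  tum <- ped$tumors[ped$tumors$site %in% ls_sites(), , drop = FALSE]

  connected <- function(members) {
    comp <- members[1]
    repeat {
      nb <- Filter(function(x) any(vapply(comp, function(c)
        oracle_first_degree_pair(ped, x, c), logical(1))),
        setdiff(members, comp))
      if (length(nb) == 0L) break
      comp <- c(comp, nb)
    }
    length(comp) == length(members)
  }
  lad_of <- function(members, side) {
    allowed <- if (side == "nuclear") c("maternal", "paternal", "nuclear")
               else c(side, "nuclear")
    elig <- sdr[sdr_br %in% allowed]
    min(tum$age_at_diagnosis[tum$individual_id %in% c(members, elig)])
  }

  best <- NULL
  for (mask in seq_len(2^n - 1L)) {
    members <- aff[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
    mbr <- br[match(members, aff)]
    sides <- c("maternal", "paternal")
    ok_sides <- sides[vapply(sides, function(s)
      all(mbr %in% c(s, "nuclear")), logical(1))]
    if (length(ok_sides) == 0L) next
    if (!connected(members)) next
    side <- if (length(ok_sides) == 2L) "nuclear" else ok_sides
    tc <- sum(tum$individual_id %in% members)
    cand <- list(members = sort(members), tumor_count = tc,
                 lad = lad_of(members, side), branch = side)
    if (is.null(best)) { best <- cand; next }
    better <- cand$tumor_count > best$tumor_count ||
      (cand$tumor_count == best$tumor_count && (
        cand$lad < best$lad ||
        (cand$lad == best$lad && (
          length(cand$members) < length(best$members) ||
          (length(cand$members) == length(best$members) &&
             paste(cand$members, collapse = ";") <
             paste(best$members, collapse = ";"))))))
    if (better) best <- cand
  }
  best
}

# random small pedigree (<= 8 members) with random affected statuses; the
# proband is always affected
random_small_pedigree <- function(fam = "R") {
  rows <- list(list("fa", NA, NA, "male"), list("mo", NA, NA, "female"),
               list("pb", "fa", "mo", sample(c("male", "female"), 1)))
  ids <- c("fa", "mo", "pb")
  if (runif(1) < 0.6) {
    rows <- c(rows, list(list("mgf", NA, NA, "male"),
                         list("mgm", NA, NA, "female")))
    rows[[2]] <- list("mo", "mgf", "mgm", "female")
    ids <- c(ids, "mgf", "mgm")
    if (runif(1) < 0.5) {
      rows <- c(rows, list(list("maunt", "mgf", "mgm", "female")))
      ids <- c(ids, "maunt")
    }
  } else if (runif(1) < 0.6) {
    rows <- c(rows, list(list("pgf", NA, NA, "male"),
                         list("pgm", NA, NA, "female")))
    rows[[1]] <- list("fa", "pgf", "pgm", "male")
    ids <- c(ids, "pgf", "pgm")
    if (runif(1) < 0.5) {
      rows <- c(rows, list(list("punc", "pgf", "pgm", "male")))
      ids <- c(ids, "punc")
    }
  }
  n_sib <- sample(0:2, 1)
  for (s in seq_len(min(n_sib, 8L - length(ids)))) {
    rows <- c(rows, list(list(paste0("sib", s), "fa", "mo",
                              sample(c("male", "female"), 1))))
    ids <- c(ids, paste0("sib", s))
  }
  tumors <- list()
  for (id in ids) {
    p_aff <- if (id == "pb") 1 else 0.35
    if (runif(1) < p_aff) {
      k <- sample(1:2, 1, prob = c(0.8, 0.2))
      for (j in seq_len(k)) {
        site <- sample(c(ls_sites(), "other"), 1,
                       prob = c(rep(1, 7), 0.5))
        tumors[[length(tumors) + 1L]] <-
          list(id, site, sample(25:75, 1), j)
      }
    }
  }
  # ensure the proband carries an LS-associated tumor
  pb_tum <- Filter(function(t) t[[1]] == "pb" && t[[2]] %in% ls_sites(),
                   tumors)
  if (length(pb_tum) == 0L) {
    tumors[[length(tumors) + 1L]] <-
      list("pb", "colorectal", sample(25:75, 1), 99L)
  }
  ped_build(rows, tumors, proband = "pb", family_id = fam)
}

# ---- brute-force Mann-Whitney oracle --------------------------------------

# U oriented to x: number of (x, y) pairs with x > y, ties counting 1/2
oracle_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# exact two-tailed p by enumerating all C(n1+n2, n1) group labelings
oracle_mwu_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  obs <- abs(oracle_u(x, y) - mu)
  labelings <- utils::combn(length(pool), n1)
  stats <- apply(labelings, 2, function(idx) {
    abs(oracle_u(pool[idx], pool[-idx]) - mu)
  })
  mean(stats >= obs - 1e-12)
}
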