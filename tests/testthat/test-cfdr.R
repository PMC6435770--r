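test_that("first-degree edges are parent-child and full-sibling pairs only", {
  trio <- trio_pedigree()
  e <- first_degree_edges(trio)
  expect_equal(nrow(e), 2)           # F-C and M-C, never the spouse pair F-M
  expect_setequal(paste(e$a, e$b), c("C F", "C M"))

  # full sibs get an edge; half-sibs do not but keep the shared-parent link
  ped <- ped_build(
    list(list("F", NA, NA, "male"), list("M1", NA, NA, "female"),
         list("M2", NA, NA, "female"),
         list("A", "F", "M1", "male"), list("B", "F", "M1", "female"),
         list("H", "F", "M2", "male")),
    list(list("A", "colorectal", 40L, 1L)), proband = "A")
  e <- first_degree_edges(ped)
  pairs <- paste(e$a, e$b)
  expect_true("A B" %in% pairs)      # full siblings
  expect_false("A H" %in% pairs)     # half siblings
  expect_true("F H" %in% pairs)      # half-sib still linked to shared parent
})

test_that("first-degree edges equal the brute-force pairwise predicate on
           random pedigrees", {
  set.seed(101)
  for (i in 1:25) {
    ped <- random_small_pedigree(paste0("R", i))
    expect_equal(first_degree_edges(ped), oracle_edges(ped),
                 ignore_attr = TRUE)
  }
})

test_that("branch classification follows blood paths through each parent", {
  ped <- three_gen_pedigree(list(list("pb", "colorectal", 45L, 1L)))
  expect_equal(branch_of(ped, "mgm"), "maternal")  # maternal grandmother
  expect_equal(branch_of(ped, "mgf"), "maternal")
  expect_equal(branch_of(ped, "pgf"), "paternal")
  expect_equal(branch_of(ped, "aunt_m"), "maternal")
  expect_equal(branch_of(ped, "uncle_p"), "paternal")
  expect_equal(branch_of(ped, "sib"), "nuclear")   # full sibling
  expect_equal(branch_of(ped, "mo"), "maternal")
  expect_equal(branch_of(ped, "pb"), "nuclear")
})

test_that("spouses and their kin are unrelated: no blood path to proband", {
  # sibling's spouse married in, with a child (niece of the proband)
  ped <- ped_build(
    list(list("fa", NA, NA, "male"), list("mo", NA, NA, "female"),
         list("pb", "fa", "mo", "female"), list("sib", "fa", "mo", "male"),
         list("sibwife", NA, NA, "female"),
         list("niece", "sib", "sibwife", "female")),
    list(list("pb", "colorectal", 45L, 1L)), proband = "pb")
  expect_equal(branch_of(ped, "sibwife"), "unrelated")
  # the niece shares both of the proband's parents as ancestors -> nuclear
  expect_equal(branch_of(ped, "niece"), "nuclear")
  # and the proband's own descendants are nuclear
  ped2 <- ped_build(
    list(list("pb", NA, NA, "female"), list("husband", NA, NA, "male"),
         list("child", "husband", "pb", "male")),
    list(list("pb", "colorectal", 45L, 1L)), proband = "pb")
  expect_equal(branch_of(ped2, "child"), "nuclear")
  expect_equal(branch_of(ped2, "husband"), "unrelated")
})

test_that("cluster enumeration keeps clusters within one family branch", {
  # only the proband affected: the two per-branch singletons deduplicate
  solo <- trio_pedigree()
  cl <- enumerate_clusters(solo)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$members, "C")
  expect_equal(cl[[1]]$branch, "nuclear")

  # affected chain proband - mother - maternal grandmother: one cluster of 3
  chain <- three_gen_pedigree(list(
    list("pb", "colorectal", 45L, 1L), list("mo", "endometrial", 50L, 1L),
    list("mgm", "colorectal", 55L, 1L)))
  cl <- enumerate_clusters(chain)
  sizes <- vapply(cl, function(x) length(x$members), integer(1))
  expect_true(any(sizes == 3))
  big <- cl[[which(sizes == 3)]]
  expect_setequal(big$members, c("pb", "mo", "mgm"))
  expect_equal(big$branch, "maternal")

  # affected proband + mother + father: no cluster spans both branches
  both <- three_gen_pedigree(list(
    list("pb", "colorectal", 45L, 1L), list("mo", "endometrial", 50L, 1L),
    list("fa", "colorectal", 52L, 1L)))
  cl <- enumerate_clusters(both)
  members <- lapply(cl, `[[`, "members")
  has <- function(want) any(vapply(members, setequal, logical(1), want))
  expect_true(has(c("mo", "pb")))
  expect_true(has(c("fa", "pb")))
  expect_false(any(vapply(members, length, integer(1)) == 3))
})

test_that("cluster scoring counts metachronous tumors independently and
           filters non-LS sites", {
  ped <- ped_build(
    list(list("A", NA, NA, "female"), list("B", NA, NA, "male"),
         list("C", "B", "A", "female")),
    list(list("C", "colorectal", 45L, 1L), list("C", "endometrial", 52L, 2L),
         list("A", "other", 60L, 1L), list("B", "colorectal", 50L, 1L)),
    proband = "C")
  sc <- score_cluster(ped, "C")
  expect_equal(sc$tumor_count, 2L)         # two primaries, one individual
  expect_equal(sc$internal_min_age, 45L)
  # an 'other'-site member contributes zero tumors
  expect_equal(score_cluster(ped, c("A", "B"))$tumor_count, 1L)
  # indicator-sum oracle on random clusters
  set.seed(33)
  for (i in 1:10) {
    rp <- random_small_pedigree()
    members <- affected_ids(rp)
    tum <- rp$tumors
    expected <- sum(tum$individual_id %in% members & tum$site %in% ls_sites())
    expect_equal(score_cluster(rp, members)$tumor_count, expected)
  }
})

test_that("LAD is lowered by same-branch affected second-degree relatives
           only", {
  base <- list(list("pb", "colorectal", 48L, 1L))
  # affected maternal aunt at 41 (mother unaffected, so the aunt is not
  # first-degree-connected to the cluster) lowers the proband cluster's LAD
  ped <- three_gen_pedigree(c(base,
                              list(list("aunt_m", "colorectal", 41L, 1L))))
  cl <- enumerate_clusters(ped)
  solo <- Filter(function(x) setequal(x$members, "pb"), cl)[[1]]
  expect_equal(compute_lad(ped, solo$members, solo$branch), 41L)
  # an affected niece (second-degree, not connected through any affected
  # first-degree chain) lowers a maternal cluster's LAD the same way
  ped_n <- ped_build(
    list(list("fa", NA, NA, "male"), list("mo", NA, NA, "female"),
         list("pb", "fa", "mo", "female"), list("sib", "fa", "mo", "male"),
         list("sibwife", NA, NA, "female"),
         list("niece", "sib", "sibwife", "female")),
    c(base, list(list("mo", "gastric", 50L, 1L),
                 list("niece", "colorectal", 41L, 1L))),
    proband = "pb")
  cl_n <- enumerate_clusters(ped_n)
  mat <- Filter(function(x) setequal(x$members, c("mo", "pb")), cl_n)[[1]]
  expect_equal(mat$branch, "maternal")
  expect_equal(compute_lad(ped_n, mat$members, mat$branch), 41L)
  # without second-degree cases LAD equals the internal minimum
  ped2 <- three_gen_pedigree(list(list("pb", "colorectal", 48L, 1L)))
  expect_equal(compute_lad(ped2, "pb", "nuclear"), 48L)
  # an opposite-branch second-degree relative does not lower LAD
  ped3 <- three_gen_pedigree(c(base, list(list("mo", "gastric", 50L, 1L),
                                          list("uncle_p", "colorectal", 30L,
                                               1L))))
  cl3 <- enumerate_clusters(ped3)
  mat3 <- Filter(function(x) setequal(x$members, c("pb", "mo")), cl3)[[1]]
  expect_equal(mat3$branch, "maternal")
  expect_equal(compute_lad(ped3, mat3$members, mat3$branch), 48L)
})

test_that("CFDR selection maximises tumor count with the deterministic
           tie-break chain", {
  # 3-tumor maternal chain beats 1-tumor paternal singleton
  ped <- three_gen_pedigree(list(
    list("pb", "colorectal", 45L, 1L), list("mo", "endometrial", 50L, 1L),
    list("mo", "colorectal", 58L, 2L), list("uncle_p", "gastric", 40L, 1L)))
  r <- select_cfdr(ped)
  expect_setequal(r$member_ids, c("pb", "mo"))
  expect_equal(r$tumor_count, 3L)
  # tie on tumor count: the lower-LAD cluster wins
  tie <- three_gen_pedigree(list(
    list("pb", "colorectal", 51L, 1L),
    list("mo", "colorectal", 44L, 1L),
    list("fa", "colorectal", 46L, 1L)))
  rt <- select_cfdr(tie)
  expect_setequal(rt$member_ids, c("mo", "pb"))
  expect_equal(rt$lad, 44L)
  expect_equal(rt$branch, "maternal")
})

test_that("CFDR selection matches the exhaustive-subset oracle on random
           small pedigrees", {
  set.seed(2024)
  n_checked <- 0L
  for (i in 1:220) {
    ped <- random_small_pedigree(paste0("O", i))
    got <- select_cfdr(ped)
    want <- oracle_select_cfdr(ped)
    expect_equal(got$member_ids, want$members)
    expect_equal(got$tumor_count, want$tumor_count)
    expect_equal(got$lad, want$lad)
    expect_equal(got$branch, want$branch)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 200L)
})

test_that("adding an LS tumor to a selected-cluster member never lowers the
           count nor raises LAD", {
  set.seed(55)
  for (i in 1:40) {
    ped <- random_small_pedigree()
    before <- select_cfdr(ped)
    target <- sample(before$member_ids, 1)
    extra_age <- sample(25:75, 1)
    new_tum <- data.frame(individual_id = target, site = "colorectal",
                          age_at_diagnosis = extra_age,
                          tumor_index = max(ped$tumors$tumor_index[
                            ped$tumors$individual_id == target]) + 1L)
    ped2 <- new_pedigree(ped$family_id, ped$individuals,
                         rbind(ped$tumors, new_tum), ped$proband_id)
    after <- select_cfdr(ped2)
    expect_gte(after$tumor_count, before$tumor_count)
    expect_lte(after$lad, before$lad)
  }
})

test_that("every CFDR result has >= 1 tumor and a LAD present in the data", {
  set.seed(77)
  for (i in 1:30) {
    ped <- random_small_pedigree()
    r <- select_cfdr(ped)
    expect_gte(r$tumor_count, 1L)
    expect_true(r$lad %in% ped$tumors$age_at_diagnosis)
    # tumor_count at least the number of affected members
    expect_gte(r$tumor_count, length(r$member_ids))
  }
})

test_that("unaffected probands are excluded from cohort CFDR statistics", {
  aff <- trio_pedigree()
  unaff <- ped_build(
    list(list("F", NA, NA, "male"), list("M", NA, NA, "female"),
         list("C", "F", "M", "female")),
    list(list("M", "colorectal", 50L, 1L)),
    proband = "C", family_id = "UNAFF")
  res <- cfdr_cohort(list(aff, unaff))
  expect_equal(nrow(res), 1)
  expect_equal(attr(res, "excluded"), "UNAFF")
})
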