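freq_from_counts <- function(counts) {
  worst <- rep(names(counts), counts)
  wbs_list <- lapply(seq_along(worst), function(i) {
    fake_wbs(list(worst[i]), subject = sprintf("sub%03d", i))
  })
  worst_frequency_table(wbs_list)
}

test_that("candidate epicenters are the modal worst parcels", {
  tab <- freq_from_counts(c(p = 43, q = 27, r = 6, s = 4))
  expect_equal(lobe_epicenter(tab, 2), c("p", "q"))
  expect_equal(lobe_epicenter(tab, 3), c("p", "q", "r"))
})

test_that("rank-2 ties resolve to the lexicographically smaller ID", {
  tab <- freq_from_counts(c(p = 10, z = 5, m = 5))
  expect_equal(lobe_epicenter(tab, 2), c("p", "m"))
})

test_that("a single-parcel lobe yields that parcel", {
  tab <- freq_from_counts(c(only = 4))
  expect_equal(lobe_epicenter(tab, 2), "only")
})

test_that("early arrival is detected from s_r, s_m and d", {
  atlas <- chain_atlas(4)  # p01 - p02 - p03 - p04
  # worst progression: {p01}, {p02,p03}, {p02,p03,p04}
  wbs <- fake_wbs(list("p01", c("p02", "p03"), c("p02", "p03", "p04")),
                  lobe = "chain/left")
  ev <- epicenter_evidence(wbs, atlas, "p03")
  expect_equal(ev$worst_s1, "p01")
  expect_equal(ev$s_r, 2L)
  expect_equal(ev$s_m, 3)   # hop(p01, p03) = 2
  expect_equal(ev$d, -1)
  expect_true(ev$early)
})

test_that("the worst single deletion as its own candidate gives d = 0", {
  atlas <- chain_atlas(4)
  wbs <- fake_wbs(list("p02", c("p02", "p03")), lobe = "chain/left")
  ev <- epicenter_evidence(wbs, atlas, "p02")
  expect_equal(ev$s_r, 1L)
  expect_equal(ev$s_m, 1)
  expect_equal(ev$d, 0)
  expect_false(ev$early)
})

test_that("a candidate that never appears carries the NA sentinel", {
  atlas <- chain_atlas(4)
  wbs <- fake_wbs(list("p01", c("p01", "p02")), lobe = "chain/left")
  ev <- epicenter_evidence(wbs, atlas, "p04")
  expect_true(is.na(ev$s_r))
  expect_true(is.na(ev$d))
  expect_false(ev$early)
  expect_error(epicenter_evidence(wbs, atlas, "zz"), "outside lobe")
})

test_that("assignment precedence: worst-s1, adjacent-collapse, earliest", {
  atlas <- chain_atlas(5)
  cands <- c("p02", "p04")
  # rule 1: worst_s1 is a candidate
  w1 <- fake_wbs(list("p02", c("p02", "p03")), subject = "s1",
                 lobe = "chain/left")
  # rule 2: worst_s1 = p03 (non-candidate), adjacent candidate p02 in worst
  # size-2 set {p02, p03}
  w2 <- fake_wbs(list("p03", c("p02", "p03")), subject = "s2",
                 lobe = "chain/left")
  # rule 3: worst_s1 = p01; p04 (hop 3, s_m 4) arrives at size 2 -> d = -2;
  # p02 (hop 1, s_m 2) arrives at size 3 -> d = 1
  w3 <- fake_wbs(list("p01", c("p04", "p05"), c("p02", "p04", "p05")),
                 subject = "s3", lobe = "chain/left")
  # unassigned: no candidate ever appears
  w4 <- fake_wbs(list("p01", c("p01", "p05")), subject = "s4",
                 lobe = "chain/left")
  out <- assign_connectotypes(list(w1, w2, w3, w4), atlas, cands)
  expect_equal(out$label, c("p02", "p02", "p04", "unassigned"))
  expect_equal(out$basis, c("worst-s1-is-epicenter", "adjacent-collapse",
                            "earliest-arrival", "earliest-arrival"))
})

test_that("earliest-arrival ties on d break by the smaller s_r", {
  atlas <- chain_atlas(5)
  # worst_s1 = p01; neither candidate is adjacent to it. p03 (hop 2,
  # s_m 3) first appears at size 3 and p05 (hop 4, s_m 5) at size 5, so
  # both have d = 0; the smaller arrival size wins.
  wbs <- fake_wbs(list("p01", c("p01", "p02"), c("p02", "p03", "p04"),
                       c("p01", "p02", "p03", "p04"),
                       c("p01", "p02", "p03", "p04", "p05")),
                  subject = "s1", lobe = "chain/left")
  out <- assign_connectotypes(list(wbs), atlas, c("p05", "p03"))
  expect_equal(out$label, "p03")
  expect_equal(out$basis, "earliest-arrival")
})

test_that("adjacent-collapse requires membership in the worst pair", {
  atlas <- chain_atlas(3)
  # worst_s1 = p02 adjoins both candidates, but only p03 sits in the worst
  # size-2 set, so the collapse lands on p03
  wbs <- fake_wbs(list("p02", c("p02", "p03")), subject = "s1",
                  lobe = "chain/left")
  out <- assign_connectotypes(list(wbs), atlas, c("p01", "p03"))
  expect_equal(out$label, "p03")
  expect_equal(out$basis, "adjacent-collapse")
})

test_that("early arrivals cannot sit inside the worst set with the worst parcel", {
  # connectedness: a set of size <= hop(worst_s1, candidate) cannot contain
  # both endpoints; verified on a planted-epicenter synthetic cohort
  atlas <- recovery_atlas()
  lobe <- "lobeA/left"
  sets <- recovery_sets(atlas)
  cfg <- cohort_config(atlas, n_subjects = 6, total_streamlines = 5e4,
                       seed = 31)
  cohort <- generate_cohort(cfg)
  cands <- lobe_parcels(atlas, lobe)[c(1, 5)]
  for (cn in cohort$connectomes) {
    wbs <- worst_by_size(percolation_sweep(cn, sets))
    for (cd in cands) {
      ev <- epicenter_evidence(wbs, atlas, cd)
      if (isTRUE(ev$early)) {
        members <- strsplit(wbs$parcels[wbs$size == ev$s_r], ",")[[1]]
        h <- hop_distance(atlas, lobe, ev$worst_s1, cd)
        expect_true(!(ev$worst_s1 %in% members) || length(members) > h)
      }
      if (!is.na(ev$s_r)) expect_gte(ev$s_r, 1L)
    }
  }
})
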