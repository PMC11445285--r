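# Automated RECIST 1.1, PERCIST and Deauville scoring against hand-derived
# categories, plus ordinal mapping and invariances.

stable_tracks <- function(ids) {
  data.frame(baseline_id = ids, followup_id = ids,
             category = rep("stable", length(ids)),
             pct_change_suv_total = rep(0, length(ids)))
}

test_that("RECIST target selection honours the 5-largest / 2-per-organ rule", {
  les2 <- rbind(lesion_row(1, organ = "organA"), lesion_row(2, organ = "organB"))
  expect_equal(select_recist_targets(les2), c(1L, 2L))

  # 7 lesions, the 3 largest share one organ: 3rd largest skipped, 5 picked
  les7 <- rbind(
    lesion_row(1, organ = "organA", volume_ml = 50),
    lesion_row(2, organ = "organA", volume_ml = 40),
    lesion_row(3, organ = "organA", volume_ml = 30),
    lesion_row(4, organ = "organB", volume_ml = 20),
    lesion_row(5, organ = "organB", volume_ml = 10),
    lesion_row(6, organ = "organC", volume_ml = 5),
    lesion_row(7, organ = "organC", volume_ml = 2))
  expect_equal(select_recist_targets(les7), c(1L, 2L, 4L, 5L, 6L))

  set.seed(77)
  for (rep in 1:15) {
    les <- random_lesion_table(sample(3:9, 1))
    ids <- select_recist_targets(les)
    orc <- oracle_best_volume(les)
    expect_equal(length(ids), orc$size)
    expect_equal(sum(les$volume_ml[match(ids, les$lesion_id)]), orc$volume,
                 tolerance = 1e-12)
  }
})

test_that("RECIST categories reproduce hand-derived responses", {
  bl <- rbind(lesion_row(1, organ = "organA", lad_mm = 30),
              lesion_row(2, organ = "organB", lad_mm = 20))  # target sum 50

  # -40%: PR
  fu <- rbind(lesion_row(1, organ = "organA", lad_mm = 18),
              lesion_row(2, organ = "organB", lad_mm = 12))
  a <- recist_category(bl, stable_tracks(1:2), fu)
  expect_equal(a$category, "PR"); expect_equal(a$ordinal, 2L)

  # +24% and +12 mm: PD
  fu <- rbind(lesion_row(1, organ = "organA", lad_mm = 37),
              lesion_row(2, organ = "organB", lad_mm = 25))
  expect_equal(recist_category(bl, stable_tracks(1:2), fu)$category, "PD")

  # +24% but below the 5 mm absolute gate: SD
  bl_small <- rbind(lesion_row(1, lad_mm = 8), lesion_row(2, organ = "organB", lad_mm = 8))
  fu_small <- rbind(lesion_row(1, lad_mm = 10), lesion_row(2, organ = "organB", lad_mm = 9.8))
  expect_equal(recist_category(bl_small, stable_tracks(1:2), fu_small)$category, "SD")

  # everything disappeared, nothing new: CR, ordinal 1
  tr <- data.frame(baseline_id = 1:2, followup_id = NA_integer_,
                   category = "disappeared", pct_change_suv_total = NA_real_)
  a <- recist_category(bl, tr, empty_lesion_table())
  expect_equal(a$category, "CR"); expect_equal(a$ordinal, 1L)

  # any new lesion forces PD regardless of target shrinkage
  tr_new <- rbind(stable_tracks(1:2),
                  data.frame(baseline_id = NA_integer_, followup_id = 9L,
                             category = "new", pct_change_suv_total = NA_real_))
  fu_new <- rbind(fu, lesion_row(9, organ = "organC", lad_mm = 4))
  expect_equal(recist_category(bl, tr_new, fu_new)$category, "PD")

  # identical scans: SD
  expect_equal(recist_category(bl, stable_tracks(1:2), bl)$category, "SD")

  # no baseline lesions: not evaluable
  a <- recist_category(empty_lesion_table(), stable_tracks(integer(0)),
                       empty_lesion_table())
  expect_true(is.na(a$category)); expect_true(is.na(to_ordinal(a)))
})

test_that("PERCIST categories follow the SUVpeak rule of the hottest-SUVmax lesion", {
  bl <- rbind(lesion_row(1, suv_max = 12, suv_peak = 10),
              lesion_row(2, suv_max = 8, suv_peak = 7))

  fu <- rbind(lesion_row(1, suv_max = 9, suv_peak = 6.5),
              lesion_row(2, suv_max = 5, suv_peak = 4))
  a <- percist_category(bl, fu, stable_tracks(1:2))
  expect_equal(a$category, "PMR")  # 10 -> 6.5 = -35%

  fu <- rbind(lesion_row(1, suv_max = 16, suv_peak = 14),
              lesion_row(2, suv_max = 5, suv_peak = 4))
  expect_equal(percist_category(bl, fu, stable_tracks(1:2))$category, "PMD")  # +40%

  fu <- rbind(lesion_row(1, suv_max = 12, suv_peak = 11),
              lesion_row(2, suv_max = 8, suv_peak = 7))
  expect_equal(percist_category(bl, fu, stable_tracks(1:2))$category, "SMD")  # +10%

  # the follow-up target is re-selected: hottest lesion may differ
  fu_switch <- rbind(lesion_row(1, suv_max = 3, suv_peak = 2),
                     lesion_row(2, suv_max = 13, suv_peak = 6.0))
  a <- percist_category(bl, fu_switch, stable_tracks(1:2))
  expect_equal(a$category, "PMR")  # 10 -> 6.0 on the new hottest lesion

  a <- percist_category(bl, empty_lesion_table(),
                        data.frame(baseline_id = 1:2, followup_id = NA_integer_,
                                   category = "disappeared",
                                   pct_change_suv_total = NA_real_))
  expect_equal(a$category, "CMR"); expect_equal(a$ordinal, 1L)

  a <- percist_category(empty_lesion_table(), empty_lesion_table(),
                        stable_tracks(integer(0)))
  expect_true(is.na(a$category))
})

test_that("Deauville scores follow the five aorta/liver rules", {
  aorta <- 2.0; liver <- 3.0
  mk <- function(sp) lesion_row(1, suv_peak = sp)
  expect_equal(deauville_score(empty_lesion_table(), aorta, liver)$ordinal, 1L)
  expect_equal(deauville_score(mk(1.5), aorta, liver)$ordinal, 2L)
  expect_equal(deauville_score(mk(2.0), aorta, liver)$ordinal, 2L)  # <= aorta
  expect_equal(deauville_score(mk(2.5), aorta, liver)$ordinal, 3L)
  expect_equal(deauville_score(mk(3.0), aorta, liver)$ordinal, 3L)  # <= liver
  expect_equal(deauville_score(mk(5.0), aorta, liver)$ordinal, 4L)
  expect_equal(deauville_score(mk(9.0), aorta, liver)$ordinal, 4L)  # <= 3x liver
  expect_equal(deauville_score(mk(10.0), aorta, liver)$ordinal, 5L)
  expect_error(deauville_score(mk(5), NA, liver), "aorta")
  expect_error(deauville_score(mk(5), aorta, NA), "liver")
})

test_that("Deauville is monotone in SUVpeak and crosses each boundary once", {
  grid <- seq(0.1, 12, by = 0.05)
  scores <- vapply(grid, function(sp)
    deauville_score(lesion_row(1, suv_peak = sp), 2.0, 3.0)$ordinal, integer(1))
  expect_true(all(diff(scores) >= 0))
  expect_equal(sum(diff(scores) != 0), 3)  # boundaries 2->3, 3->4, 4->5
  expect_setequal(unique(scores), 2:5)
})

test_that("reference SUVmeans come from the organ map and flag missing organs", {
  scan <- generate_baseline_scan(profile_nsclc(), rng_seed = 4, n_lesions = 1)
  refs <- reference_suv_means(scan)
  expect_equal(unname(refs["aorta"]), 1.9, tolerance = 0.05)
  expect_equal(unname(refs["liver"]), 2.6, tolerance = 0.05)
  broken <- scan
  broken$organ_labels[broken$organ_labels == broken$organ_codes[["aorta"]]] <- 0L
  expect_error(reference_suv_means(broken), "aorta")
})

test_that("assessments are invariant to lesion relabeling", {
  set.seed(55)
  bl <- random_lesion_table(5); fu <- random_lesion_table(5)
  tr <- stable_tracks(1:5)
  a1 <- recist_category(bl, tr, fu)$category
  p1 <- percist_category(bl, fu, tr)$category
  # relabel ids 1..5 -> 11..15 consistently
  bl2 <- bl; fu2 <- fu; tr2 <- tr
  bl2$lesion_id <- bl$lesion_id + 10L
  fu2$lesion_id <- fu$lesion_id + 10L
  tr2$baseline_id <- tr$baseline_id + 10L
  tr2$followup_id <- tr$followup_id + 10L
  expect_equal(recist_category(bl2, tr2, fu2)$category, a1)
  expect_equal(percist_category(bl2, fu2, tr2)$category, p1)
})

test_that("the 1-5 ordinal map is the documented bijection", {
  expect_equal(petHetero:::to_ordinal_code("PR"), 2L)
  expect_equal(petHetero:::to_ordinal_code("PMD"), 4L)
  expect_equal(petHetero:::to_ordinal_code(c("CR", "SD", "SMD", "CMR")),
               c(1L, 3L, 3L, 1L))
  dv <- deauville_score(lesion_row(1, suv_peak = 5), 2, 3)
  expect_equal(to_ordinal(dv), 4L)
})
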