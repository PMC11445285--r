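# Patient-level feature engineering: whole-patient aggregates, response
# features, heterogeneity features, lesion subsets, and the design matrix.

test_that("a singleton lesion table reproduces the lesion's own values", {
  les <- lesion_row(1, suv_max = 9, suv_peak = 7, volume_ml = 4, suv_mean = 3)
  les$suv_hetero <- 1.2
  g <- patient_single_timepoint_features(les)
  expect_equal(unname(g["global_suv_max"]), 9)
  expect_equal(unname(g["global_suv_peak"]), 7)
  expect_equal(unname(g["global_volume"]), 4)
  expect_equal(unname(g["global_suv_total"]), 12)
  expect_equal(unname(g["global_suv_mean"]), 3)
  expect_equal(unname(g["global_suv_hetero"]), 1.2)
  expect_equal(unname(g["lesion_count"]), 1)
})

test_that("two-lesion aggregates follow forced arithmetic", {
  les <- rbind(lesion_row(1, volume_ml = 2, suv_mean = 2),   # suv_total 4
               lesion_row(2, volume_ml = 3, suv_mean = 3))   # suv_total 9
  g <- patient_single_timepoint_features(les)
  expect_equal(unname(g["global_volume"]), 5)
  expect_equal(unname(g["global_suv_total"]), 13)
  expect_equal(unname(g["global_suv_mean"]), 2.6)
})

test_that("empty lesion tables yield count 0, sums 0 and missing maxima", {
  g <- patient_single_timepoint_features(empty_lesion_table())
  expect_equal(unname(g["lesion_count"]), 0)
  expect_equal(unname(g["global_volume"]), 0)
  expect_equal(unname(g["global_suv_total"]), 0)
  expect_true(is.na(g["global_suv_max"]))
  expect_true(is.na(g["global_suv_mean"]))
})

test_that("pooled global SUVhetero equals the SD of all lesion voxels pooled", {
  scan <- generate_baseline_scan(profile_dlbcl(), rng_seed = 21, n_lesions = 3)
  tab <- quantify_scan(scan)
  g <- patient_single_timepoint_features(tab)
  vox <- scan$pet[scan$lesion_labels > 0L]
  expect_equal(unname(g["global_suv_hetero"]),
               sqrt(mean((vox - mean(vox))^2)), tolerance = 1e-9)
  expect_equal(unname(g["global_suv_mean"]), mean(vox), tolerance = 1e-9)
})

test_that("response features are percent changes with missing-safe denominators", {
  bl <- patient_single_timepoint_features(lesion_row(1, suv_max = 10, volume_ml = 2))
  fu <- patient_single_timepoint_features(lesion_row(1, suv_max = 6, volume_ml = 2))
  r <- patient_response_features(bl, fu)
  expect_equal(unname(r["response_global_suv_max"]), -40)
  r0 <- patient_response_features(bl, bl)
  expect_true(all(r0[startsWith(names(r0), "response_")] == 0))
  # no baseline lesions: responses missing, never infinite
  bl_empty <- patient_single_timepoint_features(empty_lesion_table())
  r_na <- patient_response_features(bl_empty, fu)
  expect_true(is.na(r_na["response_global_volume"]))
  expect_true(all(!is.infinite(r_na), na.rm = TRUE))
  expect_equal(unname(r_na["delta_lesion_count"]), 1)
})

test_that("heterogeneity fractions and counts behave on degenerate mixes", {
  mk_tracks <- function(cats) {
    data.frame(baseline_id = ifelse(cats == "new", NA, seq_along(cats)),
               followup_id = ifelse(cats == "disappeared", NA, seq_along(cats)),
               category = cats)
  }
  les <- do.call(rbind, lapply(1:4, lesion_row))
  h <- heterogeneity_features(mk_tracks(rep("stable", 4)), les, les)
  expect_equal(unname(h["fraction_stable"]), 1)
  expect_equal(unname(h[paste0("fraction_", c("new", "increasing", "decreasing",
                                              "disappeared"))]), rep(0, 4))
  h2 <- heterogeneity_features(mk_tracks(c("new", "new", "disappeared", "disappeared")),
                               les, les)
  expect_equal(unname(h2["fraction_new"]), 0.5)
  expect_equal(unname(h2["fraction_disappeared"]), 0.5)
  expect_true(is.na(h2["max_suv_max_stable"]))  # empty category -> missing aggregate
  expect_equal(unname(h2["count_stable"]), 0)
  # fractions always sum to 1 with tracks present; counts sum to track count
  expect_equal(sum(h2[paste0("fraction_", c("new", "increasing", "stable",
                                            "decreasing", "disappeared"))]), 1)
})

test_that("heterogeneity counts match generator ground truth on a seeded cohort", {
  co <- generate_cohort(profile_nsclc(n_patients = 12), master_seed = 5)
  for (i in seq_len(co$n)) {
    p <- co$patients[[i]]
    h <- heterogeneity_features(p$tracks, p$lesions_bl, p$lesions_fu)
    truth_counts <- table(factor(p$truth$categories_df$category,
                                 levels = c("new", "increasing", "stable",
                                            "decreasing", "disappeared")))
    got <- h[paste0("count_", names(truth_counts))]
    expect_equal(unname(got), as.numeric(truth_counts))
  }
})

test_that("lesion subsets implement the RECIST/PERCIST selection rules", {
  les3 <- do.call(rbind, lapply(1:3, function(i)
    lesion_row(i, organ = c("organA", "organB", "organC")[i])))
  expect_equal(nrow(select_lesion_subset(les3, "five_biggest")), 3)

  les6 <- do.call(rbind, lapply(1:6, function(i)
    lesion_row(i, organ = "organA", volume_ml = 10 - i)))
  top <- select_lesion_subset(les6, "five_biggest")
  expect_equal(top$lesion_id, c(1L, 2L))  # only 2 per organ

  lesH <- rbind(lesion_row(1, suv_peak = 3), lesion_row(2, suv_peak = 9),
                lesion_row(3, suv_peak = 9))
  expect_equal(select_lesion_subset(lesH, "one_hottest")$lesion_id, 2L)  # tie: lowest id

  expect_equal(select_lesion_subset(les6, "all"), les6)
  expect_equal(nrow(select_lesion_subset(empty_lesion_table(), "five_biggest")), 0)
})

test_that("greedy five-biggest equals the exhaustive rule-respecting oracle", {
  set.seed(31)
  for (rep in 1:20) {
    les <- random_lesion_table(sample(4:9, 1))
    sel <- select_lesion_subset(les, "five_biggest")
    expect_true(all(table(sel$organ) <= 2))
    expect_lte(nrow(sel), 5)
    orc <- oracle_best_volume(les)
    expect_equal(nrow(sel), orc$size)
    expect_equal(sum(sel$volume_ml), orc$volume, tolerance = 1e-12)
  }
})

test_that("subset total volume never exceeds the all-lesion total", {
  set.seed(8)
  for (rep in 1:10) {
    les <- random_lesion_table(sample(2:8, 1))
    v_all <- sum(les$volume_ml)
    v_sub <- sum(select_lesion_subset(les, "five_biggest")$volume_ml)
    expect_lte(v_sub, v_all + 1e-12)
    if (nrow(les) <= 5 && all(table(les$organ) <= 2)) expect_equal(v_sub, v_all)
  }
})

test_that("the full feature inventory is the documented closed set", {
  co <- generate_cohort(profile_nsclc(n_patients = 4), master_seed = 2)
  p <- co$patients[[1]]
  v <- petHetero:::patient_feature_row(p$lesions_bl, p$lesions_fu, p$tracks)
  groups <- attr(v, "groups")
  # 5 categories x 5 base features x 2 aggregates + 10 count/fraction = 60
  expect_equal(sum(groups == "Heterogeneity"), 60)
  expect_equal(sum(groups == "BL"), 7)
  expect_equal(sum(groups == "FU"), 7)
  expect_equal(sum(groups == "Response"), 8)
  expect_equal(length(v), 82)
})

test_that("design matrices respect group filters, drop constants, and impute", {
  co <- generate_cohort(profile_nsclc(n_patients = 10), master_seed = 3)
  Xbl <- assemble_design_matrix(co, "all", "BL")
  expect_true(all(startsWith(colnames(Xbl), "bl_")))
  expect_equal(nrow(Xbl), 10)
  expect_false(anyNA(Xbl))

  Xh <- assemble_design_matrix(co, "one_hottest", petHetero:::FEATURE_GROUPS)
  expect_false("bl_lesion_count" %in% colnames(Xh))  # constant 1, dropped
  expect_true("bl_lesion_count" %in% attr(Xh, "dropped_constant"))

  expect_error(assemble_design_matrix(co, "all", "Texture"), "unavailable")
})

test_that("volume partition identities tie heterogeneity sums to the globals", {
  co <- generate_cohort(profile_nsclc(n_patients = 8), master_seed = 13)
  for (i in seq_len(co$n)) {
    p <- co$patients[[i]]
    h <- heterogeneity_features(p$tracks, p$lesions_bl, p$lesions_fu)
    fu_g <- patient_single_timepoint_features(p$lesions_fu)
    s <- h[paste0("sum_volume_ml_", c("new", "increasing", "stable", "decreasing"))]
    expect_equal(sum(s, na.rm = TRUE), unname(fu_g["global_volume"]),
                 tolerance = 1e-9)
  }
})
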