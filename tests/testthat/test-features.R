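test_that("summary statistics follow the linear-interpolation quantile convention", {
  p <- patient_record("A", list(CRP_like = list(times = c(0, 2, 4, 8, 12),
                                                values = c(1, 2, 3, 4, 5))))
  s <- summarize_patient(p, c("CRP_like", "MMP_like"))
  # independent oracle: R's default type-7 quantiles
  expect_equal(s[["CRP_like_median"]], unname(quantile(1:5, 0.5)))
  expect_equal(s[["CRP_like_spread"]],
               unname(quantile(1:5, 0.9) - quantile(1:5, 0.1)))
  expect_equal(s[["CRP_like_median"]], 3)
  expect_equal(s[["CRP_like_spread"]], 3.2)
  expect_true(is.na(s[["MMP_like_median"]]))
  expect_false(attr(s, "available")[["MMP_like"]])
})

test_that("constant series have zero spread and empty records are rejected", {
  p <- patient_record("A", list(CRP_like = list(times = c(0, 4, 8),
                                                values = c(7, 7, 7))))
  s <- summarize_patient(p, "CRP_like")
  expect_equal(s[["CRP_like_median"]], 7)
  expect_equal(s[["CRP_like_spread"]], 0)
  expect_error(summarize_patient(list(series = list()), "CRP_like"), "empty")
})

test_that("K available biomarkers give a 2K-dimensional dense representation", {
  bms <- sprintf("BM%02d", 1:16)
  series <- lapply(stats::setNames(bms, bms),
                   function(b) list(times = c(0, 12, 24), values = c(3, 2, 1)))
  s <- summarize_patient(patient_record("A", series), bms)
  expect_length(unclass(s), 32)
  expect_true(all(!is.na(unclass(s))))
})

test_that("normalizer centers each feature at 0 with robust scale", {
  spec <- test_spec()
  ch <- generate_cohort(30, spec, seed = 3)
  raws <- lapply(ch$patients, summarize_patient,
                 biomarker_names = spec$biomarker_names)
  nrm <- fit_normalizer(raws)
  normed <- do.call(rbind, lapply(raws, function(s)
    unclass(normalize_summary(s, nrm))))
  meds <- apply(normed, 2, stats::median, na.rm = TRUE)
  expect_true(all(abs(meds) < 1e-10))
  # round trip
  back <- denormalize_summary(normalize_summary(raws[[1]], nrm), nrm)
  expect_equal(unclass(back), unclass(raws[[1]]), tolerance = 1e-12)
})

test_that("zero-dispersion features fall back to scale 1", {
  s1 <- make_patient("A")
  raws <- list(summarize_patient(s1, c("CRP_like", "SCORE_like")),
               summarize_patient(s1, c("CRP_like", "SCORE_like")))
  nrm <- fit_normalizer(raws)
  expect_true(all(nrm$scale == 1))
  # location of a two-patient feature set is the midpoint
  p2 <- patient_record("B", list(
    CRP_like = list(times = c(0, 4, 12, 24), values = c(50, 40, 30, 25)),
    SCORE_like = list(times = c(0, 12, 24), values = c(9, 7, 6))))
  nrm2 <- fit_normalizer(list(summarize_patient(s1, c("CRP_like", "SCORE_like")),
                              summarize_patient(p2, c("CRP_like", "SCORE_like"))))
  expect_equal(unname(nrm2$location[["CRP_like_median"]]),
               stats::median(c(stats::median(c(40, 30, 20, 15)),
                               stats::median(c(50, 40, 30, 25)))))
})

test_that("distance matches hand-computed values and overlap normalization", {
  bms <- c("A", "B")
  mk <- function(med_a, spr_a, med_b = NA, spr_b = NA) {
    feats <- c(A_median = med_a, A_spread = spr_a,
               B_median = med_b, B_spread = spr_b)
    vpsbi:::new_summary(feats, c(A = !is.na(med_a), B = !is.na(med_b)),
                        normalized = TRUE)
  }
  # |CB| = 1, delta median 1: sqrt(3/2)
  expect_equal(summary_distance(mk(1, 0), mk(0, 0)), sqrt(1.5))
  # |CB| = 2, each biomarker contributes 1: unchanged by the 1/|CB| scaling
  expect_equal(summary_distance(mk(1, 0, 1, 0), mk(0, 0, 0, 0)), sqrt(1.5))
  # identity and incomparability
  expect_equal(summary_distance(mk(1, 2), mk(1, 2)), 0)
  expect_identical(summary_distance(mk(1, 0), mk(NA, NA, 1, 0)), Inf)
})

test_that("distance is a symmetric missing-data-aware semimetric (oracle check)", {
  bms <- sprintf("BM%d", 1:5)
  set.seed(42)
  for (k in 1:100) {
    a <- random_summary(bms)
    b <- random_summary(bms)
    d <- summary_distance(a, b)
    expect_identical(d, summary_distance(b, a))
    expect_equal(d, distance_oracle(a, b), tolerance = 1e-12)
    if (is.finite(d)) expect_gte(d, 0)
    expect_equal(summary_distance(a, a), 0)
  }
})

test_that("distance depends only on the common biomarkers", {
  bms <- c("A", "B", "C")
  set.seed(7)
  a <- random_summary(bms, p_missing = 0)
  b <- random_summary(bms, p_missing = 0)
  # knock biomarker C out of b; distance must equal the A,B-restricted one
  avail_b <- attr(b, "available"); avail_b[["C"]] <- TRUE
  b_full <- b
  avail_drop <- attr(b, "available"); avail_drop[["C"]] <- FALSE
  b_drop <- vpsbi:::new_summary(unclass(b), avail_drop, normalized = TRUE)
  # restriction oracle: recompute on the two shared biomarkers only
  a_ab <- vpsbi:::new_summary(unclass(a), c(A = TRUE, B = TRUE, C = FALSE),
                              normalized = TRUE)
  expect_equal(summary_distance(a, b_drop), summary_distance(a_ab, b_drop))
  # and changing the masked values must not matter
  feats <- unclass(b_drop)
  feats[c("C_median", "C_spread")] <- 99
  b_tweaked <- vpsbi:::new_summary(feats, avail_drop, normalized = TRUE)
  expect_equal(summary_distance(a, b_drop), summary_distance(a, b_tweaked))
})

test_that("nearest neighbour is the brute-force argmin with lexicographic ties", {
  bms <- c("A", "B")
  mk <- function(med) vpsbi:::new_summary(
    c(A_median = med, A_spread = 0, B_median = 0, B_spread = 0),
    c(A = TRUE, B = TRUE), normalized = TRUE)
  container <- structure(list(entries = list(
    reference = list(summary = mk(1.2), theta = NULL, loss = NA),
    P002 = list(summary = mk(0.4), theta = NULL, loss = 0.1),
    P001 = list(summary = mk(0.9), theta = NULL, loss = 0.2)),
    reference_id = "reference"), class = "vp_container")
  q <- mk(0)
  d <- vapply(container$entries, function(e) summary_distance(q, e$summary),
              numeric(1))
  expect_identical(nearest_entry(q, container), names(which.min(d)))
  expect_identical(nearest_entry(q, container), "P002")
  # tie between P001 and a duplicate sorts lexicographically
  container$entries$P000 <- container$entries$P001
  expect_identical(nearest_entry(mk(0.9), container), "P000")
  # all incomparable falls back to the reference
  q2 <- vpsbi:::new_summary(c(A_median = 0, A_spread = 0,
                              B_median = NA, B_spread = NA),
                            c(A = FALSE, B = FALSE), normalized = TRUE)
  expect_identical(nearest_entry(q2, container), "reference")
})
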