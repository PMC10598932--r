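test_that("normalized AUC matches hand trapezoids and identities", {
  expect_equal(normalized_auc(c(100, 100, 100)), 1)
  expect_equal(normalized_auc(c(0, 0, 0)), 0)
  # Trapezoids: (100+50)/2 + (50+0)/2 = 100 over x-range 2, full 100.
  expect_equal(normalized_auc(c(100, 50, 0)), 0.5)
  # Non-uniform x changes the weighting.
  expect_equal(normalized_auc(c(100, 50, 0), x = c(0, 3, 4)),
               (3 * 75 + 1 * 25) / 400)
  expect_error(normalized_auc(c(100, NA, 0)), "unavailable")
  expect_error(normalized_auc(c(100, -1, 0)), "non-negative")
  expect_error(normalized_auc(50), "at least two")
})

test_that("score components follow their defining ratios", {
  cfg <- scoring_config()
  # A PDO identical to the cohort average scores exactly 1.
  expect_equal(auc_score(c(90, 55, 10), c(90, 55, 10)), 1)
  # Cohort AUC 0.8 vs PDO AUC 0.4 -> ratio 2.
  expect_equal(auc_score(c(40, 40, 40), c(80, 80, 80)), 2)
  # Total-kill profile is floored, not infinite: 0.8 / 0.01.
  expect_equal(auc_score(c(0, 0, 0), c(80, 80, 80)), 80)

  expect_equal(sensitivity_score(c(100, 100, 100)), 0)
  expect_equal(sensitivity_score(c(0, 0, 0)), 1)
  expect_equal(sensitivity_score(c(100, 50, 0)), 0.5)
  # Growth stimulation gives a negative sensitivity score, never an error.
  expect_lt(sensitivity_score(c(120, 110, 110)), 0)

  fs <- final_score(c(90, 55, 10), c(90, 55, 10), config = cfg)
  expect_identical(fs$final_score, fs$auc_score + fs$sensitivity_score)
  # Hit rule is strict: a final score exactly at the threshold is no hit.
  at <- scoring_config(hit_threshold = fs$final_score)
  expect_false(final_score(c(90, 55, 10), c(90, 55, 10), config = at)$hit)
  expect_true(final_score(c(89, 55, 10), c(90, 55, 10), config = at)$hit)
})

test_that("scores are scale-free in the viability units", {
  v <- c(84, 47, 12); ref <- c(90, 60, 30)
  expect_equal(auc_score(v / 100, ref / 100, full = 1), auc_score(v, ref))
  expect_equal(sensitivity_score(v / 100, full = 1), sensitivity_score(v))
})

test_that("cohort scoring is symmetric, order-invariant and floor-guarded", {
  panel <- mini_panel()
  prof <- toy_profiles(data.frame(
    pdo = c("A", "B", "A", "B"),
    drug = c("5FU", "5FU", "Oxaliplatin", "Oxaliplatin"),
    v1 = c(90, 90, 100, 60), v2 = c(55, 55, 80, 40),
    v3 = c(10, 10, 60, 20), stringsAsFactors = FALSE))
  sm <- score_cohort(prof, panel)
  # Identical profiles share the cohort average, so both score AUC 1.
  expect_equal(unname(sm$auc_score[, "5FU"]), c(1, 1))
  expect_identical(sm$final_score, sm$auc_score + sm$sensitivity_score)

  # Permuting the input rows changes nothing.
  sm2 <- score_cohort(prof[sample(nrow(prof)), ], panel)
  expect_equal(sm2$final_score, sm$final_score)

  # A drug with one available profile stays missing, with a warning.
  prof$available[prof$pdo == "B" & prof$drug == "Oxaliplatin"] <- FALSE
  expect_warning(sm3 <- score_cohort(prof, panel), "fewer than 2")
  expect_true(all(is.na(sm3$final_score[, "Oxaliplatin"])))
  expect_false(anyNA(sm3$final_score[, "5FU"]))
})

test_that("pointwise-lower viability never lowers any score", {
  set.seed(202)
  cfg <- scoring_config()
  for (i in 1:50) {
    ref <- stats::runif(3, 10, 100)
    v <- stats::runif(3, 1, 110)
    drop <- stats::runif(3, 0, v)     # pointwise lower
    hi <- final_score(v, ref, config = cfg)
    lo <- final_score(v - drop, ref, config = cfg)
    expect_gte(lo$auc_score, hi$auc_score)
    expect_gte(lo$sensitivity_score, hi$sensitivity_score)
    expect_gte(lo$final_score, hi$final_score)
  }
})

test_that("trapezoid linearity: AUC of the mean curve = mean of AUCs", {
  set.seed(303)
  for (i in 1:200) {
    n <- sample(2:30, 1)
    v <- matrix(stats::runif(3 * n, 0, 120), n, 3)
    expect_equal(normalized_auc(colMeans(v)),
                 mean(apply(v, 1, normalized_auc)),
                 tolerance = 1e-12)
  }
})

test_that("mean over PDOs of the AUC score is at least 1 (AM-HM)", {
  panel <- mini_panel("Gemcitabine")
  set.seed(404)
  for (i in 1:25) {
    n <- sample(3:15, 1)
    prof <- toy_profiles(data.frame(
      pdo = sprintf("P%02d", 1:n), drug = "Gemcitabine",
      v1 = stats::runif(n, 20, 110), v2 = stats::runif(n, 10, 100),
      v3 = stats::runif(n, 5, 90), stringsAsFactors = FALSE))
    sm <- score_cohort(prof, panel)
    expect_gte(mean(sm$auc_score[, "Gemcitabine"]), 1 - 1e-12)
  }
  # Equality holds exactly when every PDO has the same AUC.
  prof <- toy_profiles(data.frame(pdo = c("A", "B"), drug = "Gemcitabine",
                                  v1 = c(90, 90), v2 = c(50, 50),
                                  v3 = c(10, 10)))
  expect_equal(mean(score_cohort(prof, panel)$auc_score[, "Gemcitabine"]), 1)
})

test_that("index spacing and log10M spacing agree on the packaged panel", {
  panel <- default_panel()
  prof <- random_profiles(6, panel$drug, seed = 99)
  sm_idx <- score_cohort(prof, panel, scoring_config(spacing = "index"))
  sm_log <- score_cohort(prof, panel, scoring_config(spacing = "log10M"))
  expect_equal(sm_log$final_score, sm_idx$final_score, tolerance = 1e-12)
  expect_equal(sm_log$auc_score, sm_idx$auc_score, tolerance = 1e-12)
})

test_that("cohort quartile threshold uses linear interpolation", {
  expect_equal(hit_threshold_from_cohort(c(1, 2, 3, 4)), 3.25)
  expect_equal(hit_threshold_from_cohort(rep(2.7, 10)), 2.7)
  # Near-constant set: the quartile sits at the constant.
  expect_equal(hit_threshold_from_cohort(c(rep(1.9, 100), 5)), 1.9)
  expect_error(hit_threshold_from_cohort(c(1, 2, 3)), "at least 4")
  # From a matrix, NAs are ignored.
  m <- matrix(c(1, 2, 3, 4, NA, NA), 2, 3)
  expect_equal(hit_threshold_from_cohort(m), 3.25)
})

test_that("cohort_q3 mode derives the threshold from the scored matrix", {
  panel <- mini_panel()
  prof <- random_profiles(8, panel$drug, seed = 7)
  sm <- score_cohort(prof, panel,
                     scoring_config(threshold_mode = "cohort_q3"))
  expect_equal(sm$threshold, hit_threshold_from_cohort(sm$final_score))
  expect_identical(sm$hit, sm$final_score > sm$threshold)
})

test_that("leave-one-out reference excludes the scored PDO", {
  panel <- mini_panel("5FU")
  prof <- toy_profiles(data.frame(pdo = c("A", "B", "C"), drug = "5FU",
                                  v1 = c(90, 80, 70), v2 = c(60, 50, 40),
                                  v3 = c(30, 20, 10)))
  sm <- score_cohort(prof, panel, leave_one_out = TRUE)
  # Oracle: score each PDO against the mean curve of the other two.
  for (i in 1:3) {
    others <- as.matrix(prof[-i, c("v_low", "v_medium", "v_high")])
    expected <- auc_score(as.numeric(prof[i, c("v_low", "v_medium",
                                               "v_high")]),
                          colMeans(others))
    expect_equal(unname(sm$auc_score[prof$pdo[i], "5FU"]), expected)
  }
})

test_that("score matrices round-trip through CSV", {
  panel <- mini_panel()
  prof <- random_profiles(4, panel$drug, seed = 5)
  prof$available[2] <- FALSE
  prof[2, c("v_low", "v_medium", "v_high")] <- NA
  sm <- suppressWarnings(score_cohort(prof, panel))
  df <- as.data.frame(sm)
  expect_equal(nrow(df), 12)   # every cell, present or missing

  f <- tempfile(fileext = ".csv")
  write_score_matrix(sm, f)
  back <- read_score_matrix(f)
  expect_equal(back$final_score, sm$final_score, tolerance = 1e-12)
  expect_equal(back$auc_score, sm$auc_score, tolerance = 1e-12)
  expect_equal(back$sensitivity_score, sm$sensitivity_score,
               tolerance = 1e-12)
  expect_identical(back$hit, sm$hit)
  # Missing entry stays an empty field in the file.
  raw <- readLines(f)
  expect_true(any(grepl(",,,,$|,,,$", raw)))
})
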