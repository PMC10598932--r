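score_matrix_from <- function(m, threshold = 1.9) {
  structure(list(pdo_ids = rownames(m), drugs = colnames(m),
                 auc_score = m, sensitivity_score = m * 0,
                 final_score = m, hit = m > threshold,
                 threshold = threshold, config = scoring_config()),
            class = "score_matrix")
}

test_that("heterogeneity is the sample SD of present scores", {
  m <- cbind(A = c(1, 2, 3), B = c(2, 2, 2), C = c(1, 5, NA))
  rownames(m) <- paste0("P", 1:3)
  sm <- score_matrix_from(m)
  h <- heterogeneity_score(sm)
  expect_equal(unname(h["A"]), 1)          # sd({1,2,3}) with n-1
  expect_equal(unname(h["B"]), 0)
  expect_equal(unname(h["C"]), stats::sd(c(1, 5)))
  # Translation invariance.
  expect_equal(heterogeneity_score(score_matrix_from(m + 10)), h)
  # A drug with one present score yields NA with a warning.
  m2 <- cbind(m, D = c(4, NA, NA))
  expect_warning(h2 <- heterogeneity_score(score_matrix_from(m2)),
                 "fewer than 2")
  expect_true(is.na(h2["D"]))
})

test_that("drug correlations are pairwise-complete, symmetric, unit-diagonal", {
  set.seed(21)
  m <- matrix(stats::runif(60, 0, 3), 10, 6,
              dimnames = list(paste0("P", 1:10), paste0("D", 1:6)))
  m[sample(length(m), 8)] <- NA
  dc <- suppressWarnings(drug_correlation(score_matrix_from(m)))
  expect_equal(dc$r, t(dc$r))
  expect_equal(unname(diag(dc$r)), rep(1, 6))
  expect_true(all(abs(dc$r) <= 1 + 1e-12, na.rm = TRUE))
  expect_equal(unname(dc$pair_n["D1", "D2"]),
               sum(!is.na(m[, "D1"]) & !is.na(m[, "D2"])))
  expect_s3_class(dc$linkage, "hclust")
  expect_setequal(dc$order, 1:6)

  # Exact negatives about their means correlate at -1.
  m2 <- cbind(A = c(1, 2, 3, 4), B = c(4, 3, 2, 1), C = c(1, 3, 2, 4))
  rownames(m2) <- paste0("P", 1:4)
  dc2 <- drug_correlation(score_matrix_from(m2))
  expect_equal(unname(dc2$r["A", "B"]), -1)
  expect_equal(unname(dc2$r["A", "A"]), 1)

  # Constant score vector: undefined r, recorded missing with a warning.
  m3 <- cbind(A = c(1, 2, 3, 4), B = rep(2, 4))
  rownames(m3) <- paste0("P", 1:4)
  expect_warning(dc3 <- drug_correlation(score_matrix_from(m3)),
                 "undefined")
  expect_true(is.na(dc3$r["A", "B"]))

  # Pairs below the complete-pair minimum are masked.
  m4 <- cbind(A = c(1, 2, NA, NA), B = c(2, 1, 3, 4), C = c(1, 3, 2, 5))
  rownames(m4) <- paste0("P", 1:4)
  expect_warning(dc4 <- drug_correlation(score_matrix_from(m4)), "undefined")
  expect_true(is.na(dc4$r["A", "B"]))
  expect_false(is.na(dc4$r["B", "C"]))
})

test_that("drugs sharing a latent sensitivity axis correlate strongly", {
  set.seed(33)
  latent <- stats::rnorm(25)
  m <- cbind(D1 = 1.5 + 0.5 * latent + stats::rnorm(25, 0, 0.1),
             D2 = 1.4 + 0.5 * latent + stats::rnorm(25, 0, 0.1),
             D3 = stats::rnorm(25, 1.5, 0.5))
  rownames(m) <- sprintf("P%02d", 1:25)
  dc <- drug_correlation(score_matrix_from(m))
  expect_gt(dc$r["D1", "D2"], 0.8)
  # The correlated pair clusters together: it is the first merge.
  expect_setequal(-dc$linkage$merge[1, ],
                  which(colnames(m) %in% c("D1", "D2")))
})

test_that("hit counting per PDO is monotone in the threshold", {
  m <- rbind(P1 = c(2.5, 1.2, 3.0), P2 = c(0.4, NA, 1.0))
  colnames(m) <- paste0("D", 1:3)
  expect_equal(hits_per_pdo(score_matrix_from(m, threshold = 1.9)),
               c(P1 = 2L, P2 = 0L))
  expect_equal(hits_per_pdo(score_matrix_from(m, threshold = 0.1)),
               c(P1 = 3L, P2 = 2L))   # missing pairs contribute 0
  expect_equal(hits_per_pdo(score_matrix_from(m, threshold = 10)),
               c(P1 = 0L, P2 = 0L))
  thresholds <- sort(stats::runif(10, 0, 4))
  counts <- vapply(thresholds,
                   function(t) sum(hits_per_pdo(score_matrix_from(m, t))),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("hand-rolled Welch test matches the reference implementation", {
  set.seed(55)
  for (i in 1:100) {
    x <- stats::rnorm(sample(2:12, 1), mean = stats::runif(1, -2, 2),
                      sd = stats::runif(1, 0.2, 3))
    y <- stats::rnorm(sample(2:12, 1), mean = stats::runif(1, -2, 2),
                      sd = stats::runif(1, 0.2, 3))
    w <- welch_t(x, y)
    ref <- stats::t.test(x, y, var.equal = FALSE)
    expect_equal(w$t_statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("group comparison handles edge and symmetry cases", {
  # Identical groups: t = 0, p = 1 (even with zero variance).
  g <- compare_groups(c(5, 5, 5, 5, 5, 5), rep(c("a", "b"), each = 3))
  expect_equal(g$t_statistic, 0)
  expect_equal(g$p_value, 1)

  g2 <- compare_groups(c(0, 0, 0, 0, 10, 10, 10, 11),
                       rep(c("lo", "hi"), each = 4))
  expect_lt(g2$p_value, 0.01)

  # Swapping labels negates t, keeps p.
  vals <- c(1, 3, 2, 8, 9, 7)
  lab <- rep(c("a", "b"), each = 3)
  ga <- compare_groups(vals, lab)
  gb <- compare_groups(vals, rev(lab))
  expect_equal(gb$t_statistic, -ga$t_statistic)
  expect_equal(gb$p_value, ga$p_value)

  expect_error(compare_groups(c(1, 2, 3), c("a", "a", "b")), "at least 2")
  expect_error(compare_groups(1:4, rep("a", 4)), "exactly two groups")
})
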