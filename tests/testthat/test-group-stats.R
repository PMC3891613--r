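cvrow <- function(amp, ang, excluded = FALSE) {
  data.frame(amplitude_cm_s = amp, angle_rad = ang, excluded = excluded,
             stringsAsFactors = FALSE)
}

test_that("vector averaging obeys Cartesian component arithmetic", {
  one <- average_contraction(cvrow(7.3, 0.4))
  expect_equal(one$amplitude_cm_s, 7.3)
  expect_equal(one$angle_rad, 0.4)

  opp <- average_contraction(rbind(cvrow(10, 0), cvrow(10, pi)))
  expect_true(opp$excluded)
  expect_equal(opp$reason, "degenerate-cancellation")

  ortho <- average_contraction(rbind(cvrow(10, 0), cvrow(10, pi / 2)))
  expect_equal(ortho$amplitude_cm_s, 10 / sqrt(2), tolerance = 1e-12)
  expect_equal(ortho$angle_rad, pi / 4, tolerance = 1e-12)
  expect_equal(ortho$amp_scalar_cm_s, 10)
})

test_that("averaging ignores excluded vectors and is permutation invariant", {
  set.seed(1)
  rows <- do.call(rbind, lapply(1:6, function(i)
    cvrow(runif(1, 4, 12), runif(1, -pi, pi))))
  rows <- rbind(rows, cvrow(55, 0.1, excluded = TRUE))
  a <- average_patient(rows)
  b <- average_patient(rows[sample(nrow(rows)), ])
  expect_equal(a, b)
  expect_equal(a$n_used, 6)
  expect_message(expect_null(average_contraction(cvrow(9, 0, excluded = TRUE))))
})

test_that("duplicating windows of one contraction leaves the patient mean unchanged", {
  set.seed(2)
  w <- data.frame(patient_id = "P1",
                  contraction_id = rep(1:3, each = 4),
                  amplitude_cm_s = runif(12, 5, 10),
                  angle_rad = runif(12, -pi, pi),
                  excluded = FALSE, stringsAsFactors = FALSE)
  pts <- data.frame(patient_id = "P1", hours_to_delivery = 6)
  base <- build_patient_records(w, pts)
  dup <- build_patient_records(rbind(w, w[w$contraction_id == 2, ]), pts)
  expect_equal(base$cv_cm_s, dup$cv_cm_s, tolerance = 1e-12)
  expect_equal(base$group, "labor")
})

test_that("Levene's statistic matches the hand-computed closed form", {
  # groups {1,2,3,4} and {2,4,6,8}: F = (2/1)/(5/6) = 2.4 on (1, 6) df
  lev <- levene_test(c(1, 2, 3, 4, 2, 4, 6, 8), rep(c("a", "b"), each = 4))
  expect_equal(lev$statistic, 2.4, tolerance = 1e-12)
  expect_equal(lev$df, c(1, 6))
  expect_equal(lev$p_value, pf(2.4, 1, 6, lower.tail = FALSE))
})

test_that("the t statistic matches the pooled-variance closed form on 3 vs 3", {
  pts <- data.frame(patient_id = sprintf("P%d", 1:6),
                    group = rep(c("labor", "nonlabor"), each = 3),
                    cv_cm_s = c(1, 2, 3, 4, 5, 6),
                    stringsAsFactors = FALSE)
  cmp <- compare_groups(pts)
  # t = (2 - 5) / sqrt(s_p^2 (1/3 + 1/3)), s_p^2 = 1  ->  -3.674235
  expect_equal(cmp$t_statistic, -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(cmp$ttest_p, 2 * pt(-3 / sqrt(2 / 3), df = 4), tolerance = 1e-10)
  expect_true(cmp$significant)
  expect_equal(cmp$labor_mean_cm_s, 2)
  expect_equal(cmp$nonlabor_sd_cm_s, 1)
})

test_that("identical groups are not significant and ordering does not matter", {
  pts <- data.frame(patient_id = sprintf("P%d", 1:8),
                    group = rep(c("labor", "nonlabor"), each = 4),
                    cv_cm_s = c(5, 6, 7, 8, 5, 6, 7, 8),
                    stringsAsFactors = FALSE)
  cmp <- compare_groups(pts)
  expect_equal(cmp$ttest_p, 1)
  expect_false(cmp$significant)
  shuf <- compare_groups(pts[sample(8), ])
  expect_equal(shuf$ttest_p, cmp$ttest_p)
  # label swap flips only the sign of t
  flipped <- pts
  flipped$group <- ifelse(pts$group == "labor", "nonlabor", "labor")
  pts2 <- pts; pts2$cv_cm_s <- c(5, 6, 7, 8, 9, 10, 11, 12)
  flipped2 <- pts2
  flipped2$group <- ifelse(pts2$group == "labor", "nonlabor", "labor")
  expect_equal(compare_groups(flipped2)$t_statistic,
               -compare_groups(pts2)$t_statistic)
  expect_equal(compare_groups(flipped2)$ttest_p, compare_groups(pts2)$ttest_p)
})

test_that("undersized groups are rejected and p-values are proper", {
  pts <- data.frame(patient_id = c("a", "b", "c"),
                    group = c("labor", "nonlabor", "nonlabor"),
                    cv_cm_s = c(8, 5, 6), stringsAsFactors = FALSE)
  expect_error(compare_groups(pts), class = "ehgcv_invalid_argument")
  set.seed(10)
  pts2 <- data.frame(patient_id = sprintf("P%d", 1:12),
                     group = rep(c("labor", "nonlabor"), each = 6),
                     cv_cm_s = c(rnorm(6, 8.65, 1.9), rnorm(6, 5.3, 1.47)),
                     stringsAsFactors = FALSE)
  cmp <- compare_groups(pts2)
  expect_true(all(c(cmp$shapiro_p, cmp$levene_p, cmp$ttest_p) >= 0))
  expect_true(all(c(cmp$shapiro_p, cmp$levene_p, cmp$ttest_p) <= 1))
})
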