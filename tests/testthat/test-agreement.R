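test_that("Bland-Altman reproduces hand-computed values", {
  x <- c(1, 5, 2); y <- c(3, 3, 5)      # diffs -2, 2, -3
  ba <- bland_altman(x, y)
  expect_equal(ba$bias, -1)
  expect_equal(ba$sd_diff, sqrt(7), tolerance = 1e-12)  # 2.6458
  expect_equal(ba$loa_low, -1 - 1.96 * sqrt(7), tolerance = 1e-12)
  expect_equal(ba$loa_high, -1 + 1.96 * sqrt(7), tolerance = 1e-12)
  expect_true(ba$ci_bias[1] <= ba$bias && ba$bias <= ba$ci_bias[2])
  # identical methods
  same <- bland_altman(x, x)
  expect_equal(same$bias, 0); expect_equal(same$sd_diff, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))
  # constant shift: bias -c, zero-width limits
  shifted <- bland_altman(x, x + 2)
  expect_equal(shifted$bias, -2)
  expect_equal(shifted$loa_high - shifted$loa_low, 0)
  expect_error(bland_altman(1:2, 2:3), "at least 3")
})

test_that("Bland-Altman limits cover ~95% of Gaussian differences", {
  set.seed(12)
  x <- stats::rnorm(5000); y <- x + stats::rnorm(5000, 0.2, 1)
  ba <- bland_altman(x, y)
  d <- x - y
  cover <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_gt(cover, 0.94); expect_lt(cover, 0.96)
})

test_that("Bland-Altman subsets stratify on the pair mean", {
  x <- c(10, 20, 30, 40, 50, 60); y <- x + c(1, -1, 2, -2, 1, -1)
  ba_low <- bland_altman(x, y, subset = function(m) m <= 35)
  expect_equal(ba_low$n, 3)
})

test_that("paired agreement matches the textbook formulas", {
  x <- c(2.1, 3.4, 1.9, 5.6, 4.4); y <- c(2.0, 3.9, 2.4, 5.1, 4.9)
  pa <- paired_agreement(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pa$pearson_r, r_hand, tolerance = 1e-12)
  d <- x - y
  t_hand <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  expect_equal(pa$t_statistic, t_hand, tolerance = 1e-12)
  p_hand <- 2 * stats::pt(-abs(t_hand), length(d) - 1)
  expect_equal(pa$t_p, p_hand, tolerance = 1e-12)
  # identities and sign properties
  same <- paired_agreement(x, x)
  expect_equal(same$pearson_r, 1); expect_equal(same$t_p, 1)
  z <- x - mean(x)
  expect_equal(paired_agreement(z, -z)$pearson_r, -1)
  expect_error(paired_agreement(rep(1, 5), x), "zero variance")
})

test_that("McNemar reproduces the published p-values from printed counts", {
  m1 <- mcnemar_test(18, 22)
  expect_equal(m1$statistic, 0.225)
  expect_equal(round(m1$p, 3), 0.635)
  m2 <- mcnemar_test(14, 30)
  expect_equal(m2$statistic, (abs(14 - 30) - 1)^2 / 44, tolerance = 1e-12)
  expect_equal(round(m2$p, 3), 0.024)
  # exact method: symmetric discordance -> p = 1
  expect_equal(mcnemar_test(7, 7, method = "exact")$p, 1)
  expect_equal(mcnemar_test(0, 0)$p, 1)
})

test_that("concordance reproduces the published agreement rates", {
  t1 <- concordance_counts(241, 44, 18, 22)
  expect_equal(round(100 * t1$concordance, 1), 87.7)
  expect_equal(round(100 * unname(t1$proportions), 1),
               c(74.2, 13.5, 5.5, 6.8))
  expect_equal(round(t1$mcnemar$p, 3), 0.635)
  t2 <- concordance_counts(233, 48, 14, 30)
  expect_equal(round(100 * t2$concordance, 1), 86.5)
  expect_equal(round(t2$mcnemar$p, 3), 0.024)
  # vector interface agrees with count interface
  ref <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  tst <- c(TRUE, FALSE, FALSE, TRUE, TRUE)
  ct <- concordance(ref, tst)
  expect_equal(unname(ct$counts), c(1, 2, 1, 1))
  expect_equal(concordance(ref, ref)$concordance, 1)
  expect_error(concordance(logical(0), logical(0)), "empty")
})

test_that("ICC matches an independent ANOVA mean-squares oracle", {
  ratings <- matrix(c(9, 2, 5, 8,
                      6, 1, 3, 2,
                      8, 4, 6, 8), 4, 3)
  long <- data.frame(y = as.vector(ratings),
                     subj = factor(rep(1:4, 3)),
                     rater = factor(rep(1:3, each = 4)))
  ms <- anova(stats::lm(y ~ subj + rater, data = long))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 4; k <- 3
  icc21 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  icc2k <- (msr - mse) / (msr + (msc - mse) / n)
  expect_equal(icc(ratings, "single"), icc21, tolerance = 1e-10)
  expect_equal(icc(ratings, "average"), icc2k, tolerance = 1e-10)
})

test_that("ICC behaves at the boundaries", {
  base <- c(1, 5, 9, 3, 7)
  expect_equal(icc(cbind(base, base), "single"), 1)
  set.seed(9)
  noise <- cbind(stats::rnorm(1000), stats::rnorm(1000))
  expect_lt(abs(icc(noise, "single")), 0.1)
  expect_error(icc(cbind(c(1, NA, 3), c(2, 2, 2))), "missing cells")
  expect_error(icc(matrix(1:4, 2, 2)), "at least 3 subjects")
  expect_error(icc(matrix(1:4, 4, 1)), "at least 2 raters")
})

test_that("Dice and Hausdorff match brute force and their identities", {
  a <- matrix(FALSE, 12, 12); a[3:7, 3:7] <- TRUE
  b <- matrix(FALSE, 12, 12); b[4:8, 3:7] <- TRUE  # offset by one row
  ca <- contour_agreement(a, b, spacing_mm = 1.17)
  expect_equal(ca$hausdorff_mm, 1.17, tolerance = 1e-12)
  expect_equal(ca$hausdorff_mm, hausdorff_bruteforce(a, b, 1.17),
               tolerance = 1e-12)
  expect_equal(ca$dice, 2 * 20 / 50)
  # identities and symmetry
  self <- contour_agreement(a, a, 2)
  expect_equal(self$dice, 1); expect_equal(self$hausdorff_mm, 0)
  ba <- contour_agreement(b, a, 1.17)
  expect_equal(ba$dice, ca$dice); expect_equal(ba$hausdorff_mm,
                                               ca$hausdorff_mm)
  set.seed(4)
  for (i in 1:10) {
    m1 <- random_mask(9, 9, 0.4); m2 <- random_mask(9, 9, 0.4)
    if (!any(m1) || !any(m2)) next
    expect_equal(contour_agreement(m1, m2, 1)$hausdorff_mm,
                 hausdorff_bruteforce(m1, m2, 1), tolerance = 1e-12)
  }
  # disjoint and empty cases
  disj <- matrix(FALSE, 12, 12); disj[10:11, 10:11] <- TRUE
  expect_equal(contour_agreement(a, disj)$dice, 0)
  empty <- matrix(FALSE, 12, 12)
  expect_error(contour_agreement(empty, empty), "both masks")
  expect_warning(one <- contour_agreement(a, empty), "one mask")
  expect_equal(one$dice, 0); expect_true(is.na(one$hausdorff_mm))
})

test_that("agreement report has the Table-2 layout and degenerate limits", {
  set.seed(15)
  n <- 24
  truth <- stats::runif(n, 0.18, 0.40)
  results <- data.frame(
    subject_id = sprintf("S%02d", 1:n),
    field_tesla = rep(c(1.5, 3), each = n / 2),
    ecv_true_fraction = truth,
    ecv_manual_laboratory_fraction = truth,
    ecv_manual_synthetic_fraction = truth + stats::rnorm(n, 0, 0.01),
    ecv_automated_laboratory_fraction = truth + stats::rnorm(n, 0, 0.01),
    ecv_automated_synthetic_fraction = truth)
  rep <- agreement_report(results)
  expect_equal(nrow(rep$variants), 4 * 3)  # 4 variants x (1.5T, 3T, all)
  expect_setequal(unique(rep$variants$group), c("1.5", "3", "all"))
  # automated synthetic == reference by construction here
  expect_equal(rep$bland_altman$overall$bias, 0)
  expect_equal(rep$classification[[1]]$table$concordance, 1)
  expect_equal(rep$pearson$r, 1)
  expect_length(rep$classification, 2)
  expect_false(is.null(rep$bland_altman$low))
  expect_equal(rep$recovery$comparison$mae_percent, 0)
  expect_error(agreement_report(results[, -4]), "missing reference")
})
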