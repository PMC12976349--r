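test_that("median extraction follows the standard definition", {
  m <- t1_map(matrix(as.numeric(1:16), 4, 4), 1, 1.5, "native")
  uniform <- t1_map(matrix(1200, 4, 4), 1, 1.5, "native")
  mask <- matrix(FALSE, 4, 4); mask[1:4] <- TRUE
  expect_equal(median_t1(m, mask), 2.5)      # {1,2,3,4} -> 2.5
  expect_equal(median_t1(uniform, matrix(TRUE, 4, 4)), 1200)
  expect_error(median_t1(m, matrix(FALSE, 4, 4)), "empty mask")
})

test_that("hematocrit regression recovers generating coefficients exactly", {
  set.seed(3)
  alpha <- -0.29; beta <- 1.111
  t1 <- stats::runif(40, 1300, 1900)
  d <- data.frame(sex = "female", field_tesla = 1.5,
                  t1_blood_native_ms = t1,
                  hct_fraction = alpha + beta * (1000 / t1))
  models <- fit_hct_model(d, stratify_sex = FALSE, stratify_field = FALSE)
  expect_length(models, 1)
  expect_equal(models[[1]]$intercept, alpha, tolerance = 1e-12)
  expect_equal(models[[1]]$slope, beta, tolerance = 1e-12)
  # under-sized stratum errors with the stratum name
  expect_error(fit_hct_model(d[1:5, ]), "fewer than 10")
  expect_error(fit_hct_model(d[, -4]), "missing column")
})

test_that("hematocrit prediction applies the R1 transform and clamps", {
  m0 <- hct_model(intercept = 0.42, slope = 0)
  expect_equal(as.numeric(predict_hct(m0, 1200)), 0.42)
  expect_equal(as.numeric(predict_hct(m0, 1900)), 0.42)
  m1 <- hct_model(intercept = 0, slope = 0.6)
  expect_equal(as.numeric(predict_hct(m1, 1500)), 0.40, tolerance = 1e-12)
  m2 <- hct_model(intercept = 0.72, slope = 0)
  p <- predict_hct(m2, 1500)
  expect_equal(as.numeric(p), 0.70)
  expect_true(attr(p, "clamped"))
  expect_true(attr(p, "out_of_range"))
  expect_error(predict_hct(m1, -5), "input error")
})

test_that("model selection honors strata with pooled fallback", {
  models <- list(hct_model(0.1, 1, sex = "female", field = 1.5),
                 hct_model(0.2, 1, sex = "male", field = 1.5),
                 hct_model(0.3, 1, sex = "any", field = "any"))
  expect_equal(select_hct_model(models, "male", 1.5)$intercept, 0.2)
  expect_equal(select_hct_model(models, "male", 3.0)$intercept, 0.3)
  expect_error(select_hct_model(models[1:2], "male", 3.0), "no hematocrit")
})

test_that("the ECV formula reproduces the printed validation example", {
  # 1.5 T validation means: HCT 41.7 %, quartet 1036/449/1559/311 ms
  ecv <- compute_ecv(1036, 449, 1559, 311, 0.417)
  expect_equal(round(100 * ecv, 1), 28.6)
  # no myocardial change -> 0; hand-computed quartet -> 0.24
  expect_equal(compute_ecv(1000, 1000, 1600, 320, 0.4), 0)
  expect_equal(compute_ecv(1000, 500, 1600, 320, 0.40), 0.24,
               tolerance = 1e-12)
  expect_error(compute_ecv(1000, 500, 320, 1600, 0.4),
               "non-physiological")
  expect_warning(compute_ecv(500, 1000, 1600, 320, 0.4), "negative")
  expect_error(compute_ecv(1000, 500, 1600, 320, 1.2), "hematocrit")
})

test_that("ECV is strictly decreasing in hematocrit", {
  hcts <- seq(0.2, 0.6, by = 0.05)
  ecvs <- vapply(hcts, function(h) compute_ecv(1036, 449, 1559, 311, h),
                 numeric(1))
  expect_true(all(diff(ecvs) < 0))
})

test_that("classification uses the >= boundary convention", {
  expect_true(classify_ecv(0.297, 0.295))
  expect_false(classify_ecv(0.297, 0.300))
  expect_true(classify_ecv(0.300, 0.300))
})

test_that("quantify_subject fills the variant grid and closes on truth", {
  case <- ideal_case()
  s <- case$subject
  res <- quantify_subject(case$native, case$post,
                          masks_variants = list(manual = case$oracle),
                          sex = s$sex, hct_lab = s$hct_true,
                          subject_id = s$subject_id)
  expect_equal(res$ecv$manual_laboratory, s$ecv_true, tolerance = 1e-12)
  expect_named(res$classifications, "manual_laboratory")
  # a perfectly calibrated model makes synthetic == laboratory ECV
  cfg <- ideal_config()
  truth <- true_hct_coefficients(cfg)
  row <- truth[truth$sex == s$sex & truth$field_tesla == s$field, ]
  perfect <- hct_model(row$alpha, row$beta, sex = s$sex, field = s$field)
  res2 <- quantify_subject(case$native, case$post,
                           masks_variants = list(manual = case$oracle),
                           sex = s$sex, hct_lab = s$hct_true,
                           hct_models = list(perfect))
  expect_equal(res2$ecv$manual_synthetic, res2$ecv$manual_laboratory,
               tolerance = 1e-10)
  # no laboratory hematocrit -> only synthetic variants
  res3 <- quantify_subject(case$native, case$post,
                           masks_variants = list(manual = case$oracle),
                           sex = s$sex, hct_models = list(perfect))
  expect_named(res3$ecv, "manual_synthetic")
  expect_error(quantify_subject(case$native, case$post,
                                list(manual = case$oracle), sex = s$sex),
               "neither")
})

test_that("oracle and classical contours agree to 0.5 ECV points", {
  case <- ideal_case()
  s <- case$subject
  res <- quantify_subject(case$native, case$post,
                          masks_variants = list(
                            manual = case$oracle,
                            automated = segment_classical(case$native)),
                          sex = s$sex, hct_lab = s$hct_true)
  expect_lt(abs(res$ecv$automated_laboratory - res$ecv$manual_laboratory),
            0.005)
})
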