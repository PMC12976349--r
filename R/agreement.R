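# Method-agreement statistics: Bland-Altman with confidence intervals,
# Pearson + paired t, McNemar, concordance tables, two-way random-effects
# ICC, Dice and Hausdorff.

#' Bland-Altman agreement analysis
#'
#' Differences are `x - y`. Limits of agreement use the conventional 1.96
#' normal quantile; the CI of the bias uses a t quantile with SE = SD/sqrt(n)
#' and each LoA's CI uses the large-sample SE = SD * sqrt(3/n).
#'
#' @param x,y paired numeric vectors (method 1, method 2).
#' @param subset optional predicate on the pair means `(x + y)/2` selecting
#'   a stratum (e.g. `function(m) m <= 0.35`).
#' @param label optional stratum label carried into the report.
#' @return object of class `bland_altman_report`.
#' @export
bland_altman <- function(x, y, subset = NULL, label = NULL) {
  stopifnot(length(x) == length(y))
  if (!is.null(subset)) {
    keep <- subset((x + y) / 2)
    x <- x[keep]; y <- y[keep]
  }
  n <- length(x)
  if (n < 3) stop("Bland-Altman requires at least 3 pairs")
  d <- x - y
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  loa_low <- bias - 1.96 * sd_diff
  loa_high <- bias + 1.96 * sd_diff
  tq <- stats::qt(0.975, n - 1)
  se_bias <- sd_diff / sqrt(n)
  se_loa <- sd_diff * sqrt(3 / n)
  structure(list(
    n = n, bias = bias, sd_diff = sd_diff,
    loa_low = loa_low, loa_high = loa_high,
    ci_bias = bias + c(-1, 1) * tq * se_bias,
    ci_loa_low = loa_low + c(-1, 1) * tq * se_loa,
    ci_loa_high = loa_high + c(-1, 1) * tq * se_loa,
    label = label
  ), class = "bland_altman_report")
}

#' Pearson correlation and paired t-test for two methods
#'
#' @param x,y paired numeric vectors.
#' @return list with `pearson_r`, `pearson_p`, `t_statistic`, `t_p` (both
#'   two-sided), and per-method `mean` and `sd`.
#' @export
paired_agreement <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("paired agreement requires at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: Pearson correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  d <- x - y
  if (stats::sd(d) == 0) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
  }
  list(pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
       t_statistic = unname(tt$statistic), t_p = tt$p.value,
       mean_x = mean(x), sd_x = stats::sd(x),
       mean_y = mean(y), sd_y = stats::sd(y))
}

#' McNemar's test from discordant counts
#'
#' Default is the continuity-corrected chi-squared,
#' (|b - c| - 1)^2 / (b + c) on one degree of freedom; the exact alternative
#' doubles the smaller binomial(b + c, 1/2) tail, capped at 1.
#'
#' @param b,c discordant counts (false negatives / false positives of the
#'   test method relative to the reference).
#' @param method `"cc_chi2"` (default) or `"exact"`.
#' @return list(statistic, p, method, note).
#' @export
mcnemar_test <- function(b, c, method = c("cc_chi2", "exact")) {
  method <- match.arg(method)
  stopifnot(b >= 0, c >= 0)
  if (b + c == 0)
    return(list(statistic = NA_real_, p = 1, method = method,
                note = "no discordant pairs"))
  if (method == "cc_chi2") {
    stat <- (abs(b - c) - 1)^2 / (b + c)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    stat <- min(b, c)
    p <- min(1, 2 * stats::pbinom(min(b, c), b + c, 0.5))
  }
  list(statistic = stat, p = p, method = method, note = NULL)
}

#' Concordance table for paired binary classifications
#'
#' Cross-tabulates a test method against a reference method and attaches
#' McNemar's test. "False negative" means reference-positive but
#' test-negative.
#'
#' @param ref,test equal-length logical vectors.
#' @param mcnemar_method passed to [mcnemar_test()].
#' @return object of class `concordance_table`.
#' @export
concordance <- function(ref, test, mcnemar_method = "cc_chi2") {
  stopifnot(length(ref) == length(test))
  if (length(ref) == 0) stop("empty input")
  ref <- as.logical(ref); test <- as.logical(test)
  concordance_counts(both_negative = sum(!ref & !test),
                     both_positive = sum(ref & test),
                     false_negative = sum(ref & !test),
                     false_positive = sum(!ref & test),
                     mcnemar_method = mcnemar_method)
}

#' Concordance table from 2x2 counts
#'
#' @param both_negative,both_positive,false_negative,false_positive cell
#'   counts relative to the reference method.
#' @param mcnemar_method passed to [mcnemar_test()].
#' @return object of class `concordance_table` with counts, proportions
#'   (denominator n), the concordance proportion and the McNemar result.
#' @export
concordance_counts <- function(both_negative, both_positive,
                               false_negative, false_positive,
                               mcnemar_method = "cc_chi2") {
  counts <- c(both_negative = both_negative, both_positive = both_positive,
              false_negative = false_negative,
              false_positive = false_positive)
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("empty input")
  structure(list(
    counts = counts, n = n, proportions = counts / n,
    concordance = unname((counts["both_negative"] + counts["both_positive"]) / n),
    mcnemar = mcnemar_test(false_negative, false_positive,
                           method = mcnemar_method)
  ), class = "concordance_table")
}

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' From the two-way ANOVA mean squares of a complete subjects-by-raters
#' table: ICC(2,1) ("single") and ICC(2,k) ("average").
#'
#' @param ratings numeric matrix or data.frame, rows = subjects, columns =
#'   raters; no missing cells.
#' @param form `"single"` for ICC(2,1) or `"average"` for ICC(2,k).
#' @return the ICC value.
#' @export
icc <- function(ratings, form = c("single", "average")) {
  form <- match.arg(form)
  m <- as.matrix(ratings)
  if (anyNA(m)) stop("missing cells: ICC requires a complete table")
  n <- nrow(m); k <- ncol(m)
  if (n < 3) stop("ICC requires at least 3 subjects")
  if (k < 2) stop("ICC requires at least 2 raters")
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (form == "single") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (msc - mse) / n)
  }
}

#' Dice coefficient and Hausdorff distance between two masks
#'
#' Dice = 2|a and b| / (|a| + |b|). The Hausdorff distance is the classic
#' maximum of the two directed maxima of Euclidean distances between
#' boundary-voxel centers (boundary = in-mask voxels with an 8-neighbor
#' outside), scaled by the voxel spacing.
#'
#' @param a,b logical matrices of equal shape.
#' @param spacing_mm isotropic voxel edge length (mm).
#' @return list(dice, hausdorff_mm). With exactly one empty mask, Dice is 0
#'   and the Hausdorff distance is NA with a warning; two empty masks are an
#'   error.
#' @export
contour_agreement <- function(a, b, spacing_mm = 1) {
  a <- as_binary_mask(a); b <- as_binary_mask(b)
  stopifnot(identical(dim(a), dim(b)))
  na <- sum(a); nb <- sum(b)
  if (na == 0 && nb == 0) stop("undefined: both masks are empty")
  dice <- 2 * sum(a & b) / (na + nb)
  if (na == 0 || nb == 0) {
    warning("one mask is empty: Hausdorff distance undefined")
    return(list(dice = dice, hausdorff_mm = NA_real_))
  }
  ba <- which(mask_boundary(a), arr.ind = TRUE)
  bb <- which(mask_boundary(b), arr.ind = TRUE)
  d2 <- outer(ba[, 1], bb[, 1], `-`)^2 + outer(ba[, 2], bb[, 2], `-`)^2
  directed_ab <- sqrt(max(apply(d2, 1, min)))
  directed_ba <- sqrt(max(apply(d2, 2, min)))
  list(dice = dice,
       hausdorff_mm = spacing_mm * max(directed_ab, directed_ba))
}

#' Cohort-level agreement report
#'
#' Mirrors the validation layout of the source design: per contour-by-
#' hematocrit variant means and SDs with paired t-tests against the
#' reference variant (per field strength and pooled), Bland-Altman between
#' the fully automated synthetic and the reference ECV (overall and
#' stratified at 35 %), Pearson correlation, threshold concordance with
#' McNemar at both threshold schemes, and -- when phantom ground truth is
#' available -- ECV recovery metrics.
#'
#' @param results data.frame with one row per subject: `field_tesla` plus
#'   ECV columns `ecv_<variant>_fraction`; optionally `ecv_true_fraction`.
#' @param reference reference variant name (default `"manual_laboratory"`).
#' @param comparison variant compared against the reference in Bland-Altman
#'   and classification (default `"automated_synthetic"`).
#' @param threshold_schemes list of c(ref, test) threshold pairs
#'   (fractions).
#' @param strata_cut pair-mean ECV cut (fraction) for stratified
#'   Bland-Altman.
#' @return object of class `agreement_report`.
#' @export
agreement_report <- function(results,
                             reference = "manual_laboratory",
                             comparison = "automated_synthetic",
                             threshold_schemes = list(c(0.30, 0.30),
                                                      c(0.30, 0.295)),
                             strata_cut = 0.35) {
  ecv_cols <- grep("^ecv_.*_fraction$", names(results), value = TRUE)
  ecv_cols <- setdiff(ecv_cols, "ecv_true_fraction")
  variants <- sub("^ecv_(.*)_fraction$", "\\1", ecv_cols)
  ref_col <- paste0("ecv_", reference, "_fraction")
  cmp_col <- paste0("ecv_", comparison, "_fraction")
  if (!ref_col %in% names(results))
    stop("missing reference variant column: ", ref_col)
  if (!cmp_col %in% names(results))
    stop("missing comparison variant column: ", cmp_col)
  groups <- c(as.list(sort(unique(results$field_tesla))), list("all"))
  rows <- list()
  for (g in groups) {
    sub <- if (identical(g, "all")) results
           else results[results$field_tesla == g, ]
    for (v in variants) {
      col <- paste0("ecv_", v, "_fraction")
      p <- if (v == reference) NA_real_ else {
        if (stats::sd(sub[[col]] - sub[[ref_col]]) == 0) 1
        else stats::t.test(sub[[col]], sub[[ref_col]],
                           paired = TRUE)$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = as.character(g), variant = v, n = nrow(sub),
        mean_percent = 100 * mean(sub[[col]]),
        sd_percent = 100 * stats::sd(sub[[col]]),
        p_vs_reference = p, stringsAsFactors = FALSE)
    }
  }
  variant_table <- do.call(rbind, rows)
  x <- results[[cmp_col]]; y <- results[[ref_col]]
  ba <- list(
    overall = bland_altman(x, y, label = "all"),
    low = bland_altman(x, y, subset = function(m) m <= strata_cut,
                       label = sprintf("pair mean <= %.0f%%",
                                       100 * strata_cut)),
    high = tryCatch(
      bland_altman(x, y, subset = function(m) m > strata_cut,
                   label = sprintf("pair mean > %.0f%%", 100 * strata_cut)),
      error = function(e) NULL))
  pa <- paired_agreement(x, y)
  classification <- lapply(threshold_schemes, function(th) {
    list(threshold_ref_fraction = th[1], threshold_test_fraction = th[2],
         table = concordance(classify_ecv(y, th[1]), classify_ecv(x, th[2])))
  })
  recovery <- NULL
  if ("ecv_true_fraction" %in% names(results)) {
    err <- results[[cmp_col]] - results$ecv_true_fraction
    ref_err <- results[[ref_col]] - results$ecv_true_fraction
    recovery <- list(
      comparison = list(mae_percent = 100 * mean(abs(err)),
                        bias_percent = 100 * mean(err)),
      reference = list(mae_percent = 100 * mean(abs(ref_err)),
                       bias_percent = 100 * mean(ref_err)))
  }
  structure(list(variants = variant_table, bland_altman = ba,
                 pearson = list(r = pa$pearson_r, p = pa$pearson_p),
                 classification = classification,
                 recovery = recovery,
                 reference = reference, comparison = comparison),
            class = "agreement_report")
}
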