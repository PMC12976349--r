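# Median T1 extraction, synthetic-hematocrit regression, ECV computation
# (conventional and synthetic variants) and threshold classification.

#' Median T1 over a mask
#'
#' @param map a `t1_map`.
#' @param mask logical matrix of the same shape.
#' @return median of the in-mask values (ms); even counts average the two
#'   central values.
#' @export
median_t1 <- function(map, mask) {
  stopifnot(inherits(map, "t1_map"))
  mask <- as_binary_mask(mask)
  if (!any(mask)) stop("measurement error: empty mask")
  stats::median(map$values[mask])
}

#' Fit stratified synthetic-hematocrit models
#'
#' Ordinary least squares of hematocrit (fraction) on native blood-pool R1
#' (1/s, computed as 1000 / T1 ms), one model per requested stratum of sex
#' and field strength. This is the calibration route; published per-stratum
#' coefficients can be supplied instead via [hct_model()].
#'
#' @param samples data.frame with columns `sex` ("female"/"male"),
#'   `field_tesla` (1.5 or 3), `t1_blood_native_ms`, `hct_fraction`.
#' @param stratify_sex,stratify_field logical; with both off a single pooled
#'   model is fit.
#' @param chamber blood pool the T1 was measured in ("LV" or "RV").
#' @return list of `hct_model` objects.
#' @export
fit_hct_model <- function(samples, stratify_sex = TRUE,
                          stratify_field = TRUE, chamber = "LV") {
  need <- c("sex", "field_tesla", "t1_blood_native_ms", "hct_fraction")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols) > 0)
    stop("fitting error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  key_sex <- if (stratify_sex) samples$sex else "any"
  key_field <- if (stratify_field) samples$field_tesla else "any"
  key <- paste(key_sex, key_field, sep = "|")
  models <- list()
  for (k in unique(key)) {
    sub <- samples[key == k, ]
    if (nrow(sub) < 10)
      stop("fitting error: stratum '", k, "' has fewer than 10 samples (",
           nrow(sub), ")")
    r1 <- 1000 / sub$t1_blood_native_ms
    fit <- stats::lm(sub$hct_fraction ~ r1)
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    models[[k]] <- hct_model(
      intercept = unname(stats::coef(fit)[1]),
      slope = unname(stats::coef(fit)[2]),
      sex = parts[1],
      field = if (parts[2] == "any") "any" else as.numeric(parts[2]),
      chamber = chamber,
      n = nrow(sub),
      residual_sd = stats::sigma(fit))
  }
  models
}

#' Construct a synthetic-hematocrit model
#'
#' Linear model HCT = intercept + slope * R1 with R1 the native blood-pool
#' relaxation rate in 1/s. Use directly to supply published coefficients for
#' a stratum.
#'
#' @param intercept hematocrit fraction at R1 = 0.
#' @param slope hematocrit fraction per 1/s of native blood R1.
#' @param sex,field,chamber stratum labels ("any" = pooled).
#' @param n,residual_sd optional fit diagnostics.
#' @return object of class `hct_model`.
#' @export
hct_model <- function(intercept, slope, sex = "any", field = "any",
                      chamber = "LV", n = NA_integer_,
                      residual_sd = NA_real_) {
  structure(list(intercept = intercept, slope = slope,
                 stratum = list(sex = sex, field = field, chamber = chamber),
                 n = n, residual_sd = residual_sd), class = "hct_model")
}

#' Pick the hematocrit model matching a (sex, field, chamber) stratum
#'
#' Falls back to pooled (`"any"`) strata when no exact match exists.
#'
#' @param models list of `hct_model`s (or a single model, returned as-is).
#' @param sex,field,chamber the subject's stratum.
#' @return an `hct_model`.
#' @export
select_hct_model <- function(models, sex, field, chamber = "LV") {
  if (inherits(models, "hct_model")) return(models)
  match_one <- function(m, want, got) want == "any" || identical(want, got)
  for (m in models) {
    s <- m$stratum
    if (match_one(m, s$sex, sex) &&
        (identical(s$field, "any") || isTRUE(s$field == field)) &&
        match_one(m, s$chamber, chamber))
      return(m)
  }
  stop("no hematocrit model for stratum (", sex, ", ", field, " T, ",
       chamber, ")")
}

#' Predict synthetic hematocrit from native blood-pool T1
#'
#' @param model an `hct_model`.
#' @param t1_blood_native median native blood-pool T1 (ms).
#' @return hematocrit fraction, clamped to (0.05, 0.70); attributes
#'   `clamped` and `out_of_range` (outside (0.15, 0.60)) flag questionable
#'   predictions.
#' @export
predict_hct <- function(model, t1_blood_native) {
  stopifnot(inherits(model, "hct_model"))
  if (any(t1_blood_native <= 0))
    stop("input error: native blood T1 must be positive")
  raw <- model$intercept + model$slope * (1000 / t1_blood_native)
  hct <- pmin(pmax(raw, 0.05), 0.70)
  attr(hct, "clamped") <- raw < 0.05 | raw > 0.70
  attr(hct, "out_of_range") <- raw < 0.15 | raw > 0.60
  hct
}

#' Extracellular volume fraction from a T1 quartet and hematocrit
#'
#' ECV = (1 - HCT) * (1/T1myo_post - 1/T1myo_native) /
#'                   (1/T1blood_post - 1/T1blood_native).
#' The synthetic variant is the same computation with the regressed
#' hematocrit in place of the laboratory value.
#'
#' @param t1_myo_native,t1_myo_post,t1_blood_native,t1_blood_post median T1
#'   values (ms).
#' @param hct hematocrit fraction in (0, 1).
#' @return ECV as a fraction.
#' @export
compute_ecv <- function(t1_myo_native, t1_myo_post,
                        t1_blood_native, t1_blood_post, hct) {
  if (any(c(t1_myo_native, t1_myo_post, t1_blood_native, t1_blood_post) <= 0))
    stop("input error: T1 values must be positive")
  if (any(hct <= 0 | hct >= 1))
    stop("input error: hematocrit must lie strictly in (0, 1)")
  d_blood <- 1 / t1_blood_post - 1 / t1_blood_native
  if (any(d_blood <= 0))
    stop("non-physiological contrast dynamics: blood relaxation rate did ",
         "not increase after contrast")
  d_myo <- 1 / t1_myo_post - 1 / t1_myo_native
  if (any(d_myo < 0))
    warning("negative myocardial relaxation-rate change; ECV will be negative")
  (1 - hct) * d_myo / d_blood
}

#' Classify an ECV value against a clinical threshold
#'
#' @param ecv ECV fraction.
#' @param threshold decision threshold as a fraction (e.g. 0.30).
#' @return logical; positive iff `ecv >= threshold` (boundary counts as
#'   positive).
#' @export
classify_ecv <- function(ecv, threshold) {
  stopifnot(is.numeric(ecv), is.numeric(threshold))
  ecv >= threshold
}

#' Quantify one subject across contour and hematocrit variants
#'
#' Runs refinement and median extraction for every supplied contour variant
#' and fills the contour-by-hematocrit ECV grid (laboratory variants are
#' omitted when no laboratory hematocrit is available). The LV blood pool
#' supplies both ECV blood terms and the synthetic-hematocrit predictor.
#'
#' @param native,post the subject's `t1_map` pair.
#' @param masks_variants named list of [seg_masks()] (e.g. `manual`,
#'   `automated`).
#' @param sex subject sex ("female"/"male"), used for model selection.
#' @param hct_lab laboratory hematocrit fraction, or NULL if not drawn.
#' @param hct_models list of `hct_model`s (or a single model); NULL skips
#'   the synthetic variants.
#' @param thresholds named or unnamed vector of classification thresholds
#'   (fractions).
#' @param subject_id identifier carried into results and error messages.
#' @return object of class `ecv_result`: medians, hematocrits, the ECV
#'   variant grid (`<variant>_laboratory` / `<variant>_synthetic`),
#'   classifications and quality flags.
#' @export
quantify_subject <- function(native, post, masks_variants, sex = "any",
                             hct_lab = NULL, hct_models = NULL,
                             thresholds = c(0.30, 0.295),
                             subject_id = "subject") {
  stopifnot(length(masks_variants) >= 1, !is.null(names(masks_variants)))
  if (is.null(hct_lab) && is.null(hct_models))
    stop("quantification error (", subject_id,
         "): neither laboratory hematocrit nor a synthetic model supplied")
  medians <- list(); hct_syn <- list(); ecv <- list(); flags <- character()
  for (variant in names(masks_variants)) {
    masks <- masks_variants[[variant]]
    refined <- tryCatch(refine_all(masks, native, post),
                        error = function(e)
                          stop(subject_id, ": ", conditionMessage(e),
                               call. = FALSE))
    med <- c(
      t1_myo_native = median_t1(native, refined$native$myocardium_refined),
      t1_myo_post = median_t1(post, refined$post$myocardium_refined),
      t1_blood_native = median_t1(native, refined$native$blood_refined),
      t1_blood_post = median_t1(post, refined$post$blood_refined))
    medians[[variant]] <- med
    if (!is.null(hct_lab)) {
      ecv[[paste0(variant, "_laboratory")]] <- compute_ecv(
        med["t1_myo_native"], med["t1_myo_post"],
        med["t1_blood_native"], med["t1_blood_post"], hct_lab)
    }
    if (!is.null(hct_models)) {
      model <- select_hct_model(hct_models, sex, native$field, "LV")
      h <- predict_hct(model, med[["t1_blood_native"]])
      if (any(attr(h, "clamped")))
        flags <- c(flags, paste0(variant, ": synthetic hematocrit clamped"))
      else if (any(attr(h, "out_of_range")))
        flags <- c(flags, paste0(variant,
                                 ": synthetic hematocrit outside (0.15, 0.60)"))
      hct_syn[[variant]] <- as.numeric(h)
      ecv[[paste0(variant, "_synthetic")]] <- compute_ecv(
        med["t1_myo_native"], med["t1_myo_post"],
        med["t1_blood_native"], med["t1_blood_post"], as.numeric(h))
    }
  }
  ecv <- lapply(ecv, unname)
  cls <- lapply(ecv, function(e)
    vapply(thresholds, function(th) classify_ecv(e, th), logical(1)))
  structure(list(subject_id = subject_id, sex = sex, field = native$field,
                 medians = medians, hct_lab = hct_lab,
                 hct_synthetic = hct_syn,
                 ecv = ecv, thresholds = thresholds,
                 classifications = cls, flags = flags),
            class = "ecv_result")
}
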