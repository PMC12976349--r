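# File I/O and the command-line surface: T1 maps and label rasters as NIfTI
# with JSON sidecars, cohort tables as CSV with unit-suffixed column names,
# manifests and reports as JSON.

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Read a T1 map (NIfTI + JSON sidecar)
#'
#' Acquisition metadata (contrast phase, field strength) comes from a JSON
#' sidecar next to the image; explicit arguments override it.
#'
#' @param path `.nii` / `.nii.gz` file.
#' @param phase,field optional overrides for the sidecar's `phase` and
#'   `field_tesla`.
#' @return a [t1_map()].
#' @export
read_t1map <- function(path, phase = NULL, field = NULL) {
  img <- read_nifti_2d(path)
  if (abs(img$spacing_mm[1] - img$spacing_mm[2]) > 1e-6)
    stop("format error: anisotropic spacing not supported")
  sc <- sidecar_path(path)
  meta <- if (file.exists(sc)) jsonlite::read_json(sc) else list()
  phase <- phase %||% meta$phase
  field <- field %||% meta$field_tesla
  if (is.null(phase))
    stop("format error: no contrast 'phase' in sidecar and no override given")
  if (is.null(field))
    stop("format error: no 'field_tesla' in sidecar and no override given")
  t1_map(img$values, spacing_mm = img$spacing_mm[1],
         field = as.numeric(field), phase = phase)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a T1 map (NIfTI float32 + JSON sidecar)
#'
#' @param map a `t1_map`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_t1map <- function(map, path) {
  stopifnot(inherits(map, "t1_map"))
  write_nifti_2d(map$values, path, map$spacing_mm, datatype = "float32")
  jsonlite::write_json(list(phase = map$phase, field_tesla = map$field,
                            spacing_mm = map$spacing_mm),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a phantom label raster (NIfTI uint8)
#'
#' @param labels a `label_raster`.
#' @param path `.nii` / `.nii.gz` path.
#' @return the object (read) or path (write), invisibly.
#' @export
write_label_raster <- function(labels, path) {
  stopifnot(inherits(labels, "label_raster"))
  write_nifti_2d(labels$labels, path, labels$spacing_mm, datatype = "uint8")
  invisible(path)
}

#' @rdname write_label_raster
#' @export
read_label_raster <- function(path) {
  img <- read_nifti_2d(path)
  lab <- matrix(as.integer(round(img$values)), nrow(img$values))
  if (any(lab < 0 | lab > 4))
    stop("format error: label codes outside {0..4} in ", path)
  structure(list(labels = lab, spacing_mm = img$spacing_mm[1]),
            class = "label_raster")
}

cohort_required_cols <- c("subject_id", "sex", "field_tesla",
                          "hct_true_fraction", "ecv_true_fraction")

#' Write / read a cohort table (CSV, versioned header comment)
#'
#' Columns carry units in their names (`_ms`, `_fraction`, `_tesla`).
#' Unknown columns are preserved on round-trip.
#'
#' @param cohort data.frame with at least `subject_id`, `sex`,
#'   `field_tesla`, `hct_true_fraction`, `ecv_true_fraction`.
#' @param path CSV path.
#' @return the data.frame (read) or path (write), invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  missing_cols <- setdiff(cohort_required_cols, names(cohort))
  if (length(missing_cols) > 0)
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# synthecv cohort table v1", con)
  utils::write.csv(cohort, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  cohort <- utils::read.csv(path, comment.char = "#",
                            stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_required_cols, names(cohort))
  if (length(missing_cols) > 0)
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  cohort
}

# Flatten an agreement_report into JSON-friendly lists.
report_to_list <- function(report) {
  ba_list <- function(ba) if (is.null(ba)) NULL else
    list(label = ba$label, n = ba$n, bias = ba$bias, sd_diff = ba$sd_diff,
         loa_low = ba$loa_low, loa_high = ba$loa_high,
         ci_bias = ba$ci_bias, ci_loa_low = ba$ci_loa_low,
         ci_loa_high = ba$ci_loa_high)
  list(
    reference = report$reference, comparison = report$comparison,
    variants = report$variants,
    pearson = report$pearson,
    bland_altman = lapply(report$bland_altman, ba_list),
    classification = lapply(report$classification, function(cl) list(
      threshold_ref_fraction = cl$threshold_ref_fraction,
      threshold_test_fraction = cl$threshold_test_fraction,
      counts = as.list(cl$table$counts),
      concordance = cl$table$concordance,
      mcnemar_statistic = cl$table$mcnemar$statistic,
      mcnemar_p = cl$table$mcnemar$p)),
    recovery = report$recovery)
}

#' Write an agreement report as JSON
#'
#' @param report an `agreement_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_agreement_report <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Run the full pipeline on a generated phantom cohort directory
#'
#' For every subject: read the map pair and ground-truth labels, build the
#' reference (oracle) contours and the requested automated backend's
#' contours, refine, extract medians, predict synthetic hematocrit with
#' models calibrated on the cohort itself (or supplied), and compute the
#' four contour-by-hematocrit ECV variants.
#'
#' @param cohort_dir directory written by [generate_cohort()].
#' @param backend `"oracle"`, `"classical"` or `"learned"`.
#' @param hct_models optional list of `hct_model`s; by default models are
#'   calibrated per (sex, field) stratum on the cohort's own laboratory
#'   hematocrits and refined oracle blood-pool medians.
#' @param thresholds classification thresholds (fractions).
#' @param model_artifact directory of a trained learned backend (required
#'   when `backend = "learned"`).
#' @return data.frame with one row per subject: medians, hematocrits, ECV
#'   variants (fractions) and classifications.
#' @export
run_cohort_pipeline <- function(cohort_dir, backend = "classical",
                                hct_models = NULL,
                                thresholds = c(0.30, 0.295),
                                model_artifact = NULL) {
  manifest <- jsonlite::read_json(file.path(cohort_dir, "manifest.json"))
  cohort <- read_cohort_table(file.path(cohort_dir, manifest$cohort_table))
  subjects <- manifest$subjects
  # First pass: oracle blood medians for hematocrit-model calibration.
  if (is.null(hct_models)) {
    cal <- cohort
    cal$t1_blood_native_ms <- vapply(subjects, function(s) {
      native <- read_t1map(file.path(cohort_dir, s$native))
      post <- read_t1map(file.path(cohort_dir, s$post))
      labels <- read_label_raster(file.path(cohort_dir, s$labels))
      masks <- segment_oracle(labels)
      refined <- refine_all(masks, native, post)
      median_t1(native, refined$native$blood_refined)
    }, numeric(1))
    cal$hct_fraction <- cal$hct_true_fraction
    strata_ok <- all(table(paste(cal$sex, cal$field_tesla)) >= 10)
    if (!strata_ok)
      message("cohort too small for (sex, field) stratification; ",
              "calibrating a pooled hematocrit model")
    hct_models <- fit_hct_model(cal, stratify_sex = strata_ok,
                                stratify_field = strata_ok)
  }
  rows <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    native <- read_t1map(file.path(cohort_dir, s$native))
    post <- read_t1map(file.path(cohort_dir, s$post))
    labels <- read_label_raster(file.path(cohort_dir, s$labels))
    oracle <- segment_oracle(labels)
    automated <- switch(backend,
      oracle = oracle,
      classical = segment_classical(native),
      learned = {
        if (is.null(model_artifact))
          stop("usage error: backend 'learned' requires model_artifact")
        segment_learned(native, model_artifact)
      },
      stop("usage error: unknown backend '", backend, "'"))
    info <- cohort[cohort$subject_id == s$subject_id, ]
    res <- quantify_subject(
      native, post,
      masks_variants = list(manual = oracle, automated = automated),
      sex = info$sex, hct_lab = info$hct_true_fraction,
      hct_models = hct_models, thresholds = thresholds,
      subject_id = s$subject_id)
    row <- data.frame(subject_id = res$subject_id, sex = res$sex,
                      field_tesla = res$field,
                      hct_lab_fraction = info$hct_true_fraction,
                      ecv_true_fraction = info$ecv_true_fraction,
                      stringsAsFactors = FALSE)
    for (v in names(res$medians)) {
      med <- res$medians[[v]]
      row[paste0("t1_myo_native_ms_", v)] <- med[["t1_myo_native"]]
      row[paste0("t1_myo_post_ms_", v)] <- med[["t1_myo_post"]]
      row[paste0("t1_blood_native_ms_", v)] <- med[["t1_blood_native"]]
      row[paste0("t1_blood_post_ms_", v)] <- med[["t1_blood_post"]]
    }
    for (v in names(res$hct_synthetic))
      row[paste0("hct_synthetic_fraction_", v)] <- res$hct_synthetic[[v]]
    for (v in names(res$ecv))
      row[paste0("ecv_", v, "_fraction")] <- res$ecv[[v]]
    for (v in names(res$classifications)) {
      cl <- res$classifications[[v]]
      for (j in seq_along(thresholds))
        row[sprintf("class_%s_at_%g", v, thresholds[j])] <- cl[j]
    }
    row$flags <- paste(res$flags, collapse = "; ")
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

#' Command-line entry point
#'
#' Commands: `generate` (phantom cohort), `quantify` (pipeline on a cohort
#' directory), `run-all` (generate + quantify + agreement report). Flags:
#' `--out DIR`, `--n N`, `--seed S`, `--backend NAME`, `--threshold T`
#' (repeatable, fractions). Returns the exit status (0 on success) rather
#' than quitting, so it is scriptable and testable; the shipped
#' `inst/cli/synthecv` wrapper forwards `commandArgs()` and quits with the
#' returned status.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status, invisibly.
#' @export
ecv_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: synthecv <generate|quantify|run-all> [--out DIR] [--n N]",
    "[--seed S] [--backend oracle|classical] [--threshold T]...")
  fail <- function(...) { message("error: ", ...); message(usage); 1L }
  if (length(args) < 1) return(invisible(fail("no command given")))
  cmd <- args[1]; args <- args[-1]
  opts <- list(out = "synthecv_out", n = 20L, seed = 1L,
               backend = "classical", thresholds = numeric())
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    val <- if (i < length(args)) args[i + 1] else NA
    known <- c("--out", "--n", "--seed", "--backend", "--threshold")
    if (!a %in% known) return(invisible(fail("unknown flag '", a, "'")))
    if (is.na(val)) return(invisible(fail("flag ", a, " needs a value")))
    switch(a,
      "--out" = { opts$out <- val },
      "--n" = { opts$n <- as.integer(val) },
      "--seed" = { opts$seed <- as.integer(val) },
      "--backend" = { opts$backend <- val },
      "--threshold" = { opts$thresholds <- c(opts$thresholds,
                                             as.numeric(val)) })
    i <- i + 2
  }
  if (!opts$backend %in% c("oracle", "classical"))
    return(invisible(fail("unknown backend '", opts$backend, "'")))
  if (length(opts$thresholds) == 0) opts$thresholds <- c(0.30, 0.295)
  if (any(opts$thresholds <= 0 | opts$thresholds >= 1))
    return(invisible(fail("thresholds must be fractions in (0,1)")))
  status <- tryCatch({
    t0 <- Sys.time()
    if (cmd == "generate" || cmd == "run-all") {
      cfg <- cohort_config(n_subjects = opts$n, seed = opts$seed)
      generate_cohort(cfg, opts$out)
      message(sprintf("[generate] %d subjects -> %s (%.1fs)", opts$n,
                      opts$out, as.numeric(Sys.time() - t0, units = "secs")))
    }
    if (cmd == "quantify" || cmd == "run-all") {
      t1 <- Sys.time()
      results <- run_cohort_pipeline(opts$out, backend = opts$backend,
                                     thresholds = opts$thresholds)
      utils::write.csv(results, file.path(opts$out, "results.csv"),
                       row.names = FALSE)
      report <- agreement_report(results)
      write_agreement_report(report, file.path(opts$out, "report.json"))
      n_flag <- sum(nzchar(results$flags))
      message(sprintf(
        "[quantify] backend=%s, %d subjects, %d flagged (%.1fs)",
        opts$backend, nrow(results), n_flag,
        as.numeric(Sys.time() - t1, units = "secs")))
      message("[report] ", file.path(opts$out, "report.json"))
    }
    if (!cmd %in% c("generate", "quantify", "run-all"))
      return(invisible(fail("unknown command '", cmd, "'")))
    0L
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
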