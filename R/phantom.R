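# Digital short-axis phantom: a stated world with known ground-truth
# geometry, hematocrit and ECV, emulating a basal-ventricular short-axis
# slice (LV cavity, myocardial ring, papillary muscles, RV crescent).

#' Phantom cohort configuration
#'
#' Priors default to the source cohort's descriptive statistics: laboratory
#' hematocrit 42.6 +/- 5.4 %, ECV 27.2 +/- 6.0 %, native myocardial T1
#' 1036 +/- 60 ms (1.5 T) and 1270 +/- 60 ms (3 T), post-contrast blood-pool
#' T1 311 +/- 58 ms (1.5 T) and 330 +/- 47 ms (3 T). Native blood-pool T1 is
#' derived from a linear R1-vs-hematocrit coupling, R1 = c0 + c1 * HCT
#' (1/s, HCT as fraction), with per-field defaults chosen so the marginal
#' native blood T1 matches the reported ~1550 ms (1.5 T) and ~1825 ms (3 T).
#'
#' @param n_subjects number of subjects in the cohort.
#' @param seed cohort-level seed; per-subject RNG streams derive from
#'   (seed, subject index) so cohorts are order-independent.
#' @param field_mix proportion of subjects scanned at 3 T.
#' @param prop_male proportion of male subjects.
#' @param hct_mean,hct_sd,hct_bounds truncated-normal prior on hematocrit
#'   (fraction).
#' @param ecv_mean,ecv_sd,ecv_bounds truncated-normal prior on true ECV
#'   (fraction).
#' @param t1_myo_native per-field mean/sd (ms), named list with `"1.5"` and
#'   `"3"` entries of c(mean, sd).
#' @param t1_blood_post per-field mean/sd (ms) of post-contrast blood T1.
#' @param blood_r1_c0,blood_r1_c1 per-field coupling coefficients (1/s and
#'   1/s per HCT fraction).
#' @param sex_r1_offset additive shift of c0 (+ for male, - for female),
#'   making sex-stratified hematocrit models genuinely distinct.
#' @param blood_r1_noise_sd residual SD of native blood R1 around the
#'   coupling line (1/s); set 0 for a noiseless world.
#' @param noise_sd_fraction voxelwise Gaussian noise SD as a fraction of the
#'   tissue T1 value; set 0 for noiseless maps.
#' @param partial_volume logical; render a one-voxel boundary band with
#'   50/50 linear mixing of adjacent tissue values.
#' @param raster_shape c(rows, cols) of the rendered maps.
#' @param spacing_mm isotropic voxel edge length (mm).
#' @param background_t1 named c(native=, post=) background T1 (ms).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 50L,
                          seed = 20260311L,
                          field_mix = 0.593,
                          prop_male = 0.61,
                          hct_mean = 0.426, hct_sd = 0.054,
                          hct_bounds = c(0.20, 0.60),
                          ecv_mean = 0.272, ecv_sd = 0.060,
                          ecv_bounds = c(0.10, 0.55),
                          t1_myo_native = list("1.5" = c(1036, 60),
                                               "3"   = c(1270, 60)),
                          t1_blood_post = list("1.5" = c(311, 58),
                                               "3"   = c(330, 47)),
                          blood_r1_c0 = c("1.5" = 0.262, "3" = 0.335),
                          blood_r1_c1 = c("1.5" = 0.90,  "3" = 0.50),
                          sex_r1_offset = 0.01,
                          blood_r1_noise_sd = 0.008,
                          noise_sd_fraction = 0.02,
                          partial_volume = TRUE,
                          raster_shape = c(128L, 128L),
                          spacing_mm = 1.17,
                          background_t1 = c(native = 300, post = 150)) {
  if (hct_sd < 0 || ecv_sd < 0 || blood_r1_noise_sd < 0 ||
      noise_sd_fraction < 0)
    stop("configuration error: standard deviations must be >= 0")
  if (hct_bounds[1] <= 0 || hct_bounds[2] >= 1 ||
      ecv_bounds[1] <= 0 || ecv_bounds[2] >= 1)
    stop("configuration error: truncation bounds must keep fractions in (0,1)")
  if (field_mix < 0 || field_mix > 1 || prop_male < 0 || prop_male > 1)
    stop("configuration error: mixture proportions must lie in [0,1]")
  if (spacing_mm <= 0) stop("configuration error: spacing must be positive")
  structure(list(
    n_subjects = as.integer(n_subjects), seed = as.integer(seed),
    field_mix = field_mix, prop_male = prop_male,
    hct_mean = hct_mean, hct_sd = hct_sd, hct_bounds = hct_bounds,
    ecv_mean = ecv_mean, ecv_sd = ecv_sd, ecv_bounds = ecv_bounds,
    t1_myo_native = t1_myo_native, t1_blood_post = t1_blood_post,
    blood_r1_c0 = blood_r1_c0, blood_r1_c1 = blood_r1_c1,
    sex_r1_offset = sex_r1_offset,
    blood_r1_noise_sd = blood_r1_noise_sd,
    noise_sd_fraction = noise_sd_fraction,
    partial_volume = isTRUE(partial_volume),
    raster_shape = as.integer(raster_shape), spacing_mm = spacing_mm,
    background_t1 = background_t1
  ), class = "cohort_config")
}

# Run code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

subject_seed <- function(cohort_seed, index) {
  as.integer((as.double(cohort_seed) * 7919 + as.double(index) * 104729) %%
               2147483629)
}

# Truncated-normal draw via inverse-CDF (exact, one uniform per draw).
rtruncnorm1 <- function(mean, sd, lower, upper) {
  if (sd == 0) return(min(max(mean, lower), upper))
  p <- stats::runif(1, stats::pnorm(lower, mean, sd),
                    stats::pnorm(upper, mean, sd))
  stats::qnorm(p, mean, sd)
}

field_key <- function(field) if (field >= 2) "3" else "1.5"

# Blood R1 coupling intercept for a given sex and field (1/s).
coupling_c0 <- function(config, sex, field) {
  unname(config$blood_r1_c0[[field_key(field)]]) +
    if (sex == "male") config$sex_r1_offset else -config$sex_r1_offset
}

coupling_c1 <- function(config, field) {
  unname(config$blood_r1_c1[[field_key(field)]])
}

#' True hematocrit-model coefficients implied by the phantom coupling
#'
#' Inverting R1 = c0 + c1*HCT gives HCT = -c0/c1 + (1/c1)*R1: the intercept
#' and slope a perfectly calibrated regression of hematocrit on native blood
#' R1 must recover for each (sex, field) stratum.
#'
#' @param config a [cohort_config()].
#' @return data.frame with sex, field_tesla, alpha, beta.
#' @export
true_hct_coefficients <- function(config) {
  grid <- expand.grid(sex = c("female", "male"), field = c(1.5, 3.0),
                      stringsAsFactors = FALSE)
  grid$alpha <- grid$beta <- NA_real_
  for (i in seq_len(nrow(grid))) {
    c0 <- coupling_c0(config, grid$sex[i], grid$field[i])
    c1 <- coupling_c1(config, grid$field[i])
    grid$alpha[i] <- -c0 / c1
    grid$beta[i] <- 1 / c1
  }
  names(grid)[2] <- "field_tesla"
  grid
}

# Solve the ECV relation for post-contrast myocardial T1 (ms):
# 1/T1myo_post = 1/T1myo_native + [ECV/(1-HCT)] * (1/T1b_post - 1/T1b_native)
solve_t1_myo_post <- function(t1_myo_native, ecv, hct,
                              t1_blood_native, t1_blood_post) {
  r <- 1 / t1_myo_native +
    (ecv / (1 - hct)) * (1 / t1_blood_post - 1 / t1_blood_native)
  if (r <= 0)
    stop("rendering error: ECV/HCT combination yields non-positive ",
         "post-contrast myocardial T1")
  1 / r
}

#' Draw one subject's ground truth
#'
#' Reproducible from (config seed, index): sex, field strength, hematocrit,
#' ECV and tissue T1 values are drawn from the configured truncated-normal
#' priors; native blood T1 follows the linear R1-vs-HCT coupling; the
#' post-contrast myocardial T1 is the algebraic solution of the ECV relation
#' so the phantom closes exactly under noiseless measurement.
#'
#' @param config a [cohort_config()].
#' @param index 1-based subject index, `<= n_subjects`.
#' @return object of class `subject_truth`.
#' @export
sample_subject <- function(config, index) {
  stopifnot(inherits(config, "cohort_config"))
  if (index < 1 || index > config$n_subjects)
    stop("configuration error: index out of range")
  sseed <- subject_seed(config$seed, index)
  with_seed(sseed, {
    sex <- if (stats::runif(1) < config$prop_male) "male" else "female"
    field <- if (stats::runif(1) < config$field_mix) 3.0 else 1.5
    hct <- rtruncnorm1(config$hct_mean, config$hct_sd,
                       config$hct_bounds[1], config$hct_bounds[2])
    ecv <- rtruncnorm1(config$ecv_mean, config$ecv_sd,
                       config$ecv_bounds[1], config$ecv_bounds[2])
    fk <- field_key(field)
    mp <- config$t1_myo_native[[fk]]
    t1_myo_native <- rtruncnorm1(mp[1], mp[2], mp[1] - 3 * mp[2],
                                 mp[1] + 3 * mp[2])
    r1_blood <- coupling_c0(config, sex, field) +
      coupling_c1(config, field) * hct
    if (config$blood_r1_noise_sd > 0)
      r1_blood <- r1_blood + stats::rnorm(1, 0, config$blood_r1_noise_sd)
    t1_blood_native <- 1000 / r1_blood
    bp <- config$t1_blood_post[[fk]]
    t1_blood_post <- rtruncnorm1(bp[1], bp[2], max(100, bp[1] - 3 * bp[2]),
                                 bp[1] + 3 * bp[2])
    t1_myo_post <- solve_t1_myo_post(t1_myo_native, ecv, hct,
                                     t1_blood_native, t1_blood_post)
    geometry <- sample_geometry(config)
    structure(list(
      subject_id = sprintf("S%04d", index),
      sex = sex, field = field,
      hct_true = hct, ecv_true = ecv,
      t1_blood_native = t1_blood_native, t1_blood_post = t1_blood_post,
      t1_myo_native = t1_myo_native, t1_myo_post = t1_myo_post,
      geometry = geometry, seed = sseed
    ), class = "subject_truth")
  })
}

#' Construct an explicit slice geometry
#'
#' Units mm; voxel coordinates are 0-based with voxel-center convention.
#'
#' @param raster_shape c(rows, cols).
#' @param spacing_mm isotropic voxel edge length.
#' @param lv_center LV center in (row, col) voxel coordinates.
#' @param epicardial_radius_mm,wall_thickness_mm LV dimensions.
#' @param papillary list of `list(center_offset_mm = c(dr, dc), radius_mm)`
#'   discs, offsets relative to the LV center.
#' @param rv_crescent list(center_offset_mm, radius_mm, gap_mm, reach_mm)
#'   describing the RV cavity crescent; NULL for no RV.
#' @return object of class `geometry_spec`.
#' @export
geometry_spec <- function(raster_shape = c(128L, 128L), spacing_mm = 1.17,
                          lv_center = (raster_shape - 1) / 2,
                          epicardial_radius_mm = 31,
                          wall_thickness_mm = 10,
                          papillary = list(),
                          rv_crescent = list(
                            center_offset_mm = c(0, -25),
                            radius_mm = 38, gap_mm = 4.7, reach_mm = 18)) {
  if (wall_thickness_mm >= epicardial_radius_mm)
    stop("geometry error: wall thickness must be smaller than the ",
         "epicardial radius")
  if (is.null(rv_crescent))
    rv_crescent <- list(center_offset_mm = c(0, 0), radius_mm = 0,
                        gap_mm = 0, reach_mm = 0)
  structure(list(raster_shape = as.integer(raster_shape),
                 spacing_mm = spacing_mm, lv_center = lv_center,
                 epicardial_radius_mm = epicardial_radius_mm,
                 wall_thickness_mm = wall_thickness_mm,
                 papillary = papillary, rv_crescent = rv_crescent),
            class = "geometry_spec")
}

# Geometry prior: anatomy-scale jitter around a typical basal short-axis
# slice. Units mm; voxel coordinates are 0-based, voxel-center convention.
sample_geometry <- function(config) {
  epi_r <- stats::runif(1, 28, 34)
  wall <- stats::runif(1, 8, 12)
  endo_r <- epi_r - wall
  n_pap <- 2L
  pap <- vector("list", n_pap)
  base_angles <- c(110, 250) * pi / 180
  for (i in seq_len(n_pap)) {
    a <- base_angles[i] + stats::runif(1, -0.3, 0.3)
    pr <- stats::runif(1, 2.5, 4.0)
    cd <- stats::runif(1, 0.35, 0.55) * endo_r
    if (cd + pr >= endo_r) cd <- endo_r - pr - 1
    pap[[i]] <- list(center_offset_mm = c(cd * sin(a), cd * cos(a)),
                     radius_mm = pr)
  }
  structure(list(
    raster_shape = config$raster_shape,
    spacing_mm = config$spacing_mm,
    lv_center = (config$raster_shape - 1) / 2 + c(0, 8 / config$spacing_mm),
    epicardial_radius_mm = epi_r,
    wall_thickness_mm = wall,
    papillary = pap,
    # the LV-RV tissue gap must span >= 3 voxel layers everywhere at
    # 1.17 mm spacing so the one-voxel partial-volume layers on either side
    # are always separated by pure background; narrower gaps fuse the two
    # structures at raster resolution
    rv_crescent = list(center_offset_mm = c(0, -(epi_r - 6)),
                       radius_mm = epi_r + 7,
                       gap_mm = 4.7,
                       reach_mm = 18)
  ), class = "geometry_spec")
}

# Label codes for the phantom label raster.
LBL_BACKGROUND <- 0L
LBL_LV_BLOOD <- 1L
LBL_MYOCARDIUM <- 2L
LBL_RV_BLOOD <- 3L
LBL_PAPILLARY <- 4L

#' Rasterize a subject's geometry into a label raster
#'
#' A voxel belongs to a shape iff its center lies inside it; papillary discs
#' override LV cavity voxels. Codes: 0 background, 1 LV cavity blood,
#' 2 myocardium, 3 RV cavity blood, 4 papillary muscle.
#'
#' @param subject a `subject_truth` (or bare `geometry_spec`).
#' @return object of class `label_raster` with fields `labels`, `spacing_mm`.
#' @export
build_geometry <- function(subject) {
  geom <- if (inherits(subject, "geometry_spec")) subject else subject$geometry
  stopifnot(inherits(geom, "geometry_spec"))
  if (geom$wall_thickness_mm >= geom$epicardial_radius_mm)
    stop("geometry error: wall thickness must be smaller than the epicardial radius")
  shp <- geom$raster_shape
  sp <- geom$spacing_mm
  rv <- geom$rv_crescent
  rows_mm <- (seq_len(shp[1]) - 1) * sp
  cols_mm <- (seq_len(shp[2]) - 1) * sp
  cy <- geom$lv_center[1] * sp
  cx <- geom$lv_center[2] * sp
  dy <- rows_mm - cy
  dx <- cols_mm - cx
  d_lv <- sqrt(outer(dy^2, dx^2, `+`))
  endo_r <- geom$epicardial_radius_mm - geom$wall_thickness_mm
  if (geom$epicardial_radius_mm > min(cy, cx, max(rows_mm) - cy,
                                      max(cols_mm) - cx))
    stop("geometry error: epicardium exceeds raster bounds")
  if (geom$epicardial_radius_mm + rv$reach_mm >
        min(cy, cx, max(rows_mm) - cy, max(cols_mm) - cx))
    stop("geometry error: RV crescent exceeds raster bounds")
  labels <- matrix(LBL_BACKGROUND, shp[1], shp[2])
  labels[d_lv <= geom$epicardial_radius_mm] <- LBL_MYOCARDIUM
  labels[d_lv <= endo_r] <- LBL_LV_BLOOD
  # RV crescent: inside an offset disc, outside the epicardium plus a gap,
  # within a bounded reach of the LV so it stays a crescent.
  rv_cy <- cy + rv$center_offset_mm[1]
  rv_cx <- cx + rv$center_offset_mm[2]
  d_rv <- sqrt(outer((rows_mm - rv_cy)^2, (cols_mm - rv_cx)^2, `+`))
  rv_mask <- d_rv <= rv$radius_mm &
    d_lv > geom$epicardial_radius_mm + rv$gap_mm &
    d_lv <= geom$epicardial_radius_mm + rv$reach_mm
  labels[rv_mask] <- LBL_RV_BLOOD
  for (p in geom$papillary) {
    pc_y <- cy + p$center_offset_mm[1]
    pc_x <- cx + p$center_offset_mm[2]
    if (sqrt(sum(p$center_offset_mm^2)) + p$radius_mm >= endo_r)
      stop("geometry error: papillary disc not strictly inside the cavity")
    d_p <- sqrt(outer((rows_mm - pc_y)^2, (cols_mm - pc_x)^2, `+`))
    labels[d_p <= p$radius_mm & labels == LBL_LV_BLOOD] <- LBL_PAPILLARY
  }
  structure(list(labels = labels, spacing_mm = sp), class = "label_raster")
}

#' Construct a T1 map object
#'
#' @param values 2D numeric matrix of T1 values (ms).
#' @param spacing_mm isotropic voxel edge length (mm).
#' @param field field strength in tesla (1.5 or 3).
#' @param phase `"native"` or `"post"`.
#' @return object of class `t1_map`.
#' @export
t1_map <- function(values, spacing_mm, field, phase = c("native", "post")) {
  phase <- match.arg(phase)
  stopifnot(is.matrix(values), all(is.finite(values)), spacing_mm > 0)
  structure(list(values = values, spacing_mm = spacing_mm,
                 field = field, phase = phase), class = "t1_map")
}

#' Render the native/post-contrast T1 map pair for one subject
#'
#' Every voxel receives its tissue's T1 (papillary voxels get myocardial T1);
#' optionally a one-voxel boundary band mixes 50/50 with the mean adjacent
#' tissue value (partial volume), then additive Gaussian noise with SD equal
#' to `noise_sd_fraction` times the tissue value is applied and the result
#' clamped positive. Deterministic given the subject's seed.
#'
#' @param labels a `label_raster` from [build_geometry()].
#' @param subject the `subject_truth` the raster was built from.
#' @param config the originating [cohort_config()].
#' @return list with elements `native` and `post`, each a `t1_map`.
#' @export
render_t1_pair <- function(labels, subject, config) {
  stopifnot(inherits(labels, "label_raster"),
            inherits(subject, "subject_truth"))
  if (subject$t1_myo_native <= 0 || subject$t1_myo_post <= 0 ||
      subject$t1_blood_native <= 0 || subject$t1_blood_post <= 0)
    stop("rendering error: tissue T1 values must be positive")
  lut <- function(phase) {
    v <- c(config$background_t1[[phase]],
           if (phase == "native") subject$t1_blood_native else subject$t1_blood_post,
           if (phase == "native") subject$t1_myo_native else subject$t1_myo_post,
           if (phase == "native") subject$t1_blood_native else subject$t1_blood_post,
           if (phase == "native") subject$t1_myo_native else subject$t1_myo_post)
    m <- matrix(v[labels$labels + 1L], nrow(labels$labels))
    if (config$partial_volume) m <- mix_boundary_band(m, labels$labels)
    m
  }
  with_seed(subject$seed + 1L, {
    out <- list()
    for (phase in c("native", "post")) {
      vals <- lut(phase)
      if (config$noise_sd_fraction > 0) {
        noise <- stats::rnorm(length(vals), 0,
                              config$noise_sd_fraction * abs(vals))
        vals <- vals + matrix(noise, nrow(vals))
      }
      vals <- pmax(vals, 1)
      out[[phase]] <- t1_map(vals, labels$spacing_mm, subject$field, phase)
    }
    out
  })
}

# One-voxel partial-volume band: a voxel with an 8-neighbor of a different
# tissue becomes 0.5*own + 0.5*(mean T1 of the differing neighbors).
mix_boundary_band <- function(values, labels) {
  sum_diff <- matrix(0, nrow(values), ncol(values))
  cnt_diff <- matrix(0, nrow(values), ncol(values))
  for (i in seq_len(nrow(neighbor_offsets_8))) {
    lsh <- shift_matrix(labels, neighbor_offsets_8[i, 1L],
                        neighbor_offsets_8[i, 2L], fill = -1L)
    vsh <- shift_matrix(values, neighbor_offsets_8[i, 1L],
                        neighbor_offsets_8[i, 2L], fill = 0)
    differs <- lsh != labels & lsh != -1L
    sum_diff <- sum_diff + vsh * differs
    cnt_diff <- cnt_diff + differs
  }
  band <- cnt_diff > 0
  values[band] <- 0.5 * values[band] + 0.5 * (sum_diff[band] / cnt_diff[band])
  values
}

#' Generate and write a phantom cohort
#'
#' Writes per-subject native and post-contrast maps, the ground-truth label
#' raster (NIfTI with JSON sidecars) and a cohort table of covariates and
#' truths; returns a manifest. Fully reproducible from the configuration.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if missing).
#' @return manifest list (invisibly written to `manifest.json`).
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("I/O error: cannot create ", out_dir)
  rows <- vector("list", config$n_subjects)
  files <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    subj <- sample_subject(config, i)
    labels <- build_geometry(subj)
    maps <- render_t1_pair(labels, subj, config)
    base <- file.path(out_dir, subj$subject_id)
    f_native <- paste0(base, "_native.nii.gz")
    f_post <- paste0(base, "_post.nii.gz")
    f_labels <- paste0(base, "_labels.nii.gz")
    write_t1map(maps$native, f_native)
    write_t1map(maps$post, f_post)
    write_label_raster(labels, f_labels)
    files[[i]] <- list(subject_id = subj$subject_id,
                       native = basename(f_native), post = basename(f_post),
                       labels = basename(f_labels))
    rows[[i]] <- data.frame(
      subject_id = subj$subject_id, sex = subj$sex,
      field_tesla = subj$field,
      hct_true_fraction = subj$hct_true, ecv_true_fraction = subj$ecv_true,
      t1_blood_native_ms = subj$t1_blood_native,
      t1_blood_post_ms = subj$t1_blood_post,
      t1_myo_native_ms = subj$t1_myo_native,
      t1_myo_post_ms = subj$t1_myo_post,
      subject_seed = subj$seed, stringsAsFactors = FALSE)
  }
  cohort <- do.call(rbind, rows)
  table_path <- file.path(out_dir, "cohort.csv")
  write_cohort_table(cohort, table_path)
  manifest <- list(format_version = "1.0",
                   n_subjects = config$n_subjects,
                   seed = config$seed,
                   cohort_table = basename(table_path),
                   subjects = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
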