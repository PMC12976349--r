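# Optional trainable segmentation backend. The reference design uses a
# full encoder-decoder network; no deep-learning framework is available in
# the supported dependency set, so the desk-scale stand-in is a multinomial
# elastic-net pixel classifier (a 0-hidden-layer network) on z-score
# normalized intensity plus spatial features. The features [z, y, x,
# y^2 + x^2] make every class boundary a circle of arbitrary center and
# radius in image space combined with an intensity threshold -- sufficient
# for short-axis anatomy. Everything downstream treats its output exactly
# like any other backend's.

learned_features <- function(values, spacing_mm) {
  z <- (values - mean(values)) / stats::sd(values)
  nr <- nrow(values); nc <- ncol(values)
  y <- ((seq_len(nr) - 1) - (nr - 1) / 2) * spacing_mm
  x <- ((seq_len(nc) - 1) - (nc - 1) / 2) * spacing_mm
  ym <- matrix(y, nr, nc)
  xm <- matrix(x, nr, nc, byrow = TRUE)
  cbind(z = as.vector(z), y = as.vector(ym), x = as.vector(xm),
        r2 = as.vector(ym^2 + xm^2))
}

#' Train the learned segmentation backend on a phantom cohort
#'
#' Trains one model per contrast phase (native, post) on z-score normalized
#' maps with ground-truth labels, sampling a balanced set of pixels per
#' class per image. The artifact is a directory of JSON files (per-phase
#' coefficient matrices, training configuration, seed, loss) -- fully
#' deterministic given the seed.
#'
#' @param cohort_dir directory written by [generate_cohort()].
#' @param out_dir artifact directory to create.
#' @param pixels_per_class training pixels sampled per class per image.
#' @param lambda,alpha elastic-net penalty (ridge-leaning default).
#' @param seed RNG seed for pixel subsampling.
#' @return `out_dir`, invisibly.
#' @export
train_learned_backend <- function(cohort_dir, out_dir,
                                  pixels_per_class = 300L,
                                  lambda = 1e-2, alpha = 0,
                                  seed = 1L) {
  if (!requireNamespace("glmnet", quietly = TRUE))
    stop("the learned backend requires the 'glmnet' package")
  manifest <- jsonlite::read_json(file.path(cohort_dir, "manifest.json"))
  subjects <- manifest$subjects
  if (length(subjects) < 10)
    stop("training error: cohort too small (< 10 subjects)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifact <- list(backend = "learned", format_version = "1.0",
                   seed = seed, lambda = lambda, alpha = alpha,
                   pixels_per_class = pixels_per_class,
                   n_training_subjects = length(subjects))
  for (phase in c("native", "post")) {
    feats <- list(); labs <- list()
    with_seed(seed + match(phase, c("native", "post")), {
      for (s in subjects) {
        map <- read_t1map(file.path(
          cohort_dir, if (phase == "native") s$native else s$post))
        labels <- read_label_raster(file.path(cohort_dir, s$labels))
        X <- learned_features(map$values, map$spacing_mm)
        l <- as.vector(labels$labels)
        keep <- unlist(lapply(sort(unique(l)), function(cl) {
          idx <- which(l == cl)
          if (length(idx) > pixels_per_class)
            sort(sample(idx, pixels_per_class)) else idx
        }))
        feats[[length(feats) + 1L]] <- X[keep, , drop = FALSE]
        labs[[length(labs) + 1L]] <- l[keep]
      }
    })
    X <- do.call(rbind, feats)
    yl <- factor(unlist(labs), levels = 0:4)
    # decreasing lambda path for warm-started convergence; noiseless,
    # perfectly separable cohorts diverge when fit at the target penalty
    # alone
    lambda_path <- sort(unique(c(10^(0:-2), lambda)), decreasing = TRUE)
    fit <- glmnet::glmnet(X, yl, family = "multinomial", alpha = alpha,
                          lambda = lambda_path, standardize = TRUE)
    cf <- stats::coef(fit, s = lambda)
    B <- do.call(cbind, lapply(cf, function(m) as.numeric(as.matrix(m))))
    colnames(B) <- names(cf)
    rownames(B) <- c("(Intercept)", colnames(X))
    model <- list(phase = phase, classes = as.integer(names(cf)),
                  coefficients = as.data.frame(B),
                  final_deviance =
                    (1 - fit$dev.ratio[which.min(abs(fit$lambda - lambda))]) *
                    fit$nulldev,
                  n_pixels = nrow(X))
    jsonlite::write_json(model, file.path(out_dir, paste0(phase, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(artifact, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

load_learned_model <- function(artifact_dir, phase) {
  path <- file.path(artifact_dir, paste0(phase, ".json"))
  if (!file.exists(path))
    stop("usage error: artifact ", artifact_dir, " has no model for the '",
         phase, "' contrast phase")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Segment a T1 map with a trained learned backend
#'
#' Applies the phase-matched model, takes the per-pixel argmax class, and
#' post-processes into the common mask conventions: largest connected
#' component and hole filling per structure, endocardial forced inside
#' epicardial, RV disjoint from the LV region.
#'
#' @param map a `t1_map`.
#' @param artifact_dir directory written by [train_learned_backend()].
#' @return a [seg_masks()] with provenance `"learned"`.
#' @export
segment_learned <- function(map, artifact_dir) {
  stopifnot(inherits(map, "t1_map"))
  model <- load_learned_model(artifact_dir, map$phase)
  B <- as.matrix(model$coefficients)
  X <- cbind(1, learned_features(map$values, map$spacing_mm))
  scores <- X %*% B
  pred <- model$classes[max.col(scores, ties.method = "first")]
  pred <- matrix(pred, nrow(map$values))
  epi_raw <- pred %in% c(1L, 2L, 4L); dim(epi_raw) <- dim(pred)
  endo_raw <- pred %in% c(1L, 4L); dim(endo_raw) <- dim(pred)
  if (!any(epi_raw))
    stop("segmentation-failure error: learned backend predicted no LV voxels")
  epi <- fill_holes(largest_component(epi_raw))
  endo_raw <- endo_raw & epi
  if (!any(endo_raw))
    stop("segmentation-failure error: learned backend predicted no LV cavity")
  endo <- fill_holes(largest_component(endo_raw)) & epi
  rv_raw <- pred == 3L & !epi
  if (!any(rv_raw))
    stop("segmentation-failure error: learned backend predicted no RV cavity")
  rv <- largest_component(rv_raw) & !epi
  seg_masks(epicardial = epi, endocardial = endo, rv = rv,
            spacing_mm = map$spacing_mm, provenance = "learned")
}
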