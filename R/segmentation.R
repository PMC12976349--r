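# Segmentation backends. All emit the same mask triple so downstream stages
# are backend-agnostic: epicardial (full LV disc out to the epicardium),
# endocardial (LV cavity INCLUDING papillary muscles -- contour convention;
# papillary removal is the refinement stage's job), and RV cavity.

#' Construct and validate a segmentation mask triple
#'
#' @param epicardial,endocardial,rv logical matrices of equal shape.
#' @param spacing_mm voxel edge length (mm).
#' @param provenance backend tag (e.g. "oracle", "classical", "learned").
#' @return object of class `seg_masks`.
#' @export
seg_masks <- function(epicardial, endocardial, rv, spacing_mm,
                      provenance = "unknown") {
  epicardial <- as_binary_mask(epicardial)
  endocardial <- as_binary_mask(endocardial)
  rv <- as_binary_mask(rv)
  stopifnot(identical(dim(epicardial), dim(endocardial)),
            identical(dim(epicardial), dim(rv)))
  if (any(endocardial & !epicardial))
    stop("invalid masks: endocardial region must lie inside the epicardial region")
  if (any(rv & epicardial))
    stop("invalid masks: RV cavity must be disjoint from the LV region")
  structure(list(epicardial = epicardial, endocardial = endocardial,
                 rv = rv, spacing_mm = spacing_mm, provenance = provenance),
            class = "seg_masks")
}

#' Ground-truth segmentation from a phantom label raster
#'
#' Stand-in for expert contours: epicardial = LV blood + myocardium +
#' papillary; endocardial = LV blood + papillary; RV = RV blood.
#'
#' @param labels a `label_raster`.
#' @return a [seg_masks()] with provenance `"oracle"`.
#' @export
segment_oracle <- function(labels) {
  stopifnot(inherits(labels, "label_raster"))
  seg_masks_from_labelmat(labels$labels, labels$spacing_mm, "oracle")
}

# `%in%` on a matrix drops dims; seg_masks needs matrices back.
seg_masks_from_labelmat <- function(l, spacing_mm, provenance) {
  dims <- dim(l)
  as_m <- function(v) { dim(v) <- dims; v }
  seg_masks(epicardial = as_m(l %in% c(1L, 2L, 4L)),
            endocardial = as_m(l %in% c(1L, 4L)),
            rv = as_m(l == 3L),
            spacing_mm = spacing_mm, provenance = provenance)
}

#' Classical intensity-based segmentation of a native T1 map
#'
#' Model-free backend resolving three intensity classes (background <
#' myocardium < blood in native T1) with a two-stage Otsu scheme: a first
#' threshold separates tissue from background, a second -- computed on
#' tissue voxels with the one-voxel background-adjacent shell excluded, so
#' partial-volume halos cannot form a spurious mode -- separates myocardium
#' from blood. The LV cavity is the most disc-like high-T1 component; hole
#' filling re-includes papillary muscles to form the endocardial mask; the
#' myocardial ring is the intermediate class adjacent to the cavity and the
#' epicardial mask is the filled union; the RV cavity is the largest
#' remaining high-T1 component.
#'
#' @param native a native-phase `t1_map`.
#' @return a [seg_masks()] with provenance `"classical"`.
#' @export
segment_classical <- function(native) {
  stopifnot(inherits(native, "t1_map"))
  if (native$phase != "native")
    stop("usage error: the classical backend requires a native-phase map")
  v <- native$values
  ot_bg <- otsu_threshold(as.vector(v))
  if (is.null(ot_bg) || ot_bg$between_var < 0.01 * ot_bg$total_var)
    stop("segmentation-failure error: map intensity histogram is degenerate ",
         "(no tissue/background structure found)")
  tissue <- v > ot_bg$threshold
  # One-voxel partial-volume halos along tissue/background borders would
  # both pollute the myocardium/blood histogram and bridge otherwise
  # separate structures: exclude the background-adjacent shell from the
  # second-stage histogram and from component analysis, restoring it along
  # accepted structures afterwards.
  shell <- tissue & dilate_mask(!tissue)
  core_tissue <- tissue & !shell
  if (!any(core_tissue))
    stop("segmentation-failure error: no tissue interior found")
  ot_mb <- otsu_threshold(v[core_tissue])
  if (is.null(ot_mb))
    stop("segmentation-failure error: tissue histogram is degenerate")
  high <- tissue & v > ot_mb$threshold
  mid <- tissue & v <= ot_mb$threshold
  core_mid <- mid & !shell
  high_lab <- label_components(high)
  n_comp <- max(high_lab)
  if (n_comp == 0L)
    stop("segmentation-failure error: no high-T1 (blood) component found")
  # The LV cavity is the most disc-like large high-T1 component (isoperimetric
  # circularity of the hole-filled component ~1 for a disc); the RV crescent
  # scores far lower. Partial-volume halos make both borders look
  # myocardium-adjacent, so shape, not context, is the discriminator.
  score <- rep(-Inf, min(n_comp, 4L))
  for (k in seq_along(score)) {
    comp <- fill_holes(high_lab == k)
    area <- sum(comp)
    if (area < 9) next
    perim <- sum(mask_boundary(comp))
    score[k] <- 4 * pi * area / perim^2
  }
  if (!any(is.finite(score)))
    stop("segmentation-failure error: no plausible LV cavity component")
  cavity_id <- which.max(score)
  cavity <- high_lab == cavity_id
  endocardial <- fill_holes(cavity)
  ring_seed <- dilate_mask(endocardial) & core_mid
  if (!any(ring_seed))
    stop("segmentation-failure error: no myocardial ring enclosing a cavity")
  mid_lab <- label_components(core_mid)
  ring_ids <- setdiff(unique(mid_lab[ring_seed]), 0L)
  ring <- matrix(mid_lab %in% ring_ids, nrow(v))
  ring <- ring & !endocardial
  ring <- ring | (mid & dilate_mask(ring) & !endocardial)
  epicardial <- fill_holes(endocardial | ring)
  if (!any(epicardial & !endocardial))
    stop("segmentation-failure error: empty myocardial ring")
  rv_lab <- high_lab
  rv_lab[cavity] <- 0L
  rv <- largest_component(rv_lab > 0L)
  # restore the RV's one-voxel partial-volume band (mid-class voxels
  # directly adjacent to the RV core); a no-op when no band is present
  rv <- rv | (mid & dilate_mask(rv))
  rv <- rv & !epicardial
  seg_masks(epicardial = epicardial, endocardial = endocardial, rv = rv,
            spacing_mm = native$spacing_mm, provenance = "classical")
}
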