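# Low-level raster ops shared by the phantom, segmentation and refinement
# stages. All rasters are plain numeric/logical matrices, row-major voxel
# indexing, voxel-center geometry.

# Shift a matrix by (dr, dc), padding with `fill`. Used to build vectorized
# neighborhood operations without loops.
shift_matrix <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rsrc <- seq_len(nr) - dr
  csrc <- seq_len(nc) - dc
  rok <- rsrc >= 1L & rsrc <= nr
  cok <- csrc >= 1L & csrc <= nc
  out[rok, cok] <- m[rsrc[rok], csrc[cok]]
  out
}

neighbor_offsets_8 <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
)

#' Binary erosion with a 3x3 square structuring element
#'
#' A voxel is retained iff it and all 8 of its neighbors lie inside the mask;
#' positions outside the raster are treated as background, so one voxel is
#' removed alongside every margin in a single pass.
#'
#' @param mask logical (or 0/1) matrix.
#' @return logical matrix of the same shape.
#' @export
erode_mask <- function(mask) {
  mask <- as_binary_mask(mask)
  out <- mask
  for (i in seq_len(nrow(neighbor_offsets_8))) {
    out <- out & shift_matrix(mask, neighbor_offsets_8[i, 1L],
                              neighbor_offsets_8[i, 2L], fill = FALSE)
  }
  out
}

# Binary dilation with the same 3x3 element (used for adjacency queries).
dilate_mask <- function(mask) {
  mask <- as_binary_mask(mask)
  out <- mask
  for (i in seq_len(nrow(neighbor_offsets_8))) {
    out <- out | shift_matrix(mask, neighbor_offsets_8[i, 1L],
                              neighbor_offsets_8[i, 2L], fill = FALSE)
  }
  out
}

as_binary_mask <- function(mask) {
  if (is.matrix(mask) && is.logical(mask)) return(mask)
  stopifnot(is.matrix(mask))
  mask != 0
}

# Boundary voxels: in-mask voxels with at least one 8-neighbor outside the
# mask (raster edge counts as outside). By construction mask = erode | boundary.
mask_boundary <- function(mask) {
  mask <- as_binary_mask(mask)
  mask & !erode_mask(mask)
}

#' 8-connected component labeling
#'
#' Labels connected components of a binary raster by iterative minimum-label
#' propagation (vectorized; converges in at most the component diameter).
#' Components are relabeled 1..k in decreasing size order.
#'
#' @param mask logical matrix.
#' @return integer matrix; 0 outside the mask, component id inside.
#' @export
label_components <- function(mask) {
  mask <- as_binary_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(seq_len(nr * nc), nr, nc)
  lab[!mask] <- 0L
  inf_lab <- nr * nc + 1L
  repeat {
    m <- lab
    m[!mask] <- inf_lab
    best <- m
    for (i in seq_len(nrow(neighbor_offsets_8))) {
      best <- pmin(best, shift_matrix(m, neighbor_offsets_8[i, 1L],
                                      neighbor_offsets_8[i, 2L],
                                      fill = inf_lab))
    }
    best[!mask] <- 0L
    if (identical(best, lab)) break
    lab <- best
  }
  ids <- setdiff(unique(as.vector(lab)), 0L)
  if (length(ids) == 0L) return(matrix(0L, nr, nc))
  sizes <- vapply(ids, function(i) sum(lab == i), integer(1))
  ids <- ids[order(sizes, decreasing = TRUE)]
  out <- matrix(0L, nr, nc)
  for (k in seq_along(ids)) out[lab == ids[k]] <- k
  out
}

# Largest 8-connected component of a mask (empty mask -> empty mask).
largest_component <- function(mask) {
  lab <- label_components(mask)
  lab == 1L & as_binary_mask(mask)
}

# Fill holes: background regions not 8-connected to the raster border become
# part of the mask.
fill_holes <- function(mask) {
  mask <- as_binary_mask(mask)
  bg <- !mask
  lab <- label_components(bg)
  border_ids <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_ids <- setdiff(border_ids, 0L)
  outside <- lab %in% border_ids
  dim(outside) <- dim(mask)
  mask | (bg & !outside)
}
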