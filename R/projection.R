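#' Detect nuclei in 3D as projection anchors
#'
#' Thresholds the nuclei channel (Otsu over the full 3D histogram), labels
#' 6-connected components, discards those smaller than `min_volume_vox`, and
#' returns the intensity-weighted centroid of each surviving component. The
#' axial centroid, in micrometres, is the anchor used by [local_projection()]
#' to pick in-focus planes under tissue curvature.
#'
#' @param stack a [tissue_stack()] with a `nuclei` channel role.
#' @param min_volume_vox minimum component volume in voxels.
#' @return data.frame of class `nucleus_anchors` with columns `nucleus_id`,
#'   `x_px`, `y_px`, `z_um`, `volume_vox`, ordered deterministically by the
#'   raster position of each component's first voxel. Zero rows if nothing is
#'   detected (the caller decides the fallback).
#' @export
locate_nuclei_3d <- function(stack, min_volume_vox = 27L) {
  stopifnot(inherits(stack, "tissue_stack"))
  nuc <- stack$voxels[, , , channel_of(stack, "nuclei"), drop = TRUE]
  if (length(dim(nuc)) != 3L) nuc <- array(nuc, dim(stack$voxels)[1:3])
  thr <- otsu_threshold(nuc)
  mask <- nuc > thr
  empty <- data.frame(
    nucleus_id = integer(0), x_px = numeric(0), y_px = numeric(0),
    z_um = numeric(0), volume_vox = integer(0)
  )
  class(empty) <- c("nucleus_anchors", "data.frame")
  if (!any(mask)) return(empty)
  lab <- label_components_3d(mask)
  ids <- lab[lab > 0L]
  vol <- tabulate(ids)
  keep <- which(vol >= min_volume_vox)
  if (length(keep) == 0L) return(empty)

  dm <- dim(nuc)
  idx <- which(lab > 0L)
  comp <- lab[idx]
  sel <- comp %in% keep
  idx <- idx[sel]; comp <- comp[sel]
  w <- nuc[idx]
  ## array index -> (y, x, z), 1-based
  yy <- ((idx - 1L) %% dm[1]) + 1L
  xx <- (((idx - 1L) %/% dm[1]) %% dm[2]) + 1L
  zz <- ((idx - 1L) %/% (dm[1] * dm[2])) + 1L
  f <- factor(comp, levels = keep)
  wsum <- as.vector(tapply(w, f, sum))
  anchors <- data.frame(
    nucleus_id = seq_along(keep),
    x_px = as.vector(tapply(w * xx, f, sum)) / wsum,
    y_px = as.vector(tapply(w * yy, f, sum)) / wsum,
    z_um = (as.vector(tapply(w * zz, f, sum)) / wsum - 1) * stack$z_spacing_um,
    volume_vox = vol[keep]
  )
  ## components from label_components_3d are already numbered in raster order
  class(anchors) <- c("nucleus_anchors", "data.frame")
  anchors
}

#' Curvature-aware local z-projection anchored on the nearest nucleus
#'
#' For every pixel, the anchor is the nearest detected nucleus in the xy plane
#' (ties to the smaller `nucleus_id`); the projection window is every plane
#' whose physical z lies within `thickness_um / 2` of that nucleus's axial
#' position, or the single nearest plane when none does. Both channels are
#' reduced over the window with `reducer`. Because each pixel follows its local
#' nucleus, the projection tracks a curved (domed) epithelial surface that a
#' fixed mid-stack projection would cut through.
#'
#' @param stack a [tissue_stack()].
#' @param anchors a `nucleus_anchors` data.frame from [locate_nuclei_3d()].
#' @param thickness_um axial thickness of the projected section (> 0).
#' @param reducer one of `"max"`, `"mean"`, `"sum"`.
#' @return object of class `surface_projection`: list with `image`
#'   (array `[y, x, channel]`), `anchor_map` (nucleus_id per pixel),
#'   `window_lo` / `window_hi` (plane indices per pixel), `channel_roles`,
#'   `pixel_size_um`.
#' @export
local_projection <- function(stack, anchors, thickness_um = 1,
                             reducer = c("max", "mean", "sum")) {
  stopifnot(inherits(stack, "tissue_stack"), thickness_um > 0)
  reducer <- match.arg(reducer)
  if (!is.data.frame(anchors) || nrow(anchors) == 0L) {
    stop("no nucleus anchors available; fall back to a global mid-stack ",
         "projection (see midstack_projection())")
  }
  dm <- dim(stack$voxels)
  ny <- dm[1]; nx <- dm[2]; nz <- dm[3]; nc <- dm[4]
  zs <- plane_z_um(stack)

  amap <- nearest_site_map(ny, nx, anchors$x_px, anchors$y_px)
  amap <- matrix(anchors$nucleus_id[amap], ny, nx)

  ## per anchor: plane window; group anchors sharing a window
  win_of <- lapply(seq_len(nrow(anchors)), function(i) {
    w <- which(abs(zs - anchors$z_um[i]) <= thickness_um / 2 + 1e-9)
    if (length(w) == 0L) w <- which.min(abs(zs - anchors$z_um[i]))
    w
  })
  win_key <- vapply(win_of, paste, character(1), collapse = ",")
  img <- array(0, c(ny, nx, nc))
  window_lo <- matrix(0L, ny, nx)
  window_hi <- matrix(0L, ny, nx)
  for (key in unique(win_key)) {
    ids <- anchors$nucleus_id[win_key == key]
    w <- win_of[[match(key, win_key)]]
    pix <- amap %in% ids
    for (ch in seq_len(nc)) {
      red <- reduce_planes(stack$voxels, w, ch, reducer)
      layer <- img[, , ch]
      layer[pix] <- red[pix]
      img[, , ch] <- layer
    }
    window_lo[pix] <- min(w)
    window_hi[pix] <- max(w)
  }
  structure(
    list(
      image = img,
      anchor_map = amap,
      window_lo = window_lo,
      window_hi = window_hi,
      channel_roles = stack$channel_roles,
      pixel_size_um = stack$pixel_size_um
    ),
    class = "surface_projection"
  )
}

#' Fixed mid-stack projection (baseline for comparison)
#'
#' Projects a window of the same thickness centred on the stack's axial
#' midpoint at every pixel, ignoring curvature. This is the naive alternative
#' that loses off-apex nuclei on domed tissue.
#' @inheritParams local_projection
#' @return a `surface_projection` (anchor_map all zero).
#' @export
midstack_projection <- function(stack, thickness_um = 1,
                                reducer = c("max", "mean", "sum")) {
  stopifnot(inherits(stack, "tissue_stack"))
  reducer <- match.arg(reducer)
  dm <- dim(stack$voxels)
  zs <- plane_z_um(stack)
  zmid <- (zs[1] + zs[length(zs)]) / 2
  w <- which(abs(zs - zmid) <= thickness_um / 2 + 1e-9)
  if (length(w) == 0L) w <- which.min(abs(zs - zmid))
  img <- array(0, c(dm[1], dm[2], dm[4]))
  for (ch in seq_len(dm[4])) {
    img[, , ch] <- reduce_planes(stack$voxels, w, ch, reducer)
  }
  structure(
    list(
      image = img,
      anchor_map = matrix(0L, dm[1], dm[2]),
      window_lo = matrix(min(w), dm[1], dm[2]),
      window_hi = matrix(max(w), dm[1], dm[2]),
      channel_roles = stack$channel_roles,
      pixel_size_um = stack$pixel_size_um
    ),
    class = "surface_projection"
  )
}

#' @export
print.surface_projection <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<surface_projection> %d x %d px, %d channel(s), %d anchor(s)\n",
              d[1], d[2], d[3], length(unique(x$anchor_map[x$anchor_map > 0]))))
  invisible(x)
}

## plane-wise reduction of voxels[, , w, ch] without apply() overhead
reduce_planes <- function(voxels, w, ch, reducer) {
  slices <- lapply(w, function(k) voxels[, , k, ch])
  switch(reducer,
    max = Reduce(pmax, slices),
    sum = Reduce(`+`, slices),
    mean = Reduce(`+`, slices) / length(slices)
  )
}

proj_channel <- function(projection, role) {
  idx <- projection$channel_roles[[role]]
  if (is.null(idx)) stop(sprintf("projection has no '%s' channel role", role))
  projection$image[, , idx]
}
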