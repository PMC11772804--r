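#' Construct a tissue stack
#'
#' A `tissue_stack` is the pipeline's raw input: a calibrated multi-channel 3D
#' fluorescence image. Voxels are stored as a 4D array indexed
#' `[y, x, z, channel]` (1-based, column-major, the natural R layout); physical
#' z of plane `k` is `(k - 1) * z_spacing_um`.
#'
#' @param voxels 4D non-negative numeric array `[y, x, z, channel]`.
#' @param pixel_size_um lateral pixel size in micrometres (> 0).
#' @param z_spacing_um axial plane spacing in micrometres (> 0).
#' @param channel_roles named integer vector mapping role names (for tissue
#'   stacks, `membrane` and `nuclei`) to channel indices.
#' @return object of class `tissue_stack`.
#' @export
tissue_stack <- function(voxels, pixel_size_um, z_spacing_um, channel_roles) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 4L)
  if (any(voxels < 0)) stop("voxel intensities must be non-negative")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be > 0")
  }
  if (!is.numeric(z_spacing_um) || z_spacing_um <= 0) {
    stop("z_spacing_um must be > 0")
  }
  roles <- as.integer(channel_roles)
  names(roles) <- names(channel_roles)
  if (is.null(names(roles)) || any(!nzchar(names(roles)))) {
    stop("channel_roles must be a named vector")
  }
  if (anyDuplicated(roles)) stop("channel roles must map to distinct channels")
  if (any(roles < 1L | roles > dim(voxels)[4])) {
    stop("channel_roles index outside the channel dimension")
  }
  structure(
    list(
      voxels = voxels,
      pixel_size_um = pixel_size_um,
      z_spacing_um = z_spacing_um,
      channel_roles = roles
    ),
    class = "tissue_stack"
  )
}

#' @export
print.tissue_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<tissue_stack> %d x %d px, %d planes, %d channel(s) [%s]\n",
    d[1], d[2], d[3], d[4],
    paste(sprintf("%s=%d", names(x$channel_roles), x$channel_roles),
          collapse = ", ")
  ))
  cat(sprintf("  pixel %.3g um, z-step %.3g um\n",
              x$pixel_size_um, x$z_spacing_um))
  invisible(x)
}

#' Physical z positions (um) of the planes of a stack
#' @param stack a `tissue_stack`.
#' @return numeric vector of length `n_planes`.
#' @export
plane_z_um <- function(stack) {
  (seq_len(dim(stack$voxels)[3]) - 1) * stack$z_spacing_um
}

channel_of <- function(stack, role) {
  idx <- stack$channel_roles[[role]]
  if (is.null(idx)) stop(sprintf("stack has no '%s' channel role", role))
  idx
}

#' Write a tissue stack as multi-page TIFF plus a JSON sidecar
#'
#' Pages are channel-major: all planes of channel 1 (in z order), then all
#' planes of channel 2, and so on. Intensities are rescaled to \[0, 1\] for
#' 32-bit float TIFF storage; the scale factor is recorded in the sidecar and
#' undone by [read_tissue_stack()].
#'
#' @param stack a `tissue_stack`.
#' @param tiff_path output TIFF path; the sidecar is written next to it as
#'   `<path>.json` unless `json_path` is given.
#' @param json_path optional explicit sidecar path.
#' @param extra named list merged into the sidecar (e.g. the generator seed).
#' @return invisibly, the sidecar path.
#' @export
write_tissue_stack <- function(stack, tiff_path, json_path = NULL, extra = list()) {
  stopifnot(inherits(stack, "tissue_stack"))
  json_path <- json_path %||% paste0(tiff_path, ".json")
  d <- dim(stack$voxels)
  scale <- max(stack$voxels, 1e-12)
  pages <- list()
  for (ch in seq_len(d[4])) {
    for (k in seq_len(d[3])) {
      pages[[length(pages) + 1L]] <- stack$voxels[, , k, ch] / scale
    }
  }
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32L)
  meta <- c(
    list(
      pixel_size_um = stack$pixel_size_um,
      z_spacing_um = stack$z_spacing_um,
      n_planes = d[3],
      n_channels = d[4],
      channel_roles = as.list(stack$channel_roles),
      intensity_scale = scale,
      page_order = "channel-major (all z of channel 1, then channel 2, ...)"
    ),
    extra
  )
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(json_path)
}

#' Read a tissue stack written by [write_tissue_stack()]
#' @param tiff_path TIFF path.
#' @param json_path sidecar path (default `<tiff_path>.json`).
#' @return a `tissue_stack`.
#' @export
read_tissue_stack <- function(tiff_path, json_path = NULL) {
  json_path <- json_path %||% paste0(tiff_path, ".json")
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  nz <- meta$n_planes
  nc <- meta$n_channels
  stopifnot(length(pages) == nz * nc)
  dmat <- dim(pages[[1]])
  vox <- array(0, c(dmat[1], dmat[2], nz, nc))
  i <- 1L
  for (ch in seq_len(nc)) {
    for (k in seq_len(nz)) {
      vox[, , k, ch] <- pages[[i]] * meta$intensity_scale
      i <- i + 1L
    }
  }
  roles <- unlist(meta$channel_roles)
  tissue_stack(vox, meta$pixel_size_um, meta$z_spacing_um, roles)
}

#' Write / read an integer label image as 16-bit TIFF
#'
#' Used for cell and nucleus label maps so that a manually corrected map can be
#' dropped back into the pipeline in place of the automatic one.
#' @param labels integer matrix (0 = background), values < 65536.
#' @param path file path.
#' @return `write_label_tiff` invisibly returns `path`; `read_label_tiff`
#'   returns the integer matrix.
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot(is.matrix(labels), max(labels) < 65536L)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
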