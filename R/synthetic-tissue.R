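#' Specification of a synthetic epithelial tissue stack
#'
#' Bundles and validates the parameters of the tissue simulator. The defaults
#' describe a stage-10-like follicular monolayer: a 224 um field of ~400
#' polygonal cells about 11 um across, imaged at 0.5 um/px with 1 um optical
#' sections, whose surface bulges 4 um from edge to apex so nuclear z-position
#' follows tissue curvature.
#'
#' @param field_size_px integer (ny, nx) frame size in pixels.
#' @param n_planes number of z planes.
#' @param pixel_size_um,z_spacing_um physical calibration (> 0).
#' @param n_cells_target number of cells after merging (>= 4).
#' @param multinucleation_fraction fraction of cells carrying >= 2 nuclei, in
#'   \[0, 1\]. The realised count is `round(fraction * n_cells_target)` and is
#'   recorded in the ground truth.
#' @param nuclei_per_multi_cell nuclei per multinucleated cell (>= 2).
#' @param curvature_sag_um peak-to-edge z offset of the dome surface (>= 0).
#' @param membrane_width_px drawn membrane thickness in pixels.
#' @param nucleus_radius_um nuclear radius; blobs are rendered as 3D Gaussians
#'   with sigma = radius / 2.
#' @param psf_sigma_px in-plane point-spread blur sigma (0 disables).
#' @param poisson_scale photon scale of the Poisson shot-noise model (0
#'   disables); intensities are drawn as `rpois(scale * I) / scale`.
#' @param gaussian_sd additive Gaussian read-noise sd (0 disables).
#' @param seed integer RNG seed; the whole stack is deterministic given it.
#' @return validated list of class `tissue_spec`.
#' @export
tissue_spec <- function(field_size_px = c(448L, 448L),
                        n_planes = 12L,
                        pixel_size_um = 0.5,
                        z_spacing_um = 1,
                        n_cells_target = 400L,
                        multinucleation_fraction = 0,
                        nuclei_per_multi_cell = 2L,
                        curvature_sag_um = 4,
                        membrane_width_px = 2,
                        nucleus_radius_um = 2.2,
                        psf_sigma_px = 1,
                        poisson_scale = 200,
                        gaussian_sd = 0.01,
                        seed = 1L) {
  spec <- list(
    field_size_px = as.integer(field_size_px),
    n_planes = as.integer(n_planes),
    pixel_size_um = pixel_size_um,
    z_spacing_um = z_spacing_um,
    n_cells_target = as.integer(n_cells_target),
    multinucleation_fraction = multinucleation_fraction,
    nuclei_per_multi_cell = as.integer(nuclei_per_multi_cell),
    curvature_sag_um = curvature_sag_um,
    membrane_width_px = membrane_width_px,
    nucleus_radius_um = nucleus_radius_um,
    psf_sigma_px = psf_sigma_px,
    poisson_scale = poisson_scale,
    gaussian_sd = gaussian_sd,
    seed = as.integer(seed)
  )
  with(spec, {
    stopifnot(
      length(field_size_px) == 2L, all(field_size_px >= 16L),
      n_planes >= 2L, pixel_size_um > 0, z_spacing_um > 0,
      n_cells_target >= 4L,
      multinucleation_fraction >= 0, multinucleation_fraction <= 1,
      nuclei_per_multi_cell >= 2L,
      curvature_sag_um >= 0, membrane_width_px > 0, nucleus_radius_um > 0,
      psf_sigma_px >= 0, poisson_scale >= 0, gaussian_sd >= 0
    )
  })
  class(spec) <- "tissue_spec"
  spec
}

## Dome surface height (um) above the bottom plane, clipped paraboloid.
surface_z_um <- function(x_px, y_px, spec) {
  ny <- spec$field_size_px[1]
  nx <- spec$field_size_px[2]
  z_span <- (spec$n_planes - 1) * spec$z_spacing_um
  z_edge <- (z_span - spec$curvature_sag_um) / 2
  rx <- (x_px - (nx + 1) / 2) / (nx / 2)
  ry <- (y_px - (ny + 1) / 2) / (ny / 2)
  z_edge + spec$curvature_sag_um * pmax(0, 1 - (rx^2 + ry^2))
}

#' Simulate a two-channel epithelial tissue stack with ground truth
#'
#' Builds a curved monolayer as a Voronoi tessellation of jittered-grid seeds:
#' the membrane channel is the tessellation boundary, drawn on the planes that
#' intersect the local dome surface; the nuclei channel holds one 3D Gaussian
#' blob per nucleus, centred on the surface. Multinucleated cells are rendered
#' by merging adjacent seed cells and dropping their shared membrane, so they
#' are larger and carry one nucleus per constituent, mimicking the product of a
#' failed cytokinesis. PSF blur, Poisson shot noise and Gaussian read noise are
#' then applied.
#'
#' @param spec a [tissue_spec()].
#' @return list with elements `stack` (a [tissue_stack()], channels
#'   `membrane` = 1 and `nuclei` = 2) and `truth` (a `ground_truth`: the cell
#'   label matrix, nucleus table and multinucleation flags).
#' @export
generate_epithelium_stack <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  ny <- spec$field_size_px[1]
  nx <- spec$field_size_px[2]
  n_multi <- round(spec$multinucleation_fraction * spec$n_cells_target)
  k_nuc <- spec$nuclei_per_multi_cell
  n_seeds <- spec$n_cells_target + n_multi * (k_nuc - 1L)
  mean_diam <- sqrt(ny * nx / n_seeds)
  if (mean_diam < 4) {
    stop(sprintf(
      "field %dx%d px too small for %d cells (mean cell diameter %.1f px < 4)",
      ny, nx, n_seeds, mean_diam
    ))
  }
  z_span <- (spec$n_planes - 1) * spec$z_spacing_um
  if (spec$curvature_sag_um > z_span) {
    stop("curvature_sag_um exceeds the axial extent of the stack")
  }

  with_seed(spec$seed, {
    ## --- jittered-grid seed sites ------------------------------------------
    ncol_g <- max(2L, round(sqrt(n_seeds * nx / ny)))
    nrow_g <- ceiling(n_seeds / ncol_g)
    gx <- (rep(seq_len(ncol_g), times = nrow_g) - 0.5) * nx / ncol_g
    gy <- (rep(seq_len(nrow_g), each = ncol_g) - 0.5) * ny / nrow_g
    jx <- runif(length(gx), -0.35, 0.35) * nx / ncol_g
    jy <- runif(length(gy), -0.35, 0.35) * ny / nrow_g
    keep <- sort(sample.int(length(gx), n_seeds))
    sx <- pmin(pmax(gx[keep] + jx[keep], 1), nx)
    sy <- pmin(pmax(gy[keep] + jy[keep], 1), ny)

    seed_lab <- nearest_site_map(ny, nx, sx, sy)

    ## --- merge seed-cell groups into multinucleated cells ------------------
    ## Partners are the unused neighbours sharing the longest membrane facet,
    ## so merged cells are compact (real multinucleated cells are larger and
    ## roundish, not dumbbells pinched at a sliver of shared boundary).
    facet <- label_facet_lengths(seed_lab)
    min_facet <- 6L
    group_of <- seq_len(n_seeds)          # seed cell -> final group root
    merged <- rep(FALSE, n_seeds)
    if (n_multi > 0L) {
      order_try <- sample.int(n_seeds)
      made <- 0L
      for (s in order_try) {
        if (made >= n_multi) break
        if (merged[s]) next
        nb_len <- facet[[s]]
        nb_len <- nb_len[!(as.integer(names(nb_len)) %in% which(merged)) &
                           nb_len >= min_facet]
        if (length(nb_len) < k_nuc - 1L) next
        partners <- as.integer(names(sort(nb_len, decreasing = TRUE)))[
          seq_len(k_nuc - 1L)]
        grp <- c(s, partners)
        merged[grp] <- TRUE
        group_of[grp] <- min(grp)
        made <- made + 1L
      }
      if (made < n_multi) {
        stop("could not place the requested number of multinucleated cells; ",
             "increase n_cells_target or lower multinucleation_fraction")
      }
    }
    roots <- sort(unique(group_of))
    cell_id_of_seed <- match(group_of, roots)     # seed cell -> cell id 1..n
    n_cells <- length(roots)
    cell_lab <- matrix(cell_id_of_seed[seed_lab], ny, nx)
    is_multi <- as.vector(table(factor(cell_id_of_seed,
                                       levels = seq_len(n_cells)))) >= 2L

    ## --- nuclei: one per seed cell, at its region centroid on the surface --
    g <- pixel_grid(ny, nx)
    fseed <- factor(as.vector(seed_lab), levels = seq_len(n_seeds))
    cx <- as.vector(tapply(as.vector(g$x), fseed, mean))
    cy <- as.vector(tapply(as.vector(g$y), fseed, mean))
    if (anyNA(cx)) stop("degenerate tessellation: a seed cell owns no pixels")
    nz_um <- surface_z_um(cx, cy, spec)
    nuclei <- data.frame(
      nucleus_id = seq_len(n_seeds),
      cell_id = cell_id_of_seed,
      x_px = cx, y_px = cy, z_um = nz_um
    )
    nuclei <- nuclei[order(nuclei$cell_id, nuclei$nucleus_id), ]
    nuclei$nucleus_id <- seq_len(nrow(nuclei))
    rownames(nuclei) <- NULL

    ## --- render channels ----------------------------------------------------
    zs <- (seq_len(spec$n_planes) - 1) * spec$z_spacing_um
    surf <- matrix(surface_z_um(as.vector(g$x), as.vector(g$y), spec), ny, nx)

    boundary <- cell_lab != rbind(cell_lab[-1, ], cell_lab[ny, ]) |
      cell_lab != cbind(cell_lab[, -1], cell_lab[, nx])
    brush_size <- max(3L, 2L * floor(spec$membrane_width_px / 2) + 1L)
    boundary <- EBImage::dilate(
      EBImage::Image(boundary * 1),
      EBImage::makeBrush(brush_size, "disc")
    )
    boundary <- matrix(as.numeric(boundary) > 0, ny, nx)

    mem <- array(0, c(ny, nx, spec$n_planes))
    for (k in seq_len(spec$n_planes)) {
      on_surface <- abs(zs[k] - surf) <= spec$z_spacing_um + 1e-9
      mem[, , k] <- (boundary & on_surface) * 1.0
    }

    nuc <- array(0, c(ny, nx, spec$n_planes))
    sig_xy <- spec$nucleus_radius_um / 2 / spec$pixel_size_um
    sig_z <- spec$nucleus_radius_um / 2
    half <- ceiling(3 * sig_xy)
    for (i in seq_len(nrow(nuclei))) {
      x0 <- nuclei$x_px[i]; y0 <- nuclei$y_px[i]; z0 <- nuclei$z_um[i]
      xi <- max(1L, floor(x0 - half)):min(nx, ceiling(x0 + half))
      yi <- max(1L, floor(y0 - half)):min(ny, ceiling(y0 + half))
      gy2 <- exp(-((yi - y0)^2) / (2 * sig_xy^2))
      gx2 <- exp(-((xi - x0)^2) / (2 * sig_xy^2))
      blob_xy <- outer(gy2, gx2)
      gz <- exp(-((zs - z0)^2) / (2 * sig_z^2))
      for (k in which(gz > 1e-3)) {
        nuc[yi, xi, k] <- nuc[yi, xi, k] + blob_xy * gz[k]
      }
    }

    background <- 0.02
    vox <- array(0, c(ny, nx, spec$n_planes, 2L))
    vox[, , , 1L] <- mem + background
    vox[, , , 2L] <- nuc + background

    if (spec$psf_sigma_px > 0) {
      for (ch in 1:2) for (k in seq_len(spec$n_planes)) {
        vox[, , k, ch] <- as.matrix(EBImage::gblur(
          EBImage::Image(vox[, , k, ch]), sigma = spec$psf_sigma_px
        ))
      }
    }
    if (spec$poisson_scale > 0) {
      vox[] <- rpois(length(vox), spec$poisson_scale * vox) /
        spec$poisson_scale
    }
    if (spec$gaussian_sd > 0) {
      vox[] <- vox + rnorm(length(vox), 0, spec$gaussian_sd)
    }
    vox[vox < 0] <- 0

    stack <- tissue_stack(vox, spec$pixel_size_um, spec$z_spacing_um,
                          c(membrane = 1L, nuclei = 2L))
    truth <- structure(
      list(
        cell_labels = cell_lab,
        nuclei = nuclei,
        is_multinucleated = is_multi,
        n_multinucleated = n_multi,
        spec = spec
      ),
      class = "ground_truth"
    )
    list(stack = stack, truth = truth)
  })
}

## shared-facet lengths of a label matrix (4-connectivity): for each label, a
## named integer vector of adjacent labels -> number of touching pixel pairs
label_facet_lengths <- function(lab) {
  ny <- nrow(lab); nx <- ncol(lab)
  a <- c(lab[-ny, ], lab[, -nx])
  b <- c(lab[-1, ], lab[, -1])
  keep <- a != b
  a2 <- c(a[keep], b[keep])
  b2 <- c(b[keep], a[keep])
  counts <- table(a2, b2)
  lapply(seq_len(max(lab)), function(s) {
    if (!(as.character(s) %in% rownames(counts))) return(integer(0))
    v <- counts[as.character(s), ]
    v <- v[v > 0]
    out <- as.integer(v)
    names(out) <- names(v)
    out
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d cells (%d multinucleated), %d nuclei\n",
    length(x$is_multinucleated), x$n_multinucleated, nrow(x$nuclei)
  ))
  invisible(x)
}

#' Write simulator ground truth to disk
#'
#' Nuclei and per-cell flags go to CSV; the true cell tessellation to a 16-bit
#' label TIFF.
#' @param truth a `ground_truth`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, the written paths.
#' @export
write_ground_truth <- function(truth, dir, prefix = "truth") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_nuc <- file.path(dir, paste0(prefix, "_nuclei.csv"))
  p_cell <- file.path(dir, paste0(prefix, "_cells.csv"))
  p_lab <- file.path(dir, paste0(prefix, "_cell_labels.tif"))
  write.csv(truth$nuclei, p_nuc, row.names = FALSE)
  write.csv(
    data.frame(cell_id = seq_along(truth$is_multinucleated),
               is_multinucleated = truth$is_multinucleated),
    p_cell, row.names = FALSE
  )
  write_label_tiff(truth$cell_labels, p_lab)
  invisible(c(nuclei = p_nuc, cells = p_cell, labels = p_lab))
}
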