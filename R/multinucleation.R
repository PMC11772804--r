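#' Select the central region of interest of the epithelium
#'
#' Quantification is restricted to the centre of the field because cells at the
#' edge of a curved egg chamber can lose their membrane or nucleus from the
#' projection window. Two modes: `"rectangle"` (default) shrinks the frame by
#' `margin_fraction` per side; `"adaptive"` takes the Otsu foreground of the
#' membrane channel, fills it, and erodes it by `margin_fraction` of its
#' equivalent radius.
#'
#' @param projection a `surface_projection`.
#' @param margin_fraction fraction in \[0, 0.5) removed per side (rectangle) or
#'   of the equivalent radius (adaptive).
#' @param mode `"rectangle"` or `"adaptive"`.
#' @return logical matrix mask; all downstream operations honour it.
#' @export
select_central_roi <- function(projection, margin_fraction = 0.2,
                               mode = c("rectangle", "adaptive")) {
  stopifnot(inherits(projection, "surface_projection"),
            margin_fraction >= 0, margin_fraction < 0.5)
  mode <- match.arg(mode)
  d <- dim(projection$image)
  ny <- d[1]; nx <- d[2]
  if (mode == "rectangle") {
    my <- floor(ny * margin_fraction)
    mx <- floor(nx * margin_fraction)
    roi <- matrix(FALSE, ny, nx)
    roi[(my + 1):(ny - my), (mx + 1):(nx - mx)] <- TRUE
  } else {
    mem <- proj_channel(projection, "membrane")
    thr <- otsu_threshold(mem)
    fg <- EBImage::fillHull(EBImage::Image((mem > thr) * 1))
    fg <- matrix(as.numeric(fg) > 0, ny, nx)
    r_eq <- sqrt(sum(fg) / pi)
    er <- max(1L, round(margin_fraction * r_eq))
    roi <- EBImage::erode(EBImage::Image(fg * 1),
                          EBImage::makeBrush(2L * er + 1L, "disc"))
    roi <- matrix(as.numeric(roi) > 0, ny, nx)
  }
  if (!any(roi)) stop("central ROI is empty; lower margin_fraction")
  roi
}

#' Segment epithelial cells from the membrane channel
#'
#' Smooths the membrane channel, inverts it, and floods it with a
#' tolerance-merged watershed so each catchment basin (a membrane-bounded
#' polygon) becomes one cell. Regions smaller than `min_cell_area_px` or lying
#' entirely outside the ROI are discarded. The remaining cells carry a
#' `touches_border` flag that the multinucleation statistics use to exclude
#' edge cells; two rules are available:
#'
#' * `"counting_frame"` (default): the unbiased counting-frame rule. A cell is
#'   flagged when it touches the ROI's forbidden boundary (the leftmost ROI
#'   pixel of each row and the bottommost of each column — for a rectangular
#'   ROI, its left and bottom edges) or the image frame edge; cells crossing
#'   the top/right ROI boundary are kept at full extent. Because every cell is
#'   attributed to exactly one frame position under translation, inclusion is
#'   independent of cell size — large (multinucleated) cells are not
#'   preferentially excluded.
#' * `"intersect"`: flag every cell extending beyond the ROI (simpler, but
#'   size-biased against large cells).
#'
#' @param projection a `surface_projection` with a `membrane` role.
#' @param roi logical mask from [select_central_roi()].
#' @param smooth_sigma_px Gaussian smoothing sigma before the watershed.
#' @param h watershed merge tolerance (depth, in intensity units, below which
#'   adjacent minima are merged — the h-minima depth).
#' @param min_cell_area_px minimum cell area, px.
#' @param border_rule `"counting_frame"` or `"intersect"` (see above).
#' @return object of class `cell_label_map`: list with `labels` (integer
#'   matrix over the full extent of kept cells), `cells` (data.frame
#'   `cell_id`, `area_px`, `touches_border`), `roi`, `border_rule`.
#' @export
segment_cells <- function(projection, roi, smooth_sigma_px = 2, h = 0.1,
                          min_cell_area_px = 64L,
                          border_rule = c("counting_frame", "intersect")) {
  stopifnot(inherits(projection, "surface_projection"))
  border_rule <- match.arg(border_rule)
  mem <- proj_channel(projection, "membrane")
  stopifnot(identical(dim(mem), dim(roi)))
  ny <- nrow(mem); nx <- ncol(mem)
  sm <- if (smooth_sigma_px > 0) {
    as.matrix(EBImage::gblur(EBImage::Image(mem), sigma = smooth_sigma_px))
  } else mem
  inv <- max(sm) - sm
  ws <- EBImage::watershed(EBImage::Image(inv), tolerance = h, ext = 1L)
  ws <- matrix(as.integer(ws), ny, nx)
  if (max(ws) == 0L) {
    if (diff(range(inv)) == 0) {
      ws[] <- 1L                          # boundary-free image: one region
    } else {
      stop("watershed produced no regions; review parameters")
    }
  }

  frame_edge <- matrix(FALSE, ny, nx)
  frame_edge[1, ] <- frame_edge[ny, ] <- TRUE
  frame_edge[, 1] <- frame_edge[, nx] <- TRUE

  ids <- seq_len(max(ws))
  f <- factor(ws, levels = ids)
  inside_area <- as.vector(tapply(as.vector(roi), f, sum))
  inside_area[is.na(inside_area)] <- 0
  total_area <- tabulate(ws, nbins = max(ws))
  forbidden <- if (border_rule == "counting_frame") {
    forbidden_boundary(roi) | frame_edge
  } else {
    !roi | frame_edge
  }
  border_any <- as.vector(tapply(as.vector(forbidden), f, any))
  border_any[is.na(border_any)] <- FALSE

  keep <- which(total_area >= min_cell_area_px & inside_area > 0)
  if (length(keep) == 0L) {
    stop("no cell regions of at least min_cell_area_px inside the ROI; ",
         "review smoothing sigma, h, or the ROI margin")
  }
  remap <- integer(max(ws) + 1L)          # index ws + 1 so 0 stays background
  remap[keep + 1L] <- seq_along(keep)
  labels <- matrix(remap[ws + 1L], ny, nx)

  cells <- data.frame(
    cell_id = seq_along(keep),
    area_px = as.integer(total_area[keep]),
    touches_border = border_any[keep]
  )
  structure(list(labels = labels, cells = cells, roi = roi,
                 border_rule = border_rule),
            class = "cell_label_map")
}

## forbidden boundary of an ROI mask for the counting-frame rule: the leftmost
## ROI pixel of every row plus the bottommost (largest y) of every column.
forbidden_boundary <- function(roi) {
  ny <- nrow(roi); nx <- ncol(roi)
  out <- matrix(FALSE, ny, nx)
  for (r in seq_len(ny)) {
    w <- which(roi[r, ])
    if (length(w)) out[r, w[1]] <- TRUE
  }
  for (c in seq_len(nx)) {
    w <- which(roi[, c])
    if (length(w)) out[w[length(w)], c] <- TRUE
  }
  out
}

#' Segment nuclei in the projected image
#'
#' Otsu threshold on the nuclei channel, hole filling, then a
#' distance-transform watershed to split touching nuclei; objects below
#' `min_area_px` are removed. By default the whole frame is segmented so that
#' cells crossing the ROI's inclusion edges still get all their nuclei; pass a
#' mask to restrict.
#'
#' @param projection a `surface_projection` with a `nuclei` role.
#' @param roi logical mask, or `NULL` (default) for the full frame.
#' @param min_area_px minimum nucleus area, px.
#' @param split_tolerance watershed merge tolerance on the distance map
#'   (pixels); smaller values split more aggressively.
#' @return object of class `nuclei_label_map`: list with `labels` and
#'   `centroids` (data.frame `nucleus_id`, `y_px`, `x_px`, `area_px`). Empty
#'   map (zero rows) if nothing is found.
#' @export
segment_nuclei <- function(projection, roi = NULL, min_area_px = 16L,
                           split_tolerance = 1) {
  stopifnot(inherits(projection, "surface_projection"))
  nuc <- proj_channel(projection, "nuclei")
  if (is.null(roi)) roi <- matrix(TRUE, nrow(nuc), ncol(nuc))
  stopifnot(identical(dim(nuc), dim(roi)))
  ny <- nrow(nuc); nx <- ncol(nuc)
  masked <- nuc
  masked[!roi] <- 0
  thr <- otsu_threshold(masked[roi])
  mask <- masked > thr
  empty <- structure(
    list(labels = matrix(0L, ny, nx),
         centroids = data.frame(nucleus_id = integer(0), y_px = numeric(0),
                                x_px = numeric(0), area_px = integer(0))),
    class = "nuclei_label_map"
  )
  if (!any(mask)) return(empty)
  mask <- EBImage::fillHull(EBImage::Image(mask * 1))
  dm <- EBImage::distmap(mask)
  ws <- EBImage::watershed(dm, tolerance = split_tolerance, ext = 1L)
  ws <- matrix(as.integer(ws), ny, nx)
  sizes <- tabulate(ws[ws > 0L])
  keep <- which(sizes >= min_area_px)
  if (length(keep) == 0L) return(empty)
  remap <- integer(max(ws) + 1L)
  remap[keep + 1L] <- seq_along(keep)
  labels <- matrix(remap[ws + 1L], ny, nx)
  g <- pixel_grid(ny, nx)
  f <- factor(labels[labels > 0L], levels = seq_along(keep))
  centroids <- data.frame(
    nucleus_id = seq_along(keep),
    y_px = as.vector(tapply(g$y[labels > 0L], f, mean)),
    x_px = as.vector(tapply(g$x[labels > 0L], f, mean)),
    area_px = as.integer(tabulate(labels[labels > 0L], length(keep)))
  )
  structure(list(labels = labels, centroids = centroids),
            class = "nuclei_label_map")
}

#' Count nuclei per segmented cell
#'
#' Each nucleus is assigned to the cell label under its centroid; centroids
#' falling on background are left unassigned and reported in the
#' `unassigned_nuclei` attribute.
#'
#' @param cells a `cell_label_map`.
#' @param nuclei a `nuclei_label_map` on the same frame.
#' @return data.frame of class `cell_count_table` with one row per cell:
#'   `cell_id`, `area_px`, `n_nuclei`, `touches_border`.
#' @export
count_nuclei_per_cell <- function(cells, nuclei) {
  stopifnot(inherits(cells, "cell_label_map"),
            inherits(nuclei, "nuclei_label_map"))
  if (!identical(dim(cells$labels), dim(nuclei$labels))) {
    stop("cell and nucleus label maps have different frame geometry")
  }
  tab <- cells$cells
  tab$n_nuclei <- 0L
  unassigned <- 0L
  if (nrow(nuclei$centroids) > 0L) {
    yi <- pmin(pmax(round(nuclei$centroids$y_px), 1L), nrow(cells$labels))
    xi <- pmin(pmax(round(nuclei$centroids$x_px), 1L), ncol(cells$labels))
    owner <- cells$labels[cbind(yi, xi)]
    unassigned <- sum(owner == 0L)
    cnt <- tabulate(owner[owner > 0L], nbins = nrow(tab))
    tab$n_nuclei <- as.integer(cnt)
  }
  attr(tab, "unassigned_nuclei") <- unassigned
  class(tab) <- c("cell_count_table", "data.frame")
  tab
}

qualifying_cells <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("n_nuclei", "touches_border") %in% names(table)))
  table[table$n_nuclei >= 1L & !table$touches_border, , drop = FALSE]
}

#' Multinucleation ratio (nuclei per cell)
#'
#' Total nuclei over total cells, among interior cells with at least one
#' nucleus. Zero-nucleus cells indicate segmentation error (they would be
#' fixed at the manual-validation step on real data) and are excluded; their
#' count is returned in the `qc_zero_nucleus` attribute.
#'
#' @param table a `cell_count_table`.
#' @return the ratio (>= 1), with attributes `n_cells` and `qc_zero_nucleus`.
#' @export
multinucleation_ratio <- function(table) {
  q <- qualifying_cells(table)
  if (nrow(q) == 0L) stop("no qualifying cells (interior, >= 1 nucleus)")
  interior <- table[!table$touches_border, , drop = FALSE]
  structure(sum(q$n_nuclei) / nrow(q),
            n_cells = nrow(q),
            qc_zero_nucleus = sum(interior$n_nuclei == 0L))
}

#' Multinucleation frequency (% of cells with >= 2 nuclei)
#' @inheritParams multinucleation_ratio
#' @return percentage in \[0, 100\], attribute `n_cells`.
#' @export
multinucleation_frequency <- function(table) {
  q <- qualifying_cells(table)
  if (nrow(q) == 0L) stop("no qualifying cells (interior, >= 1 nucleus)")
  structure(100 * sum(q$n_nuclei >= 2L) / nrow(q), n_cells = nrow(q))
}

#' Delta-multinucleation modifier statistic
#'
#' The screen compares each sample egg chamber to the mean of the
#' cytokinesis-sensitised control egg chambers incubated in the same replicate:
#' `delta = sample_ratio - mean(control_ratios)`. Replicate pairing is enforced
#' upstream by [assemble_screen()]; this is the bare statistic.
#'
#' @param sample_ratio nuclei/cell of the sample egg chamber.
#' @param control_ratios nuclei/cell of same-replicate control egg chambers.
#' @return the difference.
#' @export
delta_multinucleation <- function(sample_ratio, control_ratios) {
  if (length(control_ratios) == 0L) {
    stop("control_ratios must contain at least one same-replicate control")
  }
  stopifnot(is.numeric(sample_ratio), length(sample_ratio) == 1L,
            is.numeric(control_ratios))
  sample_ratio - mean(control_ratios)
}

#' Quantify one egg chamber end to end
#'
#' Convenience wrapper running anchor detection, local projection, central ROI
#' selection, cell and nucleus segmentation and nuclei-per-cell counting,
#' returning the per-sample quantification row used by the screen.
#'
#' @param stack a two-channel [tissue_stack()].
#' @param sample_id,group,replicate metadata carried into the record.
#' @param margin_fraction,roi_mode passed to [select_central_roi()].
#' @param ... passed on to [segment_cells()].
#' @return data.frame (one row) of class `egg_chamber_record`: `sample_id`,
#'   `group`, `replicate`, `nuclei_per_cell`, `pct_multinucleated`, `n_cells`.
#'   The intermediate count table is attached as attribute `counts`.
#' @export
quantify_egg_chamber <- function(stack, sample_id = "sample", group = NA_character_,
                                 replicate = NA_character_,
                                 margin_fraction = 0.2,
                                 roi_mode = "rectangle", ...) {
  anchors <- locate_nuclei_3d(stack)
  proj <- local_projection(stack, anchors)
  roi <- select_central_roi(proj, margin_fraction, roi_mode)
  cells <- segment_cells(proj, roi, ...)
  nucs <- segment_nuclei(proj)
  counts <- count_nuclei_per_cell(cells, nucs)
  rec <- data.frame(
    sample_id = sample_id, group = group, replicate = replicate,
    nuclei_per_cell = as.numeric(multinucleation_ratio(counts)),
    pct_multinucleated = as.numeric(multinucleation_frequency(counts)),
    n_cells = attr(multinucleation_ratio(counts), "n_cells")
  )
  attr(rec, "counts") <- counts
  class(rec) <- c("egg_chamber_record", "data.frame")
  rec
}
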