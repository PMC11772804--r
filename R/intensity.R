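#' ROI specifications for fluorescence quantification
#'
#' Three ROI kinds mirror the manual quantification geometry: an annular band
#' along the cell cortex (`roi_circle_band`), a band along a segmented line at
#' the cytokinetic ring (`roi_polyline_band`), and a disk in the cytoplasm for
#' background (`roi_disk`). Pixel membership is decided by pixel-centre
#' distance to the ROI path or centre.
#'
#' @param center numeric (y, x) in pixels.
#' @param radius_px circle radius.
#' @param width_px total band width (default 3, the line width used for
#'   cortical and ring measurements).
#' @param vertices matrix with columns (y, x), >= 2 rows.
#' @param diameter_px disk diameter (default 10, the cytoplasmic background
#'   ROI).
#' @return object of class `roi_spec`.
#' @export
roi_circle_band <- function(center, radius_px, width_px = 3) {
  stopifnot(length(center) == 2L, radius_px > 0, width_px > 0)
  structure(list(kind = "circle_band", center = as.numeric(center),
                 radius_px = radius_px, width_px = width_px),
            class = "roi_spec")
}

#' @rdname roi_circle_band
#' @export
roi_polyline_band <- function(vertices, width_px = 3) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2L, nrow(vertices) >= 2L, width_px > 0)
  structure(list(kind = "polyline_band", vertices = vertices,
                 width_px = width_px),
            class = "roi_spec")
}

#' @rdname roi_circle_band
#' @export
roi_disk <- function(center, diameter_px = 10) {
  stopifnot(length(center) == 2L, diameter_px > 0)
  structure(list(kind = "disk", center = as.numeric(center),
                 diameter_px = diameter_px),
            class = "roi_spec")
}

roi_mask <- function(image, roi) {
  stopifnot(inherits(roi, "roi_spec"), is.matrix(image))
  ny <- nrow(image); nx <- ncol(image)
  g <- pixel_grid(ny, nx)
  switch(roi$kind,
    circle_band = {
      d <- sqrt((g$y - roi$center[1])^2 + (g$x - roi$center[2])^2)
      abs(d - roi$radius_px) <= roi$width_px / 2
    },
    disk = {
      d <- sqrt((g$y - roi$center[1])^2 + (g$x - roi$center[2])^2)
      d <= roi$diameter_px / 2
    },
    polyline_band = {
      dmin <- matrix(Inf, ny, nx)
      v <- roi$vertices
      for (s in seq_len(nrow(v) - 1L)) {
        dmin <- pmin(dmin, dist_point_segment(g$y, g$x, v[s, ], v[s + 1L, ]))
      }
      dmin <= roi$width_px / 2
    },
    stop("unknown ROI kind")
  )
}

## distance from points (py, px) to segment a->b (each (y, x))
dist_point_segment <- function(py, px, a, b) {
  vy <- b[1] - a[1]; vx <- b[2] - a[2]
  len2 <- vy^2 + vx^2
  if (len2 == 0) return(sqrt((py - a[1])^2 + (px - a[2])^2))
  t <- pmin(pmax(((py - a[1]) * vy + (px - a[2]) * vx) / len2, 0), 1)
  sqrt((py - (a[1] + t * vy))^2 + (px - (a[2] + t * vx))^2)
}

#' Z-sum projection of two planes
#'
#' Pixelwise sum of two optical sections cross-sectioning the mitotic cell, the
#' projection on which cortical and ring intensities are measured.
#'
#' @param stack a [tissue_stack()].
#' @param plane_indices two distinct valid plane indices.
#' @param channel channel index (default 1).
#' @return 2D numeric matrix.
#' @export
zsum_project <- function(stack, plane_indices, channel = 1L) {
  stopifnot(inherits(stack, "tissue_stack"), length(plane_indices) == 2L)
  nz <- dim(stack$voxels)[3]
  if (any(plane_indices < 1L | plane_indices > nz)) {
    stop("plane index out of range")
  }
  if (plane_indices[1] == plane_indices[2]) stop("plane indices must differ")
  stack$voxels[, , plane_indices[1], channel] +
    stack$voxels[, , plane_indices[2], channel]
}

#' Mean intensity within an ROI
#' @param image 2D numeric matrix.
#' @param roi a `roi_spec`.
#' @return mean intensity over member pixels.
#' @export
measure_roi_mean <- function(image, roi) {
  m <- roi_mask(image, roi)
  if (!any(m)) stop("ROI contains no pixels of the image")
  mean(image[m])
}

#' Background-corrected intensity record
#'
#' Subtracts the mean cytoplasmic signal (by convention a 10 px diameter disk)
#' from a raw ROI mean, as done for cortical and ring fluorescence.
#'
#' @param raw_mean raw ROI mean intensity.
#' @param image the measured image (for the background ROI).
#' @param cytoplasm_roi a `roi_spec`, typically [roi_disk()].
#' @param sample_id,phase metadata (`phase` is `"metaphase"` or
#'   `"cytokinesis"`).
#' @return data.frame of class `intensity_record` with `sample_id`, `phase`,
#'   `raw_mean`, `background_mean`, `corrected`.
#' @export
background_correct <- function(raw_mean, image, cytoplasm_roi,
                               sample_id = "sample", phase = NA_character_) {
  bg <- measure_roi_mean(image, cytoplasm_roi)
  out <- data.frame(
    sample_id = sample_id, phase = phase,
    raw_mean = raw_mean, background_mean = bg, corrected = raw_mean - bg
  )
  class(out) <- c("intensity_record", "data.frame")
  out
}

#' Simulate a single-cell intensity scene with known ROI geometry
#'
#' Renders a circular cell cortex of known mean intensity, a short bright ring
#' segment, uniform cytoplasm, and a global additive offset, split evenly
#' across two planes so the z-sum projection reconstructs the nominal values
#' exactly. The true geometry is returned so ROI measurements can be checked
#' against known means.
#'
#' @param shape (ny, nx) frame size.
#' @param cortex_value,ring_value,cytoplasm_value nominal intensities (>= 0).
#' @param offset global additive offset.
#' @param noise_sd Gaussian noise sd (applied per plane).
#' @param seed RNG seed.
#' @return list with `stack` (two-plane, one-channel [tissue_stack()]) and
#'   `geometry` (list of the cortex / ring / cytoplasm `roi_spec`s used).
#' @export
generate_intensity_scene <- function(shape = c(64L, 64L), cortex_value = 100,
                                     ring_value = 150, cytoplasm_value = 20,
                                     offset = 0, noise_sd = 0, seed = 1L) {
  stopifnot(all(shape >= 32L), cortex_value >= 0, ring_value >= 0,
            cytoplasm_value >= 0)
  ny <- shape[1]; nx <- shape[2]
  center <- c((ny + 1) / 2, (nx + 1) / 2)
  radius <- min(ny, nx) / 2 - 6
  cortex <- roi_circle_band(center, radius, width_px = 3)
  ring <- roi_polyline_band(
    rbind(center + c(-5, 0), center + c(5, 0)), width_px = 3
  )
  cyto <- roi_disk(center + c(0, -radius / 2), diameter_px = 10)

  img <- matrix(0, ny, nx)
  g <- pixel_grid(ny, nx)
  inside <- sqrt((g$y - center[1])^2 + (g$x - center[2])^2) <
    radius - 1.5
  img[inside] <- cytoplasm_value
  img[roi_mask(img, cortex)] <- cortex_value
  img[roi_mask(img, ring)] <- ring_value
  img <- img + offset

  vox <- array(0, c(ny, nx, 2L, 1L))
  vox[, , 1L, 1L] <- img / 2
  vox[, , 2L, 1L] <- img / 2
  if (noise_sd > 0) {
    vox <- with_seed(seed,
      vox + array(rnorm(length(vox), 0, noise_sd), dim(vox)))
    vox[vox < 0] <- 0
  }
  list(
    stack = tissue_stack(vox, pixel_size_um = 1, z_spacing_um = 1,
                         channel_roles = c(signal = 1L)),
    geometry = list(cortex = cortex, ring = ring, cytoplasm = cyto,
                    center = center, radius_px = radius)
  )
}

#' Score division events into three cytokinesis outcome categories
#'
#' Eligibility first: events from cells larger than `max_area_px` are dropped
#' (large cells are suspected products of earlier failures), and events that
#' completed constriction without regressing but were observed for less than
#' `min_observed_min` afterwards are dropped (failure could not have been
#' ruled out). Remaining events are classified: ring regression before
#' constriction completed = failure during constriction; regression after
#' completion = post-constriction failure; otherwise no failure.
#'
#' @param events data.frame with columns `cell_id`, `constriction_completed`
#'   (logical), `observed_post_min`, `regressed` (logical),
#'   `regression_time_min` (NA unless regressed), `pre_division_area_px`, and
#'   optionally `group`.
#' @param min_observed_min minimum post-constriction observation time, minutes.
#' @param max_area_px maximum pre-division cell area; if `NULL`, defaults to
#'   twice the median area of the supplied events.
#' @return list with `events` (retained rows plus a `category` column) and
#'   `summary` (per group: `n_scored`, counts per category, `pct_failure`,
#'   `mean_regression_time_min`, `sd_regression_time_min` over
#'   post-constriction failures).
#' @export
score_division_events <- function(events, min_observed_min = 20,
                                  max_area_px = NULL) {
  need <- c("cell_id", "constriction_completed", "observed_post_min",
            "regressed", "regression_time_min", "pre_division_area_px")
  stopifnot(is.data.frame(events), all(need %in% names(events)))
  if (any(events$regressed & is.na(events$regression_time_min))) {
    stop("regressed events must carry regression_time_min")
  }
  if (any(events$observed_post_min < 0)) stop("observed_post_min must be >= 0")
  if (is.null(max_area_px)) {
    max_area_px <- 2 * median(events$pre_division_area_px)
  }
  if (!("group" %in% names(events))) events$group <- "all"

  keep <- events$pre_division_area_px <= max_area_px
  keep <- keep & !(events$constriction_completed & !events$regressed &
                     events$observed_post_min < min_observed_min)
  ev <- events[keep, , drop = FALSE]
  ev$category <- ifelse(
    !ev$constriction_completed, "failed_during_constriction",
    ifelse(ev$regressed, "failed_post_constriction", "no_failure")
  )

  groups <- unique(events$group)
  summary <- do.call(rbind, lapply(groups, function(gr) {
    e <- ev[ev$group == gr, , drop = FALSE]
    n <- nrow(e)
    n1 <- sum(e$category == "no_failure")
    n2 <- sum(e$category == "failed_during_constriction")
    n3 <- sum(e$category == "failed_post_constriction")
    rt <- e$regression_time_min[e$category == "failed_post_constriction"]
    data.frame(
      group = gr, n_scored = n,
      n_no_failure = n1, n_failed_during = n2, n_failed_post = n3,
      pct_failure = if (n > 0) 100 * (n2 + n3) / n else NA_real_,
      mean_regression_time_min = if (length(rt)) mean(rt) else NA_real_,
      sd_regression_time_min = if (length(rt) >= 2L) sd(rt) else NA_real_
    )
  }))
  rownames(summary) <- NULL
  list(events = ev, summary = summary)
}

#' Read a division-event log from CSV
#'
#' Validates the columns required by [score_division_events()] and coerces the
#' logical flags.
#' @param path CSV path.
#' @return data.frame of division events.
#' @export
read_division_events <- function(path) {
  ev <- read.csv(path)
  need <- c("cell_id", "constriction_completed", "observed_post_min",
            "regressed", "regression_time_min", "pre_division_area_px")
  if (!all(need %in% names(ev))) {
    stop("event CSV must have columns: ", paste(need, collapse = ", "))
  }
  ev$constriction_completed <- as.logical(ev$constriction_completed)
  ev$regressed <- as.logical(ev$regressed)
  ev
}

#' Simulate a division-event log with planted outcome categories
#'
#' Plants exact per-category counts (`round(n * proportions)`, remainder to the
#' first category) so recovery by [score_division_events()] can be checked
#' exactly. Optionally adds ineligible decoy events (short observation or
#' oversized cells) that the filters must drop.
#'
#' @param n number of eligible events.
#' @param proportions length-3 numeric (no failure, failure during
#'   constriction, failure post-constriction); must sum to 1.
#' @param group group label.
#' @param n_ineligible number of decoy events to append.
#' @param seed RNG seed.
#' @return data.frame in the [score_division_events()] input format, with a
#'   `planted_category` column as ground truth (NA for decoys).
#' @export
simulate_division_events <- function(n, proportions = c(0.7, 0.1, 0.2),
                                     group = "sim", n_ineligible = 0L,
                                     seed = 1L) {
  stopifnot(n >= 1L, length(proportions) == 3L, all(proportions >= 0),
            abs(sum(proportions) - 1) < 1e-8)
  counts <- round(n * proportions)
  counts[1] <- n - sum(counts[-1])
  cats <- rep(c("no_failure", "failed_during_constriction",
                "failed_post_constriction"), counts)
  with_seed(seed, {
    cats <- sample(cats)
    area <- runif(n, 80, 120)
    ev <- data.frame(
      cell_id = sprintf("%s_%03d", group, seq_len(n)),
      group = group,
      constriction_completed = cats != "failed_during_constriction",
      observed_post_min = runif(n, 25, 60),
      regressed = cats != "no_failure",
      regression_time_min = ifelse(cats == "no_failure", NA_real_,
                                   runif(n, 5, 40)),
      pre_division_area_px = area,
      planted_category = cats
    )
    if (n_ineligible > 0L) {
      half <- ceiling(n_ineligible / 2)
      dec <- data.frame(
        cell_id = sprintf("%s_decoy_%03d", group, seq_len(n_ineligible)),
        group = group,
        constriction_completed = TRUE,
        observed_post_min = c(runif(half, 0, 19), runif(n_ineligible - half,
                                                        25, 60)),
        regressed = FALSE,
        regression_time_min = NA_real_,
        pre_division_area_px = c(runif(half, 80, 120),
                                 runif(n_ineligible - half, 500, 800)),
        planted_category = NA_character_
      )
      ev <- rbind(ev, dec)
    }
    ev
  })
}
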