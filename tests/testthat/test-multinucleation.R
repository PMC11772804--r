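test_that("central ROI selection follows the margin arithmetic", {
  img <- array(0, c(100, 100, 2))
  proj <- structure(list(image = img,
                         channel_roles = c(membrane = 1L, nuclei = 2L)),
                    class = "surface_projection")
  roi <- select_central_roi(proj, margin_fraction = 0.2)
  expect_true(all(roi[21:80, 21:80]))
  expect_equal(sum(roi), 60L * 60L)
  full <- select_central_roi(proj, margin_fraction = 0)
  expect_true(all(full))
  expect_error(select_central_roi(proj, margin_fraction = 0.6))
})

test_that("cell segmentation recovers the true tessellation on clean tissue", {
  out <- generate_epithelium_stack(small_tissue_spec(
    multinucleation_fraction = 0.2, seed = 40
  ))
  anchors <- locate_nuclei_3d(out$stack)
  proj <- local_projection(out$stack, anchors)
  roi <- select_central_roi(proj)
  cells <- segment_cells(proj, roi)
  nuclei <- segment_nuclei(proj)
  counts <- count_nuclei_per_cell(cells, nuclei)
  q <- counts[!counts$touches_border, ]
  expect_gt(nrow(q), 5L)

  # each interior segmented cell maps to one true cell with the right
  # nucleus count and decent overlap
  truth <- out$truth
  tn <- table(truth$nuclei$cell_id)
  match_ok <- 0; jacc <- numeric(0)
  for (i in seq_len(nrow(q))) {
    pix <- cells$labels == q$cell_id[i]
    tlab <- as.integer(names(which.max(table(truth$cell_labels[pix]))))
    inter <- sum(pix & truth$cell_labels == tlab)
    jacc <- c(jacc, inter / sum(pix | truth$cell_labels == tlab))
    if (q$n_nuclei[i] == tn[as.character(tlab)]) match_ok <- match_ok + 1
  }
  expect_gte(match_ok / nrow(q), 0.98)
  expect_gte(median(jacc), 0.8)
  # at least one binucleated merged pair came back as a single region
  expect_true(any(q$n_nuclei >= 2L))
})

test_that("boundary-free membrane yields a single region", {
  img <- array(0, c(64, 64, 2))
  proj <- structure(list(image = img,
                         channel_roles = c(membrane = 1L, nuclei = 2L)),
                    class = "surface_projection")
  roi <- select_central_roi(proj, 0.1)
  cells <- segment_cells(proj, roi, min_cell_area_px = 10L)
  expect_equal(nrow(cells$cells), 1L)
})

test_that("nucleus segmentation splits touching blobs and drops specks", {
  ny <- 64; nx <- 64
  g <- follicleQuant:::pixel_grid(ny, nx)
  r <- 8
  img <- array(0, c(ny, nx, 2))
  d1 <- sqrt((g$y - 32)^2 + (g$x - 24)^2)
  d2 <- sqrt((g$y - 32)^2 + (g$x - 24 - 1.2 * r)^2)  # centers 1.2 x radius apart
  img[, , 2] <- pmax(exp(-d1^2 / (2 * (r / 2)^2)), exp(-d2^2 / (2 * (r / 2)^2)))
  proj <- structure(list(image = img,
                         channel_roles = c(membrane = 1L, nuclei = 2L)),
                    class = "surface_projection")
  nm <- segment_nuclei(proj, min_area_px = 12L)
  expect_equal(nrow(nm$centroids), 2L)

  blank <- proj; blank$image[, , 2] <- 0
  expect_equal(nrow(segment_nuclei(blank)$centroids), 0L)
})

test_that("nuclei are assigned to the cell under their centroid", {
  labels <- matrix(1L, 40, 40)
  cells <- structure(list(
    labels = labels,
    cells = data.frame(cell_id = 1L, area_px = 1600L, touches_border = FALSE),
    roi = matrix(TRUE, 40, 40)
  ), class = "cell_label_map")
  nuclei <- structure(list(
    labels = matrix(0L, 40, 40),
    centroids = data.frame(nucleus_id = 1:3, y_px = c(10, 20, 30),
                           x_px = c(10, 20, 30), area_px = 20L)
  ), class = "nuclei_label_map")
  counts <- count_nuclei_per_cell(cells, nuclei)
  expect_equal(counts$n_nuclei, 3L)

  # centroid on background stays unassigned
  cells$labels[8:12, 8:12] <- 0L
  counts2 <- count_nuclei_per_cell(cells, nuclei)
  expect_equal(counts2$n_nuclei, 2L)
  expect_equal(attr(counts2, "unassigned_nuclei"), 1L)

  bad <- nuclei; bad$labels <- matrix(0L, 10, 10)
  expect_error(count_nuclei_per_cell(cells, bad), "geometry")
})

test_that("ratio and frequency statistics follow their definitions", {
  tab <- data.frame(cell_id = 1:3, area_px = 100L, n_nuclei = c(1L, 1L, 2L),
                    touches_border = FALSE)
  class(tab) <- c("cell_count_table", "data.frame")
  expect_equal(as.numeric(multinucleation_ratio(tab)), 4 / 3)
  expect_equal(as.numeric(multinucleation_frequency(tab)), 100 / 3)

  mono <- tab; mono$n_nuclei <- c(1L, 1L, 1L)
  expect_equal(as.numeric(multinucleation_ratio(mono)), 1)
  expect_equal(as.numeric(multinucleation_frequency(mono)), 0)

  # zero-nucleus cells excluded but surfaced as QC; border cells excluded
  qc <- tab; qc$n_nuclei[2] <- 0L
  expect_equal(attr(multinucleation_ratio(qc), "qc_zero_nucleus"), 1L)
  expect_equal(as.numeric(multinucleation_ratio(qc)), 3 / 2)
  brd <- tab; brd$touches_border <- TRUE
  expect_error(multinucleation_ratio(brd), "no qualifying")
})

test_that("delta-multinucleation is a centred difference", {
  expect_equal(delta_multinucleation(1.2, c(1.0, 1.1)), 0.15)
  expect_equal(delta_multinucleation(1.05, c(1.0, 1.1)), 0)
  expect_error(delta_multinucleation(1.2, numeric(0)), "control")
  # centering identity: controls against their own mean average to zero
  ctrl <- c(1.02, 1.08, 1.11, 0.99)
  deltas <- vapply(ctrl, delta_multinucleation, numeric(1),
                   control_ratios = ctrl)
  expect_equal(mean(deltas), 0, tolerance = 1e-12)
})

test_that("shrinking the ROI never grows the included-cell set", {
  out <- generate_epithelium_stack(small_tissue_spec(seed = 55))
  anchors <- locate_nuclei_3d(out$stack)
  proj <- local_projection(out$stack, anchors)
  nuclei <- segment_nuclei(proj)
  included <- function(m) {
    roi <- select_central_roi(proj, m)
    counts <- count_nuclei_per_cell(segment_cells(proj, roi), nuclei)
    q <- counts[!counts$touches_border & counts$n_nuclei >= 1, ]
    nrow(q)
  }
  ns <- vapply(c(0.05, 0.15, 0.25, 0.35), included, numeric(1))
  expect_true(all(diff(ns) <= 0))
})
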