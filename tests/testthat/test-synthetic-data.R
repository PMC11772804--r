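test_that("tissue generator enforces its ground-truth contract", {
  # fraction 0: every cell mononucleated
  out0 <- generate_epithelium_stack(small_tissue_spec(seed = 3))
  per_cell <- table(out0$truth$nuclei$cell_id)
  expect_true(all(per_cell == 1L))
  expect_identical(out0$truth$n_multinucleated, 0)

  # fraction 0.1, 40 cells: exactly 4 flagged, 44 nuclei
  out <- generate_epithelium_stack(
    small_tissue_spec(multinucleation_fraction = 0.1, seed = 3)
  )
  expect_equal(sum(out$truth$is_multinucleated), 4L)
  expect_equal(nrow(out$truth$nuclei), 44L)
  expect_equal(length(out$truth$is_multinucleated), 40L)

  # flat surface: all nuclei share one z
  flat <- generate_epithelium_stack(small_tissue_spec(curvature_sag_um = 0,
                                                      seed = 5))
  expect_lt(diff(range(flat$truth$nuclei$z_um)), 1e-9)
})

test_that("ground-truth invariants hold across random specs", {
  set.seed(42)
  for (i in 1:25) {
    f <- runif(1, 0, 0.25)
    n <- sample(30:60, 1)
    out <- generate_epithelium_stack(tissue_spec(
      field_size_px = c(128L, 128L), n_planes = 8L, n_cells_target = n,
      multinucleation_fraction = f, curvature_sag_um = runif(1, 0, 3),
      psf_sigma_px = 0, poisson_scale = 0, gaussian_sd = 0,
      seed = sample.int(1e6, 1)
    ))
    truth <- out$truth
    # every nucleus inside its cell's region
    owner <- truth$cell_labels[cbind(round(truth$nuclei$y_px),
                                     round(truth$nuclei$x_px))]
    expect_identical(owner, truth$nuclei$cell_id)
    # planted count honoured, every cell has >= 1 nucleus
    expect_equal(sum(truth$is_multinucleated), round(f * n))
    expect_true(all(table(factor(truth$nuclei$cell_id,
                                 levels = seq_along(truth$is_multinucleated)))
                    >= 1L))
    # noise-free stack: half-max threshold recovers the nucleus count in 3D
    nuc <- out$stack$voxels[, , , out$stack$channel_roles[["nuclei"]]]
    nuc <- nuc - min(nuc)
    lab <- follicleQuant:::label_components_3d(nuc > max(nuc) / 2)
    expect_equal(max(lab), nrow(truth$nuclei))
  }
})

test_that("tissue stacks are deterministic given the seed", {
  s <- small_tissue_spec(multinucleation_fraction = 0.1, seed = 77)
  a <- generate_epithelium_stack(s)
  b <- generate_epithelium_stack(s)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$nuclei, b$truth$nuclei)
  c <- generate_epithelium_stack(small_tissue_spec(
    multinucleation_fraction = 0.1, seed = 78))
  expect_false(identical(a$stack$voxels, c$stack$voxels))
})

test_that("tissue generator rejects overcrowded fields", {
  expect_error(
    generate_epithelium_stack(tissue_spec(field_size_px = c(16L, 16L),
                                          n_cells_target = 200L)),
    "too small"
  )
})

test_that("constriction traces follow the piecewise model", {
  # noise-free: plateau then d0 - rate * (t - onset)
  tr <- generate_constriction_trace(trace_spec(
    d0_um = 8, onset_time_min = 2, rate_um_per_min = 0.5, dt_min = 0.5,
    n_frames = 34L, noise_sd_um = 0
  ))
  expect_equal(tr$d_um[tr$t_min == 2.5], 8 - 0.25, tolerance = 1e-12)
  expect_equal(tr$d_um[tr$t_min <= 2], rep(8, 5))
  # non-increasing after onset
  post <- tr$d_um[tr$t_min >= 2]
  expect_true(all(diff(post) <= 1e-12))
  expect_true(all(tr$d_um > 0))

  # determinism with noise
  s <- trace_spec(noise_sd_um = 0.05 * 8, seed = 12)
  expect_identical(generate_constriction_trace(s)$d_um,
                   generate_constriction_trace(s)$d_um)
})

test_that("intensity scenes reproduce their nominal values on the z-sum", {
  sc <- generate_intensity_scene(cortex_value = 100, ring_value = 150,
                                 cytoplasm_value = 20)
  img <- zsum_project(sc$stack, c(1L, 2L))
  expect_equal(measure_roi_mean(img, sc$geometry$cortex), 100)
  expect_equal(measure_roi_mean(img, sc$geometry$ring), 150)
  expect_equal(measure_roi_mean(img, sc$geometry$cytoplasm), 20)

  # additive offset shifts raw means by that constant
  sc2 <- generate_intensity_scene(cortex_value = 100, ring_value = 150,
                                  cytoplasm_value = 20, offset = 7)
  img2 <- zsum_project(sc2$stack, c(1L, 2L))
  expect_equal(measure_roi_mean(img2, sc2$geometry$cortex), 107)

  # equal compartments: corrected signal is zero
  sc3 <- generate_intensity_scene(cortex_value = 30, ring_value = 30,
                                  cytoplasm_value = 30)
  img3 <- zsum_project(sc3$stack, c(1L, 2L))
  raw <- measure_roi_mean(img3, sc3$geometry$cortex)
  rec <- background_correct(raw, img3, sc3$geometry$cytoplasm)
  expect_equal(rec$corrected, 0)
})

test_that("stack and label TIFF round-trips preserve data", {
  out <- generate_epithelium_stack(small_tissue_spec(seed = 9))
  tdir <- withr::local_tempdir()
  tp <- file.path(tdir, "stack.tif")
  write_tissue_stack(out$stack, tp, extra = list(seed = 9))
  back <- read_tissue_stack(tp)
  expect_equal(back$voxels, out$stack$voxels, tolerance = 1e-6)
  expect_equal(back$z_spacing_um, out$stack$z_spacing_um)
  expect_identical(back$channel_roles, out$stack$channel_roles)

  lp <- file.path(tdir, "labels.tif")
  write_label_tiff(out$truth$cell_labels, lp)
  expect_identical(read_label_tiff(lp), out$truth$cell_labels)

  paths <- write_ground_truth(out$truth, tdir)
  nuc <- read.csv(paths[["nuclei"]])
  expect_equal(nrow(nuc), nrow(out$truth$nuclei))

  # CSV interchange for traces and event logs
  tr <- generate_constriction_trace(trace_spec(seed = 2))
  tp2 <- file.path(tdir, "traces.csv")
  write.csv(data.frame(sample_id = "a", t_min = tr$t_min, d_um = tr$d_um),
            tp2, row.names = FALSE)
  back_tr <- read_diameter_traces(tp2)
  expect_equal(back_tr[["a"]]$d_um, tr$d_um)
  ev <- simulate_division_events(20L, c(0.5, 0.2, 0.3), seed = 4)
  ep <- file.path(tdir, "events.csv")
  write.csv(ev, ep, row.names = FALSE)
  back_ev <- read_division_events(ep)
  expect_equal(back_ev$regressed, ev$regressed)
  expect_equal(nrow(score_division_events(back_ev)$events), 20L)
})
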