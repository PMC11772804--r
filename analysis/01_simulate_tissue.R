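#!/usr/bin/env Rscript

# Simulate example inputs for the whole pipeline and write them to disk in the
# interchange formats the package reads back: a two-channel tissue stack as
# multi-page TIFF + JSON sidecar, its ground truth as CSV + 16-bit label TIFF,
# ring-diameter traces and a division-event log as CSV.
#
# Output: results/simulated/

suppressMessages(library(follicleQuant))
out_dir <- file.path("results", "simulated")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

## A small demonstration chamber (the full study condition is 448 px / 400
## cells; 192 px keeps this demo fast and the files small).
spec <- tissue_spec(field_size_px = c(192L, 192L), n_cells_target = 80L,
                    multinucleation_fraction = 0.10, seed = 42)
sim <- generate_epithelium_stack(spec)
write_tissue_stack(sim$stack, file.path(out_dir, "demo_chamber.tif"),
                   extra = list(seed = spec$seed))
write_ground_truth(sim$truth, out_dir, prefix = "demo_chamber")
cat(sprintf("tissue: %d cells, %d multinucleated, %d nuclei\n",
            length(sim$truth$is_multinucleated),
            sim$truth$n_multinucleated, nrow(sim$truth$nuclei)))

## Ring-diameter traces: one clean, one at measurement noise.
traces <- list(
  clean = generate_constriction_trace(trace_spec(noise_sd_um = 0, seed = 1)),
  noisy = generate_constriction_trace(trace_spec(noise_sd_um = 0.02 * 8,
                                                 seed = 2))
)
trace_tab <- do.call(rbind, lapply(names(traces), function(nm) {
  data.frame(sample_id = nm, t_min = traces[[nm]]$t_min,
             d_um = traces[[nm]]$d_um)
}))
write.csv(trace_tab, file.path(out_dir, "ring_traces.csv"), row.names = FALSE)

## Division-event log with planted outcome proportions.
events <- simulate_division_events(200L, c(0.7, 0.1, 0.2), n_ineligible = 40L,
                                   seed = 3)
write.csv(events, file.path(out_dir, "division_events.csv"), row.names = FALSE)

## Round-trip sanity check: the stack read back is the stack written.
back <- read_tissue_stack(file.path(out_dir, "demo_chamber.tif"))
stopifnot(max(abs(back$voxels - sim$stack$voxels)) < 1e-6)
cat("round-trip OK; outputs in", out_dir, "\n")
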