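#!/usr/bin/env Rscript

# Dose-response of the multinucleation read-out, plus a small simulated
# modifier screen. For each planted multinucleated-cell fraction the full
# pipeline (3D nucleus anchors -> local projection -> central ROI ->
# cell/nucleus segmentation -> per-cell counts) is run on independent
# simulated chambers; the recovered nuclei/cell ratio should track 1 + f for
# binucleate cells. A screen is then assembled from sensitised "control"
# chambers and two synthetic RNAi lines: one null, one true enhancer.
#
# Output: results/screen/

suppressMessages(library(follicleQuant))
out_dir <- file.path("results", "screen")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
set.seed(20261001)

fractions <- c(0, 0.05, 0.10, 0.20)
n_seeds <- 5L          # chambers per fraction in this demo run
records <- list()
for (f in fractions) {
  for (s in seq_len(n_seeds)) {
    sim <- generate_epithelium_stack(tissue_spec(
      multinucleation_fraction = f, seed = round(1e4 * f) + s
    ))
    rec <- quantify_egg_chamber(
      sim$stack, sample_id = sprintf("f%03d_s%d", round(100 * f), s),
      group = sprintf("f=%.2f", f), replicate = "r1"
    )
    records[[length(records) + 1L]] <- rec
  }
  cat(sprintf("fraction %.2f done\n", f))
}
records <- do.call(rbind, records)
dose <- do.call(rbind, lapply(split(records, records$group), function(d) {
  data.frame(group = d$group[1], n_chambers = nrow(d),
             mean_ratio = mean(d$nuclei_per_cell),
             mean_pct_multi = mean(d$pct_multinucleated))
}))
cat("\nDose-response (expected ratio = 1 + f):\n")
print(dose, row.names = FALSE)

## Simulated modifier screen: per-chamber ratios for a sensitised control
## line, a no-effect line, and an enhancer line, all in one replicate.
ratio_of <- function(f, s) {
  sim <- generate_epithelium_stack(tissue_spec(multinucleation_fraction = f,
                                               seed = s))
  as.numeric(quantify_egg_chamber(sim$stack)$nuclei_per_cell)
}
screen_records <- rbind(
  data.frame(sample_id = sprintf("ctrl_%d", 1:6), group = "anillin_ctrl",
             replicate = "r1",
             nuclei_per_cell = vapply(301:306, ratio_of, numeric(1), f = 0.10)),
  data.frame(sample_id = sprintf("null_%d", 1:4), group = "rnai_null",
             replicate = "r1",
             nuclei_per_cell = vapply(401:404, ratio_of, numeric(1), f = 0.10)),
  data.frame(sample_id = sprintf("enh_%d", 1:4), group = "rnai_enhancer",
             replicate = "r1",
             nuclei_per_cell = vapply(501:504, ratio_of, numeric(1), f = 0.25))
)
screen <- assemble_screen(screen_records, control_group = "anillin_ctrl")
cat("\nScreen calls:\n")
print(screen[, c("target", "egg_chamber_id", "ratio", "delta_ratio",
                 "p_vs_control", "call")], row.names = FALSE)

render_report(list(
  egg_chamber_records = records,
  dose_response = dose,
  screen = screen
), out_dir)
cat("\ntables written to", out_dir, "\n")
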