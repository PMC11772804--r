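# follicleQuant

Quantification of epithelial cytokinesis failure in curved monolayers such as
the *Drosophila* follicular epithelium.

Cells that fail cytokinesis become multinucleated, and in a post-mitotic
epithelium the nuclei-per-cell ratio is a permanent record of cytokinesis
efficiency. `follicleQuant` turns two-channel confocal z-stacks (membrane
marker + nuclear stain) and time-lapse measurements into that record:

* **Curvature-aware projection** — nuclei are located in 3D and every pixel
  projects a 1 µm section centred on its *nearest nucleus*, so a domed
  epithelium flattens without losing off-apex cells
  (`locate_nuclei_3d()`, `local_projection()`).
* **Multinucleation scoring** — central-ROI cell and nucleus segmentation,
  nuclei-per-cell counting with unbiased counting-frame border exclusion, the
  multinucleation ratio (nuclei/cell) and frequency (% cells with ≥ 2 nuclei)
  (`segment_cells()`, `segment_nuclei()`, `count_nuclei_per_cell()`).
* **Modifier-screen statistic** — per chamber,
  Δ ratio = (nuclei/cell)ₛₐₘₚₗₑ − (1/n) Σ (nuclei/cell)ᵢ over same-replicate
  sensitised controls, with Mann–Whitney p-values and
  enhancer/suppressor/no-effect calls (`delta_multinucleation()`,
  `assemble_screen()`).
* **Ring constriction rate** — onset detection, normalization at t₀, and the
  slope β of d = α + βt fitted by OLS over 4 consecutive timepoints inside
  the constant phase (~80–40 % of the initial diameter), accepted only when
  R² > 0.95 (`detect_onset()`, `fit_constant_phase()`).
* **Cortical fluorescence** — z-sum projection of two planes, band/disk ROI
  means, cytoplasmic background subtraction (`zsum_project()`,
  `measure_roi_mean()`, `background_correct()`).
* **Cytokinesis-failure scoring** — three-category classification of division
  event logs with size and observation-time eligibility filters
  (`score_division_events()`).
* **Synthetic data with exact ground truth** — curved tissues, constriction
  traces, intensity scenes and event logs, all deterministic per seed
  (`generate_epithelium_stack()` and friends), so every stage above is
  testable without microscopy data.

## Worked example

Simulate a chamber with 10 % binucleated cells and quantify it end to end:

```r
library(follicleQuant)

sim <- generate_epithelium_stack(tissue_spec(multinucleation_fraction = 0.10,
                                             seed = 1))
rec <- quantify_egg_chamber(sim$stack, sample_id = "demo")
rec
#>   sample_id group replicate nuclei_per_cell pct_multinucleated n_cells
#> 1      demo  <NA>      <NA>         1.07857            7.85714     140
```

A single chamber samples roughly a third of its 400 cells into the central
counting frame, so per-chamber ratios scatter around the planted 1 + f = 1.10
(here 1.079 from 140 interior cells, 7.9 % read as binucleated); the screen
averages over chambers. Running
the same quantification over five chambers per planted fraction
(`analysis/02_multinucleation_screen.R`) gives the dose-response

```
  group n_chambers mean_ratio mean_pct_multi
 f=0.00          5   1.000000       0.000000
 f=0.05          5   1.053128       5.312849
 f=0.10          5   1.097766       9.776598
 f=0.20          5   1.187753      18.775259
```

and a simulated screen in which a line with planted fraction 0.25 against
sensitised controls at 0.10 is called an enhancer (p = 0.0095, Δ ≈ +0.14)
while a line at the control fraction is `no_effect`.

Constriction rates from 100 simulated traces at 2 % measurement noise
(`analysis/03_constriction_rates.R`):

```
fitted 97/100 traces (3 rejected by the R^2 gate)
mean rate 0.601 um/min (true 0.6; bias +0.2%), SD 0.079
```

The numbered scripts under `analysis/` run each stage as a narrative:
`01_simulate_tissue.R` (write/read the interchange formats),
`02_multinucleation_screen.R`, `03_constriction_rates.R`,
`04_intensity_and_failure.R`; tables land under `results/`. The methods,
parameter choices and known limitations are documented in
`vignettes/quantifying-epithelial-cytokinesis.Rmd`.

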