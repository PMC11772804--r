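# Independent oracles used by the unit and acceptance tests. These deliberately
# avoid the code paths they check.

# Closed-form least squares for y = a + b x on a handful of points, computed
# from raw sums (the implementation goes through stats::lm).
ols_bruteforce <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y)
  b <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  a <- (sy - b * sx) / n
  res <- y - a - b * x
  sst <- sum((y - sy / n)^2)
  list(alpha = a, beta = b, r2 = 1 - sum(res^2) / sst)
}

# Exact two-sided Mann-Whitney p by full enumeration of group labelings
# (tie-free samples only).
mw_enumeration_p <- function(x, y) {
  n_a <- length(x); n_b <- length(y)
  comb <- c(x, y)
  stopifnot(!anyDuplicated(comb))
  u_of <- function(idx) {
    r <- rank(comb)
    sum(r[idx]) - n_a * (n_a + 1) / 2
  }
  u_obs <- u_of(seq_len(n_a))
  labelings <- utils::combn(n_a + n_b, n_a)
  us <- apply(labelings, 2, u_of)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Small, fast tissue used throughout the unit tests (the default spec is the
# full-size study condition exercised in the acceptance tests).
small_tissue_spec <- function(...) {
  args <- utils::modifyList(
    list(field_size_px = c(128L, 128L), n_planes = 10L, n_cells_target = 40L,
         curvature_sag_um = 3),
    list(...)
  )
  do.call(tissue_spec, args)
}

# Run the whole multinucleation pipeline on one stack and return the count
# table plus truth.
quantify_stack <- function(out, ...) {
  anchors <- locate_nuclei_3d(out$stack)
  proj <- local_projection(out$stack, anchors)
  roi <- select_central_roi(proj)
  cells <- segment_cells(proj, roi, ...)
  nuclei <- segment_nuclei(proj)
  count_nuclei_per_cell(cells, nuclei)
}
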