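#' Construct a ring-diameter trace
#'
#' Timed diameters of the cytokinetic ring along the apical-basal axis,
#' validated for the downstream fit: at least 6 samples, strictly increasing
#' times with uniform spacing (1% tolerance), positive diameters.
#'
#' @param t_min time points, minutes.
#' @param d_um ring diameters, micrometres.
#' @param sample_id identifier carried through fits and reports.
#' @return data.frame of class `diameter_trace`.
#' @export
diameter_trace <- function(t_min, d_um, sample_id = "trace") {
  stopifnot(length(t_min) == length(d_um), length(t_min) >= 6L,
            all(is.finite(t_min)), all(is.finite(d_um)), all(d_um > 0))
  dt <- diff(t_min)
  if (any(dt <= 0)) stop("t_min must be strictly increasing")
  if (max(dt) - min(dt) > 0.01 * mean(dt)) {
    stop("time step must be uniform to within 1%")
  }
  out <- data.frame(t_min = t_min, d_um = d_um)
  attr(out, "sample_id") <- sample_id
  class(out) <- c("diameter_trace", "data.frame")
  out
}

#' Read ring-diameter traces from CSV
#'
#' Expects columns `sample_id`, `t_min`, `d_um` (one row per timepoint, "."
#' decimal, header row) and returns one validated [diameter_trace()] per
#' sample.
#' @param path CSV path.
#' @return named list of `diameter_trace` objects.
#' @export
read_diameter_traces <- function(path) {
  tab <- read.csv(path)
  need <- c("sample_id", "t_min", "d_um")
  if (!all(need %in% names(tab))) {
    stop("trace CSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(tab, tab$sample_id), function(d) {
    d <- d[order(d$t_min), ]
    diameter_trace(d$t_min, d$d_um, sample_id = d$sample_id[1])
  })
  out[unique(tab$sample_id)]
}

#' Specification of a synthetic constriction trace
#'
#' Defaults describe a follicle-cell cytokinetic ring: initial diameter 8 um,
#' a 2 min pre-constriction plateau, constant-rate closure at 0.6 um/min down
#' to 30% of the initial diameter, then an exponential slow tail toward a small
#' midbody plateau, sampled every minute for 18 min.
#'
#' @param d0_um initial ring diameter (> 0).
#' @param onset_time_min time of constriction onset (>= 0).
#' @param rate_um_per_min constant-phase constriction rate (> 0).
#' @param tail_fraction normalized diameter at which constriction decelerates,
#'   in \[0, 1).
#' @param dt_min sampling interval (> 0).
#' @param n_frames number of samples; the trace must be long enough to contain
#'   the plateau and the whole constant phase.
#' @param noise_sd_um additive Gaussian measurement noise sd.
#' @param seed integer RNG seed.
#' @return validated list of class `trace_spec`.
#' @export
trace_spec <- function(d0_um = 8, onset_time_min = 2, rate_um_per_min = 0.6,
                       tail_fraction = 0.3, dt_min = 1, n_frames = 18L,
                       noise_sd_um = 0, seed = 1L) {
  spec <- list(
    d0_um = d0_um, onset_time_min = onset_time_min,
    rate_um_per_min = rate_um_per_min, tail_fraction = tail_fraction,
    dt_min = dt_min, n_frames = as.integer(n_frames),
    noise_sd_um = noise_sd_um, seed = as.integer(seed)
  )
  with(spec, {
    stopifnot(d0_um > 0, onset_time_min >= 0, rate_um_per_min > 0,
              tail_fraction >= 0, tail_fraction < 1, dt_min > 0,
              n_frames >= 6L, noise_sd_um >= 0)
    if ((n_frames - 1L) * dt_min <
        onset_time_min + d0_um * (1 - tail_fraction) / rate_um_per_min) {
      stop("trace too short to contain the onset plus the constant phase")
    }
  })
  class(spec) <- "trace_spec"
  spec
}

#' Simulate a ring-diameter trace
#'
#' Piecewise model: a flat plateau at `d0_um` before onset, a linear decline at
#' `rate_um_per_min` until the diameter reaches `tail_fraction * d0_um`, then a
#' slope-continuous exponential approach to a small residual plateau (5% of
#' `d0_um`, the unresolved midbody). Gaussian noise is added and diameters are
#' clipped to stay positive. Deterministic given the seed.
#'
#' @param spec a [trace_spec()].
#' @return a [diameter_trace()]; the generating parameters (including the true
#'   onset index and rate) are attached as attribute `params`.
#' @export
generate_constriction_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  t <- (seq_len(spec$n_frames) - 1) * spec$dt_min
  d_tail <- spec$tail_fraction * spec$d0_um
  t_tail <- spec$onset_time_min +
    (spec$d0_um - d_tail) / spec$rate_um_per_min
  d_plateau <- 0.05 * spec$d0_um
  d <- ifelse(
    t <= spec$onset_time_min,
    spec$d0_um,
    ifelse(
      t <= t_tail,
      spec$d0_um - spec$rate_um_per_min * (t - spec$onset_time_min),
      d_plateau + (d_tail - d_plateau) *
        exp(-spec$rate_um_per_min * (t - t_tail) /
              max(d_tail - d_plateau, 1e-9))
    )
  )
  d <- with_seed(spec$seed, d + rnorm(length(d), 0, spec$noise_sd_um))
  d <- pmax(d, 1e-3)
  out <- diameter_trace(t, d, sample_id = sprintf("sim_seed%d", spec$seed))
  attr(out, "params") <- spec
  ## true t0 = last frame at/before onset (1-based index)
  attr(out, "true_t0_index") <- max(which(t <= spec$onset_time_min))
  out
}

#' Detect constriction onset
#'
#' t0 is the frame prior to the first sustained drop in ring diameter: the
#' first frame whose diameter falls below `(1 - delta_rel)` of the starting
#' diameter and that is followed by `persist` frames of (noise-tolerant)
#' non-increasing diameter.
#'
#' @param trace a [diameter_trace()].
#' @param delta_rel relative drop that counts as a change.
#' @param persist number of subsequent frames that must not rise by more than
#'   `delta_rel * d[1] / 2`.
#' @return 1-based index of t0 (the last pre-constriction frame).
#' @export
detect_onset <- function(trace, delta_rel = 0.05, persist = 3L) {
  stopifnot(inherits(trace, "diameter_trace"), delta_rel > 0, persist >= 1L)
  d <- trace$d_um
  n <- length(d)
  thresh <- (1 - delta_rel) * d[1]
  tol <- delta_rel * d[1] / 2
  for (f in 2:n) {
    if (d[f] < thresh) {
      upto <- min(f + persist, n)
      if (all(diff(d[f:upto]) <= tol)) return(f - 1L)
    }
  }
  stop("no constriction detected")
}

#' Normalize a trace to its diameter at t0
#' @param trace a [diameter_trace()].
#' @param t0_index index from [detect_onset()].
#' @return numeric vector `d / d[t0]`, exactly 1 at t0.
#' @export
normalize_trace <- function(trace, t0_index) {
  stopifnot(inherits(trace, "diameter_trace"),
            t0_index >= 1L, t0_index <= nrow(trace))
  d0 <- trace$d_um[t0_index]
  if (d0 == 0) stop("diameter at t0 is zero")
  out <- trace$d_um / d0
  out[t0_index] <- 1
  out
}

#' Fit the constant phase of ring constriction
#'
#' Enumerates every window of 4 consecutive post-onset timepoints whose
#' normalized diameters all lie in `band` (the roughly linear ~80-40% stretch
#' of closure), fits `d = alpha + beta * t` by ordinary least squares on the
#' absolute diameters of each window, and keeps windows with R^2 above
#' `r2_threshold`. The best window (highest R^2, earliest on ties) defines the
#' constriction rate `|beta|` in um/min.
#'
#' @param trace a [diameter_trace()].
#' @param t0_index onset index from [detect_onset()].
#' @param band inclusive normalized-diameter band, default `c(0.40, 0.80)`.
#' @param r2_threshold minimal R^2 for a window to count as linear; traces
#'   with no passing window are rejected (flagged) rather than fitted.
#' @return object of class `constriction_fit`: list with `t0_index`,
#'   `d_t0_um`, `window` (4 indices), `alpha_um`, `beta_um_per_min` (signed),
#'   `rate_um_per_min` (= |beta|), `r2`, `normalized_trace`, `sample_id`.
#' @export
fit_constant_phase <- function(trace, t0_index, band = c(0.40, 0.80),
                               r2_threshold = 0.95) {
  stopifnot(inherits(trace, "diameter_trace"), length(band) == 2L,
            band[1] < band[2])
  norm <- normalize_trace(trace, t0_index)
  n <- nrow(trace)
  if (t0_index > n - 3L) stop("no constant phase in band")
  starts <- seq.int(t0_index, n - 3L)
  in_band <- norm >= band[1] & norm <= band[2]
  cand <- starts[vapply(starts, function(s) all(in_band[s:(s + 3L)]),
                        logical(1))]
  if (length(cand) == 0L) stop("no constant phase in band")
  fits <- lapply(cand, function(s) {
    idx <- s:(s + 3L)
    x <- trace$t_min[idx]
    y <- trace$d_um[idx]
    sst <- sum((y - mean(y))^2)
    if (sst == 0) return(NULL)           # flat window: R^2 undefined, skip
    m <- lm(y ~ x)
    r2 <- 1 - sum(m$residuals^2) / sst
    list(start = s, alpha = unname(coef(m)[1]), beta = unname(coef(m)[2]),
         r2 = r2)
  })
  fits <- Filter(function(f) !is.null(f) && f$r2 > r2_threshold, fits)
  if (length(fits) == 0L) stop("R2 threshold not met")
  r2s <- vapply(fits, `[[`, numeric(1), "r2")
  best <- fits[[which.max(r2s)]]          # which.max -> earliest on ties
  structure(
    list(
      t0_index = t0_index,
      d_t0_um = trace$d_um[t0_index],
      window = best$start:(best$start + 3L),
      alpha_um = best$alpha,
      beta_um_per_min = best$beta,
      rate_um_per_min = abs(best$beta),
      r2 = best$r2,
      normalized_trace = norm,
      sample_id = attr(trace, "sample_id")
    ),
    class = "constriction_fit"
  )
}

#' @export
print.constriction_fit <- function(x, ...) {
  cat(sprintf(
    "<constriction_fit> %s: rate %.3f um/min (beta %.3f), R^2 %.4f, window %d..%d\n",
    x$sample_id %||% "?", x$rate_um_per_min, x$beta_um_per_min, x$r2,
    min(x$window), max(x$window)
  ))
  invisible(x)
}

#' Pointwise mean and SD of normalized traces aligned at t0
#'
#' Traces are supplied as numeric vectors of normalized diameters whose first
#' element is t0 (use `normalize_trace(trace, t0)[t0:length(...)]`); they may
#' have different lengths. The mean and SD are computed over the traces present
#' at each timepoint; SD is `NA` where fewer than two traces remain.
#'
#' @param traces list of numeric vectors (normalized, t0-first).
#' @param dt_min common sampling interval, minutes.
#' @return data.frame with `t_min`, `mean`, `sd`, `n`.
#' @export
mean_trace_with_sd <- function(traces, dt_min) {
  stopifnot(is.list(traces), length(traces) >= 1L, dt_min > 0)
  len <- max(vapply(traces, length, integer(1)))
  m <- vapply(traces, function(x) c(x, rep(NA_real_, len - length(x))),
              numeric(len))
  m <- matrix(m, nrow = len)
  n <- rowSums(!is.na(m))
  data.frame(
    t_min = (seq_len(len) - 1) * dt_min,
    mean = rowMeans(m, na.rm = TRUE),
    sd = apply(m, 1, function(r) if (sum(!is.na(r)) >= 2L) sd(r, na.rm = TRUE)
               else NA_real_),
    n = n
  )
}
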