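#' Mann-Whitney U comparison of two groups
#'
#' The non-parametric unpaired two-sample test used for all group comparisons.
#' U is computed from midranks; the two-sided p-value uses the exact null
#' distribution when the combined sample size is at most `exact_limit` and
#' there are no ties, and otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param x,y numeric samples (each non-empty).
#' @param exact_limit switch point for the exact path (combined n).
#' @return object of class `group_comparison`: list with `n_a`, `n_b`, `U`
#'   (for `x`), `p_two_sided`, `median_a`, `median_b`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 12L) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  stopifnot(is.numeric(x), is.numeric(y))
  n_a <- length(x); n_b <- length(y)
  r <- rank(c(x, y))                      # midranks
  U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (n_a + n_b) <= exact_limit && !ties
  p <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
  structure(
    list(
      n_a = n_a, n_b = n_b, U = U, p_two_sided = p,
      median_a = median(x), median_b = median(y),
      method = if (exact) "exact" else "normal_approx"
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> n = %d vs %d, U = %g, p = %.4g (%s), medians %.3g / %.3g\n",
    x$n_a, x$n_b, x$U, x$p_two_sided, x$method, x$median_a, x$median_b
  ))
  invisible(x)
}

#' Assemble the modifier-screen table
#'
#' For each non-control group ("target"), every egg chamber's
#' delta-multinucleation ratio is computed against the mean of the control egg
#' chambers of the *same replicate* (the controls incubated alongside it); a
#' group-level Mann-Whitney p-value compares the target's ratios with the
#' pooled same-replicate controls. A target is called an `enhancer` when
#' p < alpha with median delta > 0, a `suppressor` when p < alpha with median
#' delta < 0, and `no_effect` otherwise.
#'
#' @param records data.frame of egg-chamber records with columns `sample_id`,
#'   `group`, `replicate`, `nuclei_per_cell` (e.g. rows from
#'   [quantify_egg_chamber()]).
#' @param control_group name of the sensitised-control group.
#' @param alpha significance level for the call.
#' @param bh add a Benjamini-Hochberg adjusted p column across targets
#'   (off by default; the per-target p-values are reported unadjusted).
#' @return data.frame of class `screen_table`, one row per target egg chamber:
#'   `target`, `replicate`, `egg_chamber_id`, `ratio`, `delta_ratio`,
#'   `p_vs_control`, `call` (plus `p_bh` when `bh = TRUE`).
#' @export
assemble_screen <- function(records, control_group, alpha = 0.05, bh = FALSE) {
  need <- c("sample_id", "group", "replicate", "nuclei_per_cell")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  if (!any(records$group == control_group)) {
    stop(sprintf("no rows for control group '%s'", control_group))
  }
  ctrl <- records[records$group == control_group, , drop = FALSE]
  targ <- records[records$group != control_group, , drop = FALSE]
  missing_rep <- !(targ$replicate %in% ctrl$replicate)
  if (any(missing_rep)) {
    stop("no same-replicate controls for rows: ",
         paste(targ$sample_id[missing_rep], collapse = ", "))
  }

  out <- do.call(rbind, lapply(unique(targ$group), function(gr) {
    tg <- targ[targ$group == gr, , drop = FALSE]
    delta <- vapply(seq_len(nrow(tg)), function(i) {
      cc <- ctrl$nuclei_per_cell[ctrl$replicate == tg$replicate[i]]
      delta_multinucleation(tg$nuclei_per_cell[i], cc)
    }, numeric(1))
    pooled_ctrl <- ctrl$nuclei_per_cell[ctrl$replicate %in% tg$replicate]
    cmp <- mann_whitney_u(tg$nuclei_per_cell, pooled_ctrl)
    med <- median(delta)
    call <- if (cmp$p_two_sided < alpha && med > 0) "enhancer"
      else if (cmp$p_two_sided < alpha && med < 0) "suppressor"
      else "no_effect"
    data.frame(
      target = gr, replicate = tg$replicate, egg_chamber_id = tg$sample_id,
      ratio = tg$nuclei_per_cell, delta_ratio = delta,
      p_vs_control = cmp$p_two_sided, call = call
    )
  }))
  rownames(out) <- NULL
  if (bh) {
    per_target <- !duplicated(out$target)
    adj <- p.adjust(out$p_vs_control[per_target], method = "BH")
    out$p_bh <- adj[match(out$target, out$target[per_target])]
  }
  class(out) <- c("screen_table", "data.frame")
  out
}

#' Write analysis tables and a plain-text summary
#'
#' Writes each supplied table as a UTF-8 CSV (header row, "." decimal) with a
#' deterministic column order (as given), plus a `summary.txt` with row counts.
#' These CSVs are also the plot-data exports consumed by the analysis scripts.
#'
#' @param tables named list of data.frames (e.g. `screen`,
#'   `constriction_fits`, `failure_summary`).
#' @param out_dir output directory (created if missing).
#' @return invisibly, a named character vector of written paths.
#' @export
render_report <- function(tables, out_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables),
            all(nzchar(names(tables))))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    stopifnot(is.data.frame(tables[[nm]]))
    p <- file.path(out_dir, paste0(nm, ".csv"))
    ok <- tryCatch({
      write.csv(tables[[nm]], p, row.names = FALSE, fileEncoding = "UTF-8")
      TRUE
    }, error = function(e) {
      stop(sprintf("failed to write '%s': %s", p, conditionMessage(e)))
    })
    paths[nm] <- p
  }
  sum_path <- file.path(out_dir, "summary.txt")
  lines <- c(
    "follicleQuant report",
    sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    "",
    vapply(names(tables), function(nm) {
      sprintf("%-24s %d rows, %d columns", nm, nrow(tables[[nm]]),
              ncol(tables[[nm]]))
    }, character(1))
  )
  writeLines(lines, sum_path)
  paths["summary"] <- sum_path
  invisible(paths)
}
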