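#' Count consistent parameter sets
#'
#' Number of screen records whose monoclonal run is premalignant and whose
#' polyclonal run is controlled.
#'
#' @param records screen records from [run_screen()].
#' @param scenario optional scenario filter (`"P1"`, `"P10"`, `"P100"`).
#' @param s_h optional healthy specific-affinity filter.
#' @return An integer count.
#' @export
count_consistent <- function(records, scenario = NULL, s_h = NULL) {
  if (nrow(records) == 0) return(0L)
  keep <- records$consistent
  if (!is.null(scenario)) keep <- keep & records$scenario %in% scenario
  if (!is.null(s_h)) keep <- keep & records$s_h %in% s_h
  sum(keep)
}

octant_label <- function(s_fold, u_fold, v_fold) {
  sgn <- function(x) c("-", "0", "+")[sign(log(x)) + 2]
  paste0("s", sgn(s_fold), ":u", sgn(u_fold), ":v", sgn(v_fold))
}

#' Summarize the consistent parameter region
#'
#' Per-scenario summary of the consistent parameter sets: count, smallest
#' efficiency fold-change, whether all unspecific/specific affinity folds
#' are below 1, the fraction of sets in which the specific affinity is
#' decreased more strongly than the unspecific affinity (`s_fold < u_fold`),
#' and the octant membership of each set (sign pattern of the log folds;
#' fold 1 counts as neither decreased nor increased).
#'
#' @param records screen records from [run_screen()].
#' @return A data frame with one row per (scenario, `s_h`) present in
#'   `records` and columns `scenario`, `s_h`, `n_consistent`, `min_v_fold`,
#'   `frac_s_decrease_exceeds_u_decrease`, `all_u_below_one`,
#'   `all_s_below_one`, plus a list column `octant_counts` (named integer
#'   vectors).  Scenarios without consistent sets carry `NA` in the
#'   numeric summaries.
#' @export
summarize_consistent <- function(records) {
  if (nrow(records) == 0)
    stop("`records` is empty")
  groups <- unique(records[c("scenario", "s_h")])
  rownames(groups) <- NULL
  out <- lapply(seq_len(nrow(groups)), function(i) {
    rec <- records[records$scenario == groups$scenario[i] &
                     records$s_h == groups$s_h[i] &
                     records$consistent, , drop = FALSE]
    if (nrow(rec) == 0) {
      data.frame(scenario = groups$scenario[i], s_h = groups$s_h[i],
                 n_consistent = 0L, min_v_fold = NA_real_,
                 frac_s_decrease_exceeds_u_decrease = NA_real_,
                 all_u_below_one = NA, all_s_below_one = NA,
                 octant_counts = I(list(integer(0))))
    } else {
      oct <- table(octant_label(rec$s_fold, rec$u_fold, rec$v_fold))
      data.frame(
        scenario = groups$scenario[i], s_h = groups$s_h[i],
        n_consistent = nrow(rec), min_v_fold = min(rec$v_fold),
        frac_s_decrease_exceeds_u_decrease =
          mean(rec$s_fold < rec$u_fold),
        all_u_below_one = all(log(rec$u_fold) < 0),
        all_s_below_one = all(log(rec$s_fold) < 0),
        octant_counts = I(list(setNames(as.integer(oct), names(oct)))))
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit the u-v bounding band
#'
#' The consistent parameter sets obey a tight relation between the
#' unspecific-affinity fold `u_fold` and the efficiency fold `v_fold`: in
#' log-log coordinates all consistent points lie between two parallel
#' lines.  The common slope is fitted by least squares on the per-`v_fold`
#' midpoints of the `log(u_fold)` range, and the two intercepts are set to
#' the extreme residuals, so that the band is the minimal parallel band (of
#' that slope) enclosing every point.
#'
#' @param records screen records from [run_screen()]; only consistent rows
#'   are used.
#' @return An object of class `tn_band` with fields `slope`,
#'   `intercept_low`, `intercept_high`, `n_outside` (always 0 for the
#'   fitted band), `n_points`; or `NULL` when fewer than two distinct
#'   `v_fold` values are present among consistent records
#'   (under-determined).
#' @export
fit_uv_band <- function(records) {
  rec <- records[records$consistent, , drop = FALSE]
  if (nrow(rec) == 0 || length(unique(rec$v_fold)) < 2)
    return(NULL)
  lv <- log(rec$v_fold)
  lu <- log(rec$u_fold)
  mids <- vapply(split(lu, lv), function(x) (min(x) + max(x)) / 2,
                 numeric(1))
  vmid <- as.numeric(names(mids))
  slope <- stats::coef(stats::lm(mids ~ vmid))[[2]]
  resid <- lu - slope * lv
  structure(list(slope = slope,
                 intercept_low = min(resid),
                 intercept_high = max(resid),
                 n_outside = 0L, n_points = nrow(rec)),
            class = "tn_band")
}

#' @export
print.tn_band <- function(x, ...) {
  cat("<tn_band> log(u_fold) = slope * log(v_fold) + b\n")
  cat(sprintf("  slope = %.4f, intercepts [%.4f, %.4f] (width %.4f)\n",
              x$slope, x$intercept_low, x$intercept_high,
              x$intercept_high - x$intercept_low))
  cat(sprintf("  %d consistent points, %d outside the band\n",
              x$n_points, x$n_outside))
  invisible(x)
}

#' Count points outside a band
#'
#' @param band a `tn_band` from [fit_uv_band()].
#' @param records screen records; only consistent rows are tested.
#' @return Number of consistent points outside the closed band.
#' @export
band_outside <- function(band, records) {
  rec <- records[records$consistent, , drop = FALSE]
  resid <- log(rec$u_fold) - band$slope * log(rec$v_fold)
  tol <- 1e-12
  sum(resid < band$intercept_low - tol | resid > band$intercept_high + tol)
}

#' Text report of a screen
#'
#' Human-readable summary: record and consistency counts, per-scenario
#' characterization and the u-v band.
#'
#' @param records screen records from [run_screen()].
#' @param file optional path; when given the report is written there.
#' @return The report lines, invisibly when `file` is given.
#' @export
screen_report <- function(records, file = NULL) {
  lines <- c(
    sprintf("screen records:          %d", nrow(records)),
    sprintf("consistent records:      %d", count_consistent(records)),
    sprintf("non-converged runs:      %d mono, %d poly",
            sum(!records$mono_converged), sum(!records$poly_converged)))
  if (nrow(records) > 0 && any(records$consistent)) {
    s <- summarize_consistent(records)
    for (i in seq_len(nrow(s))) {
      lines <- c(lines, sprintf(
        "  %s (s_h = %g): n = %d, min v_fold = %s, frac(s<u) = %s",
        s$scenario[i], s$s_h[i], s$n_consistent[i],
        format(s$min_v_fold[i], digits = 4),
        format(s$frac_s_decrease_exceeds_u_decrease[i], digits = 3)))
    }
    band <- fit_uv_band(records)
    if (!is.null(band))
      lines <- c(lines, sprintf(
        "u-v band: slope %.3f, width %.3f, %d points outside",
        band$slope, band$intercept_high - band$intercept_low,
        band_outside(band, records)))
  }
  if (is.null(file)) {
    cat(lines, sep = "\n")
    invisible(lines)
  } else {
    writeLines(lines, file)
    invisible(lines)
  }
}

#' Diagnostic plots of the consistent region
#'
#' `plot_consistent_marginals()` draws per-parameter histograms of the
#' consistent fold-changes (log2 scale); `plot_uv_band()` draws the
#' consistent points in the log-log u-v plane together with the fitted
#' bounding band.
#'
#' @param records screen records from [run_screen()].
#' @param band optionally a precomputed [fit_uv_band()] result.
#' @return The input, invisibly.
#' @export
plot_consistent_marginals <- function(records) {
  rec <- records[records$consistent, , drop = FALSE]
  if (nrow(rec) == 0) stop("no consistent records to plot")
  old <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(old))
  for (par_name in c("s_fold", "u_fold", "v_fold")) {
    graphics::hist(log2(rec[[par_name]]), breaks = 20,
                   main = par_name, xlab = "log2 fold-change",
                   col = "grey80")
    graphics::abline(v = 0, col = "firebrick", lwd = 2)
  }
  invisible(records)
}

#' @rdname plot_consistent_marginals
#' @export
plot_uv_band <- function(records, band = fit_uv_band(records)) {
  rec <- records[records$consistent, , drop = FALSE]
  if (nrow(rec) == 0) stop("no consistent records to plot")
  plot(log(rec$v_fold), log(rec$u_fold), pch = 16,
       col = grDevices::adjustcolor("steelblue", 0.5),
       xlab = "log v fold-change", ylab = "log u fold-change")
  if (!is.null(band)) {
    graphics::abline(band$intercept_low, band$slope, col = "firebrick")
    graphics::abline(band$intercept_high, band$slope, col = "firebrick")
  }
  invisible(records)
}
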