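#' Integration settings
#'
#' Controls the adaptive integrator and the steady-state stopping rule.  The
#' state is examined on a fixed checkpoint grid (every `check_interval`
#' hours); abundances below `abundance_floor` are clamped to exactly 0 at
#' checkpoints (the continuous logistic never reaches 0 on its own, and the
#' zero branches of the model equations must be able to engage), and the run
#' is declared converged at the first checkpoint where
#' `max_i |c_i(t) - c_i(t - dt)| / max(c_i(t - dt), abundance_floor)` falls
#' below `rel_change_tol`.  Checking on a fixed grid makes the criterion
#' independent of the solver's internal step sequence.
#'
#' @param rel_change_tol relative-change threshold of the steady-state
#'   criterion (default `1e-6`).
#' @param check_interval checkpoint spacing in hours (default 1).
#' @param t_max horizon in hours after which a non-converged run is stopped
#'   and flagged (default `1e6`; reaching it is not an error).
#' @param rtol,atol relative/absolute tolerances of the Dormand-Prince 5(4)
#'   stepper.
#' @param abundance_floor cells; abundances below it are treated as extinct.
#' @param stop_at_convergence stop at the convergence checkpoint (`TRUE`,
#'   default) or keep integrating to `t_max`.
#' @return An object of class `tn_settings`.
#' @export
integration_settings <- function(rel_change_tol = 1e-6, check_interval = 1,
                                 t_max = 1e6, rtol = 1e-8, atol = 1e-10,
                                 abundance_floor = 1e-9,
                                 stop_at_convergence = TRUE) {
  stopifnot(rel_change_tol > 0, check_interval > 0,
            t_max >= check_interval, rtol > 0, atol >= 0,
            abundance_floor >= 0, is.logical(stop_at_convergence))
  structure(list(rel_change_tol = rel_change_tol,
                 check_interval = check_interval, t_max = t_max,
                 rtol = rtol, atol = atol,
                 abundance_floor = abundance_floor,
                 stop_at_convergence = stop_at_convergence),
            class = "tn_settings")
}

#' Integrate the full model
#'
#' Solves the model ODE system from an initial state, sampling the state at
#' every checkpoint and applying optional timed kill events.  Integration
#' stops at the steady-state criterion (see [integration_settings()]) or at
#' `t_max`, whichever comes first.
#'
#' @param config a [model_config()] with `n == q`.
#' @param c0 initial abundance vector of length `m`, e.g. from
#'   [make_initial_state()].
#' @param settings an [integration_settings()].
#' @param events `NULL` or a data frame with columns `time` and `fraction`:
#'   at each `time` (a positive multiple of `check_interval`, in increasing
#'   order) the fraction of cells is removed from every species.
#' @param save_trajectory keep the state at every checkpoint (`TRUE`,
#'   default) or only the final state.
#' @return An object of class `tn_trajectory` with elements `times`
#'   (checkpoint times), `states` (time x species matrix, present when
#'   `save_trajectory`), `final` (named final state), `converged`,
#'   `t_converged`, `t_end`, `config` and `settings`.  Trajectory states at
#'   an event time are the pre-kill states.
#' @examples
#' cfg <- model_config(q = 2, n = 2)
#' c0 <- make_initial_state(transplant_spec(total_cells = 10), cfg)
#' tr <- integrate_model(cfg, c0)
#' tr$converged
#' @export
integrate_model <- function(config, c0, settings = integration_settings(),
                            events = NULL, save_trajectory = TRUE) {
  stopifnot(inherits(config, "tn_config"), inherits(settings, "tn_settings"))
  if (length(c0) != config$m)
    stop("`c0` must have length m = 2q")
  if (any(c0 < 0)) stop("initial abundances must be non-negative")
  ev_t <- numeric(0)
  ev_f <- numeric(0)
  if (!is.null(events) && nrow(as.data.frame(events)) > 0) {
    events <- as.data.frame(events)
    stopifnot(all(c("time", "fraction") %in% names(events)))
    ev_t <- as.numeric(events$time)
    ev_f <- as.numeric(events$fraction)
    if (any(ev_f < 0 | ev_f > 1))
      stop("event fractions must lie in [0, 1]")
    if (is.unsorted(ev_t, strictly = TRUE))
      stop("event times must be strictly increasing")
    onf <- ev_t / settings$check_interval
    if (any(ev_t <= 0) || any(abs(onf - round(onf)) > 1e-8) ||
        any(ev_t > settings$t_max))
      stop("event times must be positive multiples of `check_interval` ",
           "within [0, t_max]")
  }
  A <- build_affinity_matrix(config)
  res <- .engine_integrate(as.numeric(c0), A, A, config$p,
                           efficiency_vector(config), config$tau,
                           unclass(settings), ev_t, ev_f, save_trajectory)
  out <- list(times = res$times, states = res$states,
              final = setNames(as.numeric(res$final),
                               species_labels(config)),
              converged = res$converged,
              t_converged = if (is.na(res$t_converged)) NA_real_
                            else res$t_converged,
              t_end = res$t_end, n_steps = res$n_steps,
              config = config, settings = settings)
  if (save_trajectory) colnames(out$states) <- species_labels(config)
  class(out) <- "tn_trajectory"
  out
}

#' @export
print.tn_trajectory <- function(x, ...) {
  cat("<tn_trajectory>", x$config$m, "species\n")
  cat(sprintf("  t_end = %g h, converged = %s%s\n", x$t_end,
              x$converged,
              if (isTRUE(x$converged)) sprintf(" (t = %g h)", x$t_converged)
              else ""))
  cat(sprintf("  final total = %g cells, preleukemic fraction = %.4g\n",
              sum(x$final), preleukemic_fraction(x$final, x$config)))
  invisible(x)
}

#' @export
plot.tn_trajectory <- function(x, log = "y", ...) {
  if (is.null(x$states))
    stop("trajectory was integrated with save_trajectory = FALSE")
  s <- x$states
  s[s <= 0] <- NA  # log axis
  graphics::matplot(x$times, s, type = "l", lty = 1,
                    col = c(rep("forestgreen", x$config$q),
                            rep("firebrick", x$config$q)),
                    xlab = "time [h]", ylab = "abundance [cells]",
                    log = log, ...)
  graphics::legend("bottomright", c("healthy", "preleukemic"),
                   col = c("forestgreen", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' Preleukemic fraction of a state
#'
#' Share of the total cell count contributed by the preleukemic species
#' (species `q+1..2q`); 0 by convention for an empty system.
#'
#' @param c abundance vector of length `m`.
#' @param config a [model_config()].
#' @return A scalar in `[0, 1]`.
#' @export
preleukemic_fraction <- function(c, config) {
  tot <- sum(c)
  if (tot <= 0) return(0)
  sum(c[(config$q + 1L):config$m]) / tot
}

#' Run the physiological (healthy-only) experiment
#'
#' Transplants 500 healthy cells into an empty system, lets it evolve over a
#' fixed horizon and removes 99% of all cells midway: the system grows to
#' the physiological steady state (`v_h * sum(p)` cells in total; with the
#' default symmetric parameters every clone at 100 cells) and re-establishes
#' it after the perturbation.
#'
#' @param clonality `"polyclonal"` or `"monoclonal"`.
#' @param config a [model_config()].
#' @param settings an [integration_settings()]; the stopping rule is not
#'   applied (the run always covers `[0, t_end]`).
#' @param t_end horizon in hours (default 400).
#' @param kill_time time of the kill event in hours (default 200).
#' @param kill_fraction fraction of cells removed (default 0.99).
#' @param total_cells transplanted cells (default 500).
#' @return A `tn_trajectory` over `[0, t_end]`.
#' @export
run_physiological <- function(clonality = c("polyclonal", "monoclonal"),
                              config = model_config(),
                              settings = integration_settings(),
                              t_end = 400, kill_time = 200,
                              kill_fraction = 0.99, total_cells = 500) {
  clonality <- match.arg(clonality)
  spec <- transplant_spec(total_cells = total_cells, n_preleukemic = 0,
                          clonality = clonality)
  c0 <- make_initial_state(spec, config)
  settings$t_max <- t_end
  settings$stop_at_convergence <- FALSE
  events <- if (kill_fraction > 0 && kill_time < t_end)
    data.frame(time = kill_time, fraction = kill_fraction) else NULL
  integrate_model(config, c0, settings, events = events,
                  save_trajectory = TRUE)
}

#' Export a trajectory as tidy CSV (plus JSON manifest)
#'
#' Writes one row per (checkpoint, species) with columns `time`,
#' `species_index` (1-based), `species_class` (`healthy`/`preleukemic`),
#' `clone_index` (1-based) and `abundance`, and a JSON sidecar holding the
#' full configuration, settings and convergence information.
#'
#' @param trajectory a `tn_trajectory` integrated with
#'   `save_trajectory = TRUE`.
#' @param file output CSV path; the manifest is written next to it with
#'   extension `.manifest.json`.
#' @return `file`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, file) {
  stopifnot(inherits(trajectory, "tn_trajectory"))
  df <- as.data.frame(trajectory)
  data.table::fwrite(df, file)
  cfg <- trajectory$config
  manifest <- list(
    package_version = as.character(utils::packageVersion("tniche")),
    config = {x <- unclass(cfg); x},
    settings = unclass(trajectory$settings),
    converged = trajectory$converged,
    t_converged = trajectory$t_converged,
    t_end = trajectory$t_end)
  jsonlite::write_json(manifest, sub("\\.csv$", "", file) %+%
                       ".manifest.json", auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(file)
}

`%+%` <- function(a, b) paste0(a, b)

#' @export
as.data.frame.tn_trajectory <- function(x, ...) {
  if (is.null(x$states))
    stop("trajectory was integrated with save_trajectory = FALSE")
  q <- x$config$q
  nt <- length(x$times)
  data.frame(
    time = rep(x$times, times = x$config$m),
    species_index = rep(seq_len(x$config$m), each = nt),
    species_class = rep(rep(c("healthy", "preleukemic"), each = q * nt)),
    clone_index = rep(rep(seq_len(q), each = nt), times = 2),
    abundance = as.vector(x$states))
}
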