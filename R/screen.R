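#' Fold-change grid
#'
#' Geometric grid of fold-changes applied to the preleukemic parameters
#' relative to their healthy counterparts: `step^k` for
#' `k = -(n_values-1)/2 .. (n_values-1)/2`.  With the defaults (41 values,
#' 20% relative spacing) the grid is centred on 1 and spans
#' `1.2^-20 ~ 1/38.3` to `1.2^20 ~ 38.3`.
#'
#' @param n_values odd number of grid values (default 41).
#' @param step ratio between neighbouring values (default 1.2).
#' @return An ascending numeric vector of length `n_values`.
#' @examples
#' g <- make_fold_grid()
#' g[21]          # exactly 1
#' range(g)       # ~0.0261 .. ~38.34
#' @export
make_fold_grid <- function(n_values = 41, step = 1.2) {
  stopifnot(n_values >= 1, n_values == as.integer(n_values), step > 1)
  if (n_values %% 2 == 0)
    stop("`n_values` must be odd so that the grid is centred on 1")
  k <- (n_values - 1) / 2
  step^seq(-k, k)
}

#' Outcome classification thresholds
#'
#' Criteria deciding whether a steady state counts as premalignant
#' (monoclonal runs) or controlled (polyclonal runs), expressed relative to
#' the physiological cell count:
#' \itemize{
#'   \item monoclonal premalignant: total cell count at least 300% of the
#'     physiological count AND preleukemic cells at least 80% of the total;
#'   \item polyclonal controlled: total at most 120% of the physiological
#'     count AND preleukemic cells at most 50% of the total.
#' }
#' All bounds are inclusive.
#'
#' @param mono_min_total_frac,mono_min_prelk_frac,poly_max_total_frac,poly_max_prelk_frac
#'   the four thresholds (defaults 3.0, 0.8, 1.2, 0.5).
#' @param reference_total physiological cell count; when `NULL` it is taken
#'   as `v_h * sum(p)` of the configuration in use (see
#'   [reference_total()]).
#' @return An object of class `tn_thresholds`.
#' @export
classification_thresholds <- function(mono_min_total_frac = 3.0,
                                      mono_min_prelk_frac = 0.8,
                                      poly_max_total_frac = 1.2,
                                      poly_max_prelk_frac = 0.5,
                                      reference_total = NULL) {
  stopifnot(mono_min_total_frac > 0, mono_min_prelk_frac > 0,
            poly_max_total_frac > 0, poly_max_prelk_frac > 0,
            poly_max_prelk_frac < mono_min_prelk_frac)
  structure(list(mono_min_total_frac = mono_min_total_frac,
                 mono_min_prelk_frac = mono_min_prelk_frac,
                 poly_max_total_frac = poly_max_total_frac,
                 poly_max_prelk_frac = poly_max_prelk_frac,
                 reference_total = reference_total),
            class = "tn_thresholds")
}

resolve_reference <- function(thresholds, config) {
  ref <- thresholds$reference_total
  if (is.null(ref)) ref <- reference_total(config)
  if (!is.numeric(ref) || ref <= 0)
    stop("`reference_total` must be positive")
  ref
}

#' Classify steady-state totals (vectorized)
#'
#' Workhorse behind [classify_outcome()] and [run_screen()]: applies the
#' classification thresholds to precomputed totals and preleukemic
#' fractions.
#'
#' @param total total cell count(s).
#' @param prelk_frac preleukemic fraction(s), in `[0, 1]`.
#' @param clonality `"monoclonal"` (returns the premalignant verdict) or
#'   `"polyclonal"` (returns the controlled verdict).
#' @param thresholds a [classification_thresholds()] with a resolved
#'   `reference_total`.
#' @return A logical vector.
#' @export
classify_totals <- function(total, prelk_frac,
                            clonality = c("monoclonal", "polyclonal"),
                            thresholds = classification_thresholds()) {
  clonality <- match.arg(clonality)
  ref <- thresholds$reference_total
  if (is.null(ref))
    stop("`thresholds$reference_total` must be set; see ",
         "`classification_thresholds()`")
  if (clonality == "monoclonal") {
    total >= thresholds$mono_min_total_frac * ref &
      prelk_frac >= thresholds$mono_min_prelk_frac
  } else {
    total <= thresholds$poly_max_total_frac * ref &
      prelk_frac <= thresholds$poly_max_prelk_frac
  }
}

#' Classify a final state
#'
#' Computes the total cell count and preleukemic fraction of a final state
#' and applies the classification criteria for the given clonality.
#'
#' @param final_state abundance vector of length `m` (typically
#'   `trajectory$final`).
#' @param config a [model_config()].
#' @param thresholds a [classification_thresholds()].
#' @param clonality `"monoclonal"` or `"polyclonal"`.
#' @return A list with `total`, `prelk_frac` and the verdict:
#'   `premalignant` (monoclonal) or `controlled` (polyclonal).
#' @export
classify_outcome <- function(final_state, config,
                             thresholds = classification_thresholds(),
                             clonality = c("monoclonal", "polyclonal")) {
  clonality <- match.arg(clonality)
  thresholds$reference_total <- resolve_reference(thresholds, config)
  total <- sum(final_state)
  frac <- preleukemic_fraction(final_state, config)
  verdict <- classify_totals(total, frac, clonality, thresholds)
  out <- list(total = total, prelk_frac = frac)
  out[[if (clonality == "monoclonal") "premalignant" else "controlled"]] <-
    verdict
  out
}

# per-member initial abundances of the three polyclonal species classes
# (paired healthy, unpaired healthy, seeded preleukemic) under the even
# allocation, obtained by averaging the actual transplant vector per class
poly_class_c0 <- function(config, n_pre, total_cells = 500) {
  spec <- transplant_spec(total_cells = total_cells, n_preleukemic = n_pre,
                          clonality = "polyclonal", allocation = "even")
  c0 <- make_initial_state(spec, config)
  q <- config$q
  h <- c0[seq_len(q)]
  paired <- mean(h[seq_len(n_pre)])
  unpaired <- if (n_pre < q) mean(h[(n_pre + 1L):q]) else 0
  c(paired, unpaired, 1)
}

#' Evaluate one preleukemic parameter set
#'
#' Sets `s_p = s_fold * s_h`, `u_p = u_fold * u_h`, `v_p = v_fold * v_h`,
#' runs the monoclonal and the polyclonal variant of the scenario from the
#' transplantation start to steady state, and classifies both outcomes.  A
#' parameter set is *consistent* with the transformation-assay observations
#' when the monoclonal run is premalignant and the polyclonal run is
#' controlled.
#'
#' @param s_fold,u_fold,v_fold positive fold-changes of the preleukemic
#'   specific affinity, unspecific affinity and resource utilization
#'   efficiency.
#' @param scenario `"P1"`, `"P10"` or `"P100"` (1, 10 or 100 preleukemic
#'   cells among the 500 transplanted).
#' @param config a [model_config()]; its `s_p`, `u_p`, `v_p` fields are
#'   overridden by the folds.
#' @param settings an [integration_settings()].
#' @param thresholds a [classification_thresholds()].
#' @param method `"reduced"` (default) integrates the exact class-reduced
#'   system in compiled code; `"full"` integrates all `2q` species.  Both
#'   converge to the same steady state (the reduced path is validated
#'   against the full path in the package tests).
#' @return A one-row data frame: the screen record for this parameter set,
#'   with scenario, `s_h`, folds, steady-state totals and preleukemic
#'   fractions, convergence flags and the three verdicts.
#' @examples
#' \donttest{
#' evaluate_parameter_set(0.2, 0.3, 6, scenario = "P100")
#' }
#' @export
evaluate_parameter_set <- function(s_fold, u_fold, v_fold,
                                   scenario = c("P1", "P10", "P100"),
                                   config = model_config(),
                                   settings = integration_settings(),
                                   thresholds = classification_thresholds(),
                                   method = c("reduced", "full")) {
  scenario <- match.arg(scenario)
  method <- match.arg(method)
  stopifnot(s_fold > 0, u_fold > 0, v_fold > 0)
  n_pre <- scenario_n_preleukemic(scenario)
  thresholds$reference_total <- resolve_reference(thresholds, config)

  if (method == "reduced") {
    res <- screen_chunk(s_fold, u_fold, v_fold, scenario, config, settings)
  } else {
    cfg <- model_config(q = config$q, n = config$n, p = config$p,
                        tau = config$tau, s_h = config$s_h, u_h = config$u_h,
                        v_h = config$v_h, s_p = s_fold * config$s_h,
                        u_p = u_fold * config$u_h, v_p = v_fold * config$v_h)
    run1 <- function(clonality) {
      spec <- transplant_spec(n_preleukemic = n_pre, clonality = clonality)
      tr <- integrate_model(cfg, make_initial_state(spec, cfg), settings,
                            save_trajectory = FALSE)
      list(total = sum(tr$final),
           frac = preleukemic_fraction(tr$final, cfg),
           converged = tr$converged, t_converged = tr$t_converged)
    }
    mono <- run1("monoclonal")
    poly <- run1("polyclonal")
    res <- data.frame(
      mono_total = mono$total, mono_prelk_frac = mono$frac,
      mono_converged = mono$converged, mono_t_converged = mono$t_converged,
      poly_total = poly$total, poly_prelk_frac = poly$frac,
      poly_converged = poly$converged, poly_t_converged = poly$t_converged)
  }
  assemble_records(scenario, config$s_h, s_fold, u_fold, v_fold, res,
                   thresholds)
}

# run the compiled reduced-system sweep for vectors of folds (one scenario)
screen_chunk <- function(s_fold, u_fold, v_fold, scenario, config, settings,
                         total_cells = 500) {
  n_pre <- scenario_n_preleukemic(scenario)
  if (length(unique(config$p)) != 1)
    stop("the reduced screen path requires a homogeneous supply vector `p`")
  if (config$n != config$q)
    stop("the screen requires n == q")
  as.data.frame(.engine_screen(
    as.numeric(s_fold), as.numeric(u_fold), as.numeric(v_fold),
    config$s_h, config$u_h, config$v_h, config$q, n_pre,
    as.integer(total_cells), config$p[1], config$tau,
    poly_class_c0(config, n_pre, total_cells), unclass(settings)))
}

assemble_records <- function(scenario, s_h, s_fold, u_fold, v_fold, res,
                             thresholds) {
  rec <- data.frame(scenario = scenario, s_h = s_h, s_fold = s_fold,
                    u_fold = u_fold, v_fold = v_fold, res,
                    row.names = NULL)
  rec$mono_premalignant <- classify_totals(rec$mono_total,
                                           rec$mono_prelk_frac,
                                           "monoclonal", thresholds)
  rec$poly_controlled <- classify_totals(rec$poly_total,
                                         rec$poly_prelk_frac,
                                         "polyclonal", thresholds)
  rec$consistent <- rec$mono_premalignant & rec$poly_controlled
  rec
}

#' Run the transformation-assay parameter screen
#'
#' Evaluates every combination of scenario, healthy specific affinity and
#' (s, u, v) fold-change triple on the grid, running the monoclonal and
#' polyclonal transplantation for each and classifying the outcomes.  The
#' default screen (3 scenarios x 41^3 grid points at `s_h = 1`) evaluates
#' 206,763 parameter sets.
#'
#' Records are produced in deterministic order: scenario, then `s_h`, then
#' the grid in lexicographic (s, u, v) order with `v_fold` varying fastest.
#' When `out_dir` is given, each (scenario, `s_h`, `s_fold`) slice is
#' written to disk as it completes and an existing slice file is reused on
#' resume, so an interrupted sweep can be continued with `resume = TRUE`.
#'
#' @param scenarios character vector among `"P1"`, `"P10"`, `"P100"`.
#' @param s_h_values healthy specific affinities to screen (default 1; the
#'   robustness analysis also uses 0.2 and 5).
#' @param grid fold-change grid from [make_fold_grid()].
#' @param config base [model_config()].
#' @param settings an [integration_settings()].
#' @param thresholds a [classification_thresholds()].
#' @param workers parallel worker processes for slices (forked via
#'   \pkg{parallel}; default 1).
#' @param out_dir optional directory for slice CSVs and the run manifest.
#' @param resume reuse completed slice files found in `out_dir`.
#' @param progress print a progress line per block.
#' @return A data frame with one row per evaluated parameter set (columns:
#'   `scenario`, `s_h`, `s_fold`, `u_fold`, `v_fold`, `mono_total`,
#'   `mono_prelk_frac`, `mono_converged`, `mono_t_converged`, `poly_total`,
#'   `poly_prelk_frac`, `poly_converged`, `poly_t_converged`,
#'   `mono_premalignant`, `poly_controlled`, `consistent`).
#' @examples
#' \donttest{
#' toy <- run_screen(scenarios = "P100", grid = make_fold_grid(3, 4))
#' nrow(toy)  # 27
#' }
#' @export
run_screen <- function(scenarios = c("P1", "P10", "P100"), s_h_values = 1,
                       grid = make_fold_grid(), config = model_config(),
                       settings = integration_settings(),
                       thresholds = classification_thresholds(),
                       workers = 1L, out_dir = NULL, resume = FALSE,
                       progress = FALSE) {
  scenarios <- match.arg(scenarios, c("P1", "P10", "P100"),
                         several.ok = TRUE)
  stopifnot(length(grid) >= 1, all(grid > 0), length(s_h_values) >= 1)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  uv <- expand.grid(v_fold = grid, u_fold = grid,
                    KEEP.OUT.ATTRS = FALSE)  # v varies fastest
  blocks <- expand.grid(s_fold = grid, s_h = s_h_values,
                        scenario = scenarios, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  # deterministic order: scenario, s_h, s_fold
  blocks <- blocks[order(match(blocks$scenario, scenarios),
                         match(blocks$s_h, s_h_values),
                         match(blocks$s_fold, grid)), , drop = FALSE]

  eval_block <- function(b) {
    sc <- blocks$scenario[b]
    sh <- blocks$s_h[b]
    sf <- blocks$s_fold[b]
    slice_file <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("slice_%s_sh%g_s%03d.csv", sc, sh,
                                 match(sf, grid)))
    if (resume && !is.null(out_dir) && file.exists(slice_file)) {
      rec <- as.data.frame(data.table::fread(slice_file))
      return(rec)
    }
    cfg <- config
    cfg$s_h <- sh
    th <- thresholds
    th$reference_total <- resolve_reference(thresholds, cfg)
    res <- screen_chunk(rep(sf, nrow(uv)), uv$u_fold, uv$v_fold, sc, cfg,
                        settings)
    rec <- assemble_records(sc, sh, sf, uv$u_fold, uv$v_fold, res, th)
    if (!is.null(out_dir)) data.table::fwrite(rec, slice_file)
    if (progress)
      message(sprintf("screen block %d/%d (%s, s_h = %g, s_fold = %g): %d consistent",
                      b, nrow(blocks), sc, sh, sf, sum(rec$consistent)))
    rec
  }

  idx <- seq_len(nrow(blocks))
  recs <- if (workers > 1L) {
    parallel::mclapply(idx, eval_block, mc.cores = workers,
                       mc.preschedule = FALSE)
  } else {
    lapply(idx, eval_block)
  }
  failed <- vapply(recs, inherits, logical(1), "try-error")
  if (any(failed))
    stop("screen blocks failed: ", paste(idx[failed], collapse = ", "))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  if (!is.null(out_dir))
    write_run_manifest(file.path(out_dir, "manifest.json"), config = config,
                       grid = grid, thresholds = thresholds,
                       settings = settings,
                       scenarios = scenarios, s_h_values = s_h_values,
                       n_records = nrow(out))
  out
}

screen_columns <- c("scenario", "s_h", "s_fold", "u_fold", "v_fold",
                    "mono_total", "mono_prelk_frac", "mono_converged",
                    "mono_t_converged", "poly_total", "poly_prelk_frac",
                    "poly_converged", "poly_t_converged",
                    "mono_premalignant", "poly_controlled", "consistent")

#' Read / write screen records
#'
#' CSV persistence for screen outputs.  `read_screen_csv()` validates that
#' all record columns are present and reports any that are missing.
#'
#' @param records a screen record data frame from [run_screen()].
#' @param file CSV path.
#' @return `write_screen_csv()` returns `file` invisibly;
#'   `read_screen_csv()` returns the records data frame.
#' @export
write_screen_csv <- function(records, file) {
  missing <- setdiff(screen_columns, names(records))
  if (length(missing) > 0)
    stop("records are missing columns: ", paste(missing, collapse = ", "))
  data.table::fwrite(records[screen_columns], file)
  invisible(file)
}

#' @rdname write_screen_csv
#' @export
read_screen_csv <- function(file) {
  rec <- as.data.frame(data.table::fread(file))
  missing <- setdiff(screen_columns, names(rec))
  if (length(missing) > 0)
    stop("screen CSV is missing columns: ",
         paste(missing, collapse = ", "))
  rec
}

#' Write a run manifest
#'
#' JSON snapshot of everything needed to re-run an experiment: the
#' configuration, grid, thresholds, settings, scenario list and package
#' version.
#'
#' @param path output JSON path.
#' @param config,grid,thresholds,settings,scenarios,s_h_values run inputs.
#' @param ... further fields stored verbatim (e.g. seeds, record counts).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, grid = NULL, thresholds = NULL,
                               settings = NULL, scenarios = NULL,
                               s_h_values = NULL, ...) {
  manifest <- list(
    package_version = as.character(utils::packageVersion("tniche")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = if (!is.null(config)) unclass(config),
    grid = grid,
    thresholds = if (!is.null(thresholds)) unclass(thresholds),
    settings = if (!is.null(settings)) unclass(settings),
    scenarios = scenarios, s_h_values = s_h_values, ...)
  jsonlite::write_json(manifest[!vapply(manifest, is.null, logical(1))],
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
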