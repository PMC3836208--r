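#' Transplantation specification
#'
#' Describes an in-silico transplantation: how many cells are put into an
#' empty system, how many of them are preleukemic, whether the graft is
#' monoclonal or polyclonal, and how cells are allocated to clones.  The
#' transformation-assay scenarios P1, P10 and P100 correspond to 1, 10 and
#' 100 preleukemic cells out of 500 transplanted.
#'
#' @param total_cells total transplanted cells (default 500).
#' @param n_preleukemic number of preleukemic cells among them (0, 1, 10 or
#'   100 in the standard scenarios).
#' @param clonality `"polyclonal"` (cells spread over all clones) or
#'   `"monoclonal"` (all cells in clone 1).
#' @param allocation `"even"` (deterministic: healthy cells split as equally
#'   as possible over clones, remainder to the lowest clone indices) or
#'   `"multinomial"` (one uniform multinomial draw; requires `seed`).
#' @param seed integer seed for multinomial allocation.
#' @return An object of class `tn_transplant`.
#' @examples
#' transplant_spec(n_preleukemic = 10)                    # scenario P10
#' transplant_spec(clonality = "monoclonal", n_preleukemic = 100)
#' @export
transplant_spec <- function(total_cells = 500, n_preleukemic = 0,
                            clonality = c("polyclonal", "monoclonal"),
                            allocation = c("even", "multinomial"),
                            seed = NULL) {
  clonality <- match.arg(clonality)
  allocation <- match.arg(allocation)
  stopifnot(total_cells >= 1, total_cells == as.integer(total_cells),
            n_preleukemic >= 0, n_preleukemic == as.integer(n_preleukemic))
  if (n_preleukemic > total_cells)
    stop("`n_preleukemic` cannot exceed `total_cells`")
  if (allocation == "multinomial" && is.null(seed))
    stop("multinomial allocation requires a `seed`")
  structure(
    list(total_cells = as.integer(total_cells),
         n_preleukemic = as.integer(n_preleukemic),
         clonality = clonality, allocation = allocation, seed = seed),
    class = "tn_transplant")
}

#' Scenario lookup
#'
#' Maps a scenario label to the number of initially preleukemic cells among
#' the 500 transplanted: P1 -> 1 (0.2%), P10 -> 10 (2%), P100 -> 100 (20%).
#'
#' @param scenario `"P1"`, `"P10"` or `"P100"`.
#' @return An integer.
#' @export
scenario_n_preleukemic <- function(scenario) {
  scenario <- match.arg(scenario, c("P1", "P10", "P100"))
  c(P1 = 1L, P10 = 10L, P100 = 100L)[[scenario]]
}

#' Build a transplantation initial state
#'
#' Produces the initial abundance vector `c(0)` of length `m = 2q` for a
#' transplantation into an empty system.  Abundances are integer-valued and
#' sum exactly to `total_cells`.
#'
#' Polyclonal: the preleukemic cells are placed one per species in species
#' `q+1 .. q+n_preleukemic`; the remaining healthy cells are distributed over
#' the `q` healthy species either as equally as possible (`"even"`, with the
#' remainder going one cell each to the lowest clone indices) or by a single
#' uniform multinomial draw (`"multinomial"`).  Monoclonal: all healthy cells
#' go to species 1 and all preleukemic cells to species `q+1`.
#'
#' @param spec a [transplant_spec()].
#' @param config a [model_config()].
#' @return A named numeric vector of length `m`.
#' @examples
#' cfg <- model_config()
#' c0 <- make_initial_state(
#'   transplant_spec(n_preleukemic = 100, clonality = "monoclonal"), cfg)
#' c0[["h1"]]; c0[["p1"]]   # 400 healthy, 100 preleukemic in clone 1
#' @export
make_initial_state <- function(spec, config) {
  stopifnot(inherits(spec, "tn_transplant"), inherits(config, "tn_config"))
  q <- config$q
  npk <- spec$n_preleukemic
  nh <- spec$total_cells - npk
  c0 <- numeric(config$m)

  if (spec$clonality == "monoclonal") {
    c0[1L] <- nh
    if (npk > 0) c0[q + 1L] <- npk
  } else {
    if (npk > q)
      stop("polyclonal transplants allow at most one preleukemic cell ",
           "per clone (n_preleukemic <= q)")
    if (npk > 0) c0[q + seq_len(npk)] <- 1
    if (spec$allocation == "even") {
      base <- nh %/% q
      rem <- nh %% q
      healthy <- rep(base, q)
      if (rem > 0) healthy[seq_len(rem)] <- healthy[seq_len(rem)] + 1
    } else {
      healthy <- local_seed_draw(spec$seed, function()
        as.numeric(rmultinom(1L, nh, prob = rep(1 / q, q))))
    }
    c0[seq_len(q)] <- healthy
  }
  setNames(c0, species_labels(config))
}

# evaluate fn() under a temporary RNG state seeded with `seed`
local_seed_draw <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Proportional cell kill
#'
#' Scales every species abundance by `1 - fraction`, mimicking an acute cell
#' loss (e.g. the 99% kill used in the perturbation experiment).  Species at
#' 0 remain exactly 0.
#'
#' @param c abundance vector.
#' @param fraction fraction of cells removed, in `[0, 1]`.
#' @return The scaled abundance vector.
#' @export
apply_cell_kill <- function(c, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      is.na(fraction) || fraction < 0 || fraction > 1)
    stop("`fraction` must be a single value in [0, 1]")
  c * (1 - fraction)
}
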