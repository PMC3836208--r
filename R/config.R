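#' Model configuration
#'
#' Bundles all scalar and vector parameters of the niche-competition model.
#' The system has `n` niches, `q` TCR-defined clones and `m = 2q` species:
#' species `1..q` are the healthy cells of each clone, species `q+1..2q` the
#' preleukemic (oncogene-transduced) cells.  Defaults follow the reference
#' parameterization: 100 niches and clones, each niche supplying 100 resource
#' units per hour (so the physiological pool holds `v_h * sum(p) = 1e4`
#' cells), a minimum cell cycle time of 8 h, healthy specific affinity
#' `s_h = 1`, healthy unspecific affinity `u_h = 1/n` (the natural anchor,
#' since resource allocation depends on relative affinities only) and
#' healthy efficiency `v_h = 1`.  Preleukemic parameters default to their
#' healthy counterparts; the screen varies them as fold-changes.
#'
#' @param q number of TCR-defined clones (positive integer).
#' @param n number of niches (positive integer).
#' @param p niche resource supply rates, resource units per hour; a scalar is
#'   recycled to length `n`.
#' @param tau minimum cell cycle time in hours (positive).
#' @param s_h,u_h,v_h specific affinity, unspecific affinity and resource
#'   utilization efficiency of the healthy species (non-negative).
#' @param s_p,u_p,v_p the same three parameters for the preleukemic species.
#'
#' @return An object of class `tn_config`: a named list with fields `n`, `q`,
#'   `m`, `p`, `tau`, `s_h`, `u_h`, `v_h`, `s_p`, `u_p`, `v_p`.
#' @examples
#' cfg <- model_config()
#' cfg$m                      # 200 species
#' sum(cfg$p) * cfg$v_h       # physiological cell count, 1e4
#' @export
model_config <- function(q = 100, n = q, p = 100, tau = 8,
                         s_h = 1, u_h = 1 / n, v_h = 1,
                         s_p = s_h, u_p = u_h, v_p = v_h) {
  stopifnot(length(q) == 1, length(n) == 1, q >= 1, n >= 1,
            q == as.integer(q), n == as.integer(n))
  if (length(p) == 1) p <- rep(as.numeric(p), n)
  if (length(p) != n) stop("`p` must be a scalar or a vector of length n")
  if (any(p < 0)) stop("niche supply rates `p` must be non-negative")
  if (!is.finite(tau) || tau <= 0) stop("`tau` must be positive")
  aff <- c(s_h = s_h, u_h = u_h, v_h = v_h, s_p = s_p, u_p = u_p, v_p = v_p)
  if (any(!is.finite(aff)) || any(aff < 0))
    stop("affinities and efficiencies must be finite and non-negative")
  structure(
    list(n = as.integer(n), q = as.integer(q), m = 2L * as.integer(q),
         p = p, tau = as.numeric(tau),
         s_h = as.numeric(s_h), u_h = as.numeric(u_h), v_h = as.numeric(v_h),
         s_p = as.numeric(s_p), u_p = as.numeric(u_p), v_p = as.numeric(v_p)),
    class = "tn_config")
}

#' @export
print.tn_config <- function(x, ...) {
  cat("<tn_config> niche-competition model\n")
  cat(sprintf("  niches n = %d, clones q = %d (m = %d species)\n",
              x$n, x$q, x$m))
  prng <- range(x$p)
  cat(sprintf("  supply p = %s per niche/h, tau = %g h\n",
              if (prng[1] == prng[2]) format(prng[1])
              else paste0("[", prng[1], ", ", prng[2], "]"), x$tau))
  cat(sprintf("  healthy:     s = %g, u = %g, v = %g\n", x$s_h, x$u_h, x$v_h))
  cat(sprintf("  preleukemic: s = %g, u = %g, v = %g\n", x$s_p, x$u_p, x$v_p))
  invisible(x)
}

#' Physiological reference cell count
#'
#' Total cell count sustained by healthy cells at steady state when every
#' niche is contested, `v_h * sum(p)`.  Used as the reference in outcome
#' classification.
#'
#' @param config a [model_config()].
#' @return A scalar.
#' @export
reference_total <- function(config) config$v_h * sum(config$p)

#' Read / write a model configuration
#'
#' Configurations are stored as flat key-value YAML or JSON (keys `n`, `q`,
#' `p`, `tau`, `s_h`, `u_h`, `v_h`, `s_p`, `u_p`, `v_p`; `p` may be a scalar
#' meaning a constant vector).  The format is chosen from the file extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param path file path.
#' @return `read_model_config()` returns a `tn_config`;
#'   `write_model_config()` returns `path` invisibly.
#' @export
read_model_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("n", "q", "p", "tau", "s_h", "u_h", "v_h", "s_p", "u_p", "v_p")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(model_config, raw[intersect(known, names(raw))])
}

#' @rdname read_model_config
#' @param config a [model_config()] to serialize.
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "tn_config"))
  x <- unclass(config)
  x$m <- NULL
  if (length(unique(x$p)) == 1) x$p <- x$p[1]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
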