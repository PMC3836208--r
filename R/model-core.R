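#' Build the niche affinity matrix
#'
#' Constructs the `m x n` affinity matrix `A` from the four affinity scalars.
#' Each clone has one preferred niche (clone `i` prefers niche `i`, which
#' requires `n == q`): a healthy species has affinity `s_h + u_h` for its
#' preferred niche and `u_h` for every other niche, and analogously
#' `s_p + u_p` / `u_p` for the preleukemic species.  Rows `1..q` are the
#' healthy block, rows `q+1..2q` the preleukemic block (the vertical
#' concatenation of the two blocks).
#'
#' @param config a [model_config()] with `n == q`.
#' @return An `m x n` numeric matrix with rownames `h1..hq, p1..pq` and
#'   colnames `niche1..nichen`.
#' @examples
#' A <- build_affinity_matrix(model_config(q = 2, n = 2, u_h = 0.5))
#' @export
build_affinity_matrix <- function(config) {
  stopifnot(inherits(config, "tn_config"))
  if (config$n != config$q)
    stop("the preferred-niche construction requires n == q")
  q <- config$q
  Ah <- matrix(config$u_h, q, q)
  diag(Ah) <- config$s_h + config$u_h
  Ap <- matrix(config$u_p, q, q)
  diag(Ap) <- config$s_p + config$u_p
  A <- rbind(Ah, Ap)
  dimnames(A) <- list(species_labels(config), paste0("niche", seq_len(q)))
  A
}

species_labels <- function(config) {
  c(paste0("h", seq_len(config$q)), paste0("p", seq_len(config$q)))
}

#' Resource acquisition rates
#'
#' Rate at which each species acquires resources from each niche.  A niche
#' distributes its total supply `p_j` among the species in proportion to
#' affinity-weighted abundance:
#' `r_ij = a_ij c_i / sum_k(a_kj c_k) * p_j` when the denominator is
#' positive, and 0 otherwise (an uncontested niche delivers nothing).  The
#' rates in each contested niche column therefore sum exactly to `p_j`.
#'
#' @param A `m x n` affinity matrix, see [build_affinity_matrix()].
#' @param c abundance vector of length `m` (non-negative).
#' @param p niche supply vector of length `n` (non-negative).
#' @return An `m x n` matrix of non-negative rates.
#' @examples
#' resource_rates(matrix(0.5), c = 10, p = 100)  # sole competitor: 100
#' @export
resource_rates <- function(A, c, p) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == length(c), ncol(A) == length(p))
  if (any(c < 0) || any(p < 0) || any(A < 0))
    stop("abundances, supplies and affinities must be non-negative")
  wc <- A * c                    # a_ij * c_i
  den <- colSums(wc)
  share <- ifelse(den > 0, p / den, 0)
  sweep(wc, 2L, share, `*`)
}

#' Carrying capacities
#'
#' Number of cells of each species the current resource flow can sustain:
#' the efficiency-weighted row sum of the resource acquisition rates,
#' `k_i = v_i * sum_j(r_ij)`.
#'
#' @param r `m x n` matrix of resource acquisition rates, see
#'   [resource_rates()].
#' @param v efficiency vector of length `m` (cells per resource unit per
#'   hour).
#' @return A vector of length `m`.
#' @export
carrying_capacities <- function(r, v) {
  r <- as.matrix(r)
  stopifnot(nrow(r) == length(v))
  as.numeric(v * rowSums(r))
}

#' Logistic growth right-hand side
#'
#' Species grow logistically towards their (dynamic) carrying capacity with
#' minimum cell cycle time `tau`:
#' `dc_i/dt = c_i/tau * (1 - c_i/k_i)` when `k_i > 0`, and 0 when
#' `k_i == 0`.  A species at abundance 0 has derivative 0, so the
#' non-negative orthant is forward-invariant.
#'
#' @param c abundance vector (non-negative).
#' @param k carrying-capacity vector, same length as `c`.
#' @param tau minimum cell cycle time in hours.
#' @return The derivative vector `dc/dt`.
#' @examples
#' growth_rhs(c = 50, k = 100, tau = 8)  # (50/8) * (1 - 0.5) = 3.125
#' @export
growth_rhs <- function(c, k, tau) {
  stopifnot(length(c) == length(k), tau > 0)
  ifelse(k > 0, c / tau * (1 - c / k), 0)
}

#' Full model right-hand side
#'
#' Composition of [resource_rates()], [carrying_capacities()] and
#' [growth_rhs()] for a given configuration: the complete vector field of
#' the model.  Mainly useful for inspection and for driving external ODE
#' solvers; [integrate_model()] uses the package's compiled engine.
#'
#' @param c abundance vector of length `m`.
#' @param config a [model_config()].
#' @param A optional precomputed affinity matrix (defaults to
#'   [build_affinity_matrix()] of `config`).
#' @return The derivative vector `dc/dt` of length `m`.
#' @export
model_rhs <- function(c, config, A = NULL) {
  if (is.null(A)) A <- build_affinity_matrix(config)
  v <- rep(c(config$v_h, config$v_p), each = config$q)
  r <- resource_rates(A, c, config$p)
  growth_rhs(c, carrying_capacities(r, v), config$tau)
}

#' Species efficiency vector
#'
#' The length-`m` vector `(v_h, ..., v_h, v_p, ..., v_p)` pairing each
#' species with its resource utilization efficiency.
#'
#' @param config a [model_config()].
#' @return A numeric vector of length `m`.
#' @export
efficiency_vector <- function(config) {
  rep(c(config$v_h, config$v_p), each = config$q)
}
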