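# Phenotype-structured tissue dynamics in the mammary duct neighbour
# volume: capacity-limited proliferation and apoptosis modulated by the
# TGF-beta influx through power-law sensing factors, degradation, stepwise
# mutation, and a direct-to-malignant mutation channel during proliferation.
#
# Per phenotype phi (N = cells per neighbour volume, B_in = average ligand
# influx per cell from the cellular model):
#   prolif(phi) = r_p(phi) x^(-g_p(phi)) N(phi) (1 - sum(N)/C_phi)
#   death(phi)  = r_a x^(+g_a(phi)) N(phi) + r_d N(phi)
#   x = gamma B_in(phi) / alpha  (floored)
# plus the unidirectional stepwise mutation flux r_m N(phi-1) -> N(phi) and
# the rerouting of a fraction p_Phi of every non-malignant proliferation
# gain directly to phi = Phi. Positive sensing exponents mean TGF-beta
# downregulates proliferation and promotes apoptosis (healthy end); the
# negative malignant entries flip both (the "Jekyll and Hyde" switch).

#' TGF-beta response factor
#'
#' Dimensionless power-law response `(gamma * B_in / alpha)^g` encoding the
#' serial amplification cascade with which a cell senses the entering
#' TGF-beta flux. The factor is 1 when `g = 0` or when the scaled signal is
#' 1, and is increasing in `B_in` iff `g > 0`. A zero influx with a
#' negative exponent is clamped at a configurable floor on the scaled
#' signal (`floor`, default 1e-12) rather than diverging.
#'
#' @param B_in TGF-beta influx entering a cell (nmol/s); non-negative,
#'   vectorized.
#' @param g Sensing exponent (dimensionless).
#' @param gamma,alpha Dimensional constants (1/nmol, 1/s).
#' @param floor Lower clamp on the scaled signal.
#' @return Dimensionless factor(s).
#' @export
#' @examples
#' response_factor(5, 0)    # neutral exponent: 1
#' response_factor(1, 0.3)  # unit scaled signal: 1
response_factor <- function(B_in, g, gamma = 1, alpha = 1, floor = 1e-12) {
  if (any(B_in < 0)) stop("B_in must be non-negative")
  x <- pmax(gamma * B_in / alpha, floor)
  x^g
}

#' Time derivatives of the tissue model
#'
#' @param N Cell counts per phenotype (length `Phi + 1`, cells per
#'   neighbour volume).
#' @param B_in Average TGF-beta influx per cell of each phenotype
#'   (length `Phi + 1`, nmol/s).
#' @param params Parameter set.
#' @return Numeric vector `dN/dt` (cells per neighbour volume per second).
#' @export
tissue_rhs <- function(N, B_in, params = default_parameters()) {
  nphi <- params$Phi + 1L
  stopifnot(length(N) == nphi, length(B_in) == nphi)
  if (any(N < 0)) stop("tissue state must be non-negative")
  if (any(B_in < 0)) stop("B_in must be non-negative")
  Ntot <- sum(N)
  fl <- params$response_floor
  prolif <- params$r_p *
    response_factor(B_in, -params$g_p, params$gamma, params$alpha, fl) *
    N * (1 - Ntot / params$C_phi)
  death <- params$r_a *
    response_factor(B_in, params$g_a, params$gamma, params$alpha, fl) * N +
    params$r_d * N
  # unidirectional stepwise mutation on standing populations
  out_step <- params$r_m * N * c(rep(1, nphi - 1L), 0)
  in_step  <- c(0, params$r_m * N[-nphi])
  # fraction p_Phi of every non-malignant proliferation gain lands at Phi
  keep <- c(rep(1 - params$p_Phi, nphi - 1L), 1)
  jump <- params$p_Phi * sum(prolif[-nphi])
  keep * prolif + c(rep(0, nphi - 1L), jump) - death - out_step + in_step
}

#' Simulate the tissue model
#'
#' Integrates the phenotype-structured population dynamics under a given
#' (constant or time-varying) TGF-beta influx. From a healthy duct
#' neighbourhood the default parameters reproduce the canonical
#' progression: healthy cells decline, pre-neoplastic phenotypes rise in
#' order, and the malignant sub-population stays near zero for a long
#' latency before a steep proliferation phase.
#'
#' @param init Initial cell counts per phenotype.
#' @param B_in Either a numeric vector (constant influx) or a function of
#'   time (seconds) returning the influx vector.
#' @param params Parameter set.
#' @param t_grid Strictly increasing time grid (seconds).
#' @param atol,rtol Integrator tolerances.
#' @return A [trajectory()] with model id `"tissue"`, columns `N.phi` and
#'   time reported in months.
#' @export
simulate_tissue <- function(init, B_in, params = default_parameters(), t_grid,
                            atol = 1e-12, rtol = 1e-10) {
  nphi <- params$Phi + 1L
  stopifnot(length(init) == nphi)
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0)) {
    stop("t_grid must be strictly increasing")
  }
  influx <- if (is.function(B_in)) B_in else function(t) B_in
  rhs <- function(t, y, p) {
    y[y < 0] <- 0
    list(tissue_rhs(y, influx(t), params))
  }
  sol <- deSolve::lsoda(y = as.numeric(init), times = t_grid, func = rhs,
                        parms = NULL, atol = atol, rtol = rtol)
  if (attr(sol, "istate")[1] < 0) {
    stop(sprintf("tissue integration failed near t = %g s", max(sol[, 1])))
  }
  state <- sol[, -1, drop = FALSE]
  state[state < 0] <- 0
  colnames(state) <- sprintf("N.%d", seq_len(nphi) - 1L)
  trajectory(sol[, 1] / (DAYS_PER_MONTH * SECONDS_PER_DAY), state,
             model = "tissue", time_unit = "month",
             units = setNames(rep("1/V_neigh", nphi), colnames(state)),
             meta = list(atol = atol, rtol = rtol))
}

#' Phenotype fraction along a tissue trajectory
#'
#' @param traj A tissue (or multiscale) [trajectory()] with columns `N.phi`.
#' @param phi Phenotype index.
#' @param t Time in the trajectory's time unit (months).
#' @return Fraction `N(phi, t) / sum_psi N(psi, t)` in `[0, 1]`.
#' @export
phenotype_fraction <- function(traj, phi, t) {
  v <- trajectory_at(traj, t)
  N <- v[grep("^N\\.", names(v))]
  if (sum(N) <= 0) stop("phenotype fraction undefined: zero total population")
  unname(N[sprintf("N.%d", phi)] / sum(N))
}
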