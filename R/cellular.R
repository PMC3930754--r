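# Cellular exchange model: per-phenotype TGF-beta synthesis, receptor
# binding, internalization, healthy-only ubiquitination, and paracrine
# exchange through the shared diffusive region.
#
# Per phenotype phi = 0..Phi (averages over the sub-population):
#   dB_e/dt  = r_syn b_sM(phi) - r_b B_e R - r_pc B_e + r_pc B_dr / sum(N)
#   dR/dt    = r_syn R_sM(phi) - r_b B_e R
#   dB_i/dt  = r_b B_e R - r_sgn B_i - r_u B_i [phi == 0]
#   dB_dr/dt = sum_phi N(phi) r_pc B_e(phi) - r_pc B_dr
#
# The diffusive region is shared: ligand entering it loses the identity of
# its producer and the return flux is split equally over all neighbour
# cells. Ubiquitination is restricted to healthy cells (phi = 0).

#' Paracrine rate from Fick's law
#'
#' Discretizing Fick's first law across the exchange surface between the
#' extracellular region and the diffusive region gives the first-order
#' paracrine rate `r_pc = D_eff * S / (d * V_dr)`: effective diffusion
#' coefficient (reduced by the porous extracellular matrix) times exchange
#' surface, over inter-membrane distance times diffusive-region volume.
#'
#' @param D_eff Effective diffusion coefficient (um^2/s).
#' @param S Orthogonal exchange surface (um^2).
#' @param d Inter-membrane distance (um), bridged by E-cadherin.
#' @param V_dr Diffusive-region volume (um^3).
#' @return Paracrine rate (1/s).
#' @export
#' @examples
#' derive_paracrine_rate(1, 1, 1, 1)        # 1
#' derive_paracrine_rate(10, 100, 0.05, 2000)  # the tabulated default, 10/s
derive_paracrine_rate <- function(D_eff, S, d, V_dr) {
  stopifnot(D_eff > 0, S > 0)
  if (d <= 0 || V_dr <= 0) {
    stop("inter-membrane distance and diffusive-region volume must be positive")
  }
  D_eff * S / (d * V_dr)
}

cellular_state_vec <- function(state, nphi) {
  stopifnot(length(state$B_e) == nphi, length(state$R) == nphi,
            length(state$B_i) == nphi, length(state$B_dr) == 1)
  c(state$B_e, state$R, state$B_i, state$B_dr)
}

cellular_state_names <- function(nphi) {
  phi <- seq_len(nphi) - 1L
  c(sprintf("B_e.%d", phi), sprintf("R.%d", phi), sprintf("B_i.%d", phi), "B_dr")
}

#' Time derivatives of the cellular exchange model
#'
#' @param state List with fields `B_e`, `R`, `B_i` (length `Phi + 1`
#'   vectors, nmol) and scalar `B_dr` (nmol), or a `tgfb_state`.
#' @param N_neigh Cell counts per phenotype in the neighbour volume
#'   (length `Phi + 1`); must have positive total when any paracrine term
#'   is active.
#' @param params Parameter set.
#' @return List with derivative fields `B_e`, `R`, `B_i`, `B_dr` (nmol/s).
#' @export
cellular_rhs <- function(state, N_neigh, params = default_parameters()) {
  nphi <- params$Phi + 1L
  stopifnot(length(N_neigh) == nphi)
  B_e <- state$B_e; R <- state$R; B_i <- state$B_i; B_dr <- state$B_dr
  if (any(c(B_e, R, B_i, B_dr) < 0)) stop("cellular state must be non-negative")
  Ntot <- sum(N_neigh)
  if (params$r_pc > 0 && Ntot <= 0) {
    stop("total neighbour count must be positive when paracrine exchange is active")
  }
  ret <- if (Ntot > 0) params$r_pc * B_dr / Ntot else 0
  bind <- params$r_b * B_e * R
  ubiq <- params$r_u * B_i * c(1, rep(0, nphi - 1L))  # healthy cells only
  list(
    B_e  = params$r_syn * params$beta_sM - bind - params$r_pc * B_e + ret,
    R    = params$r_syn * params$R_sM - bind,
    B_i  = bind - params$r_sgn * B_i - ubiq,
    B_dr = sum(N_neigh * params$r_pc * B_e) - params$r_pc * B_dr
  )
}

#' Simulate the cellular exchange model
#'
#' Adaptive integration of the per-phenotype exchange system with the
#' neighbour composition held fixed over the run (quasi-static tissue).
#'
#' @param init Initial state (list with `B_e`, `R`, `B_i`, `B_dr`), e.g.
#'   [default_initial_state()].
#' @param N_neigh Neighbour cell counts per phenotype.
#' @param params Parameter set.
#' @param t_grid Strictly increasing time grid (seconds).
#' @param atol,rtol Integrator tolerances.
#' @return A [trajectory()] with model id `"cellular"`; columns `B_e.phi`,
#'   `R.phi`, `B_i.phi` for each phenotype plus the shared `B_dr`.
#' @export
simulate_cellular <- function(init, N_neigh = init$N_neigh,
                              params = default_parameters(), t_grid,
                              atol = 1e-10, rtol = 1e-08) {
  nphi <- params$Phi + 1L
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0)) {
    stop("t_grid must be strictly increasing")
  }
  y0 <- cellular_state_vec(init, nphi)
  if (any(y0 < 0)) stop("cellular state must be non-negative")
  idx <- list(B_e = 1:nphi, R = nphi + 1:nphi, B_i = 2L * nphi + 1:nphi,
              B_dr = 3L * nphi + 1L)
  rhs <- function(t, y, p) {
    y[y < 0] <- 0  # guard against tiny integrator undershoot
    d <- cellular_rhs(list(B_e = y[idx$B_e], R = y[idx$R], B_i = y[idx$B_i],
                           B_dr = y[idx$B_dr]),
                      N_neigh = N_neigh, params = params)
    list(c(d$B_e, d$R, d$B_i, d$B_dr))
  }
  sol <- deSolve::lsoda(y = y0, times = t_grid, func = rhs, parms = NULL,
                        atol = atol, rtol = rtol)
  if (attr(sol, "istate")[1] < 0) {
    stop(sprintf("cellular integration failed near t = %g s", max(sol[, 1])))
  }
  state <- sol[, -1, drop = FALSE]
  colnames(state) <- cellular_state_names(nphi)
  trajectory(sol[, 1], state, model = "cellular", time_unit = "s",
             units = setNames(rep("nmol", ncol(state)), colnames(state)),
             meta = list(N_neigh = N_neigh, atol = atol, rtol = rtol))
}

#' Per-phenotype summary of the cellular trajectory
#'
#' Extracts, at time `t`, the synthesized extracellular TGF-beta, the
#' membrane receptors and the internalized compound for each phenotype,
#' sorted by increasing severity. Boolean flags report whether a column is
#' monotone decreasing in the phenotype index: a monotone-decreasing
#' receptor column is the expression pattern of an antitumorigenic isoform
#' (receptor expression falling with cellular aggressiveness).
#'
#' @param traj A cellular [trajectory()].
#' @param t Time (seconds) within the trajectory span.
#' @return A `data.frame` with columns `phenotype`, `B_e`, `R`, `B_i`, and
#'   attribute `antitumorigenic` (named logical per column).
#' @export
internalized_summary <- function(traj, t) {
  stopifnot(inherits(traj, "tgfb_trajectory"), traj$model == "cellular")
  v <- trajectory_at(traj, t)
  nphi <- (length(v) - 1L) / 3L
  phi <- seq_len(nphi) - 1L
  out <- data.frame(phenotype = phi,
                    B_e = unname(v[sprintf("B_e.%d", phi)]),
                    R   = unname(v[sprintf("R.%d", phi)]),
                    B_i = unname(v[sprintf("B_i.%d", phi)]))
  attr(out, "antitumorigenic") <- vapply(out[c("B_e", "R", "B_i")],
                                         function(col) all(diff(col) < 0),
                                         logical(1))
  out
}
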