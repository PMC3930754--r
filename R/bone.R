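# Bone-niche (basic multicellular unit) model: a delay differential
# equation system for one remodeling cycle triggered by a microfracture,
# optionally perturbed by a constant population of metastatic cancer cells.
#
# States (per the reference volumes V_osteon, V_frac and surface S_frac):
#   Ocy osteocytes, Oc osteoclasts, Lng lining/pre-osteoblast cells,
#   Ob mature osteoblasts, RANKL, BMP, CSF (nmol per reference volume),
#   z bone mineral density (%), beta bone-niche TGF-beta (nmol/V_frac),
# plus the damage signal dmg (apoptosed osteocytes not yet resorbed).
#
# The fracture removes D osteocytes over the apoptosis duration; surviving
# osteocytes emit RANKL/BMP/CSF in proportion to the damage signal, which
# osteoclasts clear as they resorb. Lining cells recruited by BMP mature
# into osteoblasts after a TGF-beta dependent delay tau(beta), with
# attrition exp(-a_Lng tau) during the transit; osteoblasts rebuild bone
# and rebury as osteocytes. Resorbing osteoclasts extract TGF-beta from the
# matrix; cancer cells both secrete and absorb niche TGF-beta, lengthening
# the maturation delay and tipping the cycle toward a net density loss.

.bone_state_names <- c("Ocy", "Oc", "Lng", "Ob", "RANKL", "BMP", "CSF",
                       "z", "beta")
.bone_units <- c(Ocy = "1/V_osteon", Oc = "1/V_frac", Lng = "1/S_frac",
                 Ob = "1/S_frac", RANKL = "nmol/V_frac", BMP = "nmol/V_frac",
                 CSF = "nmol/V_frac", z = "%", beta = "nmol/V_frac")

#' TGF-beta dependent maturation delay
#'
#' Saturating (Hill-1) delay `tau(beta) = tau_bar + Delta * beta /
#' (beta + beta_bar)`: positive and finite for all `beta >= 0`, monotone
#' non-decreasing, bounded in `[tau_bar, tau_bar + Delta]` (6.02 to 28.38
#' days at the defaults), and equal to `tau_bar + Delta/2` at the
#' half-saturation level `beta_bar`.
#'
#' @param beta Bone-niche TGF-beta (nmol/V_frac); vectorized.
#' @param params Parameter set.
#' @return Delay in days.
#' @export
#' @examples
#' delay_tau(0)      # 6.02
#' delay_tau(8e-08)  # tau_bar + Delta/2
delay_tau <- function(beta, params = default_parameters()) {
  if (any(beta < 0)) stop("beta must be non-negative")
  params$tau_bar + params$Delta * beta / (beta + params$beta_bar)
}

#' Microfracture event
#'
#' @param params Parameter set (for the default damage size
#'   `Ocy_max / 30`, the canonical microfracture).
#' @param onset Onset time (day).
#' @param D Osteocytes undergoing apoptosis (1/V_osteon).
#' @param duration Apoptosis duration (day); the removal pulse has rate
#'   `D / duration`. At the defaults (30 osteocytes over 1 day) this equals
#'   the tabulated osteocyte apoptosis rate.
#' @return Named list of class `fracture_event`.
#' @export
fracture_event <- function(params = default_parameters(), onset = 0,
                           D = params$Ocy_max / 30, duration = 1) {
  stopifnot(duration > 0, D >= 0, D <= params$Ocy_max)
  structure(list(onset = onset, D = D, duration = duration),
            class = "fracture_event")
}

apoptosis_pulse <- function(t, fracture) {
  inside <- t >= fracture$onset & t < fracture$onset + fracture$duration
  ifelse(inside, fracture$D / fracture$duration, 0)
}

#' Time derivatives of the bone-niche model
#'
#' Right-hand side of the DDE system. `lag` supplies the delayed values of
#' BMP and the lining-cell pool; when `NULL` the delayed arguments are
#' evaluated at the current time and the system reduces to an ODE (the
#' zero-delay configuration used for cross-checking the integrator).
#'
#' @param t Time (day).
#' @param state Named vector over `Ocy, Oc, Lng, Ob, RANKL, BMP, CSF, z,
#'   beta, dmg`.
#' @param params Parameter set.
#' @param fracture A [fracture_event()].
#' @param N_c Number of cancer cells in the niche.
#' @param lag Function `(t_past, idx) -> values` returning past state
#'   values (index into the state vector), or `NULL`.
#' @param delay_scale Multiplier on `tau(beta)`; 0 gives the zero-delay
#'   ODE limit.
#' @return Named vector of derivatives (per day).
#' @export
bone_rhs <- function(t, state, params = default_parameters(),
                     fracture = fracture_event(params), N_c = params$N_c,
                     lag = NULL, delay_scale = 1) {
  s <- as.list(pmax(state, 0))
  pulse <- apoptosis_pulse(t, fracture)
  tau <- delay_scale * delay_tau(s$beta, params)
  if (is.null(lag) || tau <= 0) {
    BMP_lag <- s$BMP
    Lng_lag <- s$Lng
  } else {
    v <- lag(t - tau, c(6L, 3L))  # (BMP, Lng) at t - tau
    BMP_lag <- max(v[1], 0)
    Lng_lag <- max(v[2], 0)
  }
  # attrition of the maturing cohort during the delay
  surv <- exp(-params$a_Lng * tau)
  M <- params$m_Lng * BMP_lag * Lng_lag * surv / params$L_ref
  dmg_frac <- s$dmg / params$Ocy_max
  bury <- params$f_Ocy * params$kappa * s$Ob
  c(Ocy   = bury - pulse,
    Oc    = params$r_Oc * s$RANKL * s$CSF - params$a_Oc * s$Oc,
    Lng   = params$p_Lng * s$BMP - M - params$a_Lng * s$Lng,
    Ob    = M - params$a_Ob * s$Ob - bury,
    RANKL = params$p_RKL * dmg_frac * s$Ocy + params$r_RKL * s$Ob -
            params$d_RKL * s$RANKL,
    BMP   = params$p_BMP * dmg_frac - params$d_BMP * s$BMP,
    CSF   = params$p_CSF * dmg_frac - params$d_CSF * s$CSF -
            params$k_CSF * s$Oc * s$CSF,
    z     = params$f_bn * params$s_f * s$Ob - params$r_bn * params$s_r * s$Oc,
    beta  = params$r_beta * s$Oc * s$z - params$d_beta * s$beta +
            params$c_sec * N_c - params$c_abs * N_c * s$beta,
    dmg   = pulse - params$k_dmg * s$Oc * s$dmg)
}

#' Integrate a delay differential system
#'
#' Method-of-steps integration (dense interpolated history) of a DDE whose
#' right-hand side accesses the past through a `lag(t_past, idx)` accessor.
#' Before the initial time the accessor returns the constant pre-run
#' history. Non-negativity of the output is enforced by clipping at zero;
#' the number of clipped entries is recorded in the trajectory metadata.
#'
#' @param func Function `(t, y, lag) -> list(dy)`.
#' @param y0 Named initial state.
#' @param times Strictly increasing output times; the maximum delay must be
#'   shorter than the span covered by the constant history.
#' @param history Named vector of state values for `t <= times[1]`
#'   (defaults to `y0`).
#' @param atol,rtol Integrator tolerances.
#' @param ... Passed to [deSolve::dede()].
#' @return A [trajectory()] (model id `"dde"`; callers relabel).
#' @export
integrate_dde <- function(func, y0, times, history = y0,
                          atol = 1e-10, rtol = 1e-08, ...) {
  stopifnot(length(times) >= 2, all(diff(times) > 0))
  t0 <- times[1]
  lagfn <- function(t_past, idx) {
    if (t_past <= t0) history[idx] else deSolve::lagvalue(t_past, idx)
  }
  wrapped <- function(t, y, p) func(t, y, lagfn)
  sol <- deSolve::dede(y = y0, times = times, func = wrapped, parms = NULL,
                       atol = atol, rtol = rtol, ...)
  if (attr(sol, "istate")[1] < 0) {
    stop(sprintf("DDE integration failed near t = %g", max(sol[, 1])))
  }
  state <- sol[, -1, drop = FALSE]
  clips <- sum(state < 0)
  state[state < 0] <- 0
  colnames(state) <- names(y0)
  trajectory(sol[, 1], state, model = "dde", time_unit = "day",
             meta = list(clips = clips, atol = atol, rtol = rtol))
}

#' Simulate one bone remodeling cycle
#'
#' Integrates the bone-niche DDE from the healthy pre-fracture steady state
#' with a single microfracture at time zero. The control run (`N_c = 0`)
#' shows the canonical sequence: osteocyte drop, RANKL/CSF rise, an
#' osteoclast wave with a dip in bone density, a delayed osteoblast wave,
#' and density recovery to a near-neutral balance. A cancer load shifts the
#' maturation delay toward its upper bound and leaves a net density loss.
#'
#' @param params Parameter set.
#' @param N_c Cancer cells in the niche (default: the tabulated load).
#' @param horizon_days Length of the run (day); the default 200 covers one
#'   full remodeling cycle.
#' @param fracture A [fracture_event()].
#' @param init Initial/history bone state (defaults to the healthy steady
#'   state of [default_initial_state()]).
#' @param dt_out Output resolution (day).
#' @param delay_scale Multiplier on the maturation delay (0 = ODE limit).
#' @param atol,rtol Integrator tolerances.
#' @return A [trajectory()] with model id `"bone"`, time in days and the
#'   nine canonical state columns; the damage signal and clip count are in
#'   `meta`.
#' @export
simulate_fracture <- function(params = default_parameters(),
                              N_c = params$N_c, horizon_days = 200,
                              fracture = fracture_event(params),
                              init = NULL, dt_out = 0.25, delay_scale = 1,
                              atol = 1e-10, rtol = 1e-08) {
  stopifnot(horizon_days > 0)
  if (is.null(init)) init <- default_initial_state(params)
  y0 <- c(Ocy = init$Ocy, Oc = init$Oc, Lng = init$Lng, Ob = init$Ob,
          RANKL = init$RANKL, BMP = init$BMP, CSF = init$CSF,
          z = init$BMD, beta = init$beta_bone, dmg = 0)
  times <- seq(0, horizon_days, by = dt_out)
  func <- function(t, y, lag) {
    list(unname(bone_rhs(t, setNames(y, names(y0)), params, fracture, N_c,
                         lag = lag, delay_scale = delay_scale)))
  }
  traj <- integrate_dde(func, y0, times, history = y0,
                        atol = atol, rtol = rtol)
  dmg <- traj$state[, "dmg"]
  state <- traj$state[, .bone_state_names, drop = FALSE]
  trajectory(traj$time, state, model = "bone", time_unit = "day",
             units = .bone_units,
             meta = list(N_c = N_c, damage = dmg, clips = traj$meta$clips,
                         fracture = unclass(fracture),
                         delay_scale = delay_scale))
}

#' Remodeling balance of a bone trajectory
#'
#' Signed change in bone mineral density over the cycle,
#' `z(end) - z(start)`, in percentage points. Negative values indicate net
#' resorption (osteolytic outcome), positive net formation (osteoblastic).
#'
#' @param traj A bone [trajectory()].
#' @return Signed density change (percentage points).
#' @export
remodeling_balance <- function(traj) {
  z <- traj$state[, "z"]
  unname(z[length(z)] - z[1])
}

#' Mixed-lesion variability index
#'
#' Without spatial structure, co-occurring osteolytic and osteoblastic
#' lesions are proxied by the variability of per-cycle remodeling balances
#' across spatially independent remodeling units whose matrix TGF-beta
#' release fluctuates randomly: each cycle is simulated with the extraction
#' rate `r_beta` scaled by an independent draw, and the index is the
#' standard deviation of the resulting balances. High variability indicates
#' mixed lesions; low variability a uniformly osteolytic (negative mean
#' balance) or osteoblastic (positive) pattern.
#'
#' @param params Parameter set.
#' @param n_fractures Number of remodeling cycles (at least 2).
#' @param dist Release-intensity distribution: list with `family`
#'   (`"lognormal"` or `"uniform"`) and its parameters (`meanlog`/`sdlog`,
#'   or `min`/`max`).
#' @param seed RNG seed; the index is deterministic given the seed.
#' @param N_c,horizon_days,dt_out Passed to [simulate_fracture()].
#' @return List with `index` (sd of balances), `balances`, `multipliers`.
#' @export
mixed_lesion_index <- function(params = default_parameters(), n_fractures,
                               dist = list(family = "lognormal",
                                           meanlog = 0, sdlog = 0.5),
                               seed = 1L, N_c = params$N_c,
                               horizon_days = 200, dt_out = 0.5) {
  stopifnot(n_fractures >= 2)
  if (is.null(dist$family)) stop("release distribution must name a family")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  mult <- switch(dist$family,
    lognormal = rlnorm(n_fractures, dist$meanlog, dist$sdlog),
    uniform   = runif(n_fractures, dist$min, dist$max),
    stop(sprintf("unknown release distribution family '%s'", dist$family))
  )
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  balances <- vapply(mult, function(k) {
    p <- params
    p$r_beta <- params$r_beta * k
    remodeling_balance(simulate_fracture(p, N_c = N_c,
                                         horizon_days = horizon_days,
                                         dt_out = dt_out))
  }, numeric(1))
  list(index = sd(balances), balances = balances, multipliers = mult)
}
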