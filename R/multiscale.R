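# Loose coupling of the cellular and tissue scales. Cellular reactions
# relax within minutes to hours while tissue turnover acts over weeks to
# months, so the tissue sees only time-averaged cellular quantities: at
# each coupling step the exchange model is re-equilibrated under the
# current tissue composition and the averaged per-cell ligand influx
# r_sgn * B_i(phi) is passed to the tissue equations.

#' Coupling schedule
#'
#' @param tissue_step_days Tissue time advanced per coupling step (days).
#' @param cellular_horizon_days Horizon of each cellular re-equilibration
#'   run (days); the cellular model relaxes within a fraction of this.
#' @param averaging_window Fraction of the cellular horizon (from the end)
#'   over which the influx is time-averaged.
#' @param rhs_tol Relative convergence tolerance on the cellular
#'   right-hand side (per second, applied to the internalized
#'   compartments): if the final relative derivatives exceed it a warning
#'   is raised and the last-window average is used regardless.
#' @return Named list of class `coupling_schedule`.
#' @export
coupling_schedule <- function(tissue_step_days = DAYS_PER_MONTH,
                              cellular_horizon_days = 0.25,
                              averaging_window = 0.1,
                              rhs_tol = 1e-06) {
  stopifnot(tissue_step_days > 0, cellular_horizon_days > 0,
            averaging_window > 0, averaging_window <= 1)
  structure(list(tissue_step_days = tissue_step_days,
                 cellular_horizon_days = cellular_horizon_days,
                 averaging_window = averaging_window,
                 rhs_tol = rhs_tol),
            class = "coupling_schedule")
}

#' Quasi-steady TGF-beta influx under a tissue composition
#'
#' Runs the cellular exchange model from the canonical initial state with
#' the neighbour counts taken from the tissue state (continuous averages;
#' both models are mean-field) and returns the per-phenotype influx
#' `r_sgn * B_i(phi)` time-averaged over the trailing window.
#'
#' @param N Tissue cell counts per phenotype (total must be positive).
#' @param params Parameter set.
#' @param schedule A [coupling_schedule()].
#' @param init Cellular initial state (defaults to the canonical one).
#' @return Numeric vector `B_in` (nmol/s per cell), length `Phi + 1`.
#' @export
quasi_steady_influx <- function(N, params = default_parameters(),
                                schedule = coupling_schedule(),
                                init = default_initial_state(params)) {
  stopifnot(sum(N) > 0)
  horizon <- schedule$cellular_horizon_days * SECONDS_PER_DAY
  t_grid <- seq(0, horizon, length.out = 201)
  traj <- simulate_cellular(init, N_neigh = N, params = params, t_grid = t_grid)
  nphi <- params$Phi + 1L
  keep <- traj$time >= (1 - schedule$averaging_window) * horizon
  Bi <- traj$state[keep, sprintf("B_i.%d", seq_len(nphi) - 1L), drop = FALSE]
  # convergence audit on the internalized compartments at the final point
  fin <- pmax(trajectory_at(traj, max(traj$time)), 0)
  d <- cellular_rhs(list(B_e = fin[sprintf("B_e.%d", 0:(nphi - 1))],
                         R = fin[sprintf("R.%d", 0:(nphi - 1))],
                         B_i = fin[sprintf("B_i.%d", 0:(nphi - 1))],
                         B_dr = fin[["B_dr"]]),
                    N_neigh = N, params = params)
  rel <- max(abs(d$B_i) / pmax(fin[sprintf("B_i.%d", 0:(nphi - 1))], 1e-08))
  if (rel > schedule$rhs_tol) {
    warning(sprintf(paste0("cellular model not converged within %g days ",
                           "(max relative |dB_i/dt| = %.3g/s); ",
                           "using last-window average"),
                    schedule$cellular_horizon_days, rel))
  }
  params$r_sgn * colMeans(Bi)
}

#' Run the coupled cellular-tissue model
#'
#' Alternates cellular re-equilibration and tissue advancement: at each
#' step the influx vector is recomputed by [quasi_steady_influx()] under
#' the current composition and held fixed while the tissue advances by one
#' step. Deterministic given parameters and schedule.
#'
#' @param params Parameter set.
#' @param horizon_months Total tissue time to simulate (months).
#' @param schedule A [coupling_schedule()].
#' @param init Initial tissue composition (defaults to the healthy duct
#'   neighbourhood of [default_initial_state()]).
#' @param points_per_step Tissue output points per coupling step.
#' @return A [trajectory()] with model id `"multiscale"` (time in months,
#'   columns `N.phi`); the per-step influx table is in `meta$B_in` (one row
#'   per coupling step).
#' @export
run_multiscale <- function(params = default_parameters(), horizon_months,
                           schedule = coupling_schedule(),
                           init = NULL, points_per_step = 8) {
  stopifnot(horizon_months >= 0)
  nphi <- params$Phi + 1L
  if (is.null(init)) init <- default_initial_state(params)$N_neigh
  stopifnot(length(init) == nphi)
  step_months <- schedule$tissue_step_days / DAYS_PER_MONTH
  month_s <- DAYS_PER_MONTH * SECONDS_PER_DAY
  times <- c(0)
  states <- matrix(as.numeric(init), nrow = 1,
                   dimnames = list(NULL, sprintf("N.%d", 0:(nphi - 1L))))
  influx_log <- NULL
  t_now <- 0
  N_now <- as.numeric(init)
  while (t_now < horizon_months - 1e-09) {
    step <- min(step_months, horizon_months - t_now)
    B_in <- quasi_steady_influx(N_now, params, schedule)
    influx_log <- rbind(influx_log, c(t = t_now, B_in))
    t_grid <- seq(0, step * month_s, length.out = points_per_step + 1)
    seg <- simulate_tissue(N_now, B_in, params, t_grid)
    times <- c(times, t_now + seg$time[-1])
    states <- rbind(states, seg$state[-1, , drop = FALSE])
    N_now <- pmax(seg$state[nrow(seg$state), ], 0)
    t_now <- t_now + step
  }
  if (!is.null(influx_log)) {
    colnames(influx_log) <- c("t_month", sprintf("B_in.%d", 0:(nphi - 1L)))
  }
  trajectory(times, states, model = "multiscale", time_unit = "month",
             units = setNames(rep("1/V_neigh", nphi), colnames(states)),
             meta = list(B_in = influx_log, schedule = unclass(schedule)))
}

#' First time a phenotype reaches a population fraction
#'
#' @param traj A tissue or multiscale [trajectory()].
#' @param phi Phenotype index.
#' @param threshold Fraction threshold in `(0, 1)` (a threshold of 0 is
#'   reached at time zero whenever the phenotype is present).
#' @return First time (months) at which the phenotype-`phi` fraction
#'   reaches the threshold, linearly interpolated; `Inf` if never.
#' @export
takeover_time <- function(traj, phi, threshold) {
  N <- traj$state[, grep("^N\\.", colnames(traj$state)), drop = FALSE]
  tot <- rowSums(N)
  frac <- ifelse(tot > 0, N[, sprintf("N.%d", phi)] / tot, 0)
  hit <- which(frac >= threshold)
  if (length(hit) == 0) return(Inf)
  i <- hit[1]
  if (i == 1) return(traj$time[1])
  # linear interpolation across the crossing
  f0 <- frac[i - 1]; f1 <- frac[i]
  traj$time[i - 1] + (threshold - f0) / (f1 - f0) * (traj$time[i] - traj$time[i - 1])
}
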