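# Intracellular Smad pathway: eight-variable mass-action ODE system and the
# order reduction used by the cellular exchange model.
#
# States (all nmol except the mRNA readout m, arbitrary units):
#   B     free TGF-beta ligand
#   R_in  inactive membrane receptor
#   R_act active ligand-bound receptor (internalized signaling complex)
#   S_c   cytoplasmic Smad
#   pS_c  phosphorylated cytoplasmic Smad
#   pS_n  nuclear phospho-Smad
#   S_n   nuclear (dephosphorylated) Smad
#   m     target-gene mRNA
#
# Reactions: B + R_in -> R_act; R_act + S_c -> pS_c (the complex is consumed
# upon signaling, which is the decay channel the order reduction collapses);
# pS_c -> pS_n (nuclear import, rate k_t); pS_n -> S_n (dephosphorylation by
# the nuclear phosphatase pool P, constant over a run); pS_n drives
# transcription of m. The Smad material S_c + pS_c + pS_n + S_n is conserved.

.smad_state_names <- c("B", "R_in", "R_act", "S_c", "pS_c", "pS_n", "S_n", "m")

#' Default Smad pathway rate constants
#'
#' Mass-action rate constants of the intracellular pathway. The
#' phosphorylation rate times the resting cytoplasmic Smad pool equals the
#' reduced Smad signaling rate `r_sgn = 0.003018` 1/s of the cellular model
#' (see [reduce_model()]).
#'
#' @return Named list of class `smad_rates`: `k_act` ligand-receptor
#'   activation (1/(nmol s)), `k_phos` phosphorylation (1/(nmol s)), `k_t`
#'   nucleo-cytoplasmic translocation (1/s), `k_dephos` dephosphorylation
#'   (1/(nmol s)), `k_transc` transcription (1/s), `P` nuclear phosphatase
#'   abundance (nmol, constant along the dynamics).
#' @export
default_smad_rates <- function() {
  r <- list(k_act = 0.0074, k_phos = 3.018e-04, k_t = 5.6e-03,
            k_dephos = 3.95e-04, k_transc = 1e-03, P = 1)
  class(r) <- "smad_rates"
  r
}

#' Default Smad pathway initial state
#'
#' A resting cell stimulated by an extracellular ligand bolus: free ligand
#' and inactive receptors present, a large cytoplasmic Smad pool, empty
#' phospho and nuclear pools.
#'
#' @param B,R_in,S_c Initial ligand, receptor and cytoplasmic Smad (nmol).
#' @return Named numeric vector over the eight state variables.
#' @export
default_smad_state <- function(B = 2, R_in = 2, S_c = 10) {
  setNames(c(B, R_in, 0, S_c, 0, 0, 0, 0), .smad_state_names)
}

check_smad_args <- function(state, rates) {
  if (!all(.smad_state_names %in% names(state))) {
    stop("smad state must contain: ", paste(.smad_state_names, collapse = ", "))
  }
  if (any(state[.smad_state_names] < 0)) stop("smad state must be non-negative")
  if (any(unlist(rates) < 0)) stop("smad rates must be non-negative")
  invisible(TRUE)
}

#' Time derivatives of the Smad pathway system
#'
#' Mass-action right-hand side of the eight-variable intracellular model.
#' Without synthesis or degradation terms the total Smad material
#' `S_c + pS_c + pS_n + S_n` has derivative zero.
#'
#' @param state Named numeric vector (see [default_smad_state()]).
#' @param rates A `smad_rates` list.
#' @return Named numeric vector of time derivatives (1/s).
#' @export
#' @examples
#' d <- smad_rhs(default_smad_state(), default_smad_rates())
#' sum(d[c("S_c", "pS_c", "pS_n", "S_n")])  # Smad conservation: 0
smad_rhs <- function(state, rates) {
  check_smad_args(state, rates)
  s <- as.list(state[.smad_state_names])
  v_act    <- rates$k_act * s$B * s$R_in        # receptor activation
  v_phos   <- rates$k_phos * s$R_act * s$S_c    # Smad phosphorylation
  v_import <- rates$k_t * s$pS_c                # nuclear import
  v_deph   <- rates$k_dephos * rates$P * s$pS_n # nuclear dephosphorylation
  c(B     = -v_act,
    R_in  = -v_act,
    R_act =  v_act - v_phos,
    S_c   = -v_phos,
    pS_c  =  v_phos - v_import,
    pS_n  =  v_import - v_deph,
    S_n   =  v_deph,
    m     =  rates$k_transc * s$pS_n)
}

#' Simulate the Smad pathway
#'
#' Adaptive stiff-safe integration (lsoda, absolute tolerance 1e-10 nmol,
#' relative 1e-8; the rates span several orders of magnitude). Without
#' source terms the free ligand and the active receptor decay to zero while
#' the cytoplasmic/nuclear Smad pools and the mRNA readout converge to
#' stationary values set by the initial condition.
#'
#' @param init Named initial state (see [default_smad_state()]).
#' @param rates A `smad_rates` list.
#' @param t_grid Strictly increasing time grid (seconds).
#' @param atol,rtol Integrator tolerances.
#' @return A [trajectory()] with model id `"smad"`.
#' @export
simulate_smad <- function(init, rates = default_smad_rates(), t_grid,
                          atol = 1e-10, rtol = 1e-08) {
  check_smad_args(init, rates)
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0)) {
    stop("t_grid must be strictly increasing")
  }
  rhs <- function(t, y, p) {
    y[y < 0] <- 0  # guard against tiny integrator undershoot
    list(unname(smad_rhs(setNames(y, .smad_state_names), rates)))
  }
  sol <- deSolve::lsoda(y = unname(init[.smad_state_names]), times = t_grid,
                        func = rhs, parms = NULL, atol = atol, rtol = rtol)
  if (attr(sol, "istate")[1] < 0) {
    stop(sprintf("smad integration failed near t = %g s", max(sol[, 1])))
  }
  state <- sol[, -1, drop = FALSE]
  colnames(state) <- .smad_state_names
  trajectory(sol[, 1], state, model = "smad", time_unit = "s",
             units = setNames(c(rep("nmol", 7), "au"), .smad_state_names),
             meta = list(atol = atol, rtol = rtol))
}

#' Reduced Smad signaling rate
#'
#' Order reduction of the pathway used by the cellular exchange model:
#' holding the cytoplasmic Smad pool constant at its (large) resting value
#' collapses the consumption of the internalized signaling complex into a
#' single first-order decay with rate `r_sgn = k_phos * S_c0`. With the
#' default rates and resting pool this reproduces the tabulated Smad
#' signaling rate 0.003018 1/s.
#'
#' @param rates A `smad_rates` list.
#' @param S_c0 Resting cytoplasmic Smad pool held constant (nmol).
#' @return The reduced first-order signaling rate `r_sgn` (1/s).
#' @export
#' @examples
#' reduce_model(default_smad_rates())  # 0.003018
reduce_model <- function(rates = default_smad_rates(), S_c0 = 10) {
  stopifnot(S_c0 >= 0, rates$k_phos >= 0)
  rates$k_phos * S_c0
}
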