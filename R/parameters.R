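# Parameter housekeeping: defaults, units, validation, config I/O.
#
# All rate symbols follow the field's usual naming (r_syn, r_pc, RANKL, ...).
# Per-phenotype vectors are indexed phi = 0..Phi and stored in increasing
# order of aggressiveness: phi = 0 is healthy epithelium, phi = Phi is the
# aggressive/malignant phenotype.

# section membership used by the config loader and the serializer
.param_sections <- list(
  cellular = c("beta_sM", "R_sM", "r_syn", "r_sgn", "r_pc", "r_b", "r_u"),
  tissue   = c("Phi", "r_p", "r_a", "r_d", "r_m", "g_p", "g_a", "p_Phi",
               "C_phi", "alpha", "gamma", "response_floor"),
  bone     = c("f_Ocy", "a_Ocy", "r_Oc", "a_Oc", "p_Lng", "m_Lng", "a_Lng",
               "a_Ob", "p_RKL", "r_RKL", "d_RKL", "p_BMP", "d_BMP", "p_CSF",
               "d_CSF", "r_bn", "f_bn", "r_beta", "d_beta", "N_c", "tau_bar",
               "Delta", "Ocy_max", "beta_bar", "kappa",
               "k_CSF", "k_dmg", "L_ref", "s_f", "s_r", "c_sec", "c_abs")
)

.phenotype_vectors <- c("beta_sM", "R_sM", "r_p", "g_p", "g_a", "C_phi")

# symbols that may legitimately be negative (sensing exponents)
.sign_free <- c("g_p", "g_a")

#' Default model parameters
#'
#' Returns the full parameter set of the multi-scale model: per-phenotype
#' gene-expression synthesis levels, cellular exchange rates, tissue
#' proliferation/apoptosis/mutation rates and sensing exponents, and the
#' bone-niche (basic multicellular unit) rates and delays.
#'
#' Per-phenotype vectors have length `Phi + 1` and are ordered by increasing
#' phenotype index, from healthy (`phi = 0`) to aggressive/malignant
#' (`phi = Phi`). Cellular and tissue rates are per second; bone rates are
#' per day. Unit strings for every symbol are available from
#' [parameter_units()].
#'
#' The handful of bone closure constants that tie cell counts to bone
#' mineral density percentage points (`s_f`, `s_r`), the chemoattractant
#' depletion and damage clearance coefficients (`k_CSF`, `k_dmg`), the
#' maturation normalization (`L_ref`) and the cancer-cell TGF-beta
#' secretion/absorption coefficients (`c_sec`, `c_abs`) are fixed by a
#' one-off calibration of the control remodeling cycle (balance-neutral
#' control, circa one percentage point of density loss at the default
#' cancer load); see the package vignette for the calibration rationale.
#'
#' @return A named list of class `tgfb_params`.
#' @seealso [load_parameters()], [validate_parameters()],
#'   [default_initial_state()]
#' @export
#' @examples
#' p <- default_parameters()
#' p$r_pc          # paracrine rate, 1/s
#' p$C_phi         # cell capacities per neighbour volume
default_parameters <- function() {
  p <- list(
    ## cellular scale (seconds)
    beta_sM = c(1.853, 1.724, 1.614, 1.669),  # TGF-beta gene expression [nmol]
    R_sM    = c(7.47, 6.713, 5.017, 4.128),   # receptor gene expression [nmol]
    r_syn   = 133.333,    # synthesis rate [1/s]
    r_sgn   = 0.003018,   # Smad signaling rate [1/s]
    r_pc    = 10,         # paracrine rate [1/s]
    r_b     = 0.0074,     # ligand-receptor binding rate [1/(nmol s)]
    r_u     = 0.007,      # ubiquitination rate, healthy cells only [1/s]

    ## tissue scale (seconds)
    Phi     = 3L,                                   # malignant phenotype index
    r_p     = c(1e-06, 1e-06, 1e-06, 1e-06),        # proliferation rates [1/s]
    r_a     = 9e-08,                                # apoptosis rate [1/s]
    r_d     = 1e-08,                                # degradation rate [1/s]
    r_m     = 1e-14,                                # stepwise mutation rate [1/s]
    g_p     = c(0.12, 0.06, 0, -0.06),              # proliferation sensing exponents
    g_a     = c(0.12, 0.06, 0, -0.06),              # apoptosis sensing exponents
    p_Phi   = 5e-07,                # probability of malignant mutation at division
    C_phi   = c(6, 6, 6, 8),       # cell capacities [1/V_neigh]
    alpha   = 1,                   # dimensional constant [1/s]
    gamma   = 1,                   # dimensional constant [1/nmol]
    response_floor = 1e-12,        # floor on the scaled signal (degenerate-input guard)

    ## bone niche (days)
    f_Ocy   = 0.00032,   # osteocyte formation (osteoblast burial) [S_frac/(V_osteon day)]
    a_Ocy   = 30,        # osteocyte apoptosis rate after microfracture [1/(V_osteon day)]
    r_Oc    = 0.8,       # osteoclast recruitment [V_frac/(nmol^2 day)]
    a_Oc    = 0.0625,    # osteoclast apoptosis [1/day]
    p_Lng   = 50,        # lining cell recruitment by BMP [um/(nmol day)]
    m_Lng   = 50,        # lining cell maturation [um/(nmol day)]
    a_Lng   = 0.1525,    # lining cell apoptosis [1/day]
    a_Ob    = 0.1525,    # osteoblast apoptosis [1/day]
    p_RKL   = 300,       # RANKL production by osteocytes [nmol V_osteon/(V_frac day)]
    r_RKL   = 2.5,       # RANKL production by osteoblasts [nmol S_frac/(V_frac day)]
    d_RKL   = 8.6643,    # RANKL degradation [1/day]
    p_BMP   = 1,         # BMP production [nmol V_osteon/(V_frac day)]
    d_BMP   = 8.6643,    # BMP degradation [1/day]
    p_CSF   = 0.1,       # CSF production [nmol V_osteon/(V_frac day)]
    d_CSF   = 69.3147,   # CSF degradation [1/day]
    r_bn    = 9.4e-04,   # bone resorption rate [V_frac/(nmol day)]
    f_bn    = 5.9098e-06,# bone formation rate [S_frac/(nmol day)]
    r_beta  = 2.2e-10,   # TGF-beta extraction from matrix by resorption [nmol/day]
    d_beta  = 0.1189,    # TGF-beta degradation in the niche [1/day]
    N_c     = 2000,      # cancer cells in the niche [-]
    tau_bar = 6.02,      # base maturation delay [day]
    Delta   = 22.36,     # delay increment at saturating TGF-beta [day]
    Ocy_max = 900,       # osteocytes in the healthy osteon [1/V_osteon]
    beta_bar = 8e-08,    # half-saturation TGF-beta for the delay [nmol/V_frac]
    kappa   = 1,         # buried-osteoblast factor [V_osteon/V_frac]

    ## bone closure constants (one-off control calibration, then frozen)
    k_CSF   = 10,        # CSF depletion by osteoclasts [V_frac/day]
    k_dmg   = 0.3,       # damage-signal clearance by osteoclast resorption [V_frac/day]
    L_ref   = 1,         # maturation-flux normalization [nmol um/S_frac]
    s_f     = 162648,    # formation unit reconciliation [% V_osteon nmol/(S_frac cell)]
    s_r     = 394.597,   # resorption unit reconciliation [% V_frac nmol/cell]
    c_sec   = 1.92e-12,  # TGF-beta secretion per cancer cell [nmol/(V_frac day)]
    c_abs   = 2.5e-05    # TGF-beta absorption per cancer cell [1/day]
  )
  class(p) <- "tgfb_params"
  p
}

#' Unit strings for every model parameter
#'
#' Units are carried as metadata only; the package performs no automatic
#' unit conversion. `V_neigh`, `V_osteon`, `V_frac` and `S_frac` are the
#' effective reference volumes/surfaces of the neighbour region, the osteon,
#' and the fracture.
#'
#' @return Named character vector mapping parameter names to unit strings.
#' @export
parameter_units <- function() {
  c(beta_sM = "nmol", R_sM = "nmol", r_syn = "1/s", r_sgn = "1/s",
    r_pc = "1/s", r_b = "1/(nmol s)", r_u = "1/s", Phi = "-",
    r_p = "1/s", r_a = "1/s", r_d = "1/s", r_m = "1/s", g_p = "-", g_a = "-",
    p_Phi = "-", C_phi = "1/V_neigh", alpha = "1/s", gamma = "1/nmol",
    response_floor = "-",
    f_Ocy = "S_frac/(V_osteon day)", a_Ocy = "1/(V_osteon day)",
    r_Oc = "V_frac/(nmol^2 day)", a_Oc = "1/day",
    p_Lng = "um/(nmol day)", m_Lng = "um/(nmol day)", a_Lng = "1/day",
    a_Ob = "1/day", p_RKL = "nmol V_osteon/(V_frac day)",
    r_RKL = "nmol S_frac/(V_frac day)", d_RKL = "1/day",
    p_BMP = "nmol V_osteon/(V_frac day)", d_BMP = "1/day",
    p_CSF = "nmol V_osteon/(V_frac day)", d_CSF = "1/day",
    r_bn = "V_frac/(nmol day)", f_bn = "S_frac/(nmol day)",
    r_beta = "nmol/day", d_beta = "1/day", N_c = "-", tau_bar = "day",
    Delta = "day", Ocy_max = "1/V_osteon", beta_bar = "nmol/V_frac",
    kappa = "V_osteon/V_frac", k_CSF = "V_frac/day", k_dmg = "V_frac/day",
    L_ref = "nmol um/S_frac", s_f = "% V_osteon nmol/(S_frac cell)",
    s_r = "% V_frac nmol/cell", c_sec = "nmol/(V_frac day)",
    c_abs = "1/day")
}

#' Validate a parameter set
#'
#' Checks the structural invariants of a parameter set: every rate,
#' capacity and delay is non-negative, the base delay is strictly positive,
#' and every per-phenotype vector has length `Phi + 1`. Sensing exponents
#' (`g_p`, `g_a`) are the only sign-free symbols.
#'
#' @param params A list of class `tgfb_params` (or a plain named list with
#'   the same fields).
#' @return `params`, invisibly, if valid; otherwise an error naming the
#'   offending symbol.
#' @export
validate_parameters <- function(params) {
  stopifnot(is.list(params))
  known <- unlist(.param_sections, use.names = FALSE)
  missing <- setdiff(known, names(params))
  if (length(missing) > 0) {
    stop("parameter set is missing: ", paste(missing, collapse = ", "))
  }
  phi_len <- params$Phi + 1L
  for (nm in .phenotype_vectors) {
    if (length(params[[nm]]) != phi_len) {
      stop(sprintf("'%s' must have length Phi + 1 = %d (got %d)",
                   nm, phi_len, length(params[[nm]])))
    }
  }
  for (nm in setdiff(known, .sign_free)) {
    v <- params[[nm]]
    if (!is.numeric(v) || anyNA(v)) {
      stop(sprintf("'%s' must be numeric and non-missing", nm))
    }
    if (any(v < 0)) {
      stop(sprintf("'%s' must be non-negative", nm))
    }
  }
  if (params$tau_bar <= 0) stop("'tau_bar' (base delay) must be strictly positive")
  if (params$Phi < 1) stop("'Phi' must be at least 1")
  if (any(params$C_phi <= 0)) stop("'C_phi' capacities must be strictly positive")
  invisible(params)
}

#' Default initial state
#'
#' Initial values for every state variable of the three models: the
#' per-phenotype cellular compartments, the shared diffusive-region ligand,
#' the neighbour-volume cell counts, and the bone-niche variables (healthy
#' pre-fracture steady state: a full osteon of osteocytes, bone mineral
#' density at 100 per cent, all signalling species at zero).
#'
#' @param params Parameter set, used only for `Phi` (vector lengths).
#' @return A named list of class `tgfb_state`.
#' @export
#' @examples
#' s <- default_initial_state()
#' s$B_dr     # diffusive-region TGF-beta, nmol
#' s$N_neigh  # healthy duct: 6 healthy neighbours, no mutated cells
default_initial_state <- function(params = default_parameters()) {
  nphi <- params$Phi + 1L
  state <- list(
    B_e  = rep(2, nphi),   # extracellular TGF-beta per cell [nmol]
    R    = rep(2, nphi),   # membrane receptors [nmol]
    B_i  = rep(1, nphi),   # internalized receptor-ligand complex [nmol]
    B_dr = 0.1,            # diffusive-region TGF-beta [nmol]
    N_neigh = c(6, rep(0, nphi - 1L)),  # cells per neighbour volume
    Ocy  = 900,  # osteocytes [1/V_osteon]
    Oc   = 0,    # osteoclasts [1/V_frac]
    Lng  = 0,    # lining (pre-osteoblast) cells [1/S_frac]
    Ob   = 0,    # mature osteoblasts [1/S_frac]
    RANKL = 0,   # [nmol/V_frac]
    BMP  = 0,    # [nmol/V_frac]
    CSF  = 0,    # [nmol/V_frac]
    BMD  = 100,  # bone mineral density [%]
    beta_bone = 0  # bone-niche TGF-beta [nmol/V_frac]
  )
  class(state) <- "tgfb_state"
  state
}

#' Serialize a parameter set to the configuration dialect
#'
#' Writes the parameter set as a YAML document with one section per model
#' (`cellular`, `tissue`, `bone`). [load_parameters()] on the result
#' reproduces the input exactly.
#'
#' @param params A validated parameter set.
#' @param path Optional file path; when `NULL` the YAML text is returned.
#' @return The YAML text (invisibly when written to `path`).
#' @export
write_parameters <- function(params, path = NULL) {
  validate_parameters(params)
  doc <- lapply(.param_sections, function(keys) {
    sec <- params[keys]
    names(sec) <- keys
    sec
  })
  txt <- yaml::as.yaml(doc, precision = 15)
  if (is.null(path)) return(txt)
  writeLines(txt, path, useBytes = TRUE)
  invisible(txt)
}

#' Load parameters from configuration text
#'
#' Parses a sectioned key/value configuration (YAML dialect; sections
#' `cellular`, `tissue`, `bone`). Missing keys fall back to the defaults of
#' [default_parameters()]; every override is logged with a message. Unknown
#' sections or keys are rejected, as is any negative rate.
#'
#' @param text Configuration text. Mutually exclusive with `file`.
#' @param file Path to a configuration file.
#' @param quiet Suppress the per-override log messages.
#' @return A validated `tgfb_params` list.
#' @export
#' @examples
#' p <- load_parameters(text = "bone:\n  N_c: 0\n", quiet = TRUE)
#' p$N_c
load_parameters <- function(text = NULL, file = NULL, quiet = FALSE) {
  if (is.null(text) == is.null(file)) {
    stop("provide exactly one of 'text' or 'file'")
  }
  raw <- tryCatch(
    if (is.null(file)) yaml::yaml.load(text) else yaml::yaml.load_file(file),
    error = function(e) stop("configuration parse failure: ", conditionMessage(e),
                             call. = FALSE)
  )
  params <- default_parameters()
  if (is.null(raw)) return(validate_parameters(params))
  if (!is.list(raw)) stop("configuration must be a set of sections")
  bad_sec <- setdiff(names(raw), names(.param_sections))
  if (length(bad_sec) > 0) {
    stop("unknown configuration section(s): ", paste(bad_sec, collapse = ", "))
  }
  for (sec in names(raw)) {
    entries <- raw[[sec]]
    if (is.null(entries)) next
    bad <- setdiff(names(entries), .param_sections[[sec]])
    if (length(bad) > 0) {
      stop(sprintf("unknown key(s) in section '%s': %s",
                   sec, paste(bad, collapse = ", ")))
    }
    for (key in names(entries)) {
      value <- entries[[key]]
      if (!is.numeric(value)) stop(sprintf("'%s' must be numeric", key))
      if (!(key %in% .sign_free) && any(value < 0)) {
        stop(sprintf("validation error: '%s' must be non-negative", key))
      }
      if (key == "Phi") value <- as.integer(value)
      if (!isTRUE(all.equal(unname(value), unname(params[[key]])))) {
        if (!quiet) message(sprintf("config override: %s = %s", key,
                                    paste(signif(value, 8), collapse = ", ")))
      }
      params[[key]] <- value
    }
  }
  validate_parameters(params)
  params
}

#' @export
print.tgfb_params <- function(x, ...) {
  cat("<tgfb_params> multi-scale TGF-beta model parameters\n")
  cat(sprintf("  phenotypes: 0..%d   cellular rates [1/s], bone rates [1/day]\n", x$Phi))
  cat(sprintf("  beta_sM: %s\n", paste(x$beta_sM, collapse = ", ")))
  cat(sprintf("  R_sM:    %s\n", paste(x$R_sM, collapse = ", ")))
  cat(sprintf("  N_c = %g cancer cells; tau in [%g, %g] day\n",
              x$N_c, x$tau_bar, x$tau_bar + x$Delta))
  invisible(x)
}

#' @export
print.tgfb_state <- function(x, ...) {
  cat("<tgfb_state> initial state\n")
  cat(sprintf("  B_e: %s  B_dr: %g\n", paste(x$B_e, collapse = ","), x$B_dr))
  cat(sprintf("  N_neigh: %s\n", paste(x$N_neigh, collapse = ",")))
  cat(sprintf("  bone: Ocy=%g BMD=%g\n", x$Ocy, x$BMD))
  invisible(x)
}
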