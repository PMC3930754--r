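# First-order variance-based sensitivity analysis: for each parameter X_i
# the index S_i = Var(E[Y | X_i]) / Var(Y), estimated by a nested
# Monte-Carlo sampler with uniform priors centred on the nominal values.

#' Uniform priors around nominal parameter values
#'
#' Builds the prior table for a set of scalar parameters. The spread
#' follows a 10-per-cent rule with three interpretations:
#' `"sd10"` (default) sets the prior standard deviation to 10 per cent of
#' the nominal value, i.e. a uniform on `theta * (1 +/- 0.1 * sqrt(3))`;
#' `"var10"` sets the prior variance to `0.1 * theta`; `"halfwidth10"`
#' uses `theta +/- 0.1 * theta`. Supports are truncated at zero for
#' non-negative parameters.
#'
#' @param nominal Named numeric vector of nominal values.
#' @param rule Spread rule, one of `"sd10"`, `"var10"`, `"halfwidth10"`.
#' @return Data frame with columns `name`, `nominal`, `min`, `max`.
#' @export
lsa_priors <- function(nominal, rule = c("sd10", "var10", "halfwidth10")) {
  rule <- match.arg(rule)
  half <- switch(rule,
    sd10 = 0.1 * sqrt(3) * abs(nominal),
    var10 = sqrt(3 * 0.1 * abs(nominal)),
    halfwidth10 = 0.1 * abs(nominal))
  lo <- nominal - half
  lo[nominal >= 0] <- pmax(lo[nominal >= 0], 0)
  data.frame(name = names(nominal), nominal = unname(nominal),
             min = unname(lo), max = unname(nominal + half),
             stringsAsFactors = FALSE)
}

draw_from_priors <- function(priors, n) {
  m <- vapply(seq_len(nrow(priors)), function(i) {
    runif(n, priors$min[i], priors$max[i])
  }, numeric(n))
  if (n == 1) m <- matrix(m, nrow = 1)
  colnames(m) <- priors$name
  m
}

#' First-order sensitivity index of one parameter
#'
#' Nested Monte-Carlo estimator of `S_i = Var(E[Y | X_i]) / Var(Y)`:
#' `n_outer` draws of the target parameter, each with `n_inner` draws of
#' all remaining parameters; the conditional means over the inner loop give
#' the numerator and the pooled sample gives the total variance. Tiny
#' negative estimates are clamped to zero (with a message). Reproducible
#' given the seed.
#'
#' @param model_fn Deterministic function: named parameter vector -> scalar.
#' @param target Name of the parameter whose index is estimated.
#' @param priors Prior table from [lsa_priors()].
#' @param n_outer,n_inner Sampling sizes (both at least 2).
#' @param seed RNG seed.
#' @return List of class `sensitivity_result`: `parameter`, `S`, `n_outer`,
#'   `n_inner`, `seed`, `var_total`.
#' @export
#' @examples
#' pr <- lsa_priors(c(a = 1, b = 2))
#' first_order_index(function(p) p[["a"]], "a", pr, 50, 20, seed = 1)$S  # ~1
first_order_index <- function(model_fn, target, priors, n_outer, n_inner,
                              seed = 1L) {
  stopifnot(n_outer >= 2, n_inner >= 2, target %in% priors$name)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  outer_draws <- draw_from_priors(priors[priors$name == target, , drop = FALSE],
                                  n_outer)[, 1]
  others <- priors[priors$name != target, , drop = FALSE]
  ys <- matrix(NA_real_, n_outer, n_inner)
  for (i in seq_len(n_outer)) {
    inner <- draw_from_priors(others, n_inner)
    for (j in seq_len(n_inner)) {
      p <- setNames(c(outer_draws[i], inner[j, ]),
                    c(target, colnames(inner)))
      ys[i, j] <- model_fn(p[priors$name])
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  v_tot <- var(as.vector(ys))
  if (!is.finite(v_tot) || v_tot <= 0) {
    stop("sensitivity index undefined: total output variance is zero")
  }
  cond_means <- rowMeans(ys)
  # unbiased-ish correction: subtract the inner-loop noise on the means
  s_num <- var(cond_means) - mean(apply(ys, 1, var)) / n_inner
  S <- s_num / v_tot
  if (S < 0) {
    message(sprintf("clamping small negative index for '%s' (%.3g) to 0",
                    target, S))
    S <- 0
  }
  structure(list(parameter = target, S = S, n_outer = n_outer,
                 n_inner = n_inner, seed = seed, var_total = v_tot),
            class = "sensitivity_result")
}

# scalar model outputs at a fixed observation time, per model id
lsa_model_fn <- function(model = c("cellular", "tissue", "bone"), output,
                         params = default_parameters(),
                         observe_time = NULL) {
  model <- match.arg(model)
  base <- params
  obs <- observe_time
  if (model == "cellular") {
    if (is.null(obs)) obs <- 7200  # seconds; past the exchange relaxation
    function(theta) {
      p <- apply_theta(base, theta)
      init <- default_initial_state(p)
      traj <- simulate_cellular(init, N_neigh = init$N_neigh, params = p,
                                t_grid = seq(0, obs, length.out = 41),
                                atol = 1e-08, rtol = 1e-06)
      trajectory_at(traj, obs)[[output]]
    }
  } else if (model == "tissue") {
    if (is.null(obs)) obs <- 24  # months
    function(theta) {
      p <- apply_theta(base, theta)
      init <- default_initial_state(p)
      B_in <- quasi_steady_influx(init$N_neigh, p)
      month_s <- DAYS_PER_MONTH * SECONDS_PER_DAY
      traj <- simulate_tissue(init$N_neigh, B_in, p,
                              seq(0, obs * month_s, length.out = 97),
                              atol = 1e-10, rtol = 1e-08)
      trajectory_at(traj, obs)[[output]]
    }
  } else {
    if (is.null(obs)) obs <- 200  # days, end of the remodeling cycle
    function(theta) {
      p <- apply_theta(base, theta)
      traj <- simulate_fracture(p, horizon_days = obs, dt_out = 2,
                                atol = 1e-08, rtol = 1e-06)
      v <- trajectory_at(traj, obs)
      if (output == "BMD") v[["z"]] else v[[output]]
    }
  }
}

# map a named theta vector (entries like "beta_sM.0", "r_u", "tau_bar")
# onto a parameter set
apply_theta <- function(params, theta) {
  for (nm in names(theta)) {
    if (grepl("\\.", nm)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      params[[parts[1]]][as.integer(parts[2]) + 1L] <- theta[[nm]]
    } else {
      params[[nm]] <- theta[[nm]]
    }
  }
  params
}

# flatten selected parameters (phenotype vectors become name.phi entries)
flatten_params <- function(params, names_wanted) {
  out <- numeric(0)
  for (nm in names_wanted) {
    v <- params[[nm]]
    if (length(v) > 1) {
      out <- c(out, setNames(v, sprintf("%s.%d", nm, seq_along(v) - 1L)))
    } else {
      out <- c(out, setNames(v, nm))
    }
  }
  out
}

#' First-order sensitivity report for a model
#'
#' Computes `S_i` for every (parameter, output) pair of one of the three
#' models, with uniform priors from the 10-per-cent rule around the
#' default values and outputs evaluated at a fixed observation time
#' (cellular: 7200 s; tissue: 24 months; bone: end of the 200-day cycle).
#' Per-phenotype vector parameters are sampled entry by entry.
#'
#' @param model `"cellular"`, `"tissue"` or `"bone"`.
#' @param outputs Character vector of output names (state columns; for the
#'   bone model `"BMD"` refers to the density column).
#' @param parameters Names of parameters to vary (defaults to the natural
#'   set of the model).
#' @param params Baseline parameter set.
#' @param n_outer,n_inner Sampling sizes.
#' @param seed RNG seed.
#' @param rule Prior spread rule, see [lsa_priors()].
#' @param observe_time Observation time override (model time unit).
#' @return Long-format data frame: `model`, `output`, `parameter`, `S`.
#' @export
lsa_report <- function(model, outputs, parameters = NULL,
                       params = default_parameters(),
                       n_outer = 24, n_inner = 8, seed = 1L,
                       rule = "sd10", observe_time = NULL) {
  if (is.null(parameters)) {
    parameters <- switch(model,
      cellular = c("beta_sM", "R_sM", "r_syn", "r_b", "r_pc", "r_u", "r_sgn"),
      tissue   = c("r_p", "r_a", "r_d", "g_p", "g_a", "C_phi"),
      bone     = c("r_beta", "d_beta", "a_Lng", "tau_bar", "r_Oc", "a_Oc"))
  }
  nominal <- flatten_params(params, parameters)
  priors <- lsa_priors(nominal, rule = rule)
  rows <- list()
  k <- 0L
  for (out_nm in outputs) {
    fn <- lsa_model_fn(model, out_nm, params, observe_time)
    for (tgt in priors$name) {
      k <- k + 1L
      res <- first_order_index(fn, tgt, priors, n_outer, n_inner,
                               seed = seed + k)
      rows[[k]] <- data.frame(model = model, output = out_nm,
                              parameter = tgt, S = res$S,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
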