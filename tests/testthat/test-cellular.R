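test_that("Fick-law paracrine rate: value, proportionality, domain errors", {
  expect_equal(derive_paracrine_rate(1, 1, 1, 1), 1)
  expect_equal(derive_paracrine_rate(10, 100, 0.05, 2000), 10)  # tabulated default
  r1 <- derive_paracrine_rate(3, 7, 0.2, 500)
  expect_equal(derive_paracrine_rate(3, 7, 0.4, 500), r1 / 2)
  expect_equal(derive_paracrine_rate(6, 7, 0.2, 500), 2 * r1)
  expect_error(derive_paracrine_rate(1, 1, 0, 1), "positive")
  expect_error(derive_paracrine_rate(1, 1, 1, 0), "positive")
})

test_that("cellular derivatives vanish for a fully silent system", {
  p <- default_parameters()
  p$beta_sM <- rep(0, 4); p$R_sM <- rep(0, 4)
  zero <- list(B_e = rep(0, 4), R = rep(0, 4), B_i = rep(0, 4), B_dr = 0)
  d <- cellular_rhs(zero, N_neigh = c(6, 0, 0, 0), params = p)
  expect_equal(unlist(d), unlist(list(B_e = rep(0, 4), R = rep(0, 4),
                                      B_i = rep(0, 4), B_dr = 0)),
               ignore_attr = TRUE)
})

test_that("ligand mass balance holds identically at random states", {
  # d/dt [ sum_phi N(B_e + B_i) + B_dr ] must equal total synthesis minus
  # the Smad signaling and healthy-cell ubiquitination sinks
  set.seed(7)
  p <- default_parameters()
  for (k in 1:20) {
    st <- list(B_e = runif(4, 0, 5), R = runif(4, 0, 5),
               B_i = runif(4, 0, 5), B_dr = runif(1, 0, 5))
    N <- c(runif(1, 1, 8), runif(3, 0, 4))
    d <- cellular_rhs(st, N, p)
    lhs <- sum(N * (d$B_e + d$B_i)) + d$B_dr
    rhs <- sum(N * p$r_syn * p$beta_sM) - p$r_sgn * sum(N * st$B_i) -
      p$r_u * N[1] * st$B_i[1]
    expect_lt(abs(lhs - rhs) / max(abs(rhs), 1), 1e-10)
  }
})

test_that("isolated healthy cells reach the binding-equals-synthesis steady state", {
  # equal ligand/receptor synthesis makes a true fixed point; without
  # paracrine loss the binding flux must balance the synthesis flux and the
  # internalized pool its first-order sinks
  p <- default_parameters()
  p$beta_sM <- rep(2, 4); p$R_sM <- rep(2, 4); p$r_pc <- 0
  init <- default_initial_state(p)
  traj <- simulate_cellular(init, N_neigh = c(6, 0, 0, 0), params = p,
                            t_grid = seq(0, 20000, length.out = 51))
  fin <- trajectory_at(traj, 20000)
  bind <- p$r_b * fin[["B_e.0"]] * fin[["R.0"]]
  expect_equal(bind, p$r_syn * 2, tolerance = 1e-06)
  expect_equal(fin[["B_i.0"]], p$r_syn * 2 / (p$r_sgn + p$r_u),
               tolerance = 1e-06)
  # and B_dr decouples entirely when r_pc = 0
  expect_equal(unname(traj$state[, "B_dr"]), rep(init$B_dr, 51))
})

test_that("published initial values integrate without invariant violations", {
  p <- default_parameters()
  init <- default_initial_state(p)
  traj <- simulate_cellular(init, params = p,
                            t_grid = seq(0, 3600, length.out = 101))
  expect_true(all(traj$state > -1e-09))
  expect_true(all(is.finite(traj$state)))
})

test_that("adaptive solution matches an independent RK4 oracle at the endpoint", {
  p <- default_parameters()
  init <- default_initial_state(p)
  N <- init$N_neigh
  t_end <- 50
  traj <- simulate_cellular(init, N, p, t_grid = c(0, t_end / 2, t_end),
                            atol = 1e-11, rtol = 1e-09)
  f <- function(t, y) {
    d <- cellular_rhs(list(B_e = y[1:4], R = y[5:8], B_i = y[9:12],
                           B_dr = y[13]), N, p)
    c(d$B_e, d$R, d$B_i, d$B_dr)
  }
  oracle <- rk4_integrate(f, c(init$B_e, init$R, init$B_i, init$B_dr),
                          seq(0, t_end, by = 0.005))
  expect_lt(rel_err(traj$state[3, , drop = FALSE],
                    oracle[nrow(oracle), , drop = FALSE]), 1e-06)
})

test_that("homogeneous phenotypes make paracrine exchanges cancel out", {
  p <- default_parameters()
  p$beta_sM <- rep(1.7, 4); p$R_sM <- rep(5, 4); p$r_u <- 0
  init <- default_initial_state(p)
  traj <- simulate_cellular(init, N_neigh = rep(2, 4), params = p,
                            t_grid = seq(0, 1000, length.out = 21))
  for (v in c("B_e", "R", "B_i")) {
    for (phi in 1:3) {
      expect_equal(unname(traj$state[, sprintf("%s.%d", v, phi)]),
                   unname(traj$state[, sprintf("%s.0", v)]),
                   tolerance = 1e-08, info = sprintf("%s.%d", v, phi))
    }
  }
})

test_that("stronger ubiquitination lowers only the healthy internalized pool", {
  p <- default_parameters(); p$r_pc <- 0
  init <- default_initial_state(p)
  run <- function(r_u) {
    q <- p; q$r_u <- r_u
    trajectory_at(simulate_cellular(init, params = q,
                                    t_grid = seq(0, 10000, length.out = 21)),
                  10000)
  }
  lo <- run(0.003); hi <- run(0.03)
  expect_lt(hi[["B_i.0"]], lo[["B_i.0"]])
  for (phi in 1:3) {
    expect_equal(hi[[sprintf("B_i.%d", phi)]], lo[[sprintf("B_i.%d", phi)]],
                 tolerance = 1e-08)
  }
})

test_that("per-phenotype summary: start values, positivity, isoform pattern flag", {
  p <- default_parameters()
  init <- default_initial_state(p)
  traj <- simulate_cellular(init, params = p,
                            t_grid = seq(0, 600, length.out = 31))
  s0 <- internalized_summary(traj, 0)
  expect_equal(s0$B_e, rep(2, 4))
  expect_equal(s0$R, rep(2, 4))
  expect_equal(s0$B_i, rep(1, 4))
  expect_equal(s0$phenotype, 0:3)
  sT <- internalized_summary(traj, 600)
  expect_true(all(sT$B_e >= 0 & sT$R >= 0 & sT$B_i >= 0))
  # receptor expression falls with aggressiveness at the defaults: the
  # antitumorigenic isoform pattern
  expect_true(attr(sT, "antitumorigenic")[["R"]])
  expect_error(internalized_summary(traj, 1e6), "span")
})
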