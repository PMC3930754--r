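test_that("maturation delay is bounded, saturating, and half-saturates at beta_bar", {
  p <- default_parameters()
  expect_equal(delay_tau(0, p), 6.02)
  expect_equal(delay_tau(1, p), 28.38, tolerance = 1e-06)
  expect_equal(delay_tau(p$beta_bar, p), p$tau_bar + p$Delta / 2)
  set.seed(3)
  beta <- c(0, 10^runif(50, -10, 0))
  tau <- delay_tau(beta, p)
  expect_true(all(tau >= p$tau_bar & tau <= p$tau_bar + p$Delta))
  expect_true(all(diff(delay_tau(seq(0, 1e-06, length.out = 30), p)) >= 0))
})

test_that("healthy steady state is an equilibrium and is invariant in time", {
  p <- default_parameters()
  quiet <- fracture_event(p, D = 0)
  s <- default_initial_state(p)
  y <- c(Ocy = s$Ocy, Oc = 0, Lng = 0, Ob = 0, RANKL = 0, BMP = 0, CSF = 0,
         z = s$BMD, beta = 0, dmg = 0)
  d <- bone_rhs(5, y, p, quiet, N_c = 0)
  expect_equal(unname(d), rep(0, 10))
  traj <- simulate_fracture(p, N_c = 0, horizon_days = 150, fracture = quiet,
                            dt_out = 1)
  expect_equal(unname(traj$state[nrow(traj$state), ]),
               unname(traj$state[1, ]), tolerance = 1e-10)
})

test_that("osteoclasts only decay without RANKL and CSF", {
  p <- default_parameters()
  y <- c(Ocy = 870, Oc = 0.4, Lng = 0, Ob = 0, RANKL = 0, BMP = 0, CSF = 0,
         z = 100, beta = 0, dmg = 10)
  d <- bone_rhs(5, y, p, fracture_event(p), N_c = 0)
  expect_lt(d[["Oc"]], 0)
})

test_that("zero-delay configuration reproduces an independent RK4 integration", {
  p <- default_parameters()
  quiet <- fracture_event(p, D = 0)
  init <- default_initial_state(p)
  init$Oc <- 0.2; init$RANKL <- 500; init$BMP <- 0.003; init$CSF <- 4e-05
  init$Lng <- 1; init$Ob <- 0.1
  traj <- simulate_fracture(p, N_c = 0, horizon_days = 40, fracture = quiet,
                            init = init, dt_out = 5, delay_scale = 0,
                            atol = 1e-12, rtol = 1e-10)
  y0 <- c(Ocy = init$Ocy, Oc = init$Oc, Lng = init$Lng, Ob = init$Ob,
          RANKL = init$RANKL, BMP = init$BMP, CSF = init$CSF, z = init$BMD,
          beta = init$beta_bone, dmg = 0)
  oracle <- rk4_integrate(function(t, y) {
    unname(bone_rhs(t, y, p, quiet, N_c = 0, lag = NULL, delay_scale = 0))
  }, y0, seq(0, 40, by = 0.0025))
  oracle <- oracle[seq(1, nrow(oracle), by = 2000), 1:9]
  expect_lt(rel_err(traj$state, oracle), 1e-06)
})

test_that("control cycle shows the canonical remodeling sequence", {
  p <- default_parameters()
  traj <- simulate_fracture(p, N_c = 0, horizon_days = 200, dt_out = 0.5)
  expect_equal(traj$meta$clips, 0)
  st <- traj$state
  # osteocyte drop completes with the apoptosis pulse
  expect_equal(unname(st[1, "Ocy"]), 900)
  expect_lt(min(st[, "Ocy"]), 880)
  # RANKL/CSF rise precedes the osteoclast wave, which precedes the
  # osteoblast wave
  expect_lt(traj$time[which.max(st[, "RANKL"])],
            traj$time[which.max(st[, "Oc"])])
  expect_lt(traj$time[which.max(st[, "CSF"])],
            traj$time[which.max(st[, "Oc"])])
  expect_lt(traj$time[which.max(st[, "Oc"])],
            traj$time[which.max(st[, "Ob"])])
  # density dips during resorption and recovers to a near-neutral balance
  expect_lt(min(st[, "z"]), 100)
  expect_gt(tail(st[, "z"], 1), min(st[, "z"]))
  expect_lt(abs(remodeling_balance(traj)), 0.2)
  # the niche TGF-beta stays within the delay's saturating range
  tau <- delay_tau(st[, "beta"], p)
  expect_true(all(tau >= p$tau_bar & tau <= p$tau_bar + p$Delta))
})

test_that("cancer load tips the balance negative; a null fracture changes nothing", {
  p <- default_parameters()
  control <- simulate_fracture(p, N_c = 0, horizon_days = 200, dt_out = 0.5)
  cancer <- simulate_fracture(p, N_c = 2000, horizon_days = 200, dt_out = 0.5)
  expect_lt(tail(cancer$state[, "z"], 1), tail(control$state[, "z"], 1))
  expect_lt(remodeling_balance(cancer), 0)
  expect_gt(abs(remodeling_balance(cancer)), abs(remodeling_balance(control)))
  quiet <- simulate_fracture(p, N_c = 0, horizon_days = 50,
                             fracture = fracture_event(p, D = 0), dt_out = 1)
  expect_equal(unname(quiet$state[nrow(quiet$state), ]),
               unname(quiet$state[1, ]), tolerance = 1e-10)
  expect_equal(remodeling_balance(quiet), 0, tolerance = 1e-10)
})

test_that("mixed-lesion index: determinism, degeneracy, and growth with spread", {
  p <- default_parameters()
  dist0 <- list(family = "lognormal", meanlog = 0, sdlog = 0)
  r0 <- mixed_lesion_index(p, 3, dist0, seed = 11, horizon_days = 120,
                           dt_out = 1)
  expect_equal(r0$index, 0)
  d1 <- list(family = "lognormal", meanlog = 0, sdlog = 0.25)
  a <- mixed_lesion_index(p, 3, d1, seed = 11, horizon_days = 120, dt_out = 1)
  b <- mixed_lesion_index(p, 3, d1, seed = 11, horizon_days = 120, dt_out = 1)
  expect_identical(a$index, b$index)
  d2 <- list(family = "lognormal", meanlog = 0, sdlog = 0.6)
  c2 <- mixed_lesion_index(p, 3, d2, seed = 11, horizon_days = 120, dt_out = 1)
  expect_gt(c2$index, a$index)
  expect_gt(a$index, 0)
  expect_error(mixed_lesion_index(p, 3, list(family = "cauchy"), seed = 1),
               "unknown release distribution")
})
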