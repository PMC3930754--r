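month_s <- 365.25 / 12 * 86400

test_that("response factor: neutral cases, monotonicity, degenerate guard", {
  expect_equal(response_factor(5, 0), 1)
  expect_equal(response_factor(0, 0), 1)
  expect_equal(response_factor(1, 0.7), 1)   # unit scaled signal
  expect_equal(response_factor(1, -2), 1)
  grid <- c(0.5, 1, 5, 50, 500)
  expect_true(all(diff(response_factor(grid, 0.3)) > 0))
  expect_true(all(diff(response_factor(grid, -0.3)) < 0))
  # zero influx with negative exponent is clamped, not infinite
  expect_true(is.finite(response_factor(0, -0.06)))
  expect_error(response_factor(-1, 0.1), "non-negative")
})

test_that("default exponents encode the Jekyll-and-Hyde sign structure", {
  # apoptosis response rises with the influx for healthy cells and falls
  # for the malignant phenotype
  p <- default_parameters()
  grid <- seq(1, 300, length.out = 40)
  healthy <- response_factor(grid, p$g_a[1])
  malignant <- response_factor(grid, p$g_a[p$Phi + 1])
  expect_true(all(diff(healthy) > 0))
  expect_true(all(diff(malignant) < 0))
})

test_that("tissue derivatives: absorbing zero state and cell-conserving mutation", {
  p <- default_parameters()
  expect_equal(tissue_rhs(rep(0, 4), rep(1, 4), p), rep(0, 4))
  # stepwise mutation alone moves cells without creating or destroying them
  q <- p; q$r_p <- rep(0, 4); q$r_a <- 0; q$r_d <- 0; q$p_Phi <- 0
  d <- tissue_rhs(c(3, 2, 1, 0.5), rep(1, 4), q)
  expect_equal(sum(d), 0)
  expect_error(tissue_rhs(c(-1, 0, 0, 0), rep(1, 4), p), "non-negative")
})

test_that("neutral sensing reduces a single population to closed-form logistic growth", {
  p <- default_parameters()
  p$g_p <- rep(0, 4); p$g_a <- rep(0, 4); p$r_m <- 0; p$p_Phi <- 0
  N0 <- 1
  t_grid <- seq(0, 36 * month_s, length.out = 49)
  traj <- simulate_tissue(c(N0, 0, 0, 0), rep(1, 4), p, t_grid)
  r <- p$r_p[1] - p$r_a - p$r_d
  K <- p$C_phi[1] * r / p$r_p[1]
  closed <- K / (1 + (K / N0 - 1) * exp(-r * t_grid))
  expect_lt(max(abs(traj$state[, "N.0"] - closed) / closed), 1e-06)
})

test_that("without mutation channels the mutated phenotypes never appear", {
  p <- default_parameters(); p$r_m <- 0; p$p_Phi <- 0
  traj <- simulate_tissue(c(6, 0, 0, 0), c(74, 230, 215, 222), p,
                          seq(0, 24 * month_s, length.out = 25))
  expect_equal(max(traj$state[, c("N.1", "N.2", "N.3")]), 0)
})

test_that("default progression shows the canonical shape within the capacity bound", {
  p <- default_parameters()
  B_in <- p$r_syn * p$beta_sM * c(p$r_sgn / (p$r_sgn + p$r_u), 1, 1, 1)
  traj <- simulate_tissue(c(6, 0, 0, 0), B_in, p,
                          seq(0, 30 * month_s, length.out = 121))
  N3 <- traj$state[, "N.3"]
  # long near-zero latency then a proliferation phase: non-decreasing
  # after its minimum
  i_min <- which.min(N3)
  expect_true(all(diff(N3[i_min:length(N3)]) >= -1e-09))
  expect_lt(N3[which(traj$time >= 3)[1]], 0.01)
  expect_gt(tail(N3, 1), 1)
  # healthy cells decline from the full duct occupancy
  expect_lt(tail(traj$state[, "N.0"], 1), 6)
  # total population bounded by the largest capacity
  expect_lt(max(rowSums(traj$state)), max(p$C_phi) * (1 + 1e-06))
})

test_that("phenotype fractions are well-defined, normalized, and start healthy", {
  p <- default_parameters()
  traj <- simulate_tissue(c(6, 0, 0, 0), c(74, 230, 215, 222), p,
                          seq(0, 12 * month_s, length.out = 13))
  expect_equal(phenotype_fraction(traj, 0, 0), 1)
  for (t in c(0, 3, 6, 12)) {
    fr <- vapply(0:3, function(phi) phenotype_fraction(traj, phi, t), 0)
    expect_equal(sum(fr), 1, tolerance = 1e-12)
    expect_true(all(fr >= 0 & fr <= 1))
  }
  empty <- trajectory(c(0, 1), cbind(N.0 = c(0, 0), N.1 = c(0, 0)),
                      model = "tissue", time_unit = "month")
  expect_error(phenotype_fraction(empty, 0, 1), "zero total population")
})

test_that("raising the influx suppresses healthy cells and favours malignant ones", {
  p <- default_parameters()
  base <- c(74, 230, 215, 222)
  run <- function(scale) {
    traj <- simulate_tissue(c(3, 0.1, 0.1, 0.1), base * scale, p,
                            seq(0, 12 * month_s, length.out = 25))
    trajectory_at(traj, 12)
  }
  lo <- run(1); hi <- run(4)
  expect_lt(hi[["N.0"]], lo[["N.0"]])
  expect_gt(hi[["N.3"]], lo[["N.3"]])
})
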