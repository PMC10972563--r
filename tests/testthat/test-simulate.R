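p <- default_parameters()

test_that("the resting steady state is stationary under constant calcium", {
  traj <- simulate_release(p, constant_transient(p, t_end = 1))
  drift <- apply(abs(sweep(traj$sites, 2, traj$sites[1, ])), 2, max)
  expect_lt(max(drift), 1e-4 * p$n_sites)
  # basal fusion trickles at ~l+-weighted occupancy, essentially zero here
  expect_lt(max(traj$fused), 0.1)
})

test_that("simulated trajectories conserve sites and keep forbidden states empty", {
  traj <- fixture_traj("wt")
  expect_lt(max(abs(rowSums(traj$sites) - p$n_sites)) / p$n_sites, 1e-6)
  expect_lt(max(traj$sites[, traj$states$forbidden]), 1e-12 * p$n_sites)
  expect_true(all(diff(traj$fused) >= -1e-9))
  expect_equal(max(abs(rowSums(traj$syt7) - 1)), 0, tolerance = 1e-9)
})

test_that("docked pool dips after each AP and recovers between APs in WT", {
  traj <- fixture_traj("wt")
  onsets <- traj$transient$ap_onsets
  for (k in seq_along(onsets)) {
    win <- traj$time >= onsets[k] & traj$time < onsets[k] + 0.05
    d <- traj$docked[win]
    dip <- min(d)
    expect_lt(dip, d[1] - 1)            # a real dip
    expect_gt(d[length(d)], dip + 1)    # and recovery before the next AP
  }
})

test_that("syt7 removal slows docking recovery but not its equilibrium", {
  # catalyst neutrality: with fusion off, equilibria at any fixed calcium
  # are exactly f7-independent (scaling docking and undocking together
  # cancels in every balance equation)
  ptiny <- default_parameters(l_plus = 1e-12)
  docked <- enumerate_states()$docked
  for (ca in c(0.05, 1)) {
    st_wt <- steady_state(ptiny, ca)
    st_ko <- steady_state(apply_genotype(ptiny, "syt7_ko"), ca)
    expect_equal(sum(st_wt$sites[docked]), sum(st_ko$sites[docked]),
                 tolerance = 1e-9)
  }
  # with the basal fusion leak on, resting docking is still essentially
  # unchanged by syt7 removal
  st_wt <- steady_state(p, p$ca_rest)
  st_ko <- steady_state(apply_genotype(p, "syt7_ko"), p$ca_rest)
  expect_equal(sum(st_wt$sites[docked]), sum(st_ko$sites[docked]),
               tolerance = 1e-3)
  # but the transient docking response differs strongly
  wt <- fixture_traj("wt"); ko <- fixture_traj("syt7_ko")
  expect_gt(docking_recovery(wt), 5 * docking_recovery(ko))
})

test_that("syt1 equilibrium matches the detailed-balance closed form in the slow-exchange limit", {
  # fusion off, Doc2alpha off, docking exchange much slower than the syt1
  # binding dynamics: the docked block then equilibrates internally
  ptiny <- apply_genotype(
    default_parameters(l_plus = 1e-12, k_docking = 5e-4,
                       k_undocking = 5e-4), "doc2_ko")
  ca <- 0.5
  st <- steady_state(ptiny, ca)
  ss <- enumerate_states()
  d0 <- st$sites[ss$docked & ss$d2 == 0 & !ss$forbidden]
  # closed form: pi_{s+1}/pi_s = (5 - s) k1+ ca / ((s+1) k1- b1^s)
  k1p <- ptiny$syt1$k_plus; k1m <- ptiny$syt1$k_minus; b1 <- ptiny$syt1$b
  ratio <- function(s) (5 - s) * k1p * ca / ((s + 1) * k1m * b1^s)
  pi_cf <- cumprod(c(1, vapply(0:4, ratio, 0)))
  pi_cf <- pi_cf / sum(pi_cf)
  expect_equal(unname(d0 / sum(d0)), pi_cf, tolerance = 1e-6)
})

test_that("the solution is insensitive to tighter solver tolerances", {
  tr <- build_transient(p, n_aps = 2, freq = 20)
  a <- simulate_release(p, tr)
  b <- simulate_release(p, tr, rtol = 5e-6, atol = 5e-6, hmax = 5e-6)
  expect_equal(max(a$fused), max(b$fused), tolerance = 1e-3)
})

test_that("the single-site stochastic oracle reproduces the ODE mean", {
  tr <- build_transient(p, n_aps = 1, freq = 20)
  mc <- simulate_site_stochastic(p, tr, n_reps = 1500, seed = 7)
  ode <- simulate_release(p, tr)
  expect_lt(abs(mc$mean_total - max(ode$fused)), 3 * mc$se_total)
  # determinism of the oracle itself
  mc2 <- simulate_site_stochastic(p, tr, n_reps = 50, seed = 11)
  mc3 <- simulate_site_stochastic(p, tr, n_reps = 50, seed = 11)
  expect_identical(mc2$fused, mc3$fused)
})

test_that("trajectories export to a labelled data frame", {
  traj <- fixture_traj("wt")
  df <- as.data.frame(traj)
  expect_equal(ncol(df), 1 + 24 + 3 + 1)
  expect_true(all(c("time_s", "E[0]", "D[2,5]", "S0", "F_cumulative")
                  %in% names(df)))
})
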