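p <- default_parameters()

test_that("fusion rate is the basal rate amplified per bound ion", {
  expect_equal(fusion_rate(0, 0, p), 3.5e-4)
  expect_equal(fusion_rate(1, 0, p) / fusion_rate(0, 0, p), 16)
  expect_equal(fusion_rate(2, 3, p), 3.5e-4 * 27.98^3 * 16^2)
  expect_error(fusion_rate(3, 0, p), "out of range")
  expect_error(fusion_rate(0, 6, p), "out of range")
})

test_that("syt7 catalyses docking and undocking identically", {
  expect_equal(docking_rates(c(1, 0, 0), p),
               c(docking = 5, undocking = 5))
  expect_equal(docking_rates(c(0, 0, 1), p),
               c(docking = 500, undocking = 500))
  p_ko <- apply_genotype(p, "syt7_ko")
  for (S in list(c(1, 0, 0), c(0.2, 0.5, 0.3), c(0, 0, 1)))
    expect_equal(docking_rates(S, p_ko), c(docking = 5, undocking = 5))
  expect_error(docking_rates(c(0.5, 0.2, 0.2), p), "sum to 1")
})

test_that("calcium binding rates respect capacity, budget and cooperativity", {
  # Doc2alpha off-rate from two ions: 2 * k2- * b2
  expect_equal(ca_binding_rates("doc2", 2, ca = 0.05, p)[["off"]],
               2 * 42 * 0.5)
  # syt1 on a docked vesicle with the budget exhausted cannot bind
  expect_equal(ca_binding_rates("syt1", 3, ca = 10, p,
                                context = c(2, 3))[["on"]], 0)
  # syt7 second-ion on-rate at rest
  expect_equal(ca_binding_rates("syt7", 1, ca = 0.05, p)[["on"]],
               1 * 28 * 0.05)
  # Doc2alpha on an empty site uses only its own free capacity
  expect_equal(ca_binding_rates("doc2", 0, ca = 1, p)[["on"]], 2 * 28)
  expect_error(ca_binding_rates("syt1", 0, ca = 1, p), "docked")
})

test_that("intensity matrix is a generator with the right structure", {
  s7 <- syt7_steady_state(p, p$ca_rest)
  Q <- build_intensity_matrix(p$ca_rest, s7, p)
  expect_equal(dim(Q), c(24, 24))
  offdiag <- Q; diag(offdiag) <- 0
  expect_true(all(offdiag >= 0))
  expect_lt(max(abs(rowSums(Q))), 1e-10 * max(Q))
  # no flux into the budget-violating docked states from anywhere
  ss <- enumerate_states()
  expect_true(all(offdiag[, ss$forbidden] == 0))
  # docking enters only at s1 = 0; with calcium-free syt7 it is basal
  g <- sum(s7 * p$syt7$f^(0:2))
  expect_equal(Q["T[1]", "D[1,0]"], 5 * g)
  Q0 <- build_intensity_matrix(p$ca_rest, c(1, 0, 0), p)
  expect_equal(Q0["T[1]", "D[1,0]"], 5)
  expect_equal(Q0["T[2]", "D[2,1]"], 0)   # never into s1 > 0
  # fusion returns the site to empty, preserving the Doc2alpha state
  expect_equal(Q["D[1,3]", "E[1]"], fusion_rate(1, 3, p))
  expect_equal(Q["D[1,3]", "E[0]"], 0)
})

test_that("at zero calcium all on-rates vanish", {
  Q <- build_intensity_matrix(0, c(1, 0, 0), p)
  ss <- enumerate_states()
  # no binding transitions: E[0] only tethers; E[1] can only unbind/tether
  expect_equal(Q["E[0]", "E[1]"], 0)
  expect_equal(Q["D[0,0]", "D[0,1]"], 0)
  expect_gt(Q["E[1]", "E[0]"], 0)
  st <- steady_state(p, ca = 0)
  expect_equal(unname(st$syt7), c(1, 0, 0))
  bound <- ss$d2 > 0 | (!is.na(ss$s1) & ss$s1 > 0)
  expect_true(all(st$sites[bound] < 1e-9 * p$n_sites))
})

test_that("syt7 steady state follows detailed balance", {
  s7 <- syt7_steady_state(p, 0.05)
  expect_equal(s7[["S[1]"]] / s7[["S[0]"]], 2 * 0.05 * 28 / 42)
  expect_equal(s7[["S[1]"]] / s7[["S[0]"]], 1 / 15)
  s7b <- syt7_steady_state(p, 1)
  expect_equal(s7b[["S[2]"]] / s7b[["S[1]"]], 1 * 28 / (2 * 0.5 * 42))
})

test_that("null-space and matrix-exponential steady states agree", {
  for (ca in c(0.05, 0.5)) {
    st1 <- steady_state(p, ca, method = "null")
    st2 <- steady_state(p, ca, method = "expm")
    expect_lt(max(abs(st1$sites - st2$sites)), 1e-6 * p$n_sites)
  }
})
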