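params <- cgmParameters()
x0 <- defaultInitialState()

test_that("reaction rates respect substrate, auxotrophy and proteome limits", {
  st <- c(V = 1, S = 2, X = 1, P = 0, A = 0, Y = 0.05,
          phiT = 0.3, phiR = 0.2, phiFp = 0.02, m = 0.1)
  r <- reactionRates(st, params)
  expect_true(all(unlist(r) >= 0) && all(is.finite(unlist(r))))

  # zero-substrate limit: no uptake, no overflow
  st_s0 <- st; st_s0[["S"]] <- 0
  r0 <- reactionRates(st_s0, params)
  expect_identical(r0$v_T, 0)
  expect_identical(r0$v_A, 0)

  # L-tyr auxotrophy: no growth without L-tyr
  st_y0 <- st; st_y0[["Y"]] <- 0
  expect_identical(reactionRates(st_y0, params)$mu, 0)

  # uptake is linear in phiT (evaluated at two points)
  st2 <- st; st2[["phiT"]] <- 2 * st[["phiT"]]
  expect_equal(reactionRates(st2, params)$v_T,
               2 * reactionRates(st, params)$v_T, tolerance = 1e-12)

  # overflow switches on above v_crit
  st_hi <- st; st_hi[["phiT"]] <- 0.5
  r_hi <- reactionRates(st_hi, params)
  expect_equal(r_hi$v_A, params$kA * (r_hi$v_T - params$v_crit))

  expect_error(reactionRates(replace(st, 2, NaN), params), "non-finite")
})

test_that("allocation fractions close to one and respond to the inducer", {
  st <- c(V = 1, S = 1, X = 1, P = 0, A = 0, Y = 0.05,
          phiT = 0.3, phiR = 0.2, phiFp = 0, m = 0.12)
  # uninduced: no production allocation; closure holds
  a0 <- allocation(st, params, iptg = 0)
  expect_identical(a0$alpha_Fp, 0)
  expect_equal(a0$alpha_T + a0$alpha_R + a0$alpha_Fp + a0$alpha_Q, 1)

  # half-saturation of the induction response
  ah <- allocation(st, params, iptg = params$KI)
  expect_equal(ah$alpha_Fp, params$alpha_Fp_max / 2)

  # closure for a sweep of states and inducer levels
  for (m in c(0.01, 0.1, 0.4)) {
    for (iptg in c(0, 0.01, 0.3)) {
      a <- allocation(replace(st, 10, m), params, iptg)
      expect_equal(sum(unlist(a)), 1, tolerance = 1e-12)
      expect_true(all(unlist(a) >= 0 & unlist(a) <= 1))
    }
  }
  expect_error(allocation(st, params, iptg = -1), "nonnegative")
})

test_that("derivatives satisfy fed-batch bookkeeping identities", {
  sched <- fixture("short_schedule")
  st <- c(V = 1.05, S = 0.03, X = 8, P = 0.1, A = 0.1, Y = 0.08,
          phiT = 0.35, phiR = 0.17, phiFp = 0, m = 0.05)

  # batch phase: no feed, constant volume
  d1 <- cgmDerivatives(2, st, params, sched)
  expect_identical(d1[["V"]], 0)

  # abiotic reactor in batch: all concentration derivatives vanish
  st_ab <- st; st_ab[["X"]] <- 0
  d_ab <- cgmDerivatives(2, st_ab, params, sched)
  expect_equal(unname(d_ab[c("S", "P", "A", "Y")]), rep(0, 4))

  # liquid-phase glycerol bookkeeping: d(SV)/dt = F*S_feed - v_T*X*V,
  # checked by expanding the product rule with the returned derivatives
  t2 <- 20  # phase 2
  d2 <- cgmDerivatives(t2, st, params, sched)
  Fr <- feedRate(t2, st, params, sched)
  v_T <- reactionRates(st, params)$v_T
  lhs <- d2[["S"]] * st[["V"]] + st[["S"]] * d2[["V"]]
  rhs <- Fr * sched$S_feed2 - v_T * st[["X"]] * st[["V"]]
  expect_equal(lhs, rhs, tolerance = 1e-12)

  expect_error(cgmDerivatives(2, replace(st, 1, 0), params, sched),
               "volume")
})

test_that("batch simulation depletes glycerol monotonically before feeding", {
  sched <- fixture("short_schedule")
  tr <- simulateProcess(x0, params, sched, seq(0, 15.6, by = 0.05))
  S <- tr$states[, "S"]
  expect_true(all(diff(S) <= 1e-10))
  expect_lt(min(S), 0.02)
  # volume constant in batch
  expect_equal(max(abs(tr$states[, "V"] - 1)), 0, tolerance = 1e-9)
})

test_that("simulated trajectories obey mass balance and state invariants", {
  tr <- fixture("ref")$truth
  # glycerol liquid-phase balance against the co-integrated quadrature
  SV <- tr$states[, "S"] * tr$states[, "V"]
  resid <- SV - (x0[["S"]] * x0[["V"]] + tr$fed_glycerol_g -
                   tr$uptake_glycerol_g)
  expect_lt(max(abs(resid)) / max(SV), 1e-6)

  # nonnegativity (post-clip) and proteome closure
  expect_true(all(tr$states >= 0))
  expect_true(all(rowSums(tr$states[, c("phiT", "phiR", "phiFp")]) <=
                    1 - params$phiQ + 1e-8))
  # volume non-decreasing (feed is never negative)
  expect_true(all(diff(tr$states[, "V"]) >= -1e-12))
  # phase index non-decreasing
  expect_true(all(diff(tr$phase) >= 0))
})

test_that("phase-2 feeding tracks the growth-rate set point within 10%", {
  tr <- fixture("ref")$truth
  sched <- fixture("ref")$schedule
  mid <- which(tr$times >= sched$t_batch_end + 4 &
                 tr$times <= sched$t_induction - 4)
  XV <- tr$states[mid, "X"] * tr$states[mid, "V"]
  mu_real <- diff(log(XV[c(1, length(mid))])) /
    diff(tr$times[mid[c(1, length(mid))]])
  expect_lt(abs(mu_real - params$mu_set) / params$mu_set, 0.1)
})

test_that("zero-inoculum runs stay abiotic", {
  sched <- fixture("short_schedule")
  x0_ab <- replace(x0, "X", 0)
  tr <- simulateProcess(x0_ab, params, sched, seq(0, 45, by = 0.5))
  expect_equal(max(tr$states[, "X"]), 0)
  expect_equal(max(tr$states[, "P"]), 0)
})

test_that("measurement selection is a pure, intracellular-blind projection", {
  st <- c(V = 1, S = 0.5, X = 10, P = 20, A = 0, Y = 0.1,
          phiT = 0.3, phiR = 0.2, phiFp = 0.05, m = 0.1)
  expect_equal(measureStates(st),
               c(X = 10, S = 0.5, P = 20, A = 0, Y = 0.1))
  # intracellular changes leave the measurement unchanged
  st2 <- st; st2[["phiR"]] <- 0.1; st2[["m"]] <- 0.4
  expect_identical(measureStates(st2), measureStates(st))
  # composition with a simulated trajectory: 5 columns, no negatives
  M <- measureStates(fixture("ref")$truth)
  expect_identical(dim(M), c(length(fixture("ref")$truth$times), 5L))
  expect_true(all(M >= 0))
})

test_that("state validation catches shape, sign and closure violations", {
  expect_silent(validateState(x0, params))
  expect_error(validateState(x0[-1], params), "length 10")
  expect_error(validateState(replace(x0, "V", -1), params), "volume")
  bad <- x0; bad[["phiT"]] <- 0.5; bad[["phiR"]] <- 0.4
  expect_error(validateState(bad, params), "phiQ")
})

test_that("model configuration round-trips through YAML", {
  sched <- fixture("short_schedule")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeModelConfig(params, sched, path)
  back <- readModelConfig(path)
  expect_equal(unclass(back$params), unclass(params))
  expect_equal(unclass(back$schedule), unclass(sched))
})
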