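test_that("unscented weights follow the scaled transform", {
  # direct substitution: n=1, alpha=1, kappa=0, beta=2
  w <- ukfWeights(1, alpha = 1, beta = 2, kappa = 0)
  expect_equal(w$lambda, 0)
  expect_equal(w$Wm, c(0, 0.5, 0.5))
  expect_equal(w$Wc[1], 2)

  # mean weights always sum to one
  for (n in c(1, 4, 10)) {
    for (al in c(0.1, 0.5, 1)) {
      wk <- ukfWeights(n, alpha = al, kappa = 3 - n)
      expect_equal(sum(wk$Wm), 1, tolerance = 1e-12)
    }
  }
  # n + lambda must stay positive
  expect_error(ukfWeights(10, alpha = 1, kappa = -10), "kappa")
  expect_silent(ukfWeights(10, alpha = 1, kappa = 3 - 10))
  expect_error(ukfWeights(3, alpha = 0), "alpha")
})

test_that("sigma points scale with the covariance and regenerate it", {
  # degenerate covariance: all points collapse onto the mean
  chi0 <- sigmaPoints(c(a = 1, b = 2), matrix(0, 2, 2), lambda = 0)
  expect_true(all(chi0 == c(1, 2)))
  expect_identical(dim(chi0), c(2L, 5L))

  # scalar case: P = 4, lambda = 0 -> {x, x+2, x-2}
  chi <- sigmaPoints(3, matrix(4), lambda = 0)
  expect_equal(drop(chi), c(3, 5, 1))

  # unscented-transform identity: mean via Wm, covariance via the
  # Wm(0)-substituted weights, for random PSD matrices
  withr::with_seed(21, {
    for (rep in 1:5) {
      n <- 6
      P <- randomPSD(n)
      x <- rnorm(n)
      w <- ukfWeights(n, alpha = 0.5, beta = 2, kappa = 0)
      chi <- sigmaPoints(x, P, w$lambda)
      expect_lt(max(abs(drop(chi %*% w$Wm) - x)), 1e-12)
      Wc2 <- w$Wc; Wc2[1] <- w$Wm[1]
      D <- chi - x
      expect_lt(max(abs(D %*% (Wc2 * t(D)) - P)), 1e-10)
    }
  })
})

test_that("prediction and update match the classical filter on linear systems", {
  n <- 4; q <- 2
  withr::with_seed(31, {
    A <- matrix(rnorm(n * n), n); A <- 0.9 * A / max(abs(eigen(A)$values))
    H <- matrix(rnorm(q * n), q)
    Q <- randomPSD(n, 0.1); R <- randomPSD(q, 0.05)
    P <- randomPSD(n)
    x <- rnorm(n)
    y <- rnorm(q)
  })
  w <- ukfWeights(n, alpha = 0.5, beta = 2, kappa = 0)

  pr <- ukfPredict(x, P, function(M) A %*% M, Q, w)
  kf <- kfStep(x, P, A, Q, H, R, y)
  expect_lt(max(abs(pr$x - kf$x_prior)), 1e-8)
  expect_lt(max(abs(pr$P - kf$P_prior)), 1e-8)

  up <- ukfUpdate(pr$x, pr$P, y, function(M) H %*% M, R, w)
  expect_lt(max(abs(up$x - kf$x)), 1e-8)
  expect_lt(max(abs(up$P - kf$P)), 1e-8)

  # Q = 0 with identity dynamics leaves the state untouched
  id <- ukfPredict(x, P, function(M) M, matrix(0, n, n), w)
  expect_equal(id$x, stats::setNames(x, NULL), tolerance = 1e-12)
  expect_equal(id$P, P, tolerance = 1e-10)
})

test_that("update limits: infinite noise ignores, zero innovation shrinks", {
  n <- 4; q <- 2
  withr::with_seed(37, {
    H <- matrix(rnorm(q * n), q)
    R0 <- randomPSD(q, 0.05)
    P <- randomPSD(n)
    x <- rnorm(n)
    y <- rnorm(q)
  })
  w <- ukfWeights(n, alpha = 0.5, beta = 2, kappa = 0)
  h <- function(M) H %*% M

  base <- ukfUpdate(x, P, y, h, R0, w)
  huge <- ukfUpdate(x, P, y, h, 1e9 * R0, w)
  expect_lt(sqrt(sum((huge$x - x)^2)),
            1e-3 * sqrt(sum((base$gain %*% base$innovation)^2)))

  # measurement equal to the prediction: mean unchanged, covariance
  # still contracts by K Py K'
  y0 <- drop(H %*% x)
  z <- ukfUpdate(x, P, y0, h, R0, w)
  expect_equal(z$x, stats::setNames(x, NULL), tolerance = 1e-9)
  expect_equal(z$P, P - z$gain %*% z$Py %*% t(z$gain), tolerance = 1e-9)
  dP <- eigen(P - z$P, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(dP >= -1e-9))
})

test_that("constraint projection clips sigma points and recombines", {
  w1 <- ukfWeights(1, alpha = 1, beta = 2, kappa = 0)  # Wm = (0, .5, .5)

  # feasible posterior passes through bit-identical
  ok <- constrainPosterior(c(s = 2), matrix(1), 0, w1)
  expect_false(ok$constrained)
  expect_identical(ok$x, c(s = 2))

  # hand enumeration over the 3 points: x=-1, P=1 -> points (-1, 0, -2),
  # all clipped to 0 -> mean 0, zero spread
  c1 <- constrainPosterior(c(s = -1), matrix(1), 0, w1)
  expect_true(c1$constrained)
  expect_equal(unname(c1$x), 0)
  expect_equal(drop(c1$P), 0, tolerance = 1e-12)

  # x=-0.1, P=1 -> points (-0.1, 0.9, -1.1) -> (0, 0.9, 0):
  # mean = 0.45; covariance = 2*0.45^2 + 0.5*0.45^2 + 0.5*0.45^2
  c2 <- constrainPosterior(c(s = -0.1), matrix(1), 0, w1)
  expect_equal(unname(c2$x), 0.45, tolerance = 1e-12)
  expect_equal(drop(c2$P), 3 * 0.45^2, tolerance = 1e-10)

  # multivariate case stays PSD and feasible
  withr::with_seed(41, {
    for (rep in 1:5) {
      n <- 5
      w <- ukfWeights(n, alpha = 0.5, beta = 2, kappa = 0)
      P <- randomPSD(n)
      x <- rnorm(n) - 1
      cc <- constrainPosterior(x, P, rep(0, n), w)
      expect_true(all(cc$x >= 0))
      ev <- eigen(cc$P, symmetric = TRUE, only.values = TRUE)$values
      expect_true(all(ev >= -1e-9))
    }
  })
})

test_that("filter cadence: one update per online row, two predicts between", {
  sched <- fixture("short_schedule")
  times <- seq(0, 20, by = 120 / 3600)
  truth <- simulateProcess(defaultInitialState(), cgmParameters(), sched,
                           times)
  ds <- datasetFromTruth(truth, sched,
                         meas_sd = c(0.2, 0.05, 0.1, 0.05, 0.01),
                         seed = 60)
  ds$online <- ds$online[1:21, ]
  cfg <- ukfConfig(x0 = defaultInitialState(), Q = rep(1e-6, 10),
                   R = c(0.04, 0.0025, 0.01, 0.0025, 1e-4))
  res <- runFilter(ds, models = NULL, cfg, cgmParameters(), sched,
                   defaultInitialState(),
                   measurements = ds$measurements[1:21, ])
  expect_identical(res$n_updates, 21L)
  expect_identical(res$n_predicts, 2L * 20L)
})

test_that("with overwhelming measurement noise the filter is the open-loop model", {
  sched <- fixture("short_schedule")
  times <- seq(0, 20, by = 120 / 3600)
  params <- cgmParameters(); x0 <- defaultInitialState()
  truth <- simulateProcess(x0, params, sched, times)
  ds <- datasetFromTruth(truth, sched,
                         meas_sd = c(0.2, 0.05, 0.1, 0.05, 0.01),
                         seed = 61)
  cfg <- ukfConfig(x0 = x0, Q = rep(0, 10), R = rep(1e12, 5),
                   P0 = diag(1e-16, 10), constrain = FALSE)
  res <- runFilter(ds, models = NULL, cfg, params, sched, x0,
                   measurements = ds$measurements)
  # reference: the transition model stepped deterministically at the
  # same cadence (and the same time bookkeeping), without any filter
  # machinery
  x <- matrix(as.numeric(x0), nrow = 10)
  path <- matrix(NA_real_, length(times), 10)
  path[1, ] <- x
  dt_h <- cfg$dt_predict / 3600
  for (i in seq_len(length(times) - 1)) {
    t_cur <- times[i]
    for (s in 1:2) {
      x <- phesensor:::propagateCGM(x, t_cur, dt_h, cfg$nsub, params,
                                    sched)
      t_cur <- t_cur + dt_h
    }
    path[i + 1, ] <- x
  }
  expect_lt(max(abs(res$x_post - path)), 1e-5)
  # and no gross divergence from the stiff reference either
  drift <- abs(res$x_post[, measuredStates] - measureStates(truth))
  expect_lt(max(drift), 0.5)
})

test_that("measurement feedback corrects a perturbed initial biomass", {
  sched <- fixture("short_schedule")
  times <- seq(0, 20, by = 120 / 3600)
  params <- cgmParameters(); x0 <- defaultInitialState()
  truth <- simulateProcess(x0, params, sched, times)
  ds <- datasetFromTruth(truth, sched,
                         meas_sd = c(0.1, 0.02, 0.05, 0.02, 0.005),
                         seed = 62)
  x0_bad <- x0; x0_bad[["X"]] <- 1.3 * x0[["X"]]
  cfg <- ukfConfig(x0 = x0_bad, Q = rep(1e-6, 10),
                   R = c(0.1, 0.02, 0.05, 0.02, 0.005)^2)
  res <- runFilter(ds, models = NULL, cfg, params, sched, x0_bad,
                   measurements = ds$measurements)
  open <- simulateProcess(x0_bad, params, sched, times)
  tru_X <- truth$states[, "X"]
  rmse_ukf <- sqrt(mean((res$x_post[, "X"] - tru_X)^2))
  rmse_open <- sqrt(mean((open$states[, "X"] - tru_X)^2))
  expect_lt(rmse_ukf, rmse_open)
})

test_that("filter configuration validates cadence and builds default P0", {
  x0 <- defaultInitialState()
  expect_error(ukfConfig(x0, Q = rep(1e-6, 10), R = rep(1, 5),
                         dt_predict = 70), "multiple")
  cfg <- ukfConfig(x0, Q = rep(1e-6, 10), R = rep(1, 5))
  d <- diag(cfg$P0)
  expect_equal(d[2], 10 * (0.1 * x0[["S"]])^2)  # inflated glycerol entry
  expect_equal(d[3], max((0.1 * x0[["X"]])^2, 1e-6))
  expect_true(all(diag(cfg$Q) == 1e-6))
})
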