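test_that("phase-offset centering subtracts the phase start and inverts", {
  X <- matrix(c(1, 3, 2, 4), nrow = 2)  # rows [1,2], [3,4]
  ctr <- phaseOffsetCenter(X, n_ref = 1)
  expect_equal(ctr$Xc, matrix(c(0, 2, 0, 2), nrow = 2))
  expect_equal(unname(ctr$x0_ref), c(1, 2))
  # first centered row is exactly zero; adding the reference reconstructs
  expect_equal(unname(ctr$Xc[1, ]), c(0, 0))
  expect_equal(sweep(ctr$Xc, 2, ctr$x0_ref, "+"), X)
  expect_error(phaseOffsetCenter(X[1, , drop = FALSE]), "2 rows")
})

test_that("training outputs interpolate the trajectory exactly and stay bracketed", {
  tr <- fixture("ref")$truth
  # trajectory knots reproduce exactly
  knots <- tr$times[c(10, 500, 1800)]
  expect_equal(buildTrainingOutputs(tr, knots),
               measureStates(tr)[c(10, 500, 1800), ])
  # midpoint linearity on a hand-made two-knot trajectory
  toy <- tr
  toy$times <- c(0, 1)
  toy$states <- rbind(toy$states[1, ], toy$states[1, ])
  toy$states[, "P"] <- c(0, 2)
  expect_equal(unname(buildTrainingOutputs(toy, 0.5)[, "P"]), 1)
  # random query times lie within the bracketing knot envelope
  withr::with_seed(42, {
    tq <- runif(200, min(tr$times), max(tr$times))
    Yq <- buildTrainingOutputs(tr, tq)
    idx <- findInterval(tq, tr$times)
    Y <- measureStates(tr)
    lo <- pmin(Y[idx, ], Y[idx + 1, ]); hi <- pmax(Y[idx, ], Y[idx + 1, ])
    expect_true(all(Yq >= lo - 1e-12 & Yq <= hi + 1e-12))
  })
  expect_error(buildTrainingOutputs(tr, max(tr$times) + 1),
               "extrapolation")
})

test_that("SIMPLS recovers exact linear relations and matches OLS at full rank", {
  # single input, y = 2x: coefficient 2, zero residual, x=5 -> 10
  x <- matrix(seq(0, 5, by = 0.5))
  y <- 2 * x
  fit <- simplsFit(x, y, 1)
  expect_equal(drop(fit$coef), 2, tolerance = 1e-12)
  expect_equal(fit$rmse_train, 0, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(drop(predict(fit, matrix(5))), 10, tolerance = 1e-10)

  # full-rank problems: 8 LVs == normal-equations OLS solution
  withr::with_seed(7, {
    for (rep in 1:5) {
      X <- matrix(rnorm(50 * 8), 50)
      Y <- matrix(rnorm(50 * 5), 50)
      f8 <- simplsFit(X, Y, 8)
      Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
      B_ols <- solve(crossprod(Xc), crossprod(Xc, Yc))
      expect_lt(max(abs(f8$coef - B_ols)), 1e-8)
    }
  })
})

test_that("SIMPLS scores are orthogonal and residuals shrink with more LVs", {
  withr::with_seed(11, {
    X <- matrix(rnorm(30 * 8), 30)
    Y <- matrix(rnorm(30 * 5), 30)
    prev <- Inf
    for (a in 1:8) {
      fit <- simplsFit(X, Y, a)
      G <- crossprod(fit$scores)
      expect_lt(max(abs(G - diag(diag(G), a))), 1e-8)
      rn <- sqrt(sum(fit$rmse_train^2))
      expect_lte(rn, prev + 1e-12)
      prev <- rn
    }
  })
  # requesting more components than the rank supports fails informatively
  Xr <- cbind(1:10, 2 * (1:10), rnorm(10))
  expect_error(simplsFit(Xr, matrix(rnorm(10)), 3), "maximum")
})

test_that("prediction is self-consistent and validates input shape", {
  withr::with_seed(3, {
    X <- matrix(rnorm(40 * 8), 40)
    Y <- matrix(rnorm(40 * 5), 40)
  })
  fit <- simplsFit(X, Y, 4)
  Yhat <- sweep(X, 2, fit$x_mean) %*% fit$coef +
    rep(1, 40) %o% fit$y_mean
  expect_equal(predict(fit, X), Yhat, tolerance = 1e-12)
  expect_error(predict(fit, X[, 1:5]), "input columns")
})

test_that("offset centering absorbs constant shifts present at the phase start", {
  # shifting an input channel by a constant (as between two processes
  # with different absolute sensor levels) must not change predictions
  withr::with_seed(13, {
    X <- matrix(rnorm(60 * 8), 60)
    Y <- X %*% matrix(rnorm(8 * 5), 8) + 0.01 * matrix(rnorm(60 * 5), 60)
  })
  ctr <- phaseOffsetCenter(X, n_ref = 1)
  fit <- simplsFit(ctr$Xc, Y, 4)
  X_shift <- sweep(X, 2, c(100, -5, 3, 0, 0, 1, 0, 42), "+")
  ctr2 <- phaseOffsetCenter(X_shift, n_ref = 1)
  expect_equal(predict(fit, ctr2$Xc), predict(fit, ctr$Xc),
               tolerance = 1e-9)
})

test_that("RMSECV fold construction and LV selection behave", {
  # noiseless rank-2 latent structure: 2 LVs chosen (first minimum)
  hits <- 0L
  for (s in 1:10) {
    withr::with_seed(100 + s, {
      TT <- matrix(rnorm(80 * 2), 80)
      X <- TT %*% matrix(rnorm(2 * 8), 2)
      Y <- TT %*% matrix(rnorm(2 * 5), 2)
    })
    cv <- crossvalidateLV(X, Y, max_lv = 6, k = 5, seed = s)
    if (cv$chosen_lv == 2L) hits <- hits + 1L
  }
  expect_gte(hits, 9L)

  cv <- crossvalidateLV(X, Y, max_lv = 6, k = 5, seed = 1)
  # the chosen count minimizes the aggregate RMSECV up to the near-tie
  # parsimony tolerance
  expect_true(all(cv$aggregate[cv$chosen_lv] <= 1.01 * cv$aggregate))
  # contiguous blocks whose sizes differ by at most one
  sizes <- table(cv$fold_id)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_true(all(diff(cv$fold_id) >= 0))
  expect_error(crossvalidateLV(X[1:3, ], Y[1:3, ], k = 5), "folds")
})

test_that("per-output RMSE matches a brute-force loop", {
  expect_equal(unname(rmsePerOutput(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_equal(unname(rmsePerOutput(c(0, 0), c(3, 4))), sqrt(12.5))
  withr::with_seed(5, {
    A <- matrix(rnorm(20 * 5), 20); B <- matrix(rnorm(20 * 5), 20)
  })
  loop <- vapply(1:5, function(j) {
    s <- 0
    for (i in 1:20) s <- s + (A[i, j] - B[i, j])^2
    sqrt(s / 20)
  }, numeric(1))
  expect_equal(unname(rmsePerOutput(A, B)), loop, tolerance = 1e-12)
  expect_error(rmsePerOutput(A, B[1:10, ]), "dimension")
})
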