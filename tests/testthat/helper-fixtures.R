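# Shared fixtures, computed lazily and cached for the whole test run.
# Everything is generated in code; seeds are fixed so all tests are
# reproducible.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!exists(name, envir = .fixture_cache)) {
    val <- switch(
      name,
      params = cgmParameters(),
      x0 = defaultInitialState(),
      # reference process (0.3 mM IPTG), full 70 h study horizon
      ref = makeScenario("reference_high_iptg", seed = 1),
      # calibration / test processes (0.01 mM IPTG, boosted production)
      cal = makeScenario("low_iptg_A", seed = 2),
      training = trainPLSR(fixture("ref"), seed = 1),
      # short three-phase run for cheap filter tests
      short_schedule = feedSchedule(t_batch_end = 15.65,
                                    t_induction = 36.65, t_end = 45),
      stop("unknown fixture: ", name))
    assign(name, val, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# textbook linear Kalman filter (independent oracle for the UKF)
kfStep <- function(x, P, A, Q, H, R, y) {
  xp <- drop(A %*% x)
  Pp <- A %*% P %*% t(A) + Q
  S <- H %*% Pp %*% t(H) + R
  K <- t(solve(S, H %*% t(Pp)))
  innov <- y - drop(H %*% xp)
  list(x_prior = xp, P_prior = Pp,
       x = xp + drop(K %*% innov),
       P = Pp - K %*% S %*% t(K))
}

# random symmetric PSD matrix
randomPSD <- function(n, scale = 1) {
  A <- matrix(stats::rnorm(n * n), n)
  scale * crossprod(A) / n + 1e-6 * diag(n)
}

# dataset wrapper around an arbitrary truth trajectory, with direct
# (noisy-truth) measurements instead of PLSR outputs
datasetFromTruth <- function(truth, schedule, meas_sd, seed,
                             n_per_phase = NULL, noise_cv = 0.02) {
  if (is.null(n_per_phase)) {
    present <- tabulate(truth$phase, 3) > 1
    n_per_phase <- ifelse(present, c(3, 6, 3), 0)
  }
  offline <- sampleOffline(truth, schedule, n_per_phase = n_per_phase,
                           noise_cv = noise_cv, seed = seed + 500L)
  meas <- withr::with_seed(seed + 900L, {
    tru <- measureStates(truth)
    tru + matrix(stats::rnorm(length(tru)), nrow = nrow(tru)) %*%
      diag(meas_sd)
  })
  colnames(meas) <- measuredStates
  structure(list(online = data.frame(time_h = truth$times,
                                     phase = truth$phase),
                 offline = offline, schedule = schedule, truth = truth,
                 measurements = meas, name = "synthetic_direct",
                 seed = seed),
            class = "process_dataset")
}
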