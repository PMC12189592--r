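#' Observation-model parameters for synthetic online signals
#'
#' The state-to-sensor map that turns a simulated trajectory into the
#' eight routine online channels. It is deliberately simple but preserves
#' the correlation structure a real stirred-tank run shows: CO2, stirrer
#' and aeration track oxygen demand (growth-dominated), cumulative base
#' tracks growth-linked ammonia plus L-phe (weakly, it is an ampholyte)
#' plus acetate (strongly), pH and temperature are controlled setpoints
#' carrying almost no information.
#'
#' @param c_mu,c_f,c_m CO2-evolution coefficients: per growth \[g/g\], per
#'   product flux \[g/g\] and maintenance \[1/h\].
#' @param k_stirrer stirrer cascade gain \[rpm per OUR unit\];
#'   `stirrer_range` \[rpm\] and `aeration_range` \[L/min\] bound the
#'   cascade (stirrer first, then aeration).
#' @param k_aeration aeration cascade gain.
#' @param k_o2 oxygen-demand coefficient of the pO2 map; `po2_setpoint`
#'   is the controller floor \[%\].
#' @param k_co2,co2_baseline off-gas CO2 map \[%\].
#' @param rho_feed2,rho_feed3 feed densities \[g/L\] for the mass-flow
#'   channel.
#' @param a1_ml_g base demand per biomass formed; `a2_ml_g` per g L-phe;
#'   `a3_ml_g` per g acetate (a3 >> a2).
#' @param sd named vector of additive noise standard deviations per
#'   channel; pH and temperature use AR(1) noise with coefficient
#'   `ar_rho`.
#' @return List of class `observation_params`.
#' @export
observationParams <- function(c_mu = 1.0, c_f = 0.3, c_m = 0.05,
                              k_stirrer = 250,
                              stirrer_range = c(300, 1200),
                              k_aeration = 1.5,
                              aeration_range = c(0.5, 5),
                              k_o2 = 110, po2_setpoint = 40,
                              k_co2 = 0.5, co2_baseline = 0.04,
                              rho_feed2 = 1078, rho_feed3 = 1200,
                              a1_ml_g = 1.2, a2_ml_g = 0.4,
                              a3_ml_g = 4,
                              sd = c(stirrer_rpm = 5, aeration_l_min = 0.02,
                                     po2_pct = 0.7, temp_c = 0.05,
                                     ph = 0.01, co2_offgas_pct = 0.02,
                                     feed_massflow_g_h = 0.5,
                                     base_cumulative_ml = 0.3),
                              ar_rho = 0.9) {
  if (!(a3_ml_g > a2_ml_g && a2_ml_g > 0))
    stop("observationParams: need a3 > a2 > 0")
  if (any(sd < 0)) stop("observationParams: noise sds must be >= 0")
  structure(list(c_mu = c_mu, c_f = c_f, c_m = c_m,
                 k_stirrer = k_stirrer, stirrer_range = stirrer_range,
                 k_aeration = k_aeration, aeration_range = aeration_range,
                 k_o2 = k_o2, po2_setpoint = po2_setpoint, k_co2 = k_co2,
                 co2_baseline = co2_baseline, rho_feed2 = rho_feed2,
                 rho_feed3 = rho_feed3, a1 = a1_ml_g, a2 = a2_ml_g,
                 a3 = a3_ml_g, sd = sd, ar_rho = ar_rho),
            class = "observation_params")
}

# seeded AR(1) noise series (stationary start)
ar1Noise <- function(n, sd, rho) {
  if (sd == 0) return(rep(0, n))
  e <- stats::rnorm(n, sd = sd * sqrt(1 - rho^2))
  as.numeric(stats::filter(e, rho, method = "recursive",
                           init = stats::rnorm(1, sd = sd)))
}

#' Generate the eight online channels from a simulated trajectory
#'
#' Deterministic given the seed. The trajectory must already be on the
#' desired online cadence (120 s in the study layout).
#'
#' @param traj a `cgm_trajectory` on the online time grid.
#' @param obs an [observationParams()].
#' @param seed integer seed for all channel noise.
#' @return Data frame: `time_h`, the eight channels ([onlineChannels]),
#'   `phase`.
#' @export
generateOnlineSignals <- function(traj, obs, seed = 1) {
  if (length(traj$times) < 2)
    stop("generateOnlineSignals: trajectory too short")
  st <- traj$states
  mu <- traj$rates[, "mu"]; v_F <- traj$rates[, "v_F"]
  XV <- st[, "X"] * st[, "V"]
  tms <- traj$times

  our <- (obs$c_mu * mu + obs$c_f * v_F + obs$c_m * (st[, "X"] > 0)) * XV
  stirrer0 <- pmin(pmax(obs$stirrer_range[1] + obs$k_stirrer * our,
                        obs$stirrer_range[1]), obs$stirrer_range[2])
  our_sat <- diff(obs$stirrer_range) / obs$k_stirrer
  aeration0 <- pmin(pmax(obs$aeration_range[1] +
                           obs$k_aeration * pmax(0, our - our_sat),
                         obs$aeration_range[1]), obs$aeration_range[2])
  kla_rel <- (stirrer0 / obs$stirrer_range[1])^1.4 *
    (aeration0 / obs$aeration_range[1])^0.5
  po2_0 <- pmax(100 - obs$k_o2 * our / kla_rel, obs$po2_setpoint - 2)
  co2_0 <- obs$co2_baseline + obs$k_co2 * our / aeration0

  rho <- ifelse(traj$phase == 3L, obs$rho_feed3,
                ifelse(traj$phase == 2L, obs$rho_feed2, 0))
  feed0 <- traj$feed_rate * rho

  # cumulative base: growth ammonia (integral) + L-phe + acetate terms
  grown <- c(0, cumsum(diff(tms) *
                         (utils::head(mu * XV, -1) +
                            utils::tail(mu * XV, -1)) / 2))
  base0 <- obs$a1 * grown + obs$a2 * st[, "P"] * st[, "V"] +
    obs$a3 * st[, "A"] * st[, "V"]

  withr::with_seed(seed, {
    n <- length(tms)
    sdv <- obs$sd
    online <- data.frame(
      time_h = tms,
      stirrer_rpm = stirrer0 + stats::rnorm(n, sd = sdv[["stirrer_rpm"]]),
      aeration_l_min = aeration0 +
        stats::rnorm(n, sd = sdv[["aeration_l_min"]]),
      po2_pct = po2_0 + stats::rnorm(n, sd = sdv[["po2_pct"]]),
      temp_c = 37 + ar1Noise(n, sdv[["temp_c"]], obs$ar_rho),
      ph = 7 + ar1Noise(n, sdv[["ph"]], obs$ar_rho),
      co2_offgas_pct = co2_0 +
        stats::rnorm(n, sd = sdv[["co2_offgas_pct"]]),
      feed_massflow_g_h = feed0 +
        stats::rnorm(n, sd = sdv[["feed_massflow_g_h"]]),
      base_cumulative_ml = base0 +
        stats::rnorm(n, sd = sdv[["base_cumulative_ml"]]),
      phase = traj$phase)
  })
  online
}

#' Sparse offline samples with measurement noise
#'
#' Emulates manual sampling plus HPLC/gravimetric analytics: per-phase
#' sample counts at jittered regular times (none in the batch phase by
#' default, matching the study's sampling gap), multiplicative lognormal
#' noise with the requested coefficient of variation plus a small
#' additive floor, clipped at zero. `noise_cv = 0` returns the
#' interpolated truth exactly.
#'
#' @param traj a `cgm_trajectory` (the truth).
#' @param schedule the [feedSchedule()] defining the phases.
#' @param n_per_phase integer 3-vector of samples per phase.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @param floor_sd additive noise floor per output \[g/L\] (scaled to zero
#'   when `noise_cv = 0`).
#' @return Data frame: `time_h`, `X`, `S`, `P`, `A`, `Y`, `phase`.
#' @export
sampleOffline <- function(traj, schedule, n_per_phase = c(0, 6, 8),
                          noise_cv = 0.05, seed = 1,
                          floor_sd = c(X = 0.05, S = 0.01, P = 0.05,
                                       A = 0.01, Y = 0.002)) {
  if (any(n_per_phase < 0)) stop("sampleOffline: negative sample count")
  t0 <- min(traj$times); t1 <- max(traj$times)
  bounds <- c(t0, schedule$t_batch_end, schedule$t_induction, t1)

  withr::with_seed(seed, {
    times <- unlist(lapply(1:3, function(ph) {
      np <- n_per_phase[ph]
      if (np == 0) return(numeric(0))
      lo <- bounds[ph]; hi <- min(bounds[ph + 1], t1)
      if (lo >= t1)
        stop("sampleOffline: phase ", ph,
             " samples requested outside the trajectory span")
      grid <- seq(lo, hi, length.out = np + 2)[-c(1, np + 2)]
      jit <- stats::runif(np, -0.2, 0.2) * (hi - lo) / (np + 1)
      pmin(pmax(grid + jit, lo + 1e-6), hi - 1e-6)
    }))
    truth <- interpMeasured(traj, times)
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      fac <- matrix(stats::rlnorm(length(truth), meanlog = -sdlog^2 / 2,
                                  sdlog = sdlog), nrow = nrow(truth))
      add <- matrix(stats::rnorm(length(truth)), nrow = nrow(truth)) *
        rep(floor_sd[measuredStates], each = nrow(truth))
      vals <- pmax(truth * fac + add, 0)
    } else {
      vals <- truth
    }
  })
  out <- data.frame(time_h = times, vals)
  names(out) <- c("time_h", measuredStates)
  out$phase <- activePhase(times, schedule)
  out
}

#' Simulate the process with additive discrete-time process noise
#'
#' Steps the coarse-grained model between consecutive grid points
#' (fixed-step RK4) and adds zero-mean Gaussian noise with covariance
#' `diag(q_diag)` after each step, clipping states at zero. This is the
#' generating model the filter assumes (additive process noise at the
#' transition), used to study noise-covariance calibration and filter
#' consistency. The glycerol bookkeeping integrals are trapezoid
#' approximations here, not solver-grade.
#'
#' @param x0 initial state.
#' @param params,schedule model parameterization and feed schedule.
#' @param times strictly increasing grid \[h\].
#' @param q_diag 10-vector of per-step noise variances.
#' @param seed integer seed.
#' @param nsub RK4 substeps per grid interval.
#' @return A `cgm_trajectory`.
#' @export
simulateNoisyProcess <- function(x0, params, schedule, times, q_diag,
                                 seed = 1, nsub = 6) {
  if (is.unsorted(times, strictly = TRUE))
    stop("simulateNoisyProcess: times must be strictly increasing")
  sdv <- sqrt(q_diag)
  st <- matrix(NA_real_, length(times), 10,
               dimnames = list(NULL, stateNames))
  st[1, ] <- x0
  withr::with_seed(seed, {
    x <- matrix(as.numeric(x0), nrow = 10)
    for (i in seq_len(length(times) - 1)) {
      x <- propagateCGM(x, times[i], times[i + 1] - times[i], nsub,
                        params, schedule)
      x <- pmax(x + stats::rnorm(10, sd = sdv), 0)
      x[1] <- max(x[1], 1e-6)
      st[i + 1, ] <- x
    }
  })
  rts <- t(vapply(seq_along(times), function(i)
    unlist(reactionRates(stats::setNames(st[i, ], stateNames), params,
                         iptgAt(times[i], schedule))), numeric(6)))
  fr <- vapply(seq_along(times), function(i)
    feedRate(times[i], stats::setNames(st[i, ], stateNames), params,
             schedule), numeric(1))
  vTXV <- rts[, "v_T"] * st[, "X"] * st[, "V"]
  fS <- fr * vapply(activePhase(times, schedule), function(ph)
    feedConcentrations(ph, schedule)[["S"]], numeric(1))
  cumtrap <- function(v) c(0, cumsum(diff(times) *
                                       (utils::head(v, -1) +
                                          utils::tail(v, -1)) / 2))
  structure(list(times = times, states = st, rates = rts,
                 phase = activePhase(times, schedule), feed_rate = fr,
                 fed_glycerol_g = cumtrap(fS),
                 uptake_glycerol_g = cumtrap(vTXV),
                 params = params, schedule = schedule),
            class = "cgm_trajectory")
}

#' Build a complete synthetic process dataset
#'
#' The three named scenarios mirror the study design: one reference
#' process induced with 0.3 mM IPTG and two processes induced with
#' 0.01 mM, which showed the *higher* product titer. Since the
#' coarse-grained model cannot explain that phenotype mechanistically,
#' the low-IPTG truths apply a phenomenological production override: the
#' production-phase specific feed rate (and with it the carbon-limited
#' production rate) is multiplied by `production_boost`. All scenarios
#' share the phase-1 settings; only seeds and induction differ. The batch
#' end is detected on the truth run as glycerol dropping below 0.01 g/L
#' (a stand-in for the pO2 spike used at the real reactor), and induction
#' follows 21 h of biomass production.
#'
#' @param name one of `"reference_high_iptg"`, `"low_iptg_A"`,
#'   `"low_iptg_B"`.
#' @param seed integer seed driving all noise in the dataset.
#' @param t_end process horizon \[h\].
#' @param params nominal model parameters ([cgmParameters()]).
#' @param obs observation model ([observationParams()]).
#' @param x0 initial state.
#' @param production_boost multiplier applied to the truth's `q_feed3` in
#'   the low-IPTG scenarios.
#' @param n_per_phase,noise_cv offline sampling layout (see
#'   [sampleOffline()]).
#' @param cadence_s online cadence \[s\].
#' @return Object of class `process_dataset`: `online`, `offline`,
#'   `schedule`, `truth` (a `cgm_trajectory`), `params_true`,
#'   `params_nominal`, `x0`, `name`, `seed`.
#' @export
makeScenario <- function(name = c("reference_high_iptg", "low_iptg_A",
                                  "low_iptg_B"),
                         seed = 1, t_end = 70,
                         params = cgmParameters(),
                         obs = observationParams(),
                         x0 = defaultInitialState(),
                         production_boost = 1.5,
                         n_per_phase = c(0, 6, 8), noise_cv = 0.05,
                         cadence_s = 120) {
  name <- match.arg(name)
  low <- name != "reference_high_iptg"
  params_true <- params
  if (low) params_true$q_feed3 <- params$q_feed3 * production_boost
  iptg <- if (low) 0.01 else 0.3

  # batch-end detection on a feed-free probe run of the truth model
  probe_sched <- feedSchedule(t_batch_end = t_end, t_induction = t_end + 1,
                              t_end = t_end + 2, iptg_mM = iptg)
  probe <- simulateProcess(x0, params_true, probe_sched,
                           seq(0, 30, by = 0.05))
  idx <- which(probe$states[, "S"] < 0.01)[1]
  if (is.na(idx))
    stop("makeScenario: glycerol not depleted within 30 h; ",
         "check the parameterization")
  t_batch_end <- probe$times[idx]
  schedule <- feedSchedule(t_batch_end = t_batch_end,
                           t_induction = t_batch_end + 21,
                           t_end = t_end, iptg_mM = iptg)

  times <- seq(0, t_end, by = cadence_s / 3600)
  truth <- simulateProcess(x0, params_true, schedule, times)
  online <- generateOnlineSignals(truth, obs, seed = seed * 13L + 1L)
  offline <- sampleOffline(truth, schedule, n_per_phase = n_per_phase,
                           noise_cv = noise_cv, seed = seed * 13L + 2L)
  structure(list(online = online, offline = offline, schedule = schedule,
                 truth = truth, params_true = params_true,
                 params_nominal = params, x0 = x0, name = name,
                 seed = seed),
            class = "process_dataset")
}

#' @export
print.process_dataset <- function(x, ...) {
  cat("<process_dataset> ", x$name, " (seed ", x$seed, ")\n", sep = "")
  cat("  online: ", nrow(x$online), " rows x 8 channels; offline: ",
      nrow(x$offline), " samples; phases at ",
      signif(x$schedule$t_batch_end, 4), " / ",
      signif(x$schedule$t_induction, 4), " h\n", sep = "")
  invisible(x)
}

#' Write / read a process dataset as a plain-text directory
#'
#' `online.csv`, `offline.csv`, `truth.csv` (optional), `schedule.json`
#' and `manifest.json`.
#'
#' @param dataset a `process_dataset`.
#' @param dir directory path.
#' @param truth include the ground-truth trajectory.
#' @return `writeProcessDataset` returns `dir` invisibly;
#'   `readProcessDataset` the reassembled `process_dataset` (without
#'   model parameter objects, which live in the model config).
#' @export
writeProcessDataset <- function(dataset, dir, truth = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$online, file.path(dir, "online.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$offline, file.path(dir, "offline.csv"),
                   row.names = FALSE)
  s <- dataset$schedule
  jsonlite::write_json(
    list(t_batch_end_h = s$t_batch_end, t_induction_h = s$t_induction,
         t_end_h = s$t_end, S_feed2_g_l = s$S_feed2,
         S_feed3_g_l = s$S_feed3, P_feed2_g_l = s$P_feed2,
         Y_feed2_g_l = s$Y_feed2, iptg_mM = s$iptg),
    file.path(dir, "schedule.json"), auto_unbox = TRUE, digits = NA)
  if (truth && !is.null(dataset$truth)) {
    tr <- data.frame(time_h = dataset$truth$times, dataset$truth$states,
                     dataset$truth$rates, phase = dataset$truth$phase)
    utils::write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  jsonlite::write_json(list(name = dataset$name, seed = dataset$seed,
                            cadence_s = round(diff(dataset$online$time_h[1:2])
                                              * 3600)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname writeProcessDataset
#' @export
readProcessDataset <- function(dir) {
  s <- jsonlite::read_json(file.path(dir, "schedule.json"),
                           simplifyVector = TRUE)
  schedule <- feedSchedule(t_batch_end = s$t_batch_end_h,
                           t_induction = s$t_induction_h,
                           t_end = s$t_end_h, S_feed2 = s$S_feed2_g_l,
                           S_feed3 = s$S_feed3_g_l,
                           P_feed2 = s$P_feed2_g_l,
                           Y_feed2 = s$Y_feed2_g_l, iptg_mM = s$iptg_mM)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  out <- list(online = utils::read.csv(file.path(dir, "online.csv")),
              offline = utils::read.csv(file.path(dir, "offline.csv")),
              schedule = schedule, truth = NULL, name = man$name,
              seed = man$seed)
  tp <- file.path(dir, "truth.csv")
  if (file.exists(tp)) out$truth_table <- utils::read.csv(tp)
  class(out) <- "process_dataset"
  out
}
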