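#' Train the three phase PLS models on a reference process
#'
#' Splits the online table by phase, builds the training outputs by
#' interpolating the process-model trajectory onto the online time
#' stamps (offline samples are far too sparse to train on directly), and
#' fits one SIMPLS model per phase with five-fold RMSECV latent-variable
#' selection.
#'
#' @param dataset a `process_dataset` whose `truth` trajectory plays the
#'   role of the fitted process model of the reference run.
#' @param max_lv,k,seed,folds,n_ref see [fitPhaseModel()].
#' @return List of class `plsr_training`: `models` (three
#'   `phase_pls_model`s), `cv` (per-phase `cv_report`s), `rmse_train`
#'   (3 x 5 matrix), `chosen_lv` (3-vector).
#' @export
trainPLSR <- function(dataset, max_lv = 8, k = 5, seed = 1,
                      folds = "blocks", n_ref = 3) {
  if (is.null(dataset$truth))
    stop("trainPLSR: dataset carries no truth trajectory to train against")
  online <- dataset$online
  phases <- sort(unique(online$phase))
  if (!identical(as.integer(phases), 1:3))
    stop("trainPLSR: dataset must contain all three phases; missing ",
         paste(setdiff(1:3, phases), collapse = ", "))
  Y_all <- buildTrainingOutputs(dataset$truth, online$time_h)
  models <- lapply(1:3, function(ph) {
    idx <- which(online$phase == ph)
    if (length(idx) <= k)
      stop("trainPLSR: phase ", ph, " too short for ", k, "-fold CV")
    fitPhaseModel(as.matrix(online[idx, onlineChannels]),
                  Y_all[idx, , drop = FALSE], phase = ph,
                  max_lv = max_lv, k = k, seed = seed, folds = folds,
                  n_ref = n_ref)
  })
  rmse_train <- do.call(rbind, lapply(models, function(m) m$rmse_train))
  rownames(rmse_train) <- paste0("phase", 1:3)
  structure(list(models = models,
                 cv = lapply(models, function(m) m$cv),
                 rmse_train = rmse_train,
                 chosen_lv = vapply(models, function(m) m$n_lv,
                                    integer(1))),
            class = "plsr_training")
}

#' @export
print.plsr_training <- function(x, ...) {
  cat("<plsr_training> latent variables per phase:",
      paste(x$chosen_lv, collapse = "/"), "\n")
  print(signif(x$rmse_train, 3))
  invisible(x)
}

#' Open-loop trajectory of the filter's nominal model
#'
#' Simulates the nominal parameterization from the filter's initial
#' state over the dataset's online grid — the pure model-based estimate
#' the hybrid filter is compared against.
#'
#' @param dataset a `process_dataset`.
#' @param params,x0 nominal parameterization and initial state.
#' @param atol,rtol integrator tolerances.
#' @return A `cgm_trajectory`.
#' @export
openLoopTrajectory <- function(dataset, params, x0, atol = 1e-8,
                               rtol = 1e-8) {
  simulateProcess(x0, params, dataset$schedule, dataset$online$time_h,
                  atol = atol, rtol = rtol)
}

#' Per-state RMSE of an estimate against offline samples
#'
#' Estimates are linearly interpolated to the offline sampling times.
#'
#' @param est a `filter_result`, `cgm_trajectory`, or a data frame with
#'   `time_h` plus the five measured-state columns.
#' @param offline offline table (`time_h` + [measuredStates]).
#' @return Named 5-vector of RMSEs \[g/L\].
#' @export
evaluateEstimates <- function(est, offline) {
  if (nrow(offline) == 0) stop("evaluateEstimates: offline table empty")
  if (inherits(est, "filter_result")) {
    tms <- est$times; Y <- est$x_post[, measuredStates, drop = FALSE]
  } else if (inherits(est, "cgm_trajectory")) {
    tms <- est$times; Y <- measureStates(est)
  } else {
    tms <- est$time_h; Y <- as.matrix(est[, measuredStates])
  }
  keep <- offline$time_h >= min(tms) & offline$time_h <= max(tms)
  if (!any(keep))
    stop("evaluateEstimates: no overlap between estimates and samples")
  off <- offline[keep, , drop = FALSE]
  pred <- vapply(measuredStates, function(cn)
    stats::approx(tms, Y[, cn], xout = off$time_h)$y,
    numeric(nrow(off)))
  rmsePerOutput(matrix(pred, ncol = 5, dimnames = list(NULL, measuredStates)),
                as.matrix(off[, measuredStates]))
}

#' Side-by-side evaluation of the hybrid filter and the open-loop model
#'
#' @param result a `filter_result`.
#' @param openloop the matching open-loop `cgm_trajectory`.
#' @param offline offline samples of the evaluated process.
#' @param path optional CSV output path.
#' @return Data frame with columns `state`, `cgm_rmse`, `ukf_rmse`
#'   (5 rows, \[g/L\]).
#' @export
evaluateRun <- function(result, openloop, offline, path = NULL) {
  tab <- data.frame(state = measuredStates,
                    cgm_rmse = as.numeric(evaluateEstimates(openloop,
                                                            offline)),
                    ukf_rmse = as.numeric(evaluateEstimates(result,
                                                            offline)))
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  tab
}

#' Run the complete three-process soft-sensor study on synthetic data
#'
#' Mirrors the study workflow end to end: (1) simulate the reference
#' process and train the phase PLS models on it; (2) run PLSR on the
#' calibration process, build `R` from its offline RMSEs and calibrate
#' the `Q` diagonal by pattern search; (3) run the hybrid filter on the
#' held-out test process and compare per-state RMSEs against the
#' open-loop model. All artifacts are written as plain-text files; the
#' run is deterministic given `seed`.
#'
#' @param dir output directory.
#' @param seed master seed (scenario seeds are derived from it).
#' @param t_end process horizon \[h\].
#' @param q_budget evaluation budget of the Q calibration.
#' @param q_groups search-dial grouping for [estimateQ()]; the default
#'   ties the six reactor states and the four intracellular states to two
#'   shared dials, keeping the demo affordable.
#' @param quiet suppress progress messages.
#' @return List of class `demo_result`: `tables` (evaluation data
#'   frames), `training`, `noise`, `files` (paths written).
#' @export
runDemo <- function(dir, seed = 1, t_end = 70, q_budget = 40,
                    q_groups = c(1, 1, 1, 1, 1, 1, 2, 2, 2, 2),
                    quiet = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  params <- cgmParameters()
  x0 <- defaultInitialState()

  say("simulating the three processes ...")
  ref <- makeScenario("reference_high_iptg", seed = seed, t_end = t_end)
  cal <- makeScenario("low_iptg_A", seed = seed + 1, t_end = t_end)
  tst <- makeScenario("low_iptg_B", seed = seed + 2, t_end = t_end)

  say("training phase PLS models on the reference process ...")
  training <- trainPLSR(ref, seed = seed)

  say("calibrating R and Q on the calibration process ...")
  yhat_cal <- predictOnline(training$models, cal$online)
  est_cal <- data.frame(time_h = cal$online$time_h, yhat_cal)
  rmse_cal <- evaluateEstimates(est_cal, cal$offline)
  R <- buildR(rmse_cal)
  config <- ukfConfig(x0 = x0, Q = rep(1e-4, 10), R = R)
  calib <- estimateQ(cal, training$models, config, params, cal$schedule,
                     x0, q_init = rep(1e-4, 10), budget = q_budget,
                     groups = q_groups, seed = seed)
  config$Q <- diag(calib$q, 10)

  say("running the hybrid filter on the held-out test process ...")
  res_tst <- runFilter(tst, training$models, config, params,
                       tst$schedule, x0)
  ol_tst <- openLoopTrajectory(tst, params, x0)
  tab_tst <- evaluateRun(res_tst, ol_tst, tst$offline,
                         file.path(dir, "evaluation_test.csv"))
  res_cal <- runFilter(cal, training$models, config, params,
                       cal$schedule, x0)
  ol_cal <- openLoopTrajectory(cal, params, x0)
  tab_cal <- evaluateRun(res_cal, ol_cal, cal$offline,
                         file.path(dir, "evaluation_calibration.csv"))

  writeProcessDataset(ref, file.path(dir, "reference_high_iptg"))
  writeProcessDataset(cal, file.path(dir, "low_iptg_A"))
  writeProcessDataset(tst, file.path(dir, "low_iptg_B"))
  filterResultTable(res_tst, file.path(dir, "filter_test.csv"))
  utils::write.csv(data.frame(phase = 1:3,
                              n_lv = training$chosen_lv,
                              training$rmse_train),
                   file.path(dir, "plsr_training.csv"), row.names = FALSE)
  writeNoiseSpec(diag(R), calib$q,
                 list(R = "PLSR RMSE vs offline samples, low_iptg_A",
                      Q = "pattern search on low_iptg_A offline MSE"),
                 file.path(dir, "noise_spec.json"))
  utils::write.csv(calib$trace, file.path(dir, "q_trace.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, t_end_h = t_end, q_budget = q_budget,
         chosen_lv = training$chosen_lv,
         r_diag = diag(R), q_diag = calib$q),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)

  files <- c("evaluation_test.csv", "evaluation_calibration.csv",
             "filter_test.csv", "plsr_training.csv", "noise_spec.json",
             "q_trace.csv", "manifest.json")
  structure(list(tables = list(test = tab_tst, calibration = tab_cal),
                 training = training,
                 noise = list(r_diag = diag(R), q_diag = calib$q,
                              calibration = calib),
                 files = file.path(dir, files)),
            class = "demo_result")
}

#' @export
print.demo_result <- function(x, ...) {
  cat("<demo_result> held-out process, RMSE vs offline samples [g/L]:\n")
  print(transform(x$tables$test,
                  cgm_rmse = signif(cgm_rmse, 3),
                  ukf_rmse = signif(ukf_rmse, 3)), row.names = FALSE)
  invisible(x)
}
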