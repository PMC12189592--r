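#' Measurement-noise covariance from PLSR errors
#'
#' The diagonal of `R` is the squared per-output RMSE of the PLSR
#' estimates against offline measurements of the calibration process
#' (squared RMSE = MSE). RMSEs below the floor are raised to it first:
#' a sampling layout with no samples in a phase where an output actually
#' varies (glycerol, whose high concentrations occur only in the
#' unsampled batch phase) otherwise yields an unrealistically small
#' diagonal entry and an overconfident filter.
#'
#' @param rmse_per_output positive 5-vector \[g/L\], ordered as
#'   [measuredStates].
#' @param floor minimum admissible RMSE \[g/L\].
#' @return 5 x 5 diagonal matrix \[g^2/L^2\].
#' @export
buildR <- function(rmse_per_output, floor = 1e-3) {
  if (length(rmse_per_output) != 5)
    stop("buildR: need 5 RMSE values")
  if (any(!is.finite(rmse_per_output)) || any(rmse_per_output <= 0))
    stop("buildR: RMSEs must be finite and strictly positive")
  diag(pmax(rmse_per_output, floor)^2, 5)
}

#' Offline-sample objective of a filter run
#'
#' Mean squared deviation between the posterior state estimates
#' (linearly interpolated to the offline sampling times) and the offline
#' measurements, per-output standardized by the offline standard
#' deviations so all five concentrations contribute on comparable scales.
#'
#' @param est data frame or matrix of estimates with a `time_h` column /
#'   attribute: either a `filter_result` or a `cgm_trajectory`.
#' @param offline offline sample table (`time_h` + [measuredStates]).
#' @return Scalar objective (dimensionless).
#' @export
offlineObjective <- function(est, offline) {
  if (nrow(offline) == 0) stop("offlineObjective: no offline samples")
  if (inherits(est, "filter_result")) {
    tms <- est$times; Y <- est$x_post[, measuredStates, drop = FALSE]
  } else if (inherits(est, "cgm_trajectory")) {
    tms <- est$times; Y <- measureStates(est)
  } else stop("offlineObjective: unsupported estimate object")
  keep <- offline$time_h >= min(tms) & offline$time_h <= max(tms)
  off <- offline[keep, , drop = FALSE]
  pred <- vapply(measuredStates, function(cn)
    stats::approx(tms, Y[, cn], xout = off$time_h)$y,
    numeric(nrow(off)))
  obs <- as.matrix(off[, measuredStates])
  sdv <- pmax(apply(obs, 2, stats::sd), 1e-6)
  mean(sweep((pred - obs), 2, sdv, "/")^2)
}

#' Calibrate the process-noise diagonal by pattern search
#'
#' Minimizes the offline-sample objective of the hybrid filter over the
#' diagonal of `Q`, searched in log10 space with a generalized pattern
#' search: coordinate polling with opportunistic acceptance, mesh
#' expansion (x2) on success and contraction (x0.5) on failure, stopping
#' when the mesh falls below `mesh_min` (in log10 units) or the
#' evaluation budget is exhausted. Deterministic given its inputs.
#'
#' @param dataset calibration `process_dataset`.
#' @param models phase PLS models used for the measurements.
#' @param config a [ukfConfig()]; its `Q` is replaced by the candidates.
#' @param params,schedule,x0 filter parameterization (see [runFilter()]).
#' @param q_init initial diagonal (10-vector) \[state units squared\].
#' @param lower,upper box bounds on each diagonal entry.
#' @param mesh0,mesh_min initial / stopping mesh size \[log10 units\].
#' @param budget maximum number of objective evaluations.
#' @param groups optional integer 10-vector tying states to shared
#'   search dials (`NA` = keep that entry fixed at `q_init`); the default
#'   searches all ten entries independently.
#' @param seed kept for interface stability; the search itself is
#'   deterministic.
#' @return List of class `q_calibration`: `q` (best diagonal),
#'   `objective`, `objective_init`, `trace` (data frame), `n_eval`,
#'   `converged`.
#' @export
estimateQ <- function(dataset, models, config, params, schedule, x0,
                      q_init = rep(1e-4, 10), lower = 1e-8, upper = 1e2,
                      mesh0 = 1, mesh_min = 1e-3, budget = 500,
                      groups = seq_len(10), seed = 1) {
  if (nrow(dataset$offline) < 5)
    stop("estimateQ: need at least 5 offline samples")
  if (any(q_init < lower | q_init > upper))
    stop("estimateQ: q_init outside bounds")
  dials <- sort(unique(groups[!is.na(groups)]))
  if (!length(dials)) stop("estimateQ: no free dials in groups")

  measurements <- if (is.null(models)) dataset$measurements else
    predictOnline(models, dataset$online)

  evalQ <- function(lq_dials) {
    q <- q_init
    for (d in seq_along(dials))
      q[which(groups == dials[d])] <- 10^lq_dials[d]
    cfg <- config; cfg$Q <- diag(q, 10)
    res <- try(runFilter(dataset, models = NULL, cfg, params, schedule,
                         x0, measurements = measurements), silent = TRUE)
    if (inherits(res, "try-error")) return(list(obj = Inf, q = q))
    list(obj = offlineObjective(res, dataset$offline), q = q)
  }

  lq <- vapply(dials, function(d)
    log10(mean(q_init[which(groups == d)])), numeric(1))
  llo <- log10(lower); lup <- log10(upper)
  cur <- evalQ(lq)
  if (!is.finite(cur$obj))
    stop("estimateQ: filter diverged at q_init")
  n_eval <- 1L
  trace <- data.frame(eval = 1L, objective = cur$obj, mesh = mesh0,
                      accepted = TRUE)
  obj_init <- cur$obj
  mesh <- mesh0
  while (mesh >= mesh_min && n_eval < budget) {
    improved <- FALSE
    for (d in seq_along(dials)) {
      for (dir in c(1, -1)) {
        cand <- lq
        cand[d] <- min(max(cand[d] + dir * mesh, llo), lup)
        if (cand[d] == lq[d]) next
        ev <- evalQ(cand)
        n_eval <- n_eval + 1L
        acc <- is.finite(ev$obj) && ev$obj < cur$obj
        trace <- rbind(trace, data.frame(eval = n_eval,
                                         objective = ev$obj, mesh = mesh,
                                         accepted = acc))
        if (acc) {
          lq <- cand; cur <- ev; improved <- TRUE
          break
        }
        if (n_eval >= budget) break
      }
      if (improved || n_eval >= budget) break
    }
    mesh <- if (improved) mesh * 2 else mesh / 2
    mesh <- min(mesh, 4)
  }
  q_best <- q_init
  for (d in seq_along(dials))
    q_best[which(groups == dials[d])] <- 10^lq[d]
  structure(list(q = q_best, objective = cur$obj,
                 objective_init = obj_init, trace = trace,
                 n_eval = n_eval, converged = mesh < mesh_min),
            class = "q_calibration")
}

#' @export
print.q_calibration <- function(x, ...) {
  cat("<q_calibration> objective ", signif(x$objective_init, 4), " -> ",
      signif(x$objective, 4), " in ", x$n_eval, " evaluations",
      if (x$converged) " (mesh converged)" else " (budget reached)",
      "\n", sep = "")
  invisible(x)
}

#' Serialize a calibrated noise specification
#'
#' @param r_diag 5-vector of measurement-noise diagonal entries.
#' @param q_diag 10-vector of process-noise diagonal entries.
#' @param provenance free-form list recording which dataset produced each.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
writeNoiseSpec <- function(r_diag, q_diag, provenance, path) {
  if (any(r_diag <= 0) || any(q_diag <= 0))
    stop("writeNoiseSpec: all noise entries must be positive")
  jsonlite::write_json(list(r_diag = r_diag, q_diag = q_diag,
                            provenance = provenance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
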