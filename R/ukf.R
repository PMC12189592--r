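#' Scaled unscented-transform weights
#'
#' \eqn{\lambda = \alpha^2 (n+\kappa) - n}; mean weights
#' \eqn{W_m^{(0)} = \lambda/(n+\lambda)},
#' \eqn{W_m^{(i)} = 1/(2(n+\lambda))} for \eqn{i \ge 1} (which makes the
#' weights sum to one and the sigma-point mean exact for linear maps);
#' the zeroth covariance weight adds the distribution term
#' \eqn{(1-\alpha^2+\beta)}.
#'
#' @param n state dimension.
#' @param alpha spread parameter in (0, 1].
#' @param beta distribution parameter (2 is optimal for Gaussians).
#' @param kappa secondary scaling parameter.
#' @return List with `Wm`, `Wc` (length `2n+1`) and `lambda`.
#' @export
ukfWeights <- function(n, alpha = 0.5, beta = 2, kappa = 0) {
  if (n < 1) stop("ukfWeights: n must be at least 1")
  if (alpha <= 0 || alpha > 1) stop("ukfWeights: alpha must be in (0, 1]")
  lambda <- alpha^2 * (n + kappa) - n
  if (n + lambda <= 0)
    stop("ukfWeights: n + lambda must be positive; increase kappa ",
         "(or alpha). Got n + lambda = ", n + lambda)
  Wm <- c(lambda / (n + lambda), rep(1 / (2 * (n + lambda)), 2 * n))
  Wc <- Wm
  Wc[1] <- Wc[1] + (1 - alpha^2 + beta)
  list(Wm = Wm, Wc = Wc, lambda = lambda)
}

# Cholesky factor of a symmetric PSD matrix with escalating diagonal
# jitter (1e-10 * trace/n, escalating x10 up to 1e-6 * trace/n).
cholJitter <- function(A) {
  U <- try(chol(A), silent = TRUE)
  if (!inherits(U, "try-error")) return(U)
  base <- max(sum(diag(A)) / nrow(A), .Machine$double.eps)
  for (j in 0:4) {
    U <- try(chol(A + base * 1e-10 * 10^j * diag(nrow(A))), silent = TRUE)
    if (!inherits(U, "try-error")) return(U)
  }
  stop("cholJitter: covariance is numerically degenerate ",
       "(Cholesky failed after maximal jitter)")
}

#' Generate scaled sigma points
#'
#' \eqn{\chi^{(0)} = \hat x}, \eqn{\chi^{(i)} = \hat x + } row i of
#' \eqn{chol((n+\lambda) P)}, \eqn{\chi^{(n+i)} = \hat x - } the same.
#'
#' @param x mean vector (length n).
#' @param P covariance (n x n), symmetric PSD.
#' @param lambda scaling parameter from [ukfWeights()].
#' @return n x (2n+1) matrix of sigma points (columns).
#' @export
sigmaPoints <- function(x, P, lambda) {
  n <- length(x)
  A <- (n + lambda) * P
  if (max(abs(A)) == 0) {
    chi <- matrix(x, nrow = n, ncol = 2 * n + 1)
  } else {
    U <- cholJitter(A)
    chi <- cbind(x, x + t(U), x - t(U))
  }
  dimnames(chi) <- list(names(x), NULL)
  chi
}

# Recombine propagated sigma points into mean and covariance (Gram form).
recombineSigma <- function(chi, w, extra = NULL) {
  m <- drop(chi %*% w$Wm)
  D <- chi - m
  P <- D %*% (w$Wc * t(D))
  P <- (P + t(P)) / 2
  if (!is.null(extra)) P <- P + extra
  list(mean = m, cov = P)
}

# Project a symmetric matrix onto the PSD cone (eigenvalue clamping).
psdFloor <- function(P, floor = 0) {
  e <- eigen((P + t(P)) / 2, symmetric = TRUE)
  if (min(e$values) >= floor) return((P + t(P)) / 2)
  v <- pmax(e$values, floor)
  e$vectors %*% (v * t(e$vectors))
}

#' UKF prediction step
#'
#' Generates sigma points from the posterior, propagates each through the
#' state-transition function, and recombines into the prior mean and
#' covariance with additive process noise `Q`. The covariance is
#' symmetrized.
#'
#' @param x posterior mean (length n).
#' @param P posterior covariance (n x n).
#' @param propagate function taking an n x (2n+1) matrix of sigma points
#'   (columns) and returning the propagated matrix.
#' @param Q additive process-noise covariance (n x n).
#' @param w weights from [ukfWeights()].
#' @return List with `x` (prior mean) and `P` (prior covariance).
#' @export
ukfPredict <- function(x, P, propagate, Q, w) {
  chi <- sigmaPoints(x, P, w$lambda)
  chi_f <- propagate(chi)
  if (any(!is.finite(chi_f))) {
    bad <- which(colSums(!is.finite(chi_f)) > 0)
    stop("ukfPredict: non-finite propagated sigma point(s): ",
         paste(bad, collapse = ", "))
  }
  r <- recombineSigma(chi_f, w, extra = Q)
  list(x = stats::setNames(r$mean, names(x)), P = r$cov)
}

#' UKF measurement update
#'
#' Sigma points regenerated from the prior are pushed through the
#' measurement function; the Kalman gain is obtained by solving against
#' the innovation covariance (never by explicit inversion), and the
#' posterior covariance `P - K Py K'` is symmetrized.
#'
#' @param x prior mean.
#' @param P prior covariance.
#' @param y measurement vector (length q).
#' @param h function taking an n x (2n+1) sigma matrix and returning the
#'   q x (2n+1) matrix of measurement-space points.
#' @param R additive measurement-noise covariance (q x q).
#' @param w weights from [ukfWeights()].
#' @return List with `x`, `P`, `innovation`, `gain`, `y_pred`, `Py`.
#' @export
ukfUpdate <- function(x, P, y, h, R, w) {
  if (any(!is.finite(y))) stop("ukfUpdate: non-finite measurement")
  chi <- sigmaPoints(x, P, w$lambda)
  gam <- h(chi)
  y_pred <- drop(gam %*% w$Wm)
  Dy <- gam - y_pred
  Py <- Dy %*% (w$Wc * t(Dy)) + R
  Py <- (Py + t(Py)) / 2
  Dx <- chi - drop(chi %*% w$Wm)
  Pxy <- Dx %*% (w$Wc * t(Dy))
  K <- try(t(solve(Py, t(Pxy))), silent = TRUE)
  if (inherits(K, "try-error"))
    stop("ukfUpdate: innovation covariance numerically singular; ",
         "consider a larger R")
  innov <- y - y_pred
  x_post <- x + drop(K %*% innov)
  P_post <- P - K %*% Py %*% t(K)
  P_post <- (P_post + t(P_post)) / 2
  list(x = stats::setNames(x_post, names(x)), P = P_post,
       innovation = innov, gain = K, y_pred = y_pred, Py = Py)
}

#' Constrain a posterior to its lower bounds by sigma-point projection
#'
#' If any component of the posterior mean violates its lower bound, sigma
#' points are regenerated from the posterior, every violating coordinate
#' of every point is projected onto the bound, and the points are
#' recombined (no process noise added). Applied once, without iteration.
#' The recombined covariance is projected back onto the PSD cone, since
#' clipping can interact with the negative zeroth covariance weight.
#'
#' @param x posterior mean.
#' @param P posterior covariance.
#' @param lower_bounds vector of lower bounds (length n).
#' @param w weights from [ukfWeights()].
#' @return List with `x`, `P` and `constrained` (logical; FALSE means the
#'   input was feasible and is returned unchanged, bit for bit).
#' @export
constrainPosterior <- function(x, P, lower_bounds, w) {
  if (all(x >= lower_bounds))
    return(list(x = x, P = P, constrained = FALSE))
  chi <- sigmaPoints(x, P, w$lambda)
  chi <- pmax(chi, lower_bounds)  # recycles bounds down the rows
  r <- recombineSigma(chi, w)
  xm <- pmax(r$mean, lower_bounds)  # numerical safety; see vignette
  list(x = stats::setNames(xm, names(x)), P = psdFloor(r$cov),
       constrained = TRUE)
}

#' Filter configuration
#'
#' @param x0 initial state (used to size the default `P0`).
#' @param Q process-noise covariance, a 10-vector of diagonal entries or a
#'   10 x 10 matrix.
#' @param R measurement-noise covariance, a 5-vector of diagonal entries
#'   or a 5 x 5 matrix (see [buildR()]).
#' @param P0 initial covariance; default diagonal `(10% of x0)^2` floored
#'   at 1e-6, with the glycerol entry inflated tenfold (initial substrate
#'   levels vary between processes).
#' @param alpha,beta,kappa unscented-transform parameters.
#' @param lower_bounds state lower bounds (zeros; small epsilon for V).
#' @param dt_predict,dt_update prediction / correction intervals \[s\];
#'   `dt_update` must be an integer multiple of `dt_predict`.
#' @param nsub RK4 substeps per prediction interval.
#' @param constrain apply the lower-bound projection after each update.
#' @return List of class `ukf_config`.
#' @export
ukfConfig <- function(x0, Q, R, P0 = NULL, alpha = 0.5, beta = 2,
                      kappa = 0, lower_bounds = NULL, dt_predict = 60,
                      dt_update = 120, nsub = 3, constrain = TRUE) {
  if (dt_update %% dt_predict != 0)
    stop("ukfConfig: dt_update must be an integer multiple of dt_predict")
  if (is.null(P0)) {
    d <- pmax((0.1 * x0)^2, 1e-6)
    d[["S"]] <- d[["S"]] * 10
    P0 <- diag(d)
  }
  if (!is.matrix(Q)) Q <- diag(as.numeric(Q), 10)
  if (!is.matrix(R)) R <- diag(as.numeric(R), 5)
  if (is.null(lower_bounds))
    lower_bounds <- c(1e-6, rep(0, 9))
  w <- ukfWeights(10, alpha, beta, kappa)
  structure(list(alpha = alpha, beta = beta, kappa = kappa, Q = Q, R = R,
                 P0 = P0, lower_bounds = lower_bounds,
                 dt_predict = dt_predict, dt_update = dt_update,
                 nsub = nsub, constrain = constrain, weights = w),
            class = "ukf_config")
}

# Fixed-step RK4 propagation of a sigma-point matrix through the CGM over
# [t0, t0 + dt_h], with nsub substeps. Fast enough for the 60 s filter
# cadence; ground truth uses the stiff solver instead.
propagateCGM <- function(M, t0, dt_h, nsub, params, schedule) {
  h <- dt_h / nsub
  t <- t0
  for (s in seq_len(nsub)) {
    k1 <- cgmRhsMatrix(t, M, params, schedule)
    k2 <- cgmRhsMatrix(t + h / 2, M + h / 2 * k1, params, schedule)
    k3 <- cgmRhsMatrix(t + h / 2, M + h / 2 * k2, params, schedule)
    k4 <- cgmRhsMatrix(t + h, M + h * k3, params, schedule)
    M <- M + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  M
}

#' Run the hybrid soft-sensor filter over a process dataset
#'
#' Per 120 s online tick the filter performs `dt_update / dt_predict`
#' prediction steps (60 s each, integrating every sigma point through the
#' coarse-grained model with the phase-appropriate feed law) and one
#' measurement update using the phase PLS model estimates as the
#' measurement vector, followed by the lower-bound constraint step. The
#' first online row initializes the filter and receives an update only.
#'
#' @param dataset a `process_dataset` (see [makeScenario()]); its online
#'   table drives the cadence.
#' @param models list of three `phase_pls_model`s, or `NULL` when
#'   `measurements` is supplied.
#' @param config a [ukfConfig()].
#' @param params,schedule the filter's (nominal) model parameterization.
#' @param x0 initial state estimate (named 10-vector).
#' @param measurements optional T x 5 matrix overriding the PLSR
#'   measurements (e.g. for diagnostics); negative values are passed to
#'   the update unclipped — constraints act on states, not measurements.
#' @return Object of class `filter_result`: `times`, `x_prior`, `x_post`
#'   (T x 10), `P_prior`, `P_post` (T x 10 x 10), `innovations` (T x 5),
#'   `gains` (T x 10 x 5), `measurements`, `n_predicts`, `n_updates`,
#'   `n_constrained`.
#' @export
runFilter <- function(dataset, models, config, params, schedule, x0,
                      measurements = NULL) {
  online <- dataset$online
  times <- online$time_h
  T_ <- length(times)
  if (is.null(measurements)) {
    if (is.null(models))
      stop("runFilter: need PLSR models or an explicit measurement matrix")
    measurements <- predictOnline(models, online)
  }
  stopifnot(nrow(measurements) == T_, ncol(measurements) == 5)

  w <- config$weights
  n_pred_per_tick <- config$dt_update %/% config$dt_predict
  dt_h <- config$dt_predict / 3600
  h_fun <- function(chi) chi[c(3L, 2L, 4L, 5L, 6L), , drop = FALSE]

  x <- stats::setNames(as.numeric(x0), stateNames)
  P <- config$P0
  x_prior <- x_post <- matrix(NA_real_, T_, 10,
                              dimnames = list(NULL, stateNames))
  P_prior <- P_post <- array(NA_real_, c(T_, 10, 10))
  innovations <- matrix(NA_real_, T_, 5,
                        dimnames = list(NULL, measuredStates))
  gains <- array(NA_real_, c(T_, 10, 5))
  n_predicts <- 0L; n_constrained <- 0L

  for (r in seq_len(T_)) {
    if (r > 1L) {
      t_cur <- times[r - 1L]
      for (s in seq_len(n_pred_per_tick)) {
        pr <- ukfPredict(x, P, function(M)
          propagateCGM(M, t_cur, dt_h, config$nsub, params, schedule),
          config$Q, w)
        x <- pr$x; P <- pr$P
        t_cur <- t_cur + dt_h
        n_predicts <- n_predicts + 1L
      }
    }
    x_prior[r, ] <- x
    P_prior[r, , ] <- P

    up <- ukfUpdate(x, P, measurements[r, ], h_fun, config$R, w)
    x <- up$x; P <- up$P
    if (config$constrain) {
      cn <- constrainPosterior(x, P, config$lower_bounds, w)
      if (cn$constrained) n_constrained <- n_constrained + 1L
      x <- cn$x; P <- cn$P
    }
    x_post[r, ] <- x
    P_post[r, , ] <- P
    innovations[r, ] <- up$innovation
    gains[r, , ] <- up$gain
  }

  structure(list(times = times, x_prior = x_prior, x_post = x_post,
                 P_prior = P_prior, P_post = P_post,
                 innovations = innovations, gains = gains,
                 measurements = measurements,
                 n_predicts = n_predicts, n_updates = T_,
                 n_constrained = n_constrained,
                 config = config),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("<filter_result> ", x$n_updates, " updates / ", x$n_predicts,
      " predicts, t = ", signif(min(x$times), 4), "..",
      signif(max(x$times), 4), " h\n", sep = "")
  cat("  constraint projections: ", x$n_constrained, "\n", sep = "")
  invisible(x)
}

#' Export a filter run as a tidy table
#'
#' One row per online tick: time, prior and posterior states, posterior
#' covariance diagonal and innovations.
#'
#' @param result a `filter_result`.
#' @param path optional CSV path; when given, the table is also written.
#' @return The assembled data frame (invisibly when `path` is given).
#' @export
filterResultTable <- function(result, path = NULL) {
  df <- data.frame(time_h = result$times)
  pri <- result$x_prior; colnames(pri) <- paste0("prior_", stateNames)
  pos <- result$x_post; colnames(pos) <- paste0("post_", stateNames)
  pv <- t(apply(result$P_post, 1, diag))
  colnames(pv) <- paste0("var_", stateNames)
  inn <- result$innovations
  colnames(inn) <- paste0("innov_", measuredStates)
  df <- cbind(df, pri, pos, pv, inn)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
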