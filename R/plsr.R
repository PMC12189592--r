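#' Phase-start offset centering of online inputs
#'
#' Subtracts the signal values at the start of the phase from every row,
#' so that each phase begins at the origin and models transfer between
#' processes with different absolute sensor levels. The reference row
#' `x0_ref` is the mean of the first `n_ref` rows (a small average damps
#' sensor noise at the phase start; `n_ref = 1` gives literal first-row
#' subtraction).
#'
#' @param X numeric matrix (rows = time points of one phase).
#' @param n_ref number of initial rows averaged into the reference.
#' @return List with `Xc` (centered matrix) and `x0_ref` (reference row).
#' @export
phaseOffsetCenter <- function(X, n_ref = 1) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("phaseOffsetCenter: phase needs at least 2 rows")
  n_ref <- min(n_ref, nrow(X))
  x0 <- colMeans(X[seq_len(n_ref), , drop = FALSE])
  list(Xc = sweep(X, 2, x0), x0_ref = x0)
}

#' Interpolate simulated concentrations onto online time stamps
#'
#' Builds the regression outputs for PLSR training: the five measured
#' concentrations of a simulated trajectory, linearly interpolated onto
#' the online sampling grid. Exact at trajectory knots; refuses to
#' extrapolate.
#'
#' @param traj a `cgm_trajectory` (the simulated ground truth).
#' @param online_times time stamps \[h\] of the online data.
#' @return length(online_times) x 5 matrix (columns [measuredStates]).
#' @export
buildTrainingOutputs <- function(traj, online_times) {
  interpMeasured(traj, online_times)
}

#' Fit a PLS regression by the SIMPLS algorithm
#'
#' Direct SIMPLS: successive dominant singular vectors of the deflated
#' cross-product matrix `X'Y`, with deflation orthogonal to the X-loadings,
#' so the score vectors are mutually orthogonal. Inputs and outputs are
#' mean-centered internally; the returned coefficients act on raw inputs
#' as `Yhat = (X - x_mean) B + y_mean`.
#'
#' @param X input matrix (n x p), already phase-offset-centered when used
#'   in the soft-sensor pipeline.
#' @param Y output matrix (n x q).
#' @param n_lv number of latent variables, at most `min(rank(X), p)`.
#' @return Object of class `simpls_model`: `weights` (p x a), `x_loadings`
#'   (p x a), `y_loadings` (q x a), `scores` (n x a), `coef` (p x q),
#'   `intercept` (q), `x_mean`, `y_mean`, `n_lv`, `rmse_train` (q).
#' @export
simplsFit <- function(X, Y, n_lv) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y))
    stop("simplsFit: X and Y must have the same number of rows")
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  X0 <- sweep(X, 2, x_mean); Y0 <- sweep(Y, 2, y_mean)
  rk <- effectiveRank(X0)
  if (n_lv > min(rk, p))
    stop("simplsFit: n_lv = ", n_lv, " exceeds the attainable maximum ",
         min(rk, p))

  S <- crossprod(X0, Y0)
  R_w <- matrix(0, p, n_lv); P_l <- matrix(0, p, n_lv)
  Q_l <- matrix(0, q, n_lv); TT <- matrix(0, n, n_lv)
  V <- matrix(0, p, n_lv)
  nt1 <- NULL
  for (a in seq_len(n_lv)) {
    sv <- svd(S, nu = 1, nv = 0)
    r <- sv$u[, 1]
    t_a <- X0 %*% r
    nt <- sqrt(sum(t_a^2))
    if (is.null(nt1)) nt1 <- nt
    if (nt < 1e-10 * nt1)
      stop("simplsFit: degenerate component ", a,
           "; the attainable maximum is ", a - 1L)
    t_a <- t_a / nt; r <- r / nt
    p_a <- crossprod(X0, t_a)
    q_a <- crossprod(Y0, t_a)
    v <- p_a
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, p_a)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R_w[, a] <- r; P_l[, a] <- p_a; Q_l[, a] <- q_a
    TT[, a] <- t_a; V[, a] <- v
  }
  B <- R_w %*% t(Q_l)
  fitted <- X0 %*% B
  resid <- Y0 - fitted
  obj <- structure(list(weights = R_w, x_loadings = P_l, y_loadings = Q_l,
                        scores = TT, coef = B,
                        intercept = drop(y_mean - crossprod(x_mean, B)),
                        x_mean = x_mean, y_mean = y_mean, n_lv = n_lv,
                        rmse_train = sqrt(colMeans(resid^2))),
                   class = "simpls_model")
  obj
}

#' Predict from a fitted SIMPLS model
#'
#' Deterministic affine map `Yhat = (X - x_mean) B + y_mean`. Negative
#' predicted concentrations are returned as-is; clipping, where needed,
#' happens at the state-constraint stage of the filter, never here.
#'
#' @param object a `simpls_model`.
#' @param newdata matrix of inputs with the same columns as the training
#'   inputs.
#' @param ... unused.
#' @return Matrix of predictions (rows x q).
#' @export
predict.simpls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop("predict.simpls_model: expected ", length(object$x_mean),
         " input columns, got ", ncol(newdata))
  sweep(newdata, 2, object$x_mean) %*% object$coef +
    rep(1, nrow(newdata)) %o% object$y_mean
}

#' Effective numerical rank of a (column-centered) matrix
#'
#' Number of singular values above `tol` times the largest one. Used to
#' cap the latent-variable count: online process channels are often
#' exactly constant within a phase (controlled setpoints) or collinear,
#' and components along near-null directions are numerically meaningless.
#'
#' @param X numeric matrix.
#' @param tol relative singular-value cutoff.
#' @return Integer rank estimate.
#' @export
effectiveRank <- function(X, tol = 1e-7) {
  d <- svd(as.matrix(X), nu = 0, nv = 0)$d
  if (!length(d) || d[1] == 0) return(0L)
  sum(d > tol * d[1])
}

#' Root-mean-square error per output
#'
#' @param yhat,y_ref matrices (or vectors) of equal dimension.
#' @return Named numeric vector of per-column RMSEs \[g/L\].
#' @export
rmsePerOutput <- function(yhat, y_ref) {
  yhat <- as.matrix(yhat); y_ref <- as.matrix(y_ref)
  if (!all(dim(yhat) == dim(y_ref)))
    stop("rmsePerOutput: dimension mismatch")
  if (nrow(yhat) == 0) stop("rmsePerOutput: empty alignment")
  sqrt(colMeans((yhat - y_ref)^2))
}

#' Select the number of latent variables by k-fold RMSECV
#'
#' Cross-validated error for every latent-variable count from 1 to
#' `max_lv`. Folds are contiguous time blocks by default (appropriate for
#' autocorrelated process data; set `folds = "random"` for shuffled row
#' folds). Per-output mean squared errors are standardized by the output
#' standard deviations before aggregation, so outputs on large scales
#' (biomass, tens of g/L) do not drown out small ones (L-tyr, < 0.1 g/L).
#' Counts whose aggregate RMSECV lies within `tie_tol` (relative) of the
#' minimum are treated as ties, resolved toward fewer latent variables —
#' the usual parsimony rule for the flat tail of a CV curve.
#'
#' @param X centered input matrix (n x p).
#' @param Y output matrix (n x q).
#' @param max_lv largest latent-variable count to consider.
#' @param k number of folds.
#' @param seed RNG seed (used only for `folds = "random"`).
#' @param folds `"blocks"` (contiguous, default) or `"random"`.
#' @param tie_tol relative near-tie tolerance of the parsimony rule.
#' @return Object of class `cv_report`: `rmsecv` (max_lv x q matrix of
#'   per-output RMSECVs), `aggregate` (length max_lv), `chosen_lv`,
#'   `fold_id`, `seed`.
#' @export
crossvalidateLV <- function(X, Y, max_lv = 8, k = 5, seed = 1,
                            folds = c("blocks", "random"),
                            tie_tol = 0.01) {
  folds <- match.arg(folds)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (k > n) stop("crossvalidateLV: more folds than rows")
  fold_id <- rep(seq_len(k), length.out = n)
  if (folds == "blocks") {
    fold_id <- sort(rep(seq_len(k), diff(floor(seq(0, n, length.out = k + 1)))))
  } else {
    fold_id <- withr::with_seed(seed, sample(fold_id))
  }
  y_sd <- pmax(apply(Y, 2, stats::sd), 1e-12)

  sse <- matrix(0, nrow = max_lv, ncol = ncol(Y))
  for (f in seq_len(k)) {
    tr <- fold_id != f
    max_here <- min(max_lv,
                    effectiveRank(scale(X[tr, , drop = FALSE],
                                        scale = FALSE)))
    for (a in seq_len(max_lv)) {
      fit <- simplsFit(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                       min(a, max_here))
      pred <- predict(fit, X[!tr, , drop = FALSE])
      sse[a, ] <- sse[a, ] + colSums((pred - Y[!tr, , drop = FALSE])^2)
    }
  }
  rmsecv <- sqrt(sse / n)
  agg <- sqrt(rowMeans(sweep(sse / n, 2, y_sd^2, "/")))
  chosen <- which(agg <= (1 + tie_tol) * min(agg))[1]  # fewest LVs wins
  structure(list(rmsecv = rmsecv, aggregate = agg,
                 chosen_lv = as.integer(chosen), fold_id = fold_id,
                 seed = seed, folds = folds),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> chosen_lv =", x$chosen_lv, "(", x$folds, "folds )\n")
  cat("  aggregate RMSECV:",
      paste(signif(x$aggregate, 4), collapse = " "), "\n")
  invisible(x)
}

#' Train one phase model of the soft sensor
#'
#' Offset-centers the phase's online block, selects the latent-variable
#' count by five-fold RMSECV and fits the final SIMPLS model on the whole
#' phase.
#'
#' @param X_phase online matrix rows of one phase (8 columns).
#' @param Y_phase matching training outputs (5 columns).
#' @param phase phase index 1, 2 or 3.
#' @param max_lv,k,seed,folds passed to [crossvalidateLV()].
#' @param n_ref rows averaged for the phase-start reference.
#' @return Object of class `phase_pls_model`: the `simpls_model` plus
#'   `phase`, `x0_ref`, `cv` and `n_ref`.
#' @export
fitPhaseModel <- function(X_phase, Y_phase, phase, max_lv = 8, k = 5,
                          seed = 1, folds = "blocks", n_ref = 3) {
  ctr <- phaseOffsetCenter(X_phase, n_ref = n_ref)
  max_lv <- min(max_lv, effectiveRank(scale(ctr$Xc, scale = FALSE)))
  cv <- crossvalidateLV(ctr$Xc, Y_phase, max_lv = max_lv, k = k,
                        seed = seed, folds = folds)
  fit <- simplsFit(ctr$Xc, Y_phase, cv$chosen_lv)
  structure(c(unclass(fit),
              list(phase = as.integer(phase), x0_ref = ctr$x0_ref,
                   cv = cv, n_ref = n_ref)),
            class = c("phase_pls_model", "simpls_model"))
}

#' @export
print.phase_pls_model <- function(x, ...) {
  cat("<phase_pls_model> phase", x$phase, "-", x$n_lv, "LV(s)\n")
  cat("  training RMSE [g/L]:",
      paste(measuredStates, signif(x$rmse_train, 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' Apply phase PLS models to a full online table
#'
#' For each phase present in the online data, the corresponding model is
#' applied after offset-centering with that dataset's own phase-start
#' reference (the model's training reference is not reused), so starting
#' conditions stay consistent across processes.
#'
#' @param models list of three `phase_pls_model`s (phases 1-3).
#' @param online online data frame with `time_h`, the eight channel
#'   columns ([onlineChannels]) and `phase`.
#' @return T x 5 matrix of concentration estimates (columns
#'   [measuredStates]), in online row order.
#' @export
predictOnline <- function(models, online) {
  phases <- sort(unique(online$phase))
  have <- vapply(models, function(m) m$phase, integer(1))
  if (!all(phases %in% have))
    stop("predictOnline: no trained model for phase(s) ",
         paste(setdiff(phases, have), collapse = ", "))
  out <- matrix(NA_real_, nrow = nrow(online), ncol = 5,
                dimnames = list(NULL, measuredStates))
  for (ph in phases) {
    m <- models[[match(ph, have)]]
    idx <- which(online$phase == ph)
    Xp <- as.matrix(online[idx, onlineChannels, drop = FALSE])
    ctr <- phaseOffsetCenter(Xp, n_ref = m$n_ref)
    out[idx, ] <- predict(m, ctr$Xc)
  }
  out
}
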