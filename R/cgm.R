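#' Biomass-specific reaction rates of the coarse-grained model
#'
#' Rates are gated by the proteome sectors: glycerol uptake by `phiT`,
#' protein synthesis (= growth) by `phiR`, product formation by `phiFp`.
#' Overflow metabolism produces acetate whenever the catabolic flux
#' exceeds the respiratory capacity threshold `v_crit`. Growth requires
#' L-tyrosine (auxotrophy) via a Monod factor.
#'
#' \deqn{v_T = k_T \phi_T S/(K_S+S)}
#' \deqn{v_R = \mu = k_R \phi_R \frac{m}{K_{mR}+m} \frac{Y}{K_Y+Y}}
#' \deqn{v_F = k_F \phi_{Fp} m/(K_{mF}+m)}
#' \deqn{v_A = k_A \max(0, v_T - v_{crit}), \quad v_Y = c_Y \mu}
#'
#' @param state named 10-vector (see [stateNames]).
#' @param params a [cgmParameters()].
#' @param iptg inducer concentration \[mM\] (unused by the rates themselves,
#'   accepted for interface symmetry with [allocation()]).
#' @return Named list with `v_T`, `v_R`, `v_F`, `v_A`, `mu`, `v_Y`
#'   \[g/(g h), mu in 1/h\].
#' @export
reactionRates <- function(state, params, iptg = 0) {
  if (any(!is.finite(state)))
    stop("reactionRates: non-finite state component")
  S <- max(state[["S"]], 0); Y <- max(state[["Y"]], 0)
  phiT <- max(state[["phiT"]], 0); phiR <- max(state[["phiR"]], 0)
  phiFp <- max(state[["phiFp"]], 0); m <- max(state[["m"]], 0)
  v_T <- params$kT * phiT * S / (params$KS + S)
  mu <- params$kR * phiR * (m / (params$KmR + m)) * (Y / (params$KY + Y))
  v_F <- params$kF * phiFp * m / (params$KmF + m)
  v_A <- params$kA * max(0, v_T - params$v_crit)
  list(v_T = v_T, v_R = mu, v_F = v_F, v_A = v_A, mu = mu,
       v_Y = params$cY * mu)
}

#' Proteome allocation targets
#'
#' Allocation fractions toward which the proteome sectors relax (at rate
#' `mu`). Housekeeping is fixed at `phiQ`; the production sector responds
#' to the inducer through a saturating (Hill-1) function; ribosomes take a
#' metabolite-dependent share of the remainder; transport/catabolism gets
#' what is left. The four fractions always sum to one.
#'
#' @inheritParams reactionRates
#' @return Named list `alpha_T`, `alpha_R`, `alpha_Fp`, `alpha_Q`.
#' @export
allocation <- function(state, params, iptg = 0) {
  if (iptg < 0) stop("allocation: iptg must be nonnegative")
  m <- max(state[["m"]], 0)
  alpha_Q <- params$phiQ
  alpha_Fp <- params$alpha_Fp_max * iptg / (params$KI + iptg)
  alpha_R <- params$alpha_R_max * (m / (params$KmR + m)) *
    (1 - alpha_Fp - alpha_Q)
  alpha_T <- 1 - alpha_R - alpha_Fp - alpha_Q
  if (alpha_T < 0)
    stop("allocation: parameters imply negative alpha_T")
  list(alpha_T = alpha_T, alpha_R = alpha_R, alpha_Fp = alpha_Fp,
       alpha_Q = alpha_Q)
}

#' Volumetric feed rate of the active phase
#'
#' Phase 1: no feed. Phase 2: closed-loop exponential law
#' `F = (mu_set / Y_XS_eff) X V / S_feed2` targeting the growth set point;
#' being state-driven it stays consistent when the filter perturbs the
#' state. Phase 3: `F = q_feed3 X V / S_feed3`.
#'
#' @param t time \[h\].
#' @param state named 10-vector.
#' @param params a [cgmParameters()].
#' @param schedule a [feedSchedule()].
#' @return Feed rate \[L/h\], always nonnegative.
#' @export
feedRate <- function(t, state, params, schedule) {
  phase <- activePhase(t, schedule)
  XV <- max(state[["X"]], 0) * max(state[["V"]], 0)
  if (phase == 1L) return(0)
  if (phase == 2L)
    return(params$mu_set / params$Y_XS_eff * XV / schedule$S_feed2)
  params$q_feed3 * XV / schedule$S_feed3
}

# Feed concentrations (S, P, Y) of the active phase; zero in phase 1.
feedConcentrations <- function(phase, schedule) {
  if (phase == 1L) return(c(S = 0, P = 0, Y = 0))
  if (phase == 2L)
    return(c(S = schedule$S_feed2, P = schedule$P_feed2,
             Y = schedule$Y_feed2))
  c(S = schedule$S_feed3, P = 0, Y = 0)
}

#' Time derivative of the process state
#'
#' Liquid-phase balances for a fed-batch reactor (feed in, no outflow)
#' plus first-order relaxation of the proteome fractions toward their
#' allocation targets and the intracellular metabolite balance.
#'
#' @param t time \[h\].
#' @param state named 10-vector (see [stateNames]).
#' @param params a [cgmParameters()].
#' @param schedule a [feedSchedule()].
#' @return Named numeric 10-vector `d(state)/dt`.
#' @export
cgmDerivatives <- function(t, state, params, schedule) {
  if (state[["V"]] <= 0)
    stop("cgmDerivatives: volume must be strictly positive")
  stats::setNames(drop(cgmRhsMatrix(t, matrix(state, nrow = 10),
                                    params, schedule)), stateNames)
}

# Vectorized right-hand side: `M` is a 10 x k matrix of states (columns =
# e.g. sigma points); returns the 10 x k matrix of derivatives. Negative
# excursions are clamped to zero inside the kinetic terms only, so the
# rhs stays well defined for slightly infeasible filter states. Hot path
# of the filter: no dimnames, minimal allocations.
cgmRhsMatrix <- function(t, M, params, schedule) {
  phase <- activePhase(t, schedule)
  fc <- feedConcentrations(phase, schedule)
  iptg <- if (t >= schedule$t_induction) schedule$iptg else 0

  V <- pmax.int(M[1L, ], 1e-9); S <- pmax.int(M[2L, ], 0)
  X <- pmax.int(M[3L, ], 0); Y <- pmax.int(M[6L, ], 0)
  phiT <- pmax.int(M[7L, ], 0); phiR <- pmax.int(M[8L, ], 0)
  phiFp <- pmax.int(M[9L, ], 0); m <- pmax.int(M[10L, ], 0)

  msat <- m / (params$KmR + m)
  v_T <- params$kT * phiT * S / (params$KS + S)
  mu <- params$kR * phiR * msat * (Y / (params$KY + Y))
  v_F <- params$kF * phiFp * m / (params$KmF + m)
  v_A <- params$kA * pmax.int(0, v_T - params$v_crit)

  Fr <- if (phase == 1L) 0 else if (phase == 2L)
    params$mu_set / params$Y_XS_eff * X * V / schedule$S_feed2
  else params$q_feed3 * X * V / schedule$S_feed3
  D <- Fr / V  # dilution rate [1/h]

  alpha_Fp <- params$alpha_Fp_max * iptg / (params$KI + iptg)
  alpha_R <- params$alpha_R_max * msat * (1 - alpha_Fp - params$phiQ)

  muX <- mu * X
  rbind(Fr,
        -v_T * X + D * (fc[[1L]] - M[2L, ]),
        muX - D * M[3L, ],
        v_F * X + D * (fc[[2L]] - M[4L, ]),
        v_A * X - D * M[5L, ],
        -params$cY * muX + D * (fc[[3L]] - M[6L, ]),
        mu * ((1 - alpha_R - alpha_Fp - params$phiQ) - M[7L, ]),
        mu * (alpha_R - M[8L, ]),
        mu * (alpha_Fp - M[9L, ]),
        params$Y_MS * v_T - mu / params$Y_XM - v_F / params$Y_PM -
          v_A / params$Y_AM - mu * m,
        deparse.level = 0)
}

#' Simulate the fed-batch process
#'
#' Integrates the coarse-grained model over a time grid with a stiff-capable
#' solver ([deSolve::lsoda]), restarting the integration at the phase
#' boundaries so the feed discontinuities are handled exactly. Two
#' bookkeeping quantities are co-integrated at solver accuracy: cumulative
#' glycerol fed and cumulative glycerol taken up, used by the liquid-phase
#' mass-balance diagnostics.
#'
#' @param x0 named initial state 10-vector.
#' @param params a [cgmParameters()].
#' @param schedule a [feedSchedule()].
#' @param times strictly increasing time grid \[h\].
#' @param atol,rtol absolute/relative integrator tolerances.
#' @return Object of class `cgm_trajectory`: list with `times`, `states`
#'   (T x 10), `rates` (T x 6: v_T, v_R, v_F, v_A, mu, v_Y), `phase`,
#'   `feed_rate`, `fed_glycerol_g`, `uptake_glycerol_g`, plus the inputs.
#' @export
simulateProcess <- function(x0, params, schedule, times,
                            atol = 1e-9, rtol = 1e-9) {
  if (is.unsorted(times, strictly = TRUE))
    stop("simulateProcess: times must be strictly increasing")
  validateState(x0, params)

  rhs <- function(t, y, parms) {
    dy <- drop(cgmRhsMatrix(t, matrix(y[1:10], nrow = 10,
                                      dimnames = list(stateNames, NULL)),
                            params, schedule))
    st <- stats::setNames(y[1:10], stateNames)
    Fr <- feedRate(t, st, params, schedule)
    fc <- feedConcentrations(activePhase(t, schedule), schedule)
    S <- max(st[["S"]], 0)
    v_T <- params$kT * max(st[["phiT"]], 0) * S / (params$KS + S)
    list(c(dy,
           fed = Fr * fc[["S"]],
           used = v_T * max(st[["X"]], 0) * max(st[["V"]], 1e-12)))
  }

  # integrate piecewise between phase boundaries falling inside the grid
  brk <- c(schedule$t_batch_end, schedule$t_induction)
  brk <- brk[brk > min(times) & brk < max(times)]
  edges <- sort(unique(c(times, brk)))
  y <- c(x0, fed = 0, used = 0)
  rows <- matrix(NA_real_, nrow = length(edges), ncol = 12L)
  rows[1L, ] <- y
  t_cursor <- edges[1]
  for (seg_end in c(brk, max(edges))) {
    idx <- which(edges > t_cursor & edges <= seg_end)
    if (!length(idx)) { t_cursor <- seg_end; next }
    tt <- c(t_cursor, edges[idx])
    sol <- try(deSolve::lsoda(y, tt, rhs, parms = NULL,
                              atol = atol, rtol = rtol), silent = TRUE)
    if (inherits(sol, "try-error") || nrow(sol) < length(tt))
      stop("simulateProcess: integrator failure after t = ",
           signif(t_cursor, 6), " h")
    rows[idx, ] <- sol[-1L, -1L, drop = FALSE]
    y <- sol[nrow(sol), -1L]
    # clip tiny negative excursions before restarting across a boundary
    y[1:10] <- pmax(y[1:10], 0)
    t_cursor <- seg_end
  }

  keep <- edges %in% times
  st <- rows[keep, 1:10, drop = FALSE]
  st[st < 0 & st > -10 * atol] <- 0
  colnames(st) <- stateNames
  tms <- edges[keep]

  rts <- t(vapply(seq_along(tms), function(i) {
    r <- reactionRates(stats::setNames(st[i, ], stateNames), params,
                       iptgAt(tms[i], schedule))
    unlist(r)
  }, numeric(6)))
  fr <- vapply(seq_along(tms), function(i)
    feedRate(tms[i], stats::setNames(st[i, ], stateNames), params,
             schedule), numeric(1))

  structure(list(times = tms, states = st, rates = rts,
                 phase = activePhase(tms, schedule), feed_rate = fr,
                 fed_glycerol_g = rows[keep, 11L],
                 uptake_glycerol_g = rows[keep, 12L],
                 params = params, schedule = schedule),
            class = "cgm_trajectory")
}

#' @export
print.cgm_trajectory <- function(x, ...) {
  cat("<cgm_trajectory> ", length(x$times), " points, t = ",
      signif(min(x$times), 4), "..", signif(max(x$times), 4), " h\n",
      sep = "")
  cat("  phases 1/2/3: ", paste(tabulate(x$phase, 3), collapse = "/"),
      " points; final X = ", signif(x$states[nrow(x$states), "X"], 4),
      " g/L, P = ", signif(x$states[nrow(x$states), "P"], 4), " g/L\n",
      sep = "")
  invisible(x)
}

#' Measurement function: select the five measured concentrations
#'
#' Pure selection (no noise) of biomass, glycerol, L-phe, acetate and
#' L-tyrosine, in that fixed order, from a state vector or a matrix of
#' states.
#'
#' @param states named 10-vector, a T x 10 state matrix, or a
#'   `cgm_trajectory`.
#' @return Named 5-vector or T x 5 matrix (columns [measuredStates]).
#' @export
measureStates <- function(states) {
  if (inherits(states, "cgm_trajectory")) states <- states$states
  if (is.matrix(states)) return(states[, measuredStates, drop = FALSE])
  states[measuredStates]
}

#' Interpolate trajectory concentrations onto arbitrary time points
#'
#' Linear interpolation of the five measured concentrations; refuses to
#' extrapolate outside the trajectory span.
#'
#' @param traj a `cgm_trajectory`.
#' @param times query times \[h\], within the trajectory span.
#' @return length(times) x 5 matrix (columns [measuredStates]).
#' @export
interpMeasured <- function(traj, times) {
  if (min(times) < min(traj$times) - 1e-9 ||
      max(times) > max(traj$times) + 1e-9)
    stop("interpMeasured: query times outside trajectory span; ",
         "extrapolation is not supported")
  Y <- measureStates(traj)
  out <- vapply(measuredStates, function(cn)
    stats::approx(traj$times, Y[, cn], xout = times, rule = 1)$y,
    numeric(length(times)))
  out <- matrix(out, ncol = 5, dimnames = list(NULL, measuredStates))
  out
}
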