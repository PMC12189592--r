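#' State vector layout of the coarse-grained process model
#'
#' Ten states: reactor volume `V` \[L\], glycerol `S`, biomass `X`,
#' L-phenylalanine `P`, acetate `A`, L-tyrosine `Y` (all \[g/L\]), the
#' proteome mass fractions `phiT` (transport/catabolism), `phiR`
#' (ribosomes), `phiFp` (production proteins) and the intracellular
#' metabolite mass fraction `m` (all dimensionless).
#'
#' @format Character vector of length 10, in the fixed internal order.
#' @export
stateNames <- c("V", "S", "X", "P", "A", "Y", "phiT", "phiR", "phiFp", "m")

#' Measured concentration ordering
#'
#' The fixed ordering of the five measured concentrations used everywhere
#' a measurement vector appears: biomass, glycerol, L-phe, acetate, L-tyr.
#'
#' @format Character vector of length 5 (names refer to [stateNames]).
#' @export
measuredStates <- c("X", "S", "P", "A", "Y")

#' Online channel ordering
#'
#' Fixed column order of the eight online process channels.
#'
#' @format Character vector of length 8.
#' @export
onlineChannels <- c("stirrer_rpm", "aeration_l_min", "po2_pct", "temp_c",
                    "ph", "co2_offgas_pct", "feed_massflow_g_h",
                    "base_cumulative_ml")

#' Kinetic and stoichiometric parameters of the coarse-grained model
#'
#' Constructs the parameter set of the proteome-allocation process model.
#' Reaction rates are gated by proteome sectors: transport/catabolism
#' (`phiT`), ribosomes (`phiR`), housekeeping (`phiQ`, fixed) and L-phe
#' production proteins (`phiFp`). The numeric defaults are engineering
#' choices tuned to reproduce the qualitative phenotype of the process
#' (batch ends at roughly 13-17 h from 4 g/L glycerol, tens of g/L
#' L-phe after induction, low acetate); they are not measured values.
#'
#' @param kT_per_h,kR_per_h,kF_per_h catalytic rate constants of substrate
#'   uptake, protein synthesis and product formation \[1/h\].
#' @param KS_g_l glycerol half-saturation of uptake \[g/L\].
#' @param KmR,KmF metabolite-pool half-saturations of protein synthesis and
#'   product formation \[mass fraction\].
#' @param KY_g_l L-tyrosine half-saturation of growth \[g/L\] (the strain is
#'   an L-tyr auxotroph).
#' @param cY_g_g L-tyrosine demand per biomass formed \[g/g\].
#' @param Y_MS,Y_XM,Y_PM,Y_AM yield coefficients: metabolite per substrate,
#'   biomass per metabolite, product per metabolite, acetate per metabolite
#'   \[g/g\].
#' @param v_crit_g_gh catabolic capacity threshold above which overflow
#'   metabolism sets in \[g/(g h)\].
#' @param kA overflow gain \[-\].
#' @param phiQ fixed housekeeping proteome fraction \[-\].
#' @param alpha_Fp_max maximal allocation to production proteins under full
#'   induction \[-\]; must be below `1 - phiQ`.
#' @param alpha_R_max maximal allocation to ribosomes \[-\].
#' @param KI_mM inducer (IPTG) half-saturation of the production-protein
#'   allocation response \[mM\].
#' @param mu_set_per_h growth-rate set point of the biomass production
#'   phase \[1/h\].
#' @param q_feed3_g_gh specific glycerol feed rate of the production phase
#'   \[g glycerol / (g biomass h)\].
#' @param Y_XS_eff effective biomass-per-substrate yield used by the
#'   closed-loop exponential feed law \[g/g\].
#'
#' @return A named list of class `cgm_parameters`.
#' @export
cgmParameters <- function(kT_per_h = 2.5,
                          kR_per_h = 1.8,
                          kF_per_h = 2.0,
                          KS_g_l = 0.1,
                          KmR = 0.05,
                          KmF = 0.05,
                          KY_g_l = 0.005,
                          cY_g_g = 0.015,
                          Y_MS = 0.7,
                          Y_XM = 0.8,
                          Y_PM = 0.6,
                          Y_AM = 0.5,
                          v_crit_g_gh = 0.6,
                          kA = 0.3,
                          phiQ = 0.45,
                          alpha_Fp_max = 0.25,
                          alpha_R_max = 0.6,
                          KI_mM = 0.002,
                          mu_set_per_h = 0.1,
                          q_feed3_g_gh = 0.18,
                          Y_XS_eff = 0.5) {
  p <- list(kT = kT_per_h, kR = kR_per_h, kF = kF_per_h,
            KS = KS_g_l, KmR = KmR, KmF = KmF, KY = KY_g_l, cY = cY_g_g,
            Y_MS = Y_MS, Y_XM = Y_XM, Y_PM = Y_PM, Y_AM = Y_AM,
            v_crit = v_crit_g_gh, kA = kA, phiQ = phiQ,
            alpha_Fp_max = alpha_Fp_max, alpha_R_max = alpha_R_max,
            KI = KI_mM, mu_set = mu_set_per_h, q_feed3 = q_feed3_g_gh,
            Y_XS_eff = Y_XS_eff)
  bad <- names(p)[!vapply(p, function(v) is.numeric(v) && length(v) == 1 &&
                            is.finite(v) && v > 0, logical(1))]
  if (length(bad))
    stop("cgmParameters: non-positive or non-finite parameter(s): ",
         paste(bad, collapse = ", "))
  if (p$phiQ >= 1)
    stop("cgmParameters: phiQ must lie in (0, 1)")
  if (p$alpha_Fp_max >= 1 - p$phiQ)
    stop("cgmParameters: alpha_Fp_max must be below 1 - phiQ, got ",
         p$alpha_Fp_max, " vs ", 1 - p$phiQ)
  if (p$alpha_R_max >= 1)
    stop("cgmParameters: alpha_R_max must be below 1")
  class(p) <- "cgm_parameters"
  p
}

#' Three-phase feed schedule
#'
#' Phase 1 is a batch (no feed). Phase 2 (biomass production) feeds
#' glycerol with L-phe/L-tyr supplements using a closed-loop exponential
#' law targeting the growth-rate set point. Phase 3 (induced production)
#' feeds concentrated glycerol at a fixed biomass-specific rate.
#'
#' @param t_batch_end end of the batch phase \[h\].
#' @param t_induction induction time = start of the production phase \[h\];
#'   must exceed `t_batch_end`.
#' @param t_end process end \[h\].
#' @param S_feed2,S_feed3 glycerol concentration of feed 2 / feed 3 \[g/L\].
#' @param P_feed2,Y_feed2 L-phe / L-tyr concentration of feed 2 \[g/L\].
#' @param iptg_mM inducer concentration applied from `t_induction` on \[mM\].
#'
#' @return A named list of class `feed_schedule`.
#' @export
feedSchedule <- function(t_batch_end, t_induction, t_end = 70,
                         S_feed2 = 312.5, S_feed3 = 800,
                         P_feed2 = 1.65, Y_feed2 = 3.75,
                         iptg_mM = 0.3) {
  if (!(t_batch_end > 0 && t_induction > t_batch_end))
    stop("feedSchedule: need 0 < t_batch_end < t_induction")
  if (t_end <= t_induction)
    stop("feedSchedule: t_end must exceed t_induction")
  s <- list(t_batch_end = t_batch_end, t_induction = t_induction,
            t_end = t_end, S_feed2 = S_feed2, S_feed3 = S_feed3,
            P_feed2 = P_feed2, Y_feed2 = Y_feed2, iptg = iptg_mM)
  class(s) <- "feed_schedule"
  s
}

#' Process phase at a given time
#'
#' @param t time \[h\] (vectorized).
#' @param schedule a [feedSchedule()].
#' @return Integer vector in `{1, 2, 3}`.
#' @export
activePhase <- function(t, schedule) {
  1L + (t >= schedule$t_batch_end) + (t >= schedule$t_induction)
}

#' Inducer concentration at a given time
#'
#' IPTG is a schedule input (zero before induction), not a dynamic state.
#'
#' @inheritParams activePhase
#' @return IPTG concentration \[mM\] (vectorized over `t`).
#' @export
iptgAt <- function(t, schedule) {
  ifelse(t >= schedule$t_induction, schedule$iptg, 0)
}

#' Default initial state of the reference process
#'
#' 1 L starting volume with 4 g/L glycerol, an inoculum corresponding to
#' OD600 0.05 (about 0.017 g/L dry weight), a small L-tyrosine supply, and
#' preculture-like proteome fractions.
#'
#' @return Named numeric vector of length 10 (see [stateNames]).
#' @export
defaultInitialState <- function() {
  c(V = 1, S = 4, X = 0.017, P = 0, A = 0, Y = 0.05,
    phiT = 0.32, phiR = 0.2, phiFp = 1e-4, m = 0.1)
}

#' Validate a state vector of the coarse-grained model
#'
#' Checks length, finiteness, nonnegativity, strictly positive volume and
#' the proteome closure `phiT + phiR + phiFp <= 1 - phiQ` (the metabolite
#' pool `m` is not protein and is bounded only by nonnegativity).
#'
#' @param state numeric vector of length 10.
#' @param params a [cgmParameters()].
#' @param tol slack allowed on the inequality constraints.
#' @return Invisibly `state`; signals an error when invalid.
#' @export
validateState <- function(state, params, tol = 1e-8) {
  if (length(state) != 10)
    stop("validateState: state vector must have length 10, got ",
         length(state))
  if (any(!is.finite(state)))
    stop("validateState: non-finite state component")
  if (state[[1]] <= 0)
    stop("validateState: volume must be strictly positive")
  if (any(state < -tol))
    stop("validateState: negative state component(s): ",
         paste(stateNames[state < -tol], collapse = ", "))
  phisum <- state[[7]] + state[[8]] + state[[9]]
  if (phisum > 1 - params$phiQ + tol)
    stop("validateState: proteome fractions exceed 1 - phiQ (",
         signif(phisum, 4), " > ", 1 - params$phiQ, ")")
  invisible(state)
}

#' Read / write model configuration as YAML
#'
#' Parameters and schedule are stored with explicit units in the key names
#' so a different model parameterization can be swapped in without code
#' changes.
#'
#' @param params a [cgmParameters()].
#' @param schedule a [feedSchedule()].
#' @param path file path to write to / read from.
#' @return `writeModelConfig` returns `path` invisibly; `readModelConfig`
#'   returns `list(params =, schedule =)`.
#' @export
writeModelConfig <- function(params, schedule, path) {
  cfg <- list(
    parameters = list(
      kT_per_h = params$kT, kR_per_h = params$kR, kF_per_h = params$kF,
      KS_g_l = params$KS, KmR = params$KmR, KmF = params$KmF,
      KY_g_l = params$KY, cY_g_g = params$cY,
      Y_MS = params$Y_MS, Y_XM = params$Y_XM, Y_PM = params$Y_PM,
      Y_AM = params$Y_AM, v_crit_g_gh = params$v_crit, kA = params$kA,
      phiQ = params$phiQ, alpha_Fp_max = params$alpha_Fp_max,
      alpha_R_max = params$alpha_R_max, KI_mM = params$KI,
      mu_set_per_h = params$mu_set, q_feed3_g_gh = params$q_feed3,
      Y_XS_eff = params$Y_XS_eff),
    schedule = list(
      t_batch_end_h = schedule$t_batch_end,
      t_induction_h = schedule$t_induction,
      t_end_h = schedule$t_end,
      S_feed2_g_l = schedule$S_feed2, S_feed3_g_l = schedule$S_feed3,
      P_feed2_g_l = schedule$P_feed2, Y_feed2_g_l = schedule$Y_feed2,
      iptg_mM = schedule$iptg))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname writeModelConfig
#' @export
readModelConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  p <- cfg$parameters
  s <- cfg$schedule
  list(
    params = do.call(cgmParameters, p),
    schedule = feedSchedule(
      t_batch_end = s$t_batch_end_h, t_induction = s$t_induction_h,
      t_end = s$t_end_h, S_feed2 = s$S_feed2_g_l, S_feed3 = s$S_feed3_g_l,
      P_feed2 = s$P_feed2_g_l, Y_feed2 = s$Y_feed2_g_l, iptg_mM = s$iptg_mM))
}
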