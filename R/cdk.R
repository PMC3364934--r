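# Reduced Cdk network: a relaxation oscillator built from two coupled
# switches -- a G1/S module (E2F-driven cyclin A antagonising Cdh1, gated by
# growth factor through cyclin D and pRB/E2F) and the mitotic module (cyclin B
# accumulation gated by Cdh1, bistable Cdk1 activation through the
# Wee1/Cdc25 double positive feedback, mitotic exit through Cdc20).  p21
# inhibits Cdk2/Cdk1 as quasi-equilibrium activity factors 1/(1+P/K); Wee1
# also damps Cdk2 with relative weight rho2 < 1.  The global factor s rescales
# every Cdk-network derivative, so eps-style period calibration is exact
# arithmetic.

.cdk_activity_factors <- function(states, p) {
  list(fp1 = 1 / (1 + states[, "P"] / p$K_ip1),
       fp2 = 1 / (1 + states[, "P"] / p$K_ip2),
       fw2 = 1 / (1 + p$rho2 * states[, "W"] / p$K_iw2))
}

.cdk_observables <- function(getp = function(p) p) {
  list(
    Cdk1 = function(times, states, params) {
      f <- .cdk_activity_factors(states, getp(params))
      states[, "Mb"] * f$fp1
    },
    Cdk2 = function(times, states, params) {
      f <- .cdk_activity_factors(states, getp(params))
      (states[, "Me"] + states[, "Ma"]) * f$fp2 * f$fw2
    },
    Me_act = function(times, states, params) {
      f <- .cdk_activity_factors(states, getp(params))
      states[, "Me"] * f$fp2 * f$fw2
    },
    Ma_act = function(times, states, params) {
      f <- .cdk_activity_factors(states, getp(params))
      states[, "Ma"] * f$fp2 * f$fw2
    },
    Wee1 = function(times, states, params) states[, "W"])
}

#' Cdk-network right-hand side (reference R implementation)
#'
#' State: \code{(Rb, E2F, Md, Me, Ma, Cb, Mb, W, C25, Ch1, A20, P, X)}.
#' \code{inputs} supplies the circadian protein-synthesis contributions
#' (\code{wee1} = k_sw*Mw, \code{p21} = v_s1p21*Mp21, \code{cyclinE} =
#' k_ce2*Mce), zero in autonomous mode.  The compiled rhs used by the
#' integrator is checked against this function.
#'
#' @param state numeric length-13 state.
#' @param params a \code{\link{cdk_params}}.
#' @param inputs named numeric: \code{wee1}, \code{p21}, \code{cyclinE}
#'   synthesis contributions (uM/h).
#' @param t time, h (unused; the autonomous network is time-invariant).
#' @return derivative vector, uM/h.
#' @export
cdk_rhs <- function(state, params = cdk_params(),
                    inputs = c(wee1 = 0, p21 = 0, cyclinE = 0), t = 0) {
  p <- params
  st <- pmax(state, 0)
  Rb <- st[1]; E2F <- st[2]; Md <- st[3]; Me <- st[4]; Ma <- st[5]
  Cb <- st[6]; Mb <- st[7]; W <- st[8]; C25 <- state[9]; Ch1 <- state[10]
  A20 <- state[11]; P <- st[12]; X <- st[13]
  in_w <- if ("wee1" %in% names(inputs)) inputs[["wee1"]] else 0
  in_p <- if ("p21" %in% names(inputs)) inputs[["p21"]] else 0
  in_e <- if ("cyclinE" %in% names(inputs)) inputs[["cyclinE"]] else 0

  mm <- function(x, K) x / (K + x)
  pos <- function(x) pmax(x, 0)
  fp1 <- 1 / (1 + P / p$K_ip1)
  fp2 <- 1 / (1 + P / p$K_ip2)
  fw2 <- 1 / (1 + p$rho2 * W / p$K_iw2)
  Mea <- Me * fp2 * fw2; Maa <- Ma * fp2 * fw2; Mba <- Mb * fp1
  E2Fa <- E2F * p$K_IRb^p$n_IRb / (p$K_IRb^p$n_IRb + Rb^p$n_IRb)
  pool25 <- p$v_spbi / p$v_spbi_ref
  kdegB <- p$k_db + p$k_dbch * pos(Ch1) + p$k_dba * pos(A20)

  d <- c(
    p$v_spRB - p$k_dRb * Rb -
      p$k_pRb * (Md + p$c_e * Mea) * mm(Rb, p$K_pRb),
    p$v_sE2F - p$k_dE2F * E2F - p$k_dE2Fa * Maa * E2F,
    p$v_sd * mm(p$GF, p$K_agf) - p$k_dd * Md - p$k_ddb * Mba * Md,
    p$v_se * E2Fa + in_e - p$k_de * Me - p$k_dea * Maa * Me,
    p$v_sa * E2Fa - p$k_da * Ma - p$k_dach * pos(Ch1) * Ma -
      p$k_daa * pos(A20) * Ma,
    p$v_cb - kdegB * Cb,
    (p$V_250 + p$V_25 * pos(C25)) * pool25 * pos(Cb - Mb) -
      p$k_iw * W * Mb - kdegB * Mb,
    p$v_swee1 + in_w - p$k_dw * W - p$V_iw * Mba * mm(W, p$K_iww),
    p$V_a25 * Mba / (1 + X / p$K_xc) * mm(pos(1 - C25), p$K_ac25) -
      p$V_i25 * mm(pos(C25), p$K_ic25),
    p$V_ach * mm(pos(1 - Ch1), p$K_ach) -
      (p$k_icha * Maa + p$k_ichb * Mba) * mm(pos(Ch1), p$K_ich),
    p$V_a20 * Mba * mm(pos(1 - A20), p$K_a20) -
      p$V_i20 * mm(pos(A20), p$K_i20),
    p$v_bp21 + p$v_ep21 * E2Fa + in_p - p$k_dp21 * P,
    p$k_aatr * (Mea + Maa) * pos(p$X_tot - X) - p$k_dx * X)
  bad <- which(!is.finite(d))
  if (length(bad))
    stop("non-finite Cdk derivative for state '",
         .cdk_state_names[bad[1]], "'")
  p$s * d
}

.cdk_default_init <- c(Rb = 2, E2F = 0.5, Md = 0.1, Me = 0.05, Ma = 0.05,
                       Cb = 0.03, Mb = 0.003, W = 0.24, C25 = 0, Ch1 = 1,
                       A20 = 0, P = 0.01, X = 0)

#' Build the reduced Cdk-network model
#'
#' @param params a \code{\link{cdk_params}}.
#' @return a \code{\link{model_spec}} with observables \code{Cdk1} (active
#'   cyclin B/Cdk1), \code{Cdk2} (active cyclin E/Cdk2 + cyclin A/Cdk2),
#'   \code{Me_act}, \code{Ma_act} and \code{Wee1}.
#' @export
cdk_model <- function(params = cdk_params()) {
  model_spec(
    state_names = .cdk_state_names,
    rhs = function(t, state, p) cdk_rhs(state, p, t = t),
    params = params,
    observables = .cdk_observables(),
    default_init = .cdk_default_init,
    native = list(model = "cdk", pack = .pack_cdk),
    name = "cdk network (autonomous)")
}

#' Autonomous period of the Cdk network
#'
#' Integrates the uncoupled network (Wee1 fed only by its basal synthesis)
#' and reports the limit-cycle period measured on the Cdk1 observable, or
#' quiescence when a stable steady state is found.
#'
#' @param params a \code{\link{cdk_params}}.
#' @param config optional \code{\link{simulation_config}}; the default spans
#'   at least ten cycles at the slowest plausible period for the given
#'   time-scale \code{s}.
#' @return list with \code{status} (\code{"oscillatory"}, \code{"quiescent"}
#'   or \code{"undecided"}), \code{period} (h or NA) and the
#'   \code{attractor}.
#' @export
autonomous_period <- function(params = cdk_params(), config = NULL) {
  if (is.null(config)) {
    t_end <- max(480, 480 / params$s)
    config <- simulation_config(t_end = t_end, t_transient = t_end / 3,
                                dt_out = min(0.1, 0.1 / params$s))
  }
  att <- find_attractor(cdk_model(params), config = config,
                        ref_observable = "Cdk1")
  if (att$type == "steady_state")
    return(list(status = "quiescent", period = NA_real_, attractor = att))
  if (att$type == "limit_cycle")
    return(list(status = "oscillatory", period = att$period,
                cv = att$period_cv, attractor = att))
  list(status = "undecided", period = NA_real_, attractor = att)
}

#' Growth-factor threshold for oscillation onset
#'
#' Bisects GF in [0, 1] uM for the boundary between quiescence and sustained
#' oscillation of the default network.
#'
#' @param params a \code{\link{cdk_params}}.
#' @param tol bisection tolerance on GF (uM).
#' @return the critical GF (uM).
#' @export
gf_threshold <- function(params = cdk_params(), tol = 1e-3) {
  osc_at <- function(gf) {
    params$GF <- gf
    autonomous_period(params)$status == "oscillatory"
  }
  lo <- 0; hi <- 1
  if (osc_at(lo) || !osc_at(hi))
    stop("no threshold in range [0, 1] uM")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (osc_at(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
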