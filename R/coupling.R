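# The three molecular coupling channels between the circadian clock and the
# Cdk network: clock-controlled mRNA balances for Wee1 (induced by
# CLOCK-BMAL1), p21 (repressed by REV-ERBalpha) and cyclin E (repressed,
# via c-Myc, by CLOCK-BMAL1), and assembly of the unidirectionally forced
# coupled system.  Units bridge: Bn and Rn arrive in nM from the clock, the
# mRNAs and proteins are in uM; the Hill ratios Bn/K_aw, Rn/K_ip21, Bn/K_ice
# are dimensionless so no conversion is applied.

#' Wee1 mRNA balance
#'
#' \code{dMw/dt = v_sw * Bn^nmw / (K_aw^nmw + Bn^nmw)
#'   - V_dmw * Mw / (K_dmw + Mw)}.
#'
#' @param Mw Wee1 mRNA, uM.
#' @param Bn CLOCK-BMAL1, nM.
#' @param p a \code{\link{coupling_params}}.
#' @return net rate, uM/h (vectorised over \code{Mw}, \code{Bn}).
#' @export
wee1_mrna_rhs <- function(Mw, Bn, p = coupling_params()) {
  syn <- ifelse(Bn <= 0, 0,
                p$v_sw * Bn^p$nmw / (p$K_aw^p$nmw + Bn^p$nmw))
  syn - p$V_dmw * Mw / (p$K_dmw + Mw)
}

#' Wee1 protein synthesis rate
#'
#' Basal synthesis plus the clock-dependent term: \code{v_swee1 + k_sw * Mw}.
#' This feeds the Wee1 protein balance of the Cdk network, which supplies its
#' own degradation and Cdk1-driven inactivation terms.
#'
#' @param Mw Wee1 mRNA, uM.
#' @param p a \code{\link{coupling_params}} (supplies \code{k_sw}).
#' @param v_swee1 basal Wee1 synthesis rate, uM/h.
#' @return synthesis rate, uM/h.
#' @export
wee1_protein_synthesis <- function(Mw, p = coupling_params(),
                                   v_swee1 = 0.06) {
  v_swee1 + p$k_sw * Mw
}

#' p21 coupling channel
#'
#' mRNA: \code{dMp21/dt = v_smp21 * K_ip21^n / (K_ip21^n + Rn^n)
#'   - V_dmp21 * Mp21 / (K_dmp21 + Mp21)} (repression by REV-ERBalpha);
#' the protein gains \code{v_s1p21 * Mp21} on top of the clock-independent
#' basal + E2F-activated term supplied by the Cdk network.
#'
#' @param Mp21 p21 mRNA, uM.
#' @param Rn REV-ERBalpha, nM.
#' @param p a \code{\link{coupling_params}}.
#' @return list with \code{mrna_rate} (uM/h) and
#'   \code{protein_contribution} (uM/h).
#' @export
p21_coupling_rhs <- function(Mp21, Rn, p = coupling_params()) {
  n <- p$nmp21
  syn <- p$v_smp21 * p$K_ip21^n / (p$K_ip21^n + pmax(Rn, 0)^n)
  list(mrna_rate = syn - p$V_dmp21 * Mp21 / (p$K_dmp21 + Mp21),
       protein_contribution = p$v_s1p21 * Mp21)
}

#' Cyclin E coupling channel
#'
#' mRNA: \code{dMce/dt = v_sce * K_ice^n / (K_ice^n + Bn^n)
#'   - V_dmce * Mce / (K_dmce + Mce)} (indirect repression by CLOCK-BMAL1
#' through c-Myc); the protein gains \code{k_ce2 * Mce} on top of the
#' E2F-activated, pRB-inhibited term supplied by the Cdk network.
#'
#' @param Mce cyclin E mRNA, uM.
#' @param Bn CLOCK-BMAL1, nM.
#' @param p a \code{\link{coupling_params}}.
#' @return list with \code{mrna_rate} (uM/h) and
#'   \code{protein_contribution} (uM/h).
#' @export
cyclinE_coupling_rhs <- function(Mce, Bn, p = coupling_params()) {
  n <- p$nce
  syn <- p$v_sce * p$K_ice^n / (p$K_ice^n + pmax(Bn, 0)^n)
  list(mrna_rate = syn - p$V_dmce * Mce / (p$K_dmce + Mce),
       protein_contribution = p$k_ce2 * Mce)
}

#' Assemble the coupled clock / cell-cycle system
#'
#' Concatenates the clock and Cdk-network states with the three
#' clock-controlled mRNA species and routes the protein-synthesis
#' contributions of the active channels into the Cdk network.  Forcing is
#' unidirectional: there is no feedback from the cell cycle onto the clock.
#' In mu-mode every active mRNA synthesis term is multiplied by \code{mu}
#' with the three maximal rates pinned to 1 uM/h.
#'
#' @param cdk a \code{\link{cdk_params}} or the \code{\link{model_spec}} from
#'   \code{\link{cdk_model}}.
#' @param clock a \code{\link{clock_params}} or the \code{\link{model_spec}}
#'   from \code{\link{clock_model}}.
#' @param coupling a \code{\link{coupling_params}}.
#' @return a \code{\link{model_spec}} over the 20-variable coupled state with
#'   observables \code{Cdk1}, \code{Cdk2}, \code{Me_act}, \code{Ma_act},
#'   \code{Wee1}, \code{BMAL1}, \code{REVERB}, \code{PER}, \code{Wee1_mRNA},
#'   \code{p21_mRNA}, \code{cycE_mRNA}.
#' @export
assemble_coupled_system <- function(cdk = cdk_params(),
                                    clock = clock_model(),
                                    coupling = coupling_params()) {
  cdk_p <- if (inherits(cdk, "model_spec")) cdk$params else cdk
  clock_init <- if (inherits(clock, "model_spec")) clock$default_init
                else c(Mp = 1, PER = 1, Mr = 0.3, Rn = 0.5)
  clock_p <- if (inherits(clock, "model_spec")) clock$params else clock
  stopifnot(inherits(cdk_p, "cdk_params"), inherits(clock_p, "clock_params"),
            inherits(coupling, "coupling_params"))
  if (!is.null(coupling$mu) &&
      !all(c(coupling$v_sw, coupling$v_smp21, coupling$v_sce) == 1))
    stop("mu-mode requires v_sw = v_smp21 = v_sce = 1 uM/h")
  params <- structure(list(clock = clock_p, cdk = cdk_p,
                           coupling = coupling), class = "coupled_params")
  state_names <- c(.clock_state_names, .cdk_state_names,
                   .coupling_state_names)
  rhs <- function(t, state, p) {
    sc <- state[1:4]; sd <- state[5:17]; sm <- pmax(state[18:20], 0)
    Bn <- bmal1_level(max(state[2], 0), p$clock, max(state[4], 0))
    Rn <- max(state[4], 0)
    cp <- p$coupling
    dm <- c(cp$mu_w * wee1_mrna_rhs_scaled(sm[1], Bn, cp),
            cp$mu_p * p21_syn(Rn, cp),
            cp$mu_c * ce_syn(Bn, cp)) -
      c(cp$V_dmw * sm[1] / (cp$K_dmw + sm[1]),
        cp$V_dmp21 * sm[2] / (cp$K_dmp21 + sm[2]),
        cp$V_dmce * sm[3] / (cp$K_dmce + sm[3]))
    inputs <- c(wee1 = cp$k_sw * sm[1], p21 = cp$v_s1p21 * sm[2],
                cyclinE = cp$k_ce2 * sm[3])
    c(clock_rhs(sc, p$clock, t),
      cdk_rhs(sd, p$cdk, inputs, t),
      dm)
  }
  obs <- c(.cdk_observables(function(p) p$cdk),
           .clock_observables(function(p) p$clock),
           list(Wee1_mRNA = function(times, states, params) states[, "Mw"],
                p21_mRNA = function(times, states, params) states[, "Mp21"],
                cycE_mRNA = function(times, states, params) states[, "Mce"]))
  model_spec(
    state_names = state_names,
    rhs = rhs,
    params = params,
    observables = obs,
    default_init = c(clock_init, .cdk_default_init,
                     Mw = 0, Mp21 = 0, Mce = 0),
    native = list(model = "coupled", pack = function(p)
      c(.pack_clock(p$clock), .pack_cdk(p$cdk), .pack_coupling(p$coupling))),
    breaks_fn = function(t0, t1, p) .clock_breaks(t0, t1, p$clock),
    name = "coupled clock + cdk network")
}

# synthesis-only helpers used by the composite R rhs (degradation is applied
# once, outside the mu multiplier, matching the compiled rhs)
wee1_mrna_rhs_scaled <- function(Mw, Bn, p) {
  if (Bn <= 0) 0 else p$v_sw * Bn^p$nmw / (p$K_aw^p$nmw + Bn^p$nmw)
}
p21_syn <- function(Rn, p)
  p$v_smp21 * p$K_ip21^p$nmp21 / (p$K_ip21^p$nmp21 + max(Rn, 0)^p$nmp21)
ce_syn <- function(Bn, p)
  p$v_sce * p$K_ice^p$nce / (p$K_ice^p$nce + max(Bn, 0)^p$nce)
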