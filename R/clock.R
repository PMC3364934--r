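# Reduced mammalian circadian clock: Per mRNA / PER protein negative feedback
# with saturating (zero-order) degradation, CLOCK-BMAL1 (Bn) as an algebraic
# observable repressed by PER, and REV-ERBalpha (Rn) induced downstream of Bn
# through its own mRNA (so the Rn peak lags the Bn peak).  Light acts as a
# square-wave increment on the Per transcription rate.

#' Light-dark schedule
#'
#' @param L_duration light-phase duration (h), default 16.
#' @param D_duration dark-phase duration (h), default 8.
#' @param phase_origin time (h) at which a light phase begins; the package
#'   convention is that t = 0 starts an L phase.
#' @return an object of class \code{ld_schedule}.
#' @export
ld_schedule <- function(L_duration = 16, D_duration = 8, phase_origin = 0) {
  stopifnot(L_duration > 0, D_duration > 0)
  structure(list(L_duration = L_duration, D_duration = D_duration,
                 phase_origin = phase_origin), class = "ld_schedule")
}

#' Light-driven Per transcription rate
#'
#' Square wave: \code{v_sP_basal} during darkness, plus the light increment
#' (0.3 nM/h by default) during the light phase.
#'
#' @param t time(s), h.
#' @param schedule an \code{\link{ld_schedule}}.
#' @param params a \code{\link{clock_params}}.
#' @return Per mRNA synthesis rate(s), nM/h.
#' @export
ld_drive <- function(t, schedule = ld_schedule(), params = clock_params()) {
  stopifnot(all(t >= -1e9))
  per <- schedule$L_duration + schedule$D_duration
  u <- (t - schedule$phase_origin) %% per
  params$v_sP_basal +
    ifelse(u < schedule$L_duration, params$v_sP_light_increment, 0)
}

#' CLOCK-BMAL1 level from PER
#'
#' \code{Bn = B_tot * K_BP^n / (K_BP^n + PER^n)}: with no PER, Bn equals
#' \code{B_tot}; PER represses Bn activity.  When \code{n_RB > 0}, nuclear
#' REV-ERBalpha further represses Bn (reduced stand-in for its repression of
#' Bmal1 transcription).  A non-negative \code{bn_clamp} in the parameters
#' (Cry-deletion emulation) overrides the computed value.
#'
#' @param per PER concentration(s), nM.
#' @param params a \code{\link{clock_params}}.
#' @param rn REV-ERBalpha concentration(s), nM (used when \code{n_RB > 0}).
#' @return Bn, nM.
#' @export
bmal1_level <- function(per, params = clock_params(), rn = 0) {
  if (params$bn_clamp >= 0)
    return(rep(params$bn_clamp, max(length(per), length(rn))))
  b <- params$B_tot * params$K_BP^params$n_BP /
    (params$K_BP^params$n_BP + pmax(per, 0)^params$n_BP)
  if (params$n_RB > 0)
    b <- b * params$K_RB^params$n_RB /
      (params$K_RB^params$n_RB + pmax(rn, 0)^params$n_RB)
  b
}

#' Clock right-hand side (reference R implementation)
#'
#' State: \code{(Mp, PER, Mr, Rn)} -- Per mRNA, PER protein, Rev-Erba mRNA,
#' nuclear REV-ERBalpha, all nM.  The compiled rhs used by the integrator is
#' checked against this function.
#'
#' @param state numeric length-4 state.
#' @param params a \code{\link{clock_params}}.
#' @param t time, h.
#' @param schedule optional \code{\link{ld_schedule}} overriding the LD
#'   fields stored in \code{params}.
#' @return derivative vector, nM/h.
#' @export
clock_rhs <- function(state, params = clock_params(), t = 0,
                      schedule = NULL) {
  if (any(state < -1e-6)) stop("negative clock state beyond tolerance")
  st <- pmax(state, 0)
  Mp <- st[1]; PER <- st[2]; Mr <- st[3]; Rn <- st[4]
  if (!is.null(schedule)) {
    params$L_duration <- schedule$L_duration
    params$D_duration <- schedule$D_duration
    params$phase_origin <- schedule$phase_origin
  }
  vsP <- if (params$ld_on > 0.5)
    ld_drive(t, ld_schedule(params$L_duration, params$D_duration,
                            params$phase_origin), params)
  else params$v_sP_basal
  Bn <- bmal1_level(PER, params, Rn)
  hillrep <- function(x, K, n) K^n / (K^n + x^n)
  hill <- function(x, K, n) if (x <= 0) 0 else x^n / (K^n + x^n)
  mm <- function(x, K) x / (K + x)
  act <- if (params$K_ab > 0) hill(Bn, params$K_ab, params$n_ab) else 1
  # PER degradation saturates and is protected at high PER (complex
  # formation); the protection term makes the Per loop self-sustained
  degP <- params$v_dP * PER /
    (params$K_dP + PER +
       if (params$K_st > 0) PER^2 / params$K_st else 0)
  c(vsP * hillrep(PER, params$K_IP, params$n_P) * act -
      params$v_mP * mm(Mp, params$K_mP),
    params$k_sP * Mp - degP,
    params$v_sr * hill(Bn, params$K_ar, params$n_r) -
      params$v_mr * mm(Mr, params$K_mr),
    params$k_sr * Mr - params$v_dr * mm(Rn, params$K_dr))
}

.clock_breaks <- function(t0, t1, params) {
  if (params$ld_on <= 0.5) return(numeric())
  per <- params$L_duration + params$D_duration
  k <- floor((t0 - params$phase_origin) / per):ceiling(
    (t1 - params$phase_origin) / per)
  br <- sort(c(params$phase_origin + k * per,
               params$phase_origin + params$L_duration + k * per))
  br[br > t0 & br < t1]
}

.clock_observables <- function(getp = function(p) p) {
  list(
    BMAL1 = function(times, states, params)
      bmal1_level(states[, "PER"], getp(params), states[, "Rn"]),
    REVERB = function(times, states, params) states[, "Rn"],
    PER = function(times, states, params) states[, "PER"],
    Per_mRNA = function(times, states, params) states[, "Mp"])
}

#' Build the reduced clock model
#'
#' @param params a \code{\link{clock_params}}.
#' @param ld logical: apply the LD square wave (\code{FALSE} gives the
#'   free-running clock).
#' @param schedule an \code{\link{ld_schedule}} copied into the parameters.
#' @return a \code{\link{model_spec}} with observables \code{BMAL1},
#'   \code{REVERB}, \code{PER}, \code{Per_mRNA}.
#' @export
clock_model <- function(params = clock_params(), ld = TRUE,
                        schedule = ld_schedule()) {
  params$ld_on <- as.numeric(ld)
  params$L_duration <- schedule$L_duration
  params$D_duration <- schedule$D_duration
  params$phase_origin <- schedule$phase_origin
  model_spec(
    state_names = .clock_state_names,
    rhs = function(t, state, p) clock_rhs(state, p, t),
    params = params,
    observables = .clock_observables(),
    default_init = c(Mp = 1, PER = 1, Mr = 0.3, Rn = 0.5),
    native = list(model = "clock", pack = .pack_clock),
    breaks_fn = .clock_breaks,
    name = if (ld) "clock (LD-forced)" else "clock (free-running)")
}
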