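# Parameter containers for the three model layers.  Each constructor returns a
# validated named list; .pack_*() flattens it into the numeric vector layout
# expected by the compiled right-hand sides (orders here and in src/engine.cpp
# must match -- a dual-route test compares the two rhs implementations).

.clock_param_names <- c(
  "v_sP_basal", "v_sP_light_increment", "K_IP", "n_P", "v_mP", "K_mP", "k_sP",
  "v_dP", "K_dP", "K_st", "B_tot", "K_BP", "n_BP", "K_RB", "n_RB", "K_ab",
  "n_ab", "v_sr", "K_ar", "n_r", "v_mr", "K_mr",
  "k_sr", "v_dr", "K_dr", "ld_on", "L_duration", "D_duration", "phase_origin",
  "bn_clamp")

.cdk_param_names <- c(
  "s", "GF", "K_agf", "v_sd", "k_dd", "k_ddb",
  "v_spRB", "k_dRb", "k_pRb", "K_pRb", "c_e", "K_IRb", "n_IRb",
  "v_sE2F", "k_dE2F", "k_dE2Fa",
  "v_se", "k_de", "k_dea",
  "v_sa", "k_da", "k_dach", "k_daa",
  "v_cb", "k_db", "k_dbch", "k_dba",
  "V_250", "V_25", "k_iw", "v_swee1", "k_dw", "V_iw", "K_iww",
  "V_a25", "V_i25", "K_ac25", "K_ic25", "K_xc",
  "V_ach", "k_icha", "k_ichb", "K_ach", "K_ich",
  "V_a20", "V_i20", "K_a20", "K_i20",
  "v_bp21", "v_ep21", "k_dp21", "K_ip1", "K_ip2",
  "rho2", "K_iw2", "k_aatr", "k_dx", "X_tot",
  "v_spbi", "v_spbi_ref")

.coupling_param_names <- c(
  "mu_w", "mu_p", "mu_c",
  "v_sw", "K_aw", "nmw", "V_dmw", "K_dmw", "k_sw",
  "v_smp21", "K_ip21", "nmp21", "V_dmp21", "K_dmp21", "v_s1p21",
  "v_sce", "K_ice", "nce", "V_dmce", "K_dmce", "k_ce2")

.clock_state_names <- c("Mp", "PER", "Mr", "Rn")
.cdk_state_names <- c("Rb", "E2F", "Md", "Me", "Ma", "Cb", "Mb", "W", "C25",
                      "Ch1", "A20", "P", "X")
.coupling_state_names <- c("Mw", "Mp21", "Mce")

#' Parameters of the reduced circadian clock
#'
#' A four-variable reduced mammalian circadian oscillator: Per mRNA, PER
#' protein, Rev-Erba mRNA and nuclear REV-ERBalpha (Rn).  Nuclear CLOCK-BMAL1
#' (Bn) is an algebraic observable, repressed by PER:
#' \code{Bn = B_tot * K_BP / (K_BP + PER)}.  Concentrations are in nM, time in
#' hours.  The default set free-runs with a period of about 23.8 h and locks
#' to 24 h under a 16:8 LD cycle acting on Per transcription, with PER peaking
#' at the end of the light phase and Bn peaking during the dark phase.
#'
#' @param ... name = value overrides of the default parameter set.
#' @return an object of class \code{clock_params} (a named list).
#' @export
clock_params <- function(...) {
  p <- list(
    v_sP_basal = 0.5, v_sP_light_increment = 0.3,
    K_IP = 1, n_P = 4, v_mP = 0.25, K_mP = 0.3,
    k_sP = 0.45, v_dP = 1.05, K_dP = 0.3, K_st = 1,
    B_tot = 6.38, K_BP = 0.8, n_BP = 1, K_RB = 0.25, n_RB = 4,
    K_ab = 0, n_ab = 4,
    v_sr = 0.6, K_ar = 1.276, n_r = 2, v_mr = 0.3, K_mr = 0.2,
    k_sr = 0.1, v_dr = 0.1, K_dr = 0.025,
    ld_on = 1, L_duration = 16, D_duration = 8, phase_origin = 0,
    bn_clamp = -1)
  p <- .apply_overrides(p, list(...), "clock_params")
  num <- setdiff(names(p), c("ld_on", "bn_clamp"))
  stopifnot(all(vapply(p[num], function(x) is.numeric(x) && x >= 0, TRUE)))
  stopifnot(p$L_duration > 0, p$D_duration > 0)
  structure(p, class = "clock_params")
}

#' Parameters of the reduced Cdk network
#'
#' A thirteen-variable reduced cyclin/Cdk network: active pRB, E2F, the four
#' cyclin/Cdk complexes (cyclin D/Cdk4-6 \code{Md}, cyclin E/Cdk2 \code{Me},
#' cyclin A/Cdk2 \code{Ma}, total and active cyclin B/Cdk1 \code{Cb}/\code{Mb}),
#' Wee1 protein, active Cdc25 and the APC co-activators Cdh1 and Cdc20
#' (fractions), the Cdk inhibitor p21 and an optional ATR/Chk1 checkpoint
#' activity \code{X}.  Concentrations are in uM, time in hours.  All
#' Cdk-network derivatives are multiplied by the dimensionless time-scale
#' \code{s}, so the autonomous period obeys \code{T(s) = T(1)/s} exactly.
#'
#' Printed reference values kept by this container: \code{v_cb} (cyclin B
#' synthesis, uM/h), \code{v_spRB} (pRB synthesis), \code{v_spbi} (Cdc25
#' synthesis, acting as a Cdc25 pool scale relative to \code{v_spbi_ref}),
#' \code{v_swee1} (basal Wee1 synthesis) and \code{k_aatr} (checkpoint
#' activation, uM^-1 h^-1).
#'
#' @param ... name = value overrides of the default parameter set.
#' @return an object of class \code{cdk_params} (a named list).
#' @export
cdk_params <- function(...) {
  p <- list(
    s = 1, GF = 1, K_agf = 0.2,
    v_sd = 0.8, k_dd = 0.4, k_ddb = 2,
    v_spRB = 0.8, k_dRb = 0.4, k_pRb = 2, K_pRb = 2, c_e = 0.25,
    K_IRb = 0.45, n_IRb = 4,
    v_sE2F = 0.15, k_dE2F = 0.05, k_dE2Fa = 1.5,
    v_se = 0.4, k_de = 0.25, k_dea = 5,
    v_sa = 0.3, k_da = 0.1, k_dach = 1.5, k_daa = 20,
    v_cb = 0.055, k_db = 0.04, k_dbch = 1.5, k_dba = 3,
    V_250 = 0.4, V_25 = 8, k_iw = 20, v_swee1 = 0.06, k_dw = 0.25,
    V_iw = 4, K_iww = 0.1,
    V_a25 = 30, V_i25 = 1.2, K_ac25 = 0.01, K_ic25 = 0.01, K_xc = 0.3,
    V_ach = 1.5, k_icha = 20, k_ichb = 20, K_ach = 0.02, K_ich = 0.02,
    V_a20 = 10, V_i20 = 0.5, K_a20 = 0.005, K_i20 = 0.005,
    v_bp21 = 0.001, v_ep21 = 0.01, k_dp21 = 5, K_ip1 = 2, K_ip2 = 4,
    rho2 = 0.1, K_iw2 = 0.5,
    k_aatr = 0, k_dx = 0.05, X_tot = 1,
    v_spbi = 0.12, v_spbi_ref = 0.12)
  p <- .apply_overrides(p, list(...), "cdk_params")
  stopifnot(p$s > 0, all(vapply(p, function(x) is.numeric(x) && x >= 0, TRUE)))
  stopifnot(p$rho2 >= 0, p$rho2 < 1)
  structure(p, class = "cdk_params")
}

#' Parameters of the circadian coupling channels
#'
#' The three clock-controlled mRNA balances coupling the circadian clock to
#' the Cdk network: Wee1 mRNA induced by CLOCK-BMAL1, p21 mRNA repressed by
#' REV-ERBalpha and cyclin E mRNA repressed (via c-Myc) by CLOCK-BMAL1,
#' together with the rates at which each mRNA feeds its protein target.
#'
#' Coupling modes are selected with \code{modes} (any of \code{"wee1"},
#' \code{"p21"}, \code{"cyclinE"}).  With \code{mu = NULL} each active channel
#' uses its own maximal transcription rate (\code{v_sw}, \code{v_smp21},
#' \code{v_sce}).  In multi-coupling mode a single dimensionless strength
#' \code{mu} multiplies the transcription of every active channel while the
#' three rates are pinned to 1 uM/h; passing a different rate together with
#' \code{mu} is a validation error.
#'
#' @param modes character vector of active coupling channels.
#' @param mu dimensionless multi-coupling strength, or \code{NULL}.
#' @param ... name = value overrides of the default parameter set.
#' @return an object of class \code{coupling_params}.
#' @export
coupling_params <- function(modes = character(), mu = NULL, ...) {
  if (length(modes))
    modes <- match.arg(modes, c("wee1", "p21", "cyclinE"), several.ok = TRUE)
  p <- list(
    v_sw = 0.1, K_aw = 2, nmw = 4, V_dmw = 0.5, K_dmw = 0.5, k_sw = 5,
    v_smp21 = 0.46, K_ip21 = 0.05, nmp21 = 1, V_dmp21 = 0.5, K_dmp21 = 0.5,
    v_s1p21 = 50,
    v_sce = 0.1, K_ice = 1, nce = 4, V_dmce = 0.5, K_dmce = 0.5, k_ce2 = 5)
  dots <- list(...)
  if (!is.null(mu)) {
    stopifnot(is.numeric(mu), length(mu) == 1, mu >= 0)
    bad <- intersect(names(dots), c("v_sw", "v_smp21", "v_sce"))
    bad <- bad[vapply(bad, function(nm) !isTRUE(all.equal(dots[[nm]], 1)), TRUE)]
    if (length(bad))
      stop("in mu-mode the rates ", paste(bad, collapse = ", "),
           " must equal 1 uM/h exactly")
    p$v_sw <- p$v_smp21 <- p$v_sce <- 1
  }
  p <- .apply_overrides(p, dots, "coupling_params")
  stopifnot(all(vapply(p, function(x) is.numeric(x) && x >= 0, TRUE)))
  strength <- if (is.null(mu)) 1 else mu
  p$mu_w <- if ("wee1" %in% modes) strength else 0
  p$mu_p <- if ("p21" %in% modes) strength else 0
  p$mu_c <- if ("cyclinE" %in% modes) strength else 0
  structure(c(p, list(modes = modes, mu = mu)), class = "coupling_params")
}

.apply_overrides <- function(p, dots, what) {
  if (length(dots) == 0) return(p)
  if (is.null(names(dots)) || any(names(dots) == ""))
    stop(what, ": overrides must be named")
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop(what, ": unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  p
}

.pack_clock <- function(p) {
  stopifnot(inherits(p, "clock_params"))
  unlist(p[.clock_param_names], use.names = FALSE)
}

.pack_cdk <- function(p) {
  stopifnot(inherits(p, "cdk_params"))
  unlist(p[.cdk_param_names], use.names = FALSE)
}

.pack_coupling <- function(p) {
  stopifnot(inherits(p, "coupling_params"))
  unlist(p[.coupling_param_names], use.names = FALSE)
}

#' @export
print.clock_params <- function(x, ...) {
  cat("<clock_params> reduced 4-variable circadian clock\n")
  .print_params(unclass(x))
  invisible(x)
}

#' @export
print.cdk_params <- function(x, ...) {
  cat("<cdk_params> reduced 13-variable Cdk network (time scale s =",
      x$s, ")\n")
  .print_params(unclass(x))
  invisible(x)
}

#' @export
print.coupling_params <- function(x, ...) {
  cat("<coupling_params> modes:",
      if (length(x$modes)) paste(x$modes, collapse = ", ") else "(none)",
      if (!is.null(x$mu)) paste0(" [mu-mode, mu = ", x$mu, "]") else "", "\n")
  .print_params(x[.coupling_param_names])
  invisible(x)
}

.print_params <- function(p) {
  p <- p[vapply(p, is.numeric, TRUE)]
  v <- unlist(p)
  out <- paste0(names(v), "=", signif(v, 4))
  cat(strwrap(paste(out, collapse = "  "), width = 78, indent = 2,
              exdent = 2), sep = "\n")
}
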