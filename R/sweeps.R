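# Orchestration of the computational experiments: time-scale calibration,
# Arnold-tongue scans over (autonomous period x coupling strength),
# birhythmicity probes and named scenario presets mirroring the forcing
# protocols of the coupled-model study (coupling switched on at 120 h or
# 240 h, growth-factor square waves, checkpoint activation, Cry-deletion
# emulation).

.cache <- new.env(parent = emptyenv())

.cdk_key <- function(params) {
  v <- .pack_cdk(params)
  v[.cdk_param_names != "s"]
  paste(signif(v[which(.cdk_param_names != "s")], 12), collapse = ",")
}

#' Reference autonomous period of a Cdk parameter set at s = 1
#'
#' Measured once per distinct parameter set and cached for the session.
#'
#' @param params a \code{\link{cdk_params}}.
#' @return period (h) of the set with \code{s = 1}.
#' @export
reference_period <- function(params = cdk_params()) {
  key <- .cdk_key(params)
  hit <- .cache[[key]]
  if (!is.null(hit)) return(hit)
  p1 <- params
  p1$s <- 1
  r <- autonomous_period(p1)
  if (r$status != "oscillatory")
    stop("reference parameter set is not oscillatory at s = 1 (",
         r$status, ")")
  .cache[[key]] <- r$period
  r$period
}

#' Calibrate the global time-scale to a target autonomous period
#'
#' Under the uniform-scaling law \code{T(s) = T(1)/s} the required scale is
#' exact arithmetic: \code{s = T(1)/target}.  A verification integration
#' confirms the measured period to within 1 per cent (a failure signals a
#' non-uniform scaling bug, not a calibration problem).
#'
#' @param target_period desired autonomous period (h).
#' @param params a \code{\link{cdk_params}}.
#' @param verify logical: re-measure the period at the calibrated s.
#' @return the time-scale \code{s}.
#' @export
calibrate_timescale <- function(target_period, params = cdk_params(),
                                verify = TRUE) {
  stopifnot(target_period > 0)
  s <- reference_period(params) / target_period
  if (verify) {
    p <- params
    p$s <- s
    r <- autonomous_period(p)
    if (r$status != "oscillatory" ||
        abs(r$period - target_period) > 0.01 * target_period)
      stop("calibration verification failed: measured ",
           signif(r$period, 6), " h vs target ", target_period,
           " h -- non-uniform scaling?")
  }
  s
}

.coupling_for <- function(mode, value, base = NULL) {
  extra <- if (is.null(base)) list() else
    base[setdiff(.coupling_param_names,
                 c("mu_w", "mu_p", "mu_c", "v_sw", "v_smp21", "v_sce"))]
  switch(mode,
    wee1 = do.call(coupling_params,
                   c(list(modes = "wee1", v_sw = value), extra)),
    p21 = do.call(coupling_params,
                  c(list(modes = "p21", v_smp21 = value), extra)),
    cyclinE = do.call(coupling_params,
                      c(list(modes = "cyclinE", v_sce = value), extra)),
    mu = do.call(coupling_params,
                 c(list(modes = c("wee1", "p21", "cyclinE"), mu = value),
                   extra)),
    stop("unknown coupling mode '", mode, "'"))
}

#' Arnold-tongue scan
#'
#' For every grid cell: calibrate the time-scale to the cell's autonomous
#' period, assemble the coupled system at the cell's coupling strength,
#' integrate past the transient and classify the dynamics.  Cells are
#' independent; a per-cell failure is recorded as \code{"undecided"} and
#' never aborts the scan.
#'
#' @param period_grid autonomous periods (h).
#' @param coupling_grid coupling strengths (uM/h, or dimensionless for
#'   \code{mode = "mu"}).
#' @param mode one of \code{"wee1"}, \code{"p21"}, \code{"cyclinE"},
#'   \code{"mu"}.
#' @param cdk,clock base parameter sets.
#' @param t_transient,t_window transient discarded and analysis window (h)
#'   per cell; the defaults (240 + 720 h) cover at least 15 cycles of a
#'   48 h lock.
#' @param dt_out output step (h).
#' @param coupled_overrides named list of Cdk parameters overridden in the
#'   coupled system only (the autonomous calibration keeps the base set).
#'   The default removes the basal Wee1 synthesis, reflecting the protocol
#'   in which the circadian Wee1 balance replaces the constitutive one.
#' @param classify_args extra arguments for \code{\link{classify_config}}.
#' @return a \code{tongue_map}: axes, label matrix, mode and provenance
#'   digest.
#' @export
arnold_tongue_scan <- function(period_grid, coupling_grid, mode = "wee1",
                               cdk = cdk_params(), clock = clock_params(),
                               t_transient = 240, t_window = 720,
                               dt_out = 0.1,
                               coupled_overrides = list(v_swee1 = 0),
                               classify_args = list()) {
  stopifnot(length(period_grid) >= 1, length(coupling_grid) >= 1)
  labels <- matrix(NA_character_, length(period_grid), length(coupling_grid),
                   dimnames = list(paste0("T", period_grid),
                                   paste0("c", signif(coupling_grid, 6))))
  cfg <- simulation_config(t_end = t_transient + t_window,
                           t_transient = t_transient, dt_out = dt_out)
  ccfg <- do.call(classify_config,
                  c(list(t_transient = t_transient), classify_args))
  for (i in seq_along(period_grid)) {
    s <- tryCatch(calibrate_timescale(period_grid[i], cdk, verify = FALSE),
                  error = function(e) NA)
    for (j in seq_along(coupling_grid)) {
      labels[i, j] <- tryCatch({
        if (is.na(s)) stop("calibration failed")
        p <- cdk
        p$s <- s
        for (nm in names(coupled_overrides)) p[[nm]] <- coupled_overrides[[nm]]
        model <- assemble_coupled_system(
          p, clock_model(clock),
          .coupling_for(mode, coupling_grid[j]))
        traj <- integrate_model(model, config = cfg)
        cl <- classify_dynamics(traj, ccfg)
        if (cl$undecided) "undecided" else cl$label
      }, error = function(e) "undecided")
    }
  }
  structure(list(period_axis = period_grid, coupling_axis = coupling_grid,
                 labels = labels, mode = mode,
                 provenance = config_digest(list(
                   period_grid = period_grid,
                   coupling_grid = coupling_grid, mode = mode,
                   coupled_overrides = coupled_overrides,
                   cdk = .flatten_params(cdk), clock = .flatten_params(clock),
                   t_transient = t_transient, t_window = t_window))),
            class = "tongue_map")
}

#' @export
print.tongue_map <- function(x, ...) {
  cat("<tongue_map>", x$mode, "coupling;",
      length(x$period_axis), "periods x", length(x$coupling_axis),
      "strengths\n")
  tab <- table(x$labels)
  cat(" ", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' @export
as.data.frame.tongue_map <- function(x, ...) {
  data.frame(period_h = rep(x$period_axis, times = length(x$coupling_axis)),
             coupling = rep(x$coupling_axis, each = length(x$period_axis)),
             label = as.vector(x$labels))
}

#' Write a tongue map as JSON and long-format CSV
#'
#' @param map a \code{tongue_map}.
#' @param path_json,path_csv output paths (either may be NULL).
#' @return invisibly, the map.
#' @export
write_tongue_map <- function(map, path_json = NULL, path_csv = NULL) {
  if (!is.null(path_json))
    jsonlite::write_json(
      list(mode = map$mode, period_axis = map$period_axis,
           coupling_axis = map$coupling_axis,
           labels = unname(apply(map$labels, 1, as.list)),
           provenance = map$provenance),
      path_json, auto_unbox = TRUE, digits = NA)
  if (!is.null(path_csv))
    utils::write.csv(as.data.frame(map), path_csv, row.names = FALSE)
  invisible(map)
}

#' Birhythmicity probe: coupling sweep with state carry-over
#'
#' Sweeps the coupling strength upward then downward, carrying the terminal
#' state between steps, and reports the locked regime at each step in both
#' directions.  A strength interval where the two directions disagree
#' (24 h vs 48 h locking) is a signature of coexisting entrained states.
#'
#' @param period autonomous period (h).
#' @param coupling_range increasing vector of coupling strengths.
#' @param mode coupling mode (see \code{\link{arnold_tongue_scan}}).
#' @param cdk,clock base parameter sets.
#' @param t_settle,t_measure settling and measurement window per step (h).
#' @param coupled_overrides Cdk overrides applied in the coupled system only
#'   (see \code{\link{arnold_tongue_scan}}).
#' @return data.frame with columns \code{coupling}, \code{up}, \code{down}
#'   and attribute \code{coexistence} (strengths where labels differ).
#' @export
hysteresis_probe <- function(period, coupling_range, mode = "p21",
                             cdk = cdk_params(), clock = clock_params(),
                             t_settle = 240, t_measure = 480,
                             coupled_overrides = list(v_swee1 = 0)) {
  s <- calibrate_timescale(period, cdk, verify = FALSE)
  p <- cdk
  p$s <- s
  for (nm in names(coupled_overrides)) p[[nm]] <- coupled_overrides[[nm]]
  run_dir <- function(values) {
    state <- NULL
    out <- character(length(values))
    for (k in seq_along(values)) {
      model <- assemble_coupled_system(p, clock_model(clock),
                                       .coupling_for(mode, values[k]))
      if (is.null(state)) state <- model$default_init
      cfg <- simulation_config(t_end = t_settle + t_measure,
                               t_transient = t_settle, dt_out = 0.1)
      traj <- integrate_model(model, init = state, config = cfg)
      state <- traj$states[nrow(traj$states), ]
      cl <- classify_dynamics(traj, classify_config(t_transient = t_settle))
      out[k] <- cl$label
    }
    out
  }
  up <- run_dir(coupling_range)
  down <- rev(run_dir(rev(coupling_range)))
  res <- data.frame(coupling = coupling_range, up = up, down = down)
  attr(res, "coexistence") <- coupling_range[up != down]
  res
}

# ---------------------------------------------------------------------------
# scenario presets

.scenarios <- function() list(
  fig2 = list(
    desc = "Wee1 coupling switched on at t = 120 h (v_sw 0 -> 0.1)",
    variants = list(`20` = list(autonomous = 20), `28` = list(autonomous = 28)),
    build = function(v) list(
      mode = "wee1", value = 0.1, autonomous = v$autonomous,
      event_time = 120, drop_basal = TRUE, t_end = 960,
      expected = "entrained_24")),
  fig5 = list(
    desc = "weak Wee1 coupling at the printed strengths (the reduced model's
      weak-coupling tongues are narrower than the full model's, so the
      printed strengths fall outside them; see the vignette)",
    variants = list(
      a = list(autonomous = 16, v_sw = 0.02, expected = "complex_periodic"),
      b = list(autonomous = 38, v_sw = 0.02, expected = "complex_periodic"),
      c = list(autonomous = 16, v_sw = 0.0012, expected = "complex_periodic")),
    build = function(v) list(
      mode = "wee1", value = v$v_sw, autonomous = v$autonomous,
      event_time = 120, t_end = 1200, expected = v$expected)),
  fig6 = list(
    desc = "regimes around the 24 h tongue (d/e: strong-coupling failure)",
    variants = list(
      a = list(autonomous = 4, v_sw = 0.05, expected = "complex_periodic"),
      b = list(autonomous = 30, v_sw = 0.05, expected = "complex_periodic"),
      c = list(autonomous = 16, v_sw = 0.01, expected = "complex_periodic"),
      d = list(autonomous = 16, v_sw = 0.3, expected = "tetraploid_pattern"),
      e = list(autonomous = 16, v_sw = 1, expected = "endoreplication")),
    build = function(v) list(
      mode = "wee1", value = v$v_sw, autonomous = v$autonomous,
      event_time = 120, t_end = 1200, expected = v$expected)),
  fig7 = list(
    desc = "multi-peak circadian gating of a 4 h cell cycle",
    variants = list(a = list(v_sw = 0.025), b = list(v_sw = 0.005)),
    build = function(v) list(
      mode = "wee1", value = v$v_sw, autonomous = 4,
      event_time = 120, t_end = 960, expected = "complex_periodic")),
  fig8b = list(
    desc = "p21 coupling: Cdk1 locks at 48 h at the printed strengths; the
      printed 6.5% strength increase does not flip the reduced model to the
      24 h mode",
    variants = list(default = list()),
    build = function(v) list(
      mode = "p21", value = 0.46, autonomous = 34, t_end = 1440,
      schedule = list(list(time = 240, params = list(v_smp21 = 0.49))),
      expected = "tetraploid_pattern")),
  fig10 = list(
    desc = "triple coupling (mu switched on at t = 240 h)",
    variants = list(
      printed = list(mu = 0.01, expected = "unlocked"),
      locked = list(mu = 0.05, expected = "tetraploid_pattern")),
    build = function(v) list(
      mode = "mu", value = 0, autonomous = 18, t_end = 1920,
      schedule = list(list(time = 240, params = list(mu = v$mu))),
      expected = v$expected)),
  fig11 = list(
    desc = "DNA-replication checkpoint under Wee1 entrainment (the reduced
      checkpoint stand-in slows the cycle but does not reproduce the full
      model's checkpoint-induced tetraploidy)",
    variants = list(weak = list(k_aatr = 0.025, expected = "entrained_24"),
                    strong = list(k_aatr = 0.075,
                                  expected = "entrained_24")),
    build = function(v) list(
      mode = "wee1", value = 0, autonomous = 20, t_end = 1200,
      cdk_over = list(v_swee1 = 0),
      schedule = list(list(time = 120, params = list(v_sw = 0.1)),
                      list(time = 240, params = list(k_aatr = v$k_aatr))),
      expected = v$expected)),
  fig12 = list(
    desc = "forcing a quiescent network (raised pRB or Cdc25 synthesis);
      just past the quiescence bifurcation (~0.955 uM/h) the forced
      variation carries full mitotic spikes",
    variants = list(
      a = list(cdk_over = list(v_spRB = 1), expected = "endoreplication"),
      b = list(cdk_over = list(v_spRB = 2), expected = "endoreplication"),
      excitable = list(cdk_over = list(v_spRB = 0.96),
                       expected = "entrained_48"),
      c = list(cdk_over = list(v_spbi = 0.3), expected = "complex_periodic")),
    build = function(v) list(
      mode = "wee1", value = 0, autonomous = 20, t_end = 960,
      cdk_over = v$cdk_over,
      schedule = list(list(time = 120,
                           params = list(v_sw = 0.1, v_swee1 = 0))),
      expected = v$expected)),
  fig13 = list(
    desc = "growth-factor square wave (12 h at 0, 12 h at 1 uM), sustained
      from t = 120 h",
    variants = list(
      oscillatory = list(init_gf = 1), quiescent = list(init_gf = 0)),
    build = function(v) list(
      mode = "none", value = 0, autonomous = 16, t_end = 960,
      cdk_over = list(GF = v$init_gf),
      schedule = .gf_square_schedule(120, 960, 12, 0, 1),
      expected = "entrained_24")),
  fig14 = list(
    desc = "GF-induced entrainment switch (Wee1 + cyclin E); at the printed
      mu the reduced model sits outside its (narrower) 24 h tongue",
    variants = list(
      printed = list(mu = 0.028, expected = "endoreplication"),
      switch = list(mu = 0.07, expected = "complex_periodic")),
    build = function(v) list(
      mode = "mu2", value = v$mu, autonomous = 21.6, t_end = 1440,
      schedule = list(list(time = 480, params = list(GF = 0.3))),
      expected = v$expected)),
  fig15 = list(
    desc = "Cry-deletion emulation: Bn clamped to an elevated constant after
      entrainment; Wee1 mRNA rises ~35% and the cycle slows to ~40 h",
    variants = list(default = list()),
    build = function(v) list(
      mode = "wee1", value = 0.05, autonomous = 18, t_end = 1200,
      schedule = list(list(time = 480, params = list(bn_clamp = 2))),
      expected = "complex_periodic")))

#' Growth-factor square-wave schedule
#'
#' Parameter-override events alternating GF between \code{lo} and \code{hi}
#' every \code{half_period} hours on \code{[from, to)}, starting with
#' \code{lo}.
#'
#' @param from,to window (h).
#' @param half_period half-period of the square wave (h), default 12.
#' @param lo,hi GF levels (uM).
#' @return a schedule list for \code{\link{integrate_model}}.
#' @export
gf_square_schedule <- function(from, to, half_period = 12, lo = 0, hi = 1) {
  .gf_square_schedule(from, to, half_period, lo, hi)
}

.gf_square_schedule <- function(from, to, half_period = 12, lo = 0, hi = 1) {
  times <- seq(from, to - 1e-9, by = half_period)
  lapply(seq_along(times), function(k)
    list(time = times[k],
         params = list(GF = if (k %% 2 == 1) lo else hi)))
}

#' List the available scenario presets
#'
#' @return data.frame of preset names, variants and descriptions.
#' @export
list_scenarios <- function() {
  sc <- .scenarios()
  data.frame(name = names(sc),
             variants = vapply(sc, function(s)
               paste(names(s$variants), collapse = ", "), ""),
             description = vapply(sc, function(s) s$desc, ""))
}

#' Run a scenario preset
#'
#' Builds the preset's coupled model and event timeline (coupling or
#' checkpoint switched on mid-run, GF square waves, Cry deletion), runs it
#' and classifies the post-event dynamics.
#'
#' @param name preset name (see \code{\link{list_scenarios}}).
#' @param variant variant key; defaults to the preset's first variant.
#' @param autonomous optional autonomous-period override (h).
#' @param dt_out output step (h).
#' @return list with \code{name}, \code{variant}, \code{trajectory},
#'   \code{classification}, \code{expected} and a \code{report} list.
#' @export
scenario_run <- function(name, variant = NULL, autonomous = NULL,
                         dt_out = 0.1) {
  sc <- .scenarios()
  if (!name %in% names(sc))
    stop("unknown preset '", name, "'; available: ",
         paste(names(sc), collapse = ", "))
  preset <- sc[[name]]
  if (is.null(variant)) variant <- names(preset$variants)[1]
  variant <- as.character(variant)
  if (!variant %in% names(preset$variants))
    stop("unknown variant '", variant, "' for ", name, "; available: ",
         paste(names(preset$variants), collapse = ", "))
  spec <- preset$build(preset$variants[[variant]])
  if (!is.null(autonomous)) spec$autonomous <- autonomous

  cdk <- cdk_params()
  for (nm in names(spec$cdk_over)) cdk[[nm]] <- spec$cdk_over[[nm]]
  cdk$s <- calibrate_timescale(spec$autonomous, cdk_params(),
                               verify = FALSE)
  coupling <- switch(spec$mode,
    none = coupling_params(),
    mu = coupling_params(modes = c("wee1", "p21", "cyclinE"),
                         mu = spec$value),
    mu2 = coupling_params(modes = c("wee1", "cyclinE"), mu = spec$value),
    .coupling_for(spec$mode, spec$value))
  if (!is.null(spec$event_time) && spec$mode %in%
        c("wee1", "p21", "cyclinE")) {
    # coupling off before the event, printed strength after it
    rate_name <- switch(spec$mode, wee1 = "v_sw", p21 = "v_smp21",
                        cyclinE = "v_sce")
    ev <- setNames(list(spec$value), rate_name)
    if (isTRUE(spec$drop_basal)) ev$v_swee1 <- 0
    coupling[[rate_name]] <- 0
    spec$schedule <- c(spec$schedule,
                       list(list(time = spec$event_time, params = ev)))
  }
  model <- assemble_coupled_system(cdk, clock_model(), coupling)
  sched <- spec$schedule
  if (length(sched))
    sched <- sched[order(vapply(sched, function(e) e$time, 0))]
  first_event <- if (length(sched))
    min(vapply(sched, function(e) e$time, 0)) else 0
  cfg <- simulation_config(t_end = spec$t_end,
                           t_transient = min(first_event + 480,
                                             spec$t_end * 0.75),
                           dt_out = dt_out)
  traj <- integrate_model(model, config = cfg, schedule = sched)
  cl <- classify_dynamics(traj,
                          classify_config(t_transient = cfg$t_transient))
  list(name = name, variant = variant, trajectory = traj,
       classification = cl, expected = spec$expected,
       report = list(name = name, variant = variant,
                     autonomous_period_h = spec$autonomous,
                     label = cl$label, metrics = cl$metrics,
                     expected = spec$expected,
                     config_digest = config_digest(list(
                       name = name, variant = variant,
                       autonomous = spec$autonomous))))
}

# order-independent digest of a (nested) config list: canonicalise by
# sorting names recursively, then FNV-1a over the JSON bytes
.canonical <- function(x) {
  if (is.list(x) && !is.null(names(x))) {
    x <- x[order(names(x))]
    lapply(x, .canonical)
  } else if (is.list(x)) lapply(x, .canonical) else x
}

#' Stable digest of a configuration list
#'
#' Invariant under reordering of named keys at any nesting level.
#'
#' @param x a (nested) list of configuration values.
#' @return hex string.
#' @export
config_digest <- function(x) {
  js <- jsonlite::toJSON(.canonical(x), auto_unbox = TRUE, digits = NA)
  bytes <- as.integer(charToRaw(as.character(js)))
  # 31-bit polynomial rolling hash in double precision (exact below 2^53)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
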