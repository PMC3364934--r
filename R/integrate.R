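# Piecewise integration over a parameter-override schedule, plus attractor
# detection (steady state vs limit cycle).

#' Integrate a model over a parameter schedule
#'
#' Integrates \code{model} on a uniform output grid with the package's
#' adaptive embedded Runge-Kutta pair (Dormand-Prince 5(4)).  The schedule is
#' a list of events \code{list(time =, params = list(name = value))}; at each
#' event the named parameters switch as step changes while the state is
#' carried continuously.  Forcing discontinuities declared by the model
#' (light-dark switches) are landed on exactly.
#'
#' @param model a \code{\link{model_spec}}.
#' @param init initial state vector; defaults to \code{model$default_init}.
#' @param config a \code{\link{simulation_config}}.
#' @param schedule list of parameter-switch events (possibly empty).
#' @return a \code{trajectory}.
#' @export
integrate_model <- function(model, init = NULL, config, schedule = NULL) {
  stopifnot(inherits(model, "model_spec"), inherits(config, "simulation_config"))
  if (is.null(init)) init <- model$default_init
  stopifnot(length(init) == length(model$state_names))
  init <- as.numeric(init)

  ev_times <- numeric()
  if (length(schedule)) {
    ev_times <- vapply(schedule, function(e) e$time, 0)
    stopifnot(!is.unsorted(ev_times), all(ev_times > 0),
              all(ev_times < config$t_end))
  }
  out_times <- seq(0, config$t_end, by = config$dt_out)
  bounds <- c(0, ev_times, config$t_end)

  params <- model$params
  states <- NULL
  times_all <- numeric()
  is_out_all <- logical()
  params_used <- list()
  minval <- 0
  y <- init
  for (seg in seq_len(length(bounds) - 1)) {
    a <- bounds[seg]; b <- bounds[seg + 1]
    if (seg > 1) params <- .override_params(params, schedule[[seg - 1]]$params)
    params_used[[seg]] <- list(from = a, params = params)
    if (b <= a) next
    grid <- out_times[out_times > a & out_times <= b]
    brk <- numeric()
    if (!is.null(model$breaks_fn)) brk <- model$breaks_fn(a, b, params)
    full <- sort(unique(c(a, grid, brk, b)))
    is_out <- full %in% c(if (seg == 1) a else numeric(), grid)
    res <- tryCatch(
      .cpp_call(model, params, y, full, config),
      error = function(e) stop("integration failed in segment ", seg,
                               " [", a, ", ", b, "] h: ",
                               conditionMessage(e), call. = FALSE))
    minval <- min(minval, res$minval)
    states <- rbind(states, res$states)
    times_all <- c(times_all, full)
    is_out_all <- c(is_out_all, is_out)
    y <- res$states[nrow(res$states), ]
  }
  keep <- is_out_all
  times <- times_all[keep]
  st <- states[keep, , drop = FALSE]
  # clip truncation-level negative concentrations only; genuinely negative
  # states of generic (non-concentration) models are preserved
  st[st < 0 & st > -1e3 * config$abs_tol] <- 0
  colnames(st) <- model$state_names

  obs <- list()
  if (length(model$observables)) {
    seg_from <- vapply(params_used, function(s) s$from, 0)
    seg_id <- findInterval(times, seg_from)
    for (nm in names(model$observables)) {
      v <- numeric(length(times))
      for (k in unique(seg_id)) {
        idx <- seg_id == k
        v[idx] <- model$observables[[nm]](times[idx],
                                          st[idx, , drop = FALSE],
                                          params_used[[k]]$params)
      }
      obs[[nm]] <- v
    }
  }
  .new_trajectory(times, st, obs, params_used, model, config, schedule, minval)
}

.cpp_call <- function(model, params, y, full, config) {
  if (!is.null(model$native)) {
    cpp_integrate(model$native$model, model$native$pack(params), y, full,
                  config$rel_tol, config$abs_tol)
  } else {
    rfn <- function(t, yy) model$rhs(t, yy, params)
    cpp_integrate("rfun", numeric(), y, full, config$rel_tol, config$abs_tol,
                  rfn)
  }
}

# apply named overrides to a (possibly composite) parameter object
.override_params <- function(params, ov) {
  if (is.null(ov) || !length(ov)) return(params)
  if (inherits(params, "coupled_params")) {
    for (nm in names(ov)) {
      if (nm == "mu") {
        params$coupling <- .set_mu(params$coupling, ov[[nm]])
      } else if (nm %in% names(params$cdk)) {
        params$cdk[[nm]] <- ov[[nm]]
      } else if (nm %in% names(params$clock)) {
        params$clock[[nm]] <- ov[[nm]]
      } else if (nm %in% names(params$coupling)) {
        params$coupling[[nm]] <- ov[[nm]]
      } else stop("schedule names unknown parameter '", nm, "'")
    }
    return(params)
  }
  cls <- class(params)
  unknown <- setdiff(names(ov), names(params))
  if (length(unknown))
    stop("schedule names unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  params[names(ov)] <- ov
  class(params) <- cls
  params
}

.set_mu <- function(cp, mu) {
  stopifnot(inherits(cp, "coupling_params"))
  cp$mu <- mu
  cp$mu_w <- if ("wee1" %in% cp$modes) mu else 0
  cp$mu_p <- if ("p21" %in% cp$modes) mu else 0
  cp$mu_c <- if ("cyclinE" %in% cp$modes) mu else 0
  cp
}

#' Find the attractor of a model
#'
#' Integrates the model and decides between a stable steady state (terminal
#' derivative below \code{abs_tol} and a flat terminal window) and a limit
#' cycle (period from \code{\link{estimate_period}} on a reference
#' observable).  When neither criterion is met within \code{t_end} the result
#' is flagged \code{"undecided"} rather than raising an error.
#'
#' @param model a \code{\link{model_spec}}.
#' @param init initial state; defaults to the model default.
#' @param config a \code{\link{simulation_config}}; \code{t_end} should cover
#'   at least ten putative cycles.
#' @param ref_observable observable used for period estimation; defaults to
#'   \code{"Cdk1"} when present, otherwise the state with the largest
#'   relative range.
#' @param flat_tol absolute peak-to-trough range below which a terminal
#'   window counts as flat.
#' @return an object of class \code{attractor}: a list with \code{type}
#'   (\code{"steady_state"}, \code{"limit_cycle"} or \code{"undecided"}) and,
#'   as relevant, \code{state}, \code{period}, \code{period_cv},
#'   \code{cycle} (a one-cycle \code{trajectory}) and the full trajectory.
#' @export
find_attractor <- function(model, init = NULL, config, ref_observable = NULL,
                           flat_tol = 1e-6) {
  traj <- integrate_model(model, init, config)
  n <- length(traj$times)
  yend <- traj$states[n, ]
  dend <- model$rhs(traj$times[n], yend, traj$params_used[[length(
    traj$params_used)]]$params)
  win <- traj$times >= max(config$t_transient,
                           max(traj$times) - 0.25 * diff(range(traj$times)))
  flat <- all(apply(traj$states[win, , drop = FALSE], 2,
                    function(v) diff(range(v))) < flat_tol)
  # a flat terminal window with a residual derivative below the flatness
  # tolerance counts as settled (the strict abs_tol criterion alone rejects
  # states that converged to within solver noise)
  if (max(abs(dend)) < max(config$abs_tol, flat_tol) && flat) {
    return(structure(list(type = "steady_state",
                          state = setNames(yend, model$state_names),
                          trajectory = traj), class = "attractor"))
  }
  if (is.null(ref_observable)) {
    ref_observable <- if ("Cdk1" %in% names(traj$observables)) "Cdk1"
    else {
      rel <- apply(traj$states[win, , drop = FALSE], 2, function(v)
        diff(range(v)) / max(abs(v), 1e-12))
      model$state_names[which.max(rel)]
    }
  }
  ser <- traj_series(traj, ref_observable, after = config$t_transient)
  pk <- detect_peaks(ser$values, ser$times, min_prominence = 0.2)
  # a genuine limit cycle needs real amplitude and a resolvable period;
  # sub-tolerance ripple around a slowly settling state is not a cycle
  if (diff(range(ser$values)) < 100 * flat_tol ||
      (length(pk$peak_times) >= 3 &&
       estimate_period(pk)$period < 5 * config$dt_out))
    pk$peak_times <- numeric()
  if (length(pk$peak_times) >= 3) {
    est <- estimate_period(pk)
    i2 <- length(pk$peak_times)
    keep <- traj$times >= pk$peak_times[i2 - 1] &
      traj$times <= pk$peak_times[i2]
    cyc <- traj
    cyc$times <- traj$times[keep]
    cyc$states <- traj$states[keep, , drop = FALSE]
    cyc$observables <- lapply(traj$observables, function(v) v[keep])
    return(structure(list(type = "limit_cycle", period = est$period,
                          period_cv = est$cv, cycle = cyc,
                          ref_observable = ref_observable,
                          trajectory = traj), class = "attractor"))
  }
  structure(list(type = "undecided", trajectory = traj), class = "attractor")
}

#' @export
print.attractor <- function(x, ...) {
  cat("<attractor>", x$type)
  if (x$type == "limit_cycle")
    cat(sprintf(": period %.3f h (CV %.2g) on %s", x$period, x$period_cv,
                x$ref_observable))
  cat("\n")
  invisible(x)
}
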