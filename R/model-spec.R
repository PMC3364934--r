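# ModelSpec / SimulationConfig / Trajectory containers.

#' Define an ODE model
#'
#' A \code{model_spec} bundles the state layout, the right-hand side, named
#' observables and a default parameter set.  Built-in models (see
#' \code{\link{clock_model}}, \code{\link{cdk_model}},
#' \code{\link{assemble_coupled_system}}) also carry a pointer to their
#' compiled rhs so that \code{\link{integrate_model}} can avoid calling back
#' into R; user-supplied models integrate through the same adaptive stepper
#' via their R \code{rhs}.
#'
#' @param state_names character vector of unique state identifiers.
#' @param rhs function \code{(t, state, params)} returning the derivative
#'   vector (length equal to \code{state_names}).
#' @param params default parameter object passed to \code{rhs}.
#' @param observables named list of functions \code{(times, states, params)}
#'   mapping a trajectory to a numeric vector; must not mutate state.
#' @param default_init default initial state (named or positional).
#' @param native internal: list \code{(model, pack)} naming a compiled rhs.
#' @param breaks_fn optional function \code{(t0, t1, params)} returning times
#'   in \code{(t0, t1)} where the rhs is discontinuous (forcing switches); the
#'   integrator lands on them exactly.
#' @param name model label used in diagnostics.
#' @return an object of class \code{model_spec}.
#' @export
model_spec <- function(state_names, rhs, params = list(),
                       observables = list(), default_init = NULL,
                       native = NULL, breaks_fn = NULL, name = "model") {
  stopifnot(is.character(state_names), length(state_names) >= 1,
            !anyDuplicated(state_names), is.function(rhs))
  if (length(observables))
    stopifnot(!is.null(names(observables)),
              all(vapply(observables, is.function, TRUE)))
  if (is.null(default_init)) default_init <- rep(0, length(state_names))
  stopifnot(length(default_init) == length(state_names))
  structure(list(state_names = state_names, rhs = rhs, params = params,
                 observables = observables,
                 default_init = setNames(as.numeric(default_init), state_names),
                 native = native, breaks_fn = breaks_fn, name = name),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$name, "--", length(x$state_names), "states",
      if (!is.null(x$native)) "(compiled rhs)" else "(R rhs)", "\n")
  cat("  states:", paste(x$state_names, collapse = ", "), "\n")
  if (length(x$observables))
    cat("  observables:", paste(names(x$observables), collapse = ", "), "\n")
  invisible(x)
}

#' Simulation settings
#'
#' @param t_end end time (h).
#' @param t_transient initial window (h) discarded by analysis routines.
#' @param dt_out output sampling interval (h); 0.1 h resolves the narrow
#'   Cdk1 spikes of the relaxation regime.
#' @param rel_tol,abs_tol solver tolerances.
#' @param event_times times (h) at which a parameter schedule may switch.
#' @return an object of class \code{simulation_config}.
#' @export
simulation_config <- function(t_end, t_transient = 0, dt_out = 0.1,
                              rel_tol = 1e-7, abs_tol = 1e-9,
                              event_times = numeric()) {
  stopifnot(t_end > 0, t_transient >= 0, t_transient < t_end, dt_out > 0,
            rel_tol > 0, abs_tol > 0)
  structure(list(t_end = t_end, t_transient = t_transient, dt_out = dt_out,
                 rel_tol = rel_tol, abs_tol = abs_tol,
                 event_times = sort(unique(event_times))),
            class = "simulation_config")
}

.new_trajectory <- function(times, states, observables, params_used, model,
                            config, schedule = NULL, min_before_clip = 0) {
  structure(list(times = times, states = states, observables = observables,
                 params_used = params_used, model_name = model$name,
                 state_names = colnames(states), config = config,
                 schedule = schedule, min_before_clip = min_before_clip),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", x$model_name, "--", length(x$times), "samples, t in [",
      min(x$times), ",", max(x$times), "] h, dt =",
      signif(diff(x$times[1:2]), 4), "h\n")
  cat("  states:", paste(x$state_names, collapse = ", "), "\n")
  if (length(x$observables))
    cat("  observables:", paste(names(x$observables), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  df <- data.frame(time_h = x$times, x$states, check.names = FALSE)
  for (nm in names(x$observables)) df[[nm]] <- x$observables[[nm]]
  df
}

#' Extract an observable or state series from a trajectory
#'
#' @param traj a \code{trajectory}.
#' @param name observable or state name.
#' @param after drop samples with time < \code{after} (h).
#' @return list with \code{times} and \code{values}.
#' @export
traj_series <- function(traj, name, after = 0) {
  stopifnot(inherits(traj, "trajectory"))
  v <- if (name %in% names(traj$observables)) traj$observables[[name]]
       else if (name %in% colnames(traj$states)) traj$states[, name]
       else stop("no state or observable named '", name, "'")
  keep <- traj$times >= after
  list(times = traj$times[keep], values = v[keep])
}

#' Write / read a trajectory as CSV
#'
#' The CSV has a \code{time_h} column followed by states and observables; the
#' parameter snapshots are written to a JSON sidecar \code{<path>.params.json}.
#'
#' @param traj a \code{trajectory}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  sidecar <- paste0(path, ".params.json")
  snap <- lapply(traj$params_used, function(seg)
    list(from_h = seg$from, params = .flatten_params(seg$params)))
  jsonlite::write_json(snap, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param state_names optional explicit state column names; remaining numeric
#'   columns are treated as observables.
#' @export
read_trajectory_csv <- function(path, state_names = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot("time_h" %in% names(df))
  times <- df$time_h
  rest <- df[setdiff(names(df), "time_h")]
  if (is.null(state_names)) state_names <- names(rest)
  obs_names <- setdiff(names(rest), state_names)
  states <- as.matrix(rest[state_names])
  obs <- as.list(rest[obs_names])
  model <- list(name = paste0("csv:", basename(path)))
  cfg <- simulation_config(t_end = max(times),
                           dt_out = if (length(times) > 1)
                             diff(times[1:2]) else 0.1)
  .new_trajectory(times, states, obs, list(), model, cfg)
}

.flatten_params <- function(p) {
  if (is.null(p)) return(NULL)
  p <- unclass(p)
  p[vapply(p, function(x) is.numeric(x) || is.character(x), TRUE)]
}
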