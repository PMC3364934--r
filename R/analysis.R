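# Trajectory readouts: peak detection, amplitude bimodality, period and
# phase-locking estimation, stroboscopic (Poincare) sampling and the
# categorical dynamics classifier.

#' Detect peaks in a uniformly sampled series
#'
#' Local maxima whose topographic prominence exceeds \code{min_prominence}
#' times the peak-to-trough range of the series.
#'
#' @param series numeric vector on a uniform time grid.
#' @param times matching time vector (h).
#' @param min_prominence prominence threshold as a fraction of the series
#'   range.
#' @return an object of class \code{peak_list}: \code{peak_times},
#'   \code{peak_heights}, plus the detection settings.
#' @export
detect_peaks <- function(series, times, min_prominence = 0.05) {
  if (length(series) == 0) stop("empty series")
  stopifnot(length(series) == length(times), length(series) >= 3)
  rng <- diff(range(series))
  if (rng == 0)
    return(structure(list(peak_times = numeric(), peak_heights = numeric(),
                          observable_name = NULL,
                          settings = list(min_prominence = min_prominence)),
                     class = "peak_list"))
  n <- length(series)
  d <- diff(series)
  # local maxima with plateau handling: last index of a rising-then-falling run
  sgn <- sign(d)
  nz <- which(sgn != 0)
  cand <- integer()
  prev_up <- FALSE
  prev_i <- 0L
  for (i in nz) {
    if (sgn[i] < 0 && prev_up) cand <- c(cand, prev_i + 1L)
    prev_up <- sgn[i] > 0
    prev_i <- i
  }
  if (!length(cand))
    return(structure(list(peak_times = numeric(), peak_heights = numeric(),
                          observable_name = NULL,
                          settings = list(min_prominence = min_prominence)),
                     class = "peak_list"))
  prom <- vapply(cand, function(i) {
    h <- series[i]
    lmin <- h; j <- i
    while (j > 1) { j <- j - 1L
      if (series[j] > h) break
      if (series[j] < lmin) lmin <- series[j] }
    rmin <- h; j <- i
    while (j < n) { j <- j + 1L
      if (series[j] > h) break
      if (series[j] < rmin) rmin <- series[j] }
    h - max(lmin, rmin)
  }, 0)
  keep <- prom >= min_prominence * rng
  structure(list(peak_times = times[cand[keep]],
                 peak_heights = series[cand[keep]],
                 observable_name = NULL,
                 settings = list(min_prominence = min_prominence)),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat("<peak_list>", length(x$peak_times), "peaks")
  if (length(x$peak_times) >= 2)
    cat(sprintf(", mean interval %.3f h",
                mean(diff(x$peak_times))))
  cat("\n")
  invisible(x)
}

#' Split peak amplitudes into large / minute classes
#'
#' One-dimensional two-cluster split at the largest gap in log-amplitude.
#' The split is kept (\code{bimodal = TRUE}) when the two cluster means are
#' at least \code{min_separation}-fold apart (the Cdk1 module's bistability
#' makes mitotic peaks either minute or very large); otherwise every peak is
#' labelled large.
#'
#' @param peaks a \code{peak_list} with at least one peak.
#' @param min_separation minimal fold separation between class means.
#' @return list with \code{labels} ("large"/"minute"), \code{bimodal},
#'   \code{separation} (fold ratio of geometric class means).
#' @export
split_amplitude_classes <- function(peaks, min_separation = 5) {
  h <- peaks$peak_heights
  stopifnot(length(h) >= 1)
  if (length(h) == 1)
    return(list(labels = "large", bimodal = FALSE, separation = 1))
  lh <- log(pmax(h, 1e-300))
  o <- order(lh)
  gaps <- diff(lh[o])
  cut <- which.max(gaps)
  lower <- o[seq_len(cut)]
  upper <- o[(cut + 1):length(h)]
  sep <- exp(mean(lh[upper]) - mean(lh[lower]))
  if (sep >= min_separation) {
    labels <- rep("large", length(h))
    labels[lower] <- "minute"
    list(labels = labels, bimodal = TRUE, separation = sep)
  } else {
    list(labels = rep("large", length(h)), bimodal = FALSE, separation = sep)
  }
}

#' Mean period from a peak train
#'
#' @param peaks a \code{peak_list} with at least three peaks.
#' @return list with \code{period} (mean successive interval, h) and
#'   \code{cv} (coefficient of variation of the intervals).
#' @export
estimate_period <- function(peaks) {
  tt <- peaks$peak_times
  if (length(tt) < 3) stop("insufficient peaks (need >= 3)")
  iv <- diff(tt)
  list(period = mean(iv), cv = stats::sd(iv) / mean(iv))
}

#' Stroboscopic (Poincare) section of a forced trajectory
#'
#' Samples a pair of observables once per forcing period after the transient
#' and counts distinct points under a relative merge tolerance.  A locked
#' p:q rhythm leaves q distinct points; a count that keeps growing up to the
#' cap indicates quasiperiodicity or chaos.
#'
#' @param traj a \code{trajectory}.
#' @param T_force forcing period (h), default 24.
#' @param observables character pair of observable names.
#' @param t_transient discarded initial window (h); defaults to the
#'   trajectory config's value.
#' @param merge_tol relative L2 distance under which two section points are
#'   identified.
#' @param cap maximum number of distinct points tracked.
#' @param min_cycles minimal number of forcing cycles required after the
#'   transient.
#' @return list with \code{points} (matrix), \code{distinct}, \code{capped}.
#' @export
stroboscopic_map <- function(traj, T_force = 24,
                             observables = c("Cdk1", "Cdk2"),
                             t_transient = NULL, merge_tol = 1e-3,
                             cap = 32, min_cycles = 20) {
  if (is.null(t_transient)) t_transient <- traj$config$t_transient
  t_max <- max(traj$times)
  n_cyc <- floor((t_max - t_transient) / T_force)
  if (n_cyc < min_cycles)
    stop("trajectory too short: ", n_cyc, " forcing cycles after transient, ",
         "need >= ", min_cycles)
  ts <- t_transient + (0:(n_cyc - 1)) * T_force
  pts <- vapply(observables, function(nm) {
    s <- traj_series(traj, nm)
    stats::approx(s$times, s$values, xout = ts)$y
  }, numeric(length(ts)))
  scale <- pmax(apply(pts, 2, function(v) diff(range(v))),
                apply(abs(pts), 2, max), 1e-12)
  norm <- sweep(pts, 2, scale, "/")
  reps <- norm[1, , drop = FALSE]
  for (i in seq_len(nrow(norm))[-1]) {
    dd <- sqrt(rowSums((reps - matrix(norm[i, ], nrow(reps), ncol(norm),
                                      byrow = TRUE))^2))
    if (all(dd > merge_tol)) {
      reps <- rbind(reps, norm[i, ])
      if (nrow(reps) > cap) break
    }
  }
  list(points = pts, distinct = min(nrow(reps), cap + 1),
       capped = nrow(reps) > cap)
}

#' Twin-trajectory divergence test
#'
#' Integrates the model twice from initial conditions separated by
#' \code{delta0} (relative) and reports the growth factor of the state-space
#' distance over the analysis window.  Exponential growth (factor much
#' greater than 1 that scales with the window) indicates sensitive
#' dependence on initial conditions.
#'
#' @param model a \code{\link{model_spec}}.
#' @param init initial state.
#' @param config a \code{\link{simulation_config}}.
#' @param delta0 relative initial offset.
#' @return list with \code{growth} (log10 distance growth over the window)
#'   and the distance series.
#' @export
twin_divergence <- function(model, init = NULL, config, delta0 = 1e-6) {
  if (is.null(init)) init <- model$default_init
  t1 <- integrate_model(model, init, config)
  init2 <- init * (1 + delta0) + delta0 * mean(abs(init))
  t2 <- integrate_model(model, init2, config)
  keep <- t1$times >= config$t_transient
  d <- sqrt(rowSums((t1$states[keep, , drop = FALSE] -
                     t2$states[keep, , drop = FALSE])^2))
  d <- pmax(d, 1e-300)
  n <- length(d)
  early <- stats::median(d[seq_len(max(3, floor(n * 0.1)))])
  late <- stats::median(d[seq(floor(n * 0.9), n)])
  list(growth = log10(late / early), distance = d, times = t1$times[keep])
}

#' Peak phase within the LD cycle
#'
#' Maps peak times to [0, 24) h with the package convention that t = 0
#' starts a light phase, and reports whether every peak falls in the second
#' half of the light phase (the gate in which mitosis clusters upon
#' entrainment).
#'
#' @param peaks a non-empty \code{peak_list}.
#' @param schedule an \code{\link{ld_schedule}}.
#' @return list with \code{phases}, \code{circular_mean_h},
#'   \code{in_light}, \code{all_in_second_half_L}.
#' @export
phase_in_ld <- function(peaks, schedule = ld_schedule()) {
  if (!length(peaks$peak_times)) stop("empty peak list")
  per <- schedule$L_duration + schedule$D_duration
  ph <- (peaks$peak_times - schedule$phase_origin) %% per
  ang <- 2 * pi * ph / per
  cm <- (atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi) * per) %% per
  if (cm > per - 1e-9) cm <- 0
  list(phases = ph, circular_mean_h = cm,
       in_light = ph < schedule$L_duration,
       all_in_second_half_L = all(ph >= schedule$L_duration / 2 &
                                    ph < schedule$L_duration))
}

#' Classifier settings
#'
#' Tolerances for \code{\link{classify_dynamics}}.  Entrainment requires a
#' mean large-peak interval within \code{period_tol} of the target, an
#' interval CV below \code{cv_tol} and a phase drift against the forcing
#' below \code{drift_tol} h per cycle.  A Cdk1 peak train with no internal
#' bimodality counts as minute when its tallest peak is below
#' \code{ratio_minute} times the tallest Cdk2 peak.
#'
#' @param T_force forcing period (h).
#' @param t_transient discarded initial window (h).
#' @param min_prominence peak prominence threshold (fraction of range).
#' @param period_tol relative tolerance on the locked period.
#' @param cv_tol maximal interval coefficient of variation.
#' @param drift_tol maximal phase drift (h per forcing cycle).
#' @param ratio_minute cross-observable minute-peak threshold.
#' @param quiescent_rel relative amplitude below which a series counts as
#'   flat (variation around a steady level).
#' @param strobo_cap distinct stroboscopic point cap before a chaos check.
#' @param merge_tol stroboscopic merge tolerance.
#' @param model optional \code{\link{model_spec}} enabling the
#'   twin-trajectory divergence confirmation for chaos.
#' @return a list of class \code{classify_config}.
#' @export
classify_config <- function(T_force = 24, t_transient = 240,
                            min_prominence = 0.05, period_tol = 0.01,
                            cv_tol = 0.02, drift_tol = 0.05,
                            ratio_minute = 0.1, quiescent_rel = 0.05,
                            strobo_cap = 32, merge_tol = 1e-3,
                            model = NULL) {
  structure(as.list(environment()), class = "classify_config")
}

.peak_info <- function(traj, name, cfg) {
  s <- traj_series(traj, name, after = cfg$t_transient)
  rng <- diff(range(s$values))
  level <- max(abs(s$values), 1e-300)
  pk <- detect_peaks(s$values, s$times, cfg$min_prominence)
  cls <- if (length(pk$peak_heights))
    split_amplitude_classes(pk) else list(labels = character(),
                                          bimodal = FALSE, separation = 1)
  large <- pk
  large$peak_times <- pk$peak_times[cls$labels == "large"]
  large$peak_heights <- pk$peak_heights[cls$labels == "large"]
  list(series = s, peaks = pk, classes = cls, large = large,
       rel_amp = rng / level,
       max_height = if (length(pk$peak_heights)) max(pk$peak_heights) else 0)
}

.locked_at <- function(large, target, cfg) {
  if (length(large$peak_times) < 3) return(FALSE)
  est <- estimate_period(large)
  abs(est$period - target) / target < cfg$period_tol &&
    est$cv < cfg$cv_tol &&
    abs(est$period - target) < cfg$drift_tol
}

#' Classify the dynamical regime of a coupled-run trajectory
#'
#' Decision cascade over the Cdk1 and Cdk2 observables (see the package
#' vignette): quiescent, endoreplication, entrained_24 / entrained_48,
#' tetraploid_pattern, complex_periodic, chaotic, unlocked; an "undecided"
#' flag is set when the trajectory is too short to decide.  The classifier
#' only uses relative amplitudes and peak intervals, so it is invariant to a
#' uniform rescaling of all amplitudes and to time translation by multiples
#' of the forcing period.
#'
#' @param traj a \code{trajectory} carrying \code{Cdk1} and \code{Cdk2}
#'   observables.
#' @param config a \code{\link{classify_config}}.
#' @return an object of class \code{dynamics_class}: \code{label},
#'   \code{undecided} flag and a \code{metrics} list.
#' @export
classify_dynamics <- function(traj, config = classify_config()) {
  cfg <- config
  i1 <- .peak_info(traj, "Cdk1", cfg)
  i2 <- .peak_info(traj, "Cdk2", cfg)
  mk <- function(label, undecided = FALSE, ...)
    structure(list(label = label, undecided = undecided,
                   metrics = list(...), settings = cfg),
              class = "dynamics_class")

  # (i) quiescent: flat, or only sub-prominence variation in both
  if ((i1$rel_amp < cfg$quiescent_rel || length(i1$peaks$peak_times) == 0) &&
      (i2$rel_amp < cfg$quiescent_rel || length(i2$peaks$peak_times) == 0))
    return(mk("quiescent", rel_amp_cdk1 = i1$rel_amp,
              rel_amp_cdk2 = i2$rel_amp))

  cdk1_minute <- length(i1$large$peak_times) == 0 ||
    (!i1$classes$bimodal && i1$max_height < cfg$ratio_minute * i2$max_height)

  # (ii) endoreplication: large periodic Cdk2, Cdk1 only minute
  if (cdk1_minute && .locked_at(i2$large, cfg$T_force, cfg))
    return(mk("endoreplication",
              cdk2_period = estimate_period(i2$large)$period,
              cdk1_max = i1$max_height, cdk2_max = i2$max_height))

  if (!cdk1_minute && length(i1$large$peak_times) < 3)
    return(mk("unlocked", undecided = TRUE,
              n_large_cdk1 = length(i1$large$peak_times)))

  # (iii) 1:1 and 2:1 entrainment: both observables lock to the same period
  for (mult in c(1, 2)) {
    tgt <- mult * cfg$T_force
    if (!cdk1_minute && .locked_at(i1$large, tgt, cfg) &&
        .locked_at(i2$large, tgt, cfg)) {
      est <- estimate_period(i1$large)
      return(mk(if (mult == 1) "entrained_24" else "entrained_48",
                locked_period = est$period, interval_cv = est$cv,
                locking_ratio = paste0("1:", mult)))
    }
  }

  # (iv) tetraploid pattern: periodic with two large Cdk2 peaks per Cdk1 peak
  if (!cdk1_minute && length(i1$large$peak_times) >= 3) {
    est1 <- estimate_period(i1$large)
    n1 <- length(i1$large$peak_times); n2 <- length(i2$large$peak_times)
    ratio <- if (n1 > 1) (n2 - 1) / (n1 - 1) else NA
    if (est1$cv < 0.05 && !is.na(ratio) && ratio > 1.8 && ratio < 2.2)
      return(mk("tetraploid_pattern", cdk1_period = est1$period,
                cdk2_per_cdk1 = ratio))
  }

  # (v) complex periodic: p:q commensurate with the forcing, or a finite
  # multi-point stroboscopic section
  strobo <- tryCatch(
    stroboscopic_map(traj, cfg$T_force, t_transient = cfg$t_transient,
                     merge_tol = cfg$merge_tol, cap = cfg$strobo_cap,
                     min_cycles = 10),
    error = function(e) NULL)
  if (!cdk1_minute && length(i1$large$peak_times) >= 3) {
    est1 <- estimate_period(i1$large)
    if (est1$cv < cfg$cv_tol) {
      for (q in 1:4) for (p in 1:6) {
        tgt <- cfg$T_force * p / q
        if (abs(est1$period - tgt) / tgt < cfg$period_tol &&
            !(p == 1 && q == 1) && !(p == 2 && q == 1))
          return(mk("complex_periodic", cdk1_period = est1$period,
                    locking_ratio = paste0(q, ":", p),
                    strobo_points = if (is.null(strobo)) NA
                                    else strobo$distinct))
      }
    }
  }
  if (!is.null(strobo) && !strobo$capped && strobo$distinct > 1)
    return(mk("complex_periodic", strobo_points = strobo$distinct))

  # (vi) chaotic: non-saturating section plus sensitive dependence
  if (!is.null(strobo) && strobo$capped) {
    growth <- NA_real_
    if (!is.null(cfg$model)) {
      tw <- twin_divergence(cfg$model, config = traj$config)
      growth <- tw$growth
    }
    irregular <- length(i1$peaks$peak_times) >= 5 &&
      estimate_period(i1$peaks)$cv > 0.1
    if ((is.na(growth) && irregular) || (!is.na(growth) && growth > 2))
      return(mk("chaotic", strobo_points = strobo$distinct,
                divergence_log10 = growth))
  }

  mk("unlocked",
     own_period = if (length(i1$large$peak_times) >= 3)
       estimate_period(i1$large)$period else NA_real_,
     strobo_points = if (is.null(strobo)) NA else strobo$distinct)
}

#' @export
print.dynamics_class <- function(x, ...) {
  cat("<dynamics_class>", x$label,
      if (x$undecided) "(undecided)" else "", "\n")
  if (length(x$metrics)) {
    m <- vapply(x$metrics, function(v) {
      v <- unlist(v)
      if (is.numeric(v)) v <- signif(v, 5)
      paste(v, collapse = ",")
    }, "")
    cat(strwrap(paste(paste0(names(m), "=", m), collapse = "  "),
                width = 78, indent = 2, exdent = 2), sep = "\n")
  }
  invisible(x)
}

#' Synthetic classifier fixture
#'
#' Builds a deterministic two-observable bump-train trajectory with known
#' ground truth, used to test the classifier and the period estimator.
#' Cdk2 peaks every \code{period} h; Cdk1 peaks either match Cdk2
#' (\code{amp_ratio = 1}) or alternate tall/short with fold ratio
#' \code{amp_ratio} (>= 5 makes every second peak minute, doubling the large
#' Cdk1 period, the tetraploid pattern), or are uniformly minute
#' (\code{cdk1 = "minute"}, the endoreplication pattern).
#'
#' @param period Cdk2 inter-peak interval (h).
#' @param amp_ratio fold ratio between alternating Cdk1 peak amplitudes.
#' @param cdk1 \code{"large"} or \code{"minute"}.
#' @param jitter peak-time jitter as a fraction of \code{period}.
#' @param seed RNG seed (jitter only).
#' @param t_end,dt grid.
#' @param t_transient transient recorded in the config (h).
#' @param width Gaussian bump width (h).
#' @param scale overall amplitude scale.
#' @return a \code{trajectory} with \code{Cdk1}/\code{Cdk2} observables and
#'   a \code{ground_truth} field (expected label under 24 h forcing, true
#'   period, true peak times).
#' @export
synthetic_trace <- function(period = 24, amp_ratio = 1,
                            cdk1 = c("large", "minute"), jitter = 0,
                            seed = 1, t_end = 24 * 50, dt = 0.1,
                            t_transient = 240, width = 1, scale = 1) {
  cdk1 <- match.arg(cdk1)
  stopifnot(period > 0, amp_ratio >= 1, jitter >= 0)
  set.seed(seed)
  times <- seq(0, t_end, by = dt)
  centers <- seq(14, t_end - 2, by = period)  # late-L phase convention
  jit <- if (jitter > 0)
    stats::runif(length(centers), -jitter * period, jitter * period)
  else rep(0, length(centers))
  c2 <- centers + jit
  bump <- function(ctrs, amps) {
    v <- numeric(length(times))
    for (i in seq_along(ctrs))
      v <- v + amps[i] * exp(-0.5 * ((times - ctrs[i]) / width)^2)
    v
  }
  a1 <- rep(c(1, 1 / amp_ratio), length.out = length(c2))
  if (cdk1 == "minute") a1 <- rep(0.01, length(c2))
  cdk1_v <- scale * bump(c2, a1)
  cdk2_v <- scale * bump(c2 - 0.25 * period, rep(1, length(c2)))
  states <- cbind(Cdk1_s = cdk1_v, Cdk2_s = cdk2_v)
  cfg <- simulation_config(t_end = t_end, t_transient = t_transient,
                           dt_out = dt)
  traj <- .new_trajectory(times, states,
                          list(Cdk1 = cdk1_v, Cdk2 = cdk2_v),
                          list(list(from = 0, params = NULL)),
                          list(name = "synthetic"), cfg)
  label <- if (cdk1 == "minute") {
    if (abs(period - 24) < 0.24) "endoreplication" else "unlocked"
  } else if (amp_ratio >= 5) "tetraploid_pattern"
  else if (abs(period - 24) / 24 < 0.005) "entrained_24"
  else if (abs(period - 48) / 48 < 0.005) "entrained_48"
  else "complex_periodic"
  traj$ground_truth <- list(label = label, period = period,
                            cdk1_peak_times = c2, amp_ratio = amp_ratio,
                            cdk1_class = cdk1)
  traj
}
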