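# peak detection, amplitude classes, period estimation, stroboscopic maps
# and the regime classifier (on constructed fixtures with known truth)

test_that("detect_peaks finds sinusoid peaks and ignores flat traces", {
  tt <- seq(0, 240, by = 0.1)
  pk <- detect_peaks(sin(2 * pi * tt / 24), tt)
  expect_equal(length(pk$peak_times), 10)
  expect_equal(mean(diff(pk$peak_times)), 24, tolerance = 1e-3)

  expect_length(detect_peaks(rep(1, 100), seq_len(100))$peak_times, 0)
  expect_error(detect_peaks(numeric(), numeric()), "empty")
})

test_that("detect_peaks prominence threshold separates two-scale spikes", {
  # alternating tall (1.0) and tiny (0.01) bumps, ground truth known
  tt <- seq(0, 200, by = 0.05)
  ctr <- seq(5, 195, by = 10)
  amp <- rep(c(1, 0.01), length.out = length(ctr))
  y <- rowSums(vapply(seq_along(ctr),
                      function(i) amp[i] * exp(-((tt - ctr[i]) / 0.8)^2),
                      numeric(length(tt))))
  pk <- detect_peaks(y, tt, min_prominence = 0.05)
  expect_equal(length(pk$peak_times), sum(amp == 1))
  expect_true(all(abs(pk$peak_times - ctr[amp == 1]) < 0.2))
  # with a permissive threshold both scales are reported
  pk2 <- detect_peaks(y, tt, min_prominence = 0.001)
  expect_equal(length(pk2$peak_times), length(ctr))
})

test_that("split_amplitude_classes finds the documented splits", {
  mk <- function(h) list(peak_times = seq_along(h), peak_heights = h)
  # oracle for the fixture {1.0, 1.1, 0.01, 0.012}: exhaustive search over
  # split points of the sorted log-heights gives the largest gap between
  # 0.012 and 1.0; geometric means 0.010954 and 1.0488 -> ratio 95.74
  r <- split_amplitude_classes(mk(c(1.0, 1.1, 0.01, 0.012)))
  expect_true(r$bimodal)
  expect_equal(sum(r$labels == "large"), 2)
  expect_equal(r$separation, sqrt(1 * 1.1) / sqrt(0.01 * 0.012),
               tolerance = 1e-10)
  expect_equal(r$separation, 95.74, tolerance = 1e-3)

  r2 <- split_amplitude_classes(mk(c(1.0, 1.05, 0.98)))
  expect_false(r2$bimodal)
  expect_true(all(r2$labels == "large"))

  r3 <- split_amplitude_classes(mk(1.0))
  expect_equal(r3$labels, "large")
})

test_that("estimate_period matches interval statistics", {
  mk <- function(tt) list(peak_times = tt, peak_heights = rep(1, length(tt)))
  expect_equal(estimate_period(mk(c(0, 24, 48, 72))),
               list(period = 24, cv = 0))
  expect_equal(estimate_period(mk(c(0, 20, 40)))$period, 20)
  expect_error(estimate_period(mk(c(0, 24))), "insufficient")

  # jittered train: oracle = direct statistics of the generated intervals
  set.seed(11)
  iv <- 24 + runif(50, -0.5, 0.5)
  est <- estimate_period(mk(cumsum(c(0, iv))))
  expect_equal(est$period, mean(iv), tolerance = 1e-12)
  expect_equal(est$cv, sd(iv) / mean(iv), tolerance = 1e-12)
  expect_lt(abs(est$period - 24), 0.2)
  expect_lt(est$cv, 0.02)
})

test_that("stroboscopic_map counts locked multiplicities k = 1, 2, 3", {
  mk_periodic <- function(k) {
    tt <- seq(0, 24 * 60, by = 0.1)
    v1 <- 2 + sin(2 * pi * tt / (24 * k))
    v2 <- 2 + cos(2 * pi * tt / (24 * k))
    cfg <- simulation_config(t_end = max(tt), t_transient = 240,
                             dt_out = 0.1)
    cdkclock:::.new_trajectory(tt, cbind(a = v1, b = v2),
                               list(Cdk1 = v1, Cdk2 = v2),
                               list(), list(name = "per"), cfg)
  }
  for (k in 1:3) {
    sm <- stroboscopic_map(mk_periodic(k), 24)
    expect_equal(sm$distinct, k, info = paste("k =", k))
    expect_false(sm$capped)
  }
  expect_error(stroboscopic_map(synthetic_trace(t_end = 480), 24),
               "too short")
})

test_that("stroboscopic count of a chaotic forced oscillator keeps growing", {
  # forced Duffing oscillator in a standard chaotic regime, integrated by
  # the same engine through an R rhs
  duff <- model_spec(
    c("x", "v"),
    function(t, y, p) c(y[2],
                        y[1] - y[1]^3 - 0.25 * y[2] + 0.4 * cos(t)),
    default_init = c(0.1, 0), name = "duffing")
  Tf <- 2 * pi
  cfg <- simulation_config(t_end = 260 * Tf, t_transient = 20 * Tf,
                           dt_out = Tf / 40)
  traj <- integrate_model(duff, config = cfg)
  sm_all <- stroboscopic_map(traj, Tf, observables = c("x", "v"), cap = 64)
  expect_true(sm_all$capped)  # no saturation below the cap
})

test_that("classifier matches ground truth on the synthetic fixture grid", {
  for (period in c(12, 24, 36, 48))
    for (amp_ratio in c(1, 10, 100))
      for (jitter in c(0, 0.01)) {
        tr <- synthetic_trace(period = period, amp_ratio = amp_ratio,
                              jitter = jitter, seed = 7)
        cl <- classify_dynamics(tr)
        expect_equal(cl$label, tr$ground_truth$label,
                     info = sprintf("period=%g ratio=%g jitter=%g",
                                    period, amp_ratio, jitter))
      }
  # endoreplication and quiescent fixtures
  endo <- synthetic_trace(period = 24, cdk1 = "minute")
  expect_equal(classify_dynamics(endo)$label, "endoreplication")
  flat <- synthetic_trace(period = 24)
  flat$observables$Cdk1[] <- 1
  flat$observables$Cdk2[] <- 0.5
  expect_equal(classify_dynamics(flat)$label, "quiescent")
})

test_that("classifier is invariant to rescaling and 24 h translation", {
  base <- synthetic_trace(period = 48, amp_ratio = 1, jitter = 0.005,
                          seed = 3)
  lab0 <- classify_dynamics(base)$label
  resc <- base
  resc$observables <- lapply(resc$observables, function(v) v * 137.5)
  expect_equal(classify_dynamics(resc)$label, lab0)
  shift <- base
  shift$times <- shift$times + 48
  expect_equal(classify_dynamics(shift)$label, lab0)
})

test_that("estimate_period recovers generator period within 1% at low jitter", {
  for (period in c(12, 24, 36)) {
    tr <- synthetic_trace(period = period, jitter = 0.01, seed = 5)
    s <- traj_series(tr, "Cdk1", after = 240)
    est <- estimate_period(detect_peaks(s$values, s$times))
    expect_lt(abs(est$period - period) / period, 0.01)
  }
})

test_that("phase_in_ld maps times into the LD cycle", {
  mk <- function(tt) list(peak_times = tt, peak_heights = rep(1, length(tt)))
  ph <- phase_in_ld(mk(158))
  expect_equal(ph$phases, 14)
  expect_true(ph$in_light)
  expect_true(ph$all_in_second_half_L)
  ph2 <- phase_in_ld(mk(20))
  expect_equal(ph2$phases, 20)
  expect_false(ph2$in_light)
  # circular mean across midnight
  ph3 <- phase_in_ld(mk(c(23, 25)))
  expect_equal(ph3$circular_mean_h, 0, tolerance = 1e-9)
  expect_error(phase_in_ld(mk(numeric())), "empty")
})
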