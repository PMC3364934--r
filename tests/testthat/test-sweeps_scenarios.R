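# calibration, tongue scans, hysteresis probe, scenario presets, digests

test_that("calibrate_timescale applies the exact scaling law", {
  Tref <- cached("Tref", reference_period())
  expect_equal(calibrate_timescale(Tref, verify = FALSE), 1, tolerance = 1e-9)
  s2 <- calibrate_timescale(Tref / 2)  # verified integration inside
  expect_equal(s2, 2, tolerance = 1e-9)
})

test_that("printed eps pairs support the uniform-scaling reading", {
  expect_equal(21.58 * 20, 431.6, tolerance = 1e-12)
  expect_equal(15.37 * 28, 430.36, tolerance = 1e-12)
  expect_lt(abs(21.58 * 20 - 15.37 * 28) / (21.58 * 20), 0.003)
})

tongue_small <- function() cached("tongue_small", arnold_tongue_scan(
  c(20, 24, 28), c(0.002, 0.1), mode = "wee1",
  t_transient = 360, t_window = 720))

test_that("tongue scan labels every cell and never entrains at near-zero coupling", {
  map <- tongue_small()
  expect_true(all(!is.na(map$labels)))
  expect_false(any(startsWith(map$labels[, "c0.002"], "entrained")))
  # full-strength coupling entrains on both sides of 24 h
  expect_equal(unname(map$labels["T20", "c0.1"]), "entrained_24")
  expect_equal(unname(map$labels["T28", "c0.1"]), "entrained_24")
})

test_that("tongue map serialises to JSON and long CSV", {
  map <- tongue_small()
  js <- tempfile(fileext = ".json")
  cs <- tempfile(fileext = ".csv")
  write_tongue_map(map, js, cs)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$period_axis, map$period_axis)
  df <- utils::read.csv(cs)
  expect_equal(nrow(df), length(map$labels))
  expect_setequal(names(df), c("period_h", "coupling", "label"))
  unlink(c(js, cs))
})

test_that("config digest is stable under key reordering", {
  a <- config_digest(list(x = 1, y = list(b = 2, a = "s"), z = 1:3))
  b <- config_digest(list(z = 1:3, y = list(a = "s", b = 2), x = 1))
  c <- config_digest(list(z = 1:3, y = list(a = "s", b = 3), x = 1))
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("gf_square_schedule alternates GF and respects the window", {
  sc <- gf_square_schedule(120, 280, 12, 0, 1)
  times <- vapply(sc, function(e) e$time, 0)
  gfs <- vapply(sc, function(e) e$params$GF, 0)
  expect_equal(times, seq(120, 276, by = 12))
  expect_equal(gfs, rep(c(0, 1), length.out = length(times)))
})

test_that("hysteresis probe returns direction-resolved labels", {
  hp <- hysteresis_probe(20, c(0.08, 0.1), mode = "wee1",
                         t_settle = 360, t_measure = 480)
  expect_s3_class(hp, "data.frame")
  expect_equal(names(hp), c("coupling", "up", "down"))
  # far inside the 1:1 tongue both sweep directions agree
  expect_equal(hp$up[2], "entrained_24")
  expect_equal(hp$up, hp$down)
  expect_true(is.numeric(attr(hp, "coexistence")) ||
                length(attr(hp, "coexistence")) == 0)
})

test_that("scenario presets reproduce their frozen outcomes", {
  expect_error(scenario_run("nope"), "available")
  sc <- list_scenarios()
  expect_true(all(c("fig2", "fig8b", "fig13", "fig15") %in% sc$name))

  r <- scenario_run("fig2", "20")
  expect_equal(r$classification$label, "entrained_24")
  expect_equal(r$classification$metrics$locked_period, 24, tolerance = 0.01)

  r <- scenario_run("fig6", "e")   # endoreplication at strong coupling
  expect_equal(r$classification$label, "endoreplication")

  r <- scenario_run("fig13", "quiescent")  # GF-wave entrainment from G0
  expect_equal(r$classification$label, "entrained_24")
})

test_that("weak coupling fails to entrain (fig5 presets)", {
  r <- scenario_run("fig5", "c")
  expect_false(startsWith(r$classification$label, "entrained"))
})

test_that("Cry-deletion emulation slows the entrained cycle (fig15)", {
  r <- scenario_run("fig15")
  tr <- r$trajectory
  s1 <- traj_series(tr, "Cdk1")
  pre <- s1$times >= 240 & s1$times < 480
  post <- s1$times >= 600
  iv_pre <- diff(detect_peaks(s1$values[pre], s1$times[pre], 0.05)$peak_times)
  iv_post <- diff(detect_peaks(s1$values[post], s1$times[post],
                               0.05)$peak_times)
  expect_equal(mean(iv_pre), 24, tolerance = 0.01)     # entrained before
  expect_gt(mean(iv_post), 36)                         # slowed to ~40 h
  expect_lt(mean(iv_post), 44)
  # Wee1 mRNA rises by roughly a third upon the clamp
  mw <- traj_series(tr, "Wee1_mRNA")
  ratio <- max(mw$values[post]) / max(mw$values[pre])
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 1.6)
  # the clamped clock is arrhythmic: Bn flat after the event
  bn <- traj_series(tr, "BMAL1", after = 600)
  expect_lt(diff(range(bn$values)), 1e-9)
})

test_that("forced circadian spikes appear only just past the pRB bifurcation", {
  ra <- scenario_run("fig12", "excitable")
  rb <- scenario_run("fig12", "b")
  amp <- function(r) {
    s <- traj_series(r$trajectory, "Cdk1", after = 600)
    diff(range(s$values))
  }
  expect_gt(amp(ra) / amp(rb), 20)
  expect_true(startsWith(ra$classification$label, "entrained"))
})
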