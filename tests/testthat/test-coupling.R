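# coupling channels: Hill identities, hand-computed rates, steady states,
# monotonicity, mu-mode equivalence, and the compiled-vs-R rhs cross-check

test_that("wee1 mRNA balance matches hand calculations", {
  p <- coupling_params(modes = "wee1")
  expect_equal(wee1_mrna_rhs(0, 0, p), 0)
  # Hill half-saturation at Bn = K_aw
  expect_equal(wee1_mrna_rhs(0, p$K_aw, p), p$v_sw / 2)
  # v_sw = 0.1, Bn >> K_aw, Mw = K_dmw: 0.1 - 0.5/2 = -0.15
  expect_equal(wee1_mrna_rhs(p$K_dmw, 1e6, p), 0.1 - 0.25,
               tolerance = 1e-10)
})

test_that("wee1 protein synthesis combines basal and mRNA terms", {
  p <- coupling_params(modes = "wee1")
  expect_equal(wee1_protein_synthesis(0, p, v_swee1 = 0.06), 0.06)
  expect_equal(wee1_protein_synthesis(0, p, v_swee1 = 0), 0)
  expect_equal(wee1_protein_synthesis(0.02, p, v_swee1 = 0), 0.1)  # k_sw = 5
})

test_that("p21 channel: repression limits and closed-form steady state", {
  p <- coupling_params(modes = "p21")
  expect_equal(p21_coupling_rhs(0, 0, p)$mrna_rate, p$v_smp21)
  expect_equal(p21_coupling_rhs(0, p$K_ip21, p)$mrna_rate, p$v_smp21 / 2)
  # Rn clamped to 0: Mp21 converges to M* solving v_smp21 = V_dmp21 M/(K+M),
  # i.e. M* = K_dmp21 * v_smp21 / (V_dmp21 - v_smp21) = 0.5*0.46/0.04 = 5.75
  mstar <- p$K_dmp21 * p$v_smp21 / (p$V_dmp21 - p$v_smp21)
  expect_equal(mstar, 5.75)
  expect_equal(p21_coupling_rhs(mstar, 0, p)$mrna_rate, 0, tolerance = 1e-12)
  # monotone approach from below
  m <- model_spec("Mp21",
                  function(t, y, p2) p21_coupling_rhs(y, 0, p)$mrna_rate,
                  default_init = 0, name = "p21mrna")
  tr <- integrate_model(m, config = simulation_config(1600, dt_out = 2))
  expect_true(all(diff(tr$states[, 1]) >= -1e-9))
  expect_equal(unname(tr$states[nrow(tr$states), 1]), mstar,
               tolerance = 1e-2)
  expect_equal(p21_coupling_rhs(0.1, 0, p)$protein_contribution, 5)
})

test_that("cyclin E channel: repression limits", {
  p <- coupling_params(modes = "cyclinE")
  expect_equal(cyclinE_coupling_rhs(0, 0, p)$mrna_rate, p$v_sce)
  expect_equal(cyclinE_coupling_rhs(0, p$K_ice, p)$mrna_rate, p$v_sce / 2)
  expect_lt(cyclinE_coupling_rhs(0, 1e9, p)$mrna_rate, 1e-12)
  expect_equal(cyclinE_coupling_rhs(0.3, 0, p)$protein_contribution, 1.5)
})

test_that("mRNA synthesis is monotone in its circadian driver", {
  p <- coupling_params(modes = c("wee1", "p21", "cyclinE"))
  bn <- seq(0, 10, by = 0.1)
  syn_w <- wee1_mrna_rhs(0, bn, p)
  expect_true(all(diff(syn_w) >= 0))
  syn_e <- vapply(bn, function(b)
    cyclinE_coupling_rhs(0, b, p)$mrna_rate, 0)
  expect_true(all(diff(syn_e) <= 0))
  rn <- seq(0, 5, by = 0.05)
  syn_p <- vapply(rn, function(r)
    p21_coupling_rhs(0, r, p)$mrna_rate, 0)
  expect_true(all(diff(syn_p) <= 0))
})

test_that("coupling_params validates the mu-mode contract", {
  cp <- coupling_params(modes = c("wee1", "p21", "cyclinE"), mu = 0.01)
  expect_equal(c(cp$v_sw, cp$v_smp21, cp$v_sce), c(1, 1, 1))
  expect_equal(c(cp$mu_w, cp$mu_p, cp$mu_c), rep(0.01, 3))
  expect_error(coupling_params(modes = "wee1", mu = 0.01, v_sw = 0.5),
               "mu-mode")
  expect_error(assemble_coupled_system(
    cdk_params(), clock_model(),
    local({ cp2 <- coupling_params(modes = "wee1", mu = 0.01)
            cp2$v_sw <- 0.5; cp2 })),
    "mu-mode")
})

test_that("compiled and R right-hand sides agree on random states", {
  set.seed(1)
  model <- assemble_coupled_system(cdk_params(),
                                   clock_model(),
                                   coupling_params(modes = c("wee1", "p21",
                                                             "cyclinE")))
  pk <- model$native$pack(model$params)
  for (i in 1:25) {
    y <- runif(20, 0, 2)
    y[c(13, 14, 15)] <- runif(3)  # fractions
    t <- runif(1, 0, 48)
    d_r <- model$rhs(t, y, model$params)
    d_c <- cdkclock:::cpp_rhs("coupled", t, y, pk)
    expect_equal(unname(d_r), unname(d_c), tolerance = 1e-12)
  }
})

test_that("mu = 0 gives the direct sum of the uncoupled models", {
  model <- assemble_coupled_system(
    cdk_params(), clock_model(),
    coupling_params(modes = c("wee1", "p21", "cyclinE"), mu = 0))
  cfg <- simulation_config(t_end = 60, dt_out = 0.5)
  tr <- integrate_model(model, config = cfg)
  clk <- integrate_model(clock_model(), config = cfg)
  cdk <- integrate_model(cdk_model(), config = cfg)
  expect_equal(tr$states[, 1:4], clk$states, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(tr$states[, 5:17], cdk$states, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_true(all(tr$states[, 18:20] == 0))  # mRNAs never synthesised
})

test_that("mu-mode with one flag equals the single-mode system", {
  cdk <- cdk_params(s = reference_period() / 20)
  m1 <- assemble_coupled_system(cdk, clock_model(),
                                coupling_params(modes = "wee1", mu = 0.05))
  m2 <- assemble_coupled_system(cdk, clock_model(),
                                coupling_params(modes = "wee1",
                                                v_sw = 0.05))
  cfg <- simulation_config(t_end = 120, dt_out = 0.5)
  t1 <- integrate_model(m1, config = cfg)
  t2 <- integrate_model(m2, config = cfg)
  expect_equal(t1$states, t2$states, tolerance = 1e-6)
})

test_that("each mRNA converges to its scalar steady state under a clamp", {
  # driver clamped via bn_clamp; closed-form steady state of the scalar
  # balance synthesis = V_dm * M / (K_dm + M)
  cp <- coupling_params(modes = "wee1", v_sw = 0.1)
  bn <- 3
  syn <- cp$v_sw * bn^4 / (cp$K_aw^4 + bn^4)
  mstar <- cp$K_dmw * syn / (cp$V_dmw - syn)
  clk <- clock_params(bn_clamp = bn)
  model <- assemble_coupled_system(cdk_params(), clock_model(clk), cp)
  tr <- integrate_model(model, config = simulation_config(300, dt_out = 1))
  expect_equal(tr$states[nrow(tr$states), "Mw"], mstar, tolerance = 1e-4,
               ignore_attr = TRUE)
})
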