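test_that("AP metrics recover a constructed trapezoid waveform", {
  tr <- trapezoid_trace()
  m <- ap_metrics(tr)
  expect_true(m$detected)
  expect_equal(m$resting, -85)
  expect_equal(m$peak, 35)
  expect_equal(m$amplitude, 120)
  # linear repolarisation over 300 ms: 90% repolarisation at 270 ms
  expect_equal(m$apd90, 270, tolerance = 0.01)
  expect_equal(m$apd50, 150, tolerance = 0.01)
  # plateau mean between the APD20 and APD50 crossing levels
  expect_equal(m$plateau, 35 - 120 * 0.35, tolerance = 1)

  flat <- trapezoid_trace()
  flat$V_myo <- -85
  expect_false(ap_metrics(flat)$detected)
})

test_that("metrics are pure and robust to sampling density", {
  m1 <- ap_metrics(trapezoid_trace(dt = 0.5))
  m2 <- ap_metrics(trapezoid_trace(dt = 0.5))
  expect_identical(m1, m2)
  m3 <- ap_metrics(trapezoid_trace(dt = 0.1))
  expect_equal(m1$apd90, m3$apd90, tolerance = 0.005)
  expect_equal(m1$resting, m3$resting)
})

test_that("gap-current decomposition: zero when uncoupled, reduced when
           dynamic", {
  g0 <- igap_components(trace_uncoupled())
  expect_equal(g0$early_peak, 0)
  expect_equal(g0$late, 0)

  tr_d <- simulate_pair(1, "Cx45", 3, n_beats = 1, t_end = 450)
  cfg_d <- attr(tr_d, "config")
  tr_s <- simulate_pair(1, "static", realized_gj_max(cfg_d), n_beats = 1,
                        t_end = 450)
  cd <- igap_components(tr_d); cs <- igap_components(tr_s)
  expect_lt(cd$early_peak, cs$early_peak)
  # early peak sits inside the early window
  expect_lte(cd$early_time - cd$t_upstroke, 10)
  expect_gte(cd$early_time - cd$t_upstroke, 0)
})

test_that("delta I_gap,peak is zero for identical configs and negative
           for gated ones", {
  tr_s <- trace_static_n2()
  expect_equal(delta_igap_peak(tr_s, tr_s), 0)

  cfg_f <- coupling_config(2, gj_model = "Cx43", g_j_max = 3,
                           freeze_gates = TRUE)
  tr_f <- simulate_coupled(coupled_system(cfg_f), 450)
  expect_lt(abs(delta_igap_peak(tr_f, trace_static_n2())), 0.05)

  tr_d <- simulate_pair(4, "Cx45", 3, n_beats = 1, t_end = 450)
  tr_sm <- simulate_pair(4, "static",
                         realized_gj_max(attr(tr_d, "config")),
                         n_beats = 1, t_end = 450)
  expect_lt(delta_igap_peak(tr_d, tr_sm), 0)

  # mismatched configurations are refused
  expect_error(delta_igap_peak(tr_d, trace_uncoupled()), "mismatch")
})

test_that("a single-cell sweep grid reduces to delta_igap_peak", {
  sw <- sweep_delta_igap(ratios = 2, conductances = 3,
                         phenotype = "Cx45", t_end = 450,
                         output_dt = 0.1)
  tr_d <- simulate_pair(2, "Cx45", 3, n_beats = 1, t_end = 450)
  tr_s <- simulate_pair(2, "static",
                        realized_gj_max(attr(tr_d, "config")),
                        n_beats = 1, t_end = 450)
  expect_equal(sw$delta[1, 1], delta_igap_peak(tr_d, tr_s),
               tolerance = 0.02)
  expect_equal(sweep_argmax_conductance(sw), 3)
})

test_that("spontaneous-activity detection separates paced, ectopic and
           suppressed regimes", {
  # paced-only run: no spontaneous events
  expect_length(detect_spontaneous(trace_uncoupled()), 0)

  # strong depolarising coupling, no stimulus: ectopic upstroke fires
  cfg <- coupling_config(2, fibroblast = "passive", gj_model = "static",
                         g_j_max = 8,
                         fib_params = passive_fibroblast(G_f = 4, E_f = 0))
  tr <- simulate_coupled(coupled_system(cfg, stimulus = NULL), 3000,
                         output_dt = 0.5)
  expect_gt(length(detect_spontaneous(tr)), 0)

  # very high density/coupling: sustained depolarisation block, no events
  # once the depolarised quasi-steady state is reached
  cfg_hi <- coupling_config(8, fibroblast = "passive",
                            gj_model = "static", g_j_max = 8,
                            fib_params = passive_fibroblast(G_f = 8,
                                                            E_f = 0))
  tr_hi <- simulate_coupled(coupled_system(cfg_hi, stimulus = NULL),
                            6000, output_dt = 0.5)
  late <- tr_hi[tr_hi$t > 1000, ]
  expect_length(detect_spontaneous(late), 0)
  # and the membrane sits depolarised (inexcitable), not resting
  expect_gt(tail(tr_hi$V_myo, 1), -40)
})
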