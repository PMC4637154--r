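test_that("transjunctional voltage and gap current follow the stated
           conventions", {
  expect_equal(transjunctional_voltage(-50, -50), 0)
  expect_equal(gap_current(10, 3), 30)
  expect_equal(gap_current(0, 5), 0)
  expect_error(gap_current(10, -1), "G_j")

  # resting models: depolarised fibroblast, polarised myocyte -> V_j > 0
  tr <- simulate_pair(1, "static", 3, n_beats = 1, t_end = 450)
  vj0 <- tr$V_j[1]
  expect_gt(vj0, 30); expect_lt(vj0, 40)
  # during the upstroke the myocyte depolarises first: V_j swings strongly
  # negative
  expect_lt(min(tr$V_j), -80)
})

test_that("charge is conserved at every F-M junction", {
  cfg <- coupling_config(3, gj_model = "Cx45", g_j_max = 3)
  sys <- coupled_system(cfg)
  y <- sys$y0
  # perturb states so nothing is at equilibrium
  y[sys$index$myo[1]] <- -60
  y[sys$index$fib[c(1, 6, 11)]] <- c(-40, -55, -20)
  out <- coupled_rhs(sys, t = 0, y = y)
  # current into the myocyte equals minus the summed current into the
  # fibroblasts, by the same I_gap in both equations
  V_m <- y[sys$index$myo[1]]
  for (i in 1:3) {
    V_f <- y[sys$index$fib[1 + (i - 1) * 5]]
    expect_equal(unname(out$aux$I_gap[i]),
                 unname(out$aux$G_j[i] * (V_f - V_m)), tolerance = 1e-12)
  }
  expect_equal(out$aux$I_gap_total, sum(out$aux$I_gap), tolerance = 1e-12)
  # the fibroblast voltage equation receives exactly -I_gap: recompute
  fs <- list(Vf = y[sys$index$fib[1]], r = y[sys$index$fib[2]],
             s = y[sys$index$fib[3]], Ki = y[sys$index$fib[4]],
             Nai = y[sys$index$fib[5]])
  d_expect <- maccannell_rhs(fs, cfg$fib_params,
                             I_inj = -out$aux$I_gap[1])$deriv$Vf
  expect_equal(unname(out$deriv[sys$index$fib[1]]), unname(d_expect),
               tolerance = 1e-12)
})

test_that("N = 0 reduces exactly to the uncoupled myocyte", {
  stim <- stimulus_protocol(n_beats = 1)
  tr0 <- simulate_coupled(coupled_system(coupling_config(0), stim),
                          300, output_dt = 0.5)
  p <- lr1_params()
  rhs <- function(t, y, parms)
    list(unlist(lr1_rhs(y, stimulus_current(t, stim) * p$C_m, p)$deriv,
                use.names = FALSE))
  ref <- deSolve::lsoda(lr1_init(), seq(0, 300, by = 0.5), rhs, NULL,
                        rtol = 1e-6, atol = 1e-8, hmax = 1)
  expect_lt(max(abs(tr0$V_myo - ref[, "V"])), 1e-5)
  expect_true(all(tr0$I_gap_total == 0))
})

test_that("frozen-open dynamic coupling reproduces static traces", {
  stim <- stimulus_protocol(n_beats = 1)
  for (ph in c("Cx43", "Cx45", "Cx43/Cx45")) {
    for (N in c(1, 4, 8)) {
      cfg_d <- coupling_config(N, gj_model = ph, g_j_max = 3,
                               freeze_gates = TRUE)
      cfg_s <- coupling_config(N, gj_model = "static",
                               g_j_max = realized_gj_max(cfg_d))
      tr_d <- simulate_coupled(coupled_system(cfg_d, stim), 300,
                               output_dt = 0.5)
      tr_s <- simulate_coupled(coupled_system(cfg_s, stim), 300,
                               output_dt = 0.5)
      # 1e-6 relative on a ~100 mV signal
      expect_lt(max(abs(tr_d$V_myo - tr_s$V_myo)), 1e-4)
      ig_d <- tr_d$I_gap_total; ig_s <- tr_s$I_gap_total
      expect_lt(max(abs(ig_d - ig_s)) / max(abs(ig_s)), 1e-5)
    }
  }
  # conductance extremes at a fixed fibroblast count
  for (g in c(0.5, 8)) {
    cfg_d <- coupling_config(2, gj_model = "Cx45", g_j_max = g,
                             freeze_gates = TRUE)
    cfg_s <- coupling_config(2, gj_model = "static",
                             g_j_max = realized_gj_max(cfg_d))
    tr_d <- simulate_coupled(coupled_system(cfg_d, stim), 300,
                             output_dt = 0.5)
    tr_s <- simulate_coupled(coupled_system(cfg_s, stim), 300,
                             output_dt = 0.5)
    expect_lt(max(abs(tr_d$V_myo - tr_s$V_myo)), 1e-4)
  }
})

test_that("static coupling shortens APD, lowers the plateau and
           depolarises rest", {
  m0 <- ap_metrics(trace_uncoupled())
  m2 <- ap_metrics(trace_static_n2())
  expect_lt(m2$apd90, m0$apd90)
  expect_lt(m2$plateau, m0$plateau)
  expect_gt(m2$resting, m0$resting)
})

test_that("APD90 shortens monotonically with fibroblast count", {
  apd <- sapply(c(0, 2, 8), function(N) {
    tr <- if (N == 0) trace_uncoupled() else if (N == 2)
      trace_static_n2() else
        simulate_pair(N, "static", 3, n_beats = 1, t_end = 450)
    ap_metrics(tr)$apd90
  })
  expect_true(all(diff(apd) < 0))
})

test_that("a hyperpolarised passive fibroblast leaves the resting
           potential unchanged", {
  quiet <- stimulus_protocol(n_beats = 0)
  tr0 <- simulate_coupled(coupled_system(coupling_config(0), quiet),
                          2000, output_dt = 10)
  cfg <- coupling_config(2, fibroblast = "passive", gj_model = "static",
                         g_j_max = 3,
                         fib_params = passive_fibroblast(E_f = -80))
  tr80 <- simulate_coupled(coupled_system(cfg, quiet), 2000,
                           output_dt = 10)
  expect_lt(abs(tail(tr80$V_myo, 1) - tail(tr0$V_myo, 1)), 1)
})

test_that("output sampling density does not change the solution", {
  sys <- coupled_system(coupling_config(1, gj_model = "Cx43"))
  tr1 <- simulate_coupled(sys, 300, output_dt = 0.1)
  tr2 <- simulate_coupled(sys, 300, output_dt = 0.2)
  shared <- tr1$t %in% tr2$t
  expect_lt(max(abs(tr1$V_myo[shared] - tr2$V_myo)), 0.05)
})

test_that("coupling configuration validates and classifies fibrosis", {
  expect_error(coupling_config(-1), "n_fibroblasts")
  expect_error(coupling_config(1, g_j_max = 0), "g_j_max")
  expect_equal(fm_ratio_class(2), "normal")
  expect_equal(fm_ratio_class(3), "diseased")
  cfg <- coupling_config(1, gj_model = "Cx43", g_j_max = 3)
  expect_equal(cfg$N_C, 60L)                    # 3 nS / 50 pS
  expect_equal(realized_gj_max(cfg), 3)
})
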