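hc100 <- hemichannel(g_H = 100, g_L = 25, lambda = 0.01,
                     A_open = 0.02, A_close = 0.1, V0 = 30)

test_that("channel state conductance is the series combination", {
  expect_equal(channel_state_conductance("HH", hc100, hc100), 50)
  hcB <- hc100; hcB$g_L <- 25
  # A open (100 pS) in series with B residual (25 pS) -> 20 pS
  expect_equal(channel_state_conductance("HL", hc100, hcB), 20)
  g <- sapply(c("HH", "HL", "LH", "LL"), channel_state_conductance,
              hcA = hc100, hcB = hc100)
  expect_true(g[["HH"]] > g[["HL"]])
  expect_true(g[["HH"]] > g[["LH"]])
  expect_true(g[["HL"]] > g[["LL"]])
  expect_true(g[["LH"]] > g[["LL"]])
})

test_that("transjunctional voltage divides by hemichannel resistance", {
  expect_equal(unname(hemichannel_voltages(80, "HH", hc100, hc100)),
               c(40, 40))
  expect_equal(unname(hemichannel_voltages(0, "HL", hc100, hc100)),
               c(0, 0))
  set.seed(7)
  for (k in 1:20) {
    hcA <- hemichannel(runif(1, 40, 150), runif(1, 5, 30), 0.01,
                       0.02, 0.1, V0 = 30)
    hcB <- hemichannel(runif(1, 40, 150), runif(1, 5, 30), 0.01,
                       0.02, 0.1, V0 = 30)
    vj <- runif(1, -120, 120)
    st <- sample(c("HH", "HL", "LH", "LL"), 1)
    v <- hemichannel_voltages(vj, st, hcA, hcB)
    expect_equal(unname(v[1] + v[2]), vj)            # Kirchhoff
    # division by resistance: v_A/v_B = gB/gA
    gA <- if (substr(st, 1, 1) == "H") hcA$g_H else hcA$g_L
    gB <- if (substr(st, 2, 2) == "H") hcB$g_H else hcB$g_L
    expect_equal(unname(v[1] * gA), unname(v[2] * gB), tolerance = 1e-10)
  }
})

test_that("gate rates are positive, finite, and favour H at rest", {
  v <- seq(-120, 120, by = 5)
  for (hc in list(connexin_hemichannel("Cx43"),
                  connexin_hemichannel("Cx45"))) {
    r <- vapply(v, function(u) gate_rates(u, hc), numeric(2))
    expect_true(all(r > 0 & is.finite(r)))
    r0 <- gate_rates(0, hc)
    expect_gt(r0[["rate_LH"]] / (r0[["rate_HL"]] + r0[["rate_LH"]]), 0.5)
  }
})

test_that("two-state gate equilibrium matches integrated kinetics", {
  hc <- connexin_hemichannel("Cx43")
  for (u in c(-60, 0, 25, 50)) {
    r <- gate_rates(u, hc)
    eq <- r[["rate_LH"]] / (r[["rate_HL"]] + r[["rate_LH"]])
    # integrate df_H/dt = (1-f) rate_LH - f rate_HL to its limit
    out <- deSolve::lsoda(c(f = 0.5), c(0, 20 / min(r)),
                          function(t, y, p)
                            list((1 - y) * r[["rate_LH"]] -
                                   y * r[["rate_HL"]]), NULL,
                          rtol = 1e-10, atol = 1e-12)
    expect_equal(unname(out[2, "f"]), unname(eq), tolerance = 1e-6)
  }
})

test_that("master equation conserves probability and has the stationary
           distribution in its null space", {
  set.seed(11)
  for (ph in c("Cx43", "Cx45", "Cx43/Cx45")) {
    pop <- gj_population(ph)
    for (k in 1:5) {
      f <- runif(4); f <- f / sum(f)
      pop$fractions <- setNames(f, c("HH", "HL", "LH", "LL"))
      vj <- runif(1, -110, 110)
      expect_lt(abs(sum(population_rhs(pop, vj))), 1e-14)
    }
    vj <- runif(1, -110, 110)
    pop$fractions <- gj_stationary(vj, pop$hcA, pop$hcB)
    expect_lt(max(abs(population_rhs(pop, vj))), 1e-12)
  }
})

test_that("stationary solve agrees with long-time integration", {
  set.seed(3)
  pop <- gj_population("Cx43/Cx45")
  for (vj in runif(12, -110, 110)) {
    direct <- gj_stationary(vj, pop$hcA, pop$hcB)
    rhs <- function(t, y, p) {
      pop$fractions <- y
      list(population_rhs(pop, vj))
    }
    out <- deSolve::lsoda(c(HH = 1, HL = 0, LH = 0, LL = 0),
                          c(0, 2e5), rhs, NULL, rtol = 1e-10,
                          atol = 1e-12, maxsteps = 50000)
    expect_equal(unname(out[2, -1]), unname(direct), tolerance = 1e-6)
  }
})

test_that("population conductance is the occupancy-weighted channel sum", {
  hc <- hc100
  pop <- gj_population("Cx43", N_C = 60, hcA = hc, hcB = hc)
  expect_equal(dynamic_conductance(pop), 3)        # 60 x 50 pS
  pop$fractions <- c(HH = 0, HL = 0, LH = 0, LL = 1)
  g_LL <- channel_state_conductance("LL", hc, hc)
  expect_equal(dynamic_conductance(pop), 60 * g_LL / 1000)
  set.seed(5)
  for (k in 1:10) {
    f <- runif(4); f <- f / sum(f)
    pop$fractions <- setNames(f, c("HH", "HL", "LH", "LL"))
    G <- dynamic_conductance(pop)
    expect_gte(G, 60 * g_LL / 1000 - 1e-12)
    expect_lte(G, 60 * 50 / 1000 + 1e-12)
  }
})

test_that("fraction sum stays 1 under an AP-shaped V_j clamp", {
  pop <- gj_population("Cx45")
  # stylised V_j excursion: sharp negative swing then plateau recovery
  vj_clamp <- function(t)
    ifelse(t < 5, -100 * t / 5,
           ifelse(t < 200, -80 + 75 * (t - 5) / 195, 30 * exp(-(t - 200) / 50)))
  rhs <- function(t, y, p) {
    pop$fractions <- y
    list(population_rhs(pop, vj_clamp(t)))
  }
  out <- deSolve::lsoda(c(HH = 1, HL = 0, LH = 0, LL = 0),
                        seq(0, 400, by = 1), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(rowSums(out[, -1]) - 1)), 1e-9)
  expect_true(all(out[, -1] > -1e-12))
})

test_that("homotypic curves are symmetric, bounded and Cx45-steeper", {
  c43 <- steady_state_curve("Cx43")
  c45 <- steady_state_curve("Cx45")
  for (cur in list(c43, c45)) {
    expect_true(all(cur$G_norm > 0 & cur$G_norm <= 1))
    expect_lt(max(abs(cur$G_norm - rev(cur$G_norm))), 1e-3)
  }
  sel <- c43$V_j > 0 & c43$V_j <= 80
  expect_true(all(c45$G_norm[sel] < c43$G_norm[sel]))
})

test_that("heterotypic curve is asymmetric with enhanced negative-V_j
           sensitivity", {
  het <- steady_state_curve("Cx43/Cx45")
  expect_lt(het$G_norm[het$V_j == -60], het$G_norm[het$V_j == 60])
  expect_gt(max(abs(het$G_norm - rev(het$G_norm))), 0.1)
  expect_true(all(het$G_norm > 0 & het$G_norm <= 1))
})

test_that("half-inactivation voltage is recovered on a synthetic curve", {
  v <- seq(-120, 120, by = 1)
  g <- 0.3 + 0.7 / (1 + exp((abs(v) - 40) / 6))
  syn <- data.frame(V_j = v, G_norm = g / max(g))
  expect_equal(half_inactivation_voltage(syn), 40, tolerance = 0.5 / 40)
  flat <- data.frame(V_j = v, G_norm = rep(1, length(v)))
  expect_error(half_inactivation_voltage(flat), "crossing")
})

test_that("calibrated half-inactivation voltages match the isoform ranges", {
  v43 <- half_inactivation_voltage(steady_state_curve("Cx43"))
  v45 <- half_inactivation_voltage(steady_state_curve("Cx45"))
  expect_gte(v43, 55); expect_lte(v43, 60)
  expect_gte(v45, 23); expect_lte(v45, 30)
})

test_that("modified-Boltzmann fit recovers its own generating parameters", {
  v <- seq(-110, 110, by = 2)
  tru <- list(G_max = 1, G_res = 0.28, Vp = 52, Vn = 52, Ap = 0.14,
              An = 0.14)
  g <- tru$G_res + (tru$G_max - tru$G_res) /
    ((1 + exp(tru$Ap * (v - tru$Vp))) * (1 + exp(-tru$An * (v + tru$Vn))))
  fit <- fit_modified_boltzmann(data.frame(V_j = v, G_norm = g))
  expect_equal(fit$G_max, tru$G_max, tolerance = 1e-6)
  expect_equal(fit$G_res, tru$G_res, tolerance = 1e-6)
  expect_equal(fit$V_half_pos, tru$Vp, tolerance = 1e-6)
  expect_equal(fit$V_half_neg, tru$Vn, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("fitted V_half agrees across methods and polarities", {
  c43 <- steady_state_curve("Cx43")
  f43 <- fit_modified_boltzmann(c43)
  expect_lt(abs(f43$V_half_pos - f43$V_half_neg), 1)   # homotypic symmetry
  c45 <- steady_state_curve("Cx45")
  f45 <- fit_modified_boltzmann(c45)
  expect_lt(abs(f45$V_half_cross_pos - half_inactivation_voltage(c45)), 2)
})

test_that("frozen-open population equals the static conductance", {
  cfg <- coupling_config(1, gj_model = "Cx43", g_j_max = 3,
                         freeze_gates = TRUE)
  tr <- simulate_coupled(coupled_system(cfg), 300, output_dt = 0.5)
  expect_true(all(abs(tr$G_j - realized_gj_max(cfg)) < 1e-12))
})
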