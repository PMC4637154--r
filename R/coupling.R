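#' Transjunctional voltage
#'
#' Convention: `V_j = V_fib - V_myo`, so that during the action-potential
#' upstroke (myocyte depolarising first) V_j swings strongly negative.
#'
#' @param V_fib fibroblast membrane potential (mV).
#' @param V_myo myocyte membrane potential (mV).
#' @return V_j (mV).
#' @export
transjunctional_voltage <- function(V_fib, V_myo) V_fib - V_myo

#' Gap junctional current
#'
#' Ohmic: `I_gap = G_j * V_j`. Positive I_gap is a depolarising current into
#' the myocyte and an equal-magnitude current out of the fibroblast, so
#' charge is conserved at the junction by construction.
#'
#' @param V_j transjunctional voltage (mV).
#' @param G_j junctional conductance (nS), >= 0.
#' @return I_gap (pA).
#' @export
gap_current <- function(V_j, G_j) {
  if (any(G_j < 0)) stop("G_j must be >= 0")
  G_j * V_j
}

#' Fibrosis classification of an F-M ratio
#'
#' @param N fibroblasts per myocyte.
#' @return "normal" for N <= 2, "diseased" for N > 2.
#' @export
fm_ratio_class <- function(N) ifelse(N <= 2, "normal", "diseased")

#' Configuration of one fibroblast-myocyte coupling unit
#'
#' @param n_fibroblasts number of identical fibroblasts coupled to the
#'   myocyte (star topology), >= 0.
#' @param fibroblast "active" (MacCannell) or "passive" (RC).
#' @param gj_model "static" (constant conductance) or a dynamic phenotype:
#'   "Cx43", "Cx45", "Cx43/Cx45".
#' @param g_j_max maximal junctional conductance per F-M connection (nS).
#'   For dynamic models the channel count is `N_C = round(g_j_max / g_HH)`
#'   and the realised maximum is `N_C * g_HH`; for paired static/dynamic
#'   comparisons use [realized_gj_max()] as the static conductance.
#' @param fib_params optional [passive_fibroblast()] or
#'   [active_fibroblast()] override.
#' @param contingent gating mode of the dynamic model (see
#'   [gj_population()]).
#' @param orientation heterotypic orientation flag (+1: side A = Cx43 on the
#'   myocyte side, side B = Cx45 on the fibroblast side).
#' @param freeze_gates if TRUE the four-state fractions are held at their
#'   initial value (all channels open); a frozen-open dynamic model is
#'   equivalent to the static model at the realised maximum.
#' @return List of class `coupling_config`.
#' @export
coupling_config <- function(n_fibroblasts = 1,
                            fibroblast = c("active", "passive"),
                            gj_model = c("static", "Cx43", "Cx45",
                                         "Cx43/Cx45"),
                            g_j_max = 3, fib_params = NULL,
                            contingent = TRUE, orientation = 1,
                            freeze_gates = FALSE) {
  fibroblast <- match.arg(fibroblast)
  gj_model <- match.arg(gj_model)
  n_fibroblasts <- as.integer(n_fibroblasts)
  if (n_fibroblasts < 0) stop("n_fibroblasts must be >= 0")
  if (n_fibroblasts > 0 && g_j_max <= 0)
    stop("g_j_max must be > 0 nS when fibroblasts are coupled")
  if (is.null(fib_params))
    fib_params <- if (fibroblast == "active") active_fibroblast() else
      passive_fibroblast()
  cfg <- list(n_fibroblasts = n_fibroblasts, fibroblast = fibroblast,
              gj_model = gj_model, g_j_max = g_j_max,
              fib_params = fib_params, contingent = contingent,
              orientation = orientation, freeze_gates = freeze_gates,
              fibrosis = fm_ratio_class(n_fibroblasts))
  if (gj_model != "static") {
    pop <- gj_population(gj_model, N_C = 1, contingent = contingent,
                         orientation = orientation)
    g_HH <- gj_state_conductances(pop$hcA, pop$hcB)[["HH"]] / 1000  # nS
    cfg$N_C <- max(1L, as.integer(round(g_j_max / g_HH)))
    cfg$hcA <- pop$hcA
    cfg$hcB <- pop$hcB
    cfg$g_states <- gj_state_conductances(pop$hcA, pop$hcB)
  }
  class(cfg) <- "coupling_config"
  cfg
}

#' Realised maximal junctional conductance of a configuration
#'
#' For dynamic models this is `N_C * g_HH` (nS), the all-open conductance
#' after rounding to an integer channel count; for the static model it is
#' `g_j_max` itself.
#'
#' @param config a [coupling_config()].
#' @return Conductance (nS).
#' @export
realized_gj_max <- function(config) {
  if (config$gj_model == "static") config$g_j_max
  else config$N_C * config$g_states[["HH"]] / 1000
}

#' Assemble an integrable fibroblast-myocyte system
#'
#' One myocyte, N identical fibroblasts each connected to it by its own gap
#' junction (star topology, no fibroblast-fibroblast coupling), and a
#' stimulus applied to the myocyte.
#'
#' @param config a [coupling_config()].
#' @param stimulus a [stimulus_protocol()] (applied to the myocyte,
#'   amplitude in pA/pF of myocyte capacitance), or NULL for none.
#' @param myocyte a [myocyte_model()].
#' @return List of class `coupled_system` with the flat initial state vector
#'   and an index map.
#' @export
coupled_system <- function(config = coupling_config(),
                           stimulus = stimulus_protocol(),
                           myocyte = myocyte_model()) {
  stopifnot(inherits(config, "coupling_config"))
  N <- config$n_fibroblasts
  y_myo <- myocyte$init()
  names(y_myo) <- paste0("myo.", myocyte$state_names)

  fib_names <- if (config$fibroblast == "active")
    active_fibroblast_state_names() else "Vf"
  y_fib <- NULL
  if (N > 0) {
    one <- if (config$fibroblast == "active")
      active_fibroblast_init(params = config$fib_params) else
        c(Vf = config$fib_params$E_f)
    y_fib <- rep(one, N)
    names(y_fib) <- paste0("fib", rep(seq_len(N), each = length(one)), ".",
                           rep(fib_names, N))
  }
  dynamic <- config$gj_model != "static" && N > 0
  y_gj <- NULL
  if (dynamic) {
    y_gj <- rep(c(1, 0, 0, 0), N)
    names(y_gj) <- paste0("gj", rep(seq_len(N), each = 4), ".",
                          rep(gj_state_labels(), N))
  }
  idx <- list(
    myo = seq_along(y_myo),
    n_fib_states = length(fib_names),
    fib = if (N > 0) length(y_myo) + seq_len(N * length(fib_names)) else
      integer(0),
    gj = if (dynamic) length(y_myo) + N * length(fib_names) +
      seq_len(4 * N) else integer(0))
  structure(list(config = config, stimulus = stimulus, myocyte = myocyte,
                 y0 = c(y_myo, y_fib, y_gj), index = idx,
                 dynamic = dynamic),
            class = "coupled_system")
}

#' @export
print.coupled_system <- function(x, ...) {
  cfg <- x$config
  cat("Coupled F-M system:", x$myocyte$name, "myocyte +", cfg$n_fibroblasts,
      cfg$fibroblast, "fibroblast(s)\n")
  cat("  GJ model:", cfg$gj_model,
      if (cfg$gj_model != "static")
        paste0("(N_C = ", cfg$N_C, ", realised G_j,max = ",
               signif(realized_gj_max(cfg), 4), " nS)")
      else paste0("(G_j = ", cfg$g_j_max, " nS)"),
      "| fibrosis:", cfg$fibrosis, "\n")
  invisible(x)
}

# Fast vectorized four-state fraction derivatives for N junctions.
# F: N x 4 matrix (HH, HL, LH, LL); V_j: length-N vector. Returns N x 4.
gj_fraction_derivs <- function(F, V_j, hcA, hcB, contingent = TRUE) {
  gAh <- hcA$g_H; gAl <- hcA$g_L; gBh <- hcB$g_H; gBl <- hcB$g_L
  # voltage share of side A in each state (gB/(gA+gB)), HH HL LH LL order
  shareA <- c(gBh / (gAh + gBh), gBl / (gAh + gBl),
              gBh / (gAl + gBh), gBl / (gAl + gBl))
  if (!contingent) shareA <- rep(shareA[1], 4)
  clamp <- function(z) pmin(pmax(z, -6), 6)
  rate <- function(hc, u) {             # u: sensed voltage matrix N x 4
    x <- hc$polarity * u - hc$V0
    list(close = hc$lambda * exp(clamp(hc$A_close * x)),
         open = hc$lambda * exp(clamp(-hc$A_open * x)))
  }
  vA <- outer(V_j, shareA)              # N x 4 drop across A
  uB <- -(outer(V_j, rep(1, 4)) - vA)   # side B senses -v_B
  rA <- rate(hcA, vA)
  rB <- rate(hcB, uB)
  fHH <- F[, 1]; fHL <- F[, 2]; fLH <- F[, 3]; fLL <- F[, 4]
  dHH <- -(rA$close[, 1] + rB$close[, 1]) * fHH +
    rA$open[, 3] * fLH + rB$open[, 2] * fHL
  dHL <- rB$close[, 1] * fHH - (rB$open[, 2] + rA$close[, 2]) * fHL +
    rA$open[, 4] * fLL
  dLH <- rA$close[, 1] * fHH - (rA$open[, 3] + rB$close[, 3]) * fLH +
    rB$open[, 4] * fLL
  dLL <- rA$close[, 2] * fHL + rB$close[, 3] * fLH -
    (rA$open[, 4] + rB$open[, 4]) * fLL
  cbind(dHH, dHL, dLH, dLL)
}

#' Full state derivative of a coupled system
#'
#' `C_myo dV_myo/dt = -I_myo + sum_i I_gap_i + I_stim`;
#' `C_fib dV_fib_i/dt = -I_fib_i - I_gap_i`; four-state fraction derivatives
#' appended for dynamic gap-junction models. With N = 0 this reduces exactly
#' to the uncoupled myocyte.
#'
#' @param system a [coupled_system()].
#' @param t time (ms), used to evaluate the stimulus.
#' @param y flat state vector (defaults to the system's initial state).
#' @return List: `deriv` (flat, same layout as `y`) and `aux` with per-
#'   fibroblast `V_j` (mV), `G_j` (nS), `I_gap` (pA) and total gap current.
#' @export
coupled_rhs <- function(system, t = 0, y = system$y0) {
  cfg <- system$config
  idx <- system$index
  N <- cfg$n_fibroblasts
  myo <- system$myocyte

  ym <- y[idx$myo]
  names(ym) <- myo$state_names
  V_myo <- ym[["V"]]

  V_j <- G_j <- I_gap <- numeric(0)
  dfib <- dgj <- NULL
  if (N > 0) {
    yf <- matrix(y[idx$fib], nrow = N, byrow = TRUE)
    V_fib <- yf[, 1]
    if (system$dynamic) {
      F <- matrix(y[idx$gj], nrow = N, byrow = TRUE)
      G_j <- cfg$N_C * as.numeric(F %*% cfg$g_states) / 1000
    } else {
      G_j <- rep(cfg$g_j_max, N)
    }
    V_j <- transjunctional_voltage(V_fib, V_myo)
    I_gap <- gap_current(V_j, G_j)
    if (cfg$fibroblast == "active") {
      st <- list(Vf = yf[, 1], r = yf[, 2], s = yf[, 3],
                 Ki = yf[, 4], Nai = yf[, 5])
      dfib <- maccannell_rhs(st, cfg$fib_params, I_inj = -I_gap)$deriv
      dfib <- as.numeric(t(matrix(unlist(dfib, use.names = FALSE),
                                  nrow = N)))
    } else {
      dfib <- passive_fibroblast_rhs(V_fib, cfg$fib_params, -I_gap)
    }
    if (system$dynamic) {
      dgj <- if (cfg$freeze_gates) rep(0, 4 * N) else
        as.numeric(t(gj_fraction_derivs(F, V_j, cfg$hcA, cfg$hcB,
                                        cfg$contingent)))
    }
  }
  I_stim <- stimulus_current(t, system$stimulus) * myo$C_m
  dmyo <- myo$rhs(ym, I_inj = sum(I_gap) + I_stim)$deriv
  list(deriv = c(unlist(dmyo, use.names = FALSE), dfib, dgj),
       aux = list(V_j = V_j, G_j = G_j, I_gap = I_gap,
                  I_gap_total = sum(I_gap)))
}

#' Integrate a coupled fibroblast-myocyte system
#'
#' Adaptive stiff integration (lsoda, relative tolerance 1e-6) with uniform
#' output sampling. Deterministic: no randomness anywhere in the system.
#'
#' @param system a [coupled_system()].
#' @param t_end end time (ms); must cover the stimulus protocol.
#' @param output_dt output sampling interval (ms).
#' @param rtol,atol integrator tolerances.
#' @return A `fm_trace` data.frame: columns `t`, `V_myo`, `stim` and, per
#'   fibroblast i, `V_fib_i`, `V_j_i`, `G_j_i`, `I_gap_i`, plus
#'   `I_gap_total`. For N = 1 the unsuffixed aliases `V_fib`, `V_j`, `G_j`,
#'   `I_gap` are used. The configuration is attached as attribute "config".
#' @export
simulate_coupled <- function(system, t_end = 600, output_dt = 0.1,
                             rtol = 1e-6, atol = 1e-8, y0 = NULL) {
  stopifnot(inherits(system, "coupled_system"), t_end > 0)
  if (!is.null(y0)) {
    if (length(y0) != length(system$y0))
      stop("restart state has ", length(y0), " components, system needs ",
           length(system$y0))
    system$y0 <- setNames(as.numeric(y0)[match(names(system$y0),
                                               names(y0))],
                          names(system$y0))
    if (any(is.na(system$y0))) stop("restart state is missing components")
  }
  times <- seq(0, t_end, by = output_dt)
  rhs <- function(t, y, parms) list(coupled_rhs(system, t, y)$deriv)
  hmax <- if (!is.null(system$stimulus) && system$stimulus$n_beats > 0)
    max(0.25, system$stimulus$duration / 2) else 5
  out <- deSolve::lsoda(system$y0, times, rhs, NULL,
                        rtol = rtol, atol = atol, hmax = hmax)
  if (attr(out, "istate")[1] < 0)
    stop("solver failure at t = ", max(out[, 1]), " ms")
  out <- as.data.frame(out)
  names(out)[1] <- "t"
  build_trace(out, system)
}

# Assemble the fm_trace data.frame from raw integrator output.
build_trace <- function(out, system) {
  cfg <- system$config
  N <- cfg$n_fibroblasts
  tr <- data.frame(t = out$t, V_myo = out[["myo.V"]],
                   stim = stimulus_current(out$t, system$stimulus))
  total <- 0
  for (i in seq_len(N)) {
    V_fib <- out[[paste0("fib", i, ".Vf")]]
    V_j <- transjunctional_voltage(V_fib, tr$V_myo)
    if (system$dynamic) {
      F <- as.matrix(out[paste0("gj", i, ".", gj_state_labels())])
      G_j <- cfg$N_C * as.numeric(F %*% cfg$g_states) / 1000
    } else G_j <- rep(cfg$g_j_max, nrow(out))
    I_gap <- gap_current(V_j, G_j)
    sfx <- if (N == 1) "" else paste0("_", i)
    tr[[paste0("V_fib", sfx)]] <- V_fib
    tr[[paste0("V_j", sfx)]] <- V_j
    tr[[paste0("G_j", sfx)]] <- G_j
    tr[[paste0("I_gap", sfx)]] <- I_gap
    total <- total + I_gap
  }
  tr$I_gap_total <- if (N > 0) total else 0
  attr(tr, "config") <- cfg
  attr(tr, "stimulus") <- system$stimulus
  class(tr) <- c("fm_trace", "data.frame")
  tr
}

#' Convenience wrapper: simulate one pair configuration
#'
#' Builds and integrates a coupled system in one call, pacing the myocyte
#' for `n_beats` and returning the full trace.
#'
#' @inheritParams coupling_config
#' @param n_beats number of paced beats.
#' @param cycle_length pacing cycle length (ms).
#' @param t_end simulation end (ms); default covers all beats.
#' @param output_dt sampling interval (ms).
#' @param ... further arguments to [coupling_config()].
#' @return An `fm_trace` (see [simulate_coupled()]).
#' @export
simulate_pair <- function(n_fibroblasts = 1, gj_model = "Cx43",
                          g_j_max = 3, fibroblast = "active",
                          n_beats = 1, cycle_length = 1000,
                          t_end = NULL, output_dt = 0.1, ...) {
  cfg <- coupling_config(n_fibroblasts = n_fibroblasts,
                         fibroblast = fibroblast, gj_model = gj_model,
                         g_j_max = g_j_max, ...)
  stim <- stimulus_protocol(n_beats = n_beats, cycle_length = cycle_length)
  if (is.null(t_end)) t_end <- stim$onset + n_beats * cycle_length - 400
  simulate_coupled(coupled_system(cfg, stim), t_end = t_end,
                   output_dt = output_dt)
}
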