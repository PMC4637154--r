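#' Passive (RC) fibroblast membrane model
#'
#' The fibroblast membrane is a capacitance in parallel with an ohmic
#' conductance pulling towards a fixed resting potential:
#' `C_f dV_f/dt = -G_f (V_f - E_f) + I_inj`.
#'
#' @param C_f membrane capacitance (pF), > 0.
#' @param G_f membrane conductance (nS), >= 0.
#' @param E_f resting (reversal) potential (mV).
#' @return List of class `passive_fibroblast`.
#' @export
passive_fibroblast <- function(C_f = 6.3, G_f = 2, E_f = -20) {
  if (!is.numeric(C_f) || C_f <= 0) stop("C_f must be > 0 pF")
  if (!is.numeric(G_f) || G_f < 0) stop("G_f must be >= 0 nS")
  structure(list(C_f = C_f, G_f = G_f, E_f = E_f),
            class = c("passive_fibroblast", "fibroblast_model"))
}

#' Passive fibroblast voltage derivative
#'
#' @param V_f membrane potential (mV), may be a vector.
#' @param params a [passive_fibroblast()] object.
#' @param I_inj injected current (pA; positive depolarizes).
#' @return dV_f/dt (mV/ms); nS * mV = pA and pA / pF = mV/ms.
#' @export
passive_fibroblast_rhs <- function(V_f, params, I_inj = 0) {
  stopifnot(inherits(params, "passive_fibroblast"))
  (-params$G_f * (V_f - params$E_f) + I_inj) / params$C_f
}

#' Active (MacCannell-type) ventricular fibroblast model
#'
#' Four membrane currents: an inwardly rectifying K+ current, a time- and
#' voltage-dependent delayed-rectifier K+ current (activation gate r,
#' inactivation gate s), an electrogenic Na+/K+-ATPase, and a background Na+
#' conductance that balances Na+ influx so the uncoupled cell rests near
#' -49.6 mV. Intracellular K+ and Na+ are dynamic. Capacitance 6.3 pF.
#'
#' @param C_f membrane capacitance (pF).
#' @param g_Kv delayed-rectifier conductance (nS/pF).
#' @param g_K1 inward-rectifier conductance (nS/pF).
#' @param g_bNa background Na+ conductance (nS/pF).
#' @param I_NaK_max maximal pump current (pA/pF).
#' @param K_o,Na_o external concentrations (mM).
#' @param Vol_i intracellular volume (pL) for ion bookkeeping.
#' @param T_K absolute temperature (K).
#' @return List of class `active_fibroblast`.
#' @export
active_fibroblast <- function(C_f = 6.3, g_Kv = 0.25, g_K1 = 0.4822,
                              g_bNa = 0.0086, I_NaK_max = 2.002,
                              K_o = 5.3581, Na_o = 130.011,
                              Vol_i = 1.3668, T_K = 306.15) {
  if (C_f <= 0) stop("C_f must be > 0 pF")
  structure(list(C_f = C_f, g_Kv = g_Kv, g_K1 = g_K1, g_bNa = g_bNa,
                 I_NaK_max = I_NaK_max, K_mK = 1.0, K_mNa = 11.0,
                 V_rev = -150, B_NaK = 200, K_o = K_o, Na_o = Na_o,
                 Vol_i = Vol_i, RTF = 1000 * 8.314 * T_K / 96485),
            class = c("active_fibroblast", "fibroblast_model"))
}

# State layout of the active fibroblast in flat vectors.
active_fibroblast_state_names <- function() c("Vf", "r", "s", "Ki", "Nai")

#' Initial state of the active fibroblast
#'
#' @param V_f initial membrane potential (mV).
#' @param params an [active_fibroblast()] object.
#' @return Named vector (Vf, r, s, Ki, Nai); gates at their steady state for
#'   `V_f`, concentrations at the published resting values.
#' @export
active_fibroblast_init <- function(V_f = -49.6, params = active_fibroblast()) {
  c(Vf = V_f,
    r = 1 / (1 + exp(-(V_f + 20) / 11)),
    s = 1 / (1 + exp((V_f + 23) / 7)),
    Ki = 129.4349, Nai = 8.5547)
}

#' MacCannell fibroblast membrane currents
#'
#' @param state named list/vector with Vf (mV), gates r and s in [0,1], Ki
#'   and Nai (mM); components may be vectors.
#' @param params an [active_fibroblast()] object.
#' @return List with `I_Kv`, `I_K1`, `I_NaK`, `I_bNa` and `I_total`, all
#'   cell-total pA, plus the reversal potentials `E_K`, `E_Na` (mV).
#' @export
maccannell_currents <- function(state, params = active_fibroblast()) {
  s <- as.list(state)
  p <- params
  if (any(s$r < -1e-9 | s$r > 1 + 1e-9 | s$s < -1e-9 | s$s > 1 + 1e-9))
    stop("gate out of [0,1] in active fibroblast state")
  if (any(s$Ki <= 0 | s$Nai <= 0))
    stop("non-positive intracellular concentration")
  V <- s$Vf
  E_K <- p$RTF * log(p$K_o / s$Ki)
  E_Na <- p$RTF * log(p$Na_o / s$Nai)

  I_Kv <- p$g_Kv * s$r * s$s * (V - E_K)

  dv <- V - E_K
  a_K1 <- 0.1 / (1 + exp(0.06 * (dv - 200)))
  b_K1 <- (3 * exp(2e-4 * (dv + 100)) + exp(0.1 * (dv - 10))) /
    (1 + exp(-0.5 * dv))
  I_K1 <- p$g_K1 * a_K1 / (a_K1 + b_K1) * dv

  I_NaK <- p$I_NaK_max * (p$K_o / (p$K_o + p$K_mK)) *
    (s$Nai^1.5 / (s$Nai^1.5 + p$K_mNa^1.5)) *
    (V - p$V_rev) / (V + p$B_NaK)

  I_bNa <- p$g_bNa * (V - E_Na)

  # scale pA/pF -> cell-total pA
  lapply(list(I_Kv = I_Kv, I_K1 = I_K1, I_NaK = I_NaK, I_bNa = I_bNa,
              I_total = I_Kv + I_K1 + I_NaK + I_bNa),
         function(i) i * p$C_f) |>
    c(list(E_K = E_K, E_Na = E_Na))
}

#' Time derivative of the active fibroblast state
#'
#' @inheritParams maccannell_currents
#' @param I_inj injected current (pA; positive depolarizes).
#' @return List `deriv` (per-ms derivatives of Vf, r, s, Ki, Nai) and
#'   `currents` from [maccannell_currents()].
#' @export
maccannell_rhs <- function(state, params = active_fibroblast(), I_inj = 0) {
  s <- as.list(state)
  p <- params
  cur <- maccannell_currents(s, p)
  V <- s$Vf
  r_inf <- 1 / (1 + exp(-(V + 20) / 11))
  s_inf <- 1 / (1 + exp((V + 23) / 7))
  tau_r <- 20.3 + 138 * exp(-((V + 20) / 25.9)^2)
  tau_s <- 1574 + 5268 * exp(-((V + 23) / 22.7)^2)
  # pA -> mM/ms: I/(F * Vol); F in C/mmol, Vol in pL
  iconv <- 1 / (96.485 * p$Vol_i * 1000)
  d <- list(
    Vf = (-cur$I_total + I_inj) / p$C_f,
    r = (r_inf - s$r) / tau_r,
    s = (s_inf - s$s) / tau_s,
    Ki = -(cur$I_Kv + cur$I_K1 - 2 * cur$I_NaK) * iconv,
    Nai = -(cur$I_bNa + 3 * cur$I_NaK) * iconv)
  list(deriv = d, currents = cur)
}

#' Simulate an uncoupled active fibroblast
#'
#' Free-running (unstimulated) integration, used to find the resting state.
#'
#' @param t_end duration (ms).
#' @param init initial state, default [active_fibroblast_init()].
#' @param params an [active_fibroblast()] object.
#' @param output_dt output sampling step (ms).
#' @return data.frame with columns t, Vf, r, s, Ki, Nai.
#' @export
simulate_fibroblast <- function(t_end = 30000, init = NULL,
                                params = active_fibroblast(),
                                output_dt = 10) {
  if (is.null(init)) init <- active_fibroblast_init(params = params)
  rhs <- function(t, y, parms) {
    list(unlist(maccannell_rhs(y, params)$deriv, use.names = FALSE))
  }
  out <- deSolve::lsoda(init, seq(0, t_end, by = output_dt), rhs, NULL,
                        rtol = 1e-6, atol = 1e-8)
  out <- as.data.frame(out)
  names(out)[1] <- "t"
  out
}

#' Stimulus protocol
#'
#' Periodic rectangular current pulses.
#'
#' @param amplitude pulse amplitude (pA/pF of the stimulated cell; positive
#'   depolarizes). The default is 1.5x the diastolic threshold of the LR1
#'   myocyte for a 2-ms pulse (threshold ~14.6 pA/pF).
#' @param duration pulse width (ms).
#' @param cycle_length basic cycle length (ms).
#' @param n_beats number of pulses (>= 0).
#' @param onset time of the first pulse (ms).
#' @return List of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(amplitude = 22, duration = 2,
                              cycle_length = 1000, n_beats = 1, onset = 10) {
  if (duration >= cycle_length) stop("duration must be < cycle_length")
  if (n_beats < 0) stop("n_beats must be >= 0")
  structure(list(amplitude = amplitude, duration = duration,
                 cycle_length = cycle_length, n_beats = n_beats,
                 onset = onset),
            class = "stimulus_protocol")
}

# Stimulus current (pA/pF) at time t; vectorized in t.
stimulus_current <- function(t, stim) {
  if (is.null(stim) || stim$n_beats == 0) return(0 * t)
  tt <- t - stim$onset
  beat <- floor(tt / stim$cycle_length)
  phase <- tt - beat * stim$cycle_length
  on <- tt >= 0 & beat < stim$n_beats & phase < stim$duration
  ifelse(on, stim$amplitude, 0)
}

# Times of each stimulus pulse onset.
stimulus_times <- function(stim) {
  if (is.null(stim) || stim$n_beats == 0) return(numeric(0))
  stim$onset + stim$cycle_length * seq_len(stim$n_beats) - stim$cycle_length
}
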