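#' Luo-Rudy 1991 guinea-pig ventricular myocyte model
#'
#' Parameters of the LR1 ionic model. Conductances are in mS/cm^2 so that all
#' ionic currents evaluate in uA/cm^2, numerically equal to pA/pF for a
#' specific membrane capacitance of 1 uF/cm^2. Cell-total currents are
#' obtained by multiplying by the whole-cell capacitance `C_m` (pF).
#'
#' @param C_m whole-cell membrane capacitance (pF).
#' @param G_Na,G_si,G_K,G_K1,G_Kp,G_b maximal conductances (mS/cm^2).
#' @param K_o,K_i,Na_o,Na_i extracellular/intracellular K+ and Na+ (mM),
#'   fixed in this model.
#' @return A list of class `lr1_params`.
#' @export
lr1_params <- function(C_m = 153.4,
                       G_Na = 23, G_si = 0.09, G_K = 0.282,
                       G_K1 = 0.6047, G_Kp = 0.0183, G_b = 0.03921,
                       K_o = 5.4, K_i = 145, Na_o = 140, Na_i = 18) {
  stopifnot(C_m > 0, K_o > 0, K_i > 0)
  RTF <- 1000 * 8.314 * 310 / 96485  # mV at 37 C
  p <- list(
    C_m = C_m, G_Na = G_Na, G_si = G_si,
    G_K = G_K * sqrt(K_o / 5.4), G_K1 = G_K1 * sqrt(K_o / 5.4),
    G_Kp = G_Kp, G_b = G_b,
    E_Na = RTF * log(Na_o / Na_i),
    # I_K reversal includes the Na permeability ratio PR_NaK = 0.01833
    E_K  = RTF * log((K_o + 0.01833 * Na_o) / (K_i + 0.01833 * Na_i)),
    E_K1 = RTF * log(K_o / K_i),
    E_b  = -59.87)
  class(p) <- "lr1_params"
  p
}

#' @export
print.lr1_params <- function(x, ...) {
  cat("LR1 myocyte parameters: C_m =", x$C_m, "pF; G_Na =", x$G_Na,
      "mS/cm^2; E_Na =", round(x$E_Na, 1), "mV; E_K1 =",
      round(x$E_K1, 1), "mV\n")
  invisible(x)
}

# Names of the LR1 state variables, in flat-vector order.
lr1_state_names <- function() c("V", "m", "h", "j", "d", "f", "X", "Cai")

#' Default LR1 initial state (quiescent)
#'
#' @param V resting membrane potential to initialise gates at (mV).
#' @return Named numeric vector (V, m, h, j, d, f, X, Cai).
#' @export
lr1_init <- function(V = -84.5) {
  r <- lr1_rates(V)
  c(V = V,
    m = r$a_m / (r$a_m + r$b_m), h = r$a_h / (r$a_h + r$b_h),
    j = r$a_j / (r$a_j + r$b_j), d = r$a_d / (r$a_d + r$b_d),
    f = r$a_f / (r$a_f + r$b_f), X = r$a_X / (r$a_X + r$b_X),
    Cai = 2e-4)
}

# Hodgkin-Huxley rate coefficients (1/ms) of the LR1 gates, vectorized in V.
lr1_rates <- function(V) {
  a_m <- 0.32 * (V + 47.13) / (1 - exp(-0.1 * (V + 47.13)))
  # remove the 0/0 singularity at V = -47.13 (limit 3.2)
  a_m[!is.finite(a_m)] <- 3.2
  b_m <- 0.08 * exp(-V / 11)

  low <- V < -40
  a_h <- ifelse(low, 0.135 * exp((80 + V) / -6.8), 0)
  b_h <- ifelse(low, 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V),
                1 / (0.13 * (1 + exp((V + 10.66) / -11.1))))
  a_j <- ifelse(low,
    (-1.2714e5 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
      (V + 37.78) / (1 + exp(0.311 * (V + 79.23))), 0)
  b_j <- ifelse(low,
    0.1212 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14))),
    0.3 * exp(-2.535e-7 * V) / (1 + exp(-0.1 * (V + 32))))

  a_d <- 0.095 * exp(-0.01 * (V - 5)) / (1 + exp(-0.072 * (V - 5)))
  b_d <- 0.07 * exp(-0.017 * (V + 44)) / (1 + exp(0.05 * (V + 44)))
  a_f <- 0.012 * exp(-0.008 * (V + 28)) / (1 + exp(0.15 * (V + 28)))
  b_f <- 0.0065 * exp(-0.02 * (V + 30)) / (1 + exp(-0.2 * (V + 30)))
  a_X <- 0.0005 * exp(0.083 * (V + 50)) / (1 + exp(0.057 * (V + 50)))
  b_X <- 0.0013 * exp(-0.06 * (V + 20)) / (1 + exp(-0.04 * (V + 20)))

  list(a_m = a_m, b_m = b_m, a_h = a_h, b_h = b_h, a_j = a_j, b_j = b_j,
       a_d = a_d, b_d = b_d, a_f = a_f, b_f = b_f, a_X = a_X, b_X = b_X)
}

#' LR1 ionic currents
#'
#' All currents in pA/pF (uA/cm^2). Vectorized over cells: every state
#' argument may be a vector of equal length.
#'
#' @param V membrane potential (mV); `m,h,j,d,f,X` gates; `Cai` intracellular
#'   Ca2+ (mM).
#' @param p an [lr1_params()] object.
#' @return List with components `I_Na`, `I_si`, `I_K`, `I_K1`, `I_Kp`, `I_b`
#'   and their sum `I_total` (pA/pF).
#' @export
lr1_currents <- function(V, m, h, j, d, f, X, Cai, p = lr1_params()) {
  I_Na <- p$G_Na * m^3 * h * j * (V - p$E_Na)

  E_si <- 7.7 - 13.0287 * log(Cai)
  I_si <- p$G_si * d * f * (V - E_si)

  # time-independent rectification factor Xi of I_K
  Xi <- ifelse(V > -100,
               2.837 * (exp(0.04 * (V + 77)) - 1) /
                 ((V + 77) * exp(0.04 * (V + 35))), 1)
  Xi[!is.finite(Xi)] <- 2.837 * 0.04 / exp(0.04 * (-77 + 35))  # V = -77 limit
  I_K <- p$G_K * X * Xi * (V - p$E_K)

  dv <- V - p$E_K1
  a_K1 <- 1.02 / (1 + exp(0.2385 * (dv - 59.215)))
  b_K1 <- (0.49124 * exp(0.08032 * (dv + 5.476)) +
             exp(0.06175 * (dv - 594.31))) /
    (1 + exp(-0.5143 * (dv + 4.753)))
  I_K1 <- p$G_K1 * a_K1 / (a_K1 + b_K1) * dv

  Kp <- 1 / (1 + exp((7.488 - V) / 5.98))
  I_Kp <- p$G_Kp * Kp * (V - p$E_K1)
  I_b <- p$G_b * (V - p$E_b)

  list(I_Na = I_Na, I_si = I_si, I_K = I_K, I_K1 = I_K1, I_Kp = I_Kp,
       I_b = I_b, I_total = I_Na + I_si + I_K + I_K1 + I_Kp + I_b)
}

#' Time derivative of the LR1 myocyte state
#'
#' @param state named numeric vector from [lr1_init()] (or a list of equal
#'   length vectors for several cells).
#' @param I_inj injected current (pA, cell-total; positive depolarizes). Gap
#'   junctional and stimulus currents both enter here.
#' @param p an [lr1_params()] object.
#' @return List: `deriv` (same layout as `state`, units per ms) and
#'   `currents` from [lr1_currents()].
#' @export
lr1_rhs <- function(state, I_inj = 0, p = lr1_params()) {
  s <- as.list(state)
  if (is.null(s$V)) stop("state must carry named components V, m, h, ...")
  cur <- lr1_currents(s$V, s$m, s$h, s$j, s$d, s$f, s$X, s$Cai, p)
  r <- lr1_rates(s$V)
  dV <- -cur$I_total + I_inj / p$C_m
  if (any(!is.finite(dV)))
    stop("non-finite dV/dt in myocyte model (V = ",
         paste(signif(s$V[!is.finite(dV)], 4), collapse = ", "), " mV)")
  d <- list(
    V = dV,
    m = r$a_m * (1 - s$m) - r$b_m * s$m,
    h = r$a_h * (1 - s$h) - r$b_h * s$h,
    j = r$a_j * (1 - s$j) - r$b_j * s$j,
    d = r$a_d * (1 - s$d) - r$b_d * s$d,
    f = r$a_f * (1 - s$f) - r$b_f * s$f,
    X = r$a_X * (1 - s$X) - r$b_X * s$X,
    Cai = -1e-4 * cur$I_si + 0.07 * (1e-4 - s$Cai))
  list(deriv = d, currents = cur)
}

#' Myocyte model interface
#'
#' Wraps a ventricular action-potential model behind a uniform interface so
#' the coupling engine and cable do not depend on a particular formulation.
#'
#' @param name model name; `"lr1"` (Luo-Rudy 1991) is currently provided.
#' @param params optional parameter override, an [lr1_params()] object.
#' @return List of class `myocyte_model` with elements `name`, `params`,
#'   `C_m` (pF), `init()` and `rhs(state, I_inj)`.
#' @export
myocyte_model <- function(name = "lr1", params = NULL) {
  name <- match.arg(tolower(name), "lr1")
  p <- if (is.null(params)) lr1_params() else params
  structure(list(
    name = name, params = p, C_m = p$C_m,
    state_names = lr1_state_names(),
    init = function() lr1_init(),
    rhs = function(state, I_inj = 0) lr1_rhs(state, I_inj, p)),
    class = "myocyte_model")
}
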