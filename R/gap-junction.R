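#' Hemichannel parameters for the four-state gap-junction model
#'
#' A gap-junction channel is two hemichannels (connexons) in series. Each
#' hemichannel carries one voltage gate switching between a high- (H) and a
#' residual low-conductance (L) state; neither state is fully closed. The
#' gate's transition rates depend exponentially on the voltage dropped across
#' that hemichannel:
#' closing (H->L) rate  `lambda * exp( A_close * (P*v - V0))`,
#' opening (L->H) rate  `lambda * exp(-A_open  * (P*v - V0))`,
#' with `P` the gating polarity. The two-state equilibrium open fraction is a
#' Boltzmann in `P*v` with midpoint `V0` and slope `1/(A_open + A_close)`, so
#' the H state dominates at v = 0 whenever `V0 > 0`.
#'
#' @param g_H high (open) state conductance (pS), > g_L.
#' @param g_L residual (low) state conductance (pS), > 0.
#' @param lambda base transition rate (1/ms), > 0.
#' @param A_open,A_close voltage sensitivities of the opening/closing rates
#'   (1/mV), >= 0.
#' @param polarity gating polarity, +1 or -1.
#' @param V0 half-gating offset (mV) of the single gate.
#' @param label optional connexin isoform label.
#' @return List of class `hemichannel`.
#' @export
hemichannel <- function(g_H, g_L, lambda, A_open, A_close,
                        polarity = 1, V0 = 0, label = "") {
  if (!(g_H > g_L && g_L > 0)) stop("need g_H > g_L > 0 (pS)")
  if (lambda <= 0) stop("lambda must be > 0 (1/ms)")
  if (!polarity %in% c(-1, 1)) stop("polarity must be +1 or -1")
  structure(list(g_H = g_H, g_L = g_L, lambda = lambda,
                 A_open = A_open, A_close = A_close,
                 polarity = polarity, V0 = V0, label = label),
            class = "hemichannel")
}

#' Built-in connexin hemichannel parameter sets
#'
#' Default hemichannel parameters for Cx43 and Cx45. Unitary conductances
#' follow single-channel measurements (Cx43 main state ~100 pS, residual
#' ~25 pS; Cx45 ~32 pS main, ~8 pS residual). Gate rate parameters are
#' calibrated so the homotypic steady-state curves reach half-inactivation
#' (midpoint between the V_j = 0 maximum and the large-|V_j| residual
#' plateau) at 55-60 mV for Cx43 and 23-30 mV for Cx45, and so that Cx45 is
#' the more voltage-sensitive isoform at every |V_j|.
#'
#' @param isoform "Cx43" or "Cx45".
#' @return A [hemichannel()] object.
#' @export
connexin_hemichannel <- function(isoform = c("Cx43", "Cx45")) {
  isoform <- match.arg(isoform)
  switch(isoform,
    Cx43 = hemichannel(g_H = 100, g_L = 25, lambda = 0.003,
                       A_open = 0.02, A_close = 0.12,
                       polarity = 1, V0 = 31, label = "Cx43"),
    Cx45 = hemichannel(g_H = 32, g_L = 8, lambda = 0.008,
                       A_open = 0.03, A_close = 0.15,
                       polarity = 1, V0 = 13, label = "Cx45"))
}

# Channel state bookkeeping: states ordered HH, HL, LH, LL; first letter is
# the gate of hemichannel A, second of hemichannel B.
gj_state_labels <- function() c("HH", "HL", "LH", "LL")

#' Conductance of one channel state
#'
#' Series combination of the two hemichannel conductances appropriate to the
#' state: `g = gA*gB/(gA + gB)`.
#'
#' @param state_label one of "HH", "HL", "LH", "LL".
#' @param hcA,hcB [hemichannel()] objects for side A and B.
#' @return Conductance in pS.
#' @export
channel_state_conductance <- function(state_label, hcA, hcB) {
  state_label <- match.arg(state_label, gj_state_labels())
  gA <- if (substr(state_label, 1, 1) == "H") hcA$g_H else hcA$g_L
  gB <- if (substr(state_label, 2, 2) == "H") hcB$g_H else hcB$g_L
  gA * gB / (gA + gB)
}

# All four state conductances (pS), named vector in HH, HL, LH, LL order.
gj_state_conductances <- function(hcA, hcB) {
  vapply(gj_state_labels(), channel_state_conductance, numeric(1),
         hcA = hcA, hcB = hcB)
}

#' Voltage division across the two series hemichannels
#'
#' The transjunctional voltage divides in proportion to the hemichannel
#' resistances in the given channel state: `v_A = V_j gB/(gA+gB)`,
#' `v_B = V_j gA/(gA+gB)`; `v_A + v_B = V_j` exactly.
#'
#' @param V_j transjunctional voltage (mV).
#' @param state_label one of "HH", "HL", "LH", "LL".
#' @param hcA,hcB [hemichannel()] objects.
#' @return Named numeric vector `c(v_A, v_B)` (mV).
#' @export
hemichannel_voltages <- function(V_j, state_label, hcA, hcB) {
  state_label <- match.arg(state_label, gj_state_labels())
  gA <- if (substr(state_label, 1, 1) == "H") hcA$g_H else hcA$g_L
  gB <- if (substr(state_label, 2, 2) == "H") hcB$g_H else hcB$g_L
  v_A <- V_j * gB / (gA + gB)
  c(v_A = v_A, v_B = V_j - v_A)
}

#' Hemichannel gate transition rates
#'
#' @param v voltage sensed by the hemichannel (mV); for side B of a channel
#'   this is minus the drop across it (the two connexons face each other).
#' @param params a [hemichannel()] object.
#' @return Named vector `c(rate_HL, rate_LH)` in 1/ms; both strictly
#'   positive, exponential in voltage. The exponent is clamped at +/-6, a
#'   rate-saturation guard: transition rates level off instead of growing
#'   without bound at extreme voltages.
#' @export
gate_rates <- function(v, params) {
  x <- params$polarity * v - params$V0
  clamp <- function(z) pmin(pmax(z, -6), 6)
  c(rate_HL = params$lambda * exp(clamp(params$A_close * x)),
    rate_LH = params$lambda * exp(clamp(-params$A_open * x)))
}

#' Gap-junction population (mean-field four-state occupancy)
#'
#' @param phenotype one of "Cx43", "Cx45", "Cx43/Cx45".
#' @param N_C number of channels in the junction (>= 1).
#' @param fractions occupancy of HH, HL, LH, LL; must be >= 0 and sum to 1.
#' @param contingent logical; if TRUE (default) the gate rates are evaluated
#'   at the state-dependent series voltage division (gating of each
#'   hemichannel depends on the partner's state); if FALSE each gate sees a
#'   fixed share of V_j computed from the open-state divider.
#' @param hcA,hcB hemichannel overrides; defaults follow the phenotype with
#'   side A = Cx43 and side B = Cx45 in the heterotypic channel.
#' @param orientation +1 (default) or -1; -1 swaps the sides of the
#'   heterotypic channel.
#' @return List of class `gj_population`.
#' @export
gj_population <- function(phenotype = c("Cx43", "Cx45", "Cx43/Cx45"),
                          N_C = 60, fractions = c(1, 0, 0, 0),
                          contingent = TRUE, hcA = NULL, hcB = NULL,
                          orientation = 1) {
  phenotype <- match.arg(phenotype)
  if (is.null(hcA) || is.null(hcB)) {
    sides <- switch(phenotype,
      "Cx43" = list(connexin_hemichannel("Cx43"), connexin_hemichannel("Cx43")),
      "Cx45" = list(connexin_hemichannel("Cx45"), connexin_hemichannel("Cx45")),
      "Cx43/Cx45" = list(connexin_hemichannel("Cx43"),
                         connexin_hemichannel("Cx45")))
    if (orientation < 0) sides <- rev(sides)
    if (is.null(hcA)) hcA <- sides[[1]]
    if (is.null(hcB)) hcB <- sides[[2]]
  }
  fractions <- as.numeric(fractions)
  if (length(fractions) != 4 || any(fractions < -1e-12) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be 4 non-negative numbers summing to 1")
  if (N_C < 1) stop("N_C must be >= 1")
  names(fractions) <- gj_state_labels()
  structure(list(phenotype = phenotype, N_C = as.integer(round(N_C)),
                 fractions = fractions, contingent = contingent,
                 hcA = hcA, hcB = hcB),
            class = "gj_population")
}

#' @export
print.gj_population <- function(x, ...) {
  g <- gj_state_conductances(x$hcA, x$hcB)
  cat("Gap-junction population:", x$phenotype, "| N_C =", x$N_C,
      "| g_HH =", round(g["HH"], 1), "pS | G_j =",
      signif(dynamic_conductance(x), 4), "nS\n")
  cat("  fractions:", paste(sprintf("%s=%.3f", names(x$fractions),
                                    x$fractions), collapse = " "), "\n")
  invisible(x)
}

# 4x4 master-equation rate matrix Q at a given V_j; Q[i,j] is the rate from
# state i to state j, diagonal such that rows sum to zero. Transitions flip
# one gate at a time; under contingent gating the rates are evaluated at the
# voltage division of the *current* state.
gj_rate_matrix <- function(V_j, hcA, hcB, contingent = TRUE) {
  labels <- gj_state_labels()
  Q <- matrix(0, 4, 4, dimnames = list(labels, labels))
  share0 <- hemichannel_voltages(V_j, "HH", hcA, hcB)  # fixed-divider option
  for (i in seq_len(4)) {
    st <- labels[i]
    v <- if (contingent) hemichannel_voltages(V_j, st, hcA, hcB) else {
      share0
    }
    rA <- gate_rates(v[["v_A"]], hcA)    # side A senses +v_A
    rB <- gate_rates(-v[["v_B"]], hcB)   # side B faces the other way
    gateA <- substr(st, 1, 1); gateB <- substr(st, 2, 2)
    toA <- paste0(if (gateA == "H") "L" else "H", gateB)
    toB <- paste0(gateA, if (gateB == "H") "L" else "H")
    Q[i, toA] <- if (gateA == "H") rA[["rate_HL"]] else rA[["rate_LH"]]
    Q[i, toB] <- if (gateB == "H") rB[["rate_HL"]] else rB[["rate_LH"]]
    Q[i, i] <- -sum(Q[i, ])
  }
  Q
}

#' Master-equation derivative of the four-state occupancy
#'
#' @param pop a [gj_population()] object (its `fractions` are used).
#' @param V_j transjunctional voltage (mV).
#' @param hcA,hcB optional hemichannel overrides (default: those in `pop`).
#' @return Named derivative vector d(f_HH, f_HL, f_LH, f_LL)/dt (1/ms);
#'   components sum to zero.
#' @export
population_rhs <- function(pop, V_j, hcA = pop$hcA, hcB = pop$hcB) {
  Q <- gj_rate_matrix(V_j, hcA, hcB, pop$contingent)
  drop(pop$fractions %*% Q)
}

#' Stationary four-state distribution at fixed V_j
#'
#' Solves the null space of the rate matrix directly (linear solve with the
#' normalisation constraint), without time integration.
#'
#' @inheritParams population_rhs
#' @param contingent see [gj_population()].
#' @return Named fractions (HH, HL, LH, LL) summing to 1.
#' @export
gj_stationary <- function(V_j, hcA, hcB, contingent = TRUE) {
  Q <- gj_rate_matrix(V_j, hcA, hcB, contingent)
  A <- rbind(t(Q), rep(1, 4))
  b <- c(0, 0, 0, 0, 1)
  f <- qr.solve(A, b)
  f <- pmax(f, 0); f <- f / sum(f)
  names(f) <- gj_state_labels()
  f
}

#' Junctional conductance of a population
#'
#' `G_j = N_C * sum_state f_state * g_state`, converted pS -> nS.
#'
#' @param pop a [gj_population()] object.
#' @param hcA,hcB optional hemichannel overrides.
#' @return Conductance in nS.
#' @export
dynamic_conductance <- function(pop, hcA = pop$hcA, hcB = pop$hcB) {
  g <- gj_state_conductances(hcA, hcB)
  pop$N_C * sum(pop$fractions * g) / 1000
}

#' Steady-state conductance-voltage curve
#'
#' For each V_j on the grid the stationary occupancy is solved directly and
#' the conductance normalised by its maximum over the grid.
#'
#' @param phenotype "Cx43", "Cx45" or "Cx43/Cx45" (or a [gj_population()]
#'   object carrying custom hemichannels).
#' @param V_j numeric grid (mV), strictly increasing, spanning at least
#'   +/-100 mV.
#' @param contingent gating mode, see [gj_population()].
#' @return data.frame of class `gj_curve` with columns `V_j` and `G_norm`
#'   (normalised steady-state conductance, in (0, 1]).
#' @export
steady_state_curve <- function(phenotype = "Cx43",
                               V_j = seq(-120, 120, by = 1),
                               contingent = TRUE) {
  pop <- if (inherits(phenotype, "gj_population")) phenotype else
    gj_population(phenotype, contingent = contingent)
  if (any(diff(V_j) <= 0)) stop("V_j grid must be strictly increasing")
  if (min(V_j) > -100 || max(V_j) < 100)
    stop("V_j grid must span at least +/-100 mV")
  g <- gj_state_conductances(pop$hcA, pop$hcB)
  G <- vapply(V_j, function(v)
    sum(gj_stationary(v, pop$hcA, pop$hcB, pop$contingent) * g), numeric(1))
  out <- data.frame(V_j = V_j, G_norm = G / max(G))
  attr(out, "phenotype") <- pop$phenotype
  class(out) <- c("gj_curve", "data.frame")
  out
}

#' Half-inactivation voltage of a homotypic steady-state curve
#'
#' The |V_j| at which the normalised conductance crosses the midpoint
#' between its maximum and its large-|V_j| residual plateau, found by linear
#' interpolation on the positive branch. The residual plateau is the mean of
#' the curve over the outermost 10 mV of the positive branch.
#'
#' @param curve a [steady_state_curve()] result (or any data.frame with
#'   columns V_j, G_norm).
#' @return Half-inactivation voltage (mV, positive).
#' @export
half_inactivation_voltage <- function(curve) {
  pos <- curve[curve$V_j >= 0, ]
  pos <- pos[order(pos$V_j), ]
  g_max <- max(curve$G_norm)
  plateau <- mean(pos$G_norm[pos$V_j >= max(pos$V_j) - 10])
  target <- (g_max + plateau) / 2
  below <- which(pos$G_norm <= target)
  if (!length(below) || below[1] == 1)
    stop("no midpoint crossing within the V_j grid")
  i <- below[1]
  v1 <- pos$V_j[i - 1]; v2 <- pos$V_j[i]
  g1 <- pos$G_norm[i - 1]; g2 <- pos$G_norm[i]
  v1 + (target - g1) * (v2 - v1) / (g2 - g1)
}

#' Fit a two-sided (modified) Boltzmann to a steady-state curve
#'
#' Least-squares fit of
#' `G(V) = G_res + (G_max - G_res) / ((1 + exp(A_pos*(V - V_half_pos))) *
#'  (1 + exp(-A_neg*(V + V_half_neg))))`
#' which fits both polarities of V_j simultaneously and allows a nonzero
#' residual conductance.
#'
#' @param curve data.frame with columns V_j, G_norm covering both
#'   polarities.
#' @return List with `G_max`, `G_res`, `V_half_pos`, `V_half_neg` (both
#'   reported positive), `slope_pos`, `slope_neg` (mV per e-fold, = 1/A),
#'   `rss` and the `fit` object.
#' @export
fit_modified_boltzmann <- function(curve) {
  if (min(curve$V_j) >= 0 || max(curve$V_j) <= 0)
    stop("curve must cover both polarities of V_j")
  d <- data.frame(v = curve$V_j, g = curve$G_norm)
  start <- list(G_max = max(d$g), G_res = min(d$g),
                Vp = 40, Vn = 40, Ap = 0.15, An = 0.15)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      g ~ G_res + (G_max - G_res) /
        ((1 + exp(Ap * (v - Vp))) * (1 + exp(-An * (v + Vn)))),
      data = d, start = start,
      lower = c(0, 0, 1, 1, 1e-3, 1e-3),
      upper = c(2, 1, 150, 150, 2, 2),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("modified-Boltzmann fit failed: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  # midpoint crossings of the fitted model itself: where it crosses halfway
  # between its value at V_j = 0 and the residual plateau (comparable to
  # half_inactivation_voltage(); the raw Boltzmann midpoint parameters Vp,
  # Vn shift away from these when the two branches overlap near 0)
  gfun <- function(v) cf["G_res"] + (cf["G_max"] - cf["G_res"]) /
    ((1 + exp(cf["Ap"] * (v - cf["Vp"]))) *
       (1 + exp(-cf["An"] * (v + cf["Vn"]))))
  crossing <- function(sgn) {
    target <- (gfun(0) + cf["G_res"]) / 2
    tryCatch(stats::uniroot(function(v) gfun(sgn * v) - target,
                            c(1e-3, 140), tol = 1e-6)$root,
             error = function(e) NA_real_)
  }
  list(G_max = unname(cf["G_max"]), G_res = unname(cf["G_res"]),
       V_half_pos = unname(cf["Vp"]), V_half_neg = unname(cf["Vn"]),
       V_half_cross_pos = crossing(+1), V_half_cross_neg = crossing(-1),
       slope_pos = unname(1 / cf["Ap"]), slope_neg = unname(1 / cf["An"]),
       rss = sum(stats::resid(fit)^2), fit = fit)
}
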