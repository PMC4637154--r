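# Linear-interpolated time at which series y crosses level, moving in
# direction sign (+1 upward, -1 downward), searching from index i0.
cross_time <- function(t, y, level, i0 = 1, sign = -1) {
  n <- length(y)
  if (i0 >= n) return(NA_real_)
  for (i in seq(i0 + 1, n)) {
    if (sign < 0 && y[i] <= level && y[i - 1] > level ||
        sign > 0 && y[i] >= level && y[i - 1] < level) {
      return(t[i - 1] + (level - y[i - 1]) * (t[i] - t[i - 1]) /
               (y[i] - y[i - 1]))
    }
  }
  NA_real_
}

# Index of maximal dV/dt within [t1, t2]; returns list(i, t, dvdt).
upstroke_in_window <- function(t, V, t1 = -Inf, t2 = Inf) {
  dv <- diff(V) / diff(t)
  tm <- (t[-1] + t[-length(t)]) / 2
  sel <- tm >= t1 & tm <= t2
  if (!any(sel)) return(NULL)
  k <- which(sel)[which.max(dv[sel])]
  list(i = k, t = tm[k], dvdt = dv[k])
}

#' Action-potential morphology metrics
#'
#' Resting potential is the minimum of V_myo over the diastolic interval
#' preceding the upstroke; APD50/APD90 run from the time of maximal dV/dt to
#' 50%/90% repolarisation towards that resting value; the plateau potential
#' is the mean of V_myo between the APD20 and APD50 times.
#'
#' @param trace an `fm_trace` (or any data.frame with columns t, V_myo).
#' @param beat_index which paced beat to analyse (default: the last).
#' @param min_amplitude detection threshold (mV); below it a no-AP result
#'   (all-NA metrics, `detected = FALSE`) is returned.
#' @return List of class `ap_metrics`: `resting`, `peak`, `amplitude` (mV),
#'   `dvdt_max` (mV/ms), `t_upstroke` (ms), `apd50`, `apd90` (ms),
#'   `plateau` (mV), `detected`.
#' @export
ap_metrics <- function(trace, beat_index = NULL, min_amplitude = 40) {
  st <- attr(trace, "stimulus")
  onsets <- if (!is.null(st)) stimulus_times(st) else numeric(0)
  if (length(onsets)) {
    if (is.null(beat_index)) beat_index <- length(onsets)
    if (beat_index < 1 || beat_index > length(onsets))
      stop("beat ", beat_index, " not in trace")
    t1 <- onsets[beat_index]
    t2 <- if (beat_index < length(onsets)) onsets[beat_index + 1] else
      max(trace$t)
  } else {
    t1 <- min(trace$t); t2 <- max(trace$t)
  }
  t <- trace$t; V <- trace$V_myo
  up <- upstroke_in_window(t, V, t1, t2)
  no_ap <- list(resting = NA_real_, peak = NA_real_, amplitude = NA_real_,
                dvdt_max = NA_real_, t_upstroke = NA_real_,
                apd50 = NA_real_, apd90 = NA_real_, plateau = NA_real_,
                detected = FALSE)
  class(no_ap) <- "ap_metrics"
  if (is.null(up)) return(no_ap)
  dia <- t >= max(min(t), t1 - 100) & t <= up$t
  if (!any(dia)) dia <- t <= up$t
  resting <- min(V[t >= t1 & t <= up$t], V[dia])
  win <- t >= up$t & t <= t2
  peak <- max(V[win])
  amplitude <- peak - resting
  if (!is.finite(amplitude) || amplitude < min_amplitude) return(no_ap)
  i0 <- which(win)[1]
  repol <- function(frac)
    cross_time(t, V, resting + (1 - frac) * amplitude, i0 = i0, sign = -1)
  t20 <- repol(0.20); t50 <- repol(0.50); t90 <- repol(0.90)
  apd50 <- t50 - up$t
  apd90 <- t90 - up$t
  plateau <- if (is.finite(t20) && is.finite(t50) && t50 > t20)
    mean(V[t >= t20 & t <= t50]) else NA_real_
  structure(list(resting = resting, peak = peak, amplitude = amplitude,
                 dvdt_max = up$dvdt, t_upstroke = up$t,
                 apd50 = apd50, apd90 = apd90, plateau = plateau,
                 detected = TRUE),
            class = "ap_metrics")
}

#' @export
print.ap_metrics <- function(x, ...) {
  if (!x$detected) { cat("no action potential detected\n"); return(invisible(x)) }
  cat(sprintf(paste0("AP: rest %.1f mV, peak %.1f mV, amplitude %.1f mV, ",
                     "dV/dt_max %.0f mV/ms\n    plateau %.1f mV, ",
                     "APD50 %.1f ms, APD90 %.1f ms\n"),
              x$resting, x$peak, x$amplitude, x$dvdt_max, x$plateau,
              x$apd50, x$apd90))
  invisible(x)
}

#' Early/late decomposition of the gap junctional current
#'
#' The early, transient-outward-like component is the largest |I_gap| within
#' `early_window` ms of the upstroke (maximal dV/dt); the late, background
#' component is I_gap at the APD50 time.
#'
#' @param trace an `fm_trace` containing `I_gap_total`.
#' @param beat_index paced beat to analyse (default first, the beat the
#'   dynamic-static peak difference is defined on).
#' @param early_window width of the early window after the upstroke (ms).
#' @return List of class `gap_components`: `early_peak` (pA, magnitude),
#'   `early_time` (ms), `late` (pA, signed, at the APD50 time),
#'   `t_upstroke`.
#' @export
igap_components <- function(trace, beat_index = 1, early_window = 10) {
  if (is.null(trace$I_gap_total)) stop("trace carries no I_gap_total")
  m <- ap_metrics(trace, beat_index = beat_index)
  if (!m$detected) stop("no upstroke detected in trace")
  t <- trace$t; ig <- trace$I_gap_total
  sel <- t >= m$t_upstroke & t <= m$t_upstroke + early_window
  i_early <- which(sel)[which.max(abs(ig[sel]))]
  t50 <- m$t_upstroke + m$apd50
  late <- if (is.finite(t50)) stats::approx(t, ig, xout = t50)$y else
    NA_real_
  structure(list(early_peak = abs(ig[i_early]), early_time = t[i_early],
                 late = late, t_upstroke = m$t_upstroke),
            class = "gap_components")
}

#' @export
print.gap_components <- function(x, ...) {
  cat(sprintf("I_gap: early peak %.1f pA at %.2f ms; late %.1f pA\n",
              x$early_peak, x$early_time, x$late))
  invisible(x)
}

#' Dynamic-minus-static early-peak difference
#'
#' Signed difference of the early-peak magnitudes between a dynamic and a
#' static trace from otherwise identical configurations. Gating can only
#' inactivate channels away from the static (all-open) conductance, so the
#' value is expected <= 0.
#'
#' @param dynamic,static `fm_trace` objects whose configurations agree in
#'   fibroblast count/type and realised maximal conductance.
#' @param tol_gj relative tolerance on the realised conductance match.
#' @return Difference in pA (|early|_dynamic - |early|_static).
#' @export
delta_igap_peak <- function(dynamic, static, tol_gj = 0.05) {
  cd <- attr(dynamic, "config"); cs <- attr(static, "config")
  if (is.null(cd) || is.null(cs)) stop("traces carry no configuration")
  if (cd$n_fibroblasts != cs$n_fibroblasts ||
      cd$fibroblast != cs$fibroblast)
    stop("configuration mismatch between dynamic and static traces")
  gd <- realized_gj_max(cd); gs <- realized_gj_max(cs)
  if (abs(gd - gs) > tol_gj * max(gd, gs))
    stop("realised G_j,max mismatch: ", signif(gd, 4), " vs ",
         signif(gs, 4), " nS")
  igap_components(dynamic)$early_peak - igap_components(static)$early_peak
}

#' Sweep of the peak-current difference over F-M ratio and conductance
#'
#' For each grid cell a static and a dynamic pair simulation are run with
#' identical configurations and the first-beat early-peak difference is
#' recorded. Failed runs are flagged (NA) and the sweep continues.
#'
#' @param ratios F-M ratios (fibroblasts per myocyte), integers >= 1.
#' @param conductances junctional conductances (nS).
#' @param phenotype dynamic phenotype ("Cx43", "Cx45", "Cx43/Cx45").
#' @param fibroblast fibroblast model for the pairs.
#' @param t_end,output_dt simulation window passed to [simulate_coupled()].
#' @param ... further arguments to [coupling_config()].
#' @return List of class `gj_sweep`: `ratios`, `conductances`, matrices
#'   `delta` (pA, dynamic - static), `early_static`, `early_dynamic`
#'   (ratios in rows, conductances in columns), and `phenotype`.
#' @export
sweep_delta_igap <- function(ratios = c(1, 2, 4, 6, 8),
                             conductances = c(0.5, 1, 2, 3, 4, 6, 8),
                             phenotype = "Cx45", fibroblast = "active",
                             t_end = 420, output_dt = 0.05, ...) {
  nr <- length(ratios); nc <- length(conductances)
  delta <- es <- ed <- matrix(NA_real_, nr, nc,
                              dimnames = list(ratios, conductances))
  stim <- stimulus_protocol(n_beats = 1)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    res <- tryCatch({
      cfg_d <- coupling_config(ratios[i], fibroblast = fibroblast,
                               gj_model = phenotype,
                               g_j_max = conductances[j], ...)
      cfg_s <- coupling_config(ratios[i], fibroblast = fibroblast,
                               gj_model = "static",
                               g_j_max = realized_gj_max(cfg_d))
      tr_d <- simulate_coupled(coupled_system(cfg_d, stim), t_end,
                               output_dt)
      tr_s <- simulate_coupled(coupled_system(cfg_s, stim), t_end,
                               output_dt)
      c(igap_components(tr_d)$early_peak, igap_components(tr_s)$early_peak)
    }, error = function(e) c(NA_real_, NA_real_))
    ed[i, j] <- res[1]; es[i, j] <- res[2]
    delta[i, j] <- res[1] - res[2]
  }
  structure(list(ratios = ratios, conductances = conductances,
                 delta = delta, early_static = es, early_dynamic = ed,
                 phenotype = phenotype),
            class = "gj_sweep")
}

#' @export
print.gj_sweep <- function(x, ...) {
  cat("Delta I_gap,peak sweep (", x$phenotype, "), pA:\n", sep = "")
  print(round(x$delta, 2))
  invisible(x)
}

#' Conductance maximising |delta I_gap,peak| at a given ratio
#'
#' @param sweep a [sweep_delta_igap()] result.
#' @param ratio F-M ratio to inspect (default: the highest in the sweep).
#' @return Conductance (nS) at which the absolute peak difference is
#'   largest.
#' @export
sweep_argmax_conductance <- function(sweep, ratio = max(sweep$ratios)) {
  i <- match(ratio, sweep$ratios)
  if (is.na(i)) stop("ratio not in sweep")
  row <- abs(sweep$delta[i, ])
  if (all(is.na(row))) stop("all runs failed at ratio ", ratio)
  sweep$conductances[which.max(row)]
}

#' Detect spontaneous (unstimulated) action potentials
#'
#' Scans the myocyte voltage for upstrokes (dV/dt above `dvdt_threshold`
#' with local amplitude above `min_amplitude`) and reports those occurring
#' more than `margin` ms away from every stimulus onset.
#'
#' @param trace an `fm_trace`.
#' @param stimulus_onsets pulse onset times (ms); defaults to the protocol
#'   stored in the trace.
#' @param dvdt_threshold upstroke detection threshold (mV/ms).
#' @param min_amplitude minimal AP amplitude (mV).
#' @param margin exclusion margin around each stimulus (ms).
#' @param refractory minimal separation of detected events (ms).
#' @return Numeric vector of spontaneous upstroke times (ms); empty if
#'   none.
#' @export
detect_spontaneous <- function(trace, stimulus_onsets = NULL,
                               dvdt_threshold = 10, min_amplitude = 40,
                               margin = 50, refractory = 100) {
  if (is.null(stimulus_onsets)) {
    st <- attr(trace, "stimulus")
    stimulus_onsets <- if (!is.null(st)) stimulus_times(st) else numeric(0)
  }
  t <- trace$t; V <- trace$V_myo
  dv <- diff(V) / diff(t)
  tm <- (t[-1] + t[-length(t)]) / 2
  cand <- which(dv >= dvdt_threshold)
  events <- numeric(0)
  last <- -Inf
  for (k in cand) {
    if (tm[k] - last < refractory) next
    # local amplitude: peak within 150 ms after minus baseline 20 ms before
    base <- min(V[t >= tm[k] - 20 & t <= tm[k]])
    pk <- max(V[t >= tm[k] & t <= tm[k] + 150])
    if (pk - base >= min_amplitude) {
      events <- c(events, tm[k])
      last <- tm[k]
    }
  }
  if (length(stimulus_onsets))
    events <- events[vapply(events, function(e)
      min(abs(e - stimulus_onsets)) > margin, logical(1))]
  events
}
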