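#' Configuration of a 1D strand with random fibroblast insertion
#'
#' A chain of resistively coupled myocytes (a discrete cell network, not a
#' continuum PDE) carrying fibroblasts in one of two topologies:
#'
#' * `"inserted"` (default): fibroblasts are interspersed *in* the
#'   conduction path -- between myocyte i and i+1 a short serial chain of
#'   k_i passive/active fibroblasts is inserted, emulating a coculture of
#'   myocytes interspersed with fibroblasts. The propagating wave must cross
#'   the inexcitable bridges, so CV falls monotonically with density.
#' * `"attached"`: fibroblasts hang off individual myocytes as electrical
#'   load (single-sided coupling); the conduction path itself is purely
#'   myocyte. In this topology modest fibroblast-mediated depolarisation
#'   speeds conduction (supernormality) before excitability collapses --
#'   the biphasic cell-attached behaviour.
#'
#' With a target F-M ratio `r`, every site receives `floor(r)` fibroblasts
#' plus one more with probability `r - floor(r)` (seeded Bernoulli
#' placement).
#'
#' @param n_cells number of myocytes (>= 20 for CV measurement).
#' @param g_mm myocyte-myocyte coupling conductance (nS, static).
#' @param g_insert coupling conductance of links that involve an inserted
#'   fibroblast (nS); tissue-level F-M junctions are weaker than
#'   myocyte-myocyte junctions.
#' @param cell_length cell length (um), used to convert CV to cm/s.
#' @param fm_ratio target fibroblast-myocyte ratio (>= 0).
#' @param topology "inserted" or "attached".
#' @param attachment optional explicit per-site fibroblast counts (length
#'   `n_cells`); overrides `fm_ratio`.
#' @param coupling a [coupling_config()] describing the fibroblast model
#'   and, in the attached topology, the per-attachment GJ model and
#'   conductance; its `n_fibroblasts` field is ignored.
#' @param stimulus end-stimulus protocol; the pulse is applied to the first
#'   `n_stim` myocytes (a single cell cannot overcome the axial load at
#'   physiological coupling).
#' @param n_stim number of stimulated cells at the strand end.
#' @param seed RNG seed for random placement (recorded; used when
#'   `fm_ratio` is fractional).
#' @return List of class `strand_config`.
#' @export
strand_config <- function(n_cells = 60, g_mm = 2500, g_insert = 750,
                          cell_length = 100, fm_ratio = 0,
                          topology = c("inserted", "attached"),
                          attachment = NULL,
                          coupling = coupling_config(
                            n_fibroblasts = 1, fibroblast = "passive",
                            gj_model = "static", g_j_max = 3),
                          stimulus = stimulus_protocol(amplitude = 100,
                                                       n_beats = 1,
                                                       onset = 5),
                          n_stim = 3, seed = 1L) {
  topology <- match.arg(topology)
  if (n_cells < 20) stop("n_cells must be >= 20 for CV measurement")
  if (!is.null(attachment) && length(attachment) != n_cells)
    stop("attachment map length must equal n_cells")
  if (fm_ratio < 0) stop("fm_ratio must be >= 0")
  structure(list(n_cells = as.integer(n_cells), g_mm = g_mm,
                 g_insert = g_insert, cell_length = cell_length,
                 fm_ratio = fm_ratio, topology = topology,
                 attachment = attachment, coupling = coupling,
                 stimulus = stimulus, n_stim = as.integer(n_stim),
                 seed = as.integer(seed)),
            class = "strand_config")
}

# Draw the per-site fibroblast counts for a target ratio, seeded and
# isolated from the global RNG stream.
draw_attachment <- function(n_cells, fm_ratio, seed) {
  base <- floor(fm_ratio)
  frac <- fm_ratio - base
  extra <- if (frac > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
            else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
    set.seed(seed)
    stats::rbinom(n_cells, 1, frac)
  } else rep(0L, n_cells)
  as.integer(base + extra)
}

# Resting state of one myocyte with nf fibroblast attachments, found by a
# long unstimulated integration of the corresponding pair system.
equilibrated_unit <- function(nf, cc, myo, t_settle = 2000) {
  cfg <- cc
  cfg$n_fibroblasts <- as.integer(nf)
  sys <- coupled_system(cfg, stimulus = NULL, myocyte = myo)
  rhs <- function(t, y, p) list(coupled_rhs(sys, t, y)$deriv)
  out <- deSolve::lsoda(sys$y0, seq(0, t_settle, length.out = 9), rhs,
                        NULL, rtol = 1e-6, atol = 1e-8, maxsteps = 50000)
  yf <- out[nrow(out), -1]
  list(myo = yf[sys$index$myo],
       fib = if (nf > 0) yf[sys$index$fib[seq_len(sys$index$n_fib_states)]]
         else NULL,
       gj = if (length(sys$index$gj)) yf[sys$index$gj[1:4]] else NULL)
}

#' Build an integrable strand system
#'
#' States are laid out site by site (myocyte block, then that site's
#' fibroblasts and any gap-junction fractions) so the Jacobian stays
#' banded. Attached-topology cells are initialised from the equilibrated
#' coupled-pair resting state, so CV is measured in the chronically coupled
#' condition; inserted-topology strands are settled by
#' [simulate_strand()]'s `t_settle` pre-run.
#'
#' @param config a [strand_config()].
#' @return List of class `strand_system`.
#' @export
build_strand <- function(config) {
  stopifnot(inherits(config, "strand_config"))
  n <- config$n_cells
  counts <- if (!is.null(config$attachment)) as.integer(config$attachment)
    else draw_attachment(n, config$fm_ratio, config$seed)
  cc <- config$coupling
  attached <- config$topology == "attached"
  dynamic <- attached && cc$gj_model != "static"
  fib_states <- if (cc$fibroblast == "active")
    active_fibroblast_state_names() else "Vf"
  k_fib <- length(fib_states)
  k_gj <- if (dynamic) 4L else 0L

  myo <- myocyte_model()
  eq <- list()
  if (attached) {
    for (nf in sort(unique(counts)))
      eq[[as.character(nf)]] <- equilibrated_unit(nf, cc, myo)
  } else {
    eq[["any"]] <- list(
      myo = myo$init(),
      fib = if (cc$fibroblast == "active")
        active_fibroblast_init(params = cc$fib_params) else
          c(Vf = cc$fib_params$E_f))
  }

  blocks <- 8L + counts * (k_fib + k_gj)
  offs <- c(0L, cumsum(blocks))
  y0 <- numeric(offs[n + 1])
  vidx <- integer(n)          # position of each myocyte's V
  fib_of <- integer(0)        # site index of each fibroblast
  fidx <- integer(0)          # position of each fibroblast's first state
  gidx <- integer(0)          # position of each junction's first fraction
  for (i in seq_len(n)) {
    o <- offs[i]
    eqi <- if (attached) eq[[as.character(counts[i])]] else eq[["any"]]
    y0[o + 1:8] <- eqi$myo
    vidx[i] <- o + 1L
    if (counts[i] > 0) {
      for (k in seq_len(counts[i])) {
        fo <- o + 8L + (k - 1L) * (k_fib + k_gj)
        y0[fo + seq_len(k_fib)] <- eqi$fib
        fib_of <- c(fib_of, i)
        fidx <- c(fidx, fo + 1L)
        if (dynamic) {
          y0[fo + k_fib + 1:4] <- eqi$gj
          gidx <- c(gidx, fo + k_fib + 1L)
        }
      }
    }
  }

  sys <- list(config = config, counts = counts, myocyte = myo,
              y0 = y0, vidx = vidx, fib_of = fib_of, fidx = fidx,
              gidx = gidx, k_fib = k_fib, dynamic = dynamic,
              bandwidth = max(blocks))
  if (!attached && length(fib_of)) {
    # serial node chain: M1, its inserted fibs, M2, ... with per-link
    # conductances (g_mm for M-M links, g_insert when a fibroblast is
    # involved)
    node_idx <- integer(0); node_is_myo <- logical(0)
    for (i in seq_len(n)) {
      node_idx <- c(node_idx, vidx[i]); node_is_myo <- c(node_is_myo, TRUE)
      fk <- fidx[fib_of == i]
      if (length(fk)) {
        node_idx <- c(node_idx, fk)
        node_is_myo <- c(node_is_myo, rep(FALSE, length(fk)))
      }
    }
    g_link <- ifelse(node_is_myo[-length(node_is_myo)] &
                       node_is_myo[-1], config$g_mm, config$g_insert)
    sys$node_idx <- node_idx; sys$node_is_myo <- node_is_myo
    sys$g_link <- g_link
  }
  class(sys) <- "strand_system"
  sys
}

#' @export
print.strand_system <- function(x, ...) {
  cat("1D strand:", x$config$n_cells, "myocytes +", sum(x$counts),
      "fibroblasts (", x$config$topology, ", target ratio",
      x$config$fm_ratio, ", seed", x$config$seed, "), g_mm =",
      x$config$g_mm, "nS\n")
  invisible(x)
}

# Strand RHS, vectorized across cells and fibroblasts.
strand_rhs <- function(t, y, sys) {
  cfg <- sys$config
  cc <- cfg$coupling
  n <- cfg$n_cells
  m <- length(sys$fib_of)
  attached <- cfg$topology == "attached"

  V <- y[sys$vidx]
  st <- list(V = V, m = y[sys$vidx + 1], h = y[sys$vidx + 2],
             j = y[sys$vidx + 3], d = y[sys$vidx + 4],
             f = y[sys$vidx + 5], X = y[sys$vidx + 6],
             Cai = y[sys$vidx + 7])

  if (m > 0) {
    if (cc$fibroblast == "active") {
      fs <- list(Vf = y[sys$fidx], r = y[sys$fidx + 1],
                 s = y[sys$fidx + 2], Ki = y[sys$fidx + 3],
                 Nai = y[sys$fidx + 4])
    } else fs <- list(Vf = y[sys$fidx])
  }

  I_myo_inj <- numeric(n)
  I_fib_inj <- if (m > 0) numeric(m) else numeric(0)
  dgj <- NULL

  if (attached || m == 0) {
    # axial current along the pure-myocyte chain (pA)
    dV_nb <- cfg$g_mm * diff(V)
    I_myo_inj[-n] <- I_myo_inj[-n] + dV_nb
    I_myo_inj[-1] <- I_myo_inj[-1] - dV_nb
    if (m > 0) {
      V_j <- fs$Vf - V[sys$fib_of]
      if (sys$dynamic) {
        F <- cbind(y[sys$gidx], y[sys$gidx + 1], y[sys$gidx + 2],
                   y[sys$gidx + 3])
        G_j <- cc$N_C * as.numeric(F %*% cc$g_states) / 1000
        dgj <- gj_fraction_derivs(F, V_j, cc$hcA, cc$hcB, cc$contingent)
      } else G_j <- rep(cc$g_j_max, m)
      I_gap <- G_j * V_j
      agg <- rowsum(I_gap, sys$fib_of)
      I_myo_inj[as.integer(rownames(agg))] <-
        I_myo_inj[as.integer(rownames(agg))] + agg
      I_fib_inj <- -I_gap
    }
  } else {
    # serial chain including inserted fibroblasts
    Vn <- y[sys$node_idx]
    I_link <- sys$g_link * diff(Vn)
    I_node <- numeric(length(Vn))
    I_node[-length(Vn)] <- I_node[-length(Vn)] + I_link
    I_node[-1] <- I_node[-1] - I_link
    I_myo_inj <- I_node[sys$node_is_myo]
    I_fib_inj <- I_node[!sys$node_is_myo]
  }

  dfib <- NULL
  if (m > 0) {
    dfib <- if (cc$fibroblast == "active")
      maccannell_rhs(fs, cc$fib_params, I_inj = I_fib_inj)$deriv
    else list(Vf = passive_fibroblast_rhs(fs$Vf, cc$fib_params,
                                          I_fib_inj))
  }

  I_stim <- numeric(n)
  I_stim[seq_len(cfg$n_stim)] <- stimulus_current(t, cfg$stimulus) *
    sys$myocyte$C_m
  dmyo <- lr1_rhs(st, I_inj = I_myo_inj + I_stim, sys$myocyte$params)$deriv

  dy <- numeric(length(y))
  for (k in 1:8) dy[sys$vidx + (k - 1)] <- dmyo[[k]]
  if (m > 0) {
    for (k in seq_len(sys$k_fib)) dy[sys$fidx + (k - 1)] <- dfib[[k]]
    if (!is.null(dgj)) for (k in 1:4) dy[sys$gidx + (k - 1)] <- dgj[, k]
  }
  list(dy)
}

#' Simulate a strand
#'
#' @param system a [build_strand()] result.
#' @param t_end end time (ms), counted after the settling pre-run.
#' @param output_dt output sampling (ms).
#' @param t_settle unstimulated settling time (ms) run before t = 0 so the
#'   strand starts from its coupled resting state; used for the inserted
#'   topology (attached strands are pre-equilibrated cell by cell).
#' @return List of class `strand_trace`: `t` and `V` (time x myocyte
#'   matrix), plus the system.
#' @export
simulate_strand <- function(system, t_end = 80, output_dt = 0.1,
                            t_settle = NULL) {
  stopifnot(inherits(system, "strand_system"))
  bw <- system$bandwidth
  y0 <- system$y0
  if (is.null(t_settle))
    t_settle <- if (system$config$topology == "inserted" &&
                      length(system$fib_of)) 250 else 0
  if (t_settle > 0) {
    sys0 <- system
    sys0$config$stimulus <- NULL
    pre <- deSolve::lsoda(y0, seq(0, t_settle, length.out = 6),
                          function(t, y, p) strand_rhs(t, y, sys0), NULL,
                          rtol = 1e-6, atol = 1e-8, maxsteps = 50000,
                          jactype = "bandint", bandup = bw, banddown = bw)
    y0 <- pre[nrow(pre), -1]
  }
  times <- seq(0, t_end, by = output_dt)
  out <- deSolve::lsoda(y0, times,
                        function(t, y, p) strand_rhs(t, y, system), NULL,
                        rtol = 1e-6, atol = 1e-8,
                        jactype = "bandint", bandup = bw, banddown = bw,
                        hmax = 1)
  if (attr(out, "istate")[1] < 0)
    stop("strand solver failure at t = ", max(out[, 1]), " ms")
  V <- out[, 1 + system$vidx, drop = FALSE]
  colnames(V) <- paste0("cell", seq_len(system$config$n_cells))
  structure(list(t = out[, 1], V = V, system = system),
            class = "strand_trace")
}

#' Per-cell activation times
#'
#' Activation is the first upward crossing of the threshold voltage,
#' linearly interpolated.
#'
#' @param trace a [simulate_strand()] result.
#' @param threshold activation threshold (mV).
#' @return Numeric vector (ms) with NA for cells that never activate.
#' @export
activation_times <- function(trace, threshold = -20) {
  apply(trace$V, 2, function(v) {
    # a genuine upstroke starts from a polarised diastole well below
    # threshold; depolarised, inexcitable cells drifting across the
    # threshold do not count as activated
    if (v[1] > threshold - 20) return(NA_real_)
    ct <- cross_time(trace$t, v, threshold, sign = +1)
    if (is.na(ct)) return(NA_real_)
    pk <- max(v[trace$t >= ct])
    if (pk - v[1] < 40) NA_real_ else ct
  })
}

#' Conduction velocity from activation times
#'
#' Linear regression of activation time on position over the central 50% of
#' the strand (boundary cells excluded).
#'
#' @param act activation times per cell (ms), as from [activation_times()].
#' @param cell_length cell length (um).
#' @param window index range used for the fit; default the central half.
#' @return List of class `cv_result`: `cv` (cm/s, NA with `block = TRUE` if
#'   any cell in the window failed to activate), `window`, `activation`.
#' @export
measure_cv <- function(act, cell_length = 100, window = NULL) {
  n <- length(act)
  if (is.null(window)) window <- seq(floor(n / 4) + 1, ceiling(3 * n / 4))
  a <- act[window]
  if (any(is.na(a))) {
    return(structure(list(cv = NA_real_, block = TRUE, window = window,
                          activation = act), class = "cv_result"))
  }
  fit <- stats::lm(a ~ window)
  slope <- unname(stats::coef(fit)[2])          # ms per cell
  cv <- (cell_length * 1e-4) / (slope * 1e-3)   # cm / s
  structure(list(cv = cv, block = FALSE, window = window,
                 activation = act), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  if (x$block) cat("conduction block (unactivated cells in window)\n")
  else cat("CV =", round(x$cv, 2), "cm/s over cells",
           min(x$window), "-", max(x$window), "\n")
  invisible(x)
}

#' Strand CV in one call
#'
#' @param config a [strand_config()].
#' @param t_end simulation time (ms).
#' @return A `cv_result` (see [measure_cv()]).
#' @export
strand_cv <- function(config, t_end = 80) {
  tr <- simulate_strand(build_strand(config), t_end = t_end)
  measure_cv(activation_times(tr), config$cell_length)
}

#' CV versus fibroblast-density sweep
#'
#' For each F-M ratio the strand is rebuilt with each seed (random
#' fibroblast placement) and CV measured; conduction block is reported, not
#' raised.
#'
#' @param ratios target F-M ratios.
#' @param seeds RNG seeds (one strand replicate per seed).
#' @param config base [strand_config()]; ratio and seed fields are
#'   overridden per run.
#' @param t_end simulation time per run (ms).
#' @return data.frame with columns ratio, seed, cv (cm/s; NA on block),
#'   block; plus a `summary` attribute with mean CV and block fraction per
#'   ratio.
#' @export
cv_density_sweep <- function(ratios = c(0, 1, 2), seeds = 1:3,
                             config = strand_config(), t_end = 80) {
  res <- expand.grid(ratio = ratios, seed = seeds)
  res$cv <- NA_real_; res$block <- FALSE
  for (k in seq_len(nrow(res))) {
    cfgk <- config
    cfgk$fm_ratio <- res$ratio[k]
    cfgk$seed <- as.integer(res$seed[k])
    cfgk$attachment <- NULL
    r <- tryCatch(strand_cv(cfgk, t_end = t_end),
                  error = function(e) list(cv = NA_real_, block = TRUE))
    res$cv[k] <- r$cv
    res$block[k] <- isTRUE(r$block)
  }
  summ <- do.call(rbind, lapply(split(res, res$ratio), function(d)
    data.frame(ratio = d$ratio[1], mean_cv = mean(d$cv, na.rm = TRUE),
               block_fraction = mean(d$block))))
  summ <- summ[order(summ$ratio), ]
  rownames(summ) <- NULL
  attr(res, "summary") <- summ
  res
}
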