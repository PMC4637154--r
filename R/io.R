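#' Write / read a trace as CSV
#'
#' Plain-text tabular output (comma separator, header row, '.' decimal),
#' with the run configuration echoed into a YAML sidecar for provenance.
#'
#' @param trace an `fm_trace` from [simulate_coupled()].
#' @param path output CSV path; the sidecar is written to
#'   `<path>.config.yaml` unless `sidecar = FALSE`.
#' @param sidecar write the configuration sidecar?
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, sidecar = TRUE) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  cfg <- attr(trace, "config")
  if (sidecar && !is.null(cfg))
    write_run_config(list(coupling = config_to_list(cfg),
                          stimulus = unclass(attr(trace, "stimulus"))),
                     paste0(path, ".config.yaml"))
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tr <- utils::read.csv(path)
  class(tr) <- c("fm_trace", "data.frame")
  tr
}

#' Write a steady-state curve as two-column tabular text
#'
#' @param curve a [steady_state_curve()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve)[c("V_j", "G_norm")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write / read a state snapshot for restart
#'
#' Flat name,value tabular text holding a system's full state vector; pass
#' the restored vector to `simulate_coupled(..., y0 = )` to resume a run.
#'
#' @param y named numeric state vector (e.g. a [coupled_system()]'s `y0`,
#'   or the last row of a raw integration).
#' @param path file path.
#' @return `path` / the restored named vector.
#' @export
write_state <- function(y, path) {
  utils::write.csv(data.frame(name = names(y), value = as.numeric(y)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path) {
  d <- utils::read.csv(path, colClasses = c("character", "numeric"))
  stats::setNames(d$value, d$name)
}

# Flatten a coupling_config into plain lists for serialisation.
config_to_list <- function(cfg) {
  out <- list(n_fibroblasts = cfg$n_fibroblasts,
              fibroblast = cfg$fibroblast, gj_model = cfg$gj_model,
              g_j_max = cfg$g_j_max, contingent = cfg$contingent,
              orientation = cfg$orientation,
              freeze_gates = cfg$freeze_gates,
              fib_params = unclass(cfg$fib_params))
  out$fib_params$RTF <- NULL
  out
}

# Rebuild a coupling_config from its serialised list.
config_from_list <- function(x) {
  fp <- if (x$fibroblast == "active") {
    keep <- intersect(names(x$fib_params),
                      names(formals(active_fibroblast)))
    do.call(active_fibroblast, x$fib_params[keep])
  } else {
    do.call(passive_fibroblast, x$fib_params[c("C_f", "G_f", "E_f")])
  }
  coupling_config(n_fibroblasts = x$n_fibroblasts,
                  fibroblast = x$fibroblast, gj_model = x$gj_model,
                  g_j_max = x$g_j_max, fib_params = fp,
                  contingent = x$contingent, orientation = x$orientation,
                  freeze_gates = x$freeze_gates)
}

#' Run configuration: serialisable description of a scenario
#'
#' A full run description that round-trips losslessly through YAML.
#'
#' @param scenario one of "pair", "sweep", "cable", "gj-curve".
#' @param coupling a [coupling_config()].
#' @param stimulus a [stimulus_protocol()].
#' @param t_end,output_dt integration window (ms).
#' @param sweep list with `ratios`, `conductances`, `phenotype` (sweep
#'   scenario).
#' @param cable list of [strand_config()]-style fields (cable scenario).
#' @param phenotype GJ phenotype (gj-curve scenario).
#' @param seed RNG seed (cable scenario only; everything else is
#'   deterministic).
#' @param outdir output directory.
#' @return List of class `run_config`.
#' @export
run_config <- function(scenario = c("pair", "sweep", "cable", "gj-curve"),
                       coupling = coupling_config(),
                       stimulus = stimulus_protocol(),
                       t_end = 610, output_dt = 0.1,
                       sweep = list(ratios = c(1, 2, 4, 6, 8),
                                    conductances = c(0.5, 1, 2, 3, 4, 6, 8),
                                    phenotype = "Cx45"),
                       cable = list(n_cells = 60, fm_ratio = 1,
                                    ratios = NULL),
                       phenotype = "Cx43", seed = 1L, outdir = ".") {
  scenario <- match.arg(scenario)
  structure(list(scenario = scenario, coupling = coupling,
                 stimulus = stimulus, t_end = t_end,
                 output_dt = output_dt, sweep = sweep, cable = cable,
                 phenotype = phenotype, seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

#' Write / read a run configuration (YAML)
#'
#' @param config a [run_config()] (or any nested list of plain values).
#' @param path file path.
#' @return `path` / the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- config
  if (inherits(x, "run_config")) {
    x <- unclass(x)
    x$coupling <- config_to_list(x$coupling)
    x$stimulus <- unclass(x$stimulus)
  }
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$scenario)) {
    x$coupling <- config_from_list(x$coupling)
    x$stimulus <- do.call(stimulus_protocol, x$stimulus)
    class(x) <- "run_config"
  }
  x
}

# Stable hash of a parameter list: md5 of its canonical YAML text.
param_hash <- function(x) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(x, f, precision = 15)
  unname(tools::md5sum(f))
}

#' Regenerate bundled reference fixtures
#'
#' Writes short, coarse-grid reference runs (an uncoupled myocyte beat, a
#' statically coupled pair beat and the Cx43/Cx45 steady-state curves) used
#' by regression tests, together with a hash of the generating model
#' parameters. If fixtures already exist with a different parameter hash,
#' the function stops and asks for explicit regeneration, so silent
#' parameter drift cannot go unnoticed.
#'
#' @param dir target directory.
#' @param force overwrite fixtures whose parameter hash changed.
#' @return The fixture parameter hash, invisibly.
#' @export
make_fixtures <- function(dir, force = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pars <- list(myocyte = unclass(lr1_params()),
               fibroblast = config_to_list(coupling_config(1))$fib_params,
               Cx43 = unclass(connexin_hemichannel("Cx43")),
               Cx45 = unclass(connexin_hemichannel("Cx45")))
  h <- param_hash(pars)
  hash_file <- file.path(dir, "PARAM_HASH")
  if (file.exists(hash_file)) {
    old <- readLines(hash_file, warn = FALSE)[1]
    if (identical(old, h) && !force) return(invisible(h))  # no-op
    if (!identical(old, h) && !force)
      stop("model parameters changed since fixtures were generated ",
           "(hash ", old, " -> ", h, "); rerun make_fixtures(dir, ",
           "force = TRUE) to re-bless them")
  }
  tr0 <- simulate_pair(0, "static", 1, n_beats = 1, t_end = 450,
                       output_dt = 1)
  write_trace(tr0, file.path(dir, "uncoupled_beat.csv"), sidecar = FALSE)
  tr1 <- simulate_pair(1, "static", 3, n_beats = 1, t_end = 450,
                       output_dt = 1)
  write_trace(tr1, file.path(dir, "pair_static_3nS.csv"), sidecar = FALSE)
  for (ph in c("Cx43", "Cx45"))
    write_curve(steady_state_curve(ph, seq(-100, 100, by = 2)),
                file.path(dir, paste0("curve_", sub("/", "-", ph), ".csv")))
  writeLines(h, hash_file)
  invisible(h)
}
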