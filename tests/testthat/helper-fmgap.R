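# Shared, lazily computed simulation fixtures (each built once per session).
.fix <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- build()
  .fix[[name]]
}

# one-beat traces used across tests
trace_uncoupled <- function()
  fixture("uncoupled", function()
    simulate_pair(0, "static", 1, n_beats = 1, t_end = 450))

trace_static_n2 <- function()
  fixture("static_n2", function()
    simulate_pair(2, "static", 3, n_beats = 1, t_end = 450))

# synthetic trapezoidal action potential: rest -85 mV, instantaneous
# upstroke to +35 mV at t = 100 ms, linear repolarisation over 300 ms
trapezoid_trace <- function(dt = 0.5) {
  t <- seq(0, 500, by = dt)
  V <- ifelse(t < 100, -85,
              ifelse(t <= 400, 35 - (t - 100) / 300 * 120, -85))
  structure(data.frame(t = t, V_myo = V, stim = 0),
            class = c("fm_trace", "data.frame"))
}
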