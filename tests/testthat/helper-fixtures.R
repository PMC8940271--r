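# Shared fixtures: small protocols and parameter sets used across tests.

wt_truth <- function(...) wt_ground_truth(...)

# Six-step light curve with short (30 s) steps: fast to simulate, and the
# emitted ground-truth landmarks are window-exact so steady state is not
# required.
short_lc_protocol <- function() light_curve_protocol(step_s = 30)

# A minimal dark + single-pulse protocol.
dark_pulse_protocol <- function(dark_s = 10, pulse_s = 0.5) {
  protocol(data.frame(
    start_s = c(0, dark_s),
    end_s = c(dark_s, dark_s + pulse_s),
    kind = c("dark", "saturating_pulse"),
    intensity = c(0, 6000)))
}

# Piecewise-linear OJIP-like pulse through fixed anchor points.
ojip_fixture <- function(f0 = 0.2, f3ms = 0.8, fm = 1.2, scale = 1,
                         offset = 0) {
  anchors_t <- c(0, 50e-6, 3e-3, 0.01, 0.7)
  anchors_f <- c(f0, f0, f3ms, fm, fm)
  tm <- sort(unique(c(anchors_t, seq(0, 0.7, by = 1e-3))))
  trace(tm, stats::approx(anchors_t, anchors_f, xout = tm)$y * scale +
          offset)
}
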