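# Small builders for hand-constructed test series.

# Piecewise-linear apex: rises with `slope_up` for `w` samples, falls with
# `slope_down` for `w` samples, embedded in a flat baseline long enough for
# full analysis windows. Returns list(x, apex_index).
triangle_series <- function(slope_up = 2, slope_down = 1, w = 240L, pad = 300L) {
  up <- cumsum(rep(slope_up, w))
  down <- up[w] - cumsum(rep(slope_down, w))
  x <- c(seq(0, 0, length.out = pad), up, down,
         rep(down[w], pad))
  list(x = x, apex = pad + w)
}

# A clean 60 bpm pulse train as a prepared series (upward pulses), built from
# the generator with no noise or drift so tests can reason about it exactly.
clean_train <- function(duration_s = 20, fraction_inverted = 0, seed = 1,
                        noise_sd = 0, drift_amplitude = 0) {
  rec <- simulate_recording(
    sim_plan(duration_s = duration_s, fraction_inverted = fraction_inverted,
             noise_sd = noise_sd, drift_amplitude = drift_amplitude,
             hr_jitter = 0),
    seed = seed)
  prepare_channel(rec, "ir")
}
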