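# shared fixture builders; everything is generated in code at test time

make_sine <- function(freq, fs, duration, amplitude = 1) {
  amplitude * sin(2 * pi * freq * (0:(round(fs * duration) - 1)) / fs)
}

# steady-state amplitude of a processed sinusoid, ignoring the edges
steady_amplitude <- function(x, trim = 0.2) {
  n <- length(x)
  core <- x[round(n * trim):round(n * (1 - trim))]
  (max(core) - min(core)) / 2
}

# a small clean cohort used by several pipeline tests
tiny_cohort <- function(n_subjects = 3, seed = 42, duration_s = 70) {
  spec <- study2_spec(n_subjects = n_subjects, seed = seed,
                      duration_s = duration_s)
  simulate_cohort(spec)
}
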