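# Shared fixtures: all synthetic, built in code.

# Noise-free configuration (clean ERP signal only).
quiet_noise <- function() {
  noise_config(rms = 0, alpha_amplitude = 0, blink_rate = 0,
               eog_noise_rms = 0)
}

# Small task for fast end-to-end runs.
small_task <- function(n_pairs = 40) task_config(n_pairs = n_pairs)

# Long-format data for a mixed design with one between (3 groups) and one
# or two within factors, filled with iid noise plus optional effects.
make_mixed_table <- function(ng = c(4, 4, 4), k1 = 3, k2 = NULL,
                             within_effect = 0) {
  N <- sum(ng)
  grp <- rep(c("G1", "G2", "G3"), ng)
  if (is.null(k2)) {
    d <- expand.grid(subject = seq_len(N), w1 = paste0("w", seq_len(k1)),
                     stringsAsFactors = FALSE)
  } else {
    d <- expand.grid(subject = seq_len(N), w1 = paste0("w", seq_len(k1)),
                     w2 = paste0("v", seq_len(k2)), stringsAsFactors = FALSE)
  }
  d$group <- grp[d$subject]
  d$y <- stats::rnorm(nrow(d)) +
    within_effect * as.integer(factor(d$w1))
  d
}

with_seed_test <- function(seed, expr) erpdistract:::with_seed(seed, expr)

# Single-channel Hann bump trace on a 1-ms grid.
bump_trace <- function(latency, amplitude, halfwidth = 55,
                       times = seq(-150, 1300, by = 1)) {
  amplitude * erpdistract:::hann_kernel(times, latency, halfwidth)
}
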