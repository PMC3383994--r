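# Shared fixtures: built in code, kept small so the default run stays fast.

# Noise-free, background-free gel for exact mass-conservation checks.
quiet_gel <- function(...) gel_model(noise_sd = 0, background = 0, ...)

# Exact calibration matching the default gel model.
default_cal <- function(gel = gel_model()) {
  calibration_curve(gel$alpha, gel$beta,
                    size_range_fitted = c(100, 1.2e4))
}

# Full inverse chain on one trace.
quantify_trace <- function(trace, cal, df = 40, window = c(200, 1e5),
                           n_bins = 200, target = 1e9) {
  tr <- subtract_background(trace, "auto")
  tr <- smooth_trace(tr, df)
  normalize_and_count(to_size_domain(tr, cal, window, n_bins), target)
}

# Random DNA sequence as a character string.
random_dna <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Exponential fragment lengths truncated at >= 1 nt.
exp_fragments <- function(n, mean_nt, seed = 1) {
  set.seed(seed)
  fragment_set(pmax(1, stats::rexp(n, 1 / mean_nt)), "single")
}
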