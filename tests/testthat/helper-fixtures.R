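# Small, fast simulation settings used across the unit tests. Sampling
# rate and duration are scaled down from the recording-scale defaults but
# keep fs above twice the highest simulated frequency and the record
# above 2^14 samples.
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(fs = 2000, duration = 10, n_subjects = 4L,
         pathways_per_subject = 10L),
    list(...))
  do.call(sim_config, args)
}

# Single-lead session wrapping a channels x time matrix of test signals.
make_session <- function(samples, fs, region = "GPi", lead = "A") {
  samples <- rbind(samples)
  recording_session(
    samples, fs,
    data.frame(subject = "t01", hemisphere = "L", lead = lead,
               region = region, contact = seq_len(nrow(samples)),
               stringsAsFactors = FALSE))
}

rms <- function(x) sqrt(mean(x^2))

# central portion of a signal, away from any filter edge transients
central <- function(x, frac = 0.8) {
  n <- length(x)
  drop <- floor(n * (1 - frac) / 2)
  x[(drop + 1L):(n - drop)]
}
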