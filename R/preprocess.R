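#' Notch filtering at a base frequency and its harmonics
#'
#' Removes mains contamination by cascading second-order IIR notch filters
#' at `base_freq`, `2*base_freq`, ..., `(n_harmonics+1)*base_freq`. Each
#' biquad is the constrained notch with quality factor `q` (bandwidth
#' `f0/q`), and the cascade is applied forward-backward so the net phase
#' shift is zero. With the default `q = 30` the passband more than 5 Hz
#' away from any notch is altered by well under 0.5 dB.
#'
#' @param session a [recording_session()] or [bipolar_session()].
#' @param base_freq fundamental contaminant frequency in Hz (mains: 60).
#' @param n_harmonics number of harmonics above the fundamental to notch;
#'   `n_harmonics = 5` notches 60, 120, 180, 240, 300 and 360 Hz.
#' @param q notch quality factor (center frequency / -3 dB bandwidth).
#'
#' @return The session with filtered samples.
#' @export
notch_filter <- function(session, base_freq = 60, n_harmonics = 5, q = 30) {
  stopifnot(inherits(session, c("recording_session", "bipolar_session")))
  if (base_freq <= 0) stop("`base_freq` must be positive", call. = FALSE)
  freqs <- base_freq * seq_len(n_harmonics + 1L)
  nyq <- session$fs / 2
  if (max(freqs) >= nyq)
    stop("notch at ", max(freqs), " Hz is at or above Nyquist (", nyq,
         " Hz); reduce `n_harmonics` or record faster", call. = FALSE)
  for (f0 in freqs) {
    ba <- design_notch(f0, session$fs, q)
    session <- map_channels(session, function(x)
      filtfilt_ba(ba$b, ba$a, x))
  }
  session
}

# Second-order constrained IIR notch (RBJ biquad): unit gain away from f0,
# zero at f0, -3 dB bandwidth f0/q.
design_notch <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' High-pass filtering to remove drift
#'
#' Zero-phase Butterworth high-pass; the default 4th order at 1 Hz removes
#' slow drift and the DC offset while leaving the analysis band untouched
#' (gain within 1% of unity a decade above the cutoff).
#'
#' @param session a [recording_session()] or [bipolar_session()].
#' @param cutoff -3 dB cutoff frequency in Hz.
#' @param order Butterworth order (per pass; applied forward-backward).
#'
#' @return The session with filtered samples.
#' @export
highpass_filter <- function(session, cutoff = 1, order = 4) {
  stopifnot(inherits(session, c("recording_session", "bipolar_session")))
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= session$fs / 2)
    stop("`cutoff` must lie in (0, fs/2)", call. = FALSE)
  bw <- signal::butter(order, cutoff / (session$fs / 2), type = "high")
  map_channels(session, function(x) filtfilt_ba(bw$b, bw$a, x))
}

#' Adjacent-contact bipolar montage
#'
#' Re-references each lead by subtracting neighbouring contacts: within a
#' lead, contacts are sorted by contact index and derived channel k is
#' contact_k minus contact_(k+1). Any signal common to a whole lead
#' (reference drift, volume-conducted common mode) cancels exactly.
#' Leads with a single contact are skipped with a warning.
#'
#' @param session a [recording_session()].
#' @return A [bipolar_session()] with `contacts - 1` channels per lead.
#' @export
bipolar_montage <- function(session) {
  stopifnot(inherits(session, "recording_session"))
  ch <- session$channels
  out_rows <- list(); out_sig <- list(); k <- 0L
  for (lead_id in unique(ch$lead)) {
    idx <- which(ch$lead == lead_id)
    idx <- idx[order(ch$contact[idx])]
    if (length(idx) < 2L) {
      warning("lead ", lead_id, " has a single contact; skipped")
      next
    }
    for (j in seq_len(length(idx) - 1L)) {
      k <- k + 1L
      a <- idx[j]; b <- idx[j + 1L]
      out_sig[[k]] <- session$samples[a, ] - session$samples[b, ]
      out_rows[[k]] <- data.frame(
        subject = ch$subject[a], hemisphere = ch$hemisphere[a],
        lead = lead_id, region = ch$region[a],
        contact_a = ch$contact[a], contact_b = ch$contact[b],
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) stop("no lead has two or more contacts", call. = FALSE)
  bipolar_session(do.call(rbind, out_sig), session$fs,
                  do.call(rbind, out_rows))
}

#' Anti-aliased decimation
#'
#' Low-pass filters (8th-order Butterworth at 80% of the target Nyquist,
#' zero phase) and keeps every `factor`-th sample. Recordings sampled at
#' 24 kHz carry no analysis content above a few hundred Hz, so decimation
#' to ~3 kHz keeps spectral estimation cheap without touching the band of
#' interest.
#'
#' @param session a [recording_session()] or [bipolar_session()].
#' @param factor integer decimation factor; 1 is the identity.
#' @param min_band highest analysis frequency (Hz) that must survive; the
#'   decimated Nyquist must exceed it.
#'
#' @return The session resampled at `fs / factor`.
#' @export
decimate_session <- function(session, factor, min_band = 500) {
  stopifnot(inherits(session, c("recording_session", "bipolar_session")))
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be >= 1", call. = FALSE)
  if (factor == 1L) return(session)
  new_fs <- session$fs / factor
  if (new_fs / 2 <= min_band)
    stop("decimation to ", new_fs, " Hz puts Nyquist at or below the ",
         min_band, " Hz analysis band", call. = FALSE)
  bw <- signal::butter(8, 0.8 / factor, type = "low")
  keep <- seq(1L, ncol(session$samples), by = factor)
  session <- map_channels(session, function(x) {
    filtfilt_ba(bw$b, bw$a, x)[keep]
  })
  session$fs <- new_fs
  session
}

#' Standard conditioning chain
#'
#' Applies, in order: harmonic notch filtering, high-pass filtering,
#' adjacent-contact bipolar montage, and anti-aliased decimation.
#'
#' @param session a [recording_session()].
#' @param notch_freq mains fundamental (Hz); `NULL` skips notching.
#' @param n_harmonics harmonics above the fundamental to notch.
#' @param highpass_cutoff high-pass cutoff (Hz); `NULL` skips.
#' @param decimate_factor integer decimation factor; 1 skips.
#' @param q notch quality factor.
#' @param min_band highest analysis frequency that must survive
#'   decimation (Hz).
#'
#' @return A [bipolar_session()] ready for transfer-function estimation.
#' @export
preprocess_session <- function(session, notch_freq = 60, n_harmonics = 5,
                               highpass_cutoff = 1, decimate_factor = 8,
                               q = 30, min_band = 500) {
  if (!is.null(notch_freq))
    session <- notch_filter(session, notch_freq, n_harmonics, q)
  if (!is.null(highpass_cutoff))
    session <- highpass_filter(session, highpass_cutoff)
  bip <- bipolar_montage(session)
  decimate_session(bip, decimate_factor, min_band = min_band)
}

# Zero-phase forward-backward IIR filtering with edge padding (odd
# reflection, 3 x filter order), so short transients do not leak into the
# record ends.
filtfilt_ba <- function(b, a, x) {
  n <- length(x)
  npad <- min(max(3L * (max(length(a), length(b)) - 1L), 12L), n - 1L)
  pre <- 2 * x[1] - x[seq(npad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - npad)]
  xp <- c(pre, x, post)
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  as.numeric(y[seq(npad + 1L, npad + n)])
}

# Frequency response of a rational digital filter at frequencies f (Hz).
freq_response <- function(b, a, f, fs) {
  w <- 2 * pi * f / fs
  num <- vapply(w, function(wi)
    sum(b * exp(-1i * wi * (seq_along(b) - 1L))), complex(1))
  den <- vapply(w, function(wi)
    sum(a * exp(-1i * wi * (seq_along(a) - 1L))), complex(1))
  num / den
}
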