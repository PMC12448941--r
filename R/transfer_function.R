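#' Welch-averaged power and cross power spectral densities
#'
#' Splits two equal-length signals into Hann-windowed segments with the
#' given overlap, removes each segment's mean, and averages periodograms
#' to estimate the input power spectral density and the input-output cross
#' power spectral density on a shared one-sided frequency grid with
#' resolution `fs / window_len`.
#'
#' @param x input signal (numeric vector).
#' @param y output signal, same length as `x`.
#' @param fs sampling rate in Hz.
#' @param window_len segment length in samples.
#' @param overlap fractional overlap between consecutive segments.
#'
#' @return A list with `freqs` (Hz), `psd_x` (real, non-negative),
#'   `cpsd_xy` (complex), `psd_y`, and `n_segments`.
#' @export
estimate_spectra <- function(x, y, fs, window_len = 4 * fs, overlap = 0.5) {
  if (length(x) != length(y))
    stop("`x` and `y` must have the same length", call. = FALSE)
  window_len <- as.integer(window_len)
  if (length(x) < 2L * window_len)
    stop("record too short for spectral averaging: need at least two ",
         "windows (", 2L * window_len, " samples), got ", length(x),
         call. = FALSE)
  step <- max(1L, as.integer(round(window_len * (1 - overlap))))
  starts <- seq(1L, length(x) - window_len + 1L, by = step)
  # periodic Hann window, density scaling
  n <- window_len
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / n))
  scale <- 1 / (fs * sum(w^2))
  nf <- n %/% 2L + 1L
  pxx <- numeric(nf); pyy <- numeric(nf); pxy <- complex(nf)
  for (s in starts) {
    xs <- x[s:(s + n - 1L)]; ys <- y[s:(s + n - 1L)]
    xs <- (xs - mean(xs)) * w
    ys <- (ys - mean(ys)) * w
    fx <- stats::fft(xs)[seq_len(nf)]
    fy <- stats::fft(ys)[seq_len(nf)]
    pxx <- pxx + Re(fx * Conj(fx))
    pyy <- pyy + Re(fy * Conj(fy))
    pxy <- pxy + Conj(fx) * fy
  }
  k <- length(starts)
  one_sided <- c(1, rep(2, nf - 2L), if (n %% 2L == 0L) 1 else 2)
  list(freqs = (seq_len(nf) - 1L) * fs / n,
       psd_x = pxx / k * scale * one_sided,
       psd_y = pyy / k * scale * one_sided,
       cpsd_xy = pxy / k * scale * one_sided,
       n_segments = k)
}

#' Regularized empirical transfer function between two signals
#'
#' Estimates the single-input single-output frequency response from `x`
#' to `y` as
#' \deqn{H(\omega) = \mathrm{CPSD}(x, y) / (\mathrm{PSD}(x) + \epsilon)}
#' using Welch-averaged spectra. The regularization constant \eqn{\epsilon}
#' keeps the magnitude finite where the input power is negligible; the
#' default is 1e-6 times the median input PSD. Only the magnitude is used
#' by the downstream feature stage; the complex response is retained.
#'
#' @inheritParams estimate_spectra
#' @param epsilon regularization constant in PSD units, or `"auto"`.
#' @param input_channel,output_channel optional channel labels carried
#'   through for audit.
#'
#' @return An object of class `transfer_function_estimate`.
#' @export
estimate_transfer_function <- function(x, y, fs, epsilon = "auto",
                                       window_len = 4 * fs, overlap = 0.5,
                                       input_channel = NA,
                                       output_channel = NA) {
  sp <- estimate_spectra(x, y, fs, window_len, overlap)
  if (identical(epsilon, "auto"))
    epsilon <- 1e-6 * stats::median(sp$psd_x)
  if (!is.numeric(epsilon) || epsilon < 0)
    stop("`epsilon` must be a non-negative PSD value or \"auto\"",
         call. = FALSE)
  if (epsilon == 0 && any(sp$psd_x == 0))
    stop("zero-power input with epsilon = 0: transfer function undefined",
         call. = FALSE)
  transfer_function_estimate(
    freqs = sp$freqs, H = sp$cpsd_xy / (sp$psd_x + epsilon),
    psd_x = sp$psd_x, cpsd_xy = sp$cpsd_xy, epsilon = epsilon,
    n_segments = sp$n_segments,
    input_channel = input_channel, output_channel = output_channel)
}

#' Construct a transfer-function estimate
#'
#' Low-level constructor; used by [estimate_transfer_function()] and
#' directly when a response is known analytically (e.g. for validating
#' the feature-extraction stage against closed-form filter responses).
#'
#' @param freqs strictly increasing frequency grid (Hz), starting >= 0.
#' @param H complex (or real magnitude) response on the grid.
#' @param psd_x,cpsd_xy optional spectra the estimate was built from.
#' @param epsilon regularization constant used.
#' @param n_segments number of Welch segments averaged.
#' @param input_channel,output_channel channel labels.
#'
#' @return An object of class `transfer_function_estimate`.
#' @export
transfer_function_estimate <- function(freqs, H, psd_x = NULL,
                                       cpsd_xy = NULL, epsilon = 0,
                                       n_segments = NA_integer_,
                                       input_channel = NA,
                                       output_channel = NA) {
  if (length(freqs) != length(H))
    stop("`freqs` and `H` must have the same length", call. = FALSE)
  if (is.unsorted(freqs, strictly = TRUE) || freqs[1] < 0)
    stop("`freqs` must be strictly increasing and start at >= 0",
         call. = FALSE)
  if (any(!is.finite(abs(H))))
    stop("|H| must be finite everywhere", call. = FALSE)
  structure(list(freqs = as.numeric(freqs), H = as.complex(H),
                 psd_x = psd_x, cpsd_xy = cpsd_xy, epsilon = epsilon,
                 n_segments = n_segments, input_channel = input_channel,
                 output_channel = output_channel),
            class = "transfer_function_estimate")
}

#' @export
print.transfer_function_estimate <- function(x, ...) {
  cat("<transfer_function_estimate> ", length(x$freqs),
      " frequencies in [", x$freqs[1], ", ", max(x$freqs), "] Hz",
      if (!is.na(x$n_segments)) paste0(", ", x$n_segments, " Welch segments"),
      "\n  epsilon = ", format(x$epsilon, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Transmission features of a transfer-function magnitude
#'
#' Extracts the features used to summarize intrinsic signal transmission:
#' the maximum gain \eqn{|H(\omega_p)|} (peak gain, also reported in dB),
#' the DC gain (magnitude at the lowest grid frequency), the roll-off
#' frequency \eqn{\omega_f} — the first frequency at which the magnitude
#' falls 3 dB below the DC gain (half power), located by linear
#' interpolation of the log-magnitude between the straddling grid bins —
#' and the peak-to-floor ratio
#' \deqn{\mathrm{PF} = \log_{10}\left(|H(\omega_p)| / |H(\omega_f)|\right).}
#' If the magnitude never crosses the -3 dB level within the grid, the
#' roll-off frequency and PF ratio are flagged undefined (`NA`) rather
#' than raising an error.
#'
#' @param tfe a [transfer_function_estimate()].
#' @param min_freq lowest frequency (Hz) considered in the peak search;
#'   defaults to the grid start.
#'
#' @return An object of class `tf_features`: a list with `peak_gain`
#'   (linear), `peak_gain_db`, `omega_p`, `dc_gain`, `omega_f`,
#'   `floor_gain`, `pf_ratio` and `rolloff_defined`.
#' @export
extract_features <- function(tfe, min_freq = NULL) {
  stopifnot(inherits(tfe, "transfer_function_estimate"))
  mag <- Mod(tfe$H)
  if (all(mag == 0))
    stop("degenerate response: |H| is zero everywhere", call. = FALSE)
  f <- tfe$freqs
  if (is.null(min_freq)) min_freq <- f[1]
  if (min_freq < f[1])
    stop("`min_freq` is below the frequency grid", call. = FALSE)
  dc_gain <- mag[1]
  search <- which(f >= min_freq)
  ip <- search[which.max(mag[search])]
  peak <- mag[ip]
  threshold <- dc_gain * 10^(-3 / 20)
  omega_f <- NA_real_; floor_gain <- NA_real_; pf_ratio <- NA_real_
  defined <- FALSE
  if (length(f) >= 2L) {
    below <- mag[-1L] < threshold & mag[-length(mag)] >= threshold
    cross <- which(below)
    if (length(cross) > 0L) {
      i <- cross[1L] # first downward crossing; ties go to lower frequency
      l1 <- log(mag[i]); l2 <- log(mag[i + 1L]); lt <- log(threshold)
      frac <- if (l1 == l2) 0 else (l1 - lt) / (l1 - l2)
      omega_f <- f[i] + frac * (f[i + 1L] - f[i])
      floor_gain <- threshold
      pf_ratio <- log10(peak / floor_gain)
      defined <- TRUE
    }
  }
  structure(list(peak_gain = peak, peak_gain_db = 20 * log10(peak),
                 omega_p = f[ip], dc_gain = dc_gain, omega_f = omega_f,
                 floor_gain = floor_gain, pf_ratio = pf_ratio,
                 rolloff_defined = defined),
            class = "tf_features")
}

#' @export
print.tf_features <- function(x, ...) {
  cat("<tf_features> peak ", format(x$peak_gain_db, digits = 4), " dB @ ",
      format(x$omega_p, digits = 4), " Hz; DC gain ",
      format(x$dc_gain, digits = 4), "; roll-off ",
      if (x$rolloff_defined) paste0(format(x$omega_f, digits = 4), " Hz")
      else "undefined",
      "; PF ratio ", format(x$pf_ratio, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.tf_features <- function(x, ...) {
  data.frame(peak_gain = x$peak_gain, peak_gain_db = x$peak_gain_db,
             omega_p = x$omega_p, dc_gain = x$dc_gain, omega_f = x$omega_f,
             floor_gain = x$floor_gain, pf_ratio = x$pf_ratio,
             rolloff_defined = x$rolloff_defined)
}

#' Per-pathway transmission features between two regions
#'
#' Computes the empirical transfer function and its features for every
#' ordered (input region -> output region) pair of bipolar channels in
#' the same hemisphere, then aggregates to one record per hemisphere with
#' the chosen reducer (undefined roll-offs excluded from the aggregate of
#' `omega_f` and `pf_ratio`). Per-pair records are retained for audit.
#'
#' @param session a [bipolar_session()].
#' @param region_a input region label.
#' @param region_b output region label.
#' @param epsilon,window_len,overlap passed to
#'   [estimate_transfer_function()]; `window_len = NULL` uses 4 s windows
#'   (`4 * fs` samples, 0.25 Hz resolution).
#' @param min_freq lowest frequency in the peak search (Hz).
#' @param reducer aggregation across SISO pairs: "mean", "median" or "max".
#'
#' @return A list with `aggregate` (one row per hemisphere) and `pairs`
#'   (one row per ordered channel pair).
#' @export
pathway_features <- function(session, region_a, region_b,
                             epsilon = "auto", window_len = NULL,
                             overlap = 0.5, min_freq = NULL,
                             reducer = c("mean", "median", "max")) {
  stopifnot(inherits(session, "bipolar_session"))
  reducer <- match.arg(reducer)
  red <- switch(reducer, mean = function(v) mean(v, na.rm = TRUE),
                median = function(v) stats::median(v, na.rm = TRUE),
                max = function(v) max(v, na.rm = TRUE))
  if (is.null(window_len)) window_len <- round(4 * session$fs)
  p <- session$pairs
  ia <- which(p$region == region_a)
  ib <- which(p$region == region_b)
  if (length(ia) == 0L || length(ib) == 0L)
    stop("no bipolar channels in region ",
         if (length(ia) == 0L) region_a else region_b, call. = FALSE)
  rows <- list(); k <- 0L
  for (i in ia) for (j in ib) {
    if (p$hemisphere[i] != p$hemisphere[j]) next
    tfe <- estimate_transfer_function(
      session$samples[i, ], session$samples[j, ], session$fs,
      epsilon = epsilon, window_len = window_len, overlap = overlap,
      input_channel = paste0(p$lead[i], ":", p$contact_a[i], "-", p$contact_b[i]),
      output_channel = paste0(p$lead[j], ":", p$contact_a[j], "-", p$contact_b[j]))
    ft <- extract_features(tfe, min_freq = min_freq)
    k <- k + 1L
    rows[[k]] <- cbind(
      data.frame(subject = p$subject[i], hemisphere = p$hemisphere[i],
                 pathway = paste0(region_a, "->", region_b),
                 input = tfe$input_channel, output = tfe$output_channel,
                 stringsAsFactors = FALSE),
      as.data.frame(ft))
  }
  if (k == 0L)
    stop("no same-hemisphere channel pairs between ", region_a, " and ",
         region_b, call. = FALSE)
  pairs_df <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(pairs_df, pairs_df$hemisphere),
    function(d) data.frame(
      subject = d$subject[1], hemisphere = d$hemisphere[1],
      pathway = d$pathway[1],
      peak_gain = red(d$peak_gain), peak_gain_db = red(d$peak_gain_db),
      omega_p = red(d$omega_p), dc_gain = red(d$dc_gain),
      omega_f = red(d$omega_f), pf_ratio = red(d$pf_ratio),
      n_pairs = nrow(d), stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  list(aggregate = agg, pairs = pairs_df)
}
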