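#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data module. The defaults emulate
#' the study conditions the pipeline is designed for: 12 subjects with
#' roughly 73 pathway observations each (~880 rows), depth recordings
#' sampled at 24 kHz with mains contamination at 60 Hz and harmonics,
#' 1/f ("pink") source activity, and a subject-clustered linear coupling
#' between tract microstructure and transmission outcomes.
#'
#' @param n_subjects number of subjects in coupled datasets.
#' @param pathways_per_subject pathway observations per subject.
#' @param fs sampling rate (Hz).
#' @param duration record duration (s); `fs * duration` must be >= 2^14
#'   so spectral estimation is meaningful.
#' @param true_beta generating fixed effects for the PF-ratio outcome,
#'   `c(intercept, FA, N, L)` on the feature scale.
#' @param true_beta_gain generating fixed effects for the maximum-gain
#'   outcome, same layout.
#' @param random_intercept_sd SD of the per-subject random intercept
#'   (outcome units).
#' @param residual_sd residual SD (outcome units).
#' @param sensor_noise_sd independent per-contact sensor noise SD (uV).
#' @param common_mode_sd SD of the shared per-lead common-mode component
#'   (uV).
#' @param line_amp amplitude of the 60 Hz contaminant (uV); harmonics at
#'   120-360 Hz are added with amplitude `line_amp / harmonic_number`.
#' @param signal_sd SD of the underlying neural source signals (uV).
#' @param source source-spectrum shape, "pink" (1/f, LFP-like) or "white".
#' @param tf_gains,tf_centers peak magnitudes and center frequencies (Hz)
#'   of the band-pass transmission filters linking the two leads, recycled
#'   across bipolar channels.
#' @param contacts_per_lead micro-contacts per lead (>= 2).
#' @param regions region labels of the two simulated leads.
#' @param fa_range range `[low, high)` of generated FA values, within
#'   \[0, 1).
#' @param lambda1 reference axial diffusivity scale (mm^2/s x 1e-3
#'   convention-free) for [simulate_tract_set()].
#' @param md reference mean diffusivity for coupled datasets; axial
#'   diffusivity is derived from FA at this (jittered) mean diffusivity,
#'   which makes FA and Ad mechanically collinear, as in real tracts.
#' @param seed default integer seed.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 12L, pathways_per_subject = 73L,
                       fs = 24000, duration = 60,
                       true_beta = c(34.63, 6.12, 1.44, -0.01),
                       true_beta_gain = c(26.31, 6.77, 1.19, 0.0),
                       random_intercept_sd = 2, residual_sd = 4,
                       sensor_noise_sd = 2, common_mode_sd = 10,
                       line_amp = 15, signal_sd = 20,
                       source = c("pink", "white"),
                       tf_gains = c(2, 3, 1.5), tf_centers = c(12, 20, 30),
                       contacts_per_lead = 4L,
                       regions = c("GPi", "VoaVop"),
                       fa_range = c(0.2, 0.6), lambda1 = 1.35, md = 0.7,
                       seed = 1L) {
  source <- match.arg(source)
  cfg <- list(n_subjects = as.integer(n_subjects),
              pathways_per_subject = as.integer(pathways_per_subject),
              fs = fs, duration = duration, true_beta = true_beta,
              true_beta_gain = true_beta_gain,
              random_intercept_sd = random_intercept_sd,
              residual_sd = residual_sd,
              sensor_noise_sd = sensor_noise_sd,
              common_mode_sd = common_mode_sd, line_amp = line_amp,
              signal_sd = signal_sd, source = source,
              tf_gains = tf_gains, tf_centers = tf_centers,
              contacts_per_lead = as.integer(contacts_per_lead),
              regions = regions, fa_range = fa_range, lambda1 = lambda1,
              md = md, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$fs) || cfg$fs <= 0 ||
      !is.numeric(cfg$duration) || cfg$duration <= 0)
    stop("`fs` and `duration` must be positive", call. = FALSE)
  if (cfg$fs * cfg$duration < 2^14)
    stop("fs * duration must be >= 2^14 samples for spectral estimation",
         call. = FALSE)
  if (cfg$fs <= 2 * max(360, cfg$tf_centers))
    stop("fs must exceed twice the highest simulated frequency",
         call. = FALSE)
  sds <- c(cfg$random_intercept_sd, cfg$residual_sd, cfg$sensor_noise_sd,
           cfg$common_mode_sd, cfg$line_amp, cfg$signal_sd)
  if (any(sds < 0)) stop("all SDs/amplitudes must be >= 0", call. = FALSE)
  if (length(cfg$fa_range) != 2L || cfg$fa_range[1] < 0 ||
      cfg$fa_range[2] >= 1 || cfg$fa_range[1] > cfg$fa_range[2])
    stop("`fa_range` must lie within [0, 1)", call. = FALSE)
  if (length(cfg$true_beta) != 4L || length(cfg$true_beta_gain) != 4L)
    stop("`true_beta` vectors must be (intercept, FA, N, L)", call. = FALSE)
  if (cfg$contacts_per_lead < 2L)
    stop("`contacts_per_lead` must be >= 2", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_subjects, " subjects x ",
      x$pathways_per_subject, " pathways; fs = ", x$fs, " Hz, ",
      x$duration, " s; source = ", x$source, "; seed = ", x$seed,
      "\n", sep = "")
  invisible(x)
}

# Evaluate expr with a locally-set RNG seed, restoring the global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# 1/f-amplitude ("pink") Gaussian noise via FFT shaping, unit SD.
pink_noise <- function(n) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  k <- seq_len(n) - 1L
  idx <- pmin(k, n - k)            # symmetric frequency index
  s <- 1 / sqrt(pmax(idx, 1))
  s[1] <- 0                        # no DC
  y <- Re(stats::fft(X * s, inverse = TRUE) / n)
  y / stats::sd(y)
}

source_noise <- function(n, kind) {
  if (kind == "pink") pink_noise(n) else stats::rnorm(n)
}

# Resonant band-pass with peak magnitude `gain` at `center` Hz: first-
# order Butterworth band-pass with quality factor 5 (bandwidth center/5),
# rescaled so the dense-grid maximum of |H| equals `gain` exactly. The
# narrow band gives the response a well-defined peak frequency, so the
# downstream peak search is meaningful at Welch-bin resolution.
design_transmission_filter <- function(gain, center, fs, q = 5) {
  nyq <- fs / 2
  bwid <- center / q
  lo <- center - bwid / 2; hi <- center + bwid / 2
  bw <- signal::butter(1, c(lo, hi) / nyq, type = "pass")
  grid <- seq(max(0.1, lo / 4), min(nyq * 0.99, hi * 4), length.out = 4096)
  mag <- Mod(freq_response(bw$b, bw$a, grid, fs))
  b <- bw$b * gain / max(mag)
  mag2 <- Mod(freq_response(b, bw$a, grid, fs))
  list(b = b, a = bw$a, gain = gain, center = center,
       true_peak_gain = max(mag2), true_peak_freq = grid[which.max(mag2)])
}

# identity transmission (y = x)
identity_filter <- function() {
  list(b = 1, a = 1, gain = 1, center = NA_real_,
       true_peak_gain = 1, true_peak_freq = NA_real_)
}

#' Simulate an LFP recording session with known transmission
#'
#' Builds a two-lead depth-recording session in which the adjacent-contact
#' bipolar derivations of the second lead are known linear-time-invariant
#' (band-pass) transformations of those of the first lead. Contact-level
#' signals are constructed by telescoping the desired bipolar sources
#' along each shaft, then contaminated with a shared per-lead common-mode
#' component, independent per-contact sensor noise, and a 60 Hz line
#' component plus harmonics (120-360 Hz) with per-contact amplitude
#' jitter. Everything is reproducible from the seed; the generating
#' filters are returned as ground truth.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @param transmission "bandpass" (default, filters from
#'   `config$tf_gains` / `config$tf_centers`) or "identity" (output
#'   bipolar sources equal the input ones).
#'
#' @return A list with `session` (a [recording_session()]) and
#'   `ground_truth` (generating filters with their analytic peak gain and
#'   peak frequency, plus the config echo).
#' @export
simulate_lfp_session <- function(config, seed = config$seed,
                                 transmission = c("bandpass", "identity")) {
  stopifnot(inherits(config, "sim_config"))
  transmission <- match.arg(transmission)
  with_seed(seed, {
    n <- round(config$fs * config$duration)
    nc <- config$contacts_per_lead
    nb <- nc - 1L
    filters <- lapply(seq_len(nb), function(k) {
      if (transmission == "identity") return(identity_filter())
      design_transmission_filter(
        config$tf_gains[(k - 1L) %% length(config$tf_gains) + 1L],
        config$tf_centers[(k - 1L) %% length(config$tf_centers) + 1L],
        config$fs)
    })
    # bipolar-level sources for lead A and their filtered images on lead B
    src <- lapply(seq_len(nb), function(k)
      config$signal_sd * source_noise(n, config$source))
    out <- lapply(seq_len(nb), function(k) {
      f <- filters[[k]]
      if (length(f$b) == 1L && length(f$a) == 1L) f$b * src[[k]]
      else as.numeric(signal::filter(f$b, f$a, src[[k]]))
    })
    lead_signals <- function(bip) {
      # telescope: contact_k = contact_{k+1} + bipolar_k; deepest contact
      # carries independent baseline activity that cancels in the montage
      base <- config$signal_sd * source_noise(n, config$source)
      sig <- matrix(0, nrow = nb + 1L, ncol = n)
      sig[nb + 1L, ] <- base
      for (k in rev(seq_len(nb))) sig[k, ] <- sig[k + 1L, ] + bip[[k]]
      sig
    }
    a_sig <- lead_signals(src)
    b_sig <- lead_signals(out)
    t_sec <- (seq_len(n) - 1L) / config$fs
    contaminate <- function(sig) {
      if (config$common_mode_sd > 0) {
        cm <- config$common_mode_sd * source_noise(n, config$source)
        sig <- sweep(sig, 2L, cm, "+")
      }
      for (i in seq_len(nrow(sig))) {
        if (config$sensor_noise_sd > 0)
          sig[i, ] <- sig[i, ] + config$sensor_noise_sd * stats::rnorm(n)
        if (config$line_amp > 0) {
          for (h in 1:6) {
            amp <- config$line_amp / h * stats::runif(1, 0.8, 1.2)
            ph <- stats::runif(1, 0, 2 * pi)
            sig[i, ] <- sig[i, ] + amp * sin(2 * pi * 60 * h * t_sec + ph)
          }
        }
      }
      sig
    }
    a_sig <- contaminate(a_sig)
    b_sig <- contaminate(b_sig)
    channels <- data.frame(
      subject = "sim01",
      hemisphere = "L",
      lead = rep(c("A", "B"), each = nc),
      region = rep(config$regions[1:2], each = nc),
      contact = rep(seq_len(nc), 2L),
      stringsAsFactors = FALSE)
    session <- recording_session(rbind(a_sig, b_sig), config$fs, channels)
    list(session = session,
         ground_truth = list(filters = filters,
                             transmission = transmission,
                             seed = seed, config = config))
  })
}

# Given lambda1 = a and target FA with prolate symmetry (lambda2 =
# lambda3 = x), solve FA^2 (a^2 + 2 x^2) = (a - x)^2 for x in (0, a].
prolate_minor_eigenvalue <- function(lambda1, fa) {
  f2 <- fa^2
  if (abs(1 - 2 * f2) < 1e-12) return(lambda1 / 4)
  lambda1 * (1 - sqrt(1 - (1 - 2 * f2) * (1 - f2))) / (1 - 2 * f2)
}

# Given target FA and mean diffusivity, return the prolate triple
# (a, x, x): r = lambda1/lambda23 from FA, then scaled to the MD.
prolate_triple_from_md <- function(fa, md) {
  f2 <- fa^2
  r <- (1 + sqrt(1 - (1 - f2) * (1 - 2 * f2))) / (1 - f2)
  x <- 3 * md / (r + 2)
  c(r * x, x, x)
}

#' Simulate a tract set with controlled anisotropy
#'
#' Generates prolate diffusion-tensor triples (lambda2 = lambda3) whose
#' fractional anisotropy equals `target_fa` to better than 1e-9, solved
#' in closed form from `lambda1`, plus random-walk streamline polylines
#' whose arc lengths are drawn uniformly within the tracking length
#' window (10-200 mm by default). Per-streamline triples are scaled by a
#' small lognormal jitter, which perturbs axial diffusivity while leaving
#' FA exactly at the target (FA is scale-invariant).
#'
#' @param config a [sim_config()] (supplies `lambda1` and the seed
#'   default).
#' @param target_fa target fractional anisotropy in \[0, 1).
#' @param n_streamlines number of streamlines; 0 gives an empty
#'   "no connection" tract set.
#' @param seed integer seed.
#' @param length_range streamline arc-length window (mm).
#' @param scale_jitter_sd SD of the lognormal eigenvalue scale jitter.
#' @param region_pair labels for origin/target regions.
#'
#' @return A [tract_set()].
#' @export
simulate_tract_set <- function(config, target_fa, n_streamlines,
                               seed = config$seed,
                               length_range = c(10, 200),
                               scale_jitter_sd = 0.05,
                               region_pair = config$regions) {
  stopifnot(inherits(config, "sim_config"))
  if (target_fa < 0 || target_fa >= 1)
    stop("`target_fa` must lie in [0, 1): FA = 1 requires degenerate ",
         "zero eigenvalues", call. = FALSE)
  with_seed(seed, {
    if (n_streamlines == 0L)
      return(tract_set(list(), matrix(numeric(0), ncol = 3L),
                       region_pair = region_pair))
    x <- prolate_minor_eigenvalue(config$lambda1, target_fa)
    ev <- t(vapply(seq_len(n_streamlines), function(i) {
      s <- stats::rlnorm(1, 0, scale_jitter_sd)
      s * c(config$lambda1, x, x)
    }, numeric(3)))
    streamlines <- lapply(seq_len(n_streamlines), function(i) {
      len <- stats::runif(1, length_range[1], length_range[2])
      npts <- 50L
      step <- len / (npts - 1L)
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      pts <- matrix(0, npts, 3L)
      pts[1, ] <- stats::rnorm(3, sd = 5)
      for (p in 2:npts) {
        dir <- dir + 0.2 * stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        pts[p, ] <- pts[p - 1L, ] + step * dir
      }
      pts
    })
    tract_set(streamlines, ev, region_pair = region_pair)
  })
}

#' Simulate a subject-clustered coupled dataset
#'
#' Generates the joined analysis table the mixed-effects stage consumes:
#' per-pathway structural measures (FA drawn uniformly within
#' `fa_range`; axial diffusivity derived from FA at a jittered mean
#' diffusivity, which makes the two mechanically collinear; fibre count
#' per area from a Poisson count over the contact disc; fibre length
#' uniform over a pallidothalamic-scale window) and two transmission
#' outcomes generated from the linear mixed model
#' \deqn{y = \beta_0 + \beta_{FA} FA + \beta_N N + \beta_L L + b_i +
#'   \epsilon,}
#' with per-subject random intercepts \eqn{b_i \sim N(0,
#' \sigma_b^2)} and residuals \eqn{\epsilon \sim N(0, \sigma^2)}. The
#' PF-ratio and maximum-gain outcomes use `config$true_beta` and
#' `config$true_beta_gain` with independent random effects.
#'
#' @param config a [sim_config()] with `n_subjects >= 2` and
#'   `pathways_per_subject >= 2`.
#' @param seed integer seed.
#'
#' @return A list with `observations` (data.frame: subject, hemisphere,
#'   pathway, fa, ad, n_per_area, length, omega_p, pf_ratio, peak_gain)
#'   and `ground_truth` (true betas, per-subject intercepts, seed).
#' @export
simulate_coupled_dataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_subjects < 2L || config$pathways_per_subject < 2L)
    stop("need >= 2 subjects and >= 2 pathways per subject", call. = FALSE)
  with_seed(seed, {
    ns <- config$n_subjects; np <- config$pathways_per_subject
    n <- ns * np
    subject <- rep(sprintf("S%02d", seq_len(ns)), each = np)
    b_pf <- stats::rnorm(ns, 0, config$random_intercept_sd)
    b_gain <- stats::rnorm(ns, 0, config$random_intercept_sd)
    fa <- stats::runif(n, config$fa_range[1], config$fa_range[2])
    md <- config$md * stats::rlnorm(n, 0, 0.05)
    ad <- vapply(seq_len(n), function(i)
      prolate_triple_from_md(fa[i], md[i])[1], numeric(1))
    count <- stats::rpois(n, 45)
    n_per_area <- count / (pi * 1.5^2)
    len <- stats::runif(n, 12, 25)
    omega_p <- stats::runif(n, 2, 40)
    xb_pf <- config$true_beta[1] + config$true_beta[2] * fa +
      config$true_beta[3] * n_per_area + config$true_beta[4] * len
    xb_gain <- config$true_beta_gain[1] + config$true_beta_gain[2] * fa +
      config$true_beta_gain[3] * n_per_area + config$true_beta_gain[4] * len
    sidx <- rep(seq_len(ns), each = np)
    pf_ratio <- xb_pf + b_pf[sidx] +
      stats::rnorm(n, 0, config$residual_sd)
    peak_gain <- xb_gain + b_gain[sidx] +
      stats::rnorm(n, 0, config$residual_sd)
    obs <- data.frame(
      subject = subject, hemisphere = rep_len(c("L", "R"), n),
      pathway = paste0(config$regions[1], "->", config$regions[2]),
      fa = fa, ad = ad, n_per_area = n_per_area, length = len,
      omega_p = omega_p, pf_ratio = pf_ratio, peak_gain = peak_gain,
      stringsAsFactors = FALSE)
    list(observations = obs,
         ground_truth = list(true_beta = config$true_beta,
                             true_beta_gain = config$true_beta_gain,
                             subject_intercepts_pf = b_pf,
                             subject_intercepts_gain = b_gain,
                             seed = seed))
  })
}
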