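test_that("Welch spectra behave on self-, sinusoid- and null-coupling", {
  fs <- 500; n <- 40 * fs
  set.seed(21)
  x <- rnorm(n)
  # self-spectrum: CPSD(x, x) = PSD(x), coherence 1
  sp <- estimate_spectra(x, x, fs, window_len = fs)
  expect_true(all(sp$psd_x >= 0))
  expect_equal(Mod(sp$cpsd_xy), sp$psd_x, tolerance = 1e-10)
  # pure sinusoid peaks at the nearest grid bin
  f0 <- 37.3
  s <- sin(2 * pi * f0 * seq_len(n) / fs)
  sps <- estimate_spectra(s, s, fs, window_len = fs)
  expect_equal(sps$freqs[which.max(sps$psd_x)], round(f0))
  # independent noises: cross-coupling decays as averaging grows
  y <- rnorm(n)
  coh <- function(win) {
    spc <- estimate_spectra(x, y, fs, window_len = win)
    mean(Mod(spc$cpsd_xy)^2 / (spc$psd_x * spc$psd_y))
  }
  expect_gt(coh(4 * fs) / coh(fs %/% 2), 2)
  expect_error(estimate_spectra(x[1:100], y[1:100], fs, window_len = fs),
               "too short")
})

test_that("the regularized estimator recovers static gain and delay", {
  fs <- 500; n <- 60 * fs
  set.seed(22)
  x <- rnorm(n)
  # static gain: y = 2x
  tf <- estimate_transfer_function(x, 2 * x, fs, window_len = fs)
  expect_true(all(abs(Mod(tf$H) - 2) < 0.01))
  # pure delay: |H| ~ 1, phase slope -2*pi*d/fs per Hz
  d <- 10L
  y <- c(rep(0, d), x[1:(n - d)])
  tfd <- estimate_transfer_function(x, y, fs, window_len = fs)
  band <- tfd$freqs > 1 & tfd$freqs < 100
  expect_true(mean(abs(Mod(tfd$H)[band] - 1)) < 0.02)
  # phase slope -2*pi*d/fs per Hz, read off below the first wrap
  nowrap <- tfd$freqs > 1 & tfd$freqs < 0.8 * fs / (2 * d)
  ph <- Arg(tfd$H)[nowrap]
  slope <- coef(lm(ph ~ tfd$freqs[nowrap]))[2]
  expect_equal(as.numeric(slope), -2 * pi * d / fs, tolerance = 0.05)
  # degenerate division guard
  expect_error(estimate_transfer_function(rep(0, 4 * fs), rep(0, 4 * fs),
                                          fs, epsilon = 0,
                                          window_len = fs),
               "zero-power")
})

test_that("a known band-pass system is recovered within Welch bias", {
  fs <- 500
  set.seed(23)
  n <- 61 * 2 * fs                      # >= 60 averages at 0.25 Hz res
  x <- rnorm(n)
  bw <- signal::butter(2, c(15, 25) / (fs / 2), "pass")
  y <- as.numeric(signal::filter(bw$b, bw$a, x))
  tf <- estimate_transfer_function(x, y, fs, window_len = 4 * fs)
  ana <- Mod(lfpcoupling:::freq_response(bw$b, bw$a, tf$freqs, fs))
  pass <- ana > 0.5 * max(ana)
  expect_lt(max(abs(Mod(tf$H)[pass] - ana[pass]) / ana[pass]), 0.05)
  bin <- tf$freqs[2] - tf$freqs[1]
  expect_lt(abs(tf$freqs[which.max(Mod(tf$H))] -
                tf$freqs[which.max(ana)]), bin + 1e-9)
})

test_that("estimation error shrinks with more Welch segments", {
  fs <- 250
  set.seed(24)
  bw <- signal::butter(2, c(10, 30) / (fs / 2), "pass")
  err <- vapply(c(8, 64), function(k) {
    n <- (k + 1) * fs
    x <- rnorm(n)
    y <- as.numeric(signal::filter(bw$b, bw$a, x))
    tf <- estimate_transfer_function(x, y, fs, window_len = 2 * fs)
    ana <- Mod(lfpcoupling:::freq_response(bw$b, bw$a, tf$freqs, fs))
    pass <- ana > 0.5 * max(ana)
    mean(abs(Mod(tf$H)[pass] - ana[pass]))
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("feature extraction matches hand-evaluated magnitude shapes", {
  # monotone decay, peak at DC: PF ratio is 3/20 by construction
  f <- seq(0, 100, by = 0.5)
  tfe <- transfer_function_estimate(f, exp(-f / 20))
  ft <- extract_features(tfe)
  expect_equal(ft$omega_p, 0)
  expect_equal(ft$pf_ratio, 3 / 20, tolerance = 1e-12)
  # piecewise shape: DC gain 4, peak 10 -> floor 4*10^(-3/20) ~ 2.832
  f2 <- seq(0, 50, by = 0.1)
  mag <- ifelse(f2 <= 10, 4,
         ifelse(f2 <= 20, 4 + 6 * (f2 - 10) / 10,
                10 * exp(-(f2 - 20) / 5)))
  ft2 <- extract_features(transfer_function_estimate(f2, mag))
  expect_equal(ft2$dc_gain, 4)
  expect_equal(ft2$peak_gain, 10)
  expect_equal(ft2$floor_gain, 4 * 10^(-3 / 20), tolerance = 1e-12)
  expect_equal(ft2$pf_ratio, log10(10 / (4 * 10^(-3 / 20))),
               tolerance = 1e-12)
  # flat response: no -3 dB crossing -> undefined flag, no error
  ft3 <- extract_features(transfer_function_estimate(f2, rep(1, length(f2))))
  expect_false(ft3$rolloff_defined)
  expect_true(is.na(ft3$omega_f) && is.na(ft3$pf_ratio))
  expect_error(extract_features(
    transfer_function_estimate(f2, rep(0, length(f2)))), "degenerate")
})

test_that("scale covariance and regularization monotonicity hold", {
  fs <- 250; n <- 30 * fs
  set.seed(25)
  x <- rnorm(n)
  bw <- signal::butter(2, c(10, 30) / (fs / 2), "pass")
  y <- as.numeric(signal::filter(bw$b, bw$a, x))
  tf1 <- estimate_transfer_function(x, y, fs, window_len = 2 * fs)
  tf3 <- estimate_transfer_function(x, 3 * y, fs, window_len = 2 * fs)
  expect_equal(Mod(tf3$H), 3 * Mod(tf1$H), tolerance = 1e-10)
  f1 <- extract_features(tf1); f3 <- extract_features(tf3)
  expect_equal(f3$peak_gain_db - f1$peak_gain_db, 20 * log10(3),
               tolerance = 1e-8)
  # broadband gain leaves the PF ratio unchanged
  expect_equal(f3$pf_ratio, f1$pf_ratio, tolerance = 1e-8)
  # |H| is pointwise non-increasing in epsilon
  eps0 <- 1e-6 * median(tf1$psd_x)
  tf_more <- estimate_transfer_function(x, y, fs, epsilon = 1000 * eps0,
                                        window_len = 2 * fs)
  expect_true(all(Mod(tf_more$H) <= Mod(tf1$H) + 1e-12))
})

test_that("pathway aggregation reduces SISO pairs as configured", {
  cfg <- small_cfg(sensor_noise_sd = 0.5, common_mode_sd = 2,
                   line_amp = 0, tf_gains = 4, tf_centers = 15,
                   duration = 30)
  sim <- simulate_lfp_session(cfg, seed = 12)
  bip <- bipolar_montage(sim$session)
  pf <- pathway_features(bip, cfg$regions[1], cfg$regions[2],
                         window_len = 4 * bip$fs)
  nb <- cfg$contacts_per_lead - 1L
  expect_equal(nrow(pf$pairs), nb * nb)
  expect_equal(pf$aggregate$n_pairs, nb * nb)
  expect_equal(pf$aggregate$pf_ratio,
               mean(pf$pairs$pf_ratio, na.rm = TRUE))
  # all generating filters share a 15 Hz peak: the aggregated peak
  # frequency lands within one bin of it for the matched pairs
  matched <- pf$pairs[substr(pf$pairs$input, 3, 5) ==
                      substr(pf$pairs$output, 3, 5), ]
  bin <- 1 / 4
  gt <- sim$ground_truth$filters[[1]]
  expect_true(all(abs(matched$omega_p - gt$true_peak_freq) <= 3 * bin))
  # unknown region errors
  expect_error(pathway_features(bip, "nope", cfg$regions[2]),
               "no bipolar channels")
})
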