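make_obs <- function(n = 20, subject = "S01", peak_gain = NULL,
                     pf_ratio = NULL, omega_p = NULL) {
  data.frame(subject = rep_len(subject, n),
             peak_gain = if (is.null(peak_gain)) rnorm(n, 25, 2)
                         else peak_gain,
             pf_ratio = if (is.null(pf_ratio)) rnorm(n, 0.5, 0.1)
                        else pf_ratio,
             omega_p = if (is.null(omega_p)) runif(n, 5, 40) else omega_p,
             stringsAsFactors = FALSE)
}

test_that("observation filtering removes exactly the planted rows", {
  set.seed(51)
  # all-identical rows: SD = 0, nothing removed
  same <- make_obs(10, peak_gain = rep(25, 10), pf_ratio = rep(0.5, 10))
  out <- filter_observations(same)
  expect_equal(nrow(out$rows), 10L)
  expect_equal(nrow(out$audit), 0L)
  # one row far outside: brute-force mean/SD oracle agrees it must go
  obs <- make_obs(30)
  m <- mean(obs$peak_gain); s <- sd(obs$peak_gain)
  obs$peak_gain[7] <- m + 8 * s
  m2 <- mean(obs$peak_gain); s2 <- sd(obs$peak_gain)
  expect_true(abs(obs$peak_gain[7] - m2) > 3 * s2) # oracle check
  out2 <- filter_observations(obs)
  expect_equal(out2$audit$row, 7L)
  expect_equal(out2$audit$reason, "outlier_sd")
  expect_equal(nrow(out2$rows), 29L)
  # low-frequency peak removed regardless of feature values
  obs3 <- make_obs(10)
  obs3$omega_p[4] <- 1.0
  out3 <- filter_observations(obs3)
  expect_equal(out3$audit$reason, "peak_below_min_freq")
  expect_equal(out3$audit$row, 4L)
  # single pass is idempotent on its own output
  again <- filter_observations(out2$rows)
  expect_equal(nrow(again$rows), nrow(out2$rows))
  expect_warning(filter_observations(make_obs(0)), "empty")
})

test_that("VIF matches its closed form", {
  set.seed(52)
  n <- 200
  # orthogonal design -> all VIFs exactly 1
  x1 <- as.numeric(scale(rnorm(n)))
  z <- rnorm(n)
  z <- as.numeric(scale(residuals(lm(z ~ x1))))
  expect_equal(unname(compute_vif(data.frame(a = x1, b = z))), c(1, 1),
               tolerance = 1e-10)
  # sample correlation exactly 0.9 -> VIF = 1/(1 - 0.81)
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * z
  vifs <- compute_vif(data.frame(a = x1, b = x2))
  expect_equal(unname(vifs), rep(1 / (1 - 0.81), 2), tolerance = 0.01)
  # duplicated column -> infinite VIF, not an exception
  vdup <- compute_vif(data.frame(a = x1, b = x1))
  expect_true(all(is.infinite(vdup)))
  # VIF >= 1 always
  d <- as.data.frame(matrix(rnorm(n * 4), ncol = 4))
  expect_true(all(compute_vif(d) >= 1))
  expect_error(compute_vif(data.frame(a = x1)), "two predictors")
})

test_that("collinearity screening drops Ad in favour of FA", {
  set.seed(53)
  n <- 300
  fa <- runif(n, 0.2, 0.6)
  ad <- 1.5 * fa + rnorm(n, 0, 0.02)
  oth <- rnorm(n)
  d <- data.frame(fa = fa, ad = ad, n_per_area = oth,
                  length = runif(n, 10, 30))
  scr <- drop_collinear(d)
  expect_equal(scr$dropped, "ad")
  expect_true(all(scr$vifs < 5))
  expect_true("fa" %in% names(scr$design))
  # nothing flagged -> unchanged
  d2 <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  scr2 <- drop_collinear(d2)
  expect_equal(scr2$dropped, character(0))
  expect_equal(names(scr2$design), names(d2))
  # three mutually collinear predictors: iterative recomputation oracle
  base <- rnorm(n)
  d3 <- data.frame(p = base + rnorm(n, 0, 0.05),
                   q = base + rnorm(n, 0, 0.05),
                   r = base + rnorm(n, 0, 0.05),
                   s = rnorm(n))
  scr3 <- drop_collinear(d3, policy = "max_vif")
  expect_true(all(scr3$vifs < 5))
  expect_gt(length(scr3$dropped), 0)
})

test_that("Bonferroni adjustment is capped multiplication", {
  expect_equal(bonferroni_adjust(0.01, 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, 3), 1.0)
  expect_equal(bonferroni_adjust(0.2, 1), 0.2)  # identity at m = 1
  set.seed(54)
  p <- runif(10)
  expect_equal(bonferroni_adjust(p, 4),
               vapply(p, function(pi) min(1, 4 * pi), numeric(1)))
  expect_error(bonferroni_adjust(1.2), "\\[0, 1\\]")
})

test_that("the coupling fit recovers noiseless coefficients exactly", {
  cfg <- small_cfg(random_intercept_sd = 0, residual_sd = 0)
  cd <- simulate_coupled_dataset(cfg, seed = 55)
  m <- suppressWarnings(suppressMessages(
    tf_coupling(cd$observations, outcomes = "pf_ratio")))
  est <- coef(m)[, "pf_ratio"]
  truth <- c(34.63, 6.12, 1.44, -0.01)
  expect_equal(unname(est[c("(Intercept)", "fa", "n_per_area", "length")]),
               truth, tolerance = 1e-6)
})

test_that("a boundary fit reproduces ordinary least squares", {
  cfg <- sim_config(fs = 2000, duration = 10, n_subjects = 6L,
                    pathways_per_subject = 15L,
                    random_intercept_sd = 0, residual_sd = 4)
  cd <- simulate_coupled_dataset(cfg, seed = 1)
  m <- suppressMessages(tf_coupling(cd$observations,
                                    outcomes = "pf_ratio",
                                    min_peak_freq = 0))
  f <- m$fits$pf_ratio
  expect_equal(f$random_intercept_var, 0)
  ols <- lm(pf_ratio ~ fa + n_per_area + length, data = m$data)
  expect_equal(unname(f$coefficients$estimate), unname(coef(ols)),
               tolerance = 1e-6)
})

test_that("strong subject clustering is reflected in the variance components", {
  cfg <- sim_config(fs = 2000, duration = 10, n_subjects = 10L,
                    pathways_per_subject = 40L,
                    random_intercept_sd = 6, residual_sd = 1)
  cd <- simulate_coupled_dataset(cfg, seed = 56)
  m <- tf_coupling(cd$observations, outcomes = "pf_ratio")
  f <- m$fits$pf_ratio
  icc <- f$random_intercept_var /
    (f$random_intercept_var + f$residual_var)
  icc_true <- 36 / 37
  expect_gt(icc, 0.85)
  expect_lt(abs(icc - icc_true), 0.1)
})

test_that("the fitted object supports the standard model interface", {
  cfg <- small_cfg()
  cd <- simulate_coupled_dataset(cfg, seed = 57)
  m <- tf_coupling(cd$observations)
  expect_s3_class(m, "tf_coupling")
  expect_output(print(m), "random-intercept LME")
  expect_output(print(summary(m)), "Outcome: pf_ratio")
  expect_equal(dim(coef(m)), c(4L, 2L))
  pr <- predict(m, outcome = "pf_ratio")
  expect_equal(length(pr), nrow(m$data))
  re <- residuals(m, outcome = "pf_ratio")
  expect_lt(abs(mean(re)), 1)
  sm <- simulate(m, nsim = 2, seed = 1, outcome = "pf_ratio")
  expect_equal(dim(sm), c(nrow(m$data), 2L))
  tmp <- withr::local_tempfile()
  grDevices::pdf(tmp)
  expect_silent(plot(m))
  grDevices::dev.off()
})

test_that("reports serialize deterministically and round-trip", {
  cfg <- small_cfg()
  cd <- simulate_coupled_dataset(cfg, seed = 58)
  m <- tf_coupling(cd$observations)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  report(m, d1); report(m, d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  rep <- jsonlite::read_json(file.path(d1, "report.json"))
  expect_named(rep$outcomes, c("pf_ratio", "peak_gain"))
  expect_true(rep$outcomes$pf_ratio$r2_marginal >= 0 &&
              rep$outcomes$pf_ratio$r2_marginal <= 1)
  t2 <- read_table(file.path(d1, "table2_style.tsv"))
  expect_equal(t2$n_pid, rep(cfg$n_subjects, 2))
  co <- m$fits$pf_ratio$coefficients
  expect_true(all(co$ci_low <= co$estimate & co$estimate <= co$ci_high))
})
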