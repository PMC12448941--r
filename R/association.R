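#' Per-subject outlier and peak-frequency filtering
#'
#' Applies the two observation filters used before model fitting, in a
#' single pass: (1) within each subject, rows whose outcome features
#' (`peak_gain`, `pf_ratio`) deviate from the subject mean by more than
#' `sd_mult` subject SDs are removed (means and SDs are computed once on
#' the incoming table, so the filter is idempotent on its own output);
#' (2) rows whose peak-gain frequency `omega_p` lies below
#' `min_peak_freq` are removed, because the response near the 1 Hz
#' high-pass cutoff is distorted. Every removal is recorded with its
#' reason in an audit log.
#'
#' @param rows data.frame of pathway observations with at least
#'   `subject`, `peak_gain`, `pf_ratio`, `omega_p`.
#' @param sd_mult outlier threshold in subject SD units (default 3).
#' @param min_peak_freq minimum admissible `omega_p` in Hz (default 1.5).
#' @param features outcome columns screened by the SD rule.
#'
#' @return A list with `rows` (the kept observations) and `audit`
#'   (data.frame: row id, subject, reason, feature, value).
#' @export
filter_observations <- function(rows, sd_mult = 3, min_peak_freq = 1.5,
                                features = c("peak_gain", "pf_ratio")) {
  if (nrow(rows) == 0L) {
    warning("empty observation table; nothing to filter")
    return(list(rows = rows,
                audit = data.frame(row = integer(0), subject = character(0),
                                   reason = character(0),
                                   feature = character(0),
                                   value = numeric(0))))
  }
  features <- intersect(features, names(rows))
  audit <- list(); k <- 0L
  drop <- rep(FALSE, nrow(rows))
  if ("omega_p" %in% names(rows)) {
    low <- which(rows$omega_p < min_peak_freq)
    for (i in low) {
      k <- k + 1L
      audit[[k]] <- data.frame(row = i, subject = rows$subject[i],
                               reason = "peak_below_min_freq",
                               feature = "omega_p",
                               value = rows$omega_p[i],
                               stringsAsFactors = FALSE)
    }
    drop[low] <- TRUE
  }
  for (subj in unique(rows$subject)) {
    idx <- which(rows$subject == subj)
    for (feat in features) {
      v <- rows[[feat]][idx]
      m <- mean(v, na.rm = TRUE); s <- stats::sd(v, na.rm = TRUE)
      if (!is.finite(s) || s == 0) next
      out <- idx[!is.na(v) & abs(v - m) > sd_mult * s]
      for (i in out) {
        k <- k + 1L
        audit[[k]] <- data.frame(row = i, subject = subj,
                                 reason = "outlier_sd",
                                 feature = feat, value = rows[[feat]][i],
                                 stringsAsFactors = FALSE)
      }
      drop[out] <- TRUE
    }
  }
  audit <- if (k > 0L) do.call(rbind, audit)
    else data.frame(row = integer(0), subject = character(0),
                    reason = character(0), feature = character(0),
                    value = numeric(0))
  list(rows = rows[!drop, , drop = FALSE], audit = audit)
}

#' Variance inflation factors
#'
#' VIF of each predictor: `1 / (1 - R^2_j)` where `R^2_j` comes from the
#' least-squares regression of predictor j on all the others (with
#' intercept). A perfectly collinear predictor is reported as `Inf`.
#'
#' @param design data.frame or matrix of numeric predictors (>= 2
#'   columns, more rows than columns).
#' @return Named numeric vector of VIFs (always >= 1).
#' @export
compute_vif <- function(design) {
  design <- as.data.frame(design)
  if (ncol(design) < 2L)
    stop("VIF needs at least two predictors", call. = FALSE)
  if (nrow(design) <= ncol(design))
    stop("VIF needs more rows than predictors", call. = FALSE)
  vifs <- vapply(seq_len(ncol(design)), function(j) {
    # perfect collinearity is a supported input (VIF = Inf), so the
    # "essentially perfect fit" warning is expected noise here
    r2 <- suppressWarnings({
      fit <- stats::lm(design[[j]] ~ ., data = design[, -j, drop = FALSE])
      summary(fit)$r.squared
    })
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vifs) <- names(design)
  vifs
}

#' Drop collinear predictors
#'
#' Reduces a predictor set until no VIF exceeds the threshold. Under the
#' default `"fa_over_ad"` policy, when both `fa` and `ad` are flagged the
#' axial-diffusivity column is dropped and FA retained — FA and Ad are
#' mechanically related through the tensor eigenvalues, and FA is the
#' more interpretable integrity measure. The generic `"max_vif"` policy
#' iteratively drops whichever flagged predictor has the largest VIF.
#'
#' @param design data.frame of predictors.
#' @param threshold VIF threshold (default 5).
#' @param policy `"fa_over_ad"` or `"max_vif"`.
#'
#' @return A list with `design` (reduced), `dropped` (character vector)
#'   and `vifs` (VIFs of the final set).
#' @export
drop_collinear <- function(design, threshold = 5,
                           policy = c("fa_over_ad", "max_vif")) {
  policy <- match.arg(policy)
  dropped <- character(0)
  repeat {
    vifs <- compute_vif(design)
    flagged <- names(vifs)[vifs > threshold]
    if (length(flagged) == 0L) break
    victim <- if (policy == "fa_over_ad" && "ad" %in% flagged &&
                  "fa" %in% names(design)) "ad"
      else flagged[which.max(vifs[flagged])]
    design <- design[, setdiff(names(design), victim), drop = FALSE]
    dropped <- c(dropped, victim)
    if (ncol(design) < 2L) break
  }
  final_vifs <- if (ncol(design) >= 2L) compute_vif(design)
    else stats::setNames(rep(NA_real_, ncol(design)), names(design))
  list(design = design, dropped = dropped, vifs = final_vifs)
}

#' Bonferroni adjustment
#'
#' @param pvals p-values in \[0, 1\].
#' @param m number of tests (default: `length(pvals)`).
#' @return `pmin(1, m * pvals)`.
#' @export
bonferroni_adjust <- function(pvals, m = length(pvals)) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  pmin(1, m * pvals)
}

# Random-intercept LME fit for one outcome; falls back to OLS for a
# single subject. Returns the fit plus a Satterthwaite coefficient table.
fit_lme_outcome <- function(rows, outcome, predictors, bonferroni_m,
                            conf_level = 0.95) {
  fml <- stats::as.formula(paste(
    outcome, "~", paste(predictors, collapse = " + "), "+ (1 | subject)"))
  n_subj <- length(unique(rows$subject))
  if (n_subj < 2L) {
    message("single subject: falling back to ordinary least squares")
    fml_ols <- stats::as.formula(paste(
      outcome, "~", paste(predictors, collapse = " + ")))
    fit <- stats::lm(fml_ols, data = rows)
    co <- summary(fit)$coefficients
    df <- fit$df.residual
    tab <- data.frame(term = rownames(co), estimate = co[, 1],
                      se = co[, 2], df = df, t = co[, 3], p = co[, 4],
                      stringsAsFactors = FALSE)
    var_b <- 0; var_e <- summary(fit)$sigma^2
    fixed_pred <- stats::fitted(fit)
  } else {
    fit <- suppressMessages(lmerTest::lmer(fml, data = rows, REML = TRUE))
    co <- stats::coef(summary(fit))  # Satterthwaite df/t/p via lmerTest
    tab <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                      se = co[, "Std. Error"], df = co[, "df"],
                      t = co[, "t value"], p = co[, "Pr(>|t|)"],
                      stringsAsFactors = FALSE)
    vc <- lme4::VarCorr(fit)
    var_b <- as.numeric(vc$subject[1])
    var_e <- attr(vc, "sc")^2
    fixed_pred <- stats::model.matrix(fit) %*% lme4::fixef(fit)
    if (lme4::isSingular(fit))
      message("boundary fit: random-intercept variance estimated at zero")
  }
  alpha <- 1 - conf_level
  tcrit <- stats::qt(1 - alpha / 2, df = tab$df)
  tab$ci_low <- tab$estimate - tcrit * tab$se
  tab$ci_high <- tab$estimate + tcrit * tab$se
  # adjust fixed-effect tests only (not the intercept)
  tab$p_adj <- NA_real_
  slope <- tab$term != "(Intercept)"
  tab$p_adj[slope] <- bonferroni_adjust(tab$p[slope], m = bonferroni_m)
  var_f <- stats::var(as.numeric(fixed_pred))
  r2_marginal <- var_f / (var_f + var_b + var_e)
  rownames(tab) <- NULL
  list(outcome = outcome, fit = fit, coefficients = tab,
       random_intercept_var = var_b, residual_var = var_e,
       r2_marginal = r2_marginal, n_obs = nrow(rows),
       n_subjects = n_subj)
}

#' Fit the structure-function coupling model
#'
#' The central modelling entry point. Starting from a joined table of
#' per-pathway observations (structural measures `fa`, `ad`,
#' `n_per_area`, `length`; transmission outcomes `pf_ratio`,
#' `peak_gain`; peak frequency `omega_p`; `subject`), it
#' 1. removes per-subject outcome outliers beyond `sd_mult` SDs and rows
#'    whose gain peak sits below `min_peak_freq` (audited);
#' 2. screens the structural predictors for collinearity by VIF and drops
#'    offenders (by default axial diffusivity, which is mechanically
#'    collinear with FA, leaving predictors FA, N, L);
#' 3. fits, for each outcome, a REML linear mixed-effects model with the
#'    surviving fixed effects and a random intercept per subject;
#'    coefficient t-tests use Satterthwaite degrees of freedom and
#'    slope p-values are Bonferroni-adjusted across the `m` fixed-effect
#'    tests per outcome.
#'
#' Marginal R^2 (variance explained by the fixed effects relative to
#' fixed + random-intercept + residual variance) is reported per outcome.
#'
#' @param data data.frame of pathway observations.
#' @param outcomes outcome columns to model.
#' @param predictors candidate structural predictors.
#' @param sd_mult,min_peak_freq observation filters; see
#'   [filter_observations()].
#' @param vif_threshold,collinearity_policy collinearity screen; see
#'   [drop_collinear()].
#' @param bonferroni_m number of tests for the Bonferroni adjustment;
#'   default is the number of retained fixed-effect slopes.
#' @param alpha significance threshold applied to adjusted p-values.
#'
#' @return An object of class `tf_coupling` with components `fits` (one
#'   per outcome, each with the underlying `lmerModLmerTest` fit and a
#'   Satterthwaite coefficient table), `filter_audit`, `vifs`,
#'   `dropped`, `predictors`, `data` (the filtered table), and `call`.
#'   Methods: `print`, `summary`, `coef`, `predict`, `residuals`,
#'   `simulate`, `plot`.
#' @seealso [report()] to serialize the fitted object,
#'   [simulate_coupled_dataset()] for synthetic input with known
#'   coefficients.
#' @export
tf_coupling <- function(data, outcomes = c("pf_ratio", "peak_gain"),
                        predictors = c("fa", "ad", "n_per_area", "length"),
                        sd_mult = 3, min_peak_freq = 1.5,
                        vif_threshold = 5,
                        collinearity_policy = c("fa_over_ad", "max_vif"),
                        bonferroni_m = NULL, alpha = 0.05) {
  collinearity_policy <- match.arg(collinearity_policy)
  outcomes <- intersect(outcomes, names(data))
  if (length(outcomes) == 0L)
    stop("none of the requested outcome columns are present", call. = FALSE)
  predictors <- intersect(predictors, names(data))
  if (length(predictors) < 1L)
    stop("no predictor columns present", call. = FALSE)
  flt <- filter_observations(data, sd_mult = sd_mult,
                             min_peak_freq = min_peak_freq,
                             features = outcomes)
  rows <- flt$rows
  if (nrow(rows) < length(predictors) + 2L)
    stop("too few observations remain after filtering", call. = FALSE)
  if (length(predictors) >= 2L) {
    scr <- drop_collinear(rows[, predictors, drop = FALSE],
                          threshold = vif_threshold,
                          policy = collinearity_policy)
    kept <- names(scr$design)
    vifs <- scr$vifs; dropped <- scr$dropped
  } else {
    kept <- predictors; vifs <- NULL; dropped <- character(0)
  }
  if (is.null(bonferroni_m)) bonferroni_m <- length(kept)
  fits <- lapply(outcomes, function(oc)
    fit_lme_outcome(rows, oc, kept, bonferroni_m))
  names(fits) <- outcomes
  structure(list(fits = fits, filter_audit = flt$audit, vifs = vifs,
                 dropped = dropped, predictors = kept, data = rows,
                 alpha = alpha, bonferroni_m = bonferroni_m,
                 call = match.call()),
            class = "tf_coupling")
}

#' @export
print.tf_coupling <- function(x, ...) {
  cat("Structure-function coupling model (random-intercept LME)\n")
  cat("  observations: ", nrow(x$data), " (",
      nrow(x$filter_audit), " filtered out), subjects: ",
      x$fits[[1]]$n_subjects, "\n", sep = "")
  cat("  fixed effects: ", paste(x$predictors, collapse = ", "),
      if (length(x$dropped) > 0)
        paste0("  [dropped collinear: ",
               paste(x$dropped, collapse = ", "), "]"), "\n", sep = "")
  for (f in x$fits) {
    cat("  ", f$outcome, ": marginal R^2 = ",
        format(f$r2_marginal, digits = 3), "\n", sep = "")
  }
  cat("Use summary() for the coefficient tables.\n")
  invisible(x)
}

#' @export
summary.tf_coupling <- function(object, ...) {
  structure(list(model = object), class = "summary.tf_coupling")
}

#' @export
print.summary.tf_coupling <- function(x, ...) {
  m <- x$model
  if (!is.null(m$vifs)) {
    cat("Collinearity screen (VIF):\n")
    print(round(m$vifs, 3))
    if (length(m$dropped) > 0)
      cat("dropped: ", paste(m$dropped, collapse = ", "), "\n", sep = "")
    cat("\n")
  }
  for (f in m$fits) {
    cat("Outcome: ", f$outcome, "  (n = ", f$n_obs, ", subjects = ",
        f$n_subjects, ")\n", sep = "")
    tab <- f$coefficients
    disp <- data.frame(
      term = tab$term,
      estimate = sprintf("%.3f", tab$estimate),
      `95% CI` = sprintf("[%.2f, %.2f]", tab$ci_low, tab$ci_high),
      t = sprintf("%.3f", tab$t), df = sprintf("%.1f", tab$df),
      p_adj = ifelse(is.na(tab$p_adj), "-", sprintf("%.4g", tab$p_adj)),
      sig = ifelse(!is.na(tab$p_adj) & tab$p_adj < m$alpha, "*", ""),
      check.names = FALSE)
    print(disp, row.names = FALSE)
    cat("  marginal R^2 = ", format(f$r2_marginal, digits = 3),
        "; random-intercept SD = ",
        format(sqrt(f$random_intercept_var), digits = 3),
        "; residual SD = ", format(sqrt(f$residual_var), digits = 3),
        "\n\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.tf_coupling <- function(object, ...) {
  sapply(object$fits, function(f)
    stats::setNames(f$coefficients$estimate, f$coefficients$term))
}

#' @export
predict.tf_coupling <- function(object, newdata = NULL,
                                outcome = names(object$fits)[1],
                                re.form = NA, ...) {
  fit <- object$fits[[outcome]]$fit
  if (inherits(fit, "lm")) {
    if (is.null(newdata)) stats::predict(fit)
    else stats::predict(fit, newdata = newdata)
  } else if (is.null(newdata)) {
    stats::predict(fit, re.form = re.form)
  } else {
    stats::predict(fit, newdata = newdata, re.form = re.form,
                   allow.new.levels = TRUE)
  }
}

#' @export
residuals.tf_coupling <- function(object,
                                  outcome = names(object$fits)[1], ...) {
  stats::residuals(object$fits[[outcome]]$fit)
}

#' @export
simulate.tf_coupling <- function(object, nsim = 1, seed = NULL,
                                 outcome = names(object$fits)[1], ...) {
  stats::simulate(object$fits[[outcome]]$fit, nsim = nsim, seed = seed,
                  ...)
}

#' @export
plot.tf_coupling <- function(x, outcome = names(x$fits)[1],
                             predictor = "fa", ...) {
  d <- x$data
  fit <- x$fits[[outcome]]
  graphics::plot(d[[predictor]], d[[outcome]],
                 xlab = toupper(predictor), ylab = outcome,
                 pch = 19, col = "grey40",
                 main = paste("Coupling:", outcome, "vs", predictor), ...)
  tab <- fit$coefficients
  b0 <- tab$estimate[tab$term == "(Intercept)"]
  b1 <- tab$estimate[tab$term == predictor]
  if (length(b1) == 1L) {
    others <- setdiff(x$predictors, predictor)
    off <- sum(vapply(others, function(p)
      tab$estimate[tab$term == p] * mean(d[[p]]), numeric(1)))
    graphics::abline(a = b0 + off, b = b1, col = "red3", lwd = 2)
  }
  invisible(x)
}

#' Serialize a coupling analysis
#'
#' Writes a machine-readable `report.json` (coefficient tables, variance
#' components, marginal R^2, VIFs, filter audit counts), a
#' `table2_style.tsv` with one row per outcome (intercept and slope
#' estimates with 95% CIs, significance after Bonferroni adjustment,
#' R^2, n), and the full `filter_audit.tsv`. Output is deterministic:
#' regenerating from the same fitted object is byte-identical.
#'
#' @param model a [tf_coupling()] fit.
#' @param dir output directory (created if needed).
#' @return Invisibly, the parsed report list.
#' @export
report <- function(model, dir) {
  stopifnot(inherits(model, "tf_coupling"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rep <- list(
    model = "random-intercept linear mixed effects",
    predictors = model$predictors,
    dropped_collinear = model$dropped,
    vif = as.list(round(model$vifs, 6)),
    alpha = model$alpha,
    bonferroni_m = model$bonferroni_m,
    n_filtered_out = nrow(model$filter_audit),
    outcomes = lapply(model$fits, function(f) {
      tab <- f$coefficients
      list(n_obs = f$n_obs, n_subjects = f$n_subjects,
           r2_marginal = round(f$r2_marginal, 6),
           random_intercept_var = round(f$random_intercept_var, 6),
           residual_var = round(f$residual_var, 6),
           coefficients = lapply(seq_len(nrow(tab)), function(i) list(
             term = tab$term[i], estimate = round(tab$estimate[i], 6),
             ci = c(round(tab$ci_low[i], 6), round(tab$ci_high[i], 6)),
             t = round(tab$t[i], 6), df = round(tab$df[i], 3),
             p = signif(tab$p[i], 6),
             p_adj = if (is.na(tab$p_adj[i])) NULL
                     else signif(tab$p_adj[i], 6))))
    }))
  jsonlite::write_json(rep, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  t2 <- do.call(rbind, lapply(model$fits, function(f) {
    tab <- f$coefficients
    row <- data.frame(outcome = f$outcome, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(tab))) {
      nm <- if (tab$term[i] == "(Intercept)") "intercept" else tab$term[i]
      row[[paste0(nm, "_est")]] <- tab$estimate[i]
      row[[paste0(nm, "_ci")]] <-
        sprintf("[%.2f, %.2f]", tab$ci_low[i], tab$ci_high[i])
      row[[paste0(nm, "_sig")]] <-
        !is.na(tab$p_adj[i]) && tab$p_adj[i] < model$alpha
    }
    row$r2 <- f$r2_marginal; row$n_obs <- f$n_obs
    row$n_pid <- f$n_subjects
    row
  }))
  write_table(t2, file.path(dir, "table2_style.tsv"))
  write_table(model$filter_audit, file.path(dir, "filter_audit.tsv"))
  invisible(rep)
}
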