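# Genotype-specific mutation-rate modelling: through-origin linear
# mixed-effects fits of burden on age with genotype-specific slopes and a
# patient random intercept, fold-changes between genotype rates, paired
# tissue signature-rate ratios, and rank-sum comparison of signature
# proportions.

#' Fit genotype-specific mutation rates per year
#'
#' Fits `burden ~ 0 + age:genotype + (1 | patient)` by REML: no global
#' intercept (burden is ~0 at age 0), one slope (mutations/year) per
#' genotype, and a patient-level random intercept absorbing between-patient
#' rate heterogeneity. Wald 95% confidence intervals. When every patient
#' contributes a single observation the random intercept is not
#' identifiable and the model degrades to the corresponding fixed-effects
#' least-squares fit.
#'
#' @param observations data.frame with columns `burden`, `age`, `genotype`,
#'   `patient` (one row per sample).
#' @return List of class `mixed_model_fit`: `rates` data.frame (genotype,
#'   slope, se, ci_lo, ci_hi), `ranef_sd` (random-intercept SD, NA for the
#'   lm fallback), `residual_sd`, `model`.
#' @export
fit_burden_lme <- function(observations) {
  req <- c("burden", "age", "genotype", "patient")
  stopifnot(all(req %in% names(observations)))
  if (nrow(observations) < 2) stop("need at least two observations", call. = FALSE)
  obs <- observations
  obs$genotype <- factor(obs$genotype)
  levs <- levels(obs$genotype)
  # explicit genotype-specific age columns so single-genotype cohorts fit too
  for (g in levs) obs[[paste0(".age_", g)]] <- obs$age * (obs$genotype == g)
  fixed <- paste0("`", paste0(".age_", levs), "`", collapse = " + ")

  fit_lm <- function() {
    fit <- stats::lm(stats::as.formula(paste("burden ~ 0 +", fixed)), data = obs)
    sm <- summary(fit)$coefficients
    list(slopes = stats::setNames(sm[, "Estimate"], rownames(sm)),
         ses = sm[, "Std. Error"], ranef_sd = NA_real_,
         resid_sd = summary(fit)$sigma, model = fit)
  }
  fit_lmer <- function() {
    model <- suppressWarnings(suppressMessages(
      lme4::lmer(stats::as.formula(paste("burden ~ 0 +", fixed, "+ (1 | patient)")),
                 data = obs, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE))))
    sm <- suppressWarnings(summary(model)$coefficients)
    if (any(!is.finite(sm[, "Std. Error"]))) stop("degenerate mixed fit")
    vc <- as.data.frame(lme4::VarCorr(model))
    list(slopes = stats::setNames(sm[, "Estimate"], rownames(sm)),
         ses = sm[, "Std. Error"],
         ranef_sd = vc$sdcor[vc$grp == "patient"],
         resid_sd = vc$sdcor[vc$grp == "Residual"], model = model)
  }

  # random intercept is unidentifiable with one observation per patient or
  # with degenerate (e.g. noiseless) data; degrade to the fixed-effects fit
  res <- if (all(table(obs$patient) == 1L)) fit_lm() else
    tryCatch(fit_lmer(), error = function(e) fit_lm())
  slopes <- res$slopes; ses <- res$ses
  ranef_sd <- res$ranef_sd; resid_sd <- res$resid_sd; model <- res$model

  # slope uncertainty is dominated by between-patient variation, so the CI
  # uses a t quantile with patients-minus-slopes degrees of freedom rather
  # than the normal approximation (which undercovers in small cohorts)
  df <- max(1L, length(unique(obs$patient)) - length(levs))
  genos <- sub("^`?\\.age_", "", sub("`$", "", names(slopes)))
  z <- stats::qt(0.975, df)
  rates <- data.frame(genotype = genos, slope = unname(slopes),
                      se = unname(ses),
                      ci_lo = unname(slopes - z * ses),
                      ci_hi = unname(slopes + z * ses),
                      stringsAsFactors = FALSE)
  structure(list(rates = rates, ranef_sd = ranef_sd, residual_sd = resid_sd,
                 model = model), class = "mixed_model_fit")
}

#' Extract one genotype's rate from a fit
#'
#' @param fit A `mixed_model_fit`.
#' @param genotype Genotype label.
#' @return One-row data.frame (slope, se, ci_lo, ci_hi).
#' @export
genotype_rate <- function(fit, genotype) {
  r <- fit$rates[fit$rates$genotype == genotype, ]
  if (nrow(r) != 1) stop("genotype not in fit: ", genotype, call. = FALSE)
  r
}

#' Fold-change between two modelled rates
#'
#' `fold = slope_num / slope_den`, with a 95% CI by the delta method on the
#' log scale: `se_log = sqrt((se_num/slope_num)^2 + (se_den/slope_den)^2)`.
#'
#' @param rate_num,rate_den Lists or one-row data.frames with `slope` and
#'   `se` (se may be 0 for fixed inputs).
#' @return List: fold, ci_lo, ci_hi.
#' @export
fold_change <- function(rate_num, rate_den) {
  bn <- rate_num$slope; bd <- rate_den$slope
  sn <- rate_num$se %||% 0; sd_ <- rate_den$se %||% 0
  if (bd <= 0) stop("denominator rate must be > 0", call. = FALSE)
  fold <- bn / bd
  se_log <- sqrt((sn / bn)^2 + (sd_ / bd)^2)
  z <- stats::qnorm(0.975)
  list(fold = fold, ci_lo = fold * exp(-z * se_log), ci_hi = fold * exp(z * se_log))
}

#' Ratio of paired tissue signature-attributed rates
#'
#' Through-origin linear regression of tissue-A rates on tissue-B rates
#' across individuals; the slope is the fold-difference between tissues.
#'
#' @param rate_a,rate_b Paired per-individual rates (same length >= 3).
#' @return List: slope, se, ci_lo, ci_hi, n.
#' @export
signature_rate_ratio <- function(rate_a, rate_b) {
  stopifnot(length(rate_a) == length(rate_b))
  if (length(rate_a) < 3) stop("need at least 3 paired observations", call. = FALSE)
  fit <- stats::lm(rate_a ~ 0 + rate_b)
  est <- stats::coef(fit)[[1]]
  se <- summary(fit)$coefficients[1, 2]
  ci <- stats::confint(fit)[1, ]
  list(slope = est, se = se, ci_lo = unname(ci[1]), ci_hi = unname(ci[2]),
       n = length(rate_a))
}

#' Compare signature proportions between two groups
#'
#' Two-sided Wilcoxon rank-sum test; exact for small samples without ties,
#' normal approximation otherwise.
#'
#' @param group_a,group_b Numeric vectors of per-sample signature
#'   proportions.
#' @return Two-sided p-value.
#' @export
compare_signature_proportions <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  exact <- length(group_a) <= 50 && length(group_b) <= 50
  suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                       exact = exact)$p.value)
}

#' Per-individual point mutation rate
#'
#' Median crypt burden divided by age, the per-individual summary used for
#' rate ranges.
#'
#' @param burdens Per-crypt burdens for one individual.
#' @param age Age in years.
#' @return Mutations per year.
#' @export
individual_rate <- function(burdens, age) stats::median(burdens) / age
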