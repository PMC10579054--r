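arm_factor <- function(x) {
  f <- as.factor(x)
  if (nlevels(f) != 2) abort("`arm` must have exactly two levels")
  f
}

check_design <- function(fit) {
  al <- stats::alias(fit)
  if (!is.null(al$Complete) && nrow(al$Complete)) {
    abort(paste0("singular design: aliased columns ",
                 paste(rownames(al$Complete), collapse = ", ")))
  }
  if (any(is.na(coef(fit)))) {
    abort(paste0("singular design: inestimable columns ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
}

#' ANCOVA for a time-weighted-average endpoint
#'
#' Linear model of the outcome on treatment arm plus covariates (typically
#' sex, mutation type and the baseline value); reports the least-squares
#' arm difference (second arm level minus first) with its confidence
#' interval and p-value.
#'
#' @param data Data frame with one row per patient.
#' @param outcome,arm Column names of the response and the two-level arm.
#' @param covariates Character vector of covariate column names.
#' @param conf_level Confidence level, default 0.95.
#' @return An `ho_test` (method `"ANCOVA"`); `$fit` carries the `lm`.
#' @export
fit_ancova <- function(data, outcome = "twa_tla_28wk", arm = "arm",
                       covariates = character(), conf_level = 0.95) {
  df <- as.data.frame(data)[, c(outcome, arm, covariates), drop = FALSE]
  df <- df[complete.cases(df), , drop = FALSE]
  df[[arm]] <- arm_factor(df[[arm]])
  if (any(table(df[[arm]]) < 2)) abort("need at least 2 patients per arm")
  rhs <- paste(c(arm, covariates), collapse = " + ")
  fit <- lm(as.formula(paste(outcome, "~", rhs)), data = df)
  check_design(fit)
  term <- paste0(arm, levels(df[[arm]])[2])
  est <- coef(fit)[[term]]
  ci <- confint(fit, term, level = conf_level)
  p <- summary(fit)$coefficients[term, "Pr(>|t|)"]
  new_ho_test("ANCOVA", statistic = summary(fit)$coefficients[term, "t value"],
              p_value = p, estimate = est, ci_low = ci[1], ci_high = ci[2],
              conf_level = conf_level, fit = fit,
              contrast = sprintf("%s - %s", levels(df[[arm]])[2], levels(df[[arm]])[1]))
}

#' Mixed model for repeated measures (MMRM)
#'
#' Generalized least squares fit of a longitudinal outcome on
#' arm-by-visit (plus covariates) with an unstructured within-patient
#' covariance across visits (general correlation `corSymm` plus
#' per-visit variances `varIdent`). Reports the arm contrast at the last
#' visit. Single-visit data reduce to the ANCOVA estimate.
#'
#' @param data Long data frame, one row per patient-visit.
#' @param outcome,arm,visit,patient Column names.
#' @param covariates Covariate column names.
#' @param conf_level Confidence level.
#' @return An `ho_test` (method `"MMRM"`); `$fit` carries the model.
#' @export
fit_repeated_measures <- function(data, outcome, arm, visit, patient,
                                  covariates = character(), conf_level = 0.95) {
  cols <- c(outcome, arm, visit, patient, covariates)
  df <- as.data.frame(data)[, cols, drop = FALSE]
  df <- df[complete.cases(df), , drop = FALSE]
  df[[arm]] <- arm_factor(df[[arm]])
  df$.visit <- factor(df[[visit]])
  if (nlevels(df$.visit) == 1) {
    res <- fit_ancova(df, outcome = outcome, arm = arm, covariates = covariates,
                      conf_level = conf_level)
    res$method <- "MMRM (single visit: ANCOVA)"
    return(res)
  }
  df$.visit_idx <- as.integer(df$.visit)
  df$.patient <- df[[patient]]
  rhs <- paste(c(sprintf("%s * .visit", arm), covariates), collapse = " + ")
  fit <- nlme::gls(
    as.formula(paste(outcome, "~", rhs)), data = df,
    correlation = nlme::corSymm(form = ~ .visit_idx | .patient),
    weights = nlme::varIdent(form = ~ 1 | .visit),
    na.action = stats::na.omit
  )
  cf <- coef(fit)
  arm_term <- paste0(arm, levels(df[[arm]])[2])
  last <- levels(df$.visit)[nlevels(df$.visit)]
  int_term <- paste0(arm_term, ":.visit", last)
  L <- setNames(numeric(length(cf)), names(cf))
  L[arm_term] <- 1
  if (int_term %in% names(cf)) L[int_term] <- 1
  est <- sum(L * cf)
  se <- sqrt(drop(t(L) %*% vcov(fit) %*% L))
  z <- qnorm(1 - (1 - conf_level) / 2)
  new_ho_test("MMRM", statistic = est / se,
              p_value = 2 * pnorm(-abs(est / se)), estimate = est,
              ci_low = est - z * se, ci_high = est + z * se,
              conf_level = conf_level, fit = fit,
              contrast = sprintf("%s - %s at visit %s",
                                 levels(df[[arm]])[2], levels(df[[arm]])[1], last))
}

#' Negative-binomial rate-ratio model with cluster-robust (GEE-type) errors
#'
#' Fits a negative-binomial regression of per-period lesion counts on a
#' two-level grouping (period or arm) plus covariates, with standard errors
#' from a cluster-robust sandwich estimator over patients — a generalized
#' estimating equation with independence working correlation. Reports the
#' rate ratio (second group level over first) with a Wald CI. When one
#' group has no events at all the ratio sits on the boundary: a descriptive
#' result (observed rate ratio, no CI) is returned with a `"boundary"`
#' flag.
#'
#' @param data Long data frame, one row per patient-period.
#' @param count,group,patient Column names (counts; two-level group;
#'   patient id for clustering).
#' @param covariates Covariate column names.
#' @param offset_log Optional column of log-exposure offsets.
#' @param conf_level Confidence level.
#' @return An `ho_test` (method `"NB-GEE"`); `$fit` carries the model when
#'   estimable.
#' @export
fit_count_gee <- function(data, count, group, patient,
                          covariates = character(), offset_log = NULL,
                          conf_level = 0.95) {
  cols <- c(count, group, patient, covariates, offset_log)
  df <- as.data.frame(data)[, cols, drop = FALSE]
  df <- df[complete.cases(df), , drop = FALSE]
  df[[group]] <- arm_factor(df[[group]])
  if (sum(df[[count]]) < 1) abort("need at least one event overall")
  sums <- tapply(df[[count]], df[[group]], sum)
  rates <- tapply(df[[count]], df[[group]], mean)
  if (any(sums == 0)) {
    return(new_ho_test("NB-GEE (boundary)", estimate = rates[[2]] / rates[[1]],
                       flags = "boundary",
                       observed_rates = as.numeric(rates)))
  }
  rhs <- paste(c(group, covariates), collapse = " + ")
  form <- paste(count, "~", rhs)
  if (!is.null(offset_log)) form <- paste(form, "+ offset(", offset_log, ")")
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(as.formula(form), data = df)),
    error = function(e) NULL
  )
  flags <- character()
  if (is.null(fit) || !fit$converged) {
    # near-equidispersed counts: Poisson quasi-likelihood point estimates
    fit <- stats::glm(as.formula(form), data = df, family = stats::poisson())
    flags <- "poisson_fallback"
  }
  vc <- sandwich::vcovCL(fit, cluster = df[[patient]])
  term <- paste0(group, levels(df[[group]])[2])
  est <- coef(fit)[[term]]
  se <- sqrt(vc[term, term])
  z <- qnorm(1 - (1 - conf_level) / 2)
  new_ho_test("NB-GEE", statistic = est / se,
              p_value = 2 * pnorm(-abs(est / se)), estimate = exp(est),
              ci_low = exp(est - z * se), ci_high = exp(est + z * se),
              conf_level = conf_level, flags = flags, fit = fit,
              observed_rates = as.numeric(rates))
}
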