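#' Covariate-adjusted group difference in a T2 parameter
#'
#' Ordinary least-squares model `outcome ~ group + covariates` with the
#' incidence group as the reference level, so the reported coefficient is
#' control minus incidence — negative when the incidence group is elevated,
#' matching the sign convention of the published comparison tables. The
#' unadjusted two-group model is fitted alongside.
#'
#' @param data Cohort tibble: one row per subject with `group` and the
#'   outcome/covariate columns.
#' @param outcome Name of the outcome column (string).
#' @param covariates Character vector of adjustment covariates (default
#'   age, sex, BMI).
#' @param conf_level Confidence level for the Wald interval.
#' @return An object of class `cartex_comparison` (also a tibble):
#'   `outcome`, group means/SDs, `coefficient` (control - incidence),
#'   `ci_low`, `ci_high`, `p_unadjusted`, `p_adjusted`, `n`.
#' @export
#' @examples
#' d <- tibble::tibble(group = factor(rep(c("incidence", "control"), c(6, 6)),
#'                                    levels = c("incidence", "control")),
#'                     age = 50, sex = "F", bmi = 24,
#'                     y = c(rnorm(6, 38), rnorm(6, 37)))
#' adjusted_group_difference(d, "y")
adjusted_group_difference <- function(data, outcome,
                                      covariates = c("age", "sex", "bmi"),
                                      conf_level = 0.95) {
  need <- c("group", outcome, covariates)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    rlang::abort(paste("missing columns:", paste(miss, collapse = ", ")),
                 class = "cartex_input_error")
  }
  d <- data[stats::complete.cases(data[need]), need]
  d$group <- factor(as.character(d$group), levels = c("incidence", "control"))
  if (dplyr::n_distinct(d$group) < 2) {
    rlang::abort("both groups must be present", class = "cartex_input_error")
  }
  if (nrow(d) < length(covariates) + 3) {
    rlang::abort("too few complete rows", class = "cartex_input_error")
  }
  # drop covariates without variation (would make the design singular)
  keep_cov <- covariates[vapply(covariates, function(cc)
    dplyr::n_distinct(d[[cc]]) > 1, logical(1))]
  fml_adj <- stats::reformulate(c("group", keep_cov), response = outcome)
  fml_un <- stats::reformulate("group", response = outcome)
  fit_adj <- stats::lm(fml_adj, data = d)
  if (any(is.na(stats::coef(fit_adj)))) {
    bad <- names(stats::coef(fit_adj))[is.na(stats::coef(fit_adj))]
    rlang::abort(paste("singular design; offending term:", bad[1]),
                 class = "cartex_input_error")
  }
  fit_un <- stats::lm(fml_un, data = d)
  s_adj <- summary(fit_adj)$coefficients
  s_un <- summary(fit_un)$coefficients
  est <- s_adj["groupcontrol", "Estimate"]
  se <- s_adj["groupcontrol", "Std. Error"]
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  by_g <- dplyr::summarise(dplyr::group_by(d, .data$group),
                           m = mean(.data[[outcome]]),
                           s = stats::sd(.data[[outcome]]))
  out <- tibble::tibble(
    outcome = outcome,
    mean_incidence = by_g$m[by_g$group == "incidence"],
    sd_incidence = by_g$s[by_g$group == "incidence"],
    mean_control = by_g$m[by_g$group == "control"],
    sd_control = by_g$s[by_g$group == "control"],
    coefficient = est,
    ci_low = est - zq * se,
    ci_high = est + zq * se,
    p_unadjusted = s_un["groupcontrol", "Pr(>|t|)"],
    p_adjusted = s_adj["groupcontrol", "Pr(>|t|)"],
    n = nrow(d)
  )
  attr(out, "fit") <- fit_adj
  attr(out, "fit_unadjusted") <- fit_un
  class(out) <- c("cartex_comparison", class(out))
  out
}

#' Covariate-adjusted lesion prevalence odds ratio
#'
#' Logistic model `indicator ~ group + covariates` with the control group
#' as reference, so the odds ratio compares incidence to control — the
#' convention of published prevalence comparisons. Without covariates the
#' OR reduces to the 2x2 cross-product ratio.
#'
#' @param data Cohort tibble with `group` and the indicator column.
#' @param indicator Name of a binary (0/1 or logical) lesion indicator.
#' @param covariates Adjustment covariates; `character(0)` for the crude OR.
#' @param conf_level Confidence level for the Wald interval.
#' @return Tibble: `indicator`, `odds_ratio`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
logistic_prevalence_or <- function(data, indicator,
                                   covariates = c("age", "sex", "bmi"),
                                   conf_level = 0.95) {
  need <- c("group", indicator, covariates)
  d <- data[stats::complete.cases(data[need]), need]
  d$group <- factor(as.character(d$group), levels = c("control", "incidence"))
  y <- as.numeric(d[[indicator]])
  if (length(unique(y)) < 2) {
    rlang::abort("indicator must have both classes present",
                 class = "cartex_input_error")
  }
  keep_cov <- covariates[vapply(covariates, function(cc)
    dplyr::n_distinct(d[[cc]]) > 1, logical(1))]
  fml <- stats::reformulate(c("group", keep_cov), response = indicator)
  fit <- suppressWarnings(stats::glm(fml, data = d, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  est <- sm["groupincidence", "Estimate"]
  se <- sm["groupincidence", "Std. Error"]
  if (se > 50) {
    rlang::abort("separation detected: group effect is not identifiable",
                 class = "cartex_separation_error")
  }
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(indicator = indicator,
                 odds_ratio = exp(est),
                 ci_low = exp(est - zq * se),
                 ci_high = exp(est + zq * se),
                 p = sm["groupincidence", "Pr(>|z|)"],
                 n = nrow(d))
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals from regressing `x` and `y` on the
#' covariates, with a two-sided test on `n - k - 2` degrees of freedom
#' (k covariate-model columns beyond the intercept).
#'
#' @param data Tibble containing all columns.
#' @param x,y Column names of the two variables.
#' @param covariates Covariate column names (may include `group`).
#' @return Tibble: `x`, `y`, `r`, `p`, `n`.
#' @export
partial_correlation <- function(data, x, y,
                                covariates = c("age", "sex", "bmi", "group")) {
  need <- c(x, y, covariates)
  d <- data[stats::complete.cases(data[need]), need]
  if (nrow(d) < length(covariates) + 3) {
    rlang::abort("too few complete rows", class = "cartex_input_error")
  }
  mm <- stats::model.matrix(stats::reformulate(covariates), data = d)
  rx <- stats::lm.fit(mm, d[[x]])$residuals
  ry <- stats::lm.fit(mm, d[[y]])$residuals
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    rlang::abort("zero residual variance", class = "cartex_input_error")
  }
  r <- stats::cor(rx, ry)
  k <- ncol(mm) - 1
  df <- nrow(d) - k - 2
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  tibble::tibble(x = x, y = y, r = r, p = p, n = nrow(d))
}

#' Standardized group difference
#'
#' `(mean_ig - mean_cg) / ((sd_ig + sd_cg) / 2)`: the group difference in
#' units of the average of the two group SDs.
#'
#' @param mean_ig,mean_cg Group means (incidence, control).
#' @param sd_ig,sd_cg Group SDs (> 0).
#' @return The standardized difference (SD units).
#' @export
#' @examples
#' standardized_difference(32.65, 32.07, 1.55, 1.38)
standardized_difference <- function(mean_ig, mean_cg, sd_ig, sd_cg) {
  if (any(c(sd_ig, sd_cg) <= 0)) {
    rlang::abort("SDs must be positive", class = "cartex_domain_error")
  }
  (mean_ig - mean_cg) / ((sd_ig + sd_cg) / 2)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected Pearson chi-square with 1 degree of freedom (no Yates
#' continuity correction), e.g. for a sex-by-group contingency table.
#'
#' @param counts 2x2 matrix of counts with all margins > 0.
#' @return Tibble: `statistic`, `df`, `p`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(50, 36, 42, 17), 2, 2))
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) {
    rlang::abort("counts must be a 2x2 matrix", class = "cartex_input_error")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    rlang::abort("all margins must be positive", class = "cartex_input_error")
  }
  ct <- stats::chisq.test(counts, correct = FALSE)
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p = ct$p.value)
}

#' Study-style comparison table over several outcomes
#'
#' Runs [adjusted_group_difference()] for each outcome column and binds the
#' results, mirroring the layout of a published group-comparison table
#' (group means and SD, unadjusted and adjusted p, coefficient, CI).
#'
#' @param data Cohort tibble.
#' @param outcomes Character vector of outcome column names.
#' @param covariates Adjustment covariates.
#' @param bonferroni Apply a Bonferroni correction across outcomes to the
#'   adjusted p-values (off by default, mirroring single-test reporting).
#' @return Tibble of comparison rows.
#' @export
comparison_table <- function(data, outcomes,
                             covariates = c("age", "sex", "bmi"),
                             bonferroni = FALSE) {
  out <- purrr::map_dfr(outcomes, function(oc) {
    r <- adjusted_group_difference(data, oc, covariates)
    class(r) <- setdiff(class(r), "cartex_comparison")
    attr(r, "fit") <- NULL
    attr(r, "fit_unadjusted") <- NULL
    r
  })
  if (bonferroni) {
    out$p_adjusted <- stats::p.adjust(out$p_adjusted, method = "bonferroni")
  }
  out
}
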