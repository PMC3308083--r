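#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a group-comparison result
#'
#' Returns the coefficient table of the adjusted linear model behind an
#' [adjusted_group_difference()] result, one row per model term.
#'
#' @param x A `cartex_comparison`.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @method tidy cartex_comparison
#' @export
tidy.cartex_comparison <- function(x, ...) {
  sm <- summary(attr(x, "fit"))$coefficients
  tibble::tibble(term = rownames(sm),
                 estimate = unname(sm[, "Estimate"]),
                 std.error = unname(sm[, "Std. Error"]),
                 statistic = unname(sm[, "t value"]),
                 p.value = unname(sm[, "Pr(>|t|)"]))
}

#' Glance at a group-comparison result
#'
#' One-row model summary of the adjusted fit.
#'
#' @inheritParams tidy.cartex_comparison
#' @return Tibble: `outcome`, `r.squared`, `adj.r.squared`, `sigma`,
#'   `p.value` (group term), `nobs`.
#' @method glance cartex_comparison
#' @export
glance.cartex_comparison <- function(x, ...) {
  fit <- attr(x, "fit")
  sm <- summary(fit)
  tibble::tibble(outcome = x$outcome,
                 r.squared = sm$r.squared,
                 adj.r.squared = sm$adj.r.squared,
                 sigma = sm$sigma,
                 p.value = x$p_adjusted,
                 nobs = x$n)
}
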