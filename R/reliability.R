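#' Root-mean-square coefficient of variation of repeated measurements
#'
#' For each subject with repeated measurements of one parameter, the
#' coefficient of variation is the sample SD divided by the mean; the
#' precision error of the method is the root mean square of the per-subject
#' CVs, in percent. This is the standard precision summary for repeated
#' quantitative measurements (e.g. re-segmentation of the same scans).
#'
#' @param data Tibble in long format with a subject column and a value
#'   column, or a list of numeric vectors (one per subject).
#' @param subject,value Column names when `data` is a tibble.
#' @return RMS CV in percent.
#' @export
#' @examples
#' d <- tibble::tibble(subject = rep(c("a", "b"), each = 3),
#'                     value = c(98, 100, 102, 49, 50, 51))
#' rms_cv(d)  # both subjects CV 2% -> 2
rms_cv <- function(data, subject = "subject", value = "value") {
  if (is.list(data) && !is.data.frame(data)) {
    groups <- data
  } else {
    groups <- split(data[[value]], data[[subject]])
  }
  cvs <- vapply(groups, function(v) {
    if (length(v) < 2) {
      rlang::abort("every subject needs at least 2 repeats",
                   class = "cartex_input_error")
    }
    m <- mean(v)
    if (m <= 0) {
      rlang::abort("subject mean must be positive for a CV",
                   class = "cartex_domain_error")
    }
    stats::sd(v) / m
  }, numeric(1))
  100 * sqrt(mean(cvs^2))
}

#' Intraclass correlation coefficient (two-way, single measures)
#'
#' Computed from the two-way mean-squares decomposition of an
#' subjects-by-raters table. The default absolute-agreement flavour,
#' ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n),
#' penalises systematic rater offsets; the consistency flavour
#' ICC(C,1) = (MSR - MSE) / (MSR + (k-1) MSE) does not. For two raters on
#' an ordinal scale the agreement ICC coincides (up to order 1/n terms)
#' with the quadratic-weighted kappa.
#'
#' @param ratings Numeric matrix or data frame, subjects in rows, raters or
#'   occasions in columns; no missing cells.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return ICC in \[-1, 1\].
#' @export
icc <- function(ratings, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  x <- as.matrix(ratings)
  if (anyNA(x)) rlang::abort("ratings must have no missing cells",
                             class = "cartex_input_error")
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2 || k < 2) rlang::abort("need >= 2 subjects and >= 2 raters",
                                   class = "cartex_input_error")
  if (stats::var(as.vector(x)) == 0) {
    rlang::abort("zero total variance; ICC undefined",
                 class = "cartex_degenerate_error")
  }
  grand <- mean(x)
  rm_ <- rowMeans(x)
  cm <- colMeans(x)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm - grand)^2) / (k - 1)
  sse <- sum((x - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (type == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

#' Quadratic-weighted kappa for two raters on an ordinal scale
#'
#' `1 - sum(w * O) / sum(w * E)` with disagreement weights
#' `w(i, j) = (i - j)^2 / (K - 1)^2` over the declared ordered scale,
#' observed cell proportions O and chance-expected proportions E (outer
#' product of the margins). Quadratic weighting makes kappa an
#' agreement-type intraclass correlation for ordinal data.
#'
#' @param r1,r2 Score vectors from the two raters/occasions.
#' @param scale Ordered vector of admissible categories (defaults to the
#'   sorted union of observed values).
#' @return Kappa coefficient.
#' @export
#' @examples
#' quadratic_weighted_kappa(c(0, 1, 2, 3), c(0, 1, 2, 3), scale = 0:3)  # 1
quadratic_weighted_kappa <- function(r1, r2, scale = NULL) {
  if (length(r1) != length(r2)) {
    rlang::abort("rating vectors must have equal length",
                 class = "cartex_input_error")
  }
  if (is.null(scale)) scale <- sort(unique(c(r1, r2)))
  if (!all(r1 %in% scale) || !all(r2 %in% scale)) {
    rlang::abort("ratings outside the declared scale",
                 class = "cartex_input_error")
  }
  kk <- length(scale)
  if (kk < 2) rlang::abort("scale must have >= 2 categories",
                           class = "cartex_degenerate_error")
  f1 <- factor(r1, levels = scale)
  f2 <- factor(r2, levels = scale)
  O <- table(f1, f2) / length(r1)
  E <- outer(rowSums(O), colSums(O))
  idx <- seq_len(kk) - 1
  w <- outer(idx, idx, function(i, j) (i - j)^2) / (kk - 1)^2
  denom <- sum(w * E)
  if (denom == 0) {
    rlang::abort("degenerate ratings: both raters used a single category",
                 class = "cartex_degenerate_error")
  }
  1 - sum(w * O) / denom
}
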