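#' Quantize a T2 map to integer grey levels
#'
#' Two schemes: `integer_ms` maps each valid T2 value to `round(t2)` clamped
#' to \[0, 100\] — one grey level per millisecond, preserving the physical
#' scale; `fixed_bins` maps to `n_levels` uniform bins over `bin_range`.
#' Invalid pixels (failed or non-physiologic fits) are removed from the
#' mask before any pair counting.
#'
#' @param t2 Numeric matrix/array of T2 values (ms).
#' @param valid Logical mask of usable pixels, same shape as `t2`.
#' @param config A [texture_config()].
#' @return List with integer `q` (same shape; NA outside mask) and logical
#'   `mask` of retained pixels. Signals a `cartex_empty_roi` condition if no
#'   pixel survives.
#' @export
quantize_map <- function(t2, valid, config = texture_config()) {
  mask <- valid & !is.na(t2)
  q <- array(NA_integer_, dim = dim(t2) %||% length(t2))
  if (config$quantization == "integer_ms") {
    q[mask] <- pmin(pmax(as.integer(round(t2[mask])), 0L), 100L)
    n_levels <- 101L
  } else {
    w <- diff(config$bin_range) / config$n_levels
    lev <- floor((t2[mask] - config$bin_range[1]) / w)
    q[mask] <- pmin(pmax(as.integer(lev), 0L), config$n_levels - 1L)
    n_levels <- config$n_levels
  }
  if (!any(mask)) {
    rlang::abort("no valid pixels remain in the ROI",
                 class = "cartex_empty_roi")
  }
  list(q = q, mask = mask, n_levels = n_levels)
}

orientation_offset <- function(orientation) {
  # (drow, dcol); 0 deg runs along columns (anterior-posterior axis),
  # 90 deg along rows (superior-inferior axis)
  switch(as.character(orientation),
         "0" = c(0L, 1L),
         "45" = c(-1L, 1L),
         "90" = c(-1L, 0L),
         "135" = c(-1L, -1L),
         rlang::abort("orientation must be one of 0, 45, 90, 135",
                      class = "cartex_input_error"))
}

#' Grey-level co-occurrence matrix of a masked image
#'
#' Counts ordered pixel pairs `(p, p + d)` at the given offset and
#' orientation with both pixels inside the mask (pairs crossing the mask
#' boundary are discarded so background never contaminates the ROI
#' statistics), optionally adds the transposed counts (symmetric, the
#' Haralick convention), and normalises by the total pair count.
#'
#' @param q Integer matrix of grey levels (NA outside mask allowed).
#' @param mask Logical matrix of pixels belonging to the ROI.
#' @param offset Pixel offset (>= 1).
#' @param orientation One of 0, 45, 90, 135 (degrees).
#' @param symmetric Count both directions (default `TRUE`).
#' @param n_levels Number of grey levels (matrix is `n_levels x n_levels`
#'   over levels `0:(n_levels-1)`).
#' @return An object of class `glcm`: list with probability matrix `p`,
#'   `levels`, `pair_count`, `orientation`, `offset`, `symmetric`.
#' @export
#' @examples
#' q <- rbind(c(0L, 1L), c(0L, 1L))
#' g <- glcm_matrix(q, matrix(TRUE, 2, 2), 1, 0, n_levels = 2)
#' g$p
glcm_matrix <- function(q, mask, offset = 1L, orientation = 0,
                        symmetric = TRUE, n_levels = 101L) {
  stopifnot(is.matrix(q), all(dim(q) == dim(mask)))
  d <- orientation_offset(orientation) * as.integer(offset)
  nr <- nrow(q)
  nc <- ncol(q)
  r1 <- seq_len(nr)
  c1 <- seq_len(nc)
  r2 <- r1 + d[1]
  c2 <- c1 + d[2]
  rok <- r1[r2 >= 1 & r2 <= nr]
  cok <- c1[c2 >= 1 & c2 <= nc]
  lev <- 0:(n_levels - 1)
  if (length(rok) == 0 || length(cok) == 0) {
    counts <- matrix(0, n_levels, n_levels)
  } else {
    a <- q[rok, cok, drop = FALSE]
    b <- q[rok + d[1], cok + d[2], drop = FALSE]
    ok <- mask[rok, cok, drop = FALSE] &
      mask[rok + d[1], cok + d[2], drop = FALSE] &
      !is.na(a) & !is.na(b)
    va <- a[ok]
    vb <- b[ok]
    counts <- matrix(0, n_levels, n_levels)
    if (length(va) > 0) {
      tab <- table(factor(va, levels = lev), factor(vb, levels = lev))
      counts <- counts + unclass(tab)
    }
  }
  if (symmetric) counts <- counts + t(counts)
  total <- sum(counts)
  p <- if (total > 0) counts / total else counts
  dimnames(p) <- list(lev, lev)
  structure(list(p = p, levels = lev, pair_count = total,
                 orientation = orientation, offset = offset,
                 symmetric = symmetric),
            class = "glcm")
}

check_glcm <- function(g) {
  if (!inherits(g, "glcm") || g$pair_count == 0) {
    rlang::abort("GLCM has no pairs; feature undefined",
                 class = "cartex_empty_roi")
  }
  g
}

#' GLCM entropy (nats)
#'
#' `sum over nonzero cells of p * (-ln p)`: the Shannon disorder of the
#' co-occurrence distribution. High entropy means co-occurrences are spread
#' uniformly over many grey-level pairs.
#'
#' @param g A [glcm_matrix()].
#' @return Entropy in nats (>= 0).
#' @export
glcm_entropy <- function(g) {
  check_glcm(g)
  p <- g$p[g$p > 0]
  sum(-p * log(p))
}

#' GLCM contrast
#'
#' `sum of p(i, j) * (i - j)^2`: mean squared grey-level difference between
#' co-occurring pixels; 0 for a constant region, large when neighbouring
#' pixels differ strongly.
#'
#' @inheritParams glcm_entropy
#' @return Contrast (dimensionless in level^2 units, >= 0).
#' @export
glcm_contrast <- function(g) {
  check_glcm(g)
  dif2 <- outer(g$levels, g$levels, "-")^2
  sum(g$p * dif2)
}

#' GLCM variance
#'
#' With `mu = sum of i * p(i, j)` (the marginal mean of the symmetric
#' co-occurrence distribution), returns `sum of p(i, j) * (i - mu)^2`: the
#' dispersion of grey levels weighted by pair membership.
#'
#' @inheritParams glcm_entropy
#' @return Variance (level^2 units, >= 0).
#' @export
glcm_variance <- function(g) {
  check_glcm(g)
  pi_marg <- rowSums(g$p)
  mu <- sum(g$levels * pi_marg)
  sum(pi_marg * (g$levels - mu)^2)
}

#' Per-compartment texture features of a T2 map
#'
#' For each compartment and slice, computes the GLCM at the configured
#' offset for each orientation, derives contrast, entropy and variance,
#' averages the features across orientations (feature-level averaging),
#' then aggregates across slices (pair-count-weighted by default). The
#' compartment mean T2 is the unweighted mean of all valid masked T2
#' values across slices. A final `all` row holds the unweighted mean of
#' the five compartment values — the all-compartment average used as a
#' global predictor.
#'
#' @param t2map A `t2_map` from [fit_map()], or a list with `t2`, `valid`,
#'   `labels` arrays.
#' @param config A [texture_config()].
#' @return A tibble with columns `compartment` (pat, mf, mt, lf, lt, all),
#'   `mean_t2`, `contrast`, `entropy`, `variance`, `n_pixels`, `n_pairs`.
#'   Compartments with no valid pairs are returned as NA and excluded from
#'   the `all` average.
#' @export
compartment_texture <- function(t2map, config = texture_config()) {
  t2 <- t2map$t2
  valid <- t2map$valid
  labels <- t2map$labels
  d <- dim(t2)
  nsl <- if (length(d) == 3) d[3] else 1
  get_slice <- function(a, s) if (length(d) == 3) a[, , s] else a
  comps <- compartment_codes()
  rows <- purrr::map(seq_along(comps), function(k) {
    vals <- t2[labels == k & valid]
    per_slice <- purrr::map(seq_len(nsl), function(s) {
      m <- get_slice(labels, s) == k & get_slice(valid, s)
      if (!any(m)) return(NULL)
      qr <- tryCatch(quantize_map(get_slice(t2, s), m, config),
                     error = function(e) NULL)
      if (is.null(qr)) return(NULL)
      feats <- purrr::map(config$orientations, function(o) {
        g <- glcm_matrix(qr$q, qr$mask, config$offset, o,
                         config$symmetric, qr$n_levels)
        if (g$pair_count == 0) return(NULL)
        tibble::tibble(contrast = glcm_contrast(g),
                       entropy = glcm_entropy(g),
                       variance = glcm_variance(g),
                       pairs = g$pair_count)
      })
      feats <- dplyr::bind_rows(feats)
      if (nrow(feats) == 0) return(NULL)
      tibble::tibble(contrast = mean(feats$contrast),
                     entropy = mean(feats$entropy),
                     variance = mean(feats$variance),
                     pairs = sum(feats$pairs))
    })
    per_slice <- dplyr::bind_rows(per_slice)
    if (nrow(per_slice) == 0) {
      return(tibble::tibble(compartment = comps[k], mean_t2 = NA_real_,
                            contrast = NA_real_, entropy = NA_real_,
                            variance = NA_real_, n_pixels = length(vals),
                            n_pairs = 0))
    }
    w <- if (config$slice_aggregation == "pair_count_weighted") {
      per_slice$pairs / sum(per_slice$pairs)
    } else {
      rep(1 / nrow(per_slice), nrow(per_slice))
    }
    tibble::tibble(
      compartment = comps[k],
      mean_t2 = mean(vals),
      contrast = sum(w * per_slice$contrast),
      entropy = sum(w * per_slice$entropy),
      variance = sum(w * per_slice$variance),
      n_pixels = length(vals),
      n_pairs = sum(per_slice$pairs)
    )
  })
  out <- dplyr::bind_rows(rows)
  ok <- !is.na(out$mean_t2) & out$n_pairs > 0
  all_row <- tibble::tibble(
    compartment = "all",
    mean_t2 = mean(out$mean_t2[ok]),
    contrast = mean(out$contrast[ok]),
    entropy = mean(out$entropy[ok]),
    variance = mean(out$variance[ok]),
    n_pixels = sum(out$n_pixels[ok]),
    n_pairs = sum(out$n_pairs[ok])
  )
  dplyr::bind_rows(out, all_row)
}
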