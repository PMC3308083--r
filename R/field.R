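#' Build a subject's true T2 field and compartment masks
#'
#' Lays out five curved cartilage bands — one per compartment — as angular
#' sectors of an annulus on every slice, a few pixels thick, emulating the
#' resolution regime in which 3-4 pixels span the cartilage thickness. The
#' band's inner edge plays the role of the cartilage-bone interface and the
#' outer edge the articular surface. Within each band the true T2 is the
#' subject's compartment mean plus a linear depth-wise gradient and
#' zero-mean spatial texture noise; both terms are demeaned within the band
#' so the spatial mean equals the drawn compartment mean exactly.
#'
#' @param subject_params Rows of [draw_t2_parameters()] for one subject
#'   (five rows, one per compartment).
#' @param config A [sim_config()].
#' @param seed Integer seed for the spatial noise.
#' @return An object of class `t2_field`: list with `t2` and `s0` arrays
#'   (rows x cols x slices), integer `labels` array (0 background, 1-5 =
#'   pat, mf, mt, lf, lt), and `compartments`.
#' @export
build_t2_field <- function(subject_params, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  comps <- compartment_codes()
  stopifnot(all(comps %in% subject_params$compartment))
  set.seed(seed)
  g <- as.character(subject_params$group[1])
  shape <- config$image_shape
  labels2d <- band_labels(shape, config$band_thickness)
  depth2d <- attr(labels2d, "depth")
  nsl <- config$n_slices
  t2 <- array(0, dim = c(shape, nsl))
  labels <- array(0L, dim = c(shape, nsl))
  means <- subject_params$true_t2[match(comps, subject_params$compartment)]
  het <- config$heterogeneity_sd[[g]]
  span <- config$depth_gradient
  for (s in seq_len(nsl)) {
    sl <- matrix(0, shape[1], shape[2])
    for (k in seq_along(comps)) {
      idx <- which(labels2d == k)
      if (any(means[k] <= 0)) {
        rlang::abort("drawn compartment mean T2 must be positive",
                     class = "cartex_geometry_error")
      }
      grad <- span * depth2d[idx]
      grad <- grad - mean(grad)
      noise <- rnorm_trunc3(length(idx), het)
      noise <- noise - mean(noise)
      vals <- means[k] + grad + noise
      # guard the physical invariant T2 > 0 without shifting the mean:
      # shrink the fluctuation, never translate it
      lo <- min(vals)
      if (lo <= 0.5) {
        f <- (means[k] - 0.5) / (means[k] - lo)
        vals <- means[k] + f * (vals - means[k])
      }
      sl[idx] <- vals
    }
    t2[, , s] <- sl
    labels[, , s] <- labels2d
  }
  s0 <- array(0, dim = dim(t2))
  s0[labels > 0] <- config$s0
  structure(list(t2 = t2, s0 = s0, labels = labels, compartments = comps,
                 group = g),
            class = "t2_field")
}

# zero-mean gaussian truncated at 3 SD (redraw), so extreme texture
# excursions cannot push T2 non-physical
rnorm_trunc3 <- function(n, sd) {
  if (sd == 0) return(rep(0, n))
  x <- stats::rnorm(n, 0, sd)
  bad <- which(abs(x) > 3 * sd)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), 0, sd)
    bad <- bad[abs(x[bad]) > 3 * sd]
  }
  x
}

# Annulus-sector geometry shared by all slices. Five 64-degree arcs with
# 8-degree gaps; radial coordinate inside the band gives the depth fraction
# (0 = bone interface, 1 = surface).
band_labels <- function(shape, thickness) {
  r_outer <- min(shape) / 2 - 3
  r_inner <- r_outer - thickness
  if (r_inner < 6) {
    rlang::abort("image too small to hold the cartilage bands",
                 class = "cartex_geometry_error")
  }
  ctr <- (shape + 1) / 2
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  dy <- rows - ctr[1]
  dx <- cols - ctr[2]
  r <- sqrt(dx^2 + dy^2)
  theta <- (atan2(dy, dx) * 180 / pi) %% 360
  lab <- matrix(0L, shape[1], shape[2])
  depth <- matrix(0, shape[1], shape[2])
  for (k in 1:5) {
    a0 <- (k - 1) * 72 + 4
    a1 <- k * 72 - 4
    inside <- r >= r_inner & r < r_outer & theta >= a0 & theta < a1
    lab[inside] <- k
    depth[inside] <- (r[inside] - r_inner) / thickness
  }
  attr(lab, "depth") <- depth
  lab
}

#' Render a multi-echo magnitude stack from a true T2 field
#'
#' Forward-simulates the MSME acquisition: at each echo time TE the noise-free
#' signal is `S0 * exp(-TE / T2)` (zero in the background), and the measured
#' magnitude is `sqrt((A + n1)^2 + n2^2)` with two independent
#' `N(0, noise_sigma^2)` channels — the Rician magnitude model whose squared
#' expectation is `A^2 + 2 sigma^2`, i.e. exactly the noise-offset term the
#' squared-signal fit estimates.
#'
#' @param field A `t2_field` from [build_t2_field()].
#' @param config A [sim_config()].
#' @param seed Integer seed for the noise draws.
#' @return An object of class `echo_stack`: list with `data` (4D array,
#'   rows x cols x slices x echoes), `echo_times` (ms), `pixel_spacing`,
#'   `slice_thickness`, `slice_gap`.
#' @export
render_echoes <- function(field, config, seed = config$seed) {
  stopifnot(inherits(field, "t2_field"), inherits(config, "sim_config"))
  set.seed(seed)
  te <- config$echo_times
  d <- dim(field$t2)
  out <- array(0, dim = c(d, length(te)))
  inmask <- field$labels > 0
  decay <- array(0, dim = d)
  sigma <- config$noise_sigma
  for (e in seq_along(te)) {
    decay[inmask] <- field$s0[inmask] * exp(-te[e] / field$t2[inmask])
    decay[!inmask] <- 0
    if (sigma > 0) {
      n1 <- array(stats::rnorm(prod(d), 0, sigma), dim = d)
      n2 <- array(stats::rnorm(prod(d), 0, sigma), dim = d)
      out[, , , e] <- sqrt((decay + n1)^2 + n2^2)
    } else {
      out[, , , e] <- decay
    }
  }
  structure(list(data = out, echo_times = te,
                 pixel_spacing = config$pixel_spacing,
                 slice_thickness = config$slice_thickness,
                 slice_gap = config$slice_gap),
            class = "echo_stack")
}
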