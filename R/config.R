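#' Study simulation configuration
#'
#' Builds and validates the configuration object that drives the synthetic
#' cohort generator. Defaults reproduce the design of a two-group knee MRI
#' study: an "incidence" group of subjects at risk for osteoarthritis and a
#' "control" group, aged 45-55 with BMI 19-27, imaged with a sagittal
#' multi-slice multi-echo (MSME) sequence at seven echo times (10-70 ms).
#' Per-compartment true T2 distributions, demographics, and lesion-prevalence
#' marginals default to the published group parameters the generator emulates.
#'
#' The per-subject T2 model decomposes each compartment mean into a group
#' mean, a shared subject-level shift (`shared_sd`), and an independent
#' compartment deviation, so that both the per-compartment marginal SD and
#' the SD of the five-compartment average match their configured values.
#' The shared shift, standardised, is the latent severity that couples
#' ordinal lesion scores to T2 (`worms_coupling`).
#'
#' @param n_incidence,n_control Number of subjects per group (>= 1).
#' @param age,bmi Named lists with `incidence`/`control` entries, each
#'   `c(mean =, sd =)`. Ages in years, BMI in kg/m^2.
#' @param age_range,bmi_range Inclusion ranges; draws are redrawn until
#'   inside (truncation matching the study inclusion criteria).
#' @param female_fraction Named vector of P(female) per group.
#' @param t2_table Tibble with columns `compartment` (pat, mf, mt, lf, lt),
#'   `group`, `mean`, `sd` — true T2 distribution (ms) per compartment/group.
#' @param shared_sd Named vector (ms): SD of the subject-level T2 shift
#'   common to all compartments, per group.
#' @param heterogeneity_sd Named vector (ms): SD of within-compartment
#'   spatial T2 texture, per group (larger in the incidence group).
#' @param depth_gradient Span (ms) of the linear depth-wise T2 gradient
#'   from the bone interface to the articular surface.
#' @param s0 Proton-density signal amplitude (arbitrary intensity units).
#' @param noise_sigma Per-channel Gaussian noise SD of the Rician magnitude
#'   model (same units as `s0`).
#' @param echo_times Strictly increasing echo times (ms).
#' @param n_slices,image_shape Slice count and in-plane matrix `c(rows, cols)`.
#' @param pixel_spacing In-plane pixel size `c(row_mm, col_mm)`.
#' @param slice_thickness,slice_gap Slice geometry (mm).
#' @param band_thickness Cartilage band thickness in pixels (3-4 matches the
#'   resolution regime in which one pixel offsets are meaningful).
#' @param lesion_prevalence Tibble with columns `tissue` (cartilage,
#'   meniscus, bml), `threshold` (`gt0`, `ge2`), `group`, `prob`:
#'   subject-level lesion prevalence among readable subjects.
#' @param worms_missing Named vector: probability a subject has no WORMS
#'   reading, per group.
#' @param worms_coupling Logit slope linking the standardised subject T2
#'   shift to lesion presence (>= 0; 0 decouples scores from T2).
#' @param seed Integer seed recorded in the configuration; all generator
#'   functions default to it.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_incidence = 4, n_control = 3, n_slices = 2)
#' cfg$echo_times
sim_config <- function(n_incidence = 92,
                       n_control = 53,
                       age = list(incidence = c(mean = 50.65, sd = 2.89),
                                  control = c(mean = 50.30, sd = 3.03)),
                       bmi = list(incidence = c(mean = 23.78, sd = 2.25),
                                  control = c(mean = 23.90, sd = 2.23)),
                       age_range = c(45, 55),
                       bmi_range = c(19, 27),
                       female_fraction = c(incidence = 50 / 92, control = 36 / 53),
                       t2_table = default_t2_table(),
                       shared_sd = c(incidence = 1.42, control = 1.22),
                       heterogeneity_sd = c(incidence = 7, control = 6),
                       depth_gradient = 12,
                       s0 = 400,
                       noise_sigma = 10,
                       echo_times = seq(10, 70, by = 10),
                       n_slices = 3,
                       image_shape = c(64, 64),
                       pixel_spacing = c(0.313, 0.446),
                       slice_thickness = 3.0,
                       slice_gap = 0.5,
                       band_thickness = 4,
                       lesion_prevalence = default_lesion_prevalence(),
                       worms_missing = c(incidence = 4 / 92, control = 8 / 53),
                       worms_coupling = 0.8,
                       seed = 1L) {
  cfg <- list(
    n_incidence = n_incidence, n_control = n_control,
    age = age, bmi = bmi, age_range = age_range, bmi_range = bmi_range,
    female_fraction = female_fraction,
    t2_table = tibble::as_tibble(t2_table),
    shared_sd = shared_sd, heterogeneity_sd = heterogeneity_sd,
    depth_gradient = depth_gradient,
    s0 = s0, noise_sigma = noise_sigma,
    echo_times = as.numeric(echo_times),
    n_slices = n_slices, image_shape = as.integer(image_shape),
    pixel_spacing = pixel_spacing,
    slice_thickness = slice_thickness, slice_gap = slice_gap,
    band_thickness = band_thickness,
    lesion_prevalence = tibble::as_tibble(lesion_prevalence),
    worms_missing = worms_missing,
    worms_coupling = worms_coupling,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @export
default_t2_table <- function() {
  # MF/MT rows are the published group distributions; LF/LT/PAT chosen so the
  # five-compartment average equals the published all-compartment mean.
  tibble::tribble(
    ~compartment, ~group,      ~mean, ~sd,
    "mf",  "incidence", 37.68, 2.28,
    "mt",  "incidence", 30.27, 1.88,
    "lf",  "incidence", 34.50, 1.90,
    "lt",  "incidence", 29.00, 1.90,
    "pat", "incidence", 31.80, 1.90,
    "mf",  "control",   36.85, 2.16,
    "mt",  "control",   29.51, 1.77,
    "lf",  "control",   34.00, 1.80,
    "lt",  "control",   28.60, 1.80,
    "pat", "control",   31.39, 1.80
  )
}

#' @rdname sim_config
#' @export
default_lesion_prevalence <- function() {
  tibble::tribble(
    ~tissue,     ~threshold, ~group,      ~prob,
    "cartilage", "gt0",      "incidence", 59 / 88,
    "cartilage", "gt0",      "control",   33 / 45,
    "cartilage", "ge2",      "incidence", 44 / 88,
    "cartilage", "ge2",      "control",   19 / 45,
    "meniscus",  "gt0",      "incidence", 42 / 88,
    "meniscus",  "gt0",      "control",   18 / 45,
    "meniscus",  "ge2",      "incidence", 22 / 88,
    "meniscus",  "ge2",      "control",   9 / 45,
    "bml",       "gt0",      "incidence", 29 / 88,
    "bml",       "gt0",      "control",   19 / 45
  )
}

config_error <- function(field, msg) {
  rlang::abort(sprintf("invalid configuration field `%s`: %s", field, msg),
               class = "cartex_config_error")
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_incidence) || cfg$n_incidence < 1 ||
      cfg$n_incidence != round(cfg$n_incidence)) {
    config_error("n_incidence", "must be an integer >= 1")
  }
  if (!is.numeric(cfg$n_control) || cfg$n_control < 1 ||
      cfg$n_control != round(cfg$n_control)) {
    config_error("n_control", "must be an integer >= 1")
  }
  for (g in c("incidence", "control")) {
    for (fld in c("age", "bmi")) {
      v <- cfg[[fld]][[g]]
      if (is.null(v) || !all(c("mean", "sd") %in% names(v)) || v[["sd"]] <= 0) {
        config_error(fld, sprintf("group `%s` needs mean and sd > 0", g))
      }
    }
    p <- cfg$female_fraction[[g]]
    if (is.null(p) || is.na(p) || p < 0 || p > 1) {
      config_error("female_fraction", sprintf("group `%s` must be in [0, 1]", g))
    }
    if (is.na(cfg$shared_sd[[g]]) || cfg$shared_sd[[g]] < 0) {
      config_error("shared_sd", "must be >= 0")
    }
    if (is.na(cfg$heterogeneity_sd[[g]]) || cfg$heterogeneity_sd[[g]] < 0) {
      config_error("heterogeneity_sd", "must be >= 0")
    }
    m <- cfg$worms_missing[[g]]
    if (is.null(m) || is.na(m) || m < 0 || m > 1) {
      config_error("worms_missing", "must be a probability")
    }
  }
  tt <- cfg$t2_table
  need <- tidyr::expand_grid(compartment = compartment_codes(),
                             group = c("incidence", "control"))
  if (nrow(dplyr::anti_join(need, tt, by = c("compartment", "group"))) > 0) {
    config_error("t2_table", "must cover all five compartments for both groups")
  }
  if (any(tt$sd <= 0)) config_error("t2_table", "all SDs must be > 0")
  for (g in c("incidence", "control")) {
    min_var <- min(tt$sd[tt$group == g]^2)
    if (cfg$shared_sd[[g]]^2 >= min_var) {
      config_error("shared_sd",
                   "shared variance must be below every compartment variance")
    }
  }
  if (any(diff(cfg$echo_times) <= 0) || length(cfg$echo_times) < 2) {
    config_error("echo_times", "must be strictly increasing")
  }
  if (cfg$noise_sigma < 0) config_error("noise_sigma", "must be >= 0")
  if (cfg$s0 <= 0) config_error("s0", "must be > 0")
  if (cfg$depth_gradient < 0) config_error("depth_gradient", "must be >= 0")
  if (length(cfg$image_shape) != 2 || any(cfg$image_shape < 16)) {
    config_error("image_shape", "needs two dimensions of at least 16 pixels")
  }
  if (cfg$n_slices < 1) config_error("n_slices", "must be >= 1")
  if (cfg$band_thickness < 3 || cfg$band_thickness > 8) {
    config_error("band_thickness", "must be between 3 and 8 pixels")
  }
  lp <- cfg$lesion_prevalence
  if (any(lp$prob < 0 | lp$prob > 1)) {
    config_error("lesion_prevalence", "probabilities must be in [0, 1]")
  }
  if (cfg$worms_coupling < 0) config_error("worms_coupling", "must be >= 0")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  groups: incidence n=%d, control n=%d\n",
              x$n_incidence, x$n_control))
  cat(sprintf("  image: %dx%d, %d slices, bands %d px thick\n",
              x$image_shape[1], x$image_shape[2], x$n_slices,
              x$band_thickness))
  cat(sprintf("  echoes (ms): %s\n", paste(x$echo_times, collapse = ", ")))
  cat(sprintf("  s0 = %g, noise_sigma = %g (SNR %.0f), seed = %d\n",
              x$s0, x$noise_sigma,
              if (x$noise_sigma > 0) x$s0 / x$noise_sigma else Inf, x$seed))
  invisible(x)
}

#' Compartment codes and labels
#'
#' The five cartilage compartments, in mask-label order: patella (1),
#' medial femur (2), medial tibia (3), lateral femur (4), lateral tibia (5).
#'
#' @return Character vector of compartment codes.
#' @export
compartment_codes <- function() c("pat", "mf", "mt", "lf", "lt")

#' T2 fitting configuration
#'
#' Controls the noise-corrected three-parameter fit of the squared-signal
#' decay model `S(TE)^2 = S0^2 exp(-2 TE / T2) + B^2`.
#'
#' @param exclude_first_echo Drop the first echo before fitting (default
#'   `TRUE`): in multi-echo CPMG trains the first echo is free of the
#'   stimulated-echo pathways that contaminate later echoes, so mixing it
#'   with them biases the decay rate.
#' @param excluded_echoes Integer indices of echoes to exclude; overrides
#'   `exclude_first_echo` when supplied.
#' @param t2_bounds T2 search interval in ms (default `c(0.1, 200)`); fits
#'   at the bounds are treated as non-physiologic.
#' @param fallback_policy `"mark_invalid"` (default) flags pixels whose fit
#'   lands on a T2 bound or fails as invalid, excluding them downstream;
#'   `"clamp"` keeps the boundary value and flags the pixel valid.
#' @param grid_points Number of log-spaced T2 values used to bracket the
#'   global minimum of the profiled objective.
#' @param refine_iter Golden-section refinement iterations inside the
#'   bracketing interval (enough for ~1e-8 relative precision on T2).
#' @param noise_floor Optional known noise offset `b` (intensity units). By
#'   default `b` is a free per-pixel parameter. When the acquisition noise
#'   level is known — e.g. from [estimate_noise_floor()] on background
#'   pixels — fixing `b` removes the small-sample bias that the free-`b`
#'   fit incurs at high SNR, where the noise floor is weakly identified
#'   from six echoes and its non-negativity constraint truncates the
#'   estimator asymmetrically.
#'
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(exclude_first_echo = TRUE,
                       excluded_echoes = NULL,
                       t2_bounds = c(0.1, 200),
                       fallback_policy = c("mark_invalid", "clamp"),
                       grid_points = 64,
                       refine_iter = 60,
                       noise_floor = NULL) {
  fallback_policy <- match.arg(fallback_policy)
  if (!is.null(noise_floor) && (!is.numeric(noise_floor) || noise_floor < 0)) {
    config_error("noise_floor", "must be a non-negative intensity")
  }
  if (length(t2_bounds) != 2 || t2_bounds[1] <= 0 || diff(t2_bounds) <= 0) {
    config_error("t2_bounds", "must be an increasing positive interval")
  }
  if (grid_points < 8) config_error("grid_points", "must be >= 8")
  structure(list(exclude_first_echo = exclude_first_echo,
                 excluded_echoes = excluded_echoes,
                 t2_bounds = t2_bounds,
                 fallback_policy = fallback_policy,
                 grid_points = as.integer(grid_points),
                 refine_iter = as.integer(refine_iter),
                 noise_floor = noise_floor),
            class = "fit_config")
}

#' GLCM texture configuration
#'
#' @param offset Pixel offset between co-occurring pixels (default 1,
#'   appropriate when a few pixels span the cartilage thickness).
#' @param orientations Subset of `c(0, 45, 90, 135)` degrees; 0 runs along
#'   the column (anterior-posterior) axis, 90 along the row
#'   (superior-inferior) axis.
#' @param quantization `"integer_ms"` (grey level = round(T2) clamped to
#'   \[0, 100\]) or `"fixed_bins"` (uniform bins over `bin_range`).
#' @param n_levels,bin_range Fixed-bin parameters (ignored for integer-ms).
#' @param symmetric Count each pair in both directions (Haralick
#'   convention; default `TRUE`).
#' @param slice_aggregation `"pair_count_weighted"` (default) or
#'   `"unweighted"` averaging of per-slice features.
#'
#' @return An object of class `texture_config`.
#' @export
texture_config <- function(offset = 1L,
                           orientations = c(0, 45, 90, 135),
                           quantization = c("integer_ms", "fixed_bins"),
                           n_levels = 16L,
                           bin_range = c(0, 80),
                           symmetric = TRUE,
                           slice_aggregation = c("pair_count_weighted",
                                                 "unweighted")) {
  quantization <- match.arg(quantization)
  slice_aggregation <- match.arg(slice_aggregation)
  if (offset < 1) config_error("offset", "must be >= 1")
  if (length(orientations) == 0 || !all(orientations %in% c(0, 45, 90, 135))) {
    config_error("orientations", "must be a non-empty subset of 0/45/90/135")
  }
  if (quantization == "fixed_bins" &&
      (n_levels < 2 || diff(bin_range) <= 0)) {
    config_error("n_levels", "fixed_bins needs n_levels >= 2 and a range")
  }
  structure(list(offset = as.integer(offset),
                 orientations = orientations,
                 quantization = quantization,
                 n_levels = as.integer(n_levels),
                 bin_range = bin_range,
                 symmetric = symmetric,
                 slice_aggregation = slice_aggregation),
            class = "texture_config")
}
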