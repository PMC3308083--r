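#' Sample subject demographics for both study groups
#'
#' Draws per-subject covariates from the configured group distributions:
#' age and BMI from normal distributions truncated (by redraw) to the study
#' inclusion ranges, sex from a Bernoulli on the configured female fraction.
#' WOMAC pain and Kellgren-Lawrence grade are fixed at 0 — the emulated
#' cohort is asymptomatic and radiographically normal by design.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`); identical
#'   config + seed reproduces the cohort exactly.
#' @return A tibble with one row per subject: `subject_id`, `group`
#'   (factor, incidence/control), `age`, `sex` (factor F/M), `bmi`,
#'   `womac_pain`, `kl_score`.
#' @export
#' @examples
#' subjects <- sample_subjects(sim_config(n_incidence = 5, n_control = 3))
#' subjects
sample_subjects <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  draw_group <- function(g, n) {
    tibble::tibble(
      subject_id = sprintf("%s%03d", toupper(substr(g, 1, 1)), seq_len(n)),
      group = g,
      age = rtruncnorm(n, config$age[[g]][["mean"]],
                       config$age[[g]][["sd"]], config$age_range),
      sex = ifelse(stats::runif(n) < config$female_fraction[[g]], "F", "M"),
      bmi = rtruncnorm(n, config$bmi[[g]][["mean"]],
                       config$bmi[[g]][["sd"]], config$bmi_range),
      womac_pain = 0,
      kl_score = 0
    )
  }
  out <- dplyr::bind_rows(draw_group("incidence", config$n_incidence),
                          draw_group("control", config$n_control))
  out$group <- factor(out$group, levels = c("incidence", "control"))
  out$sex <- factor(out$sex, levels = c("F", "M"))
  out
}

# truncation by redraw: keeps the shape of the parent normal inside the
# inclusion window instead of piling mass at the edges
rtruncnorm <- function(n, mean, sd, range) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < range[1] | x > range[2])
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < range[1] | x[bad] > range[2]]
  }
  x
}

#' Draw per-subject true T2 parameters
#'
#' For each subject, draws a shared T2 shift (common to all five
#' compartments) and independent compartment deviations so that each
#' compartment's marginal distribution matches the configured mean/SD while
#' compartments remain positively correlated within subject. The
#' standardised shared shift (`z`) is the latent severity used to couple
#' lesion scores to T2.
#'
#' @param subjects Tibble from [sample_subjects()].
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed + 1`).
#' @return A tibble with one row per subject x compartment: `subject_id`,
#'   `group`, `compartment`, `true_t2` (ms), and the subject-level `z`.
#' @export
draw_t2_parameters <- function(subjects, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- nrow(subjects)
  grp <- as.character(subjects$group)
  z <- stats::rnorm(n)
  shift <- z * config$shared_sd[grp]
  comps <- compartment_codes()
  nc <- length(comps)
  tt <- config$t2_table
  key <- paste(tt$group, tt$compartment)
  long_g <- rep(grp, each = nc)
  long_c <- rep(comps, times = n)
  row_i <- match(paste(long_g, long_c), key)
  mu <- tt$mean[row_i]
  resid_sd <- sqrt(tt$sd[row_i]^2 - config$shared_sd[long_g]^2)
  out <- tibble::tibble(
    subject_id = rep(subjects$subject_id, each = nc),
    group = factor(long_g, levels = c("incidence", "control")),
    compartment = long_c,
    true_t2 = unname(mu + rep(shift, each = nc) +
                       stats::rnorm(n * nc, 0, resid_sd)),
    z = rep(z, each = nc)
  )
  out
}
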