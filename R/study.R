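#' Simulate cohort tables without images
#'
#' Generates the subject covariates, true per-compartment T2 parameters and
#' WORMS scores for a configured study — everything except the image
#' stacks. Useful for fast statistical calibration work where the imaging
#' and fitting stages are not needed.
#'
#' @param config A [sim_config()].
#' @param seed Base seed (defaults to `config$seed`).
#' @return List with tibbles `subjects`, `params` (long, subject x
#'   compartment true T2), `worms`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  subjects <- sample_subjects(config, seed = seed)
  params <- draw_t2_parameters(subjects, config, seed = seed + 1L)
  worms <- sample_worms(subjects, params, config, seed = seed + 2L)
  list(subjects = subjects, params = params, worms = worms)
}

#' Run the full simulate-fit-texture stage for a cohort
#'
#' For every subject: builds the true T2 field and compartment masks,
#' renders the multi-echo magnitude stack with Rician noise, fits the
#' noise-corrected T2 map (first echo excluded), and computes
#' per-compartment mean T2 and GLCM texture features. Subjects are
#' processed one at a time (images are discarded after fitting), so memory
#' stays flat at cohort scale.
#'
#' @param config A [sim_config()].
#' @param fit_cfg A [fit_config()].
#' @param texture_cfg A [texture_config()].
#' @param seed Base seed (defaults to `config$seed`); per-subject seeds are
#'   derived as `seed + 100 + i`.
#' @param progress Print a dot every 10 subjects.
#' @return List with `cohort` — the wide per-subject analysis table
#'   (covariates, per-compartment `mean_t2_*`, `contrast_*`, `entropy_*`,
#'   `variance_*` including `_all`, WORMS max scores and lesion
#'   indicators) — plus the `subjects`, `params`, `worms`, and long
#'   `features` tibbles.
#' @export
run_study <- function(config,
                      fit_cfg = fit_config(),
                      texture_cfg = texture_config(),
                      seed = config$seed,
                      progress = FALSE) {
  sim <- simulate_cohort(config, seed = seed)
  feats <- purrr::map(seq_len(nrow(sim$subjects)), function(i) {
    sid <- sim$subjects$subject_id[i]
    sp <- sim$params[sim$params$subject_id == sid, ]
    sseed <- seed + 100L + i
    field <- build_t2_field(sp, config, seed = sseed)
    stack <- render_echoes(field, config, seed = sseed)
    tmap <- fit_map(stack, field$labels, fit_cfg)
    tx <- compartment_texture(tmap, texture_cfg)
    if (progress && i %% 10 == 0) cat(".")
    tx$subject_id <- sid
    tx
  })
  if (progress) cat("\n")
  features <- dplyr::bind_rows(feats)
  cohort <- build_cohort_table(sim$subjects, features, sim$worms)
  c(list(cohort = cohort, features = features), sim)
}

#' Assemble the wide per-subject analysis table
#'
#' Joins covariates, per-compartment imaging features (pivoted wide as
#' `mean_t2_<comp>`, `contrast_<comp>`, ...) and WORMS summaries (max
#' scores per tissue, lesion indicators at both thresholds) into the
#' one-row-per-subject table the statistics stage consumes.
#'
#' @param subjects,features,worms Tibbles from [run_study()] components.
#' @return The cohort tibble.
#' @export
build_cohort_table <- function(subjects, features, worms = NULL) {
  wide <- tidyr::pivot_wider(
    features[c("subject_id", "compartment", "mean_t2", "contrast",
               "entropy", "variance")],
    names_from = "compartment",
    values_from = c("mean_t2", "contrast", "entropy", "variance")
  )
  out <- dplyr::left_join(subjects, wide, by = "subject_id")
  if (!is.null(worms)) {
    hit <- function(tissue, thr) {
      cols <- worms_columns(tissue)
      m <- as.matrix(worms[cols])
      v <- rowSums(if (thr == "gt0") m > 0 else m >= 2, na.rm = TRUE) > 0
      v[rowSums(!is.na(m)) == 0] <- NA
      as.numeric(v)
    }
    wsum <- tibble::tibble(
      subject_id = worms$subject_id,
      worms_max_cart = worms_max_score(worms, "cartilage"),
      worms_max_men = worms_max_score(worms, "meniscus"),
      worms_max_bml = worms_max_score(worms, "bml"),
      cart_gt0 = hit("cartilage", "gt0"),
      cart_ge2 = hit("cartilage", "ge2"),
      men_gt0 = hit("meniscus", "gt0"),
      men_ge2 = hit("meniscus", "ge2"),
      bml_gt0 = hit("bml", "gt0")
    )
    out <- dplyr::left_join(out, wsum, by = "subject_id")
  }
  out
}
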