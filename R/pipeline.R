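#' Write an echo stack or label volume as NIfTI
#'
#' @param x An `echo_stack`, `t2_field` label array, or numeric array.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param pixel_spacing,slice_spacing Voxel dimensions (mm).
#' @return The path, invisibly.
#' @export
write_nifti_volume <- function(x, path,
                               pixel_spacing = c(0.313, 0.446),
                               slice_spacing = 3.5) {
  arr <- if (inherits(x, "echo_stack")) {
    pixel_spacing <- x$pixel_spacing
    slice_spacing <- x$slice_thickness + x$slice_gap
    x$data
  } else {
    x
  }
  img <- RNifti::asNifti(arr, pixdim = c(pixel_spacing, slice_spacing,
                                         rep(1, length(dim(arr)) - 3)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a multi-echo NIfTI stack with an echo-time sidecar
#'
#' Expects a 4D NIfTI plus a JSON or YAML sidecar (same basename,
#' `.json`/`.yaml` extension) carrying `echo_times` in ms.
#'
#' @param path NIfTI path.
#' @return An `echo_stack`.
#' @export
read_echo_stack <- function(path) {
  img <- RNifti::readNifti(path)
  base <- sub("\\.nii(\\.gz)?$", "", path)
  sidecar <- NULL
  if (file.exists(paste0(base, ".json"))) {
    sidecar <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  } else if (file.exists(paste0(base, ".yaml"))) {
    sidecar <- yaml::read_yaml(paste0(base, ".yaml"))
  }
  if (is.null(sidecar$echo_times)) {
    rlang::abort("sidecar with echo_times not found", class = "cartex_input_error")
  }
  pd <- RNifti::pixdim(img)
  structure(list(data = unclass(img)[, , , , drop = FALSE],
                 echo_times = as.numeric(sidecar$echo_times),
                 pixel_spacing = pd[1:2],
                 slice_thickness = pd[3], slice_gap = 0),
            class = "echo_stack")
}

#' Run the full study pipeline and write a report bundle
#'
#' Orchestrates simulate -> fit -> texture -> score -> analyze for a
#' configured synthetic study and writes all intermediates and results to
#' an output directory: per-subject NIfTI echo stacks, masks and T2/B/
#' validity maps (optional), the cohort CSV, the long feature CSV, a
#' group-comparison table over the standard outcomes, a prevalence table,
#' and a JSON manifest recording the seed and a configuration hash so a
#' rerun with the same configuration is reproducible (and byte-identical
#' in its CSV outputs).
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if missing).
#' @param fit_cfg,texture_cfg Stage configurations.
#' @param write_images Write per-subject NIfTI volumes (default `FALSE`;
#'   tables are always written).
#' @param outcomes Outcome columns for the comparison table.
#' @return Invisibly, a list with `cohort`, `comparisons`, `prevalence`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, outdir,
                         fit_cfg = fit_config(),
                         texture_cfg = texture_config(),
                         write_images = FALSE,
                         outcomes = c("mean_t2_all", "mean_t2_mf",
                                      "mean_t2_mt", "contrast_all",
                                      "entropy_all", "variance_all")) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage `%s` failed: %s",
                           name, conditionMessage(e)),
                   class = "cartex_pipeline_error")
    })
  }
  res <- stage("simulate+fit+texture",
               run_study(config, fit_cfg, texture_cfg))
  if (write_images) {
    img_dir <- file.path(outdir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    stage("write-images", {
      for (i in seq_len(nrow(res$subjects))) {
        sid <- res$subjects$subject_id[i]
        sp <- res$params[res$params$subject_id == sid, ]
        sseed <- config$seed + 100L + i
        field <- build_t2_field(sp, config, seed = sseed)
        stack <- render_echoes(field, config, seed = sseed)
        tmap <- fit_map(stack, field$labels, fit_cfg)
        write_nifti_volume(stack, file.path(img_dir, paste0(sid, "_echoes.nii.gz")))
        jsonlite::write_json(list(echo_times = config$echo_times),
                             file.path(img_dir, paste0(sid, "_echoes.json")),
                             auto_unbox = FALSE)
        write_nifti_volume(field$labels,
                           file.path(img_dir, paste0(sid, "_mask.nii.gz")),
                           config$pixel_spacing,
                           config$slice_thickness + config$slice_gap)
        t2w <- tmap$t2
        t2w[!tmap$valid] <- 0
        write_nifti_volume(t2w, file.path(img_dir, paste0(sid, "_t2map.nii.gz")),
                           config$pixel_spacing,
                           config$slice_thickness + config$slice_gap)
      }
    })
  }
  cohort_csv <- file.path(outdir, "cohort.csv")
  stage("score", {
    utils::write.csv(res$cohort, cohort_csv, row.names = FALSE)
    utils::write.csv(res$features, file.path(outdir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(dplyr::select(res$worms, -dplyr::any_of("group")),
                     file.path(outdir, "worms.csv"), row.names = FALSE)
  })
  missing_oc <- setdiff(outcomes, names(res$cohort))
  if (length(missing_oc) > 0) {
    rlang::abort(sprintf("pipeline stage `analyze` failed: unknown outcome(s) %s",
                         paste(missing_oc, collapse = ", ")),
                 class = "cartex_pipeline_error")
  }
  # statistical degeneracies (singular tiny designs, too few rows) produce a
  # flagged NA row rather than aborting the bundle; the manifest records them
  comparisons <- purrr::map_dfr(outcomes, function(oc) {
    tryCatch({
      r <- adjusted_group_difference(res$cohort, oc)
      class(r) <- setdiff(class(r), "cartex_comparison")
      attr(r, "fit") <- NULL
      attr(r, "fit_unadjusted") <- NULL
      r$note <- NA_character_
      r
    }, error = function(e) {
      warning(sprintf("comparison for `%s` not estimable: %s",
                      oc, conditionMessage(e)), call. = FALSE)
      tibble::tibble(outcome = oc, mean_incidence = NA_real_,
                     sd_incidence = NA_real_, mean_control = NA_real_,
                     sd_control = NA_real_, coefficient = NA_real_,
                     ci_low = NA_real_, ci_high = NA_real_,
                     p_unadjusted = NA_real_, p_adjusted = NA_real_,
                     n = NA_integer_, note = conditionMessage(e))
    })
  })
  prevalence <- stage("score-prevalence", prevalence_table(res$worms))
  utils::write.csv(comparisons, file.path(outdir, "comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(prevalence, file.path(outdir, "prevalence.csv"),
                   row.names = FALSE)
  yaml::write_yaml(config_as_list(config), file.path(outdir, "config.yaml"))
  manifest <- list(seed = config$seed,
                   config_hash = rlang::hash(config_as_list(config)),
                   n_subjects = nrow(res$cohort),
                   partial = any(!is.na(comparisons$note)),
                   package_version = as.character(utils::packageVersion("cartex")),
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort = res$cohort, comparisons = comparisons,
                 prevalence = prevalence, manifest = manifest))
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$t2_table <- as.data.frame(out$t2_table)
  out$lesion_prevalence <- as.data.frame(out$lesion_prevalence)
  lapply(out, function(x) if (is.data.frame(x)) lapply(x, unname) else x)
}
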