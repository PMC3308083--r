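#' WORMS score columns and scales
#'
#' Column naming follows the cohort CSV schema: `cart_*` for the five
#' cartilage compartments (8-point scale 0, 1, 2, 2.5, 3, 4, 5, 6 — 2.5 is
#' the full-thickness focal defect half grade), `men_*` for the six meniscus
#' regions (medial/lateral x anterior/body/posterior, scale 0-4), `bml_*`
#' for bone-marrow lesions (scale 0-3).
#'
#' @param tissue One of `"cartilage"`, `"meniscus"`, `"bml"`.
#' @return Character vector of column names (`worms_columns`) or numeric
#'   vector of admissible scores (`worms_scale`).
#' @export
worms_columns <- function(tissue = c("cartilage", "meniscus", "bml")) {
  tissue <- match.arg(tissue)
  switch(tissue,
         cartilage = paste0("cart_", compartment_codes()),
         meniscus = paste0("men_", c("ma", "mb", "mp", "la", "lb", "lp")),
         bml = paste0("bml_", compartment_codes()))
}

#' @rdname worms_columns
#' @export
worms_scale <- function(tissue = c("cartilage", "meniscus", "bml")) {
  tissue <- match.arg(tissue)
  switch(tissue,
         cartilage = c(0, 1, 2, 2.5, 3, 4, 5, 6),
         meniscus = 0:4,
         bml = 0:3)
}

#' Validate a table of WORMS scores
#'
#' Checks every score column against its tissue's admissible scale. The
#' cartilage half grade 2.5 is accepted; half grades anywhere else are
#' rejected. Rows with `readings_available = FALSE` must have all scores
#' missing, and vice versa.
#'
#' @param records Tibble with the [worms_columns()] score columns and
#'   optionally `readings_available`.
#' @return The validated tibble, invisibly classed as checked.
#' @export
#' @examples
#' tbl <- tibble::tibble(cart_pat = 2.5, cart_mf = 0, cart_mt = 0,
#'                       cart_lf = 0, cart_lt = 0)
#' validate_worms(tbl)
validate_worms <- function(records) {
  for (tissue in c("cartilage", "meniscus", "bml")) {
    cols <- intersect(worms_columns(tissue), names(records))
    scale <- worms_scale(tissue)
    for (cc in cols) {
      v <- records[[cc]]
      bad <- which(!is.na(v) & !(v %in% scale))
      if (length(bad) > 0) {
        rlang::abort(
          sprintf("invalid %s score %s in column `%s` (row %d)",
                  tissue, format(v[bad[1]]), cc, bad[1]),
          class = "cartex_worms_error")
      }
    }
  }
  if ("readings_available" %in% names(records)) {
    score_cols <- intersect(c(worms_columns("cartilage"),
                              worms_columns("meniscus"),
                              worms_columns("bml")), names(records))
    miss <- rowSums(!is.na(as.matrix(records[score_cols]))) == 0
    if (any(records$readings_available & miss) ||
        any(!records$readings_available & !miss)) {
      rlang::abort("readings_available inconsistent with missing scores",
                   class = "cartex_worms_error")
    }
  }
  invisible(records)
}

#' Per-subject WORMS max score
#'
#' The maximum score over a tissue's compartments for each subject — the
#' per-patient summary used to relate morphologic severity to T2.
#'
#' @param records WORMS score tibble (one row per subject).
#' @param tissue `"cartilage"`, `"meniscus"` or `"bml"`.
#' @return Numeric vector, NA where readings are unavailable.
#' @export
worms_max_score <- function(records, tissue = "cartilage") {
  cols <- intersect(worms_columns(tissue), names(records))
  if (length(cols) == 0) {
    rlang::abort(sprintf("no %s score columns present", tissue),
                 class = "cartex_worms_error")
  }
  m <- as.matrix(records[cols])
  out <- apply(m, 1, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  unname(out)
}

#' Lesion prevalence for a tissue at a threshold
#'
#' A subject counts as lesioned when any compartment of the tissue meets
#' the threshold (`gt0`: score > 0; `ge2`: score >= 2). Subjects without
#' readings are excluded from the denominator (list-wise, matching how
#' unread subjects drop out of published prevalence tables).
#'
#' @param records WORMS score tibble; optional `readings_available` and
#'   `group` columns.
#' @param tissue `"cartilage"`, `"meniscus"` or `"bml"`.
#' @param threshold `"gt0"` or `"ge2"` (`ge2` is not defined for BML).
#' @param group Optional group filter (e.g. `"incidence"`).
#' @param by_compartment Also return the per-compartment breakdown.
#' @return A one-row tibble: `tissue`, `threshold`, `group`,
#'   `n_with_lesion`, `n_readable`, `proportion`; with `by_compartment`,
#'   an added list column of per-compartment counts.
#' @export
#' @examples
#' rec <- tibble::tibble(cart_pat = c(2, 0, 1), cart_mf = 0, cart_mt = 0,
#'                       cart_lf = 0, cart_lt = 0)
#' lesion_prevalence(rec, "cartilage", "gt0")
lesion_prevalence <- function(records, tissue = "cartilage",
                              threshold = c("gt0", "ge2"),
                              group = NULL, by_compartment = FALSE) {
  threshold <- match.arg(threshold)
  if (tissue == "bml" && threshold == "ge2") {
    rlang::abort("BML prevalence is defined at > 0 only",
                 class = "cartex_worms_error")
  }
  if (!is.null(group) && "group" %in% names(records)) {
    records <- records[as.character(records$group) == group, , drop = FALSE]
  }
  if ("readings_available" %in% names(records)) {
    records <- records[records$readings_available, , drop = FALSE]
  }
  cols <- intersect(worms_columns(tissue), names(records))
  m <- as.matrix(records[cols])
  readable <- rowSums(!is.na(m)) > 0
  m <- m[readable, , drop = FALSE]
  if (nrow(m) == 0) {
    rlang::abort("no readable records", class = "cartex_worms_error")
  }
  hit <- if (threshold == "gt0") m > 0 else m >= 2
  les <- rowSums(hit, na.rm = TRUE) > 0
  out <- tibble::tibble(
    tissue = tissue, threshold = threshold,
    group = group %||% "all",
    n_with_lesion = sum(les), n_readable = nrow(m),
    proportion = sum(les) / nrow(m)
  )
  if (by_compartment) {
    out$by_compartment <- list(tibble::tibble(
      compartment = cols,
      n_with_lesion = colSums(hit, na.rm = TRUE),
      proportion = colSums(hit, na.rm = TRUE) / nrow(m)
    ))
  }
  out
}

#' Prevalence summary table across tissues and groups
#'
#' Convenience wrapper producing the study-style prevalence table:
#' cartilage and meniscus at both thresholds, BML at > 0, for each group
#' present in the records.
#'
#' @param records WORMS score tibble with a `group` column.
#' @return Tibble of [lesion_prevalence()] rows.
#' @export
prevalence_table <- function(records) {
  groups <- unique(as.character(records$group))
  specs <- list(c("cartilage", "gt0"), c("cartilage", "ge2"),
                c("meniscus", "gt0"), c("meniscus", "ge2"),
                c("bml", "gt0"))
  purrr::map_dfr(groups, function(g) {
    purrr::map_dfr(specs, function(sp) {
      lesion_prevalence(records, sp[1], sp[2], group = g)
    })
  })
}
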