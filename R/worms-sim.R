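#' Sample WORMS-style ordinal lesion scores for a cohort
#'
#' Generates per-subject semiquantitative lesion scores whose cohort-level
#' marginals match the configured subject-level prevalences: cartilage
#' (five compartments, scale 0, 1, 2, 2.5, 3, 4, 5, 6), meniscus (six
#' regions, scale 0-4) and bone-marrow lesions (five compartments, scale
#' 0-3). Cartilage and meniscus lesion presence is coupled to the subject's
#' standardised T2 shift through a logistic link whose intercept is solved
#' so the marginal prevalence is preserved; coupling > 0 therefore yields a
#' positive association between WORMS max and mean T2 without changing the
#' prevalence targets. A configurable fraction of subjects per group has no
#' reading (`readings_available = FALSE`, all scores missing).
#'
#' @param subjects Tibble from [sample_subjects()].
#' @param params Tibble from [draw_t2_parameters()] (supplies `z`).
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed + 2`).
#' @return A tibble with one row per subject: score columns `cart_pat`,
#'   `cart_mf`, `cart_mt`, `cart_lf`, `cart_lt`, `men_ma`, `men_mb`,
#'   `men_mp`, `men_la`, `men_lb`, `men_lp`, `bml_pat`, ..., `bml_lt`, and
#'   `readings_available`.
#' @export
sample_worms <- function(subjects, params, config, seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- nrow(subjects)
  grp <- as.character(subjects$group)
  zt <- dplyr::distinct(params, .data$subject_id, .data$z)
  z <- zt$z[match(subjects$subject_id, zt$subject_id)]
  beta <- config$worms_coupling
  lp <- config$lesion_prevalence

  prev <- function(tissue, thr, g) {
    p <- lp$prob[lp$tissue == tissue & lp$threshold == thr & lp$group == g]
    if (length(p) != 1) config_error("lesion_prevalence",
                                     sprintf("missing %s/%s/%s", tissue, thr, g))
    p
  }

  # intercepts solved per group so E_z[plogis(a + beta z)] = target
  present_prob <- function(tissue, g) {
    p <- prev(tissue, "gt0", g)
    a <- solve_link_intercept(p, beta)
    idx <- grp == g
    out <- numeric(n)
    out[idx] <- stats::plogis(a + beta * z[idx])
    out
  }

  cart_w <- c(pat = 48, lt = 17, mf = 11, lf = 8, mt = 4)      # relative compartment involvement
  men_w <- c(mp = 38, mb = 11, lp = 10, la = 6, lb = 4, ma = 1)

  cart_cols <- paste0("cart_", compartment_codes())
  men_cols <- paste0("men_", c("ma", "mb", "mp", "la", "lb", "lp"))
  bml_cols <- paste0("bml_", compartment_codes())
  scores <- matrix(0, n, length(cart_cols) + length(men_cols) + length(bml_cols),
                   dimnames = list(NULL, c(cart_cols, men_cols, bml_cols)))

  p_cart <- present_prob("cartilage", "incidence") * (grp == "incidence") +
    present_prob("cartilage", "control") * (grp == "control")
  p_men <- present_prob("meniscus", "incidence") * (grp == "incidence") +
    present_prob("meniscus", "control") * (grp == "control")
  p_bml <- ifelse(grp == "incidence", prev("bml", "gt0", "incidence"),
                  prev("bml", "gt0", "control"))
  # severity (max >= 2) conditional on presence, per group
  p_cart_sev <- vapply(grp, function(g)
    min(1, prev("cartilage", "ge2", g) / max(prev("cartilage", "gt0", g), 1e-12)),
    numeric(1))
  p_men_sev <- vapply(grp, function(g)
    min(1, prev("meniscus", "ge2", g) / max(prev("meniscus", "gt0", g), 1e-12)),
    numeric(1))

  has_cart <- stats::runif(n) < p_cart
  has_men <- stats::runif(n) < p_men
  has_bml <- stats::runif(n) < p_bml
  sev_cart <- has_cart & stats::runif(n) < p_cart_sev
  sev_men <- has_men & stats::runif(n) < p_men_sev

  for (i in seq_len(n)) {
    if (has_cart[i]) {
      primary <- sample(names(cart_w), 1, prob = cart_w)
      extra <- stats::runif(length(cart_w)) < 0.15
      lesioned <- union(primary, names(cart_w)[extra])
      for (cc in lesioned) scores[i, paste0("cart_", cc)] <- 1
      if (sev_cart[i]) {
        scores[i, paste0("cart_", primary)] <-
          sample(c(2, 2.5, 3), 1, prob = c(0.5, 0.3, 0.2))
      }
    }
    if (has_men[i]) {
      primary <- sample(names(men_w), 1, prob = men_w)
      extra <- stats::runif(length(men_w)) < 0.08
      lesioned <- union(primary, names(men_w)[extra])
      for (mm in lesioned) scores[i, paste0("men_", mm)] <- 1
      if (sev_men[i]) {
        scores[i, paste0("men_", primary)] <- sample(c(2, 3), 1, prob = c(0.8, 0.2))
      }
    }
    if (has_bml[i]) {
      cc <- sample(compartment_codes(), 1)
      scores[i, paste0("bml_", cc)] <- sample(1:3, 1, prob = c(0.6, 0.3, 0.1))
    }
  }

  readable <- stats::runif(n) >= config$worms_missing[grp]
  out <- tibble::as_tibble(as.data.frame(scores))
  out <- dplyr::bind_cols(tibble::tibble(subject_id = subjects$subject_id,
                                         group = subjects$group), out)
  out$readings_available <- readable
  out[!readable, c(cart_cols, men_cols, bml_cols)] <- NA_real_
  out
}

# solve a in E[plogis(a + beta Z)] = p for Z ~ N(0,1), by quadrature + uniroot
solve_link_intercept <- function(p, beta) {
  if (p <= 0) return(-Inf)
  if (p >= 1) return(Inf)
  if (beta == 0) return(stats::qlogis(p))
  zg <- seq(-6, 6, length.out = 201)
  w <- stats::dnorm(zg)
  w <- w / sum(w)
  f <- function(a) sum(w * stats::plogis(a + beta * zg)) - p
  stats::uniroot(f, c(-20, 20), tol = 1e-10)$root
}
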