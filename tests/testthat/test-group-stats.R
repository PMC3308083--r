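make_cohort <- function(n1 = 60, n2 = 40, delta = 1, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    group = factor(rep(c("incidence", "control"), c(n1, n2)),
                   levels = c("incidence", "control")),
    age = round(runif(n1 + n2, 45, 55), 1),
    sex = sample(c("F", "M"), n1 + n2, TRUE),
    bmi = round(runif(n1 + n2, 19, 27), 1),
    y = c(rnorm(n1, 37 + delta, 2), rnorm(n2, 37, 2))
  )
}

test_that("degenerate covariates reduce the adjusted estimate to the raw difference", {
  d <- make_cohort(seed = 5)
  d$age <- 50
  d$sex <- "F"
  d$bmi <- 24
  r <- adjusted_group_difference(d, "y")
  raw <- mean(d$y[d$group == "control"]) - mean(d$y[d$group == "incidence"])
  expect_equal(r$coefficient, raw, tolerance = 1e-10)
  expect_equal(r$p_adjusted, r$p_unadjusted, tolerance = 1e-10)
  expect_true(r$ci_low <= r$coefficient && r$coefficient <= r$ci_high)
})

test_that("sign convention: elevated incidence group gives a negative coefficient", {
  d <- make_cohort(delta = 2, seed = 8)
  r <- adjusted_group_difference(d, "y")
  expect_lt(r$coefficient, 0)
  expect_gt(r$mean_incidence, r$mean_control)
})

test_that("permuted group labels center the coefficient at zero", {
  d <- make_cohort(delta = 2, seed = 3)
  set.seed(44)
  coefs <- replicate(200, {
    dp <- d
    dp$group <- sample(dp$group)
    adjusted_group_difference(dp, "y")$coefficient
  })
  expect_lt(abs(mean(coefs)), 3 * sd(coefs) / sqrt(200))
})

test_that("group-difference recovery matches the configured effect over replicates", {
  # true MF difference is 37.68 - 36.85 = 0.83 ms; coefficient is control -
  # incidence, so its mean over replicates should sit near -0.83
  cfg <- sim_config(seed = 1)
  set.seed(70)
  seeds <- sample.int(1e6, 300)
  coefs <- vapply(seeds, function(s) {
    subj <- sample_subjects(cfg, seed = s)
    p <- draw_t2_parameters(subj, cfg, seed = s + 1)
    mf <- p[p$compartment == "mf", ]
    d <- dplyr::left_join(subj, mf[c("subject_id", "true_t2")],
                          by = "subject_id")
    adjusted_group_difference(d, "true_t2")$coefficient
  }, numeric(1))
  expect_lt(abs(mean(coefs) - (-0.83)), 0.07)
})

test_that("coefficient sign is recovered in most replicates at study scale", {
  cfg <- sim_config(seed = 2)
  set.seed(71)
  seeds <- sample.int(1e6, 200)
  coefs <- vapply(seeds, function(s) {
    subj <- sample_subjects(cfg, seed = s)
    p <- draw_t2_parameters(subj, cfg, seed = s + 1)
    mf <- p[p$compartment == "mf", ]
    d <- dplyr::left_join(subj, mf[c("subject_id", "true_t2")],
                          by = "subject_id")
    adjusted_group_difference(d, "true_t2")$coefficient
  }, numeric(1))
  expect_gt(mean(coefs < 0), 0.9)
})

test_that("singular designs and missing groups are rejected", {
  d <- make_cohort(seed = 9)
  expect_error(adjusted_group_difference(d[d$group == "incidence", ], "y"),
               class = "cartex_input_error")
  expect_error(adjusted_group_difference(d, "nope"),
               class = "cartex_input_error")
})

test_that("crude logistic OR equals the 2x2 cross-product ratio", {
  # counts mirroring the published table: 59/88 lesioned incidence, 33/45 control
  d <- tibble::tibble(
    group = factor(rep(c("incidence", "control"), c(88, 45)),
                   levels = c("incidence", "control")),
    lesion = c(rep(c(1, 0), c(59, 29)), rep(c(1, 0), c(33, 12)))
  )
  r <- logistic_prevalence_or(d, "lesion", covariates = character(0))
  expect_equal(r$odds_ratio, (59 * 12) / (29 * 33), tolerance = 1e-6)
  # equal prevalence in both groups -> OR ~ 1
  d2 <- tibble::tibble(
    group = factor(rep(c("incidence", "control"), each = 40),
                   levels = c("incidence", "control")),
    lesion = rep(c(1, 0, 1, 0), c(20, 20, 20, 20))
  )
  r2 <- logistic_prevalence_or(d2, "lesion", covariates = character(0))
  expect_equal(r2$odds_ratio, 1, tolerance = 1e-8)
})

test_that("adjusted OR on the configured prevalence marginals is near the published value", {
  cfg <- sim_config(seed = 6)
  sim <- simulate_cohort(cfg)
  d <- build_cohort_table(sim$subjects,
                          tibble::tibble(subject_id = sim$subjects$subject_id,
                                         compartment = "mf", mean_t2 = 0,
                                         contrast = 0, entropy = 0,
                                         variance = 0),
                          sim$worms)
  r <- logistic_prevalence_or(d, "cart_gt0")
  # published adjusted OR 0.83 (95% CI 0.36-1.88); a single simulated cohort
  # must at least land inside that interval
  expect_gt(r$odds_ratio, 0.36)
  expect_lt(r$odds_ratio, 1.88)
})

test_that("partial correlation reduces to Pearson r for irrelevant covariates", {
  set.seed(15)
  n <- 400
  d <- tibble::tibble(x = rnorm(n), y = NA, age = rnorm(n), bmi = rnorm(n),
                      sex = sample(c("F", "M"), n, TRUE))
  d$y <- 0.5 * d$x + rnorm(n)
  pc <- partial_correlation(d, "x", "y", covariates = c("age", "sex", "bmi"))
  expect_equal(pc$r, cor(d$x, d$y), tolerance = 0.02)
  # exact linear dependence gives r = 1
  d$y2 <- d$x
  expect_equal(partial_correlation(d, "x", "y2",
                                   covariates = c("age", "bmi"))$r, 1,
               tolerance = 1e-10)
})

test_that("standardized difference follows its defining formula", {
  expect_equal(standardized_difference(32.65, 32.07, 1.55, 1.38),
               0.58 / 1.465, tolerance = 1e-12)
  expect_equal(round(standardized_difference(32.65, 32.07, 1.55, 1.38), 3),
               0.396)
  expect_equal(standardized_difference(5, 5, 1, 2), 0)
  expect_equal(standardized_difference(1, 0, 1, 1), 1)
  expect_error(standardized_difference(1, 0, 0, 1),
               class = "cartex_domain_error")
})

test_that("Pearson chi-square matches the closed-form oracle and printed example", {
  # females/males x incidence/control from the demographics table
  r <- chi_square_2x2(matrix(c(50, 36, 42, 17), 2, 2))
  expect_equal(r$statistic, 2.568, tolerance = 1e-3)
  expect_equal(round(r$p, 1), 0.1)
  # closed-form n(ad-bc)^2 / row/col margins on random tables
  set.seed(27)
  for (i in 1:25) {
    m <- matrix(sample(5:60, 4, TRUE), 2, 2)
    r2 <- suppressWarnings(chi_square_2x2(m))  # small expected counts warn
    a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; dd <- m[2, 2]
    n <- sum(m)
    hand <- n * (a * dd - b * cc)^2 /
      ((a + b) * (cc + dd) * (a + cc) * (b + dd))
    expect_equal(r2$statistic, hand, tolerance = 1e-10)
  }
  # perfectly proportional table
  r3 <- chi_square_2x2(matrix(c(20, 10, 40, 20), 2, 2))
  expect_equal(r3$statistic, 0, tolerance = 1e-12)
  expect_equal(r3$p, 1)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, 2)),
               class = "cartex_input_error")
})

test_that("tidy and glance expose the adjusted model", {
  d <- make_cohort(seed = 12)
  r <- adjusted_group_difference(d, "y")
  td <- tidy(r)
  expect_true("groupcontrol" %in% td$term)
  expect_equal(td$estimate[td$term == "groupcontrol"], r$coefficient)
  gl <- glance(r)
  expect_equal(gl$nobs, nrow(d))
  expect_equal(gl$p.value, r$p_adjusted)
})
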