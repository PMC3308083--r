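te7 <- seq(10, 70, 10)
te6 <- seq(20, 70, 10)

test_that("squared-signal model evaluates its closed forms exactly", {
  expect_equal(model_signal_squared(100, 40, 0, 40), 10000 * exp(-2))
  expect_equal(model_signal_squared(100, 40, 20, 20), 10000 * exp(-1) + 400)
  # zero-amplitude limit is the pure noise floor for any t2/te
  expect_equal(model_signal_squared(0, 13, 7, 55), 49)
  expect_error(model_signal_squared(100, -1, 0, 10),
               class = "cartex_domain_error")
})

test_that("noiseless signals are recovered to high relative accuracy", {
  f <- fit_pixel(sqrt(model_signal_squared(100, 40, 0, te7)), te7)
  expect_equal(f$t2, 40, tolerance = 1e-6 / 40)
  f2 <- fit_pixel(sqrt(model_signal_squared(100, 40, 20, te7)), te7)
  expect_lt(max(abs(c(f2$s0 - 100, f2$t2 - 40, f2$b - 20) / c(100, 40, 20))),
            1e-4)
  # exactness across the physiologic T2 range, with and without noise floor
  for (t2 in c(10, 25, 55, 100)) {
    for (b in c(0, 12)) {
      y <- sqrt(model_signal_squared(250, t2, b, te7))
      fk <- fit_pixel(y, te7)
      expect_lt(abs(fk$t2 - t2) / t2, 1e-4)
      expect_lt(abs(fk$s0 - 250) / 250, 1e-4)
      expect_true(fk$valid)
    }
  }
})

test_that("fit is scale-equivariant: s0 and b scale, t2 does not", {
  y <- sqrt(model_signal_squared(100, 40, 20, te7))
  base <- fit_pixel(y, te7)
  scl <- fit_pixel(3.7 * y, te7)
  expect_equal(scl$t2, base$t2, tolerance = 1e-6)
  expect_equal(scl$s0, 3.7 * base$s0, tolerance = 1e-6)
  expect_equal(scl$b, 3.7 * base$b, tolerance = 1e-6)
})

test_that("excluding the first echo equals fitting without it present", {
  y7 <- sqrt(model_signal_squared(100, 40, 15, te7))
  with_excl <- fit_pixel(y7, te7, fit_config(exclude_first_echo = TRUE))
  without <- fit_pixel(y7[-1], te6, fit_config(exclude_first_echo = FALSE))
  expect_equal(with_excl, without)
})

test_that("degenerate pixel inputs are handled", {
  expect_error(fit_pixel(c(1, 2, 3), c(10, 20, 30)),
               class = "cartex_input_error")          # < 4 usable echoes
  z <- fit_pixel(rep(0, 7), te7)
  expect_false(z$valid)
  expect_error(fit_pixel(1:6, te7), class = "cartex_input_error")
})

test_that("noise-corrected fit beats the log-linear fit for Rician bias at SNR 10", {
  set.seed(202)
  n <- 1000
  sig <- 10
  A <- 100 * exp(-te7 / 40)
  Y <- t(replicate(n, rician(A, sig)))
  stack <- array(Y, dim = c(n, 1, 1, 7))
  mask <- array(1L, dim = c(n, 1, 1))
  m <- fit_map(stack, mask, fit_config(), echo_times = te7)
  t2_nc <- m$t2[m$valid]
  t2_ll <- apply(Y[, -1], 1, function(y) {
    fit_pixel_loglinear(y, te6, fit_config(exclude_first_echo = FALSE))$t2
  })
  bias_nc <- abs(mean(t2_nc) - 40)
  bias_ll <- abs(mean(t2_ll, na.rm = TRUE) - 40)
  expect_lt(bias_nc, bias_ll)
  expect_lt(bias_nc, 1)   # mean fitted T2 within 1 ms of truth
})

test_that("fixing b at the known noise floor removes most of the high-SNR bias", {
  set.seed(77)
  n <- 800
  sig <- 10
  A <- 400 * exp(-te7 / 40)
  Y <- t(replicate(n, rician(A, sig)))
  stack <- array(Y, dim = c(n, 1, 1, 7))
  mask <- array(1L, dim = c(n, 1, 1))
  free_b <- fit_map(stack, mask, fit_config(), echo_times = te7)
  fixed_b <- fit_map(stack, mask, fit_config(noise_floor = sqrt(2) * sig),
                     echo_times = te7)
  bias_free <- abs(mean(free_b$t2[free_b$valid]) - 40)
  bias_fixed <- abs(mean(fixed_b$t2[fixed_b$valid]) - 40)
  expect_lt(bias_fixed, bias_free)
  expect_lt(bias_fixed, 0.5)
  # the background estimator recovers b = sqrt(2) sigma itself
  set.seed(78)
  bgstack <- array(sqrt(rnorm(6000, 0, sig)^2 + rnorm(6000, 0, sig)^2),
                   dim = c(10, 10, 10, 6))
  bhat <- estimate_noise_floor(bgstack, array(0L, dim = c(10, 10, 10)))
  expect_equal(bhat, sqrt(2) * sig, tolerance = 0.05)
})

test_that("fit_map recovers a uniform noiseless phantom and flags empty masks", {
  arr <- array(0, dim = c(6, 6, 2, 7))
  for (e in 1:7) arr[, , , e] <- 100 * exp(-te7[e] / 40)
  mask <- array(1L, dim = c(6, 6, 2))
  m <- fit_map(arr, mask, echo_times = te7)
  expect_true(all(m$valid))
  expect_equal(unname(as.vector(m$t2)), rep(40, 72), tolerance = 1e-6)

  empty <- fit_map(arr, array(0L, dim = c(6, 6, 2)), echo_times = te7)
  expect_false(any(empty$valid))

  expect_error(fit_map(arr, array(1L, dim = c(5, 6, 2)), echo_times = te7),
               class = "cartex_input_error")
})

test_that("non-physiologic decays are marked invalid or clamped per policy", {
  y <- rep(80, 7)  # no decay at all -> T2 at the upper bound
  f <- fit_pixel(y, te7, fit_config(fallback_policy = "mark_invalid"))
  expect_false(f$valid)
  f2 <- fit_pixel(y, te7, fit_config(fallback_policy = "clamp"))
  expect_true(f2$valid)
})

test_that("map fitting as tibble carries compartment labels", {
  cfg <- tiny_config()
  s <- sample_subjects(cfg)
  p <- draw_t2_parameters(s, cfg)
  sp <- p[p$subject_id == s$subject_id[1], ]
  f <- build_t2_field(sp, cfg, seed = 3)
  st <- render_echoes(f, cfg, seed = 3)
  m <- fit_map(st, f$labels)
  tb <- tibble::as_tibble(m)
  expect_setequal(unique(tb$compartment), compartment_codes())
  expect_gt(mean(tb$valid), 0.95)
})
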