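test_that("model specs derive their free-parameter counts", {
  expect_equal(n_par(heading_spec("CRW", "VM")), 1)
  expect_equal(n_par(heading_spec("CRW", "WC")), 1)
  expect_equal(n_par(heading_spec("CAR", "VM")), 3)
  expect_equal(n_par(heading_spec("CAR", "WC")), 3)
  expect_equal(n_par(heading_spec("CAR", "KJ")), 5)
  expect_equal(n_par(heading_spec("CAR", "KJ", "fixed_lambda", value = 1)), 4)
  expect_equal(n_par(heading_spec("CAR", "KJ", "fixed_alpha", value = 1)), 4)
  expect_equal(n_par(heading_spec("CAR", "VM", "focal_point", point = c(1, 2))), 2)
  expect_error(heading_spec("CAR", "VM", "fixed_lambda", value = 1), "KJ")
  expect_error(heading_spec("CRW", "VM", "focal_point", point = c(1, 2)), "CAR")
})

test_that("step_mean covers CRW, CAR, and focal-point geometries", {
  crw <- heading_spec("CRW", "VM")
  expect_equal(step_mean(0.7, crw, list(kappa = 2)), 0.7)
  car <- heading_spec("CAR", "VM")
  expect_equal(step_mean(0.7, car, list(alpha = -1, w = 0, kappa = 2)), -1)
  fp <- heading_spec("CAR", "VM", "focal_point", point = c(0, 100))
  expect_equal(step_mean(0.3, fp, list(w = 0, kappa = 2), location = c(0, 0)),
               pi / 2)  # bearing to a goal due north
  expect_error(step_mean(0.3, fp, list(w = 0, kappa = 2)), "location")
})

test_that("conditional log-likelihood: one-term case, KJ reduction, independent sum, rotation", {
  ser2 <- step_series(c(0.2, 0.9))
  expect_equal(heading_loglik(ser2, heading_spec("CRW", "VM"), list(kappa = 3)),
               dvonmises(0.7, 0, 3, log = TRUE))
  ser <- make_series(heading_spec("CAR", "VM"), list(alpha = 0, w = 0.5, kappa = 6),
                     300, seed = 1)
  pk <- list(alpha = 0.2, w = 0.6, kappa = 5, r = 0, lambda = 1.0)
  expect_equal(heading_loglik(ser, heading_spec("CAR", "KJ"), pk),
               heading_loglik(ser, heading_spec("CAR", "VM"), pk))
  # independent per-step summation on a 500-step asymmetric series
  serk <- make_series(heading_spec("CAR", "KJ"),
                      list(alpha = -pi / 8, w = 0.7, kappa = 6, r = 0.3,
                           lambda = 5 * pi / 8), 500, seed = 2)
  p <- list(alpha = -0.3, w = 0.65, kappa = 5.5, r = 0.25, lambda = 1.9)
  h <- serk$headings
  ll <- 0
  for (t in 2:length(h)) {
    mu <- attract(h[t - 1], p$alpha, p$w)
    ll <- ll + dkatojones(h[t], mu, p$kappa, p$r, wrap_angle(p$lambda - mu),
                          log = TRUE)
  }
  expect_equal(heading_loglik(serk, heading_spec("CAR", "KJ"), p), ll,
               tolerance = 1e-9)
  # global rotation of headings, alpha and lambda leaves the likelihood unchanged
  rot <- 1.234
  ser_r <- step_series(wrap_angle(serk$headings + rot), serk$speeds,
                       serk$time_unit)
  p_r <- p
  p_r$alpha <- wrap_angle(p$alpha + rot)
  p_r$lambda <- wrap_angle(p$lambda + rot)
  expect_equal(heading_loglik(ser_r, heading_spec("CAR", "KJ"), p_r),
               heading_loglik(serk, heading_spec("CAR", "KJ"), p),
               tolerance = 1e-9)
})

test_that("ML fitting recovers generating parameters and is optimal at the optimum", {
  ser <- make_series(heading_spec("CAR", "VM"), list(alpha = 0, w = 0.5, kappa = 6),
                     2000, seed = 5)
  f <- fit_heading(ser, heading_spec("CAR", "VM"), n_starts = 6, seed = 1)
  expect_lt(abs(wrap_angle(f$params$alpha)), 0.15)
  expect_lt(abs(f$params$w - 0.5), 0.08)
  expect_lt(abs(f$params$kappa - 6), 0.8)
  expect_equal(f$aic, -2 * f$loglik + 2 * f$k)
  f2 <- fit_heading(ser, heading_spec("CAR", "VM"), n_starts = 2, seed = 3,
                    init = f$params)
  expect_gte(f2$loglik, f$loglik - 1e-6)
  # free-alpha fits are reported on the canonical branch of the (alpha, w)
  # <-> (alpha + pi, 1/w) aliasing
  expect_lte(abs(f$params$w), 1)
  # CRW data fitted with CAR: the nested optimum sits at w = 1
  serc <- make_series(heading_spec("CRW", "VM"), list(kappa = 6), 2000, seed = 6)
  fc <- fit_heading(serc, heading_spec("CAR", "VM"), n_starts = 6, seed = 2)
  expect_lt(abs(fc$params$w - 1), 0.05)
  expect_error(fit_heading(step_series(runif(5, -1, 1)), heading_spec("CRW", "VM")),
               "at least 10")
})

test_that("maximised log-likelihoods respect the nesting hierarchy", {
  ser <- attr(simulate_trajectory(make_fixture("zigzag", n_steps = 800), seed = 9),
              "steps")
  f_crw <- fit_heading(ser, heading_spec("CRW", "VM"), n_starts = 4, seed = 1)
  f_vm <- fit_heading(ser, heading_spec("CAR", "VM"), n_starts = 4, seed = 2)
  f_kj <- fit_heading(ser, heading_spec("CAR", "KJ"), n_starts = 6, seed = 3)
  expect_gte(f_vm$loglik, f_crw$loglik - 1e-4)
  expect_gte(f_kj$loglik, f_vm$loglik - 1e-4)
  # CAR evaluated at w = 1 equals the CRW likelihood with the same kappa
  expect_equal(
    heading_loglik(ser, heading_spec("CAR", "VM"),
                   list(alpha = 0.4, w = 1, kappa = f_crw$params$kappa)),
    heading_loglik(ser, heading_spec("CRW", "VM"),
                   list(kappa = f_crw$params$kappa)))
})

test_that("AIC selection ranks candidates, prefers parsimony, and is deterministic", {
  ser <- make_series(heading_spec("CRW", "VM"), list(kappa = 6), 500, seed = 3)
  cands <- list(heading_spec("CRW", "VM"), heading_spec("CAR", "VM"))
  s1 <- select_heading(ser, cands, n_starts = 4, seed = 1)
  s2 <- select_heading(ser, cands, n_starts = 4, seed = 1)
  expect_identical(s1$table, s2$table)
  expect_true(all(diff(s1$table$aic) >= 0))
  expect_equal(s1$table$model[1], "CRW(VM)")  # AIC penalty beats the nested fit
})

test_that("residuals recover the generating innovations", {
  spec <- heading_spec("CAR", "KJ")
  truth <- list(alpha = -pi / 8, w = 0.7, kappa = 6, r = 0.3, lambda = 5 * pi / 8)
  ser <- make_series(spec, truth, 5000, seed = 4)
  res <- heading_residuals(ser, as_heading_fit(spec, truth))
  # at the true parameters the KJ residuals are the underlying VM(0, kappa) draws
  expect_gt(sampler_chisq_p(res, dvonmises, mu = 0, kappa = 6), 0.01)
  # with r = 0 the KJ residuals collapse to the symmetric-case residuals
  p0 <- list(alpha = 0.1, w = 0.6, kappa = 5, r = 0, lambda = 1)
  expect_equal(heading_residuals(ser, as_heading_fit(spec, p0)),
               heading_residuals(ser, as_heading_fit(heading_spec("CAR", "VM"), p0)))
  # CRW residuals are successive heading differences
  crw_fit <- as_heading_fit(heading_spec("CRW", "VM"), list(kappa = 6))
  expect_equal(heading_residuals(ser, crw_fit), wrap_angle(diff(ser$headings)))
})
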