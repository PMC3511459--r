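test_that("wrap_angle maps onto [-pi, pi) and respects periodicity", {
  expect_identical(wrap_angle(0), 0)
  expect_equal(wrap_angle(3 * pi), -pi)
  expect_equal(wrap_angle(-pi - 0.1), pi - 0.1)
  set.seed(1)
  th <- runif(50, -pi, pi)
  k <- sample(-3:3, 50, replace = TRUE)
  expect_equal(wrap_angle(th + 2 * pi * k), th)
  expect_true(all(wrap_angle(th) >= -pi & wrap_angle(th) < pi))
  expect_error(wrap_angle(Inf), "finite")
  expect_error(wrap_angle(NA_real_), "finite")
})

test_that("attraction map: special coefficients, fixed point, antipode continuity", {
  th <- seq(-pi, pi - 1e-9, length.out = 7)
  expect_equal(attract(th, 1.1, 1), th)            # w = 1: correlated random walk
  expect_equal(attract(th, 1.1, 0), rep(1.1, 7))   # w = 0: full collapse onto alpha
  expect_equal(attract(pi / 2, 0, 0.5), 2 * atan(0.5 * tan(pi / 4)))
  expect_equal(attract(pi / 2, 0, 0.5), 0.9272952, tolerance = 1e-6)
  expect_equal(attract(0.3, 0.3, -2.7), 0.3)       # alpha is always a fixed point
  for (w in c(0.5, -0.5, 2)) {
    near <- attract(0.7 + pi - 1e-9, 0.7, w)
    at <- attract(0.7 + pi, 0.7, w)
    expect_lt(abs(wrap_angle(near - at)), 1e-6)
  }
  # exact two-fold aliasing: attraction to alpha with strength w is
  # attraction to the antipode with strength 1/w
  g <- seq(-3, 3, length.out = 101)
  for (w in c(-2.5, -0.4, 0.3, 1.7)) {
    expect_lt(max(abs(wrap_angle(attract(g, 0.9, w) -
                                   attract(g, 0.9 + pi, 1 / w)))), 1e-10)
  }
})

test_that("attraction map is an orientation-consistent bijection with exact inverse", {
  g <- seq(-pi, pi - 1e-6, length.out = 256)
  for (w in c(-2, -0.5, 0.3, 1, 2.5)) {
    d <- wrap_angle(diff(attract(g, 0.4, w)))
    if (w > 0) expect_true(all(d > 0)) else expect_true(all(d < 0))
  }
  set.seed(2)
  for (i in 1:200) {
    y <- runif(1, -pi, pi); a <- runif(1, -pi, pi)
    w <- sample(c(-1, 1), 1) * runif(1, 0.02, 3)
    x <- attract_inverse(y, a, w)
    expect_lt(abs(wrap_angle(attract(x, a, w) - y)), 1e-10)
  }
  expect_equal(attract_inverse(g, 0.2, 1), g, tolerance = 1e-12)
  expect_error(attract_inverse(1, 0, 0), "not invertible")
})

test_that("densities normalise on the circle and match closed-form spot values", {
  # independent Bessel series for the von Mises normalising constant
  i0 <- function(x) sum((x^2 / 4)^(0:30) / factorial(0:30)^2)
  expect_lt(abs(dvonmises(0, 0, 1) - exp(1) / (2 * pi * i0(1))), 1e-10)
  expect_equal(round(dvonmises(0, 0, 1), 4), 0.3417)
  expect_equal(dwrappedcauchy(0, 0, 0.5), 1.5 / (2 * pi * 0.5))
  expect_equal(dwrappedcauchy(2.2, 1, 0), 1 / (2 * pi))  # r = 0: uniform
  expect_equal(dvonmises(0.9 + 0.3, 0.9, 2), dvonmises(0.9 - 0.3, 0.9, 2))
  set.seed(3)
  for (i in 1:5) {
    mu <- runif(1, -pi, pi); kap <- runif(1, 0.2, 20)
    r <- runif(1, 0, 0.9); nu <- runif(1, -pi, pi)
    for (f in list(function(x) dvonmises(x, mu, kap),
                   function(x) dwrappedcauchy(x, mu, r),
                   function(x) dkatojones(x, mu, kap, r, nu))) {
      expect_lt(abs(integrate(f, -pi, pi, abs.tol = 1e-10)$value - 1), 1e-6)
    }
  }
  expect_error(dvonmises(0, 0, -1), "positive")
  expect_error(dwrappedcauchy(0, 0, 1), "0, 1")
  expect_error(dkatojones(0, 0, 2, 1.2, 0), "0, 1")
})

test_that("Kato-Jones closed form agrees with the change-of-variables route", {
  g <- seq(-pi, pi - 1e-9, length.out = 41)
  # reduction: KJ(mu, kappa, 0, 0) is VM(mu, kappa), pointwise
  expect_lt(max(abs(dkatojones(g, 0.7, 3, 0, 0) - dvonmises(g, 0.7, 3))), 1e-12)
  # independent route: von Mises density of the back-transformed point times
  # a numerically differentiated jacobian of the inverse transformation
  dkj_cov <- function(y, mu, kappa, rho, nu, h = 1e-6) {
    x <- kj_untransform(y, mu, rho, nu)
    dj <- abs(wrap_angle(kj_untransform(y + h, mu, rho, nu) -
                           kj_untransform(y - h, mu, rho, nu))) / (2 * h)
    dvonmises(x, 0, kappa) * dj
  }
  set.seed(4)
  for (i in 1:30) {
    mu <- runif(1, -pi, pi); kap <- runif(1, 0.3, 8)
    r <- runif(1, 0, 0.9); nu <- runif(1, -pi, pi)
    expect_lt(max(abs(dkatojones(g, mu, kap, r, nu) - dkj_cov(g, mu, kap, r, nu))),
              1e-8)
  }
})

test_that("generating transform and its inverse compose to the identity", {
  g <- seq(-pi, pi - 1e-9, length.out = 33)
  expect_equal(kj_transform(g, 1.2, 0, 0), wrap_angle(g + 1.2))    # pure rotation
  expect_equal(kj_untransform(g, 1.2, 0, 0), wrap_angle(g - 1.2))
  set.seed(5)
  for (i in 1:50) {
    mu <- runif(1, -pi, pi); r <- runif(1, 0, 0.95); nu <- runif(1, -pi, pi)
    y <- runif(10, -pi, pi)
    rt <- kj_transform(kj_untransform(y, mu, r, nu), mu, r, nu)
    expect_lt(max(abs(wrap_angle(rt - y))), 1e-10)
  }
})

test_that("samplers agree with their densities and are reproducible from a seed", {
  set.seed(10)
  x <- rvonmises(1e5, 0, 6)
  expect_lt(abs(circ_mean_of(x)), 0.02)
  expect_gt(sampler_chisq_p(x, dvonmises, mu = 0, kappa = 6), 0.01)
  w <- rwrappedcauchy(3e4, 1, 0.4)
  expect_gt(sampler_chisq_p(w, dwrappedcauchy, mu = 1, rho = 0.4), 0.01)
  # r = 0 wrapped Cauchy is uniform: flat class counts
  u <- rwrappedcauchy(3e4, 0, 0)
  O <- hist(u, breaks = seq(-pi, pi, length.out = 25), plot = FALSE)$counts
  expect_true(all(abs(O - 1250) < 4 * sqrt(1250)))
  y <- sample_circular(1e5, "KJ", list(mu = 0.3, kappa = 4, rho = 0.5, nu = 2),
                       seed = 11)
  expect_gt(sampler_chisq_p(y, dkatojones, mu = 0.3, kappa = 4, rho = 0.5, nu = 2),
            0.01)
  # the KJ sampler IS the generating transformation of von Mises draws
  set.seed(77); a <- rkatojones(1000, 0.3, 4, 0.5, 2)
  set.seed(77); b <- kj_transform(rvonmises(1000, 0, 4), 0.3, 0.5, 2)
  expect_identical(a, b)
  expect_identical(
    sample_circular(100, "VM", list(kappa = 3), seed = 9),
    sample_circular(100, "VM", list(kappa = 3), seed = 9))
})

test_that("Kato-Jones summaries locate the mode and transformed quantiles", {
  # symmetric case: everything sits at mu
  s0 <- kj_summaries(0.8, 4, 0, 0)
  expect_equal(s0$mode, 0.8, tolerance = 1e-6)
  expect_equal(s0$median, 0.8)
  expect_equal(wrap_angle(s0$quartiles - 0.8), -wrap_angle(rev(s0$quartiles) - 0.8),
               tolerance = 1e-8)
  expect_false(s0$multimodal)
  # skewed case: mode between mu and mu + nu (shorter arc), median matches the
  # 50% point of the numerically integrated CDF
  s1 <- kj_summaries(0.5, 4, 0.4, 1.2)
  expect_gt(s1$mode, 0.5); expect_lt(s1$mode, 0.5 + 1.2)
  cdf_med <- uniroot(function(x)
    integrate(dkatojones, -pi, x, mu = 0.5, kappa = 4, rho = 0.4, nu = 1.2,
              abs.tol = 1e-12)$value - 0.5, c(-pi + 1e-9, pi - 1e-9),
    tol = 1e-12)$root
  expect_lt(abs(s1$median - cdf_med), 1e-4)
  # nu near pi with strong skew: bimodal shapes are detected
  expect_true(kj_summaries(0, 2, 0.75, 3.0)$multimodal)
})
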