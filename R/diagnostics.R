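#' Lag-1 autocorrelation of heading residuals
#'
#' Treats the (small-angle) circular residuals as linear white noise and
#' computes the sample lag-1 autocorrelation; `|rho1| > 1.96/sqrt(n)` is
#' flagged as significant departure from whiteness (the standard white-noise
#' band), indicating the time unit is finer than the scale at which the
#' animal controls its heading.
#'
#' @param residuals numeric vector of residual angles (length >= 20).
#' @return list with `rho1`, logical `significant`, and the `band` value
#'   `1.96/sqrt(n)`.
#' @export
lag1_autocorrelation <- function(residuals) {
  n <- length(residuals)
  if (n < 20) stop("need at least 20 residuals", call. = FALSE)
  x <- residuals - mean(residuals)
  c0 <- sum(x^2) / n
  if (c0 < 1e-14) stop("residuals have (numerically) zero variance", call. = FALSE)
  rho1 <- sum(x[-n] * x[-1]) / n / c0
  band <- 1.96 / sqrt(n)
  list(rho1 = rho1, significant = abs(rho1) > band, band = band)
}

## simulate n_sim heading (and optionally position) series from a fitted
## heading model, starting from the observed initial conditions
sim_from_fit <- function(series, fit, n_sim, speed_fit = NULL) {
  h <- series$headings
  v0 <- series$speeds[1]
  start <- if (!is.null(series$fixes)) series$fixes[1, ] else c(0, 0)
  needs_speed <- fit$spec$constraint == "focal_point" || !is.null(speed_fit)
  if (needs_speed && (is.na(v0) || is.null(speed_fit)))
    stop("this computation needs observed speeds and a fitted speed model",
         call. = FALSE)
  sim_paths(fit$spec, fit$params, length(h), h[1],
            v0 = if (is.na(v0)) 1 else v0, n_sim = n_sim,
            speed_params = if (needs_speed) speed_fit$params,
            start = start, time_unit = series$time_unit)
}

#' Heading-distribution goodness of fit
#'
#' Parametric-bootstrap test of whether the fitted model reproduces the
#' observed marginal distribution of headings. Starting at the observed first
#' heading, `n_sim` heading series of the observed length are simulated from
#' the fitted model; the circle is divided into 24 classes; `E_d` is the mean
#' simulated count in class `d` and `O_d` the observed count. The statistic
#' `sum((E_d - O_d)^2 / E_d)` over classes with `E_d >= 3` is referred to a
#' chi-square distribution with (included classes - 1) degrees of freedom.
#' A Monte-Carlo p-value (the rank of the observed statistic among the
#' simulated series' own statistics) is reported alongside, and 95% envelopes
#' are the 2.5/97.5 percentiles of the simulated class counts.
#'
#' @param series the observed [step_series()].
#' @param fit a [fit_heading()] result.
#' @param n_sim number of simulated series (>= 100; default 1000).
#' @param seed integer seed.
#' @param speed_fit a [fit_speed()] result; required only when the heading
#'   model is a focal-point model (whose simulation needs positions).
#' @return an object of class `gof_report` with `chi2`, `df`, `pvalue`,
#'   `pvalue_mc`, `bins` (class edges), `observed`, `expected`, `envelopes`,
#'   and `excluded` (classes with `E_d < 3`).
#' @export
heading_gof <- function(series, fit, n_sim = 1000, seed = 1L, speed_fit = NULL) {
  stopifnot(n_sim >= 100)
  set.seed(seed)
  h <- series$headings
  sims <- sim_from_fit(series, fit, n_sim, speed_fit)
  br <- seq(-pi, pi, length.out = 25)
  bi <- matrix(findInterval(sims$headings, br, rightmost.closed = TRUE),
               nrow = nrow(sims$headings))
  bi[bi == 25] <- 24
  S <- vapply(seq_len(n_sim), function(k) tabulate(bi[, k], 24), integer(24))
  E <- rowMeans(S)
  Ob <- findInterval(h, br, rightmost.closed = TRUE)
  Ob[Ob == 25] <- 24
  O <- tabulate(Ob, 24)
  incl <- E >= 3
  if (sum(incl) < 3)
    stop("fewer than 3 classes with expected count >= 3: test undefined",
         call. = FALSE)
  chi2 <- sum((E[incl] - O[incl])^2 / E[incl])
  df <- sum(incl) - 1
  chi2_k <- colSums((S[incl, , drop = FALSE] - E[incl])^2 / E[incl])
  structure(list(
    chi2 = chi2, df = df,
    pvalue = stats::pchisq(chi2, df, lower.tail = FALSE),
    pvalue_mc = (1 + sum(chi2_k >= chi2)) / (n_sim + 1),
    bins = br, observed = O, expected = E,
    envelopes = t(apply(S, 1, stats::quantile, probs = c(0.025, 0.975))),
    excluded = which(!incl)
  ), class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf("heading GOF: chi2 = %.3f (df = %d), p = %.4f (MC p = %.4f), %d class(es) excluded\n",
              x$chi2, x$df, x$pvalue, x$pvalue_mc, length(x$excluded)))
  invisible(x)
}

## tail probability of the observed endpoint under the bivariate-normal
## approximation: mass outside the density contour through the observation
p_final_location <- function(d2) exp(-d2 / 2)

#' Final-location goodness of fit
#'
#' Simulates `n_sim` full trajectories (headings and speeds) from the fitted
#' models, starting at the observed first fix, heading, and speed. The
#' simulated final locations are summarised by their mean `M` and covariance
#' `Sigma`; assuming the endpoints are approximately bivariate normal, the
#' probability of an endpoint at least as extreme as the observed one (the
#' mass outside the density contour through it) is `P_FL = exp(-D^2/2)` with
#' `D^2` the Mahalanobis distance. `P_FL < 0.05` rejects the model.
#'
#' @inheritParams heading_gof
#' @param speed_fit a [fit_speed()] result (required).
#' @return an object of class `final_location_report` with `M`, `Sigma`,
#'   `observed`, `D2`, `p_fl`.
#' @export
final_location_gof <- function(series, fit, speed_fit, n_sim = 1000, seed = 1L) {
  stopifnot(n_sim >= 100, inherits(speed_fit, "speed_fit"))
  if (is.null(series$fixes))
    stop("series carries no fix locations", call. = FALSE)
  set.seed(seed)
  sims <- sim_from_fit(series, fit, n_sim, speed_fit)
  m <- length(series$headings)
  finals <- cbind(sims$x[m + 1, ], sims$y[m + 1, ])
  M <- colMeans(finals)
  Sigma <- stats::cov(finals)
  if (!is.finite(determinant(Sigma)$modulus) ||
      min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) < 1e-10)
    stop("degenerate endpoint covariance", call. = FALSE)
  obs <- series$fixes[m + 1, ]
  d2 <- stats::mahalanobis(obs, M, Sigma)
  structure(list(M = M, Sigma = Sigma, observed = obs, D2 = d2,
                 p_fl = p_final_location(d2)),
            class = "final_location_report")
}

#' @export
print.final_location_report <- function(x, ...) {
  cat(sprintf("final-location GOF: D2 = %.3f, P_FL = %.4f (%s)\n",
              x$D2, x$p_fl, if (x$p_fl < 0.05) "rejected" else "not rejected"))
  invisible(x)
}

#' Choose the time unit by residual whiteness and goodness of fit
#'
#' Resamples the trajectory at each candidate time unit, selects among the
#' candidate heading models by AIC, and accepts the smallest time unit at
#' which some model's residuals show no significant lag-1 autocorrelation and
#' the heading-distribution test is not rejected. At each time unit the
#' accepted model is the AIC-smallest one passing both checks. If no time
#' unit qualifies, `selected` is `NA` and the per-unit table is still
#' returned.
#'
#' @param traj a [trajectory()].
#' @param time_units candidate time units, seconds (default 1..10 times the
#'   sampling interval's unit).
#' @param specs list of candidate [heading_spec()]s.
#' @param n_starts,seed passed to the fitting routines.
#' @param n_sim simulations for the GOF test at each unit.
#' @param gof_level rejection level for the heading GOF (default 0.05).
#' @return list with `selected` (time unit or `NA`), `model` (spec string or
#'   `NA`), `table` (per-unit diagnostics), and `fits` (accepted fit per unit,
#'   or `NULL`).
#' @export
choose_time_unit <- function(traj, time_units = 1:10, specs,
                             n_starts = 6, seed = 1L, n_sim = 200,
                             gof_level = 0.05) {
  rows <- list(); fits <- list()
  for (i in seq_along(time_units)) {
    T <- time_units[i]
    row <- data.frame(time_unit = T, model = NA_character_, aic = NA_real_,
                      rho1 = NA_real_, ac_significant = NA, gof_p = NA_real_,
                      ok = FALSE)
    fits[[i]] <- NULL
    res <- tryCatch({
      series <- derive_steps(traj, T)
      sel <- select_heading(series, specs, n_starts = n_starts,
                            seed = seed + 97L * i)
      accepted <- NULL
      for (f in sel$fits) {
        if (!inherits(f, "heading_fit")) next
        r <- heading_residuals(series, f)
        ac <- lag1_autocorrelation(r)
        g <- heading_gof(series, f, n_sim = n_sim, seed = seed + 131L * i)
        if (is.null(accepted)) {   # record diagnostics of the AIC-best model
          row$model <- format_model_spec(f$spec)
          row$aic <- f$aic; row$rho1 <- ac$rho1
          row$ac_significant <- ac$significant; row$gof_p <- g$pvalue
        }
        if (!ac$significant && g$pvalue >= gof_level) {
          accepted <- f
          row$model <- format_model_spec(f$spec)
          row$aic <- f$aic; row$rho1 <- ac$rho1
          row$ac_significant <- ac$significant; row$gof_p <- g$pvalue
          row$ok <- TRUE
          break
        }
      }
      accepted
    }, error = function(e) NULL)
    fits[[i]] <- res
    rows[[i]] <- row
  }
  tab <- do.call(rbind, rows)
  sel_i <- which(tab$ok)[1]
  list(selected = if (!is.na(sel_i)) tab$time_unit[sel_i] else NA,
       model = if (!is.na(sel_i)) tab$model[sel_i] else NA,
       table = tab, fits = fits)
}

#' Bootstrap distribution of the maximum-likelihood estimates
#'
#' Parametric bootstrap: `n_boot` heading series of the original length are
#' simulated from the fitted model (starting at the observed first heading)
#' and refitted; the spread of the refitted estimates approximates the
#' sampling distribution of the MLEs. Refits start from the fitted values
#' plus a few stratified random starts. Angular parameters are summarised on
#' wrapped deviations from their circular mean. Right skew of the
#' concentration estimate is expected (and flagged) when the true
#' concentration is large, since the von Mises shape is insensitive to kappa
#' there.
#'
#' @inheritParams heading_gof
#' @param n_boot number of bootstrap replicates (default 200).
#' @param n_starts starts per refit (the fitted values are always one start).
#' @return an object of class `boot_mles`: `estimates` (replicate x parameter
#'   data frame), `sd`, `skewness`, `center` (the fitted values), and
#'   `n_failed`.
#' @export
bootstrap_mles <- function(series, fit, n_boot = 200, seed = 1L,
                           n_starts = 4, speed_fit = NULL) {
  set.seed(seed)
  sims <- sim_from_fit(series, fit, n_boot, speed_fit)
  nm <- free_names(fit$spec)
  est <- matrix(NA_real_, n_boot, length(nm), dimnames = list(NULL, nm))
  nfail <- 0L
  for (b in seq_len(n_boot)) {
    bser <- step_series(sims$headings[, b], series$speeds,
                        time_unit = series$time_unit,
                        fixes = if (!is.null(series$fixes))
                          cbind(sims$x[, b], sims$y[, b]))
    rf <- tryCatch(
      fit_heading(bser, fit$spec, n_starts = n_starts, seed = seed + b,
                  init = fit$params),
      error = function(e) NULL)
    if (is.null(rf)) { nfail <- nfail + 1L; next }
    est[b, ] <- unlist(rf$params)[nm]
  }
  est <- est[stats::complete.cases(est), , drop = FALSE]
  angular <- nm %in% c("alpha", "lambda")
  dev <- est
  for (j in seq_along(nm)) {
    if (angular[j]) dev[, j] <- wrap_angle(est[, j] - circ_mean(est[, j]))
    else dev[, j] <- est[, j] - mean(est[, j])
  }
  sds <- apply(dev, 2, stats::sd)
  skew <- apply(dev, 2, function(z) mean(z^3) / stats::sd(z)^3)
  structure(list(estimates = as.data.frame(est), sd = sds, skewness = skew,
                 center = unlist(fit$params)[nm], n_failed = nfail),
            class = "boot_mles")
}

#' @export
print.boot_mles <- function(x, ...) {
  cat(sprintf("bootstrap MLE distribution (%d replicates kept, %d failed)\n",
              nrow(x$estimates), x$n_failed))
  print(data.frame(center = x$center, sd = x$sd, skewness = x$skewness))
  invisible(x)
}
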