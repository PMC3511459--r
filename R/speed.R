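#' Conditional mean speed
#'
#' The speed auto-regression
#' \deqn{v_t = a v_{t-1} + b\cos(\theta_t - c) + d\cos(\theta_t - \theta_{t-1})
#'   + c_0 + \eta_t, \qquad \eta_t \sim N(0, \sigma^2),}
#' whose mean, as a function of the current heading alone, peaks at
#' `theta = c` — interpreted as the leeward direction for a flying bird
#' (tailwind fastest, headwind slowest). The angular-velocity covariate
#' enters through the cosine of the turn.
#'
#' @param v_prev previous speed(s), m/s.
#' @param theta current heading(s), radians.
#' @param theta_prev previous heading(s), radians.
#' @param params named list with `a`, `b`, `c`, `d`, `c0` (coefficients; any
#'   excluded covariate has coefficient 0) and `sigma2`.
#' @return conditional mean speed(s), m/s.
#' @export
predict_speed <- function(v_prev, theta, theta_prev, params) {
  params$a * v_prev + params$b * cos(theta - params$c) +
    params$d * cos(theta - theta_prev) + params$c0
}

speed_covariates <- c("previous_speed", "heading_anisotropy", "angular_velocity")

#' Fit the speed auto-regression by conditional maximum likelihood
#'
#' Gaussian conditional ML (conditioning on the first heading and speed),
#' which is ordinary least squares in the linear reparameterisation
#' `b*cos(c) , b*sin(c)` of the heading-anisotropy term; the amplitude/angle
#' pair is recovered afterwards with `b > 0`, removing the
#' `(b, c) <-> (-b, c + pi)` aliasing. `sigma2` is the mean squared residual
#' (the ML estimate) and counts as a parameter in the AIC.
#'
#' The untruncated Gaussian likelihood is used: in the cruising regime the
#' probability mass below zero speed is negligible and the truncated-model
#' MLEs are essentially identical. Truncation is enforced at simulation time
#' only ([simulate_speed()]).
#'
#' @param series a [step_series()] with speeds.
#' @param covariates subset of `"previous_speed"`, `"heading_anisotropy"`,
#'   `"angular_velocity"` to include (the intercept is always present).
#' @return an object of class `speed_fit`: `params` (a, b, c, d, c0, sigma2),
#'   `se` (delta-method standard errors, `b`/`c` included), `loglik`, `aic`,
#'   `k`, `covariates`, `n`.
#' @export
fit_speed <- function(series, covariates = speed_covariates) {
  stopifnot(inherits(series, "step_series"))
  covariates <- if (length(covariates))
    match.arg(covariates, speed_covariates, several.ok = TRUE) else character(0)
  h <- series$headings; v <- series$speeds
  m <- length(h)
  if (m < 10) stop("need at least 10 steps to fit the speed model", call. = FALSE)
  if (anyNA(h) || anyNA(v)) stop("series contains NA headings or speeds", call. = FALSE)
  resp <- v[-1]
  df <- data.frame(resp = resp)
  if ("previous_speed" %in% covariates) df$vprev <- v[-m]
  if ("heading_anisotropy" %in% covariates) {
    df$costh <- cos(h[-1]); df$sinth <- sin(h[-1])
  }
  if ("angular_velocity" %in% covariates) df$costurn <- cos(h[-1] - h[-m])
  fit <- stats::lm(resp ~ ., data = df)
  if (fit$rank < ncol(stats::model.matrix(fit)))
    stop("rank-deficient speed design (e.g. constant headings with the anisotropy term)",
         call. = FALSE)
  cf <- stats::coef(fit)
  vc <- stats::vcov(fit)
  res <- stats::residuals(fit)
  sigma2 <- mean(res^2)
  p <- list(a = 0, b = 0, c = 0, d = 0, c0 = unname(cf["(Intercept)"]),
            sigma2 = sigma2)
  se <- list(c0 = sqrt(vc["(Intercept)", "(Intercept)"]))
  if ("previous_speed" %in% covariates) {
    p$a <- unname(cf["vprev"]); se$a <- sqrt(vc["vprev", "vprev"])
  }
  if ("angular_velocity" %in% covariates) {
    p$d <- unname(cf["costurn"]); se$d <- sqrt(vc["costurn", "costurn"])
  }
  if ("heading_anisotropy" %in% covariates) {
    bc <- unname(cf["costh"]); bs <- unname(cf["sinth"])
    b <- sqrt(bc^2 + bs^2)
    p$b <- b
    p$c <- atan2(bs, bc)
    ## delta method for (b, c) from the (b cos c, b sin c) covariance block
    vb <- vc[c("costh", "sinth"), c("costh", "sinth")]
    gb <- c(bc, bs) / b
    gc <- c(-bs, bc) / b^2
    se$b <- sqrt(drop(gb %*% vb %*% gb))
    se$c <- sqrt(drop(gc %*% vb %*% gc))
  }
  ll <- sum(stats::dnorm(res, 0, sqrt(sigma2), log = TRUE))
  k <- fit$rank + 1L
  structure(list(params = p, se = se, loglik = ll, aic = -2 * ll + 2 * k,
                 k = k, covariates = covariates, n = length(resp)),
            class = "speed_fit")
}

#' @export
print.speed_fit <- function(x, ...) {
  cat(sprintf("speed fit [%s]: loglik %.3f, AIC %.3f\n",
              paste(x$covariates, collapse = "+"), x$loglik, x$aic))
  p <- unlist(x$params)
  cat(paste(sprintf("  %s = %.4f", names(p), p), collapse = "\n"), "\n")
  invisible(x)
}

#' Select speed-model covariates by AIC
#'
#' Fits all 8 subsets of the three covariates and ranks them by AIC.
#'
#' @param series a [step_series()] with speeds.
#' @return list with `best` (the winning [fit_speed()]), `table` (AIC table)
#'   and `fits`.
#' @export
select_speed <- function(series) {
  subsets <- list()
  for (i in 0:7) {
    inc <- speed_covariates[bitwAnd(i, c(1, 2, 4)) > 0]
    subsets[[i + 1]] <- inc
  }
  fits <- lapply(subsets, function(s)
    tryCatch(fit_speed(series, covariates = if (length(s)) s else character(0)),
             error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  aic <- ifelse(ok, vapply(fits, function(f) f$aic %||% Inf, numeric(1)), Inf)
  k <- ifelse(ok, vapply(fits, function(f) f$k %||% NA, numeric(1)), NA)
  ord <- order(aic, k)
  tab <- data.frame(
    covariates = vapply(subsets, function(s)
      if (length(s)) paste(s, collapse = "+") else "(intercept only)",
      character(1))[ord],
    k = k[ord], aic = aic[ord])
  list(best = fits[[ord[1]]], table = tab, fits = fits[ord])
}

#' Simulate positive speeds along a heading sequence
#'
#' Each speed is drawn from the Gaussian step of the fitted auto-regression
#' and redrawn while non-positive (truncation by redraw, as in cruising-flight
#' regimes where the redraw almost never triggers). More than 1000 consecutive
#' redraws at one step signals a degenerate regime.
#'
#' @param theta headings, radians (the first element is the heading already
#'   taken with speed `v0`).
#' @param v0 initial speed, `> 0`.
#' @param params speed parameters as in [predict_speed()] (with `sigma2`).
#' @param seed optional integer seed.
#' @return numeric vector of speeds the same length as `theta` (first element
#'   `v0`), with attribute `redraws` (total number of rejected draws).
#' @export
simulate_speed <- function(theta, v0, params, seed = NULL) {
  stopifnot(v0 > 0)
  if (!is.null(seed)) set.seed(seed)
  m <- length(theta)
  v <- numeric(m)
  v[1] <- v0
  sd <- sqrt(params$sigma2)
  redraws <- 0L
  for (t in seq_len(m)[-1]) {
    mu <- predict_speed(v[t - 1], theta[t], theta[t - 1], params)
    tries <- 0L
    repeat {
      cand <- mu + sd * stats::rnorm(1)
      if (cand > 0) break
      tries <- tries + 1L
      if (tries > 1000)
        stop("degenerate speed regime: > 1000 consecutive non-positive draws",
             call. = FALSE)
    }
    redraws <- redraws + tries
    v[t] <- cand
  }
  attr(v, "redraws") <- redraws
  v
}
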