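#' Conditional mean heading for the next step
#'
#' Returns `mu_t`, the attraction-map image of the previous heading under the
#' given model: the previous heading itself for CRW; `M(theta_prev; alpha, w)`
#' for CAR, where `alpha` is the free focal direction, the fixed one, or — for
#' focal-point models — the bearing from the current location to the focal
#' point.
#'
#' @param theta_prev previous heading(s), radians.
#' @param spec a [heading_spec()].
#' @param params named list of parameter values (the free parameters of
#'   `spec`; see [heading_spec()]).
#' @param location current location(s) as a length-2 vector or an `n x 2`
#'   matrix; required iff the spec uses a focal point.
#' @export
step_mean <- function(theta_prev, spec, params, location = NULL) {
  if (spec$family == "CRW") return(wrap_angle(theta_prev))
  alpha <- switch(spec$constraint,
    fixed_alpha = spec$value,
    focal_point = {
      if (is.null(location))
        stop("focal_point model needs the current location", call. = FALSE)
      loc <- if (is.matrix(location)) location else matrix(location, ncol = 2)
      atan2(spec$point[2] - loc[, 2], spec$point[1] - loc[, 1])
    },
    params$alpha
  )
  if (is.null(alpha)) stop("missing 'alpha'", call. = FALSE)
  attract(theta_prev, alpha, params$w)
}

## resolve lambda for KJ specs (fixed or free)
resolve_lambda <- function(spec, params) {
  if (spec$constraint == "fixed_lambda") spec$value else params$lambda
}

## location rows used when evaluating steps t = 2..m (the fix at which each
## step begins)
step_locations <- function(series, locations) {
  loc <- if (!is.null(locations)) as.matrix(locations) else series$fixes
  if (is.null(loc))
    stop("focal_point model needs fix locations (see step_series())", call. = FALSE)
  m <- length(series$headings)
  loc[2:m, , drop = FALSE]
}

#' Conditional log-likelihood of a heading series
#'
#' The sum over steps `t = 2..n` of the log density of heading `t` given
#' heading `t - 1` (conditioning on the first heading, which contributes no
#' term). For VM/WC noise the per-step density is `f(theta_t - mu_t; 0, .)`;
#' for KJ noise it is the Kato-Jones density with rotation `mu_t` and
#' attraction direction `nu_t = lambda - mu_t`, so that the noise is skewed
#' toward the external forcing direction `lambda` regardless of where the
#' animal is currently headed.
#'
#' @inheritParams step_mean
#' @param series a [step_series()] with at least 2 headings and no `NA`.
#' @param locations optional `(n_steps + 1) x 2` fix matrix overriding the one
#'   stored in `series` (focal-point models only).
#' @return the log-likelihood (scalar).
#' @export
heading_loglik <- function(series, spec, params, locations = NULL) {
  stopifnot(inherits(series, "step_series"))
  h <- series$headings
  m <- length(h)
  if (m < 2) stop("need at least 2 headings", call. = FALSE)
  if (anyNA(h)) stop("series contains undefined (NA) headings", call. = FALSE)
  th_prev <- h[-m]
  th <- h[-1]
  loc <- if (spec$constraint == "focal_point") step_locations(series, locations)
  mu <- step_mean(th_prev, spec, params, location = loc)
  switch(spec$noise,
    VM = sum(dvonmises(wrap_angle(th - mu), 0, params$kappa, log = TRUE)),
    WC = sum(dwrappedcauchy(wrap_angle(th - mu), 0, params$r, log = TRUE)),
    KJ = {
      lambda <- resolve_lambda(spec, params)
      nu <- wrap_angle(lambda - mu)
      sum(dkatojones(th, mu, params$kappa, params$r, nu, log = TRUE))
    }
  )
}

## ---- parameter transforms for unconstrained optimisation ----------------
## kappa on log scale, r on logit scale, angles and w raw (angles are
## periodic, so the optimiser can roam; values are wrapped on the way out)

par_to_free <- function(params, spec) {
  nm <- free_names(spec)
  vapply(nm, function(p) switch(p,
    kappa = log(params$kappa),
    r = stats::qlogis(min(max(params$r, 1e-6), 1 - 1e-6)),
    params[[p]]), numeric(1))
}

free_to_par <- function(v, spec) {
  nm <- free_names(spec)
  out <- list()
  for (i in seq_along(nm)) {
    vi <- unname(v[i])
    out[[nm[i]]] <- switch(nm[i],
      kappa = exp(vi),
      r = stats::plogis(vi),
      alpha = wrap_angle(vi),
      lambda = wrap_angle(vi),
      vi)
  }
  out
}

## stratified start design: coarse circular grid for angles, fixed brackets
## for w, kappa, r (the literature reports multi-start but not the design)
stratified_starts <- function(spec, n, series) {
  h <- series$headings
  am <- circ_mean(h)
  grid_a <- wrap_angle(am + seq(0, 2 * pi, length.out = 5)[-5])
  ws <- c(-0.5, 0.3, 0.7, 0.95)
  ks <- c(1, 10)
  rs <- c(0.1, 0.5)
  lapply(seq_len(n), function(i) {
    list(alpha = sample(grid_a, 1),
         w = sample(ws, 1),
         kappa = sample(ks, 1),
         r = sample(rs, 1),
         lambda = wrap_angle(sample(grid_a, 1) + stats::runif(1, -0.5, 0.5)))
  })
}

## warm starts from cheap moment estimates and (for KJ) a nested
## symmetric-noise prefit, so that richer families always start at least as
## well as the models they nest
warm_starts <- function(spec, series, seed, locations) {
  h <- series$headings
  m <- length(h)
  am <- circ_mean(h)
  k_diff <- est_kappa(wrap_angle(diff(h)))
  k_dev <- est_kappa(wrap_angle(h - am))
  r_of_k <- function(k) min(max(1 - 1 / (1 + k), 0.05), 0.9)
  if (spec$noise %in% c("VM", "WC")) {
    base <- list(
      list(alpha = am, w = 0.5, kappa = k_diff, r = r_of_k(k_diff)),
      list(alpha = am, w = 1, kappa = k_diff, r = r_of_k(k_diff)),
      list(alpha = am, w = 0, kappa = k_dev, r = r_of_k(k_dev))
    )
    if (spec$family == "CRW") base <- base[1]
    return(base)
  }
  ## KJ: prefit the symmetric analogue (same family/constraint where it
  ## exists) and seed lambda on a half-circle grid around its focal direction
  vm_spec <- heading_spec(spec$family, "VM",
                          constraint = if (spec$constraint %in%
                                           c("fixed_alpha", "focal_point"))
                            spec$constraint else "none",
                          value = spec$value, point = spec$point)
  pre <- tryCatch(
    fit_heading(series, vm_spec, n_starts = 3, seed = seed + 1000,
                locations = locations),
    error = function(e) NULL)
  if (is.null(pre)) {
    anchor <- list(alpha = am, w = 0.5, kappa = k_diff)
  } else anchor <- pre$params
  lam0 <- if (!is.null(anchor$alpha)) anchor$alpha else am
  lams <- wrap_angle(lam0 + c(0.3, pi / 2, -pi / 2, pi))
  lapply(lams, function(l)
    list(alpha = anchor$alpha %||% am, w = anchor$w %||% 1,
         kappa = anchor$kappa %||% k_diff, r = 0.08, lambda = l))
}

#' Fit a heading model by conditional maximum likelihood
#'
#' Maximizes [heading_loglik()] over the model's free parameters with the
#' quasi-Newton method (`stats::optim`, BFGS) on an unconstrained scale
#' (`log kappa`, `logit r`, raw angles and `w`). Several starts are used: warm
#' starts from moment estimates (and, for KJ noise, from a nested
#' symmetric-noise prefit) plus a stratified random design; the best converged
#' start is kept. Deterministic given `seed`.
#'
#' @inheritParams heading_loglik
#' @param n_starts number of optimisation starts (default 8).
#' @param seed integer seed controlling the start design.
#' @param init optional named list of parameter values used as an additional
#'   first start (e.g. the truth in simulation studies, or a previous fit).
#' @return an object of class `heading_fit`: a list with `spec`, `params`
#'   (named list on the natural scale), `loglik`, `aic` (`-2 loglik + 2 k`),
#'   `k`, `n_steps`, and a `starts` data frame recording each start's
#'   converged objective, convergence code and gradient norm.
#' @export
fit_heading <- function(series, spec, n_starts = 8, seed = 1L,
                        locations = NULL, init = NULL) {
  stopifnot(inherits(series, "step_series"), inherits(spec, "heading_spec"))
  h <- series$headings
  if (length(h) < 10)
    stop("need at least 10 headings to fit a heading model", call. = FALSE)
  if (anyNA(h))
    stop("series contains undefined (NA) headings; drop or re-derive steps",
         call. = FALSE)
  nm <- free_names(spec)
  negll <- function(v) {
    p <- free_to_par(v, spec)
    ll <- tryCatch(heading_loglik(series, spec, p, locations),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  set.seed(seed)
  starts <- list()
  if (!is.null(init)) starts <- c(starts, list(init))
  starts <- c(starts, warm_starts(spec, series, seed, locations))
  need <- n_starts - length(starts)
  if (need > 0) starts <- c(starts, stratified_starts(spec, need, series))
  runs <- lapply(starts, function(st) {
    v0 <- par_to_free(st, spec)
    res <- tryCatch(
      stats::optim(v0, negll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) return(list(ok = FALSE, value = Inf))
    gn <- grad_norm(negll, res$par)
    list(ok = res$convergence == 0 && is.finite(res$value) && res$value < 1e10,
         value = res$value, par = res$par, convergence = res$convergence,
         gnorm = gn, start = v0)
  })
  vals <- vapply(runs, function(r) r$value, numeric(1))
  ok <- vapply(runs, function(r) isTRUE(r$ok), logical(1))
  rec <- data.frame(
    start = seq_along(runs),
    loglik = -vals,
    convergence = vapply(runs, function(r) as.numeric(r$convergence %||% NA_real_),
                         numeric(1)),
    grad_norm = vapply(runs, function(r) as.numeric(r$gnorm %||% NA_real_),
                       numeric(1)),
    converged = ok & vapply(runs, function(r) isTRUE((r$gnorm %||% Inf) < 1e-4),
                            logical(1))
  )
  if (!any(ok))
    stop(errorCondition("no optimisation start converged",
                        class = c("circmove_optim_failure", "error", "condition"),
                        starts = rec))
  best <- which.min(ifelse(ok, vals, Inf))
  params <- canonicalize_params(free_to_par(runs[[best]]$par, spec), spec)
  ll <- -vals[best]
  k <- length(nm)
  structure(list(spec = spec, params = params, loglik = ll,
                 aic = -2 * ll + 2 * k, k = k,
                 n_steps = length(h), starts = rec),
            class = "heading_fit")
}

## The attraction map carries an exact two-fold aliasing: it has fixed points
## at both alpha and its antipode, and M(theta; alpha, w) == M(theta;
## alpha + pi, 1/w) for every w != 0, so (alpha, w) and (alpha + pi, 1/w)
## parameterise the identical model and likelihood. When alpha is a free
## parameter the fit is reported in the canonical representation |w| <= 1
## (alpha the attracting fixed point). With alpha fixed (known focal
## direction or focal point) the two branches are genuinely different models
## and w is returned as estimated.
canonicalize_params <- function(params, spec) {
  if (!is.null(params$w) && !is.null(params$alpha) && abs(params$w) > 1) {
    params$alpha <- wrap_angle(params$alpha + pi)
    params$w <- 1 / params$w
  }
  params
}

## finite-difference gradient norm (convergence screen for each start)
grad_norm <- function(f, x, h = 1e-5) {
  g <- vapply(seq_along(x), function(i) {
    e <- rep(0, length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
  sqrt(sum(g^2))
}

#' @export
print.heading_fit <- function(x, ...) {
  cat(sprintf("%s fit: loglik %.3f, AIC %.3f (k = %d, %d steps)\n",
              format_model_spec(x$spec), x$loglik, x$aic, x$k, x$n_steps))
  p <- unlist(x$params)
  cat(paste(sprintf("  %s = %.4f", names(p), p), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
logLik.heading_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n_steps - 1,
            class = "logLik")
}

#' Fit several heading models and rank them by AIC
#'
#' Fits every candidate and returns the results sorted by ascending AIC, with
#' ties broken by fewer parameters and then by declaration order. A candidate
#' whose optimisation fails is retained as a flagged entry rather than
#' aborting the selection.
#'
#' @inheritParams fit_heading
#' @param specs list of [heading_spec()] candidates (at least 2).
#' @return an object of class `heading_selection`: list with `fits` (in AIC
#'   order), `table` (summary data frame) and `failed` (character vector of
#'   failed candidates).
#' @export
select_heading <- function(series, specs, n_starts = 8, seed = 1L,
                           locations = NULL) {
  stopifnot(length(specs) >= 2)
  fits <- lapply(seq_along(specs), function(i)
    tryCatch(fit_heading(series, specs[[i]], n_starts = n_starts,
                         seed = seed + i, locations = locations),
             error = function(e) structure(list(spec = specs[[i]],
                                                error = conditionMessage(e)),
                                           class = "heading_fit_failure")))
  ok <- !vapply(fits, inherits, logical(1), "heading_fit_failure")
  aic <- ifelse(ok, vapply(fits, function(f) f$aic %||% Inf, numeric(1)), Inf)
  k <- ifelse(ok, vapply(fits, function(f) f$k %||% NA_integer_, numeric(1)), NA)
  ord <- order(aic, k, seq_along(fits))
  tab <- data.frame(
    model = vapply(specs, format_model_spec, character(1))[ord],
    k = k[ord],
    loglik = ifelse(ok, vapply(fits, function(f) f$loglik %||% NA_real_,
                               numeric(1)), NA_real_)[ord],
    aic = aic[ord],
    ok = ok[ord]
  )
  tab$delta_aic <- tab$aic - min(tab$aic)
  structure(list(fits = fits[ord], table = tab,
                 failed = tab$model[!tab$ok]),
            class = "heading_selection")
}

#' @export
print.heading_selection <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Residuals of a fitted heading model
#'
#' For VM/WC noise the residual at step `t` is the wrapped difference
#' `theta_t - mu_t`; for KJ noise it is the inverse generating transformation
#' applied to `theta_t` (rotation `mu_t`, attraction direction `nu_t`), which
#' recovers the underlying VM(0, kappa) innovation. White residuals (no lag-1
#' autocorrelation) indicate the time unit is coarse enough for the i.i.d.
#' noise assumption.
#'
#' @inheritParams heading_loglik
#' @param fit a [fit_heading()] result.
#' @return numeric vector of `n_steps - 1` residual angles.
#' @export
heading_residuals <- function(series, fit, locations = NULL) {
  stopifnot(inherits(fit, "heading_fit"))
  spec <- fit$spec
  h <- series$headings
  m <- length(h)
  th_prev <- h[-m]; th <- h[-1]
  loc <- if (spec$constraint == "focal_point") step_locations(series, locations)
  mu <- step_mean(th_prev, spec, fit$params, location = loc)
  if (spec$noise == "KJ") {
    lambda <- resolve_lambda(spec, fit$params)
    nu <- wrap_angle(lambda - mu)
    kj_untransform(th, mu, fit$params$r, nu)
  } else {
    wrap_angle(th - mu)
  }
}
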