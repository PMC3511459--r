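# shared test helpers

## chi-square agreement p-value between a circular sample and a density,
## 24 equal classes with expected counts from quadrature
sampler_chisq_p <- function(x, dens, ...) {
  br <- seq(-pi, pi, length.out = 25)
  O <- hist(x, breaks = br, plot = FALSE)$counts
  E <- vapply(seq_len(24), function(d)
    stats::integrate(dens, br[d], br[d + 1], ..., abs.tol = 1e-10)$value,
    numeric(1)) * length(x)
  stats::pchisq(sum((O - E)^2 / E), 23, lower.tail = FALSE)
}

## simulate a step series from a heading model (constant speed unless a speed
## model is supplied)
make_series <- function(spec, params, n, seed, theta0 = 0,
                        speed_params = NULL, v0 = 10, time_unit = 1) {
  scn <- scenario("test", spec, params, speed_params = speed_params,
                  theta0 = theta0, v0 = v0, n_steps = n,
                  time_unit = time_unit, seed = 1)
  attr(simulate_trajectory(scn, seed = seed), "steps")
}

## fit-shaped objects at known (true) parameter values, for calibration
## studies where no estimation step is wanted
as_heading_fit <- function(spec, params) {
  structure(list(spec = spec, params = params,
                 k = n_par(spec), loglik = NA_real_, aic = NA_real_),
            class = "heading_fit")
}
as_speed_fit <- function(params) {
  structure(list(params = params), class = "speed_fit")
}

circ_mean_of <- function(x) atan2(mean(sin(x)), mean(cos(x)))
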