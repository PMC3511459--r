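#' Specify a heading model
#'
#' A heading model is a family (`CRW`: correlated random walk, the previous
#' heading carried forward unchanged; `CAR`: circular auto-regression, the
#' previous heading attracted toward a focal direction through [attract()]),
#' a circular noise family (`VM`, `WC`, or the asymmetric `KJ`), and an
#' optional constraint:
#'
#' * `fixed_lambda`: the skew target `lambda` of the Kato-Jones noise is fixed
#'   at a known direction (typically the leeward direction estimated from the
#'   speed model at time unit 1) instead of being estimated.
#' * `fixed_alpha`: the focal direction is fixed (typically at the bearing
#'   from the first to the last fix, i.e. the entire observed flight
#'   direction).
#' * `focal_point`: the focal *direction* is replaced by the bearing from the
#'   current location to a known focal point (e.g. the nesting island), so the
#'   attraction target changes along the trajectory.
#'
#' Free parameters follow from the choice: CRW(VM) or CRW(WC) has 1, CAR(VM)
#' or CAR(WC) has 3 (`alpha`, `w`, plus `kappa` or `r`), CAR(KJ) has 5
#' (`alpha`, `w`, `kappa`, `r`, `lambda`); each constraint removes exactly the
#' parameter it fixes.
#'
#' @param family `"CAR"` or `"CRW"`.
#' @param noise `"VM"`, `"WC"`, or `"KJ"`.
#' @param constraint `"none"`, `"fixed_lambda"`, `"fixed_alpha"`, or
#'   `"focal_point"`.
#' @param value fixed angle (radians) for `fixed_lambda` / `fixed_alpha`.
#' @param point length-2 numeric (x, y in meters) for `focal_point`.
#' @return an object of class `heading_spec`.
#' @export
heading_spec <- function(family = c("CAR", "CRW"),
                         noise = c("VM", "WC", "KJ"),
                         constraint = c("none", "fixed_lambda", "fixed_alpha",
                                        "focal_point"),
                         value = NULL, point = NULL) {
  family <- match.arg(family)
  noise <- match.arg(noise)
  constraint <- match.arg(constraint)
  if (constraint == "fixed_lambda") {
    if (noise != "KJ")
      stop("fixed_lambda applies only to KJ noise", call. = FALSE)
    if (is.null(value)) stop("fixed_lambda needs 'value'", call. = FALSE)
    value <- wrap_angle(value)
  }
  if (constraint == "fixed_alpha") {
    if (family != "CAR")
      stop("fixed_alpha applies only to the CAR family", call. = FALSE)
    if (is.null(value)) stop("fixed_alpha needs 'value'", call. = FALSE)
    value <- wrap_angle(value)
  }
  if (constraint == "focal_point") {
    if (family != "CAR")
      stop("focal_point applies only to the CAR family", call. = FALSE)
    if (is.null(point) || length(point) != 2 || anyNA(point))
      stop("focal_point needs a length-2 'point'", call. = FALSE)
  }
  structure(list(family = family, noise = noise, constraint = constraint,
                 value = value, point = if (!is.null(point)) as.numeric(point)),
            class = "heading_spec")
}

## names of the free parameters, in canonical order
free_names <- function(spec) {
  nm <- character(0)
  if (spec$family == "CAR" &&
      !spec$constraint %in% c("fixed_alpha", "focal_point")) nm <- c(nm, "alpha")
  if (spec$family == "CAR") nm <- c(nm, "w")
  nm <- switch(spec$noise,
    VM = c(nm, "kappa"),
    WC = c(nm, "r"),
    KJ = c(nm, "kappa", "r",
           if (spec$constraint != "fixed_lambda") "lambda"))
  nm
}

#' Number of free parameters of a heading model
#'
#' @param spec a [heading_spec()].
#' @export
n_par <- function(spec) length(free_names(spec))

#' @export
print.heading_spec <- function(x, ...) {
  cat(format_model_spec(x), "\n")
  invisible(x)
}

#' @export
format.heading_spec <- function(x, ...) format_model_spec(x)

#' Serialize a heading model spec to a one-line string
#'
#' The plain-text form used in run configs, e.g. `"CAR(KJ)"`,
#' `"CAR(KJ)|lambda=1.963"`, `"CAR(VM)|alpha=-0.393"`,
#' `"CAR(VM)|focal=4000,3000"`.
#'
#' @param spec a [heading_spec()].
#' @export
format_model_spec <- function(spec) {
  base <- sprintf("%s(%s)", spec$family, spec$noise)
  switch(spec$constraint,
    none = base,
    fixed_lambda = sprintf("%s|lambda=%.10g", base, spec$value),
    fixed_alpha = sprintf("%s|alpha=%.10g", base, spec$value),
    focal_point = sprintf("%s|focal=%.10g,%.10g", base, spec$point[1], spec$point[2])
  )
}

#' Parse a heading model spec from its string form
#'
#' @param text a string as produced by [format_model_spec()].
#' @return a [heading_spec()].
#' @export
parse_model_spec <- function(text) {
  text <- trimws(text)
  m <- regmatches(text, regexec("^(CRW|CAR)\\((VM|WC|KJ)\\)(\\|(.*))?$", text))[[1]]
  if (length(m) == 0) stop("cannot parse model spec: ", text, call. = FALSE)
  family <- m[2]; noise <- m[3]; rest <- m[5]
  if (is.na(rest) || rest == "")
    return(heading_spec(family, noise))
  kv <- strsplit(rest, "=", fixed = TRUE)[[1]]
  if (length(kv) != 2) stop("cannot parse constraint: ", rest, call. = FALSE)
  key <- kv[1]
  val <- as.numeric(strsplit(kv[2], ",", fixed = TRUE)[[1]])
  switch(key,
    lambda = heading_spec(family, noise, "fixed_lambda", value = val),
    alpha = heading_spec(family, noise, "fixed_alpha", value = val),
    focal = heading_spec(family, noise, "focal_point", point = val),
    stop("unknown constraint key: ", key, call. = FALSE)
  )
}
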