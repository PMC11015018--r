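# Estimators for f_oc (probability that a habitable planet carries the
# optimal surface-water inventory for coexisting continents and oceans)
# and f_pt (probability of plate tectonics operating for at least
# 0.5 Gyr), and their product f_i, the civilization factor of the
# modified Drake equation.

#' Expected variability range of delivered planetary water
#'
#' The span of surface water mass fractions that planetary accretion can
#' deliver.  Defaults cover stochastic planetesimal delivery (lower end,
#' 3.8% total delivered water under 0-90% impact volatile loss and 5-10%
#' planetesimal water content) up to ocean worlds (55%).
#'
#' @param var_low,var_high Lower/upper ends of the delivered-water
#'   variability, percent mass fraction; `0 < var_low < var_high`.
#' @return An object of class `variability_range`.
#' @examples
#' variability_range()           # 3.8 - 55 %
#' @export
variability_range <- function(var_low = 3.8, var_high = 55) {
  if (!is.numeric(var_low) || !is.numeric(var_high) ||
      !is.finite(var_low) || !is.finite(var_high) ||
      var_low <= 0 || var_high <= var_low)
    stop("need 0 < var_low < var_high", call. = FALSE)
  structure(list(var_low = var_low, var_high = var_high),
            class = "variability_range")
}

as_variability <- function(x) {
  if (inherits(x, "variability_range")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(variability_range(x[1], x[2]))
  stop("`variability` must be a variability_range or c(low, high)",
       call. = FALSE)
}

#' Bounds on f_oc from the ratio of window width to water variability
#'
#' Treating the delivered water mass fraction as uniformly distributed
#' over the accretion variability range, the probability of landing in a
#' permitted window of width `w` is `w / variability`.  The bounds
#' cross-pair the extremes: the lower bound divides the narrowest window
#' by the widest variability, the upper bound the widest window by the
#' narrowest variability.
#'
#' @param width_low,width_high Narrowest and widest permitted-window
#'   widths across the planet sizes considered, percent mass fraction.
#' @param variability A [variability_range()] or `c(low, high)`.
#' @return Numeric vector `c(low, high)` of probabilities.
#' @examples
#' foc_ratio_bounds(0.009, 0.04, variability_range(3.8, 55))
#' # c(0.000164, 0.0105) -> displays as 0.00016 - 0.011
#' @export
foc_ratio_bounds <- function(width_low, width_high,
                             variability = variability_range()) {
  v <- as_variability(variability)
  if (!is.finite(width_low) || !is.finite(width_high) ||
      width_low <= 0 || width_high < width_low)
    stop("need 0 < width_low <= width_high", call. = FALSE)
  if (width_high > v$var_low)
    stop("window widths must not exceed the variability lower end ",
         "(the window must be narrow relative to delivery variability)",
         call. = FALSE)
  c(low = width_low / v$var_high, high = width_high / v$var_low)
}

#' Estimate f_oc from a planet population
#'
#' Counts the fraction of planets whose surface water mass fraction lies
#' inside the radius-dependent permitted window (closed interval
#' `[fmin, fmax]`), with a binomial standard error.
#'
#' @param pop A `planet_population` (see [generate_population()] and
#'   [read_population()]), or any data frame with columns `radius_earth`
#'   and `water_fraction_pct`.
#' @param freeboard_mode Passed to [permitted_window()].
#' @return An object of class `foc_estimate`: list with `estimate`, `se`
#'   (binomial standard error `sqrt(p(1-p)/n)`), `n`, `n_in`.
#' @export
foc_from_population <- function(pop,
                                freeboard_mode = c("conservative",
                                                   "korenaga")) {
  freeboard_mode <- match.arg(freeboard_mode)
  if (!is.data.frame(pop) ||
      !all(c("radius_earth", "water_fraction_pct") %in% names(pop)))
    stop("`pop` must have columns radius_earth and water_fraction_pct",
         call. = FALSE)
  n <- nrow(pop)
  if (n == 0L) stop("population is empty", call. = FALSE)
  r <- pop$radius_earth
  w <- pop$water_fraction_pct
  if (any(!is.finite(r)) || any(r <= 0))
    stop("all radii must be positive", call. = FALSE)
  if (any(!is.finite(w)) || any(w < 0))
    stop("all water fractions must be non-negative", call. = FALSE)
  fmin <- EARTH_FMIN_PCT / r
  fmax <- switch(freeboard_mode,
                 conservative = EARTH_FMAX_PCT,
                 korenaga = KORENAGA_FMAX_PCT) / r
  n_in <- sum(w >= fmin & w <= fmax)
  p <- n_in / n
  structure(list(estimate = p, se = sqrt(p * (1 - p) / n),
                 n = n, n_in = n_in, freeboard_mode = freeboard_mode),
            class = "foc_estimate")
}

#' @export
print.foc_estimate <- function(x, ...) {
  cat(sprintf("f_oc estimate: %.4g (SE %.3g; %d of %d planets in window, %s)\n",
              x$estimate, x$se, x$n_in, x$n, x$freeboard_mode))
  invisible(x)
}

#' Upper bound on f_pt, the long-lived plate-tectonics fraction
#'
#' Product of independent reduction factors.  Defaults: only ~1/3 of
#' observed stellar compositions are likely to host planets capable of
#' density-driven tectonics, and roughly half of terrestrial planets are
#' too small (Mars/Mercury class, weak convection) for long-term plate
#' tectonics — giving 0.33 * 0.5 = 0.165, displayed as 0.17.  The result
#' is an upper bound: further unquantifiable reductions (super-Earths,
#' mantles that start too cool for subduction) only lower it.
#'
#' @param stellar_fraction Fraction of stellar compositions permitting
#'   density-driven tectonics (default 0.33).
#' @param large_enough_fraction Fraction of terrestrial planets large
#'   enough to sustain vigorous mantle convection (default 0.5).
#' @param extra_factors Optional numeric vector of additional reduction
#'   factors in \[0, 1\].
#' @return The product, a probability carrying attribute `bound = "upper"`.
#' @examples
#' fpt_estimate()              # 0.165, i.e. f_pt < 0.17
#' fpt_estimate(0.33, 1)       # stellar restriction only: 0.33
#' @export
fpt_estimate <- function(stellar_fraction = 0.33,
                         large_enough_fraction = 0.5,
                         extra_factors = numeric()) {
  f <- c(stellar_fraction, large_enough_fraction, extra_factors)
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop("all factors must lie in [0, 1]", call. = FALSE)
  structure(prod(f), bound = "upper")
}

#' Civilization factor f_i = f_oc * f_pt
#'
#' @param foc_bounds Numeric `c(low, high)` bounds on f_oc.
#' @param fpt Upper bound on f_pt (e.g. from [fpt_estimate()]).
#' @return `c(low, high)` elementwise product, attribute `bound = "upper"`
#'   (f_pt is one-sided, so both products are upper bounds).
#' @examples
#' fi_product(c(0.00016, 0.011), 0.17)   # c(2.72e-05, 1.87e-03)
#' @export
fi_product <- function(foc_bounds, fpt) {
  fpt <- as.numeric(fpt)
  if (length(foc_bounds) != 2L || any(!is.finite(foc_bounds)) ||
      any(foc_bounds < 0) || any(foc_bounds > 1) ||
      foc_bounds[1] > foc_bounds[2])
    stop("`foc_bounds` must be c(low, high) probabilities", call. = FALSE)
  if (!is.finite(fpt) || fpt < 0 || fpt > 1)
    stop("`fpt` must be a probability", call. = FALSE)
  structure(c(low = unname(foc_bounds[1]) * fpt,
              high = unname(foc_bounds[2]) * fpt),
            bound = "upper")
}

#' Bundle f_oc, f_pt and f_i into one record
#'
#' @param foc_bounds `c(low, high)` bounds on f_oc.
#' @param fpt Upper bound on f_pt.
#' @return Object of class `habitability_fractions` with fields
#'   `foc_low`, `foc_high`, `fpt_upper`, `fi_low`, `fi_high`.
#' @export
habitability_fractions <- function(foc_bounds, fpt = fpt_estimate()) {
  fi <- fi_product(foc_bounds, fpt)
  structure(list(foc_low = unname(foc_bounds[1]),
                 foc_high = unname(foc_bounds[2]),
                 fpt_upper = as.numeric(fpt),
                 fi_low = unname(fi[1]), fi_high = unname(fi[2])),
            class = "habitability_fractions")
}

#' @export
print.habitability_fractions <- function(x, ...) {
  cat("Habitability fractions (f_pt and f_i are upper bounds):\n")
  cat(sprintf("  f_oc: %.4g - %.4g\n", x$foc_low, x$foc_high))
  cat(sprintf("  f_pt: < %.4g\n", x$fpt_upper))
  cat(sprintf("  f_i = f_oc * f_pt: < %.3g - < %.3g\n", x$fi_low, x$fi_high))
  invisible(x)
}
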