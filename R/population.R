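# Seeded generator of synthetic exoplanet populations: per-planet radius
# (log-uniform over 0.5-2.35 Earth radii by default) and surface water
# mass fraction drawn from a mixture of delivery regimes.  The generator
# emulates the statistical footprint of Monte Carlo planet-formation
# populations (water fractions spanning 0-56%, with only a tiny fraction
# inside the radius-dependent permitted window); it performs no physical
# accretion modelling.

#' One component of the water-fraction mixture
#'
#' @param weight Mixture weight in `[0, 1]`.
#' @param family `"uniform"`, `"loguniform"` or `"point"`.
#' @param min,max Component support in percent mass fraction
#'   (`uniform`/`loguniform`).
#' @param at Location of a `"point"` mass (default 0: a dry planet).
#' @return Object of class `mixture_component`.
#' @export
mixture_component <- function(weight,
                              family = c("uniform", "loguniform", "point"),
                              min = NULL, max = NULL, at = 0) {
  family <- match.arg(family)
  if (!is.finite(weight) || weight < 0 || weight > 1)
    stop("`weight` must lie in [0, 1]", call. = FALSE)
  if (family == "point") {
    if (!is.finite(at) || at < 0)
      stop("`at` must be a non-negative water fraction", call. = FALSE)
    min <- max <- at
  } else {
    if (is.null(min) || is.null(max) || !is.finite(min) || !is.finite(max) ||
        min < 0 || max <= min)
      stop("`min`/`max` must satisfy 0 <= min < max", call. = FALSE)
    if (family == "loguniform" && min <= 0)
      stop("log-uniform component requires min > 0", call. = FALSE)
  }
  structure(list(weight = weight, family = family, min = min, max = max),
            class = "mixture_component")
}

#' Default water-delivery mixture
#'
#' Three regimes: dry planets that received no appreciable water (point
#' mass at 0), planets watered by stochastic planetesimal delivery
#' (uniform over 0.008-3.8% — the span allowed by 0-90% impact volatile
#' loss and 5-10% planetesimal water content), and ocean worlds
#' (log-uniform over 6-55%, the Europa/Callisto class).  The weights
#' (0.36, 0.19, 0.45) are a calibration choice placing the in-window
#' probability mass near 1e-3, the order seen in external
#' planet-formation populations — not a prediction of this package.
#'
#' @return List of three [mixture_component()]s.
#' @export
default_mixture <- function() {
  list(dry = mixture_component(0.36, "point", at = 0),
       delivered = mixture_component(0.19, "uniform", min = 0.008, max = 3.8),
       ocean_world = mixture_component(0.45, "loguniform", min = 6, max = 55))
}

#' Configuration of a synthetic planet population
#'
#' @param n Number of planets (>= 1).
#' @param radius_low,radius_high Radius bounds in Earth radii (defaults
#'   0.5 and 2.35); radii are drawn log-uniformly between them.
#' @param components List of [mixture_component()]s; weights must sum to
#'   1 (tolerance 1e-9).
#' @param water_max Maximum admissible water fraction, percent
#'   (default 56); component supports must not exceed it.
#' @param seed Integer seed making generation reproducible.
#' @return Object of class `population_config`.
#' @export
population_config <- function(n, radius_low = 0.5, radius_high = 2.35,
                              components = default_mixture(),
                              water_max = 56, seed) {
  if (!is.numeric(n) || n < 1)
    stop("`n` must be a positive integer", call. = FALSE)
  if (!is.finite(radius_low) || !is.finite(radius_high) ||
      radius_low <= 0 || radius_high < radius_low)
    stop("need 0 < radius_low <= radius_high", call. = FALSE)
  if (!length(components) ||
      !all(vapply(components, inherits, logical(1), "mixture_component")))
    stop("`components` must be a non-empty list of mixture_component",
         call. = FALSE)
  w <- vapply(components, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9)
    stop("component weights must sum to 1 (got ", sum(w), ")",
         call. = FALSE)
  if (any(vapply(components, `[[`, numeric(1), "max") > water_max))
    stop("a component exceeds `water_max`", call. = FALSE)
  if (missing(seed) || !is.numeric(seed))
    stop("an integer `seed` is required", call. = FALSE)
  structure(list(n = as.integer(n), radius_low = radius_low,
                 radius_high = radius_high, components = components,
                 water_max = water_max, seed = as.integer(seed)),
            class = "population_config")
}

sample_component <- function(comp, n) {
  switch(comp$family,
         point = rep.int(comp$min, n),
         uniform = stats::runif(n, comp$min, comp$max),
         loguniform = exp(stats::runif(n, log(comp$min), log(comp$max))))
}

config_provenance <- function(config) {
  w <- vapply(config$components, `[[`, numeric(1), "weight")
  sprintf("synthetic n=%d R=[%g,%g] weights=[%s] seed=%d",
          config$n, config$radius_low, config$radius_high,
          paste(format(w), collapse = ","), config$seed)
}

#' Generate a synthetic planet population
#'
#' Draws component membership multinomially with the configured weights,
#' radii log-uniformly over the radius bounds, and water fractions from
#' each planet's component family.  Identical configurations (including
#' the seed) give identical populations.
#'
#' @param config A [population_config()].
#' @return Object of class `planet_population`: a data frame with
#'   columns `radius_earth`, `water_fraction_pct` and `component`, plus
#'   a `provenance` attribute.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  set.seed(config$seed)
  n <- config$n
  k <- length(config$components)
  w <- vapply(config$components, `[[`, numeric(1), "weight")
  member <- sample.int(k, n, replace = TRUE, prob = w)
  radius <- if (config$radius_low == config$radius_high)
    rep.int(config$radius_low, n)
  else
    exp(stats::runif(n, log(config$radius_low), log(config$radius_high)))
  water <- numeric(n)
  for (j in seq_len(k)) {
    idx <- which(member == j)
    if (length(idx))
      water[idx] <- sample_component(config$components[[j]], length(idx))
  }
  nm <- names(config$components)
  if (is.null(nm)) nm <- paste0("component", seq_len(k))
  pop <- data.frame(radius_earth = radius, water_fraction_pct = water,
                    component = nm[member])
  attr(pop, "provenance") <- config_provenance(config)
  class(pop) <- c("planet_population", "data.frame")
  pop
}

#' @export
print.planet_population <- function(x, ...) {
  cat(sprintf("Planet population: %d planets (%s)\n", nrow(x),
              attr(x, "provenance")))
  cat(sprintf("  radius:         %.3g - %.3g R_Earth\n",
              min(x$radius_earth), max(x$radius_earth)))
  cat(sprintf("  water fraction: %.3g - %.3g %%\n",
              min(x$water_fraction_pct), max(x$water_fraction_pct)))
  invisible(x)
}

component_cdf <- function(comp, x) {
  switch(comp$family,
         point = as.numeric(x >= comp$min),
         uniform = stats::punif(x, comp$min, comp$max),
         loguniform = {
           p <- (log(pmax(x, comp$min)) - log(comp$min)) /
                (log(comp$max) - log(comp$min))
           pmin(pmax(p, 0), 1)
         })
}

# probability that a water fraction from `comp` lies in [lo, hi]
component_window_mass <- function(comp, lo, hi) {
  if (comp$family == "point")
    return(as.numeric(comp$min >= lo & comp$min <= hi))
  component_cdf(comp, hi) - component_cdf(comp, lo)
}

#' Analytic in-window probability of a population configuration
#'
#' Exact probability that a planet drawn from the configuration falls
#' inside its radius-dependent permitted water window: each component's
#' distribution function is integrated over the window, and the result
#' averaged over the log-uniform radius law by adaptive quadrature.
#' The analytic companion to [generate_population()] +
#' [foc_from_population()].
#'
#' @param config A [population_config()].
#' @param freeboard_mode Passed to [permitted_window()].
#' @param rel_tol Relative tolerance of the radius quadrature.
#' @return A probability.
#' @export
in_window_mass <- function(config,
                           freeboard_mode = c("conservative", "korenaga"),
                           rel_tol = 1e-9) {
  stopifnot(inherits(config, "population_config"))
  freeboard_mode <- match.arg(freeboard_mode)
  fmax0 <- switch(freeboard_mode,
                  conservative = EARTH_FMAX_PCT,
                  korenaga = KORENAGA_FMAX_PCT)
  w <- vapply(config$components, `[[`, numeric(1), "weight")
  p_given_r <- function(r) {
    out <- 0
    for (j in seq_along(config$components))
      out <- out + w[j] * vapply(
        r, function(ri) component_window_mass(config$components[[j]],
                                              EARTH_FMIN_PCT / ri,
                                              fmax0 / ri),
        numeric(1))
    out
  }
  rlo <- config$radius_low; rhi <- config$radius_high
  if (rlo == rhi) return(p_given_r(rlo))
  # log-uniform radius density: 1 / (r * log(rhi/rlo))
  stats::integrate(function(r) p_given_r(r) / (r * log(rhi / rlo)),
                   lower = rlo, upper = rhi,
                   rel.tol = rel_tol, subdivisions = 500L)$value
}

#' Write / read a planet population as a delimited table
#'
#' Plain tab-separated text with a two-line header: a provenance comment
#' line (`# provenance: ...`), then the column names `radius_earth` and
#' `water_fraction_pct`.  Any external dataset reshaped into this layout
#' (e.g. published Monte Carlo planet-formation output) loads the same
#' way.
#'
#' @param pop A `planet_population` or compatible data frame.
#' @param path File path.
#' @return `read_population()` returns a `planet_population`;
#'   `write_population()` returns `path` invisibly.
#' @export
write_population <- function(pop, path) {
  prov <- attr(pop, "provenance")
  if (is.null(prov)) prov <- "unspecified"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# provenance: ", prov), con)
  utils::write.table(pop[c("radius_earth", "water_fraction_pct")], con,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- if (startsWith(first, "#")) 1L else 0L
  pop <- utils::read.table(path, header = TRUE, sep = "\t", skip = skip)
  if (!all(c("radius_earth", "water_fraction_pct") %in% names(pop)))
    stop("expected columns radius_earth and water_fraction_pct in ", path,
         call. = FALSE)
  attr(pop, "provenance") <-
    if (skip) sub("^# provenance: ", "", first) else path
  class(pop) <- c("planet_population", "data.frame")
  pop
}
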