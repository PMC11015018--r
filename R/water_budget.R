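# Isostatic surface-water budget: the radius-dependent window of surface
# water mass fraction within which continents, oceans and plate tectonics
# can coexist.  All fractions are percent of planetary mass; one Earth
# ocean is defined intrinsically as 0.0224% of one Earth mass, so every
# conversion here is a ratio of dimensionless numbers and no kg-scale
# physical constants enter the model.

#' @keywords internal
EARTH_OCEAN_PCT <- 0.0224

# Earth's permitted surface-water window, percent of planetary mass.
# Lower bound: mid-ocean ridges must stay predominantly submarine so that
# hydrated oceanic crust can stabilise one-sided subduction.  Upper bound
# (conservative): significant land masses (> 5-10% of the surface) must
# remain.  The alternative "korenaga" upper bound follows a continental
# freeboard model under which a 2-3-ocean water world is still viable.
EARTH_FMIN_PCT <- 0.007
EARTH_FMAX_PCT <- 0.027
KORENAGA_FMAX_PCT <- 0.067

#' Specify a planet by radius and bulk density relative to Earth
#'
#' @param radius_rel Planet radius in Earth radii (positive).
#' @param density_rel Bulk density in Earth densities (positive, default 1).
#'
#' @return An object of class `planet_spec`: a list with `radius_rel`,
#'   `density_rel` and the derived `mass_rel = density_rel * radius_rel^3`.
#' @examples
#' planet_spec(2.35)        # largest known rocky super-Earth
#' planet_spec(0.5)         # Mars-size planet
#' @export
planet_spec <- function(radius_rel, density_rel = 1) {
  stopifnot(is.numeric(radius_rel), length(radius_rel) == 1L,
            is.numeric(density_rel), length(density_rel) == 1L)
  if (!is.finite(radius_rel) || radius_rel <= 0)
    stop("`radius_rel` must be a positive finite number", call. = FALSE)
  if (!is.finite(density_rel) || density_rel <= 0)
    stop("`density_rel` must be a positive finite number", call. = FALSE)
  structure(
    list(radius_rel = radius_rel,
         density_rel = density_rel,
         mass_rel = planet_mass(radius_rel, density_rel)),
    class = "planet_spec"
  )
}

#' @export
print.planet_spec <- function(x, ...) {
  cat(sprintf("Planet: R = %g R_Earth, rho = %g rho_Earth, M = %g M_Earth\n",
              x$radius_rel, x$density_rel, x$mass_rel))
  invisible(x)
}

#' Planetary mass from radius and bulk density (Earth units)
#'
#' Cube law: `mass_rel = density_rel * radius_rel^3`.
#'
#' @inheritParams planet_spec
#' @return Mass in Earth masses.
#' @examples
#' planet_mass(0.5)   # 0.125
#' planet_mass(2.35)  # 12.978
#' @export
planet_mass <- function(radius_rel, density_rel = 1) {
  if (any(!is.finite(radius_rel)) || any(radius_rel <= 0))
    stop("`radius_rel` must be positive", call. = FALSE)
  if (any(!is.finite(density_rel)) || any(density_rel <= 0))
    stop("`density_rel` must be positive", call. = FALSE)
  density_rel * radius_rel^3
}

as_planet_spec <- function(planet) {
  if (inherits(planet, "planet_spec")) return(planet)
  if (is.numeric(planet) && length(planet) == 1L) return(planet_spec(planet))
  stop("`planet` must be a planet_spec or a single radius in Earth radii",
       call. = FALSE)
}

#' Convert a surface-water mass fraction to Earth-ocean units
#'
#' One Earth ocean is defined as 0.0224% of one Earth mass, so a planet
#' holding `fraction_pct` percent of its mass `M` (Earth masses) as surface
#' water carries `fraction_pct / 0.0224 * M` Earth oceans.
#'
#' @param fraction_pct Surface water mass fraction in percent (>= 0).
#' @param planet A [planet_spec()] or a bare radius in Earth radii
#'   (density 1 assumed). Default: Earth.
#' @return Water amount in Earth-ocean units.
#' @examples
#' fraction_to_oceans(0.0224)       # 1 Earth ocean
#' fraction_to_oceans(0.007)        # 0.3125 ~ 0.3 Earth oceans
#' @export
fraction_to_oceans <- function(fraction_pct, planet = planet_spec(1)) {
  if (any(!is.finite(fraction_pct)) || any(fraction_pct < 0))
    stop("`fraction_pct` must be non-negative", call. = FALSE)
  planet <- as_planet_spec(planet)
  fraction_pct / EARTH_OCEAN_PCT * planet$mass_rel
}

#' Permitted surface-water window for a planet
#'
#' The window of surface water mass fraction within which mid-ocean ridges
#' stay submarine (lower bound) while significant land masses survive
#' (upper bound).  Isostatically controlled topography is nearly
#' independent of planetary size, so the absolute permitted water *mass*
#' is roughly radius-independent and the mass *fraction* bounds scale as
#' 1/radius: `fmin = 0.007 / R`, `fmax = 0.027 / R` percent
#' (conservative), or `fmax = 0.067 / R` under the freeboard-model
#' ("korenaga") upper bound that tolerates a 2-3-ocean water world.
#'
#' @param planet A [planet_spec()] or a bare radius in Earth radii.
#' @param freeboard_mode `"conservative"` (default) or `"korenaga"`.
#' @return An object of class `water_window`: list with `fmin`, `fmax`
#'   (percent mass fraction), `oceans_min`, `oceans_max` (Earth oceans),
#'   plus the `planet` and `freeboard_mode` used.
#' @examples
#' permitted_window(1)               # Earth: 0.007-0.027%, 0.31-1.21 oceans
#' permitted_window(2.35)            # super-Earth: ~0.003-0.0115%, ~2-7 oceans
#' permitted_window(1, "korenaga")   # widened upper bound
#' @export
permitted_window <- function(planet,
                             freeboard_mode = c("conservative", "korenaga")) {
  planet <- as_planet_spec(planet)
  freeboard_mode <- match.arg(freeboard_mode)
  r <- planet$radius_rel
  fmin <- EARTH_FMIN_PCT / r
  fmax <- switch(freeboard_mode,
                 conservative = EARTH_FMAX_PCT / r,
                 korenaga = KORENAGA_FMAX_PCT / r)
  structure(
    list(fmin = fmin, fmax = fmax,
         oceans_min = fraction_to_oceans(fmin, planet),
         oceans_max = fraction_to_oceans(fmax, planet),
         planet = planet, freeboard_mode = freeboard_mode),
    class = "water_window"
  )
}

#' @export
print.water_window <- function(x, ...) {
  cat(sprintf(
    "Permitted surface-water window (%s, R = %g R_Earth):\n",
    x$freeboard_mode, x$planet$radius_rel))
  cat(sprintf("  mass fraction: %.6g%% - %.6g%%\n", x$fmin, x$fmax))
  cat(sprintf("  Earth oceans:  %.4g - %.4g\n", x$oceans_min, x$oceans_max))
  invisible(x)
}

#' Width of a permitted water window
#'
#' @param window A `water_window` from [permitted_window()].
#' @return `fmax - fmin`, percent mass fraction.
#' @examples
#' window_width(permitted_window(1))     # 0.020
#' window_width(permitted_window(2.35))  # 0.008511
#' @export
window_width <- function(window) {
  if (!inherits(window, "water_window"))
    stop("`window` must be a water_window", call. = FALSE)
  window$fmax - window$fmin
}
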