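# Timescales of the single-lid to plate-tectonics transition: how long a
# global plate mosaic takes to assemble from a single subduction
# initiation point at observed trench-lengthening rates, and durations
# bracketed by geologic marker events.

#' Plate-mosaic assembly time from a trench-lengthening rate
#'
#' The plate mosaic grows by lateral propagation of new convergent
#' margins from a single subduction initiation point; at a constant
#' lengthening rate the time to reach a global network is the simple
#' quotient `target_length / rate`.
#'
#' @param target_length Total convergent-margin length to build, km
#'   (modern Earth: ~55,000 km).
#' @param rate Trench-lengthening rate, km/Myr (observed and modelled
#'   range for Cretaceous and younger subduction initiation:
#'   ~100-600 km/Myr).
#' @return Assembly time in Myr.
#' @examples
#' assembly_time(55000, 600)   # 91.67 ~ 92 Myr
#' assembly_time(55000, 100)   # 550 Myr
#' @export
assembly_time <- function(target_length, rate) {
  if (!is.finite(target_length) || target_length < 0)
    stop("`target_length` must be non-negative", call. = FALSE)
  if (!is.finite(rate) || rate <= 0)
    stop("`rate` must be positive", call. = FALSE)
  target_length / rate
}

#' Assembly-time range over a band of trench-lengthening rates
#'
#' @param target_length Convergent-margin length, km.
#' @param rate_low,rate_high Slowest and fastest lengthening rates,
#'   km/Myr (`0 < rate_low <= rate_high`).
#' @return `c(low, high)` in Myr; the fastest rate gives the shortest
#'   time.
#' @examples
#' assembly_time_range(55000, 100, 600)   # c(91.67, 550)
#' @export
assembly_time_range <- function(target_length, rate_low, rate_high) {
  if (!is.finite(rate_low) || !is.finite(rate_high) ||
      rate_low <= 0 || rate_high < rate_low)
    stop("need 0 < rate_low <= rate_high", call. = FALSE)
  c(low = assembly_time(target_length, rate_high),
    high = assembly_time(target_length, rate_low))
}

#' Bracket a transition by two dated events
#'
#' Ages are Ma before present, decreasing toward the present, so the
#' first (older) event must have the larger age.
#'
#' @param first_event_age Age of the older marker event, Ma.
#' @param last_event_age Age of the younger marker event, Ma.
#' @param label Optional text label.
#' @return Object of class `event_bracket`.
#' @examples
#' event_bracket(811, 570, "C-isotope excursions")   # Bitter Springs -> Shuram
#' event_bracket(720, 580, "Snowball glaciations")   # Sturtian -> Gaskiers
#' @export
event_bracket <- function(first_event_age, last_event_age, label = "") {
  if (!is.finite(first_event_age) || !is.finite(last_event_age))
    stop("ages must be finite", call. = FALSE)
  if (first_event_age <= last_event_age)
    stop("`first_event_age` must exceed `last_event_age` ",
         "(ages decrease toward the present)", call. = FALSE)
  structure(list(first_event_age = first_event_age,
                 last_event_age = last_event_age,
                 label = as.character(label)),
            class = "event_bracket")
}

#' Duration of an event-bracketed transition
#'
#' @param bracket An [event_bracket()].
#' @return Duration in Myr: `first_event_age - last_event_age`.
#' @examples
#' bracket_duration(event_bracket(811, 570))   # 241 Myr
#' bracket_duration(event_bracket(720, 580))   # 140 Myr
#' @export
bracket_duration <- function(bracket) {
  if (!inherits(bracket, "event_bracket"))
    stop("`bracket` must be an event_bracket", call. = FALSE)
  bracket$first_event_age - bracket$last_event_age
}
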