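# Drake equation engine: classic (ACC), modified (f_i = f_oc * f_pt) and
# COPT remote-sensing forms, evaluated as point products, interval
# arithmetic over term ranges, or seeded Monte Carlo propagation.

#' Specify one Drake-equation term
#'
#' A term is a point value, an interval, or an interval with a named
#' sampling distribution for Monte Carlo evaluation.  When no
#' distribution is given, intervals spanning more than one decade
#' (`high/low > 10`) default to log-uniform — the standard
#' non-informative choice for order-of-magnitude parameters such as the
#' broadcast lifetime L — and narrower intervals to uniform.
#'
#' @param value Point value (exclusive with `low`/`high`).
#' @param low,high Interval endpoints, `0 <= low <= high`.
#' @param dist `"point"`, `"uniform"` or `"loguniform"`; default as above.
#' @param bound Set to `"upper"` if the term is a one-sided upper bound
#'   (e.g. f_pt); the flag propagates to every derived count.
#' @return Object of class `drake_term`.
#' @examples
#' drake_term(1)                       # R* = 1 star/yr
#' drake_term(low = 0.2, high = 0.5)   # f_p, samples uniformly
#' drake_term(low = 1e3, high = 1e8)   # L, samples log-uniformly
#' @export
drake_term <- function(value = NULL, low = NULL, high = NULL,
                       dist = NULL, bound = NA_character_) {
  if (!is.null(value)) {
    if (!is.null(low) || !is.null(high))
      stop("give either `value` or `low`/`high`, not both", call. = FALSE)
    if (length(value) == 2L) { low <- value[1]; high <- value[2] }
    else { low <- high <- value }
  }
  if (is.null(low) || is.null(high))
    stop("a term needs a value or both `low` and `high`", call. = FALSE)
  low <- as.numeric(low); high <- as.numeric(high)
  if (!is.finite(low) || !is.finite(high) || low < 0)
    stop("term endpoints must be finite and non-negative", call. = FALSE)
  if (low > high)
    stop("term has low > high", call. = FALSE)
  if (is.null(dist)) {
    dist <- if (low == high) "point"
            else if (low > 0 && high / low > 10) "loguniform"
            else "uniform"
  }
  if (!dist %in% c("point", "uniform", "loguniform"))
    stop("unknown distribution: ", dist, call. = FALSE)
  if (dist == "point" && low != high)
    stop("point distribution requires low == high", call. = FALSE)
  if (dist == "loguniform" && low <= 0)
    stop("log-uniform requires low > 0", call. = FALSE)
  structure(list(low = low, high = high, dist = dist, bound = bound),
            class = "drake_term")
}

as_drake_term <- function(x, name) {
  if (inherits(x, "drake_term")) return(x)
  if (is.numeric(x) && length(x) %in% 1:2) return(drake_term(x))
  stop("term `", name, "` must be a drake_term or numeric of length 1-2",
       call. = FALSE)
}

#' Parameters of the Drake equation (ACC or COPT form)
#'
#' The ACC form is `N = R* f_p n_e f_l f_i f_c L`, with the civilization
#' factor `f_i` either given directly or split into `f_oc * f_pt` (the
#' modified equation).  The COPT form drops `f_c` and uses the
#' characteristic coexistence time `L_COPT` in place of the broadcast
#' lifetime: `COPTs = R* f_p n_e f_l f_oc f_pt L_COPT`.
#'
#' @param r_star Star-formation rate, stars/year.
#' @param f_p Fraction of stars with planetary systems.
#' @param n_e Mean number of habitable planets per system (may exceed 1).
#' @param f_l Fraction of habitable planets developing primitive life.
#' @param f_c Fraction of civilizations that become actively
#'   communicative (ignored in COPT mode).
#' @param lifetime Broadcast lifetime L in years (ACC), or the
#'   continent-ocean-plate-tectonics coexistence time L_COPT (COPT).
#' @param f_i Civilization factor; give either this or both `f_oc`,`f_pt`.
#' @param f_oc,f_pt Split civilization factor (modified equation).
#' @param mode `"acc"` or `"copt"`.
#' @return Object of class `drake_params`.
#' @seealso [drake_scenario()] for bundled parameter sets.
#' @export
drake_params <- function(r_star, f_p, n_e, f_l, f_c = 1, lifetime,
                         f_i = NULL, f_oc = NULL, f_pt = NULL,
                         mode = c("acc", "copt")) {
  mode <- match.arg(mode)
  if (is.null(f_i) && (is.null(f_oc) || is.null(f_pt)))
    stop("give `f_i`, or both `f_oc` and `f_pt`", call. = FALSE)
  if (!is.null(f_i) && (!is.null(f_oc) || !is.null(f_pt)))
    stop("give either `f_i` or the pair `f_oc`/`f_pt`, not both",
         call. = FALSE)
  terms <- list(r_star = as_drake_term(r_star, "r_star"),
                f_p = as_drake_term(f_p, "f_p"),
                n_e = as_drake_term(n_e, "n_e"),
                f_l = as_drake_term(f_l, "f_l"))
  if (is.null(f_i)) {
    terms$f_oc <- as_drake_term(f_oc, "f_oc")
    terms$f_pt <- as_drake_term(f_pt, "f_pt")
    if (is.na(terms$f_pt$bound)) terms$f_pt$bound <- "upper"
  } else {
    terms$f_i <- as_drake_term(f_i, "f_i")
  }
  if (mode == "acc") terms$f_c <- as_drake_term(f_c, "f_c")
  terms$lifetime <- as_drake_term(lifetime, "lifetime")
  for (nm in setdiff(names(terms), c("n_e", "r_star", "lifetime")))
    if (terms[[nm]]$high > 1)
      warning("fraction-type term `", nm, "` exceeds 1 at its upper end",
              call. = FALSE)
  structure(list(terms = terms, mode = mode), class = "drake_params")
}

#' @export
print.drake_params <- function(x, ...) {
  cat(sprintf("Drake equation parameters (%s mode):\n", toupper(x$mode)))
  for (nm in names(x$terms)) {
    tm <- x$terms[[nm]]
    rng <- if (tm$low == tm$high) sprintf("%g", tm$low)
           else sprintf("%g - %g (%s)", tm$low, tm$high, tm$dist)
    flag <- if (identical(tm$bound, "upper")) "  [upper bound]" else ""
    cat(sprintf("  %-8s %s%s\n", nm, rng, flag))
  }
  invisible(x)
}

params_bound <- function(params) {
  any(vapply(params$terms, function(t) identical(t$bound, "upper"),
             logical(1)))
}

#' Evaluate the Drake equation at point values
#'
#' @param params A [drake_params()] whose terms are all point values.
#' @return Expected number of ACCs (or COPT planets) in the galaxy.
#' @examples
#' p <- drake_params(1, 0.5, 5, 1, f_c = 0.2, lifetime = 1e8, f_i = 1)
#' drake_point(p)   # 5e7
#' @export
drake_point <- function(params) {
  stopifnot(inherits(params, "drake_params"))
  lows <- vapply(params$terms, `[[`, numeric(1), "low")
  highs <- vapply(params$terms, `[[`, numeric(1), "high")
  if (any(lows != highs))
    stop("all terms must be point values; use drake_interval() for ranges",
         call. = FALSE)
  prod(lows)
}

#' Evaluate the Drake equation over term intervals
#'
#' Because every term is non-negative the product is monotone in each
#' term, so the exact range of the product is the product of the ranges.
#'
#' @param params A [drake_params()].
#' @return Object of class `drake_result` with `low`, `high`, `mode`,
#'   and `bound` (`TRUE` if any factor was an upper bound).
#' @examples
#' drake_interval(drake_scenario("drake1961"))   # 20 - 5e7
#' @export
drake_interval <- function(params) {
  stopifnot(inherits(params, "drake_params"))
  low <- prod(vapply(params$terms, `[[`, numeric(1), "low"))
  high <- prod(vapply(params$terms, `[[`, numeric(1), "high"))
  new_drake_result(list(low = low, high = high), params,
                   method = "interval")
}

new_drake_result <- function(fields, params, method) {
  structure(c(fields,
              list(mode = params$mode, method = method,
                   bound = params_bound(params))),
            class = "drake_result")
}

#' @export
print.drake_result <- function(x, ...) {
  lab <- if (x$mode == "copt") "COPT planets" else "ACCs"
  lt <- if (x$bound) "< " else ""
  cat(sprintf("Drake %s evaluation (%s):\n", x$method, lab))
  if (!is.null(x$low))
    cat(sprintf("  N = %s%.4g - %s%.4g\n", lt, x$low, lt, x$high))
  if (!is.null(x$mean)) {
    cat(sprintf("  mean %.4g, median %.4g, 95%% interval [%.4g, %.4g]\n",
                x$mean, x$median, x$q025, x$q975))
    cat(sprintf("  P(N >= 1) = %.4g   (n = %d, seed = %d)\n",
                x$p_ge_1, x$n_samples, x$seed))
  }
  if (x$bound)
    cat("  (upper bounds: at least one factor is one-sided)\n")
  invisible(x)
}

sample_term <- function(term, n) {
  switch(term$dist,
         point = rep.int(term$low, n),
         uniform = stats::runif(n, term$low, term$high),
         loguniform = exp(stats::runif(n, log(term$low), log(term$high))))
}

#' Monte Carlo propagation of Drake-equation uncertainty
#'
#' Samples every term from its declared distribution (point, uniform or
#' log-uniform over its interval) and multiplies, giving a sampling
#' distribution for the expected count.  Reproducible for a given seed.
#'
#' @param params A [drake_params()].
#' @param n_samples Number of Monte Carlo samples (>= 1).
#' @param seed Integer RNG seed.
#' @return `drake_result` with `mean`, `median`, `q025`, `q975`,
#'   `p_ge_1` (probability the galaxy holds at least one), the raw
#'   `samples`, `n_samples` and `seed`.
#' @examples
#' drake_monte_carlo(drake_scenario("drake1961"), 1000, seed = 1)
#' @export
drake_monte_carlo <- function(params, n_samples, seed) {
  stopifnot(inherits(params, "drake_params"))
  if (!is.numeric(n_samples) || n_samples < 1)
    stop("`n_samples` must be a positive integer", call. = FALSE)
  if (missing(seed) || !is.numeric(seed))
    stop("a numeric `seed` is required for Monte Carlo evaluation",
         call. = FALSE)
  n_samples <- as.integer(n_samples)
  set.seed(as.integer(seed))
  samples <- rep.int(1, n_samples)
  for (term in params$terms) samples <- samples * sample_term(term, n_samples)
  q <- unname(stats::quantile(samples, c(0.025, 0.5, 0.975), names = FALSE))
  new_drake_result(
    list(mean = mean(samples), median = q[2], q025 = q[1], q975 = q[3],
         p_ge_1 = mean(samples >= 1), samples = samples,
         n_samples = n_samples, seed = as.integer(seed)),
    params, method = "monte carlo")
}

#' Scale a published ACC range by civilization-factor bounds
#'
#' Rescales a baseline ACC count range (computed with the classic
#' f_i = 1 optimism) by bounds on the replacement factor
#' f_i = f_oc * f_pt: `(base_low * fi_low, base_high * fi_high)`.
#'
#' @param base `c(low, high)` baseline counts, e.g. `c(200, 5e7)`.
#' @param fi_bounds `c(low, high)` civilization-factor bounds.
#' @return `c(low, high)`, attribute `bound = "upper"`.
#' @examples
#' scale_acc_range(c(200, 5e7), c(3e-5, 2e-3))   # c(0.006, 1e5)
#' @export
scale_acc_range <- function(base, fi_bounds) {
  if (length(base) != 2L || length(fi_bounds) != 2L ||
      any(!is.finite(c(base, fi_bounds))) || any(c(base, fi_bounds) < 0))
    stop("`base` and `fi_bounds` must be non-negative c(low, high)",
         call. = FALSE)
  if (base[1] > base[2] || fi_bounds[1] > fi_bounds[2])
    stop("ranges must have low <= high", call. = FALSE)
  structure(c(low = unname(base[1] * fi_bounds[1]),
              high = unname(base[2] * fi_bounds[2])),
            bound = "upper")
}

#' Bundled Drake-equation parameter sets
#'
#' * `"drake1961"`: the 1961 educated guesses — R* = 1/yr,
#'   f_p = 0.2-0.5, n_e = 1-5, f_l = 1, f_i = 1, f_c = 0.1-0.2,
#'   L = 1e3-1e8 yr.
#' * `"modified_acc"`: as above but with f_i replaced by
#'   f_oc = 0.00016-0.011 and f_pt = 0.17 (upper bound).
#' * `"copt"`: the remote-sensing COPT form — f_oc, f_pt as above,
#'   no f_c, L_COPT = 5e8 yr.
#'
#' @param name One of `"drake1961"`, `"modified_acc"`, `"copt"`.
#' @return A [drake_params()].
#' @export
drake_scenario <- function(name = c("drake1961", "modified_acc", "copt")) {
  name <- match.arg(name)
  switch(name,
    drake1961 = drake_params(
      r_star = 1, f_p = c(0.2, 0.5), n_e = c(1, 5), f_l = 1,
      f_i = 1, f_c = c(0.1, 0.2), lifetime = c(1e3, 1e8)),
    modified_acc = drake_params(
      r_star = 1, f_p = c(0.2, 0.5), n_e = c(1, 5), f_l = 1,
      f_oc = c(0.00016, 0.011), f_pt = 0.17, f_c = c(0.1, 0.2),
      lifetime = c(1e3, 1e8)),
    copt = drake_params(
      r_star = 1, f_p = c(0.2, 0.5), n_e = c(1, 5), f_l = 1,
      f_oc = c(0.00016, 0.011), f_pt = 0.17, lifetime = 5e8,
      mode = "copt"))
}
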