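# Constant-rate birth-death model of a sequential speciation chain: one
# focal lineage is tracked; it speciates at rate lambda and goes extinct
# at rate mu (both per lineage per Myr).  The chain counts how many new
# species arise sequentially within a tectonic era, truncated if the
# focal line dies.  A single chain — not a branching tree — is the
# reading under which rates of at most 1 per lineage per Myr give "up to
# a few hundred" species over 500-1000 Myr of plate tectonics.

#' Parameters of the sequential speciation chain
#'
#' @param lambda Speciation rate, per lineage per Myr (>= 0).  Estimated
#'   rates typically range 0-1 and rarely exceed 1 outside crisis
#'   intervals; a warning is issued above 1.
#' @param mu Extinction rate, per lineage per Myr (>= 0, default 0).
#' @param horizon Time horizon in Myr (> 0); the duration of the
#'   evolutionary era considered (e.g. 500-1000 Myr of modern plate
#'   tectonics).
#' @return Object of class `birth_death_params`.
#' @export
birth_death_params <- function(lambda, mu = 0, horizon) {
  if (!is.finite(lambda) || lambda < 0)
    stop("`lambda` must be non-negative", call. = FALSE)
  if (!is.finite(mu) || mu < 0)
    stop("`mu` must be non-negative", call. = FALSE)
  if (!is.finite(horizon) || horizon <= 0)
    stop("`horizon` must be positive", call. = FALSE)
  if (lambda > 1 || mu > 1)
    warning("rates above 1 per lineage per Myr are rare outside crisis ",
            "intervals", call. = FALSE)
  structure(list(lambda = lambda, mu = mu, horizon = horizon),
            class = "birth_death_params")
}

#' Expected number of sequential speciation events
#'
#' Along the focal line, events occur as a Poisson process of total rate
#' `lambda + mu`; each event is a speciation with probability
#' `lambda / (lambda + mu)`, otherwise the line goes extinct and the
#' chain stops.  Equivalently (Poisson thinning) speciations accrue at
#' rate `lambda` while the line survives, and the line's lifetime is
#' exponential with rate `mu`, so the expected count by the horizon `T`
#' is the closed form
#' `E[N] = lambda * (1 - exp(-mu * T)) / mu`, reducing to `lambda * T`
#' for `mu = 0`.
#'
#' @param params A [birth_death_params()].
#' @return Expected count of speciation events before extinction or the
#'   horizon, whichever comes first.
#' @examples
#' expected_chain_length(birth_death_params(1, 0, 500))      # 500
#' expected_chain_length(birth_death_params(0.5, 0.25, 1000))
#' @export
expected_chain_length <- function(params) {
  stopifnot(inherits(params, "birth_death_params"))
  if (params$lambda == 0) return(0)
  if (params$mu == 0) return(params$lambda * params$horizon)
  params$lambda * (1 - exp(-params$mu * params$horizon)) / params$mu
}

#' Simulate one sequential speciation chain
#'
#' Event-driven competing-risks simulation: waiting times between events
#' are exponential with rate `lambda + mu`; each event is a speciation
#' (probability `lambda / (lambda + mu)`) or the extinction of the focal
#' line, which terminates the chain.  Simulation stops at the horizon.
#'
#' @param params A [birth_death_params()].
#' @param seed Optional integer seed (set `NULL` to continue the current
#'   RNG stream, e.g. inside [simulate_chains()]).
#' @return Object of class `chain_result`: list with `n_speciations`,
#'   `chain_extinct` and `extinction_time` (Myr, `NA` if the line
#'   survived to the horizon).
#' @export
simulate_chain <- function(params, seed = NULL) {
  stopifnot(inherits(params, "birth_death_params"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  lambda <- params$lambda; mu <- params$mu; horizon <- params$horizon
  rate <- lambda + mu
  if (rate == 0)
    return(chain_result(0L, FALSE, NA_real_))
  # expected events before truncation, used to size vectorized draws
  exp_events <- rate * if (mu > 0) (1 - exp(-mu * horizon)) / mu else horizon
  block <- max(16L, ceiling(exp_events + 4 * sqrt(exp_events) + 4))
  p_spec <- lambda / rate
  n_spec <- 0L
  t0 <- 0
  repeat {
    times <- t0 + cumsum(stats::rexp(block, rate))
    is_spec <- stats::runif(block) < p_spec
    within <- times <= horizon
    m <- sum(within)                       # events inside the horizon
    ext <- which(!is_spec[seq_len(m)])
    if (length(ext)) {                     # focal line dies at first death
      k <- ext[1L]
      return(chain_result(n_spec + sum(is_spec[seq_len(k - 1L)]),
                          TRUE, times[k]))
    }
    if (m < block)                         # horizon reached within block
      return(chain_result(n_spec + sum(is_spec[seq_len(m)]),
                          FALSE, NA_real_))
    n_spec <- n_spec + sum(is_spec)
    t0 <- times[block]
  }
}

chain_result <- function(n_speciations, chain_extinct, extinction_time) {
  structure(list(n_speciations = as.integer(n_speciations),
                 chain_extinct = chain_extinct,
                 extinction_time = extinction_time),
            class = "chain_result")
}

#' @export
print.chain_result <- function(x, ...) {
  fate <- if (x$chain_extinct)
    sprintf("extinct at %.3g Myr", x$extinction_time)
  else "survived to horizon"
  cat(sprintf("Speciation chain: %d speciation events, %s\n",
              x$n_speciations, fate))
  invisible(x)
}

#' Replicate speciation chains
#'
#' @param params A [birth_death_params()].
#' @param n_reps Number of independent chains (>= 1).
#' @param seed Integer seed set once before the replicate loop.
#' @return Data frame with one row per chain: `n_speciations`,
#'   `chain_extinct`, `extinction_time`.
#' @export
simulate_chains <- function(params, n_reps, seed) {
  if (!is.numeric(n_reps) || n_reps < 1)
    stop("`n_reps` must be a positive integer", call. = FALSE)
  set.seed(as.integer(seed))
  reps <- lapply(seq_len(n_reps), function(i) simulate_chain(params))
  data.frame(
    n_speciations = vapply(reps, `[[`, integer(1), "n_speciations"),
    chain_extinct = vapply(reps, `[[`, logical(1), "chain_extinct"),
    extinction_time = vapply(reps, `[[`, numeric(1), "extinction_time"))
}

#' Quantiles of the chain length over replicates
#'
#' @inheritParams simulate_chains
#' @param probs Quantile probabilities (default 5%, median, 95%).
#' @return Named numeric vector of chain-length quantiles (type-1, i.e.
#'   attained integer counts).
#' @export
chain_length_quantiles <- function(params, n_reps, seed,
                                   probs = c(0.05, 0.5, 0.95)) {
  reps <- simulate_chains(params, n_reps, seed)
  stats::quantile(reps$n_speciations, probs = probs, type = 1)
}
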