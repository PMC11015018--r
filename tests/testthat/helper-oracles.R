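# Independent oracles used across test files.

# Brute-force window membership: one scalar permitted_window() call per
# planet, no vectorized shortcuts.
brute_force_foc <- function(pop, freeboard_mode = "conservative") {
  inside <- vapply(seq_len(nrow(pop)), function(i) {
    win <- permitted_window(pop$radius_earth[i], freeboard_mode)
    w <- pop$water_fraction_pct[i]
    w >= win$fmin && w <= win$fmax
  }, logical(1))
  mean(inside)
}

# CDF of a log-uniform distribution on [a, b], for KS checks.
ploguni <- function(q, a, b) pmin(pmax((log(q) - log(a)) / (log(b) - log(a)),
                                       0), 1)

# A small deterministic population for counting tests.
toy_population <- function(radius, water) {
  structure(data.frame(radius_earth = radius, water_fraction_pct = water),
            class = c("planet_population", "data.frame"))
}
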