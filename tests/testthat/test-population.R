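test_that("generation is deterministic and honours configured bounds", {
  cfg <- population_config(
    1000,
    components = list(mixture_component(1, "uniform", min = 0, max = 56)),
    seed = 31)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop), 1000)
  expect_true(all(pop$water_fraction_pct >= 0 &
                    pop$water_fraction_pct <= 56))
  expect_true(all(pop$radius_earth >= 0.5 & pop$radius_earth <= 2.35))
  expect_identical(pop, generate_population(cfg))

  cfg2 <- population_config(
    1000,
    components = list(mixture_component(1, "uniform", min = 0, max = 56)),
    seed = 32)
  expect_false(identical(pop$water_fraction_pct,
                         generate_population(cfg2)$water_fraction_pct))
})

test_that("configuration invariants are enforced with named errors", {
  comps_bad <- list(mixture_component(0.6, "point", at = 0),
                    mixture_component(0.5, "uniform", min = 1, max = 2))
  expect_error(population_config(10, components = comps_bad, seed = 1),
               "sum to 1")
  expect_error(population_config(0, seed = 1), "positive")
  expect_error(population_config(10, radius_low = 3, radius_high = 2,
                                 seed = 1), "radius")
  expect_error(population_config(10, water_max = 5, seed = 1),
               "water_max")
  expect_error(population_config(10), "seed")
  expect_error(mixture_component(0.5, "loguniform", min = 0, max = 1),
               "min > 0")
})

test_that("component membership recovers the multinomial weights", {
  cfg <- population_config(
    50000,
    components = list(
      dry = mixture_component(0.9, "point", at = 0),
      ocean = mixture_component(0.1, "loguniform", min = 6, max = 55)),
    seed = 41)
  pop <- generate_population(cfg)
  p_hat <- mean(pop$component == "ocean")
  se <- sqrt(0.1 * 0.9 / 50000)
  expect_lt(abs(p_hat - 0.1), 3 * se)
  expect_true(all(pop$water_fraction_pct[pop$component == "dry"] == 0))
  expect_true(all(pop$water_fraction_pct[pop$component == "ocean"] >= 6))
})

test_that("empirical component distributions match the configured laws", {
  n <- 1e5
  crit <- 1.628 / sqrt(n)   # Kolmogorov critical value at alpha = 0.01
  cfg_u <- population_config(
    n, components = list(mixture_component(1, "uniform", min = 0.008,
                                           max = 3.8)), seed = 51)
  x <- generate_population(cfg_u)$water_fraction_pct
  # runif has 32-bit resolution, so exact ties occur at this n; they do
  # not move the KS statistic at the tolerance tested
  d_u <- suppressWarnings(stats::ks.test(x, "punif", 0.008, 3.8)$statistic)
  expect_lt(unname(d_u), crit)

  cfg_l <- population_config(
    n, components = list(mixture_component(1, "loguniform", min = 6,
                                           max = 55)), seed = 52)
  y <- generate_population(cfg_l)$water_fraction_pct
  d_l <- suppressWarnings(stats::ks.test(y, ploguni, 6, 55)$statistic)
  expect_lt(unname(d_l), crit)
})

test_that("analytic in-window mass handles degenerate configurations", {
  dry <- population_config(
    10, components = list(mixture_component(1, "point", at = 0)), seed = 1)
  expect_equal(in_window_mass(dry), 0)

  # single radius, water uniform over exactly the window
  win <- permitted_window(1.3)
  exact <- population_config(
    10, radius_low = 1.3, radius_high = 1.3,
    components = list(mixture_component(1, "uniform", min = win$fmin,
                                        max = win$fmax)), seed = 1)
  expect_equal(in_window_mass(exact), 1)

  # point mass sitting inside its window counts fully
  onpoint <- population_config(
    10, radius_low = 1, radius_high = 1,
    components = list(mixture_component(1, "point", at = 0.01)), seed = 1)
  expect_equal(in_window_mass(onpoint), 1)
})

test_that("simulation recovers the analytic in-window probability", {
  cfg <- population_config(2e5, seed = 61)
  q <- in_window_mass(cfg)
  est <- foc_from_population(generate_population(cfg))
  se <- sqrt(q * (1 - q) / cfg$n)
  expect_lt(abs(est$estimate - q), 3 * se)
  # the default calibration sits in the externally observed range
  expect_gt(q, 0.0006)
  expect_lt(q, 0.0022)
})

test_that("populations round-trip through the two-line-header table", {
  cfg <- population_config(500, seed = 71)
  pop <- generate_population(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_population(pop, path)
  back <- read_population(path)
  expect_equal(back$radius_earth, pop$radius_earth, tolerance = 1e-12)
  expect_equal(back$water_fraction_pct, pop$water_fraction_pct,
               tolerance = 1e-12)
  expect_match(attr(back, "provenance"), "seed=71")
  expect_equal(foc_from_population(back)$estimate,
               foc_from_population(pop)$estimate)
})
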