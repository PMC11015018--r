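test_that("display rounding reproduces the mixed headline conventions", {
  expect_equal(round_display(0.010526, "sig2"), 0.011)
  expect_equal(round_display(0.000163636, "sig2"), 0.00016)
  expect_equal(round_display(91.67, "int"), 92)
  expect_equal(round_display(0.165, "dec2"), 0.17)
  expect_equal(round_display(0.008511, "sig1"), 0.009)
  expect_equal(round_display(1.2053, "dec1"), 1.2)
  expect_equal(round_display(0, "sig1"), 0)
  expect_equal(round_display(-0.165, "dec2"), -0.17)   # half away from zero
  expect_equal(round_display(c(2.72e-5, 1.87e-3), "sig1"), c(3e-5, 2e-3))
  expect_error(round_display(1, "sig3"), "arg")
})

test_that("the headline scenario reports the published display chain", {
  report <- suppressMessages(run_scenario(scenario_path("paper_headline")))
  tab <- report$table
  disp <- function(q) tab$display[tab$quantity == q]
  expect_equal(disp("foc_low"), 0.00016)
  expect_equal(disp("foc_high"), 0.011)
  expect_equal(disp("fpt_upper"), 0.17)
  expect_equal(disp("fi_low"), 3e-5)
  expect_equal(disp("fi_high"), 2e-3)
  expect_equal(disp("acc_low"), 0.006)
  expect_equal(disp("acc_high"), 1e5)
  expect_equal(disp("width_pct_R2.35"), 0.009)
  expect_equal(disp("width_pct_R0.5"), 0.04)
  expect_equal(disp("oceans_min_R2.35"), 2)
  expect_equal(disp("oceans_max_R2.35"), 7)
  # raw values accompany every display value
  expect_equal(tab$raw[tab$quantity == "foc_low"], 0.009 / 55)
  expect_true(all(c("raw", "display") %in% names(tab)))
  expect_true(all(tab$bound[tab$stage %in% c("fpt", "drake")]))
})

test_that("the tectonic scenario reports the transition timescales", {
  tab <- run_scenario(scenario_path("tectonic"))$table
  disp <- function(q) tab$display[tab$quantity == q]
  expect_equal(disp("assembly_min_myr"), 92)
  expect_equal(disp("assembly_max_myr"), 550)
  expect_equal(disp("transition_c_isotope_myr"), 241)
  expect_equal(disp("transition_glaciation_myr"), 140)
})

test_that("scenario validation names the offending field", {
  expect_error(run_scenario(list(name = "x", stages = list())), "stages")
  expect_error(run_scenario(list(name = "x", stages = "warp")), "warp")
  expect_error(run_scenario(list(stages = "water")), "name")
  expect_error(
    run_scenario(list(name = "x", stages = "population",
                      population = list(n = 10))),
    "seed")
})

test_that("same scenario and seed give byte-identical CSV output", {
  sc <- scenario_path("population_foc")
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_scenario(sc, seed = 123, out_dir = d1, format = "csv")
  run_scenario(sc, seed = 123, out_dir = d2, format = "csv")
  f1 <- readLines(file.path(d1, "population_foc.csv"))
  f2 <- readLines(file.path(d2, "population_foc.csv"))
  expect_identical(f1, f2)
  expect_match(f1[1], "stage,quantity,raw,display")
})

test_that("stochastic stages are seeded and reported end to end", {
  report <- run_scenario(scenario_path("population_foc"))
  tab <- report$table
  expect_equal(report$seed, 20240412L)
  est <- tab$raw[tab$quantity == "foc_population"]
  analytic <- tab$raw[tab$quantity == "in_window_mass_analytic"]
  se <- tab$raw[tab$quantity == "foc_population_se"]
  expect_lt(abs(est - analytic), 4 * se)

  spec <- run_scenario(scenario_path("speciation"))$table
  expect_equal(spec$raw[spec$quantity == "expected_chain_length"],
               0.5 * (1 - exp(-0.1 * 1000)) / 0.1)
  expect_lte(spec$raw[spec$quantity == "chain_q05"],
             spec$raw[spec$quantity == "chain_median"])

  # JSON report carries the scenario echo and per-quantity rows
  d <- withr::local_tempdir()
  run_scenario(scenario_path("tectonic"), out_dir = d, format = "json")
  js <- jsonlite::read_json(file.path(d, "tectonic.json"),
                            simplifyVector = TRUE)
  expect_equal(js$name, "tectonic")
  expect_equal(nrow(js$results), 4)
})

test_that("bundled Drake scenarios run through the scenario driver", {
  r1961 <- run_scenario(scenario_path("drake1961"))$table
  expect_equal(r1961$raw[r1961$quantity == "n_low"], 20)
  expect_equal(r1961$raw[r1961$quantity == "n_high"], 5e7)
  expect_true(all(c("mc_mean", "mc_p_ge_1") %in% r1961$quantity))
  expect_gte(r1961$raw[r1961$quantity == "mc_q025"], 20)
  expect_lte(r1961$raw[r1961$quantity == "mc_q975"], 5e7)

  copt <- run_scenario(scenario_path("copt"))$table
  expect_equal(copt$raw[copt$quantity == "n_low"], 2720)
  expect_equal(copt$raw[copt$quantity == "n_high"], 2.3375e6)
  expect_true(all(copt$bound))
})
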