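test_that("point evaluation is the product of the seven terms", {
  p_hi <- drake_params(1, 0.5, 5, 1, f_c = 0.2, lifetime = 1e8, f_i = 1)
  expect_equal(drake_point(p_hi), 5e7)
  p_lo <- drake_params(1, 0.2, 1, 1, f_c = 0.1, lifetime = 1e3, f_i = 1)
  expect_equal(drake_point(p_lo), 20)
  p0 <- drake_params(1, 0.2, 1, 0, f_c = 0.1, lifetime = 1e3, f_i = 1)
  expect_equal(drake_point(p0), 0)
  expect_error(drake_point(drake_scenario("drake1961")), "point")
  expect_error(drake_term(-1), "non-negative")
  expect_error(drake_term(low = 2, high = 1), "low > high")
})

test_that("point evaluation is multiplicative in every term", {
  base <- list(r_star = 1, f_p = 0.3, n_e = 2, f_l = 0.4, f_c = 0.15,
               lifetime = 1e5, f_i = 0.4)
  n0 <- drake_point(do.call(drake_params, base))
  for (nm in names(base)) {
    doubled <- base
    doubled[[nm]] <- base[[nm]] * 2
    expect_equal(drake_point(do.call(drake_params, doubled)), 2 * n0,
                 info = nm)
  }
})

test_that("interval arithmetic gives products of endpoints", {
  r <- drake_interval(drake_scenario("drake1961"))
  expect_equal(r$low, 20)
  expect_equal(r$high, 5e7)
  expect_false(r$bound)

  copt <- drake_interval(drake_scenario("copt"))
  expect_equal(copt$low, 1 * 0.2 * 1 * 1 * 0.00016 * 0.17 * 5e8)
  expect_equal(copt$low, 2720)
  expect_equal(copt$high, 1 * 0.5 * 5 * 1 * 0.011 * 0.17 * 5e8)
  expect_equal(copt$high, 2.3375e6)
  expect_true(copt$bound)    # f_pt is one-sided, the flag propagates

  degen <- drake_params(1, 0.3, 2, 1, f_c = 0.1, lifetime = 1e4, f_i = 0.5)
  rd <- drake_interval(degen)
  expect_equal(rd$low, rd$high)
})

test_that("scaling a published ACC range by f_i bounds", {
  scaled <- scale_acc_range(c(200, 5e7), c(3e-5, 2e-3))
  expect_equal(as.numeric(scaled), c(0.006, 1e5))
  expect_identical(attr(scaled, "bound"), "upper")
  expect_equal(as.numeric(scale_acc_range(c(200, 5e7), c(1, 1))), c(200, 5e7))
  expect_equal(as.numeric(scale_acc_range(c(1000, 1e8), c(3e-5, 2e-3))),
               c(0.03, 2e5))
  expect_error(scale_acc_range(c(-1, 2), c(0, 1)), "non-negative")
  expect_error(scale_acc_range(c(2, 1), c(0, 1)), "low <= high")
})

test_that("Monte Carlo samples stay inside interval bounds, reproducibly", {
  params <- drake_scenario("modified_acc")
  bounds <- drake_interval(params)
  mc <- drake_monte_carlo(params, 2e4, seed = 99)
  expect_gte(min(mc$samples), bounds$low)
  expect_lte(max(mc$samples), bounds$high)
  expect_true(mc$bound)
  expect_true(mc$p_ge_1 >= 0 && mc$p_ge_1 <= 1)
  expect_lte(mc$q025, mc$median)
  expect_lte(mc$median, mc$q975)

  mc2 <- drake_monte_carlo(params, 2e4, seed = 99)
  expect_identical(mc$samples, mc2$samples)
  expect_equal(mc$mean, mc2$mean)

  # degenerate distributions collapse onto the point product
  pt <- drake_params(1, 0.3, 2, 1, f_c = 0.1, lifetime = 1e4, f_i = 0.5)
  mc_pt <- drake_monte_carlo(pt, 500, seed = 1)
  expect_true(all(mc_pt$samples == drake_point(pt)))

  expect_error(drake_monte_carlo(params, 0, seed = 1), "positive")
  expect_error(drake_monte_carlo(params, 100), "seed")
})

test_that("wide terms default to log-uniform sampling, narrow to uniform", {
  expect_identical(drake_term(low = 1e3, high = 1e8)$dist, "loguniform")
  expect_identical(drake_term(low = 0.00016, high = 0.011)$dist,
                   "loguniform")
  expect_identical(drake_term(low = 0.2, high = 0.5)$dist, "uniform")
  expect_identical(drake_term(low = 1, high = 5)$dist, "uniform")
  expect_identical(drake_term(0.17)$dist, "point")
  expect_error(drake_term(low = 0, high = 10, dist = "loguniform"),
               "log-uniform")
  expect_error(drake_term(low = 1, high = 2, dist = "gamma"),
               "unknown distribution")
})

test_that("ACC and COPT modes agree when f_c = 1 and L = L_COPT", {
  acc <- drake_params(1, 0.3, 2, 1, f_c = 1, lifetime = 5e8,
                      f_oc = 0.001, f_pt = 0.17)
  copt <- drake_params(1, 0.3, 2, 1, lifetime = 5e8,
                       f_oc = 0.001, f_pt = 0.17, mode = "copt")
  expect_equal(drake_interval(acc)$low, drake_interval(copt)$low)
  expect_equal(drake_interval(acc)$high, drake_interval(copt)$high)

  # and splitting f_i = f_oc * f_pt changes nothing
  fi <- drake_params(1, 0.3, 2, 1, f_c = 1, lifetime = 5e8,
                     f_i = 0.001 * 0.17)
  expect_equal(drake_interval(fi)$low, drake_interval(acc)$low)
})
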