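th20k <- threshold_policy(20000)
varying_line <- linear_profile(0.1662, -0.006, -860, 1996)
constant_92 <- constant_profile(0.1492, 1171)

test_that("discount factors follow the stated exponent conventions", {
  undis <- discount_spec(0.03, "first_year_undiscounted")
  disc <- discount_spec(0.03, "first_year_discounted")
  expect_equal(discount_factor(1, undis), 1)
  expect_equal(discount_factor(1, disc), 1 / 1.03)
  expect_equal(discount_factor(5, undis), 1.03^-4)
  expect_equal(discount_factor(3, discount_spec(0)), 1)
  expect_equal(discount_factor(3, discount_spec(0, "first_year_discounted")), 1)
  expect_error(discount_factor(0, undis), "t must be")
  expect_error(discount_spec(-0.01), ">= 0")
})

test_that("linear diffusion builds the uptake path and caps at full uptake", {
  path <- linear_diffusion(0.09, 0.06, 15)
  expect_equal(path[1], 0.09)
  expect_equal(path[15], 0.93)
  expect_equal(pmin(1, path + 0.03)[1], 0.12)
  expect_equal(linear_diffusion(0.5, 0, 4), rep(0.5, 4))
  expect_equal(linear_diffusion(0.9, 0.2, 3), c(0.9, 1, 1))
})

test_that("a single undiscounted year reduces every stream to its static counterpart", {
  for (prof in list(varying_line, constant_92)) {
    sched <- schedule_set(1, 10000, 0.2, strategy = 0.4, costs = 50000)
    spec <- discount_spec(0)
    s <- static_scenario(10000, 0.2, 0.4, profile = prof, threshold = th20k,
                         strategy_cost = 50000)
    expect_equal(cumulative_value(current_value_stream(sched, prof, th20k, spec)),
                 current_value(s))
    expect_equal(cumulative_value(perfect_value_stream(sched, prof, th20k, spec)),
                 perfect_value(s))
    expect_equal(cumulative_value(actual_value_stream(sched, prof, th20k, spec)),
                 actual_value(s))
    expect_equal(cumulative_value(net_value_stream(sched, prof, th20k, spec)),
                 net_value_of_strategy(s))
  }
})

test_that("stream totals match the brute-force year loop on seeded random scenarios", {
  for (seed in 1:50) {
    sc <- random_scenario(seed)
    k <- sc$threshold$k
    for (kind in c("current", "perfect", "actual", "net")) {
      fn <- switch(kind, current = current_value_stream,
                   perfect = perfect_value_stream,
                   actual = actual_value_stream, net = net_value_stream)
      tab <- fn(sc$schedule, sc$profile, sc$threshold, sc$discount)
      expect_equal(cumulative_value(tab),
                   oracle_stream_total(sc$schedule, sc$profile, k,
                                       sc$discount$rate, sc$discount$convention,
                                       kind),
                   tolerance = 1e-9)
    }
  }
})

test_that("first-year-discounted values are the undiscounted ones divided by 1+r", {
  sched <- schedule_set(10, 10000, linear_diffusion(0.1, 0.05, 10),
                        strategy = linear_diffusion(0.15, 0.05, 10))
  r <- 0.035
  a <- actual_value_stream(sched, varying_line, th20k,
                           discount_spec(r, "first_year_undiscounted"))
  b <- actual_value_stream(sched, varying_line, th20k,
                           discount_spec(r, "first_year_discounted"))
  expect_equal(b$value, a$value / (1 + r), tolerance = 1e-12)
})

test_that("with no discounting the dynamic total is the sum of per-year static values", {
  sched <- schedule_set(8, 10000, linear_diffusion(0.1, 0.08, 8))
  tab <- current_value_stream(sched, varying_line, th20k, discount_spec(0))
  statics <- vapply(sched$baseline, function(p)
    current_value(static_scenario(10000, p, profile = varying_line,
                                  threshold = th20k)), numeric(1))
  expect_equal(cumulative_value(tab), sum(statics), tolerance = 1e-9)
})

test_that("discounted totals fall as the rate rises when yearly values are non-negative", {
  sched <- schedule_set(10, 10000, linear_diffusion(0.6, 0.04, 10))
  totals <- vapply(c(0, 0.01, 0.03, 0.06), function(r)
    cumulative_value(current_value_stream(sched, varying_line, th20k,
                                          discount_spec(r))), numeric(1))
  expect_true(all(diff(totals) < 0))
})

test_that("yearly strategy costs shift the net stream by their discounted sum", {
  sched0 <- schedule_set(5, 10000, 0.2, strategy = 0.3, costs = 0)
  sched1 <- schedule_set(5, 10000, 0.2, strategy = 0.3, costs = 1e5)
  spec <- discount_spec(0.03)
  net0 <- net_value_stream(sched0, varying_line, th20k, spec)
  net1 <- net_value_stream(sched1, varying_line, th20k, spec)
  act <- actual_value_stream(sched0, varying_line, th20k, spec)
  expect_equal(net0$value, act$value, tolerance = 1e-12)
  expect_equal(net1$value, act$value - 1e5 * act$discount_factor,
               tolerance = 1e-12)
  # unchanged uptake means an all-zero actual stream
  flat <- schedule_set(5, 10000, 0.3, strategy = 0.3)
  expect_equal(actual_value_stream(flat, varying_line, th20k, spec)$value,
               rep(0, 5))
})

test_that("cumulative windows sum the selected column and validate their bounds", {
  sched <- schedule_set(6, 10000, linear_diffusion(0.1, 0.1, 6))
  tab <- current_value_stream(sched, list(constant = constant_92,
                                          varying = varying_line),
                              th20k, discount_spec(0.03))
  expect_equal(cumulative_value(tab, 1, 6, "constant"),
               attr(tab, "totals")[["constant"]])
  expect_equal(cumulative_value(tab, 3, 3, "varying"), tab$varying[3])
  expect_equal(cumulative_value(tab, 2, 4, "varying"), sum(tab$varying[2:4]))
  expect_error(cumulative_value(tab, 0, 3), "window")
  expect_error(cumulative_value(tab, 2, 9), "window")
  expect_error(cumulative_value(tab, column = "nope"), "no value column")
})

test_that("monetary losses convert to QALYs at the threshold", {
  expect_equal(qaly_equivalent(-12896324, th20k), 644.8162)
  expect_equal(qaly_equivalent(40000, th20k), 2)
  expect_equal(qaly_equivalent(0, th20k), 0)
})

test_that("schedules broadcast scalars and reject malformed paths", {
  s <- schedule_set(4, 10000, 0.2, costs = 100)
  expect_equal(s$population, rep(10000, 4))
  expect_equal(s$costs, rep(100, 4))
  expect_error(schedule_set(4, 10000, c(0.1, 0.2)), "length 4")
  expect_error(schedule_set(4, 10000, 1.5), "\\[0, 1\\]")
  expect_error(schedule_set(4, 10000, 0.2, costs = -1), ">= 0")
  expect_error(actual_value_stream(schedule_set(4, 1000, 0.2), varying_line,
                                   th20k, discount_spec(0.03)), "strategy")
})
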