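test_that("meta-model fit agrees with closed-form least squares on the case triples", {
  fit <- nmb_metamodel(mp_triples)
  h <- ols_line(mp_triples$p, mp_triples$delta_qaly)
  cc <- ols_line(mp_triples$p, mp_triples$delta_cost)
  expect_equal(unname(coef(fit)["health", ]), unname(h), tolerance = 1e-12)
  expect_equal(unname(coef(fit)["cost", ]), unname(cc), tolerance = 1e-12)
  expect_equal(fit$r.squared[["health"]],
               ols_r2(mp_triples$p, mp_triples$delta_qaly), tolerance = 1e-12)
  expect_equal(fit$r.squared[["cost"]],
               ols_r2(mp_triples$p, mp_triples$delta_cost), tolerance = 1e-12)
  # rounded coefficients match the reported lines
  expect_equal(round(coef(fit)["health", "slope"], 4), 0.1662)
  expect_equal(round(coef(fit)["health", "intercept"], 4), -0.006)
  expect_equal(round(coef(fit)["cost", "slope"]), -860)
  expect_equal(round(coef(fit)["cost", "intercept"]), 1996)
})

test_that("noiseless linear data is recovered exactly with R-squared 1", {
  set.seed(7)
  for (i in 1:20) {
    ah <- runif(1, -0.2, 0.2); bh <- runif(1, 0, 0.2)
    ac <- runif(1, -2000, 2000); bc <- runif(1, 0, 3000)
    p <- sort(runif(sample(3:9, 1)))
    fit <- nmb_metamodel(data.frame(p = p,
                                    delta_qaly = ah * p + bh,
                                    delta_cost = ac * p + bc))
    expect_equal(unname(coef(fit)["health", ]), c(ah, bh), tolerance = 1e-9)
    expect_equal(unname(coef(fit)["cost", ]), c(ac, bc), tolerance = 1e-9)
    expect_equal(unname(fit$r.squared), c(1, 1), tolerance = 1e-9)
    # OLS residuals sum to zero
    expect_equal(unname(colSums(residuals(fit))), c(0, 0), tolerance = 1e-8)
  }
})

test_that("degenerate fits and undefined R-squared raise errors", {
  expect_error(nmb_metamodel(data.frame(p = 0.5, delta_qaly = 1, delta_cost = 1)),
               "degenerate")
  expect_error(nmb_metamodel(data.frame(p = c(0.5, 0.5),
                                        delta_qaly = c(1, 2),
                                        delta_cost = c(1, 2))), "degenerate")
  expect_error(nmb_metamodel(data.frame(x = 1:3)), "columns")
  # flat response: slope estimable but R^2 is 0/0
  expect_error(nmb_metamodel(data.frame(p = c(0.1, 0.9),
                                        delta_qaly = c(1, 1),
                                        delta_cost = c(2, 3))), "R-squared")
})

test_that("predictions and profile extraction are consistent with the coefficients", {
  fit <- nmb_metamodel(mp_triples)
  th <- threshold_policy(mp_k)
  p <- c(0, 0.3, 0.92, 1)
  cf <- coef(fit)
  expect_equal(predict(fit, p, "health"), cf["health", "slope"] * p + cf["health", "intercept"])
  expect_equal(predict(fit, p, "nmb", threshold = th),
               mp_k * predict(fit, p, "health") - predict(fit, p, "cost"))
  expect_error(predict(fit, 0.5, "nmb"), "threshold")

  rounded <- as_linear_profile(fit, rounded = TRUE)
  line <- as_nmb_line(rounded, th)
  expect_equal(line$slope, 4184)
  expect_equal(line$intercept, -2116)
  full <- as_linear_profile(fit, rounded = FALSE)
  expect_equal(net_monetary_benefit(full, th, p),
               predict(fit, p, "nmb", threshold = th), tolerance = 1e-12)
})

test_that("break-even solves the NMB root and brackets the sign change", {
  be <- break_even(nmb_line(4184, -2116))
  expect_equal(be$level, 2116 / 4184, tolerance = 1e-9)
  expect_equal(be$rounded_percent, 51L)
  expect_equal(be$status, "crosses_zero")
  # sign(NMB(p)) = sign(p - p*) around the root
  line <- nmb_line(4184, -2116)
  expect_lt(predict(line, be$level - 0.01), 0)
  expect_gt(predict(line, be$level + 0.01), 0)

  expect_equal(break_even(nmb_line(-1000, 500))$level, 0.5, tolerance = 1e-9)
  expect_equal(break_even(nmb_line(0, 1813))$status, "always_cost_effective")
  expect_equal(break_even(nmb_line(0, -10))$status, "never_cost_effective")
  expect_equal(break_even(nmb_line(100, 5))$status, "always_cost_effective")

  th <- threshold_policy(mp_k)
  expect_equal(break_even(constant_profile(0.1492, 1171), th)$status,
               "always_cost_effective")
  expect_equal(break_even(nmb_metamodel(mp_triples), th)$rounded_percent, 51L)
})

test_that("tabulated break-even finds the smallest root and flags multiplicity", {
  th <- threshold_policy(10000)
  # dH knots give NMB crossing zero twice: +, -, + pattern
  tab <- tabulated_profile(c(0, 0.25, 0.5, 0.75, 1),
                           c(0.02, -0.01, -0.01, 0.03, 0.05),
                           c(0, 0, 0, 0, 0))
  be <- break_even(tab, th)
  expect_true(be$multiple_roots)
  expect_equal(net_monetary_benefit(tab, th, be$level), 0, tolerance = 1e-6)
  # smallest root is on the first segment (0, 0.25)
  expect_lt(be$level, 0.25)

  mono <- tabulated_profile(c(0, 1), c(0, 0.1), c(500, 400))
  be2 <- break_even(mono, th)
  expect_false(be2$multiple_roots)
  expect_equal(net_monetary_benefit(mono, th, be2$level), 0, tolerance = 1e-6)
})

test_that("triples round-trip through the delimited-file reader", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(mp_triples, path, row.names = FALSE)
  expect_equal(read_marginal_triples(path), mp_triples)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_marginal_triples(bad), "delta_qaly")
})
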