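test_that("registry constants equal independent evaluations of the printed expressions", {
  e <- exp(1)
  expected <- list(
    GN = sqrt(2 * e * e^(1 / 4)) / 4,
    SN = sqrt(2 * sqrt(e)) / 4,
    SSN = sqrt(2 * sqrt(e * e^(1 / 4))) / 4,
    GT = sqrt(34) * (sqrt(17) - 1) / 136,
    TREES = 1 / sqrt(2),
    T_UNION = sqrt(e / 2))
  for (nm in names(expected)) {
    expect_equal(exp(asym_registry(nm)$logC), expected[[nm]],
                 tolerance = 1e-14, info = nm)
  }
  for (k in 1:3) {
    expect_equal(exp(asym_registry("TC_k", k = k)$logC),
                 2^(k - 1) * sqrt(2) / factorial(k), tolerance = 1e-14)
    expect_equal(exp(asym_registry("NN_k", k = k)$logC),
                 2^(k - 1) * sqrt(2) / factorial(k), tolerance = 1e-14)
    expect_equal(exp(asym_registry("GT_k", k = k)$logC),
                 2^(2 * k - 1) * sqrt(2) / factorial(2 * k), tolerance = 1e-14)
    expect_equal(exp(asym_registry("STC_k", k = k)$logC),
                 sqrt(2) / (2 * factorial(k)), tolerance = 1e-14)
  }
  # geometric bases and scales as printed
  expect_equal(exp(asym_registry("GN")$log_gamma), 8 / exp(2))
  expect_equal(asym_registry("GN")$m, 2)
  expect_equal(exp(asym_registry("GT")$log_gamma), 8 / exp(1))
  expect_equal(asym_registry("GT")$m, 1)
  expect_equal(exp(asym_registry("TC_k", k = 1)$log_gamma), 2 / exp(1))
  # Airy-root constant of the Theta form, against the known 12-digit value
  expect_equal(asym_registry("TC_THETA")$s, -2.33810741045977,
               tolerance = 1e-13)
})

test_that("log-space evaluation is increasing and matches exact sequences", {
  trees <- asym_registry("TREES")
  vals <- asymptotic_value(trees, c(10, 11, 200, 201))
  expect_true(all(diff(vals) > 0))
  # exact/asymptotic ratio approaches 1 (within 2% at l = 500)
  ratio500 <- exp(log(trees_count(500)) - asymptotic_value(trees, 500))
  expect_equal(ratio500, 1, tolerance = 0.02)
  ratio60 <- exp(log(trees_count(60)) - asymptotic_value(trees, 60))
  expect_lt(abs(ratio500 - 1), abs(ratio60 - 1))  # error shrinks with l

  # the two printed forms of the galled-network asymptotics agree to 1%
  l <- 1e4
  second_form <- 0.5 * (log(2) + 1.25) - log(8 * pi) - 2 * log(l) +
    l * log(8) + 2 * lgamma(l + 1)
  expect_equal(exp(asymptotic_value(asym_registry("GN"), l) - second_form),
               1, tolerance = 0.01)
})

test_that("binomial transfer multiplies tree-scale constants by sqrt(e)", {
  tr <- binomial_transfer(asym_registry("TREES"))
  expect_equal(exp(tr$logC), sqrt(exp(1) / 2), tolerance = 1e-14)
  expect_equal(tr$logC, asym_registry("T_UNION")$logC, tolerance = 1e-14)

  tck <- binomial_transfer(asym_registry("TC_k", k = 3))
  expect_equal(exp(tck$logC), 2^2 * sqrt(2 * exp(1)) / factorial(3),
               tolerance = 1e-14)

  gn <- binomial_transfer(asym_registry("GN"))
  expect_identical(gn$logC, asym_registry("GN")$logC)  # m = 2: unchanged

  expect_error(binomial_transfer(asym_registry("TC_OMEGA")), "tilde")
})

test_that("transfer law validated against the exact big-integer convolution", {
  tr <- binomial_transfer(asym_registry("TREES"))
  ratio <- exp(log(binomial_convolution(trees_count, 500)) -
                 asymptotic_value(tr, 500))
  expect_equal(ratio, 1, tolerance = 0.01)
})

test_that("limit ratios come out of the registry, not hardcoded values", {
  sn <- binomial_transfer(asym_registry("SN"))
  gn <- binomial_transfer(asym_registry("GN"))
  ssn <- binomial_transfer(asym_registry("SSN"))
  expect_equal(limit_ratio(sn, gn), exp(-3 / 8), tolerance = 1e-12)
  expect_equal(limit_ratio(sn, ssn), exp(-1 / 16), tolerance = 1e-12)
  expect_equal(limit_ratio(gn, gn), 1)

  gt2 <- binomial_transfer(asym_registry("GT_le_k", k = 2))
  tc2 <- binomial_transfer(asym_registry("TC_le_k", k = 2))
  expect_equal(limit_ratio(gt2, tc2), 1 / 3, tolerance = 1e-12)

  # trees vanish inside normal networks with k >= 1 reticulations
  tr <- binomial_transfer(asym_registry("TREES"))
  for (k in 1:3) {
    z <- limit_ratio(tr, binomial_transfer(asym_registry("NN_k", k = k)))
    expect_identical(as.numeric(z), 0)
    expect_match(attr(z, "dominance"), "dominates")
  }

  # galled trees vanish inside all tree-child networks (different scales)
  gt <- binomial_transfer(asym_registry("GT"))
  z <- limit_ratio(gt, gn)
  expect_identical(as.numeric(z), 0)

  # a numerator that dominates its denominator is flagged as inconsistent
  expect_error(limit_ratio(gn, gt), "dominates")
  expect_error(limit_ratio(asym_registry("TC_THETA"), gn), "tilde")
})
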