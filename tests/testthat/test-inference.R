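test_that("hdi equals the exhaustive minimal-window oracle", {
  expect_equal(unname(hdi(1:100, 0.95)), hdi_exhaustive(1:100, 0.95))
  h <- hdi(1:100, 0.95)
  expect_equal(sum(1:100 >= h["lower"] & 1:100 <= h["upper"]), 95)
  set.seed(30)
  for (rep in 1:20) {
    x <- switch(1 + rep %% 3,
                rnorm(sample(30:200, 1)),
                rexp(sample(30:200, 1)),
                rbeta(sample(30:200, 1), 2, 5))
    m <- runif(1, 0.5, 0.97)
    expect_equal(unname(suppressWarnings(hdi(x, m))), hdi_exhaustive(x, m))
  }
})

test_that("hdi approximates analytic normal quantiles and handles constants", {
  set.seed(31)
  h <- hdi(rnorm(10000), 0.95)
  expect_lt(abs(h[["lower"]] + 1.96), 0.08)
  expect_lt(abs(h[["upper"]] - 1.96), 0.08)
  hc <- hdi(rep(3.5, 50))
  expect_equal(unname(hc), c(3.5, 3.5))
  expect_error(hdi(1:5), "too few samples")
})

test_that("hdi is never wider than the equal-tailed interval", {
  set.seed(32)
  for (rep in 1:15) {
    x <- rgamma(500, shape = runif(1, 0.5, 5))
    h <- hdi(x, 0.9)
    q <- quantile(x, c(0.05, 0.95), names = FALSE)
    expect_lte(h[["upper"]] - h[["lower"]], q[2] - q[1] + 1e-12)
  }
})

test_that("probability-scale transform is the divide-by-four rule", {
  expect_equal(to_probability_scale(1), 0.25)
  expect_equal(to_probability_scale(0), 0)
  x <- rnorm(10)
  expect_equal(to_probability_scale(2 * x), 2 * to_probability_scale(x))
})

test_that("p_rope matches hand counts on a constructed sample", {
  expect_equal(p_rope(rep(0, 100)), 1)
  expect_equal(p_rope(rep(0.5, 100)), 0)
  # 40-point sample: the 38-point HDI window drops the two large outliers,
  # leaving 36 of 38 retained draws inside the ROPE
  x <- c(seq(-0.02, 0.02, length.out = 36), 0.04, 0.05, 10, 12)
  expect_equal(p_rope(x, rope = c(-0.025, 0.025)), 36 / 38)
  expect_equal(p_rope(x, rope = c(-0.025, 0.025), within_hdi = FALSE), 36 / 40)
  # a posterior far outside the ROPE scores zero
  set.seed(33)
  expect_equal(p_rope(rnorm(1000, mean = 5, sd = 0.1)), 0)
})

test_that("per-unit effects rescale by the raw predictor SD", {
  expect_equal(per_unit_effect(0.4, 5), 0.08)
  expect_equal(per_unit_effect(0, 3), 0)
  # measuring cognateness in 10% steps (10x the raw SD unit) scales the
  # per-unit effect down tenfold
  expect_equal(per_unit_effect(0.3, 3), 0.1 * per_unit_effect(0.3, 0.3))
  expect_error(per_unit_effect(0.4, 0), "positive")
})

test_that("posterior summaries report both scales and p(ROPE)", {
  set.seed(34)
  nd <- 2000
  beta <- cbind(rnorm(nd, 0.4, 0.05), rnorm(nd, 0, 0.01),
                matrix(rnorm(nd * 7, 0, 0.05), nd, 7))
  tau <- cbind(rnorm(nd, -0.4, 0.05), rnorm(nd, 0.6, 0.05))
  fit <- fake_fit(beta, tau)
  s <- summarize_posterior(fit)
  expect_equal(s$term, irt_fixed_terms())
  age <- s[s$term == "age", ]
  expect_equal(age$prob_estimate, age$estimate / 4, tolerance = 1e-12)
  expect_equal(age$p_rope, 0)             # well outside the ROPE
  expect_gt(s$p_rope[s$term == "exposure"], 0.99)  # tight null slope
  expect_true(all(s$conf.low <= s$estimate & s$estimate <= s$conf.high))
  st <- summarize_posterior(fit, include_thresholds = TRUE)
  expect_equal(st$term[1:2], c("tau_comprehension", "tau_production"))
  expect_equal(st$prob_estimate[1], plogis(0.4), tolerance = 0.02)
})

test_that("marginal effects reduce to the category pmf and respect monotonicity", {
  # single draw with only an age effect: curves follow the logistic exactly
  beta <- matrix(0, 1, 9)
  beta[1, 1] <- 1   # age slope on the standardized scale
  tau <- matrix(c(-0.5, 0.5), 1, 2)
  fit <- fake_fit(beta, tau)
  me <- suppressWarnings(marginal_effects(fit, age = c(17, 22, 27),
                                          exposure = 0.5, cognateness = 0.5,
                                          length = 5, frequency = 4.5))
  sc <- fit$scales
  z_age <- (c(17, 22, 27) - sc$mean[sc$term == "age"]) / sc$sd[sc$term == "age"]
  z_cog <- (0.5 - sc$mean[sc$term == "cognateness"]) /
    sc$sd[sc$term == "cognateness"]
  z_len <- (5 - sc$mean[sc$term == "length"]) / sc$sd[sc$term == "length"]
  # eta = z_age since all other coefficients are zero
  comp <- me[me$outcome == "comprehension", ]
  pr <- category_probabilities(z_age, -0.5, 0.5)
  expect_equal(comp$estimate, 1 - pr$p_no, tolerance = 1e-12)
  prod <- me[me$outcome == "production", ]
  expect_equal(prod$estimate, pr$p_understands_says, tolerance = 1e-12)
  # monotone non-decreasing in age when the age draw is positive
  expect_true(all(diff(comp$estimate) > 0))
  # zero-coefficient draws give flat curves at the threshold-implied baseline
  fit0 <- fake_fit(matrix(0, 1, 9), tau)
  me0 <- marginal_effects(fit0, age = c(15, 20, 25), exposure = 0.5,
                          cognateness = 0.5, length = 5, frequency = 4.5)
  c0 <- me0[me0$outcome == "comprehension", ]
  expect_equal(c0$estimate, rep(plogis(0.5), 3))
  expect_warning(marginal_effects(fit0, age = c(5, 40)), "extrapolation")
})
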