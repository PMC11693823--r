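test_that("null GLMM simulation matches the closed-form category rates", {
  cfg <- sim_config(n_participants = 100, n_tes = 30, tau = c(-0.5, 0.5),
                    beta = setNames(rep(0, 9), irt_fixed_terms()),
                    sd_participant = setNames(rep(0, 8),
                                              irt_participant_terms()),
                    sd_te = setNames(rep(0, 4), irt_te_terms()))
  sim <- simulate_glmm(cfg, seed = 40)
  freq <- as.vector(table(factor(sim$data$response, levels = 0:2))) /
    nrow(sim$data)
  expected <- c(plogis(-0.5), plogis(0.5) - plogis(-0.5), plogis(-0.5))
  expect_lt(max(abs(freq - expected)), 0.02)
})

test_that("a positive age effect raises acquisition across age quartiles", {
  cfg <- sim_config(n_participants = 80, n_tes = 20,
                    beta = setNames(c(1, rep(0, 8)), irt_fixed_terms()),
                    sd_participant = setNames(rep(0, 8),
                                              irt_participant_terms()),
                    sd_te = setNames(rep(0, 4), irt_te_terms()))
  d <- simulate_glmm(cfg, seed = 41)$data
  q <- cut(d$age, quantile(d$age, 0:4 / 4), include.lowest = TRUE)
  acq <- tapply(d$response >= 1, q, mean)
  expect_true(all(diff(acq) > 0))
})

test_that("simulators are deterministic under a fixed seed", {
  cfg <- sim_config(n_participants = 10, n_tes = 5)
  expect_identical(simulate_glmm(cfg, seed = 7), simulate_glmm(cfg, seed = 7))
  p <- accumulator_params()
  expect_identical(simulate_accumulator(p, cfg, seed = 7),
                   simulate_accumulator(p, cfg, seed = 7))
  expect_identical(make_participants(cfg, seed = 3),
                   make_participants(cfg, seed = 3))
})

test_that("accumulator closed form behaves as the theory states", {
  p0 <- accumulator_params(gamma = 0)
  # gamma = 0: accrual ignores similarity entirely
  a1 <- accumulated_instances(p0, 1, 20, 0.5, 0.5, 1, 1, similarity = 0)
  a2 <- accumulated_instances(p0, 1, 20, 0.5, 0.5, 1, 1, similarity = 1)
  expect_equal(a1, a2)
  # gamma = 1, identical forms, balanced exposure: as if exposure doubled
  p1 <- accumulator_params(gamma = 1)
  full <- accumulated_instances(p1, 1, 20, 0.5, 0.5, 1, 1, similarity = 1)
  doubled <- accumulated_instances(p0, 1, 20, 1.0, 0, 1, 1, similarity = 0)
  expect_equal(full, doubled)
  # monotone in age, token weight, and own exposure
  ph <- accumulator_params(gamma = 0.5)
  ages <- seq(12, 32, by = 2)
  A_age <- accumulated_instances(ph, 1, ages, 0.4, 0.6, 1, 1, 0.5)
  expect_true(all(diff(A_age) > 0))
  A_om <- accumulated_instances(ph, 1, 20, 0.4, 0.6, c(0.5, 1, 2),
                                c(0.5, 1, 2), 0.5)
  expect_true(all(diff(A_om) > 0))
  A_ex <- accumulated_instances(ph, 1, 20, c(0.2, 0.5, 0.8),
                                c(0.8, 0.5, 0.2), 1, 1, 0.5)
  expect_true(all(diff(A_ex) > 0))
  # and monotone in similarity for the lower-exposure language
  A_sim <- accumulated_instances(ph, 1, 20, 0.2, 0.8, 1, 1, c(0, 0.5, 1))
  expect_true(all(diff(A_sim) > 0))
})

test_that("co-activation concentrates cognate facilitation in the lower-exposure language", {
  # analytic check on a matched item grid, before any sampling noise:
  # at 80/20 exposure, the cognate-vs-non-cognate acquisition gap is larger
  # for the 20% language than for the 80% language
  p <- accumulator_params(gamma = 0.5)
  ages <- seq(12, 32, length.out = 101)
  acquired <- function(E, Eo, s) {
    mean(accumulated_instances(p, 1, ages, E, Eo, 1, 1, s) >= p$theta_comp)
  }
  gap_low <- acquired(0.2, 0.8, 1) - acquired(0.2, 0.8, 0)
  gap_high <- acquired(0.8, 0.2, 1) - acquired(0.8, 0.2, 0)
  expect_gt(gap_low, gap_high)
  expect_gt(gap_low, 0)
})

test_that("accumulator responses cross thresholds and add report noise", {
  cfg <- sim_config(n_participants = 40, n_tes = 15)
  clean <- simulate_accumulator(accumulator_params(report_noise = 0),
                                cfg, seed = 50)
  expect_true(all(clean$response == clean$response_true))
  expect_true(all(clean$response %in% 0:2))
  # all three categories occur at realistic rates
  freq <- table(factor(clean$response, levels = 0:2)) / nrow(clean)
  expect_true(all(freq > 0.05))
  noisy <- simulate_accumulator(accumulator_params(report_noise = 0.1),
                                cfg, seed = 50)
  flips <- mean(noisy$response != noisy$response_true)
  expect_lt(abs(flips - 0.1), 0.03)
  # flipped responses move to an adjacent category only
  expect_true(all(abs(noisy$response - noisy$response_true) <= 1))
})

test_that("participant generator covers the exposure-exclusion workflow", {
  cfg <- sim_config(n_participants = 50, exposure_range = c(0.5, 0.5))
  parts <- make_participants(cfg, seed = 60)
  expect_equal(parts$prop_catalan, rep(0.5, 50))
  expect_equal(parts$prop_spanish, rep(0.5, 50))
  cfg2 <- sim_config(n_participants = 50, prop_other_fraction = 0.2,
                     prop_other_value = 0.12)
  parts2 <- make_participants(cfg2, seed = 61)
  expect_equal(sum(parts2$prop_other > 0), 10)
  kept <- exclude_participants(parts2)
  expect_equal(nrow(kept), 40)
  expect_setequal(kept$participant_id,
                  parts2$participant_id[parts2$prop_other == 0])
  expect_equal(parts2$prop_catalan + parts2$prop_spanish + parts2$prop_other,
               rep(1, 50))
})

test_that("item fixtures realize requested counts with first-failure semantics", {
  fx <- make_item_fixture()
  expect_equal(nrow(fx), 1590)
  # items built to fail a later stage pass all earlier predicates
  ml <- fx[fx$lemma_count > 1, ]
  expect_true(all(ml$class == "noun" & ml$has_frequency))
  mw <- fx[fx$is_multiword, ]
  expect_true(all(mw$class == "noun" & mw$has_frequency & mw$lemma_count == 1))
  un <- fx[!fx$has_translation, ]
  expect_true(all(un$class == "noun" & un$has_frequency &
                    un$lemma_count == 1 & !un$is_multiword))
})
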