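test_that("category probabilities match the closed-form logistic pmf", {
  p <- category_probabilities(0, -1, 1)
  expect_equal(p$p_no, plogis(-1))
  expect_equal(p$p_understands, plogis(1) - plogis(-1))
  expect_equal(p$p_understands_says, plogis(-1))
  expect_equal(round(unlist(p), 5),
               c(p_no = 0.26894, p_understands = 0.46212,
                 p_understands_says = 0.26894))
  # limits and conservation
  far <- category_probabilities(50, -1, 1)
  expect_equal(unlist(far), c(p_no = 0, p_understands = 0,
                              p_understands_says = 1), tolerance = 1e-12)
  set.seed(5)
  eta <- rnorm(200, sd = 3)
  pm <- category_probabilities(eta, -0.4, 0.6)
  expect_equal(rowSums(as.matrix(pm)), rep(1, 200))
  expect_error(category_probabilities(0, 1, 1), "ordered")
})

test_that("P(response >= k) increases strictly with eta", {
  eta <- seq(-4, 4, by = 0.5)
  p <- category_probabilities(eta, -0.4, 0.6)
  expect_true(all(diff(1 - p$p_no) > 0))
  expect_true(all(diff(p$p_understands_says) > 0))
})

test_that("linear predictor expands fixed and random terms correctly", {
  rec <- tibble::tibble(age = 2, exposure = -1, cognateness = 0.5,
                        length = 1, frequency = -0.5)
  zero <- setNames(rep(0, 9), irt_fixed_terms())
  expect_equal(linear_predictor(rec, zero), 0)
  age_only <- zero
  age_only["age"] <- 1
  expect_equal(linear_predictor(rec, age_only), 2)
  # full term set against a hand-expanded sum
  set.seed(8)
  beta <- setNames(rnorm(9), irt_fixed_terms())
  expected <- beta["age"] * 2 + beta["exposure"] * -1 +
    beta["cognateness"] * 0.5 + beta["length"] * 1 +
    beta["frequency"] * -0.5 + beta["age:exposure"] * (2 * -1) +
    beta["age:cognateness"] * (2 * 0.5) +
    beta["exposure:cognateness"] * (-1 * 0.5) +
    beta["age:exposure:cognateness"] * (2 * -1 * 0.5)
  expect_equal(linear_predictor(rec, beta), unname(expected))
  # random-effect deviations add through their own design
  rp <- matrix(0, 1, 8, dimnames = list(NULL, irt_participant_terms()))
  rp[1, "(Intercept)"] <- 0.3
  rp[1, "age"] <- 0.1
  expect_equal(linear_predictor(rec, zero, re_participant = rp), 0.3 + 0.1 * 2)
  expect_error(linear_predictor(rec[, -1], zero), "missing predictor")
})

test_that("log likelihood matches direct pmf evaluation and is additive", {
  rec1 <- tibble::tibble(age = 0, exposure = 0, cognateness = 0, length = 0,
                         frequency = 0, response = 0L)
  zero <- setNames(rep(0, 9), irt_fixed_terms())
  expect_equal(log_likelihood(list(tau = c(0, 1), beta = zero), rec1),
               log(0.5))
  d <- tiny_records(20, seed = 2)
  set.seed(3)
  beta <- setNames(rnorm(9, sd = 0.5), irt_fixed_terms())
  params <- list(tau = c(-0.5, 0.5), beta = beta)
  ll <- log_likelihood(params, d)
  # independent per-record oracle
  eta <- linear_predictor(d, beta)
  pr <- as.matrix(category_probabilities(eta, -0.5, 0.5))
  expect_equal(ll, sum(log(pr[cbind(1:20, d$response + 1)])))
  # duplicating the dataset doubles the log likelihood
  expect_equal(log_likelihood(params, rbind(d, d)), 2 * ll)
  expect_error(log_likelihood(list(tau = c(1, 0), beta = beta), d), "ordered")
})

test_that("compiled log posterior matches finite-difference gradients and the R likelihood", {
  cfg <- sim_config(n_participants = 5, n_tes = 4)
  sim <- simulate_glmm(cfg, seed = 9)
  d <- sim$data
  z <- lapply(list(age = d$age, exposure = d$exposure,
                   cognateness = d$cognateness,
                   length = as.numeric(d$n_phonemes), frequency = d$zipf),
              standardize)
  X <- bivocab:::build_fixed_design(z$age, z$exposure, z$cognateness,
                                    z$length, z$frequency)
  pid <- as.integer(factor(d$participant_id))
  tid <- as.integer(factor(d$te_id))
  cdata <- list(y = as.integer(d$response), X = X, re = list(
    list(group = pid, Z = bivocab:::build_participant_design(X),
         n_groups = max(pid)),
    list(group = tid, Z = bivocab:::build_te_design(X), n_groups = max(tid))))
  D <- bivocab:::irt_n_params(cdata)
  set.seed(10)
  q <- runif(D, -0.6, 0.6)
  r <- bivocab:::irt_logp_grad(cdata, q)
  h <- 1e-6
  gfd <- vapply(seq_len(D), function(i) {
    qp <- q; qp[i] <- qp[i] + h
    qm <- q; qm[i] <- qm[i] - h
    (bivocab:::irt_logp_grad(cdata, qp)$lp -
       bivocab:::irt_logp_grad(cdata, qm)$lp) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(gfd - r$grad) / pmax(1, abs(gfd))), 1e-5)

  # likelihood part equals the R-side oracle with the same RE coefficients
  Kp <- 8; Kt <- 4
  off <- 11
  sig_p <- exp(q[off + 1:Kp]); off <- off + Kp
  yc_p <- q[off + 1:(Kp * (Kp - 1) / 2)]; off <- off + Kp * (Kp - 1) / 2
  sig_t <- exp(q[off + 1:Kt]); off <- off + Kt
  yc_t <- q[off + 1:(Kt * (Kt - 1) / 2)]; off <- off + Kt * (Kt - 1) / 2
  up <- matrix(q[off + 1:(max(pid) * Kp)], ncol = Kp, byrow = TRUE)
  off <- off + max(pid) * Kp
  ut <- matrix(q[off + 1:(max(tid) * Kt)], ncol = Kt, byrow = TRUE)
  Lp <- t(chol(bivocab:::corr_from_unconstrained(yc_p, Kp)))
  Lt <- t(chol(bivocab:::corr_from_unconstrained(yc_t, Kt)))
  coef_p <- sweep(up %*% t(Lp), 2, sig_p, `*`)
  coef_t <- sweep(ut %*% t(Lt), 2, sig_t, `*`)
  dimnames(coef_p) <- list(levels(factor(d$participant_id)),
                           irt_participant_terms())
  dimnames(coef_t) <- list(levels(factor(d$te_id)), irt_te_terms())
  recs <- tibble::tibble(age = z$age, exposure = z$exposure,
                         cognateness = z$cognateness, length = z$length,
                         frequency = z$frequency, response = d$response,
                         participant_id = d$participant_id, te_id = d$te_id)
  ll <- log_likelihood(list(tau = c(q[1], q[1] + exp(q[2])),
                            beta = setNames(q[2 + 1:9], irt_fixed_terms()),
                            re_participant = coef_p, re_te = coef_t), recs)
  expect_equal(bivocab:::irt_logp_grad(cdata, q, with_prior = FALSE)$lp, ll,
               tolerance = 1e-10)
})

test_that("sampling is deterministic under a fixed seed", {
  cfg <- sim_config(n_participants = 6, n_tes = 4)
  sim <- simulate_glmm(cfg, seed = 12)
  f1 <- suppressWarnings(fit_acquisition_model(sim$data, chains = 1,
                                               iter_warmup = 60,
                                               iter_sampling = 40, seed = 33))
  f2 <- suppressWarnings(fit_acquisition_model(sim$data, chains = 1,
                                               iter_warmup = 60,
                                               iter_sampling = 40, seed = 33))
  expect_identical(f1$draws, f2$draws)
})

test_that("prior-only sampling recovers the slope prior", {
  f <- suppressWarnings(fit_acquisition_model(prior_only = TRUE, chains = 2,
                                              iter_warmup = 300,
                                              iter_sampling = 500, seed = 14))
  m <- posterior_draws(f, paste0("b_", irt_fixed_terms()))
  expect_true(all(abs(colMeans(m)) < 0.15))
  expect_true(all(apply(m, 2, sd) > 0.85 & apply(m, 2, sd) < 1.15))
  tau <- posterior_draws(f, c("tau_comprehension", "tau_production"))
  expect_true(all(tau[, 1] < tau[, 2]))
})

test_that("intercept-only data recovers the thresholds", {
  cfg <- sim_config(n_participants = 25, n_tes = 40, tau = c(-0.5, 0.5),
                    beta = setNames(rep(0, 9), irt_fixed_terms()),
                    sd_participant = setNames(rep(0, 8),
                                              irt_participant_terms()),
                    sd_te = setNames(rep(0, 4), irt_te_terms()))
  sim <- simulate_glmm(cfg, seed = 11)
  expect_equal(nrow(sim$data), 2000)
  f <- suppressWarnings(fit_acquisition_model(sim$data, chains = 2,
                                              iter_warmup = 300,
                                              iter_sampling = 300, seed = 5))
  tau <- colMeans(posterior_draws(f, c("tau_comprehension",
                                       "tau_production")))
  expect_lt(abs(tau[1] - (-0.5)), 0.15)
  expect_lt(abs(tau[2] - 0.5), 0.15)
})

test_that("degenerate grouping drops the corresponding random-effect block", {
  cfg <- sim_config(n_participants = 6, n_tes = 1)
  w <- capture_warnings({
    sim <- simulate_glmm(cfg, seed = 15)
    f <- fit_acquisition_model(sim$data, chains = 1, iter_warmup = 50,
                               iter_sampling = 30, seed = 2)
  })
  expect_true(any(grepl("single translation equivalent", w)))
  # a lone item also makes its predictors constant; they enter as zero
  expect_true(any(grepl("constant", w)))
  expect_false(any(grepl("sd_te", f$params)))
  expect_true(any(grepl("sd_participant", f$params)))
})

test_that("diagnostics flag separated chains and credit iid draws", {
  set.seed(20)
  n <- 500
  good <- array(rnorm(n * 4), dim = c(n, 4, 1),
                dimnames = list(NULL, NULL, "theta"))
  fit_good <- structure(list(draws = good), class = "bivocab_fit")
  d <- diagnose(fit_good)
  expect_lt(d$rhat, 1.01)
  expect_gt(d$ess_bulk, 0.5 * n * 4)
  # agreement with an established ESS estimator on iid draws
  ess_coda <- sum(vapply(1:4, function(ch)
    unname(coda::effectiveSize(good[, ch, 1])), numeric(1)))
  expect_equal(unname(d$ess_bulk), ess_coda, tolerance = 0.5)
  bad <- good
  bad[, 2, 1] <- bad[, 2, 1] + 10
  fit_bad <- structure(list(draws = bad), class = "bivocab_fit")
  expect_gt(diagnose(fit_bad)$rhat, 1.5)
  one <- structure(list(draws = good[, 1, , drop = FALSE]),
                   class = "bivocab_fit")
  expect_error(diagnose(one), "single chain")
})
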