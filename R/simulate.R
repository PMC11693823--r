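#' Configuration for the synthetic checklist generators
#'
#' Defines the study conditions the generators emulate: a two-language
#' (Catalan/Spanish) checklist with children aged 12-32 months, caregiver
#' exposure proportions, translation pairs with graded cognateness, and
#' ordinal comprehension/production responses. Default fixed effects are
#' logit-scale values matching the magnitudes reported for this design
#' (probability-scale effects times four); defaults are sized so a full
#' fit-and-recover cycle runs on a single CPU.
#'
#' @param n_participants,n_tes Numbers of children and translation
#'   equivalents (each child responds to both forms of every pair).
#' @param age_range Age window in months (uniform).
#' @param exposure_range Range of the Catalan exposure proportion
#'   (uniform).
#' @param cognateness_range Range of pair cognateness (uniform).
#' @param zipf_mean,zipf_sd Normal distribution of the pair's Zipf
#'   frequency (shared by both forms, as with English-mapped counts).
#' @param length_range Integer range of per-form phoneme counts.
#' @param tau Thresholds (comprehension, production) on the latent scale.
#' @param beta Named logit-scale fixed effects over [irt_fixed_terms()]
#'   (applied to standardized predictors).
#' @param sd_participant,sd_te Named random-effect SDs over
#'   [irt_participant_terms()] / [irt_te_terms()].
#' @param corr_participant,corr_te Random-effect correlation matrices
#'   (default identity).
#' @param prop_other_fraction Fraction of children exposed to a third
#'   language.
#' @param prop_other_value Their third-language exposure proportion.
#'
#' @return A list of class `bivocab_sim_config`.
#' @export
sim_config <- function(n_participants = 100, n_tes = 60,
                       age_range = c(12, 32), exposure_range = c(0.1, 0.9),
                       cognateness_range = c(0, 1), zipf_mean = 4.5,
                       zipf_sd = 0.7, length_range = c(2, 9),
                       tau = c(-0.4, 0.6),
                       beta = c(age = 1.636, exposure = 0.928,
                                cognateness = 0.272, length = -0.24,
                                frequency = 0.44, `age:exposure` = 0.292,
                                `age:cognateness` = 0.06,
                                `exposure:cognateness` = -0.232,
                                `age:exposure:cognateness` = -0.072),
                       sd_participant = c(`(Intercept)` = 1.2, age = 0.6,
                                          exposure = 0.6, cognateness = 0.4,
                                          `age:exposure` = 0.4,
                                          `age:cognateness` = 0.3,
                                          `exposure:cognateness` = 0.3,
                                          `age:exposure:cognateness` = 0.3),
                       sd_te = c(`(Intercept)` = 0.8, age = 0.3,
                                 exposure = 0.3, `age:exposure` = 0.2),
                       corr_participant = NULL, corr_te = NULL,
                       prop_other_fraction = 0, prop_other_value = 0.12) {
  stopifnot(n_participants >= 1, n_tes >= 1,
            length(age_range) == 2, age_range[1] < age_range[2],
            all(exposure_range >= 0), all(exposure_range <= 1),
            all(cognateness_range >= 0), all(cognateness_range <= 1),
            length(tau) == 2, tau[1] < tau[2],
            prop_other_fraction >= 0, prop_other_fraction <= 1)
  missing_beta <- setdiff(irt_fixed_terms(), names(beta))
  if (length(missing_beta)) {
    stop("beta lacks term(s): ", paste(missing_beta, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(irt_participant_terms() %in% names(sd_participant)),
            all(irt_te_terms() %in% names(sd_te)),
            all(sd_participant >= 0), all(sd_te >= 0))
  if (is.null(corr_participant)) corr_participant <- diag(length(irt_participant_terms()))
  if (is.null(corr_te)) corr_te <- diag(length(irt_te_terms()))
  structure(list(
    n_participants = n_participants, n_tes = n_tes, age_range = age_range,
    exposure_range = exposure_range, cognateness_range = cognateness_range,
    zipf_mean = zipf_mean, zipf_sd = zipf_sd, length_range = length_range,
    tau = tau, beta = beta[irt_fixed_terms()],
    sd_participant = sd_participant[irt_participant_terms()],
    sd_te = sd_te[irt_te_terms()],
    corr_participant = corr_participant, corr_te = corr_te,
    prop_other_fraction = prop_other_fraction,
    prop_other_value = prop_other_value
  ), class = "bivocab_sim_config")
}

#' Generate synthetic participants with exposure profiles
#'
#' Ages are uniform over the configured window; the Catalan exposure
#' proportion is uniform over the configured range (scaled down for
#' children given third-language exposure so proportions still sum to 1).
#'
#' @param config A [sim_config()].
#' @param seed Optional seed (set it here only when calling directly;
#'   the simulators seed once at their entry point).
#'
#' @return A tibble with `participant_id`, `administration_id`, `age`,
#'   `prop_catalan`, `prop_spanish`, `prop_other`.
#' @export
make_participants <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_participants
  prop_other <- rep(0, n)
  n_other <- round(config$prop_other_fraction * n)
  if (n_other > 0) {
    prop_other[sample.int(n, n_other)] <- config$prop_other_value
  }
  cat_share <- stats::runif(n, config$exposure_range[1], config$exposure_range[2])
  prop_catalan <- cat_share * (1 - prop_other)
  tibble::tibble(
    participant_id = sprintf("p%04d", seq_len(n)),
    administration_id = sprintf("a%04d", seq_len(n)),
    age = stats::runif(n, config$age_range[1], config$age_range[2]),
    prop_catalan = prop_catalan,
    prop_spanish = 1 - prop_other - prop_catalan,
    prop_other = prop_other
  )
}

# Translation-equivalent table: cognateness and Zipf are pair-level
# (frequency is mapped from a shared English lemma); form length varies by
# language.
make_tes <- function(config) {
  n <- config$n_tes
  lens <- seq(config$length_range[1], config$length_range[2])
  tibble::tibble(
    te_id = sprintf("te%04d", seq_len(n)),
    cognateness = stats::runif(n, config$cognateness_range[1],
                               config$cognateness_range[2]),
    zipf = stats::rnorm(n, config$zipf_mean, config$zipf_sd),
    n_phonemes_catalan = sample(lens, n, replace = TRUE),
    n_phonemes_spanish = sample(lens, n, replace = TRUE)
  )
}

# Long record grid: participant x translation equivalent x language.
build_record_grid <- function(parts, tes) {
  grid <- tidyr::expand_grid(participant_id = parts$participant_id,
                             te_id = tes$te_id,
                             language = c("catalan", "spanish"))
  grid <- dplyr::left_join(grid, parts, by = "participant_id")
  grid <- dplyr::left_join(grid, tes, by = "te_id")
  grid$exposure <- ifelse(grid$language == "catalan", grid$prop_catalan,
                          grid$prop_spanish)
  grid$n_phonemes <- ifelse(grid$language == "catalan",
                            grid$n_phonemes_catalan, grid$n_phonemes_spanish)
  grid$item_id <- paste0(grid$te_id, "_", substr(grid$language, 1, 3))
  grid
}

#' Simulate checklist data directly from the ordinal model
#'
#' Draws correlated participant and item random effects, builds the
#' linear predictor with the configured fixed effects (applied to the
#' dataset's own standardized predictors, matching how the model is fit),
#' and samples ordinal responses from the cumulative-logit category
#' probabilities. Used for parameter-recovery checks.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; fixed seed gives identical tables.
#'
#' @return A list: `data` (response records ready for
#'   [fit_acquisition_model()]) and `truth` (generating parameters,
#'   including the drawn random effects).
#' @export
simulate_glmm <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "bivocab_sim_config"))
  set.seed(seed)
  parts <- make_participants(config)
  tes <- make_tes(config)
  grid <- build_record_grid(parts, tes)

  raw <- list(age = grid$age, exposure = grid$exposure,
              cognateness = grid$cognateness,
              length = as.numeric(grid$n_phonemes), frequency = grid$zipf)
  z <- lapply(names(raw), function(nm) standardize_tolerant(raw[[nm]], nm))
  names(z) <- names(raw)
  X <- build_fixed_design(z$age, z$exposure, z$cognateness, z$length,
                          z$frequency)
  Zp <- build_participant_design(X)
  Zt <- build_te_design(X)

  coef_p <- draw_random_effects(config$n_participants, config$sd_participant,
                                config$corr_participant)
  rownames(coef_p) <- parts$participant_id
  coef_t <- draw_random_effects(config$n_tes, config$sd_te, config$corr_te)
  rownames(coef_t) <- tes$te_id

  pid <- match(grid$participant_id, parts$participant_id)
  tid <- match(grid$te_id, tes$te_id)
  eta <- drop(X %*% config$beta) + rowSums(Zp * coef_p[pid, , drop = FALSE]) +
    rowSums(Zt * coef_t[tid, , drop = FALSE])
  pr <- category_probabilities(eta, config$tau[1], config$tau[2])
  u <- stats::runif(nrow(grid))
  response <- (u > pr$p_no) + (u > pr$p_no + pr$p_understands)

  data <- tibble::tibble(
    participant_id = grid$participant_id,
    administration_id = grid$administration_id,
    te_id = grid$te_id,
    item_id = grid$item_id,
    language = grid$language,
    age = grid$age,
    exposure = grid$exposure,
    cognateness = grid$cognateness,
    n_phonemes = grid$n_phonemes,
    zipf = grid$zipf,
    response = as.integer(response)
  )
  list(data = data,
       truth = list(tau = config$tau, beta = config$beta,
                    sd_participant = config$sd_participant,
                    sd_te = config$sd_te,
                    corr_participant = config$corr_participant,
                    corr_te = config$corr_te,
                    re_participant = coef_p, re_te = coef_t))
}

# coef_g = diag(sd) L u_g with L the lower Cholesky factor of corr.
draw_random_effects <- function(G, sds, corr) {
  K <- length(sds)
  u <- matrix(stats::rnorm(G * K), G, K)
  L <- t(chol(corr))
  coefs <- u %*% t(L)
  coefs <- sweep(coefs, 2, sds, `*`)
  colnames(coefs) <- names(sds)
  coefs
}

#' Parameters of the accumulator-with-co-activation simulator
#'
#' Formalizes the learning-instance account of bilingual word learning as
#' deterministic accrual plus threshold crossing: a child accumulates
#' instances for a word at a rate set by their ability, the word's token
#' frequency and the exposure to its language, plus a co-activation term
#' through which the translation equivalent contributes instances in
#' proportion to phonological similarity and to the exposure to *its*
#' language. Acquisition (comprehension, then production) occurs when the
#' accumulated total crosses a threshold; caregiver reports are flipped to
#' an adjacent category with a small misclassification probability.
#'
#' @param gamma Co-activation efficiency in \[0, 1\]; 0 disables
#'   cross-language accumulation.
#' @param rate_scale Learning instances per month for a reference-frequency
#'   word at full exposure.
#' @param theta_comp,theta_prod Instance thresholds for comprehension and
#'   production (`0 < theta_comp < theta_prod`).
#' @param ability_sd SD of the log-normal child ability multiplier.
#' @param report_noise Probability a response is flipped to an adjacent
#'   category (in \[0, 0.5)).
#'
#' @return A list of class `bivocab_accumulator_params`.
#' @export
accumulator_params <- function(gamma = 0.5, rate_scale = 10, theta_comp = 90,
                               theta_prod = 130, ability_sd = 0.3,
                               report_noise = 0.05) {
  stopifnot(gamma >= 0, gamma <= 1, rate_scale > 0,
            theta_comp > 0, theta_comp < theta_prod,
            ability_sd >= 0, report_noise >= 0, report_noise < 0.5)
  structure(list(gamma = gamma, rate_scale = rate_scale,
                 theta_comp = theta_comp, theta_prod = theta_prod,
                 ability_sd = ability_sd, report_noise = report_noise),
            class = "bivocab_accumulator_params")
}

#' Cumulative learning instances under the accumulator account
#'
#' Closed form of the accrual process: child ability x rate x age x
#' (own-language exposure x token weight + gamma x similarity x
#' other-language exposure x the translation's token weight). Exposed so
#' that tests and analyses can reason about the deterministic core without
#' reporting noise.
#'
#' @param params An [accumulator_params()].
#' @param ability Child ability multiplier(s).
#' @param age Age(s) in months.
#' @param exposure Exposure proportion to the form's language.
#' @param exposure_other Exposure proportion to the translation's language.
#' @param omega,omega_other Normalized token weights of the form and its
#'   translation.
#' @param similarity Pair cognateness in \[0, 1\].
#'
#' @return Numeric vector of accumulated instances.
#' @export
accumulated_instances <- function(params, ability, age, exposure,
                                  exposure_other, omega, omega_other,
                                  similarity) {
  ability * params$rate_scale * age *
    (exposure * omega +
       params$gamma * similarity * exposure_other * omega_other)
}

#' Simulate checklist data from the accumulator-with-co-activation account
#'
#' Generates responses from the theoretical learning process rather than
#' from the statistical model: words accrue learning instances (see
#' [accumulated_instances()]), cross comprehension/production thresholds,
#' and are reported with noise. With `gamma > 0` and unbalanced exposure,
#' cognate facilitation concentrates in the lower-exposure language, which
#' the ordinal model should detect as a negative exposure-by-cognateness
#' interaction.
#'
#' @param params An [accumulator_params()].
#' @param config A [sim_config()] (its `tau`/`beta`/SD fields are ignored;
#'   only the population layout is used).
#' @param seed Integer seed.
#'
#' @return A tibble of response records ready for
#'   [fit_acquisition_model()], with the child's `ability` and the
#'   noiseless `response_true` kept for reference.
#' @export
simulate_accumulator <- function(params = accumulator_params(),
                                 config = sim_config(), seed = 1L) {
  stopifnot(inherits(params, "bivocab_accumulator_params"),
            inherits(config, "bivocab_sim_config"))
  set.seed(seed)
  parts <- make_participants(config)
  parts$ability <- exp(stats::rnorm(nrow(parts), 0, params$ability_sd))
  tes <- make_tes(config)
  grid <- build_record_grid(parts, tes)
  grid$ability <- parts$ability[match(grid$participant_id, parts$participant_id)]
  grid$exposure_other <- ifelse(grid$language == "catalan", grid$prop_spanish,
                                grid$prop_catalan)
  omega_raw <- 10^(grid$zipf - 6)
  # normalize token weights so the median pair has weight 1 (the lognormal
  # mean would be dominated by the few highest-frequency items)
  omega_ref <- stats::median(10^(tes$zipf - 6))
  grid$omega <- omega_raw / omega_ref

  A <- accumulated_instances(params, grid$ability, grid$age, grid$exposure,
                             grid$exposure_other, grid$omega, grid$omega,
                             grid$cognateness)
  response <- (A >= params$theta_comp) + (A >= params$theta_prod)
  noisy <- response
  flip <- stats::runif(length(response)) < params$report_noise
  dir_up <- stats::runif(length(response)) < 0.5
  noisy[flip & response == 0] <- 1L
  noisy[flip & response == 2] <- 1L
  noisy[flip & response == 1] <- ifelse(dir_up[flip & response == 1], 2L, 0L)

  tibble::tibble(
    participant_id = grid$participant_id,
    administration_id = grid$administration_id,
    te_id = grid$te_id,
    item_id = grid$item_id,
    language = grid$language,
    age = grid$age,
    exposure = grid$exposure,
    cognateness = grid$cognateness,
    n_phonemes = grid$n_phonemes,
    zipf = grid$zipf,
    ability = grid$ability,
    response_true = as.integer(response),
    response = as.integer(noisy)
  )
}

#' Build an item-table fixture with prescribed filter-cascade counts
#'
#' Constructs a raw item table in which exactly the requested number of
#' items fail each cascade stage as their *first* failing stage, so that
#' [filter_items()] reproduces the prescribed exclusion log. Retained
#' items are paired into translation equivalents with alternating
#' languages.
#'
#' @param stage_counts Named numeric vector with `total` and per-stage
#'   exclusion counts `non_noun`, `missing_frequency`, `multi_lemma`,
#'   `multi_word`, `untranslated`.
#'
#' @return A tibble of raw items with the columns [filter_items()] and
#'   [pair_translations()] expect.
#' @export
#'
#' @examples
#' fx <- make_item_fixture()
#' filter_items(fx)$exclusions
make_item_fixture <- function(stage_counts = c(total = 1590, non_noun = 628,
                                               missing_frequency = 269,
                                               multi_lemma = 48,
                                               multi_word = 9,
                                               untranslated = 32)) {
  req <- c("total", "non_noun", "missing_frequency", "multi_lemma",
           "multi_word", "untranslated")
  missing <- setdiff(req, names(stage_counts))
  if (length(missing)) {
    stop("stage_counts lacks: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(stage_counts < 0)) stop("counts must be non-negative", call. = FALSE)
  n_excl <- sum(stage_counts[setdiff(req, "total")])
  n_ret <- stage_counts[["total"]] - n_excl
  if (n_ret < 0) {
    stop("infeasible counts: exclusions exceed the total", call. = FALSE)
  }
  blank <- function(n, class, has_frequency, lemma_count, is_multiword,
                    has_translation) {
    if (n == 0) return(NULL)
    tibble::tibble(class = rep(class, n), has_frequency = has_frequency,
                   lemma_count = lemma_count, is_multiword = is_multiword,
                   has_translation = has_translation)
  }
  out <- dplyr::bind_rows(
    blank(n_ret, "noun", TRUE, 1L, FALSE, TRUE),
    blank(stage_counts[["non_noun"]], "verb", TRUE, 1L, FALSE, TRUE),
    blank(stage_counts[["missing_frequency"]], "noun", FALSE, 1L, FALSE, TRUE),
    blank(stage_counts[["multi_lemma"]], "noun", TRUE, 2L, FALSE, TRUE),
    blank(stage_counts[["multi_word"]], "noun", TRUE, 1L, TRUE, TRUE),
    blank(stage_counts[["untranslated"]], "noun", TRUE, 1L, FALSE, FALSE)
  )
  n <- nrow(out)
  out$item_id <- sprintf("item%05d", seq_len(n))
  out$language <- rep_len(c("catalan", "spanish"), n)
  out$te_id <- NA_character_
  if (n_ret > 0) {
    idx <- seq_len(n_ret)
    out$te_id[idx] <- sprintf("te%04d", ceiling(idx / 2))
  }
  dplyr::select(out, "item_id", "te_id", "language", "class", "lemma_count",
                "is_multiword", "has_translation", "has_frequency")
}
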