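#' Build records for the syllabic-frequency control analysis
#'
#' Joins each word form's cognateness score (from its translation pair)
#' with its syllabic frequency and syllable count, the inputs of the
#' control regression asking whether cognates simply consist of more
#' frequent syllables.
#'
#' @param items Data frame with columns `item_id`, `te_id`, `language`,
#'   `xsampa` (syllabified, `.` separators) and `frequency` (lexical
#'   frequency used for the syllable sums).
#' @param inventory Phoneme inventory for the cognateness scoring.
#'
#' @return A tibble with `form_id`, `te_id`, `language`, `cognateness`,
#'   `syll_freq`, `n_syllables`.
#' @export
make_syllfreq_records <- function(items, inventory = xsampa_inventory()) {
  stopifnot(all(c("item_id", "te_id", "language", "xsampa", "frequency") %in%
                  names(items)))
  cg <- score_cognateness(items, inventory = inventory)
  sf <- syllabic_frequency(tibble::tibble(form_id = items$item_id,
                                          xsampa = items$xsampa,
                                          frequency = items$frequency))$forms
  out <- tibble::tibble(form_id = items$item_id, te_id = items$te_id,
                        language = items$language)
  out <- dplyr::left_join(out, cg[, c("te_id", "cognateness")], by = "te_id")
  dplyr::left_join(out, sf, by = "form_id")
}

#' Bayesian regression of cognateness on syllabic frequency
#'
#' Fits a Gaussian linear model with cognateness as the response and
#' standardized syllabic frequency and syllable count as predictors, using
#' the same prior family as the acquisition model (intercept N(-0.25,
#' 0.50), slopes N(0, 1), residual SD positive-truncated N(1, 0.25)) and
#' the package's No-U-Turn sampler. The response is left on its raw
#' \[0, 1\] scale; the Gaussian likelihood ignores the bounds, which is
#' adequate away from the extremes (see the methods vignette).
#'
#' @param records Data frame with columns `cognateness`, `syll_freq`,
#'   `n_syllables` (at least 10 rows; predictors must be non-constant).
#' @param chains,iter_warmup,iter_sampling,seed,adapt_delta Sampler
#'   settings (see [fit_acquisition_model()]).
#'
#' @return A `bivocab_lm` object; summarize with
#'   [tidy()][generics::tidy()] (default ROPE \[-0.05, 0.05\] in
#'   cognateness units per predictor SD).
#' @export
fit_cognateness_regression <- function(records, chains = 4,
                                       iter_warmup = 500,
                                       iter_sampling = 500, seed = 1L,
                                       adapt_delta = 0.8) {
  req <- c("cognateness", "syll_freq", "n_syllables")
  missing <- setdiff(req, names(records))
  if (length(missing)) {
    stop("records lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) < 10) {
    stop("need at least 10 records", call. = FALSE)
  }
  z_sf <- standardize(records$syll_freq)
  z_ns <- standardize(as.numeric(records$n_syllables))
  X <- cbind(`(Intercept)` = 1, syll_freq = as.numeric(z_sf),
             n_syllables = as.numeric(z_ns))
  y <- records$cognateness
  prior_mean <- c(-0.25, 0, 0)
  prior_sd <- c(0.5, 1, 1)
  params <- c(colnames(X), "sigma", "lp__")
  draws <- array(NA_real_, dim = c(iter_sampling, chains, length(params)),
                 dimnames = list(NULL, NULL, params))
  divergences <- integer(chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + ch - 1L)
    init <- stats::runif(ncol(X) + 1, -0.5, 0.5)
    res <- lm_nuts_chain(y, X, prior_mean, prior_sd, init,
                         as.integer(iter_warmup), as.integer(iter_sampling),
                         adapt_delta, 10L)
    u <- res$draws
    draws[, ch, ] <- cbind(u[, seq_len(ncol(X)), drop = FALSE],
                           exp(u[, ncol(X) + 1]), res$lp)
    divergences[ch] <- res$divergences
  }
  structure(list(
    draws = draws,
    params = params,
    terms = colnames(X),
    scales = tibble::tibble(
      term = c("syll_freq", "n_syllables"),
      mean = c(attr(z_sf, "scaled_mean"), attr(z_ns, "scaled_mean")),
      sd = c(attr(z_sf, "scaled_sd"), attr(z_ns, "scaled_sd"))
    ),
    chains = chains, iter_warmup = iter_warmup,
    iter_sampling = iter_sampling, seed = seed,
    divergences = divergences, n_obs = nrow(records)
  ), class = "bivocab_lm")
}

#' Tidy the syllabic-frequency regression
#'
#' @param x A `bivocab_lm`.
#' @param rope Equivalence region on the coefficient scale (cognateness
#'   units per predictor SD).
#' @param mass HDI mass.
#' @param within_hdi Whether p(ROPE) conditions on the HDI.
#' @param ... Unused.
#'
#' @return A tibble with one row per coefficient plus the residual SD.
#' @export
tidy.bivocab_lm <- function(x, rope = c(-0.05, 0.05), mass = 0.95,
                            within_hdi = TRUE, ...) {
  m <- posterior_draws(x, c(x$terms, "sigma"))
  out <- summarize_draws_matrix(m, rope, mass, within_hdi, identity)
  out$p_rope[out$term %in% c("(Intercept)", "sigma")] <- NA_real_
  dplyr::select(out, -"prob_estimate", -"prob_low", -"prob_high")
}

#' @export
print.bivocab_lm <- function(x, ...) {
  cat("Bayesian Gaussian regression (cognateness ~ syllabic frequency + syllables)\n")
  cat(sprintf("  observations: %d  chains: %d  sampling: %d  divergences: %d\n",
              x$n_obs, x$chains, x$iter_sampling, sum(x$divergences)))
  print(tidy(x))
  invisible(x)
}
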