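#' Highest density interval
#'
#' The shortest contiguous interval over the sorted sample containing
#' `ceiling(mass * n)` points. Assumes a unimodal posterior; for a
#' detectably multimodal sample the shortest single interval is still
#' returned, with a warning.
#'
#' @param x Numeric vector of posterior draws (at least 20).
#' @param mass Probability mass to cover, in (0, 1).
#'
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#'
#' @examples
#' hdi(rnorm(5000))
hdi <- function(x, mass = 0.95) {
  if (!is.numeric(x)) stop("x must be numeric", call. = FALSE)
  x <- x[is.finite(x)]
  n <- length(x)
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)", call. = FALSE)
  m <- ceiling(mass * n)
  if (n < 20 || m < 2 || m > n) {
    stop("too few samples (", n, ") for a ", mass, " HDI", call. = FALSE)
  }
  xs <- sort(x)
  widths <- xs[seq.int(m, n)] - xs[seq_len(n - m + 1L)]
  i <- which.min(widths)
  out <- c(lower = xs[i], upper = xs[i + m - 1L])
  if (is_multimodal(xs)) {
    warning("sample looks multimodal; HDI reported as the shortest single interval",
            call. = FALSE)
  }
  out
}

# Crude bimodality screen: large interior gap relative to the IQR.
is_multimodal <- function(xs) {
  n <- length(xs)
  if (n < 50) return(FALSE)
  core <- xs[seq.int(ceiling(0.05 * n), floor(0.95 * n))]
  gaps <- diff(core)
  iqr <- stats::IQR(xs)
  if (!is.finite(iqr) || iqr <= 0) return(FALSE)
  max(gaps) > 0.5 * iqr
}

#' Map logit-scale draws to the probability scale
#'
#' Divide-by-four transform: the logistic curve has maximum slope 1/4, so a
#' logit-scale coefficient `b` corresponds to at most `b / 4` change in
#' probability per unit of the predictor.
#'
#' @param logit_draws Numeric vector (or matrix) of logit-scale draws.
#'
#' @return The draws divided by 4.
#' @export
to_probability_scale <- function(logit_draws) {
  logit_draws / 4
}

#' Posterior mass in the region of practical equivalence
#'
#' Restricts the draws to those inside their own 95% (by default) HDI and
#' returns the fraction of the restricted draws lying inside the ROPE.
#' Set `within_hdi = FALSE` to use the full posterior instead.
#'
#' @param draws Numeric vector of draws, on the scale on which the ROPE is
#'   defined (for acquisition-model slopes: the probability scale, see
#'   [to_probability_scale()]).
#' @param rope Length-2 numeric, the equivalence region (default the
#'   probability-scale region \[-0.025, 0.025\]).
#' @param mass HDI mass used for the restriction.
#' @param within_hdi Restrict to the HDI before computing the proportion?
#'
#' @return A proportion in \[0, 1\].
#' @export
p_rope <- function(draws, rope = c(-0.025, 0.025), mass = 0.95,
                   within_hdi = TRUE) {
  stopifnot(length(rope) == 2, rope[1] < rope[2])
  draws <- draws[is.finite(draws)]
  if (!length(draws)) stop("no draws", call. = FALSE)
  if (within_hdi) {
    if (stats::sd(draws) == 0) {
      kept <- draws
    } else {
      h <- hdi(draws, mass = mass)
      kept <- draws[draws >= h["lower"] & draws <= h["upper"]]
    }
  } else {
    kept <- draws
  }
  mean(kept >= rope[1] & kept <= rope[2])
}

#' Probability-scale effect per raw predictor unit
#'
#' Converts a probability-scale effect per standard deviation into an
#' effect per raw unit (per month of age, per phoneme, per 10% of
#' exposure, ...) by dividing by the predictor's raw standard deviation.
#'
#' @param prob_scale_median Probability-scale posterior median for a one-SD
#'   change in the predictor.
#' @param predictor_sd_raw Standard deviation of the unstandardized
#'   predictor (positive).
#'
#' @return Probability change per raw unit.
#' @export
#'
#' @examples
#' per_unit_effect(0.4, 5) # 0.08 per month
per_unit_effect <- function(prob_scale_median, predictor_sd_raw) {
  if (any(predictor_sd_raw <= 0)) {
    stop("predictor_sd_raw must be positive", call. = FALSE)
  }
  prob_scale_median / predictor_sd_raw
}

# Shared summarizer: draws matrix -> CoefficientSummary rows.
summarize_draws_matrix <- function(m, rope, mass, within_hdi, transform) {
  rows <- lapply(colnames(m), function(term) {
    d <- m[, term]
    h <- hdi(d, mass = mass)
    td <- transform(d)
    th <- hdi(td, mass = mass)
    tibble::tibble(
      term = term,
      estimate = stats::median(d),
      conf.low = h[["lower"]],
      conf.high = h[["upper"]],
      prob_estimate = stats::median(td),
      prob_low = th[["lower"]],
      prob_high = th[["upper"]],
      p_rope = p_rope(td, rope = rope, mass = mass, within_hdi = within_hdi)
    )
  })
  dplyr::bind_rows(rows)
}

#' Summarize the posterior of an acquisition-model fit
#'
#' One row per fixed-effect term: the logit-scale posterior median and 95%
#' HDI, the probability-scale (divide-by-four) median and HDI, and
#' p(ROPE) — the share of probability-scale draws within the 95% HDI that
#' fall into the region of practical equivalence.
#'
#' @param fit A `bivocab_fit`.
#' @param rope Equivalence region on the probability scale.
#' @param mass HDI mass.
#' @param within_hdi Whether p(ROPE) conditions on the HDI (the default) or
#'   uses the full posterior.
#' @param include_thresholds Also summarize the two thresholds (as baseline
#'   acquisition probabilities `plogis(-tau)`; their `p_rope` is `NA`).
#'
#' @return A tibble of coefficient summaries.
#' @export
summarize_posterior <- function(fit, rope = c(-0.025, 0.025), mass = 0.95,
                                within_hdi = TRUE, include_thresholds = FALSE) {
  m <- posterior_draws(fit, paste0("b_", fit$fixed_terms))
  colnames(m) <- fit$fixed_terms
  out <- summarize_draws_matrix(m, rope, mass, within_hdi,
                                to_probability_scale)
  if (include_thresholds) {
    tm <- posterior_draws(fit, c("tau_comprehension", "tau_production"))
    trows <- lapply(colnames(tm), function(term) {
      d <- tm[, term]
      h <- hdi(d, mass = mass)
      pd <- stats::plogis(-d)   # baseline P(acquired) at predictor means
      ph <- hdi(pd, mass = mass)
      tibble::tibble(term = term, estimate = stats::median(d),
                     conf.low = h[["lower"]], conf.high = h[["upper"]],
                     prob_estimate = stats::median(pd),
                     prob_low = ph[["lower"]], prob_high = ph[["upper"]],
                     p_rope = NA_real_)
    })
    out <- dplyr::bind_rows(dplyr::bind_rows(trows), out)
  }
  out
}

#' Posterior marginal effect curves
#'
#' Population-level predicted probabilities of comprehension (response >= 1)
#' and production (response >= 2) over a grid of raw-unit predictor values,
#' with random effects set to zero. Grid values are converted to the model
#' scale using the standardization metadata stored on the fit; grid points
#' outside the observed predictor range are flagged with a warning as
#' extrapolation.
#'
#' @param fit A `bivocab_fit` (not prior-only).
#' @param age Ages in months (default: 25 points across the observed range).
#' @param exposure Exposure proportions (default: mean and mean +/- 1 SD of
#'   the observed exposures).
#' @param cognateness Cognateness values (default 0, 0.5, 1).
#' @param length,frequency Phoneme counts / Zipf scores (default: observed
#'   means).
#' @param mass Credible-band mass.
#'
#' @return A tibble of class `bivocab_marginal`: grid coordinates (raw
#'   units), `outcome` (`"comprehension"` / `"production"`), posterior mean
#'   `estimate` and credible band `conf.low`, `conf.high`.
#' @export
marginal_effects <- function(fit, age = NULL, exposure = NULL,
                             cognateness = NULL, length = NULL,
                             frequency = NULL, mass = 0.95) {
  if (isTRUE(fit$prior_only)) {
    stop("marginal effects need a data fit (standardization metadata)",
         call. = FALSE)
  }
  sc <- fit$scales
  get_scale <- function(term) sc[sc$term == term, ]
  defaults <- list(
    age = seq(get_scale("age")$min, get_scale("age")$max, length.out = 25),
    exposure = get_scale("exposure")$mean +
      c(-1, 0, 1) * get_scale("exposure")$sd,
    cognateness = c(0, 0.5, 1),
    length = get_scale("length")$mean,
    frequency = get_scale("frequency")$mean
  )
  vals <- list(age = age, exposure = exposure, cognateness = cognateness,
               length = length, frequency = frequency)
  vals <- lapply(names(vals), function(v) {
    if (is.null(vals[[v]])) defaults[[v]] else vals[[v]]
  })
  names(vals) <- names(defaults)
  extrap <- vapply(names(vals), function(v) {
    s <- get_scale(v)
    any(vals[[v]] < s$min - 1e-9 | vals[[v]] > s$max + 1e-9)
  }, logical(1))
  if (any(extrap)) {
    warning("grid extends beyond the observed range of: ",
            paste(names(vals)[extrap], collapse = ", "),
            " (extrapolation)", call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    age = vals$age, exposure = vals$exposure, cognateness = vals$cognateness,
    length = vals$length, frequency = vals$frequency
  )
  zgrid <- grid
  for (v in names(defaults)) {
    s <- get_scale(v)
    zgrid[[v]] <- (grid[[v]] - s$mean) / s$sd
  }
  X <- build_fixed_design(zgrid$age, zgrid$exposure, zgrid$cognateness,
                          zgrid$length, zgrid$frequency)
  beta <- posterior_draws(fit, paste0("b_", fit$fixed_terms))
  tau <- posterior_draws(fit, c("tau_comprehension", "tau_production"))
  eta <- X %*% t(beta)                     # grid x draws
  lo <- (1 - mass) / 2
  summarise_curve <- function(p) {
    tibble::tibble(
      estimate = rowMeans(p),
      conf.low = apply(p, 1, stats::quantile, probs = lo),
      conf.high = apply(p, 1, stats::quantile, probs = 1 - lo)
    )
  }
  p_comp <- stats::plogis(sweep(eta, 2, tau[, "tau_comprehension"]))
  p_prod <- stats::plogis(sweep(eta, 2, tau[, "tau_production"]))
  out <- dplyr::bind_rows(
    dplyr::bind_cols(grid, outcome = "comprehension", summarise_curve(p_comp)),
    dplyr::bind_cols(grid, outcome = "production", summarise_curve(p_prod))
  )
  class(out) <- c("bivocab_marginal", class(out))
  attr(out, "mass") <- mass
  out
}
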