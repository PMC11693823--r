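#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an acquisition-model fit
#'
#' Fixed-effect coefficient summaries in the study's reporting style:
#' logit-scale median and HDI, probability-scale (divide-by-four) median
#' and HDI, and p(ROPE). With `effects = "random"`, random-effect SDs and
#' correlations are summarized instead (median and HDI only).
#'
#' @param x A `bivocab_fit`.
#' @param effects `"fixed"` (default) or `"random"`.
#' @param rope,mass,within_hdi,include_thresholds Passed to
#'   [summarize_posterior()].
#' @param ... Unused.
#'
#' @return A tibble.
#' @export
tidy.bivocab_fit <- function(x, effects = c("fixed", "random"),
                             rope = c(-0.025, 0.025), mass = 0.95,
                             within_hdi = TRUE, include_thresholds = TRUE,
                             ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    return(summarize_posterior(x, rope = rope, mass = mass,
                               within_hdi = within_hdi,
                               include_thresholds = include_thresholds))
  }
  pars <- grep("^(sd|cor)_", x$params, value = TRUE)
  m <- posterior_draws(x, pars)
  rows <- lapply(pars, function(term) {
    h <- hdi(m[, term], mass = mass)
    tibble::tibble(term = term, estimate = stats::median(m[, term]),
                   conf.low = h[["lower"]], conf.high = h[["upper"]])
  })
  dplyr::bind_rows(rows)
}

#' Glance at an acquisition-model fit
#'
#' @param x A `bivocab_fit`.
#' @param ... Unused.
#'
#' @return A one-row tibble with data sizes, sampler settings, divergence
#'   count, and worst-case convergence diagnostics.
#' @export
glance.bivocab_fit <- function(x, ...) {
  d <- if (x$chains >= 2) diagnose(x) else
    tibble::tibble(rhat = NA_real_, ess_bulk = NA_real_)
  tibble::tibble(
    n_obs = x$n_obs,
    n_participants = x$n_participants,
    n_tes = x$n_tes,
    chains = x$chains,
    iter_warmup = x$iter_warmup,
    iter_sampling = x$iter_sampling,
    divergences = sum(x$divergences),
    max_rhat = suppressWarnings(max(d$rhat, na.rm = TRUE)),
    min_ess_bulk = suppressWarnings(min(d$ess_bulk, na.rm = TRUE))
  )
}

#' Plot posterior slope distributions against the ROPE
#'
#' Mirrors the study's coefficient display: probability-scale posterior
#' densities of the fixed slopes with the region of practical equivalence
#' shaded.
#'
#' @param object A `bivocab_fit`.
#' @param rope Equivalence region on the probability scale.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.bivocab_fit <- function(object, rope = c(-0.025, 0.025), ...) {
  m <- posterior_draws(object, paste0("b_", object$fixed_terms))
  colnames(m) <- object$fixed_terms
  long <- tidyr::pivot_longer(tibble::as_tibble(m), cols = dplyr::everything(),
                              names_to = "term", values_to = "draw")
  long$draw <- to_probability_scale(long$draw)
  long$term <- factor(long$term, levels = rev(object$fixed_terms))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$draw, y = .data$term)) +
    ggplot2::annotate("rect", xmin = rope[1], xmax = rope[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.15) +
    ggplot2::geom_violin(scale = "width", fill = "grey80", colour = NA) +
    ggplot2::stat_summary(fun = stats::median, geom = "point", size = 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "Effect on P(acquisition) per SD (probability scale)",
                  y = NULL)
}

#' Plot posterior marginal effect curves
#'
#' Predicted probability of comprehension and production across age,
#' colored by cognateness and faceted by exposure, with credible bands.
#'
#' @param object A `bivocab_marginal` tibble from [marginal_effects()].
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.bivocab_marginal <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$exposure_label <- sprintf("exposure = %.2f", df$exposure)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$estimate,
                                   colour = factor(.data$cognateness),
                                   fill = factor(.data$cognateness))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$outcome),
                        cols = ggplot2::vars(.data$exposure_label)) +
    ggplot2::labs(x = "Age (months)", y = "P(acquired)",
                  colour = "Cognateness", fill = "Cognateness") +
    ggplot2::ylim(0, 1)
}
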