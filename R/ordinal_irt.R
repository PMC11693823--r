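#' @useDynLib bivocab, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
NULL

#' Model terms of the acquisition model
#'
#' The fixed effects are the five standardized predictors plus the two- and
#' three-way interactions among age, exposure and cognateness. Participants
#' get random intercepts and slopes for age, exposure, cognateness and their
#' interactions; translation equivalents get random intercepts and slopes
#' for age, exposure and their interaction.
#'
#' @return Character vectors of term labels.
#' @export
irt_fixed_terms <- function() {
  c("age", "exposure", "cognateness", "length", "frequency",
    "age:exposure", "age:cognateness", "exposure:cognateness",
    "age:exposure:cognateness")
}

#' @rdname irt_fixed_terms
#' @export
irt_participant_terms <- function() {
  c("(Intercept)", "age", "exposure", "cognateness", "age:exposure",
    "age:cognateness", "exposure:cognateness", "age:exposure:cognateness")
}

#' @rdname irt_fixed_terms
#' @export
irt_te_terms <- function() {
  c("(Intercept)", "age", "exposure", "age:exposure")
}

# Fixed-effect design matrix from standardized predictor columns.
# Interaction regressors are products of the standardized main effects.
build_fixed_design <- function(age, exposure, cognateness, length, frequency) {
  X <- cbind(age, exposure, cognateness, length, frequency,
             age * exposure, age * cognateness, exposure * cognateness,
             age * exposure * cognateness)
  colnames(X) <- irt_fixed_terms()
  X
}

build_participant_design <- function(X) {
  Z <- cbind(1, X[, c("age", "exposure", "cognateness", "age:exposure",
                      "age:cognateness", "exposure:cognateness",
                      "age:exposure:cognateness"), drop = FALSE])
  colnames(Z) <- irt_participant_terms()
  Z
}

build_te_design <- function(X) {
  Z <- cbind(1, X[, c("age", "exposure", "age:exposure"), drop = FALSE])
  colnames(Z) <- irt_te_terms()
  Z
}

#' Ordinal category probabilities of the cumulative-logit model
#'
#' Given a latent linear predictor `eta` and ordered thresholds `tau1 <
#' tau2` (the comprehension and production boundaries), returns the
#' probability of each response category: P(No) = logistic(tau1 - eta),
#' P(Understands) = logistic(tau2 - eta) - logistic(tau1 - eta),
#' P(Understands-and-Says) = 1 - logistic(tau2 - eta). The three
#' probabilities always sum to one.
#'
#' @param eta Numeric vector of linear predictor values.
#' @param tau1,tau2 Thresholds (scalars or vectors recycled against `eta`),
#'   with `tau1 < tau2` elementwise.
#'
#' @return A tibble with columns `p_no`, `p_understands`,
#'   `p_understands_says`.
#' @export
#'
#' @examples
#' category_probabilities(0, -1, 1)
category_probabilities <- function(eta, tau1, tau2) {
  if (any(tau1 >= tau2)) {
    stop("thresholds must be ordered: tau1 < tau2", call. = FALSE)
  }
  p1 <- stats::plogis(tau1 - eta)
  p2 <- stats::plogis(tau2 - eta)
  tibble::tibble(
    p_no = p1,
    p_understands = p2 - p1,
    p_understands_says = 1 - p2
  )
}

#' Linear predictor of the acquisition model
#'
#' Builds the latent predictor eta for each record from fixed-effect
#' coefficients and (optionally) per-record random-effect deviations.
#' Interaction regressors are formed as products of the standardized main
#' effects; `data` is assumed to hold predictors on the standardized
#' (model) scale.
#'
#' @param data Data frame with numeric columns `age`, `exposure`,
#'   `cognateness`, `length`, `frequency` (standardized values).
#' @param fixed Named numeric vector of fixed-effect coefficients covering
#'   [irt_fixed_terms()].
#' @param re_participant Optional matrix/data frame (rows matching `data`)
#'   of per-record participant coefficient deviations over
#'   [irt_participant_terms()].
#' @param re_te Optional matrix/data frame of per-record
#'   translation-equivalent deviations over [irt_te_terms()].
#'
#' @return Numeric vector of linear predictor values.
#' @export
linear_predictor <- function(data, fixed, re_participant = NULL, re_te = NULL) {
  need <- c("age", "exposure", "cognateness", "length", "frequency")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("missing predictor column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(data[, need])) {
    stop("missing predictor values in data", call. = FALSE)
  }
  X <- build_fixed_design(data$age, data$exposure, data$cognateness,
                          data$length, data$frequency)
  missing_terms <- setdiff(irt_fixed_terms(), names(fixed))
  if (length(missing_terms)) {
    stop("fixed coefficients lack term(s): ",
         paste(missing_terms, collapse = ", "), call. = FALSE)
  }
  eta <- drop(X %*% fixed[irt_fixed_terms()])
  if (!is.null(re_participant)) {
    Zp <- build_participant_design(X)
    rp <- as.matrix(as.data.frame(re_participant)[, irt_participant_terms()])
    eta <- eta + rowSums(Zp * rp)
  }
  if (!is.null(re_te)) {
    Zt <- build_te_design(X)
    rt <- as.matrix(as.data.frame(re_te)[, irt_te_terms()])
    eta <- eta + rowSums(Zt * rt)
  }
  eta
}

#' Ordinal log likelihood of a parameter set
#'
#' Direct evaluation of the model's log likelihood: the sum over records of
#' the log probability of the observed response category. Serves both as a
#' user-facing utility and as an independent check on the compiled
#' log-posterior used by the sampler.
#'
#' @param params A list with elements `tau` (numeric length 2, ordered),
#'   `beta` (named fixed-effect vector), and optionally `re_participant`
#'   and `re_te`: matrices of group coefficient deviations with rownames
#'   identifying the groups and columns [irt_participant_terms()] /
#'   [irt_te_terms()].
#' @param data Response records with standardized predictor columns `age`,
#'   `exposure`, `cognateness`, `length`, `frequency`, a `response` column
#'   in `{0, 1, 2}`, and `participant_id` / `te_id` where random effects
#'   are supplied.
#'
#' @return The total log likelihood (scalar).
#' @export
log_likelihood <- function(params, data) {
  stopifnot(is.list(params), length(params$tau) == 2)
  if (params$tau[1] >= params$tau[2]) {
    stop("thresholds must be ordered: tau1 < tau2", call. = FALSE)
  }
  if (!all(data$response %in% 0:2)) {
    stop("responses must be in {0, 1, 2}", call. = FALSE)
  }
  rp <- NULL
  if (!is.null(params$re_participant)) {
    rp <- params$re_participant[as.character(data$participant_id), , drop = FALSE]
  }
  rt <- NULL
  if (!is.null(params$re_te)) {
    rt <- params$re_te[as.character(data$te_id), , drop = FALSE]
  }
  eta <- linear_predictor(data, params$beta, rp, rt)
  pr <- as.matrix(category_probabilities(eta, params$tau[1], params$tau[2]))
  ll <- log(pr[cbind(seq_len(nrow(pr)), data$response + 1L)])
  bad <- which(!is.finite(ll))
  if (length(bad)) {
    stop("non-finite log likelihood at record(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  sum(ll)
}

#' Fit the Bayesian multilevel ordinal model of word acquisition
#'
#' Fits the cumulative-logit item-response model: ordered caregiver
#' responses (No < Understands < Understands-and-Says) are modeled on a
#' latent scale with thresholds for the comprehension and production
#' boundaries; fixed effects are standardized age, exposure, cognateness,
#' length (phonemes) and frequency (Zipf) plus the two- and three-way
#' interactions of age, exposure and cognateness; participants and
#' translation equivalents contribute correlated random intercepts and
#' slopes (maximal structure, non-centered parameterization). Priors:
#' thresholds N(-0.25, 0.50), slopes N(0, 1), random-effect SDs
#' positive-truncated N(1, 0.25), correlations LKJ(2). Sampling uses the
#' package's No-U-Turn sampler; runs are reproducible under a fixed seed.
#'
#' @param data Response records: a data frame with columns
#'   `participant_id`, `te_id`, `response` (integer 0/1/2), `age` (months),
#'   `exposure` (proportion), `cognateness`, `n_phonemes`, `zipf`.
#'   Predictors are standardized internally (observation-level, pooled
#'   across languages); the scaling metadata is stored on the fit.
#' @param chains Number of MCMC chains (run sequentially).
#' @param iter_warmup,iter_sampling Warmup and post-warmup iterations per
#'   chain.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param adapt_delta Target acceptance statistic for step-size adaptation.
#' @param max_treedepth Maximum trajectory doublings per iteration.
#' @param prior_only If `TRUE`, ignore `data` likelihood and sample from
#'   the prior (no random-effect groups are instantiated).
#' @param rhat_warn,ess_warn Convergence policy: warn if any monitored
#'   parameter has split-Rhat above `rhat_warn` or bulk ESS below
#'   `ess_warn`.
#'
#' @return A `bivocab_fit` object: posterior draws (iterations x chains x
#'   parameters) of thresholds, fixed slopes, random-effect SDs and
#'   correlations, plus sampler metadata, standardization scales and data
#'   summaries. Methods: [tidy()][generics::tidy()],
#'   [glance()][generics::glance()], [diagnose()], [marginal_effects()],
#'   [ggplot2::autoplot()].
#' @export
fit_acquisition_model <- function(data = NULL, chains = 4, iter_warmup = 1000,
                                  iter_sampling = 1000, seed = 1L,
                                  adapt_delta = 0.8, max_treedepth = 10,
                                  prior_only = FALSE,
                                  rhat_warn = 1.01, ess_warn = 400) {
  if (is.null(data) && !prior_only) {
    stop("data is required unless prior_only = TRUE", call. = FALSE)
  }
  scales <- NULL
  ranges <- NULL
  re_blocks <- list()
  cdata <- NULL
  n_obs <- 0L
  n_participants <- 0L
  n_tes <- 0L

  if (!prior_only) {
    req <- c("participant_id", "te_id", "response", "age", "exposure",
             "cognateness", "n_phonemes", "zipf")
    missing <- setdiff(req, names(data))
    if (length(missing)) {
      stop("data lacks column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    if (nrow(data) == 0) stop("data is empty", call. = FALSE)
    if (!all(data$response %in% 0:2)) {
      stop("responses must be in {0, 1, 2}", call. = FALSE)
    }
    raw <- list(age = data$age, exposure = data$exposure,
                cognateness = data$cognateness,
                length = as.numeric(data$n_phonemes),
                frequency = data$zipf)
    z <- lapply(names(raw), function(nm) standardize_tolerant(raw[[nm]], nm))
    names(z) <- names(raw)
    scales <- tibble::tibble(
      term = names(z),
      mean = vapply(z, function(v) attr(v, "scaled_mean"), numeric(1)),
      sd = vapply(z, function(v) attr(v, "scaled_sd"), numeric(1)),
      min = vapply(raw, min, numeric(1)),
      max = vapply(raw, max, numeric(1))
    )
    X <- build_fixed_design(z$age, z$exposure, z$cognateness, z$length,
                            z$frequency)
    pid <- as.integer(factor(data$participant_id))
    tid <- as.integer(factor(data$te_id))
    n_participants <- max(pid)
    n_tes <- max(tid)
    re_blocks <- list()
    if (n_participants > 1) {
      re_blocks$participant <- list(group = pid, Z = build_participant_design(X),
                                    n_groups = n_participants,
                                    terms = irt_participant_terms())
    } else {
      warning("single participant: dropping the participant random-effect block",
              call. = FALSE)
    }
    if (n_tes > 1) {
      re_blocks$te <- list(group = tid, Z = build_te_design(X),
                           n_groups = n_tes, terms = irt_te_terms())
    } else {
      warning("single translation equivalent: dropping the item random-effect block",
              call. = FALSE)
    }
    n_obs <- nrow(data)
    cdata <- list(y = as.integer(data$response), X = X,
                  re = unname(lapply(re_blocks, function(b) b[c("group", "Z", "n_groups")])))
  } else {
    cdata <- list(y = integer(0),
                  X = matrix(numeric(0), nrow = 0, ncol = 9,
                             dimnames = list(NULL, irt_fixed_terms())),
                  re = list())
  }

  D <- irt_n_params(cdata)
  param_names <- irt_param_names(re_blocks)
  n_store <- length(param_names)

  draws <- array(NA_real_, dim = c(iter_sampling, chains, n_store),
                 dimnames = list(NULL, NULL, param_names))
  divergences <- integer(chains)
  stepsize <- numeric(chains)
  accept <- numeric(chains)
  treedepth_max <- integer(chains)

  for (ch in seq_len(chains)) {
    set.seed(seed + ch - 1L)
    init <- stats::runif(D, -0.5, 0.5)
    res <- irt_nuts_chain(cdata, init, as.integer(iter_warmup),
                          as.integer(iter_sampling), adapt_delta,
                          as.integer(max_treedepth))
    draws[, ch, ] <- irt_constrain_draws(res$draws, res$lp, re_blocks)
    divergences[ch] <- res$divergences
    stepsize[ch] <- res$stepsize
    accept[ch] <- res$accept_mean
    treedepth_max[ch] <- max(res$treedepth)
  }

  fit <- structure(list(
    draws = draws,
    params = param_names,
    fixed_terms = irt_fixed_terms(),
    re_blocks = lapply(re_blocks, function(b) b[c("n_groups", "terms")]),
    scales = scales,
    chains = chains,
    iter_warmup = iter_warmup,
    iter_sampling = iter_sampling,
    seed = seed,
    adapt_delta = adapt_delta,
    max_treedepth = max_treedepth,
    divergences = divergences,
    stepsize = stepsize,
    accept = accept,
    treedepth_max = treedepth_max,
    n_obs = n_obs,
    n_participants = n_participants,
    n_tes = n_tes,
    prior_only = prior_only
  ), class = "bivocab_fit")

  if (chains >= 2 && iter_sampling >= 100) {
    diag <- diagnose(fit)
    bad_rhat <- diag$term[!is.na(diag$rhat) & diag$rhat > rhat_warn]
    bad_ess <- diag$term[!is.na(diag$ess_bulk) & diag$ess_bulk < ess_warn]
    if (length(bad_rhat)) {
      warning("split-Rhat above ", rhat_warn, " for: ",
              paste(utils::head(bad_rhat, 5), collapse = ", "), call. = FALSE)
    }
    if (length(bad_ess)) {
      warning("bulk ESS below ", ess_warn, " for: ",
              paste(utils::head(bad_ess, 5), collapse = ", "), call. = FALSE)
    }
  }
  if (sum(divergences) > 0) {
    warning(sum(divergences), " divergent transition(s) after warmup",
            call. = FALSE)
  }
  fit
}

# Names of the stored (constrained) parameters, given the RE blocks kept.
irt_param_names <- function(re_blocks) {
  nm <- c("tau_comprehension", "tau_production",
          paste0("b_", irt_fixed_terms()))
  for (bl in names(re_blocks)) {
    terms <- re_blocks[[bl]]$terms
    nm <- c(nm, paste0("sd_", bl, "__", terms))
  }
  for (bl in names(re_blocks)) {
    terms <- re_blocks[[bl]]$terms
    K <- length(terms)
    if (K > 1) {
      for (i in 2:K) for (j in 1:(i - 1)) {
        nm <- c(nm, paste0("cor_", bl, "__", terms[j], "__", terms[i]))
      }
    }
  }
  c(nm, "lp__")
}

# Transform one chain's unconstrained draws into the stored constrained set.
irt_constrain_draws <- function(u, lp, re_blocks) {
  n <- nrow(u)
  P <- 9L
  out <- matrix(NA_real_, n, 0)
  tau1 <- u[, 1]
  tau2 <- tau1 + exp(u[, 2])
  out <- cbind(tau1, tau2, u[, 2 + seq_len(P), drop = FALSE])
  off <- 2L + P
  sd_cols <- list()
  cor_cols <- list()
  for (bl in names(re_blocks)) {
    K <- length(re_blocks[[bl]]$terms)
    sd_cols[[bl]] <- exp(u[, off + seq_len(K), drop = FALSE])
    off <- off + K
    nfree <- K * (K - 1) / 2
    if (nfree > 0) {
      cors <- matrix(NA_real_, n, nfree)
      for (d in seq_len(n)) {
        R <- corr_from_unconstrained(u[d, off + seq_len(nfree)], K)
        cors[d, ] <- R[lower.tri(R)][order_lowertri(K)]
      }
      cor_cols[[bl]] <- cors
    } else {
      cor_cols[[bl]] <- matrix(numeric(0), n, 0)
    }
    off <- off + nfree
  }
  for (bl in names(re_blocks)) out <- cbind(out, sd_cols[[bl]])
  for (bl in names(re_blocks)) out <- cbind(out, cor_cols[[bl]])
  cbind(out, lp)
}

# R's lower.tri() runs column-wise; the stored order is row-wise by (i, j<i).
order_lowertri <- function(K) {
  idx <- which(lower.tri(matrix(0, K, K)))
  ij <- arrayInd(idx, c(K, K))
  order(ij[, 1], ij[, 2])
}

#' Extract posterior draws as a matrix
#'
#' @param fit A `bivocab_fit` or `bivocab_lm` object.
#' @param pars Optional character vector of parameter names to keep.
#'
#' @return A matrix with one row per post-warmup draw (chains stacked) and
#'   one column per parameter.
#' @export
posterior_draws <- function(fit, pars = NULL) {
  a <- fit$draws
  m <- matrix(a, nrow = dim(a)[1] * dim(a)[2], ncol = dim(a)[3])
  colnames(m) <- dimnames(a)[[3]]
  if (!is.null(pars)) {
    missing <- setdiff(pars, colnames(m))
    if (length(missing)) {
      stop("unknown parameter(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    m <- m[, pars, drop = FALSE]
  }
  m
}

#' @export
print.bivocab_fit <- function(x, ...) {
  cat("Bayesian multilevel cumulative-logit acquisition model\n")
  if (x$prior_only) {
    cat("  (prior predictive: no data)\n")
  } else {
    cat(sprintf("  observations: %d  participants: %d  translation equivalents: %d\n",
                x$n_obs, x$n_participants, x$n_tes))
  }
  cat(sprintf("  chains: %d  warmup: %d  sampling: %d  divergences: %d\n",
              x$chains, x$iter_warmup, x$iter_sampling, sum(x$divergences)))
  s <- tidy(x)
  print(s, n = nrow(s))
  invisible(x)
}
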