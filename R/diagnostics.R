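#' Convergence diagnostics for posterior draws
#'
#' Computes rank-normalized split-Rhat (the maximum of the bulk and folded
#' variants) and bulk effective sample size for each stored parameter, in
#' the style of modern MCMC practice: chains are split in half, draws are
#' rank-normalized through the standard normal quantile function, and ESS
#' uses Geyer's initial monotone positive sequence on the combined
#' autocorrelations.
#'
#' @param fit A `bivocab_fit` or `bivocab_lm` object with at least two
#'   chains.
#' @param pars Optional parameter names to restrict to.
#'
#' @return A tibble with columns `term`, `rhat`, `ess_bulk`.
#' @export
diagnose <- function(fit, pars = NULL) {
  a <- fit$draws
  if (dim(a)[2] < 2) {
    stop("Rhat is undefined for a single chain; run at least two chains",
         call. = FALSE)
  }
  params <- dimnames(a)[[3]]
  if (!is.null(pars)) {
    missing <- setdiff(pars, params)
    if (length(missing)) {
      stop("unknown parameter(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    params <- pars
  }
  tibble::tibble(
    term = params,
    rhat = unname(vapply(params, function(p) rhat_rank(a[, , p, drop = TRUE]),
                         numeric(1))),
    ess_bulk = unname(vapply(params,
                             function(p) ess_bulk_rank(a[, , p, drop = TRUE]),
                             numeric(1)))
  )
}

# Split each column (chain) of an iterations x chains matrix in half.
split_chains <- function(m) {
  n <- nrow(m)
  h <- floor(n / 2)
  cbind(m[seq_len(h), , drop = FALSE],
        m[seq.int(n - h + 1L, n), , drop = FALSE])
}

# Rank-normalization (fractional offset 3/8) applied over all draws jointly.
rank_normalize <- function(m) {
  S <- length(m)
  z <- stats::qnorm((rank(m, ties.method = "average") - 0.375) / (S + 0.25))
  matrix(z, nrow = nrow(m), ncol = ncol(m))
}

# Classic potential scale reduction factor on an iterations x chains matrix.
rhat_basic <- function(m) {
  n <- nrow(m)
  if (n < 2) return(NA_real_)
  mu <- colMeans(m)
  v <- apply(m, 2, stats::var)
  W <- mean(v)
  B <- n * stats::var(mu)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

rhat_rank <- function(m) {
  m <- as.matrix(m)
  if (stats::sd(m) == 0) return(NA_real_)
  s <- split_chains(m)
  bulk <- rhat_basic(rank_normalize(s))
  folded <- rhat_basic(rank_normalize(abs(s - stats::median(s))))
  max(bulk, folded)
}

# Autocovariance function (biased, lags 0..n-1) via FFT.
autocov_fft <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  npad <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(xc, rep(0, npad - n)))
  ac <- Re(stats::fft(Mod(f)^2, inverse = TRUE)) / npad
  ac[seq_len(n)] / n
}

# Bulk ESS on rank-normalized split chains.
ess_bulk_rank <- function(m) {
  m <- as.matrix(m)
  if (stats::sd(m) == 0) return(NA_real_)
  z <- rank_normalize(split_chains(m))
  n <- nrow(z)
  nc <- ncol(z)
  if (n < 4) return(NA_real_)
  acov <- apply(z, 2, autocov_fft)
  chain_var <- acov[1, ] * n / (n - 1)
  W <- mean(chain_var)
  mean_acov <- rowMeans(acov)
  varplus <- W * (n - 1) / n + stats::var(colMeans(z))
  if (!is.finite(varplus) || varplus <= 0) return(NA_real_)
  rho <- 1 - (W - mean_acov) / varplus   # rho[k + 1] is lag k
  # Geyer pairs P_t = rho_{2t} + rho_{2t+1}: truncate at the first negative
  # pair sum and enforce a monotone non-increasing sequence.
  s <- 0
  prev_pair <- Inf
  for (t in 0:(floor(n / 2) - 1)) {
    i1 <- 2 * t + 1
    i2 <- 2 * t + 2
    if (i2 > length(rho)) break
    pair <- rho[i1] + rho[i2]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev_pair)
    prev_pair <- pair
    s <- s + pair
  }
  tau <- max(-1 + 2 * s, 1 / log10(n * nc + 1))
  n * nc / tau
}
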