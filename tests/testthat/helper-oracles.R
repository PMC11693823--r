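# Independent oracles used across tests.

# Plain recursive definition of the unit-cost edit distance.
lev_recursive <- function(a, b) {
  if (length(a) == 0) return(length(b))
  if (length(b) == 0) return(length(a))
  cost <- if (a[1] == b[1]) 0L else 1L
  min(lev_recursive(a[-1], b) + 1L,
      lev_recursive(a, b[-1]) + 1L,
      lev_recursive(a[-1], b[-1]) + cost)
}

# All sequences of length 0..max_len over an alphabet.
all_sequences <- function(alphabet, max_len) {
  out <- list(character(0))
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), len), stringsAsFactors = FALSE))
    out <- c(out, lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, ],
                                                                 use.names = FALSE)))
  }
  out
}

# Exhaustive minimal-window HDI: try every contiguous window of the sorted
# sample holding ceiling(mass * n) points.
hdi_exhaustive <- function(x, mass = 0.95) {
  xs <- sort(x)
  n <- length(xs)
  m <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1)) {
    lo <- xs[i]
    hi <- xs[i + m - 1]
    if (hi - lo < best[2] - best[1]) best <- c(lo, hi)
  }
  best
}

# All segmentations of a string into inventory symbols.
all_segmentations <- function(s, inventory) {
  if (!nzchar(s)) return(list(character(0)))
  out <- list()
  for (sym in inventory) {
    if (startsWith(s, sym)) {
      rest <- all_segmentations(substring(s, nchar(sym) + 1), inventory)
      out <- c(out, lapply(rest, function(r) c(sym, r)))
    }
  }
  out
}

# A small response-record tibble with standardized predictors attached,
# for linear-predictor / likelihood tests.
tiny_records <- function(n = 20, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    participant_id = sample(paste0("p", 1:4), n, replace = TRUE),
    te_id = sample(paste0("te", 1:3), n, replace = TRUE),
    age = rnorm(n), exposure = rnorm(n), cognateness = rnorm(n),
    length = rnorm(n), frequency = rnorm(n),
    response = sample(0:2, n, replace = TRUE)
  )
}

# Construct a minimal bivocab_fit whose posterior is exactly the supplied
# draws (used to test inference utilities independently of the sampler).
fake_fit <- function(beta_draws, tau_draws, scales = NULL) {
  stopifnot(ncol(beta_draws) == 9, ncol(tau_draws) == 2)
  nd <- nrow(beta_draws)
  params <- c("tau_comprehension", "tau_production",
              paste0("b_", bivocab::irt_fixed_terms()), "lp__")
  a <- array(NA_real_, dim = c(nd, 1, length(params)),
             dimnames = list(NULL, NULL, params))
  a[, 1, 1:2] <- tau_draws
  a[, 1, 2 + 1:9] <- beta_draws
  a[, 1, length(params)] <- 0
  if (is.null(scales)) {
    scales <- tibble::tibble(
      term = c("age", "exposure", "cognateness", "length", "frequency"),
      mean = c(22, 0.5, 0.5, 5, 4.5),
      sd = c(5, 0.2, 0.3, 1.5, 0.7),
      min = c(12, 0.1, 0, 2, 2.5),
      max = c(32, 0.9, 1, 9, 6.5)
    )
  }
  structure(list(draws = a, params = params,
                 fixed_terms = bivocab::irt_fixed_terms(),
                 re_blocks = list(), scales = scales, chains = 1,
                 iter_warmup = 0, iter_sampling = nd, seed = 0,
                 divergences = 0L, n_obs = 0L, n_participants = 0L,
                 n_tes = 0L, prior_only = FALSE),
            class = "bivocab_fit")
}
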