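#' Zipf lexical-frequency score
#'
#' Converts raw token counts from a child-directed-speech corpus to the
#' Zipf scale: `log10` of the add-one-smoothed frequency per billion
#' words, i.e. `log10((count + 1) / (corpus_tokens / 1e6)) + 3`. The
#' smoothing keeps zero counts finite, and the score is strictly
#' increasing in the raw count.
#'
#' @param raw_count Non-negative integer vector of token counts.
#' @param corpus_tokens Total token count of the corpus (positive scalar).
#'
#' @return Numeric vector of Zipf scores.
#' @export
#'
#' @examples
#' zipf_score(999, 1e6) # 6
#' zipf_score(0, 1e6)   # 3
zipf_score <- function(raw_count, corpus_tokens) {
  if (length(corpus_tokens) != 1L || !is.finite(corpus_tokens) || corpus_tokens <= 0) {
    stop("corpus_tokens must be a single positive number", call. = FALSE)
  }
  if (any(raw_count < 0, na.rm = TRUE)) {
    stop("raw_count must be non-negative", call. = FALSE)
  }
  log10((raw_count + 1) / (corpus_tokens / 1e6)) + 3
}

#' Map English lemma frequencies onto translation equivalents
#'
#' Both members of a translation equivalent name the same concept, so
#' both receive the raw count of the English lemma linked to their pair.
#' Forms whose pair has no English entry are flagged missing; the item
#' filter cascade later drops them.
#'
#' @param items Data frame with columns `item_id`, `te_id` and `lemma_en`
#'   (the English lemma key of the pair; `NA` if none).
#' @param english_counts Data frame with columns `lemma_en` and `count`
#'   (one row per lemma; duplicate keys are an error).
#' @param corpus_tokens Corpus total used for the Zipf transform.
#'
#' @return A tibble with `item_id`, `te_id`, `lemma_en`, `raw_count`,
#'   `zipf` and `has_frequency`. `raw_count` and `zipf` are `NA` where
#'   `has_frequency` is `FALSE`.
#' @export
map_frequencies <- function(items, english_counts, corpus_tokens = 1e6) {
  stopifnot(all(c("item_id", "te_id", "lemma_en") %in% names(items)),
            all(c("lemma_en", "count") %in% names(english_counts)))
  if (anyDuplicated(english_counts$lemma_en)) {
    stop("duplicate lemma keys in english_counts: ",
         paste(unique(english_counts$lemma_en[duplicated(english_counts$lemma_en)]),
               collapse = ", "), call. = FALSE)
  }
  out <- dplyr::left_join(
    tibble::as_tibble(items)[, c("item_id", "te_id", "lemma_en")],
    dplyr::rename(tibble::as_tibble(english_counts), raw_count = "count"),
    by = "lemma_en"
  )
  out$has_frequency <- !is.na(out$raw_count)
  out$zipf <- ifelse(out$has_frequency, zipf_score(dplyr::coalesce(out$raw_count, 0), corpus_tokens), NA_real_)
  out
}

#' Assign language exposure to responses
#'
#' A caregiver reports the child's cumulative exposure proportions to
#' Catalan, Spanish and any other language. Responses to a word form take
#' the exposure proportion of the form's language: a child exposed 65% to
#' Catalan gets 0.65 for Catalan forms and their Spanish proportion
#' (e.g. 0.35) for Spanish forms.
#'
#' @param profiles Data frame with columns `prop_catalan`, `prop_spanish`,
#'   `prop_other` (rows recycled against `language`). Proportions must
#'   each lie in \[0, 1\] and sum to 1 (tolerance 1e-6).
#' @param language Character vector of language tags (`"catalan"` or
#'   `"spanish"`).
#'
#' @return Numeric vector of exposure proportions in \[0, 1\].
#' @export
#'
#' @examples
#' prof <- data.frame(prop_catalan = 0.65, prop_spanish = 0.35, prop_other = 0)
#' assign_exposure(prof, c("catalan", "spanish"))
assign_exposure <- function(profiles, language) {
  profiles <- validate_exposure_profiles(profiles)
  bad <- setdiff(unique(language), c("catalan", "spanish"))
  if (length(bad)) {
    stop("unknown language tag(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- max(nrow(profiles), length(language))
  cat_p <- rep_len(profiles$prop_catalan, n)
  spa_p <- rep_len(profiles$prop_spanish, n)
  language <- rep_len(language, n)
  ifelse(language == "catalan", cat_p, spa_p)
}

validate_exposure_profiles <- function(profiles, tol = 1e-6) {
  req <- c("prop_catalan", "prop_spanish", "prop_other")
  missing <- setdiff(req, names(profiles))
  if (length(missing)) {
    stop("exposure profiles lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  profiles <- tibble::as_tibble(profiles)
  p <- as.matrix(profiles[, req])
  if (any(p < -tol | p > 1 + tol, na.rm = TRUE)) {
    stop("exposure proportions must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(rowSums(p) - 1) > tol, na.rm = TRUE)) {
    stop("exposure proportions must sum to 1 per participant", call. = FALSE)
  }
  profiles
}

#' Standardize a predictor
#'
#' Centers and scales a numeric vector to mean 0 and (sample, n-1)
#' standard deviation 1, keeping the original mean and sd as attributes so
#' that standardized model coefficients can be mapped back to raw units.
#'
#' @param x Numeric vector (length >= 2, non-constant).
#'
#' @return A numeric vector with attributes `scaled_mean` and `scaled_sd`.
#' @export
#'
#' @examples
#' z <- standardize(c(1, 2, 3))
#' attr(z, "scaled_sd")
standardize <- function(x) {
  if (length(x) < 2L) {
    stop("need at least two values to standardize", call. = FALSE)
  }
  m <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s <= 0) {
    stop("degenerate predictor: zero variance", call. = FALSE)
  }
  out <- (x - m) / s
  attr(out, "scaled_mean") <- m
  attr(out, "scaled_sd") <- s
  out
}

# Standardize, but let a constant predictor enter the model as zero (with a
# warning) instead of failing: degenerate designs (e.g. a single item) keep
# a well-defined, if uninformative, column.
standardize_tolerant <- function(x, label) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s <= 0) {
    warning("predictor '", label, "' is constant; entering the model as zero",
            call. = FALSE)
    out <- rep(0, length(x))
    attr(out, "scaled_mean") <- mean(x, na.rm = TRUE)
    attr(out, "scaled_sd") <- NA_real_
    return(out)
  }
  standardize(x)
}

#' Syllabic frequency of word forms
#'
#' The exploratory control analysis asks whether cognates are made of
#' more frequent syllables. For each syllable appearing in the selected
#' word forms, the lexical frequencies of all words containing it are
#' summed; a word form's syllabic frequency is then the sum of its
#' (token) syllables' table entries. Repeated syllables within a word
#' contribute once per occurrence.
#'
#' @param forms Data frame with columns `form_id`, `xsampa` (raw
#'   transcription retaining `.` syllable separators) and `frequency`
#'   (the form's lexical frequency, on whatever scale the caller uses;
#'   scores are linear in it).
#'
#' @return A list with `forms`: a tibble `form_id`, `syll_freq`,
#'   `n_syllables`; and `syllables`: the syllable -> summed-frequency
#'   table as a tibble `syllable`, `freq`.
#' @export
#'
#' @examples
#' lex <- data.frame(form_id = c("gato", "gata", "pero"),
#'                   xsampa = c("ga.to", "ga.ta", "pe.ro"),
#'                   frequency = c(10, 5, 20))
#' syllabic_frequency(lex)$forms
syllabic_frequency <- function(forms) {
  req <- c("form_id", "xsampa", "frequency")
  missing <- setdiff(req, names(forms))
  if (length(missing)) {
    stop("forms table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  forms <- tibble::as_tibble(forms)
  stripped <- gsub("[\"%]", "", forms$xsampa)
  if (any(!nzchar(stripped))) {
    stop("empty transcription in forms table", call. = FALSE)
  }
  sylls <- strsplit(stripped, ".", fixed = TRUE)
  if (any(vapply(sylls, function(s) any(!nzchar(s)), logical(1)))) {
    stop("malformed syllabification (empty syllable) in forms table", call. = FALSE)
  }
  long <- tibble::tibble(
    form_id = rep(forms$form_id, lengths(sylls)),
    frequency = rep(forms$frequency, lengths(sylls)),
    syllable = unlist(sylls)
  )
  # A syllable's frequency counts each containing word once, however many
  # times the syllable recurs within it.
  syll_table <- dplyr::summarise(
    dplyr::group_by(dplyr::distinct(long, .data$form_id, .data$syllable,
                                    .data$frequency), .data$syllable),
    freq = sum(.data$frequency), .groups = "drop"
  )
  scored <- dplyr::summarise(
    dplyr::group_by(dplyr::left_join(long, syll_table, by = "syllable"),
                    .data$form_id),
    syll_freq = sum(.data$freq),
    n_syllables = dplyr::n(),
    .groups = "drop"
  )
  scored <- scored[match(forms$form_id, scored$form_id), ]
  list(forms = scored, syllables = syll_table)
}
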