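#' Item filter cascade
#'
#' Applies the analysis item filters in a fixed order, each item counted
#' at its first failing stage: (1) keep nouns only; (2) drop items with
#' missing lexical frequency; (3) drop items covering more than one lemma;
#' (4) drop multi-word items; (5) drop items without a translation in the
#' other language. The cascade is idempotent, and the per-stage exclusion
#' counts plus the retained count always sum to the input count.
#'
#' @param items Data frame with columns `item_id`, `class` (grammatical
#'   class label), `has_frequency`, `lemma_count`, `is_multiword`,
#'   `has_translation`.
#' @param classes Character vector of recognized grammatical class
#'   labels; unknown labels are an error.
#'
#' @return A list with `items` (tibble of retained rows) and `exclusions`
#'   (tibble `stage`, `n_excluded`, ordered by stage).
#' @export
filter_items <- function(items,
                         classes = c("noun", "verb", "adjective", "adverb",
                                     "function_word", "interjection", "other")) {
  req <- c("item_id", "class", "has_frequency", "lemma_count", "is_multiword",
           "has_translation")
  missing <- setdiff(req, names(items))
  if (length(missing)) {
    stop("items table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  items <- tibble::as_tibble(items)
  bad <- setdiff(unique(items$class), classes)
  if (length(bad)) {
    stop("unknown grammatical class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(items$lemma_count < 1L)) {
    stop("lemma_count must be >= 1", call. = FALSE)
  }
  stages <- list(
    non_noun = function(d) d$class != "noun",
    missing_frequency = function(d) !d$has_frequency,
    multi_lemma = function(d) d$lemma_count > 1L,
    multi_word = function(d) d$is_multiword,
    untranslated = function(d) !d$has_translation
  )
  kept <- items
  log <- tibble::tibble(stage = names(stages), n_excluded = 0L)
  for (k in seq_along(stages)) {
    fails <- stages[[k]](kept)
    log$n_excluded[k] <- sum(fails)
    kept <- kept[!fails, , drop = FALSE]
  }
  list(items = kept, exclusions = log)
}

#' Exclude participants by third-language exposure
#'
#' Participants exposed *more than* `threshold` (default 10%) to a
#' language other than Catalan or Spanish are excluded; exposure exactly
#' at the threshold is retained (strict comparison).
#'
#' @param profiles Data frame of exposure profiles with columns
#'   `participant_id`, `prop_catalan`, `prop_spanish`, `prop_other`.
#' @param threshold Maximum tolerated third-language exposure proportion.
#'
#' @return The retained rows as a tibble.
#' @export
exclude_participants <- function(profiles, threshold = 0.10) {
  profiles <- validate_exposure_profiles(profiles)
  profiles[profiles$prop_other <= threshold, , drop = FALSE]
}

#' Pair items into translation equivalents
#'
#' Groups retained items by `te_id` and checks the one-to-one mapping:
#' each translation equivalent must have exactly one Catalan and one
#' Spanish form. Violating items are rejected with a reason rather than
#' silently dropped.
#'
#' @param items Data frame with columns `item_id`, `te_id`, `language`.
#'
#' @return A list with `pairs` (tibble `te_id`, `item_catalan`,
#'   `item_spanish`) and `rejected` (tibble `te_id`, `reason`; zero rows
#'   when the mapping is clean).
#' @export
pair_translations <- function(items) {
  req <- c("item_id", "te_id", "language")
  missing <- setdiff(req, names(items))
  if (length(missing)) {
    stop("items table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  items <- tibble::as_tibble(items)
  bad <- setdiff(unique(items$language), c("catalan", "spanish"))
  if (length(bad)) {
    stop("unknown language tag(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  stats <- dplyr::summarise(
    dplyr::group_by(items, .data$te_id),
    n = dplyr::n(),
    n_cat = sum(.data$language == "catalan"),
    n_spa = sum(.data$language == "spanish"),
    .groups = "drop"
  )
  reason <- dplyr::case_when(
    stats$n != 2L & stats$n_cat + stats$n_spa < 2L ~ "missing translation",
    stats$n_cat != 1L | stats$n_spa != 1L ~ "not one Catalan and one Spanish form",
    TRUE ~ NA_character_
  )
  rejected <- tibble::tibble(te_id = stats$te_id, reason = reason)
  rejected <- rejected[!is.na(rejected$reason), , drop = FALSE]
  good <- stats$te_id[is.na(reason)]
  ok <- items[items$te_id %in% good, , drop = FALSE]
  pairs <- tidyr::pivot_wider(ok[, c("te_id", "language", "item_id")],
                              names_from = "language", values_from = "item_id")
  pairs <- tibble::tibble(te_id = pairs$te_id,
                          item_catalan = pairs$catalan,
                          item_spanish = pairs$spanish)
  list(pairs = pairs, rejected = rejected)
}

#' Encode caregiver checklist responses as ordinal records
#'
#' Maps the three caregiver response options onto the ordered scale
#' 0 = No < 1 = Understands < 2 = Understands-and-Says (unanswered items
#' are "No" by questionnaire default), and joins each response to its
#' item's predictors and to the exposure profile of the administration it
#' came from. Longitudinal administrations share a `participant_id` and
#' differ in `administration_id`; exposure is attached per administration
#' because caregivers report it at each questionnaire completion.
#'
#' @param responses Data frame with columns `participant_id`,
#'   `administration_id`, `item_id`, `age` (months at administration) and
#'   `response` (label).
#' @param items Data frame with columns `item_id`, `te_id`, `language`,
#'   plus any item-level predictors to carry along (e.g. `cognateness`,
#'   `zipf`, `n_phonemes`).
#' @param profiles Exposure profiles with columns `participant_id`,
#'   `administration_id`, `prop_catalan`, `prop_spanish`, `prop_other`.
#' @param labels Named integer vector mapping response labels to
#'   0/1/2.
#'
#' @return A tibble with one row per response: identifiers, `age`,
#'   `response` (integer 0/1/2), `exposure`, and the item predictor
#'   columns.
#' @export
encode_responses <- function(responses, items, profiles,
                             labels = c(no = 0L, understands = 1L,
                                        understands_says = 2L)) {
  stopifnot(all(c("participant_id", "administration_id", "item_id", "age",
                  "response") %in% names(responses)),
            all(c("item_id", "te_id", "language") %in% names(items)),
            all(c("participant_id", "administration_id") %in% names(profiles)))
  responses <- tibble::as_tibble(responses)
  unmapped <- setdiff(unique(responses$response), names(labels))
  if (length(unmapped)) {
    stop("unmapped response label(s): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  out <- responses
  out$response <- unname(labels[as.character(responses$response)])
  out <- dplyr::inner_join(out, tibble::as_tibble(items), by = "item_id")
  profiles <- validate_exposure_profiles(profiles)
  out <- dplyr::inner_join(out, profiles,
                           by = c("participant_id", "administration_id"))
  if (nrow(out) < nrow(responses)) {
    stop("every response must join to a retained item and participant; ",
         nrow(responses) - nrow(out), " row(s) failed to join", call. = FALSE)
  }
  out$exposure <- ifelse(out$language == "catalan", out$prop_catalan,
                         out$prop_spanish)
  dplyr::select(out, -dplyr::any_of(c("prop_catalan", "prop_spanish",
                                      "prop_other")))
}
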