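#' Phoneme inventory for broad Catalan/Spanish X-SAMPA transcriptions
#'
#' Reads the phoneme-symbol inventory used by [tokenize_xsampa()]. The
#' bundled default covers broad Central Catalan and Castilian Spanish
#' transcriptions, including the multi-character affricate symbols
#' (`tS`, `dZ`, `ts`, `dz`) and trill digraphs. The file lists one symbol
#' per line, ordered by descending length so that maximal-munch
#' tokenization can consume the longest matching symbol first.
#'
#' @param path Path to a plain-text inventory file (one symbol per line).
#'   Defaults to the inventory shipped with the package.
#'
#' @return A character vector of phoneme symbols, sorted by descending
#'   number of characters.
#' @export
#'
#' @examples
#' head(xsampa_inventory())
xsampa_inventory <- function(path = system.file("extdata", "xsampa_inventory.txt",
                                                package = "bivocab")) {
  inv <- readLines(path, warn = FALSE)
  inv <- inv[nzchar(inv)]
  inv[order(-nchar(inv), inv)]
}

#' Tokenize X-SAMPA transcriptions into phoneme sequences
#'
#' Splits broad X-SAMPA transcriptions into phoneme tokens by
#' maximal-munch matching against a phoneme inventory: at each position
#' the longest inventory symbol that matches is consumed. Stress marks
#' (`"` and `%`) and syllable separators (`.`) are suprasegmental
#' delimiters, not phonemes, and are stripped before matching.
#'
#' @param x Character vector of X-SAMPA transcriptions.
#' @param inventory Character vector of phoneme symbols (see
#'   [xsampa_inventory()]). Must cover every multi-character symbol used
#'   in `x`.
#' @param delimiters Characters treated as non-phonemic delimiters and
#'   removed before tokenization.
#'
#' @return A list of character vectors, one per transcription, each
#'   holding the phoneme tokens in order. Concatenating the tokens of an
#'   element reconstructs its delimiter-stripped input.
#' @export
#'
#' @examples
#' tokenize_xsampa(c("\"gat", "\"ga.to"))
tokenize_xsampa <- function(x, inventory = xsampa_inventory(),
                            delimiters = c("\"", "%", ".")) {
  stopifnot(is.character(x), length(inventory) > 0)
  inventory <- inventory[order(-nchar(inventory), inventory)]
  lens <- unique(nchar(inventory))
  inv_set <- as.list(stats::setNames(rep(TRUE, length(inventory)), inventory))
  delim_pattern <- paste0("[", paste(gsub("([].\\^$*+?()[{|\"-])", "\\\\\\1", delimiters),
                                     collapse = ""), "]")
  out <- vector("list", length(x))
  for (i in seq_along(x)) {
    raw <- x[[i]]
    stripped <- gsub(delim_pattern, "", raw)
    if (!nzchar(stripped)) {
      stop("transcription ", i, " ('", raw, "') contains no phonemes", call. = FALSE)
    }
    tokens <- character(0)
    pos <- 1L
    n <- nchar(stripped)
    while (pos <= n) {
      hit <- NULL
      for (len in lens) {
        if (pos + len - 1L > n) next
        cand <- substr(stripped, pos, pos + len - 1L)
        if (!is.null(inv_set[[cand]])) {
          hit <- cand
          break
        }
      }
      if (is.null(hit)) {
        stop("unrecognized X-SAMPA symbol at position ", pos, " of '", stripped,
             "' (transcription ", i, ": '", raw, "')", call. = FALSE)
      }
      tokens <- c(tokens, hit)
      pos <- pos + nchar(hit)
    }
    out[[i]] <- tokens
  }
  out
}

#' Levenshtein distance between phoneme sequences
#'
#' Unit-cost edit distance (insertions, deletions, substitutions) between
#' two token sequences, computed by dynamic programming. Operates on
#' phoneme tokens, not characters, so multi-character X-SAMPA symbols
#' count as single segments.
#'
#' @param a,b Character vectors of phoneme tokens (empty vectors allowed),
#'   or lists of such vectors for vectorized use (recycled to a common
#'   length).
#'
#' @return An integer vector of edit distances.
#' @export
#'
#' @examples
#' phoneme_distance(c("g", "a", "t"), c("g", "a", "t", "o"))
phoneme_distance <- function(a, b) {
  if (!is.list(a)) a <- list(a)
  if (!is.list(b)) b <- list(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  vapply(seq_len(n), function(i) lev_dp(a[[i]], b[[i]]), integer(1))
}

# DP over token sequences; two-row table.
lev_dp <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  if (na == 0L) return(as.integer(nb))
  if (nb == 0L) return(as.integer(na))
  prev <- 0:nb
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    cur[1L] <- i
    for (j in seq_len(nb)) {
      cost <- if (a[[i]] == b[[j]]) 0L else 1L
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L, prev[j] + cost)
    }
    prev <- cur
  }
  as.integer(prev[nb + 1L])
}

#' Cognateness of a translation-equivalent pair
#'
#' Phonological similarity between two word forms: one minus the
#' Levenshtein distance between their phoneme sequences divided by the
#' length of the longer form. Scores lie in \[0, 1\]: 0 means the forms
#' share no alignable segments (e.g. /"taw.l@/ vs /"me.sa/), 1 means they
#' are segmentally identical (e.g. /"mar/ vs /"mar/).
#'
#' @param a,b Character vectors of phoneme tokens, or lists of such
#'   vectors for vectorized use.
#'
#' @return A numeric vector of similarity scores in \[0, 1\].
#' @export
#'
#' @examples
#' gat <- tokenize_xsampa("\"gat")[[1]]
#' gato <- tokenize_xsampa("\"ga.to")[[1]]
#' cognateness(gat, gato) # 0.75
cognateness <- function(a, b) {
  if (!is.list(a)) a <- list(a)
  if (!is.list(b)) b <- list(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  len_max <- pmax(lengths(a), lengths(b))
  if (any(len_max == 0L)) {
    stop("cognateness is undefined when both forms are empty", call. = FALSE)
  }
  1 - phoneme_distance(a, b) / len_max
}

#' Score cognateness for a table of checklist items
#'
#' Tokenizes each item's X-SAMPA transcription, pairs items by
#' translation-equivalent identifier, and computes the Levenshtein
#' distance and cognateness score of every Catalan/Spanish pair.
#'
#' @param items A data frame with columns `item_id`, `te_id`, `language`
#'   (`"catalan"` or `"spanish"`) and `xsampa`.
#' @param inventory Phoneme inventory passed to [tokenize_xsampa()].
#'
#' @return A tibble with one row per translation equivalent: `te_id`,
#'   `item_catalan`, `item_spanish`, `n_phonemes_catalan`,
#'   `n_phonemes_spanish`, `levenshtein` and `cognateness`.
#' @export
score_cognateness <- function(items, inventory = xsampa_inventory()) {
  items <- as_item_pairs(items)
  toks <- tokenize_xsampa(items$xsampa, inventory = inventory)
  items$tokens <- toks
  items$n_phonemes <- lengths(toks)
  wide <- tidyr::pivot_wider(
    dplyr::select(items, "te_id", "language", "item_id", "tokens", "n_phonemes"),
    names_from = "language",
    values_from = c("item_id", "tokens", "n_phonemes")
  )
  tibble::tibble(
    te_id = wide$te_id,
    item_catalan = wide$item_id_catalan,
    item_spanish = wide$item_id_spanish,
    n_phonemes_catalan = wide$n_phonemes_catalan,
    n_phonemes_spanish = wide$n_phonemes_spanish,
    levenshtein = phoneme_distance(wide$tokens_catalan, wide$tokens_spanish),
    cognateness = cognateness(wide$tokens_catalan, wide$tokens_spanish)
  )
}

# Validate the minimal pairing structure used by score_cognateness().
as_item_pairs <- function(items) {
  required <- c("item_id", "te_id", "language", "xsampa")
  missing <- setdiff(required, names(items))
  if (length(missing)) {
    stop("items table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  items <- tibble::as_tibble(items)
  bad_lang <- setdiff(unique(items$language), c("catalan", "spanish"))
  if (length(bad_lang)) {
    stop("unknown language tag(s): ", paste(bad_lang, collapse = ", "),
         call. = FALSE)
  }
  counts <- dplyr::count(items, .data$te_id, .data$language)
  dup <- counts$n > 1L
  if (any(dup)) {
    stop("translation equivalents with more than one form per language: ",
         paste(unique(counts$te_id[dup]), collapse = ", "), call. = FALSE)
  }
  per_te <- dplyr::count(items, .data$te_id)
  odd <- per_te$te_id[per_te$n != 2L]
  if (length(odd)) {
    stop("translation equivalents without exactly one form per language: ",
         paste(odd, collapse = ", "), call. = FALSE)
  }
  items
}
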