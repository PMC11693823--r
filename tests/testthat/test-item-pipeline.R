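test_that("filter cascade reproduces the study's stage counts", {
  items <- make_item_fixture()
  res <- filter_items(items)
  expect_equal(nrow(res$items), 604)
  expect_equal(res$exclusions$n_excluded, c(628L, 269L, 48L, 9L, 32L))
  # conservation: exclusions plus retained give back the input count
  expect_equal(sum(res$exclusions$n_excluded) + nrow(res$items), nrow(items))
  expect_equal(as.vector(table(res$items$language)), c(302L, 302L))
  # idempotence: re-filtering the retained table removes nothing
  again <- filter_items(res$items)
  expect_equal(nrow(again$items), 604)
  expect_true(all(again$exclusions$n_excluded == 0L))
})

test_that("items are counted at their first failing stage only", {
  toy <- tibble::tibble(
    item_id = paste0("i", 1:5),
    class = c("verb", "noun", "noun", "noun", "noun"),
    has_frequency = c(FALSE, FALSE, TRUE, TRUE, TRUE),
    lemma_count = c(2L, 1L, 2L, 1L, 1L),
    is_multiword = c(TRUE, FALSE, TRUE, FALSE, FALSE),
    has_translation = c(FALSE, TRUE, TRUE, FALSE, TRUE)
  )
  # by-hand sequential application: i1 falls at non-noun (despite failing
  # three later predicates), i2 at missing frequency, i3 at multi-lemma,
  # i4 at untranslated, i5 survives
  res <- filter_items(toy)
  expect_equal(res$exclusions$n_excluded, c(1L, 1L, 1L, 0L, 1L))
  expect_equal(res$items$item_id, "i5")
  expect_error(filter_items(dplyr::mutate(toy, class = "nombre")),
               "unknown grammatical class")
})

test_that("an all-clean noun table passes the cascade unchanged", {
  clean <- make_item_fixture(c(total = 10, non_noun = 0,
                               missing_frequency = 0, multi_lemma = 0,
                               multi_word = 0, untranslated = 0))
  res <- filter_items(clean)
  expect_equal(res$items, clean)
  expect_true(all(res$exclusions$n_excluded == 0L))
  expect_error(make_item_fixture(c(total = 5, non_noun = 4,
                                   missing_frequency = 4, multi_lemma = 0,
                                   multi_word = 0, untranslated = 0)),
               "infeasible")
})

test_that("third-language exclusion is strict at the 10% boundary", {
  profs <- tibble::tibble(
    participant_id = c("arabic8", "boundary10", "over12"),
    prop_other = c(0.08, 0.10, 0.12),
    prop_catalan = (1 - prop_other) * 0.6,
    prop_spanish = 1 - prop_other - prop_catalan
  )
  kept <- exclude_participants(profs)
  expect_equal(kept$participant_id, c("arabic8", "boundary10"))
  expect_equal(exclude_participants(profs, threshold = 0.09)$participant_id,
               "arabic8")
})

test_that("translation pairing enforces the one-to-one mapping", {
  items <- tibble::tibble(
    item_id = c("gos", "perro", "gat", "sol"),
    te_id = c("te_dog", "te_dog", "te_cat", "te_sun"),
    language = c("catalan", "spanish", "catalan", "catalan")
  )
  res <- pair_translations(items)
  expect_equal(res$pairs$te_id, "te_dog")
  expect_equal(res$pairs$item_catalan, "gos")
  expect_equal(res$pairs$item_spanish, "perro")
  expect_setequal(res$rejected$te_id, c("te_cat", "te_sun"))
  # the retained study fixture pairs into 302 translation equivalents
  retained <- filter_items(make_item_fixture())$items
  full <- pair_translations(retained)
  expect_equal(nrow(full$pairs), 302)
  expect_equal(nrow(full$rejected), 0)
})

test_that("response encoding maps labels, exposure, and administrations", {
  items <- tibble::tibble(
    item_id = c("gat", "gato"),
    te_id = "te_cat",
    language = c("catalan", "spanish"),
    cognateness = 0.75
  )
  profiles <- tibble::tibble(
    participant_id = "p1",
    administration_id = c("a1", "a2"),
    prop_catalan = c(0.65, 0.60),
    prop_spanish = c(0.35, 0.40),
    prop_other = 0
  )
  responses <- tibble::tibble(
    participant_id = "p1",
    administration_id = rep(c("a1", "a2"), each = 2),
    item_id = rep(c("gat", "gato"), 2),
    age = rep(c(20, 21.2), each = 2),   # 25+ days apart, same child
    response = c("understands_says", "no", "understands", "understands_says")
  )
  out <- encode_responses(responses, items, profiles)
  expect_equal(out$response, c(2L, 0L, 1L, 2L))
  expect_equal(out$exposure, c(0.65, 0.35, 0.60, 0.40))
  expect_equal(unique(out$participant_id), "p1")
  expect_equal(dplyr::n_distinct(out$administration_id), 2)
  expect_equal(out$cognateness, rep(0.75, 4))
  bad <- dplyr::mutate(responses, response = "maybe")
  expect_error(encode_responses(bad, items, profiles), "unmapped response")
  orphan <- dplyr::mutate(responses, item_id = "unknown_item")
  expect_error(encode_responses(orphan, items, profiles), "failed to join")
})
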