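test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- generator_config(n_samples = 100, seed = 1)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a, b)
  d <- generate_corpus(generator_config(n_samples = 100, seed = 2))
  expect_false(identical(a, d))
})

test_that("generated ground truth serializes and re-parses", {
  corp <- generate_corpus(generator_config(n_samples = 200, seed = 3))
  for (s in corp$actions) {
    expect_false(is_parse_error(parse_actions(s)), info = s)
  }
})

test_that("addition is the most frequent action under default weights", {
  corp <- generate_corpus(generator_config(n_samples = 800, seed = 4))
  dist <- action_distribution(corp)
  expect_equal(names(dist$type_counts)[1L], "Add")
  # stirring and concentration are near the top; rare operations are rare
  top8 <- names(dist$type_counts)[1:8]
  expect_true(all(c("Stir", "Concentrate") %in% top8))
  rare <- dist$type_counts[c("Microwave", "Sonicate", "Recrystallize")]
  rare[is.na(rare)] <- 0L
  expect_true(all(rare < dist$type_counts[["Add"]] / 5))
})

test_that("dissolution templates carry two additions as ground truth", {
  corp <- generate_corpus(generator_config(
    n_samples = 30, seed = 5,
    weights = c(dissolve = 1)))
  for (s in corp$actions) {
    types <- vapply(unclass(parse_actions(s)), `[[`, "", "type")
    expect_equal(types, c("Add", "Add"))
  }
})

test_that("substitution pools are stable, non-empty and well-formed", {
  p1 <- generate_pools(seed = 9)
  p2 <- generate_pools(seed = 9)
  expect_identical(p1, p2)
  expect_true(all(lengths(unclass(p1)) > 0))
  # quantity strings are recognized by the entity tagger
  for (q in p1$quantities) {
    tags <- tag_entities(paste0("compound X (", q, ") was added."))
    expect_true(q %in% tags$value[tags$label == "QUANTITY"], info = q)
  }
  # durations and temperatures re-tag as well
  for (d in head(p1$durations, 10)) {
    tags <- tag_entities(paste("stirred for", d))
    expect_true(d %in% tags$value[tags$label == "DURATION"], info = d)
  }
  for (tm in head(p1$temperatures, 10)) {
    tags <- tag_entities(paste("heated at", tm))
    expect_true(tm %in% tags$value[tags$label == "TEMPERATURE"], info = tm)
  }
})

test_that("the extractor recovers generated ground truth on clean text", {
  corp <- generate_corpus(generator_config(n_samples = 300, seed = 17))
  pred <- vapply(corp$sentence, function(s) {
    serialize_actions(extract_sentence(s))
  }, "", USE.NAMES = FALSE)
  expect_gte(mean(pred == corp$actions), 0.99)
})

test_that("noise mode produces InvalidAction paths and typos", {
  corp <- generate_corpus(generator_config(n_samples = 300, seed = 23,
                                           noise = TRUE, noise_rate = 0.5))
  expect_true(any(corp$actions == "InvalidAction"))
  # noisy corpora degrade extraction below the clean-text level
  pred <- vapply(corp$sentence, function(s) {
    serialize_actions(extract_sentence(s))
  }, "", USE.NAMES = FALSE)
  expect_lt(mean(pred == corp$actions), 1)
})

test_that("invalid weights are rejected", {
  expect_error(generator_config(weights = c(nonsense_template = 1)))
  expect_error(generator_config(weights = c(add_passive = -1)))
})
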