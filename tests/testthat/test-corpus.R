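heat_rec <- function(name, q, temperature = NULL, duration = NULL) {
  list(action_name = "Heat",
       compounds = list(list(name = name, quantities = as.list(q))),
       temperature = temperature, duration = duration)
}

test_that("legacy heat records prepend additions", {
  seq <- adapt_legacy(list(heat_rec("toluene", "5 mL",
                                    temperature = "50 °C")))
  expect_equal(serialize_actions(seq),
               "Add toluene (5 mL); SetTemperature 50 °C")
  # with a duration the punctual change becomes a timed stir
  seq2 <- adapt_legacy(list(heat_rec("toluene", "5 mL", duration = "2 h")))
  expect_equal(serialize_actions(seq2), "Add toluene (5 mL); Stir for 2 h")
  expect_length(adapt_legacy(list()), 0L)
})

test_that("unmappable legacy records degrade to InvalidAction", {
  seq <- adapt_legacy(list(list(action_name = "Teleport",
                                compounds = list())))
  expect_equal(serialize_actions(seq, validate = FALSE), "InvalidAction")
})

test_that("legacy mapped records keep only admissible properties", {
  rec <- list(action_name = "Wash",
              compounds = list(list(name = "brine", quantities = list())),
              temperature = "0 °C")  # temperature not allowed on Wash
  seq <- adapt_legacy(list(rec))
  expect_equal(serialize_actions(seq), "Wash with brine")
  expect_true(validate_sequence(seq)$ok)
})

test_that("combining sources appends only missing Yield actions", {
  nlp <- parse_actions("Quench with water; Concentrate")
  legacy <- parse_actions("Yield product A (5 g)")
  combined <- combine_sources(nlp, legacy)
  expect_equal(serialize_actions(combined),
               "Quench with water; Concentrate; Yield product A (5 g)")
  # prefix property
  expect_identical(serialize_actions(combined[1:2]),
                   serialize_actions(nlp))
  # nothing to add
  expect_true(sequences_equal(combine_sources(nlp, parse_actions("Stir")),
                              nlp))
  # existing identical Yield is not duplicated
  withy <- parse_actions("Concentrate; Yield product A (5 g)")
  expect_true(sequences_equal(combine_sources(withy, legacy), withy))
})

test_that("pretraining filter drops invalid and verbose no-action pairs", {
  samples <- data.frame(
    sentence = c("Add water.",
                 "Something odd happened here today",
                 "short one",
                 paste0("The spectra were recorded on a 400 MHz instrument",
                        " with NMR referencing"),
                 strrep("x", 40),
                 "Add water."),
    actions = c("Add water", "InvalidAction", "NoAction", "NoAction",
                "NoAction", "Add water"),
    stringsAsFactors = FALSE)
  out <- filter_pretraining(samples)
  # invalid removed; long keyword-free NoAction removed; duplicate removed
  expect_equal(out$actions, c("Add water", "NoAction", "NoAction"))
  expect_equal(sum(out$sentence == "Add water."), 1L)
  # short NoAction kept, keyword-bearing long NoAction kept
  expect_true("short one" %in% out$sentence)
  expect_true(any(grepl("NMR", out$sentence)))
  # idempotent and never increasing
  expect_identical(filter_pretraining(out), out)
  expect_lte(nrow(out), nrow(samples))
})

test_that("dataset splits are exact, disjoint, exhaustive and reproducible", {
  corp <- generate_corpus(generator_config(n_samples = 100, seed = 1))
  corp$sentence <- make.unique(corp$sentence)
  sp <- split_dataset(corp, c(0.8, 0.1, 0.1), seed = 7)
  expect_equal(unname(vapply(sp, nrow, 0L)), c(80L, 10L, 10L))
  sp2 <- split_dataset(corp, c(0.8, 0.1, 0.1), seed = 7)
  expect_identical(sp, sp2)
  all_sent <- c(sp$train$sentence, sp$valid$sentence, sp$test$sentence)
  expect_setequal(all_sent, corp$sentence)
  expect_equal(anyDuplicated(all_sent), 0L)
  # ratios shaped like a large pretraining corpus split
  big <- split_dataset(corp, c(0.785, 0.107, 0.108), seed = 1)
  expect_equal(unname(vapply(big, nrow, 0L)), c(78L, 11L, 11L))
})

test_that("hard-sentence selection flags the documented difficulty cues", {
  samples <- data.frame(
    sentence = c("The residue was washed, followed by drying over MgSO4.",
                 "Add water.",
                 "Water was added and the water layer was separated.",
                 "The flask was heated gently."),
    actions = c("Wash; DrySolution over MgSO4",
                "Add water",
                "Add water; Wash with water",
                "SetTemperature 40 °C"),
    stringsAsFactors = FALSE)
  out <- select_hard_sentences(samples)
  expect_true(any(grepl("followed_by", out$reason)))
  expect_true(any(grepl("repeated_compound", out$reason)))
  expect_true(any(grepl("context_verb", out$reason)))
  expect_false("Add water." %in% out$sentence)
})

test_that("TSV and JSONL corpus files round-trip", {
  corp <- generate_corpus(generator_config(n_samples = 25, seed = 5))
  tsv <- tempfile(fileext = ".tsv")
  write_corpus_tsv(corp, tsv)
  back <- read_corpus_tsv(tsv)
  expect_equal(back$sentence, corp$sentence)
  expect_equal(back$actions, corp$actions)
  jl <- tempfile(fileext = ".jsonl")
  write_corpus_jsonl(corp, jl)
  back2 <- read_corpus_jsonl(jl)
  expect_equal(back2$sentence, corp$sentence)
  expect_equal(back2$actions, corp$actions)
  expect_equal(unique(back2$source), "synthetic")
})

test_that("legacy JSONL records adapt end to end", {
  jl <- tempfile(fileext = ".jsonl")
  writeLines(jsonlite::toJSON(list(
    sentence = "The mixture was heated to 50 °C.",
    actions = list(list(action_name = "Heat",
                        compounds = list(list(name = "toluene",
                                              quantities = list("5 mL"))),
                        temperature = "50 °C"))),
    auto_unbox = TRUE), jl)
  recs <- read_legacy_jsonl(jl)
  expect_length(recs, 1L)
  expect_equal(serialize_actions(adapt_legacy(recs[[1L]]$records)),
               "Add toluene (5 mL); SetTemperature 50 °C")
})
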