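ref_sample <- list(
  sentence = paste0("Diisopropylazodicarboxylate (0.05 ml, 0.302 mmol) was ",
                    "added to the reaction mixture followed by stirring ",
                    "for 3 h at room temperature."),
  actions = paste0("Add Diisopropylazodicarboxylate (0.05 ml, 0.302 mmol); ",
                   "Stir for 3 h at room temperature"))

test_that("p = 0 is the identity and p = 1 substitutes every entity", {
  pools <- generate_pools(seed = 1)
  same <- augment_sample(ref_sample, pools, p = 0, seed = 10)
  expect_identical(same$sentence, ref_sample$sentence)
  expect_identical(same$actions, ref_sample$actions)
  expect_equal(same$n_substituted, 0L)

  all_sub <- augment_sample(ref_sample, pools, p = 1, seed = 10)
  tags <- tag_entities(ref_sample$sentence)
  tags <- tags[tags$label %in% c("COMPOUND", "QUANTITY", "DURATION",
                                 "TEMPERATURE"), ]
  expect_equal(all_sub$n_substituted, nrow(tags))
  expect_false(identical(all_sub$sentence, ref_sample$sentence))
})

test_that("the same substitution is applied to sentence and actions", {
  pools <- generate_pools(seed = 2)
  for (sd in 1:25) {
    aug <- augment_sample(ref_sample, pools, p = 0.7, seed = sd)
    # every entity string in the augmented actions occurs in the sentence
    tags <- tag_entities(aug$sentence)
    tags <- tags[tags$label %in% c("COMPOUND", "QUANTITY", "DURATION",
                                   "TEMPERATURE"), ]
    for (v in tags$value) {
      if (grepl(v, aug$actions, fixed = TRUE)) {
        expect_true(grepl(v, aug$sentence, fixed = TRUE))
      }
    }
    # and the actions string still parses
    expect_false(is_parse_error(parse_actions(aug$actions)),
                 info = aug$actions)
  }
})

test_that("identical seeds reproduce identical augmentations", {
  pools <- generate_pools(seed = 3)
  a <- augment_sample(ref_sample, pools, p = 0.5, seed = 77)
  b <- augment_sample(ref_sample, pools, p = 0.5, seed = 77)
  expect_identical(a, b)
})

test_that("the empirical substitution rate converges to p", {
  pools <- generate_pools(seed = 4)
  tags <- tag_entities(ref_sample$sentence)
  k <- sum(tags$label %in% c("COMPOUND", "QUANTITY", "DURATION",
                             "TEMPERATURE"))
  n_draw <- 2000L
  set.seed(123)
  total <- 0L
  for (i in seq_len(n_draw)) {
    total <- total + augment_sample(ref_sample, pools,
                                    p = 0.5)$n_substituted
  }
  n_ent <- n_draw * k
  rate <- total / n_ent
  se <- sqrt(0.5 * 0.5 / n_ent)
  expect_lt(abs(rate - 0.5), 3 * se)
})

test_that("corpus augmentation reaches the target size; dedup may shrink it", {
  pools <- generate_pools(seed = 5)
  corp <- generate_corpus(generator_config(n_samples = 20, seed = 6))
  out <- augment_corpus(corp, pools, p = 0.5, n_target = 100, seed = 8)
  expect_equal(nrow(out), 100L)
  expect_equal(sum(out$source == "original"), 20L)
  ded <- augment_corpus(corp, pools, p = 0.5, n_target = 100, dedup = TRUE,
                        seed = 8)
  expect_lte(nrow(ded), 100L)
  expect_equal(anyDuplicated(paste(ded$sentence, ded$actions)), 0L)
  # n_target == n, p = 0: identity corpus
  ident <- augment_corpus(corp, pools, p = 0, n_target = nrow(corp),
                          seed = 9)
  expect_equal(ident$sentence, corp$sentence)
  # an empty pool for a needed label errors
  broken <- pools
  broken$durations <- character()
  expect_error(augment_sample(list(sentence = "stirred for 2 h",
                                   actions = "Stir for 2 h"),
                              broken, p = 1, seed = 1),
               "empty substitution pool")
})
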