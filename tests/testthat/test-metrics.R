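test_that("validity counts parseable strings", {
  expect_equal(validity(c("Concentrate", "garbage!!")), 0.5)
  set.seed(21)
  canon <- vapply(replicate(50, random_valid_sequence(),
                            simplify = FALSE),
                  serialize_actions, "")
  expect_equal(validity(canon), 1.0)
  # mixed set equals an independent per-string loop
  mixed <- c(canon, replicate(50, random_noise_string()))
  oracle <- mean(vapply(mixed, function(s) {
    !inherits(parse_actions(s), "action_parse_error")
  }, TRUE))
  expect_equal(validity(mixed), oracle)
})

test_that("levenshtein similarity matches the DP oracle on random pairs", {
  expect_equal(levenshtein_similarity("abc", "abc"), 1)
  expect_equal(levenshtein_similarity("abc", "abd"), 2 / 3)
  expect_equal(levenshtein_similarity("", "abc"), 0)
  expect_equal(levenshtein_similarity("", ""), 1)
  set.seed(33)
  alphabet <- c(letters[1:6], " ", "(", ")")
  for (i in 1:300) {
    a <- paste(sample(alphabet, sample(0:25, 1), TRUE), collapse = "")
    b <- paste(sample(alphabet, sample(0:25, 1), TRUE), collapse = "")
    mx <- max(nchar(a), nchar(b))
    want <- if (mx == 0) 1 else 1 - dp_levenshtein(a, b) / mx
    expect_equal(levenshtein_similarity(a, b), want, info = paste(a, b))
    # symmetry
    expect_equal(levenshtein_similarity(a, b),
                 levenshtein_similarity(b, a))
  }
})

test_that("threshold accuracies match direct counting and are ordered", {
  got <- threshold_accuracies(c(1.0, 0.95, 0.80, 0.50))
  expect_equal(unname(got), c(0.25, 0.50, 0.75))
  expect_equal(unname(threshold_accuracies(rep(1, 5))), c(1, 1, 1))
  expect_equal(unname(threshold_accuracies(rep(0, 5))), c(0, 0, 0))
  expect_error(threshold_accuracies(numeric()), "empty")
  set.seed(44)
  for (i in 1:50) {
    sims <- runif(sample(1:40, 1))
    accs <- threshold_accuracies(sims)
    expect_equal(accs[["acc100"]], sum(sims >= 1) / length(sims))
    expect_equal(accs[["acc90"]], sum(sims >= 0.9) / length(sims))
    expect_equal(accs[["acc75"]], sum(sims >= 0.75) / length(sims))
    expect_true(accs[["acc100"]] <= accs[["acc90"]])
    expect_true(accs[["acc90"]] <= accs[["acc75"]])
  }
})

test_that("adapted BLEU handles identical, short and disjoint corpora", {
  ref <- c("Filter keep filtrate; Concentrate",
           "Add water to the mixture now")
  expect_equal(adapted_bleu(ref, ref), 1.0)
  # a single-word exact pair scores 1, not 0 as under strict 4-gram BLEU
  expect_equal(adapted_bleu("Concentrate", "Concentrate"), 1.0)
  expect_equal(adapted_bleu("alpha beta", "gamma delta"), 0)
  expect_error(adapted_bleu(c("a", "b"), "a"), "length")
})

test_that("adapted BLEU equals standard BLEU when all pairs have >= 4 words", {
  set.seed(55)
  vocabs <- c("add", "water", "stir", "for", "2", "h", "at", "0", "mix",
              "filter", "keep", "filtrate", "wash", "with", "brine")
  for (i in 1:25) {
    n_pairs <- sample(2:6, 1)
    preds <- refs <- character(n_pairs)
    for (k in seq_len(n_pairs)) {
      refs[k] <- paste(sample(vocabs, sample(4:9, 1), TRUE), collapse = " ")
      preds[k] <- if (runif(1) < 0.4) refs[k] else
        paste(sample(vocabs, sample(4:9, 1), TRUE), collapse = " ")
    }
    expect_equal(adapted_bleu(preds, refs), reference_bleu4(preds, refs),
                 tolerance = 1e-12)
  }
})

test_that("the confusion ledger aligns, counts and conserves", {
  # identical sequences: everything is a full match
  seqs <- c("Add water; Stir for 2 h", "Concentrate")
  led <- confusion_ledger(seqs, seqs)
  expect_equal(led$table["Add", "full_match"], 1L)
  expect_equal(led$table["Stir", "full_match"], 1L)
  expect_equal(led$table["Concentrate", "full_match"], 1L)
  expect_equal(sum(led$substitutions), 0L)

  # a missing action is only in the ground truth
  led2 <- confusion_ledger("Add water", "Add water; Stir for 2 h")
  expect_equal(led2$table["Stir", "only_in_ground_truth"], 1L)
  expect_equal(led2$table["Add", "type_match"], 1L)

  # a type confusion is recorded as an off-diagonal substitution
  led3 <- confusion_ledger("Wait 2 h", "Stir for 2 h")
  expect_equal(led3$substitutions["Stir", "Wait"], 1L)

  # same type, different properties: type match without full match
  led4 <- confusion_ledger("Stir for 2 h", "Stir for 3 h")
  expect_equal(led4$table["Stir", "type_match"], 1L)
  expect_equal(led4$table["Stir", "full_match"], 0L)

  # unparseable predictions count as InvalidAction
  led5 <- confusion_ledger("total garbage ((", "Concentrate")
  expect_equal(led5$substitutions["Concentrate", "InvalidAction"], 1L)
})

test_that("confusion ledger conservation holds on random sequence pairs", {
  set.seed(66)
  preds <- refs <- character(40)
  for (i in 1:40) {
    preds[i] <- serialize_actions(random_valid_sequence())
    refs[i] <- serialize_actions(random_valid_sequence())
  }
  led <- confusion_ledger(preds, refs)
  expect_true(all(led$table$full_match <= led$table$type_match))
  n_ref <- sum(vapply(refs, count_actions, 0L))
  expect_equal(sum(led$table$type_match) + sum(led$substitutions) +
                 sum(led$table$only_in_ground_truth),
               n_ref)
})

test_that("action distributions equal an independent tally", {
  corp <- data.frame(sentence = c("a", "b"),
                     actions = c("Add water; Add brine", "Concentrate"),
                     stringsAsFactors = FALSE)
  dist <- action_distribution(corp)
  expect_equal(dist$type_counts[["Add"]], 2L)
  expect_equal(dist$type_counts[["Concentrate"]], 1L)
  expect_equal(dist$actions_per_sentence, c(2L, 1L))
  empty <- action_distribution(data.frame(sentence = character(),
                                          actions = character()))
  expect_length(empty$type_counts, 0L)

  big <- generate_corpus(generator_config(n_samples = 300, seed = 12))
  dist2 <- action_distribution(big)
  oracle <- table(unlist(lapply(big$actions, function(s) {
    vapply(unclass(parse_actions(s)), `[[`, "", "type")
  })))
  for (nm in names(oracle)) {
    expect_equal(dist2$type_counts[[nm]], as.integer(oracle[[nm]]))
  }
})

test_that("the metric report combines the suite with invalid conversion", {
  preds <- c("Add water", "garbage ((", "Stir for 2 h at 0 °C")
  refs <- c("Add water", "Concentrate", "Stir for 2 h at 25 °C")
  rep <- evaluate_predictions(preds, refs)
  expect_equal(rep$validity, 2 / 3)
  expect_equal(rep$acc100, 1 / 3)
  expect_true(rep$acc100 <= rep$acc90 && rep$acc90 <= rep$acc75)
  expect_true(rep$bleu > 0 && rep$bleu < 1)
  out <- capture.output(print(rep))
  expect_true(any(grepl("validity", out)))
})
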