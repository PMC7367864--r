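tiny_corpus <- function(n = 300, seed = 31) {
  generate_corpus(generator_config(n_samples = n, seed = seed))
}

test_that("subword vocabulary round-trips every training sentence", {
  corp <- tiny_corpus(120)
  v <- build_vocabulary(c(corp$sentence, corp$actions), vocab_size = 400)
  expect_s3_class(v, "subword_vocab")
  expect_lte(v$size, 400)
  for (s in head(corp$sentence, 40)) {
    toks <- encode_subwords(v, s)
    expect_true(all(toks %in% v$tokens))
    expect_equal(decode_subwords(v, toks),
                 paste(strsplit(trimws(s), "\\s+")[[1L]], collapse = " "))
  }
})

test_that("vocabulary building is deterministic and guards its size", {
  corp <- tiny_corpus(60)
  v1 <- build_vocabulary(corp$sentence, vocab_size = 200)
  v2 <- build_vocabulary(corp$sentence, vocab_size = 200)
  expect_identical(v1, v2)
  expect_error(build_vocabulary(corp$sentence, vocab_size = 5),
               "alphabet")
})

test_that("pretraining is seed-deterministic and requires data", {
  corp <- tiny_corpus(150)
  cfg <- desk_config(train_steps = 300, vocab_size = 200)
  m1 <- pretrain(corp, cfg)
  m2 <- pretrain(corp, cfg)
  probe <- tiny_corpus(40, seed = 77)$sentence
  expect_identical(predict(m1, probe), predict(m2, probe))
  expect_error(pretrain(corp[0, ], cfg), "empty")
})

test_that("translate returns ranked deterministic n-best candidates", {
  corp <- tiny_corpus(200)
  m <- pretrain(corp, desk_config(train_steps = 400, vocab_size = 200))
  s <- corp$sentence[1:5]
  r1 <- translate(m, s, beam_size = 10, n_best = 3)
  r2 <- translate(m, s, beam_size = 10, n_best = 3)
  expect_identical(r1, r2)
  expect_true(all(r1$rank >= 1 & r1$rank <= 3))
  for (i in unique(r1$sentence_index)) {
    sc <- r1$score[r1$sentence_index == i]
    expect_true(all(diff(sc) <= 0))
  }
  expect_error(translate(m, s, beam_size = 2, n_best = 5))
  # unseen constructions decode to InvalidAction
  expect_equal(predict(m, "Totally novel construction frobnicates."),
               "InvalidAction")
})

test_that("models save to text and reload with identical behavior", {
  corp <- tiny_corpus(150)
  m <- pretrain(corp, desk_config(train_steps = 300, vocab_size = 200))
  path <- tempfile(fileext = ".json")
  save_seq2seq(m, path)
  m2 <- load_seq2seq(path)
  probe <- tiny_corpus(40, seed = 78)$sentence
  expect_identical(predict(m, probe), predict(m2, probe))
  expect_identical(m2$vocab$tokens, m$vocab$tokens)
})

test_that("ensembles require a shared vocabulary and decode jointly", {
  corp <- tiny_corpus(150)
  m1 <- pretrain(corp, desk_config(train_steps = 200, vocab_size = 200))
  m2 <- pretrain(corp, desk_config(train_steps = 300, vocab_size = 200))
  probe <- corp$sentence[1:10]
  out <- ensemble_translate(list(m1, m2), probe)
  expect_length(out, 10L)
  expect_identical(out, ensemble_translate(list(m1, m2), probe))
  other <- pretrain(tiny_corpus(60, seed = 99),
                    desk_config(train_steps = 100, vocab_size = 150))
  expect_error(ensemble_translate(list(m1, other), probe),
               "vocabular")
})

test_that("refinement selects the best checkpoint and improves accuracy", {
  # pretraining pairs come from rule extraction over noisy sentences, so
  # they contain InvalidAction labels the annotations correct
  noisy <- generate_corpus(generator_config(n_samples = 400, seed = 41,
                                            noise = TRUE,
                                            noise_rate = 0.35))
  rule_pairs <- data.frame(
    sentence = noisy$sentence,
    actions = vapply(noisy$sentence, function(s) {
      serialize_actions(extract_sentence(s))
    }, "", USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  annotated <- noisy  # ground truth by construction
  sp <- split_dataset(annotated, c(0.6, 0.2, 0.2), seed = 41)
  pre <- pretrain(rule_pairs, desk_config(train_steps = 400,
                                          vocab_size = 250),
                  valid = sp$valid)
  ref <- refine(pre, sp$train, valid = sp$valid, train_steps = 400,
                checkpoint_every = 100)
  acc_pre <- seq2seq_accuracy(pre, sp$test)
  acc_ref <- seq2seq_accuracy(ref, sp$test)
  expect_gte(acc_ref, acc_pre)
  expect_equal(ref$phase, "refined")
  expect_true(length(ref$checkpoints) > length(pre$checkpoints))
  accs <- vapply(ref$checkpoints, `[[`, 0, "accuracy")
  expect_true(any(!is.na(accs)))
})
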