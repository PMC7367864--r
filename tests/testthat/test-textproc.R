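test_that("sentence splitting is abbreviation-aware and deterministic", {
  expect_equal(nrow(split_sentences("")), 0L)
  two <- split_sentences("A. Then B.")
  expect_equal(two$text, c("A.", "Then B."))
  # decimal points and abbreviations do not split
  one <- split_sentences("Add conc. HCl (ca. 2.5 mL) slowly.")
  expect_equal(nrow(one), 1L)
  # mid-sentence "°C." followed by lower-case text does not split
  mid <- split_sentences(
    "A solution in EtOH at 30 °C. was treated with ethyl acetoacetate.")
  expect_equal(nrow(mid), 1L)
  # the worked example paragraph has four sentences
  para <- split_sentences(example_procedure()$procedure)
  expect_equal(nrow(para), 4L)
  expect_match(para$text[2L], "^After 30 min")
})

test_that("splitting a single sentence is the identity", {
  sents <- c("The mixture was stirred for 2 h at 0 °C.",
             "The residue was purified by column chromatography.")
  for (s in sents) {
    expect_equal(split_sentences(s)$text, s)
  }
})

test_that("splitting reconstructs the procedure modulo whitespace", {
  p <- example_procedure()$procedure
  sp <- split_sentences(p)
  expect_equal(gsub("\\s+", " ", paste(sp$text, collapse = " ")),
               normalize_text(p))
})

test_that("entity tags cover quantities, temperature, duration and pH", {
  tags <- tag_entities("acetaldehyde (4.95 mL, 88.2 mmol) at 0 °C")
  expect_equal(sum(tags$label == "QUANTITY"), 2L)
  expect_true("acetaldehyde" %in% tags$value[tags$label == "COMPOUND"])
  expect_equal(tags$value[tags$label == "TEMPERATURE"], "0 °C")

  ph <- tag_entities("After adjusting to pH 1.5 with 10% hydrochloric acid")
  expect_equal(as.numeric(ph$value[ph$label == "PH_VALUE"]), 1.5)

  expect_equal(nrow(tag_entities("xyzzy plugh")), 0L)

  dur <- tag_entities("stirred overnight under nitrogen")
  expect_true("overnight" %in% dur$value[dur$label == "DURATION"])
  expect_equal(sum(dur$label == "ATMOSPHERE"), 1L)
})

test_that("entity spans are valid half-open 0-based intervals", {
  sents <- c("acetaldehyde (4.95 mL, 88.2 mmol) at 0 °C",
             "The mixture was heated at 100–105 °C for 2 h under argon.",
             "washed with brine (2 x 50 mL) and dried over MgSO4")
  for (s in sents) {
    norm <- normalize_text(s)
    tags <- tag_entities(s)
    for (i in seq_len(nrow(tags))) {
      expect_gte(tags$start[i], 0L)
      expect_lte(tags$end[i], nchar(norm))
      expect_gt(tags$end[i], tags$start[i])
      if (tags$label[i] != "PH_VALUE") {
        expect_identical(substring(norm, tags$start[i] + 1L, tags$end[i]),
                         tags$value[i])
      }
    }
    # same-label spans must not overlap
    for (lab in unique(tags$label)) {
      tl <- tags[tags$label == lab, , drop = FALSE]
      if (nrow(tl) < 2L) next
      tl <- tl[order(tl$start), ]
      expect_true(all(tl$start[-1L] >= tl$end[-nrow(tl)]))
    }
  }
})

test_that("solution phrases produce SOLUTE_IN relations", {
  rel <- compound_relationships(
    "A solution of X1 in Z9 is added to a solution of Y2 in Z9")
  sol <- rel[rel$relation == "SOLUTE_IN", ]
  expect_equal(nrow(sol), 2L)
  expect_setequal(sol$from, c("X1", "Y2"))
  expect_true(all(sol$to == "Z9"))
})

test_that("the two add formulations resolve to the same ordered pair", {
  r1 <- compound_relationships("To X1 was added Y2")
  r2 <- compound_relationships("Y2 was added to X1")
  a1 <- r1[r1$relation == "ADDED_TO", c("from", "to")]
  a2 <- r2[r2$relation == "ADDED_TO", c("from", "to")]
  expect_equal(a1$from, "Y2")
  expect_equal(a1$to, "X1")
  expect_equal(a1, a2)
})

test_that("single-compound sentences yield no relation", {
  rel <- compound_relationships("The mixture was stirred in THF")
  expect_equal(nrow(rel[rel$relation == "ADDED_TO", ]), 0L)
})
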