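test_that("canonical surface forms match the documented grammar", {
  expect_equal(serialize_actions(action_sequence(
    action("Wait", duration = "30 min"))), "Wait 30 min")
  expect_equal(serialize_actions(action_sequence(list())), "")
  expect_equal(serialize_actions(action_sequence(
    action("Filter", keep_phase = "filtrate"), action("Concentrate"))),
    "Filter keep filtrate; Concentrate")
  expect_equal(serialize_actions(action_sequence(
    action("PH", materials = "10% hydrochloric acid", ph_value = 1.5))),
    "PH with 10% hydrochloric acid to pH 1.5")
  expect_equal(serialize_actions(action_sequence(
    action("Stir", duration = "12 h", temperature = "room temperature"))),
    "Stir for 12 h at room temperature")
  expect_equal(serialize_actions(action_sequence(
    action("Add", materials = list(chemical("DCM", "100 mL")),
           atmosphere = "nitrogen"))),
    "Add DCM (100 mL) under nitrogen")
  expect_error(serialize_actions(action_sequence(
    action("Stir", materials = "water"))), "materials")
})

test_that("parsing handles worked examples, case and trailing periods", {
  seq <- parse_actions("Quench with water; Concentrate")
  expect_false(is_parse_error(seq))
  expect_length(seq, 2L)
  expect_equal(seq[[1L]]$type, "Quench")
  expect_equal(seq[[1L]]$materials[[1L]]$name, "water")
  expect_equal(seq[[2L]]$type, "Concentrate")

  err <- parse_actions("Blorbify at 5 °C")
  expect_true(is_parse_error(err))
  expect_equal(err$clause, 1L)
  expect_equal(err$token, "Blorbify")

  # upper-case action names parse identically to capitalized ones
  a <- parse_actions("ADD DCM (100 mL) under nitrogen.")
  b <- parse_actions("Add DCM (100 mL) under nitrogen")
  expect_true(sequences_equal(a, b))
})

test_that("count_actions counts the flagship sequence and degenerate input", {
  expect_equal(count_actions(example_procedure()$reference), 16L)
  expect_equal(count_actions(""), 0L)
  expect_equal(count_actions("NoAction."), 1L)
  expect_error(count_actions("Blorbify now"), "clause 1")
})

test_that("serialize/parse are mutual inverses on random valid sequences", {
  set.seed(4711)
  for (rep in 1:1500) {
    seq <- random_valid_sequence()
    s <- serialize_actions(seq)
    back <- parse_actions(s)
    expect_false(is_parse_error(back),
                 info = paste("failed to re-parse:", s))
    expect_identical(serialize_actions(back), s)
    expect_true(sequences_equal(seq, back), info = s)
  }
})

test_that("parsing returns structured failures, never errors, on noise", {
  set.seed(1337)
  for (rep in 1:1500) {
    s <- random_noise_string()
    res <- expect_no_error(parse_actions(s))
    expect_true(is_parse_error(res) || inherits(res, "action_sequence"))
  }
})

test_that("materials with nested brackets and commas survive a round trip", {
  gnarly <- paste0(
    "MakeSolution with methyl 3-7-amino-2-[(2,4-dichlorophenyl)(hydroxy)",
    "methyl]-1H-benzimidazol-1-ylpropanoate (6.00 g, 14.7 mmol) and ",
    "acetic acid (7.4 mL) and methanol (147 mL)")
  seq <- parse_actions(gnarly)
  expect_false(is_parse_error(seq))
  expect_length(seq[[1L]]$materials, 3L)
  expect_equal(length(seq[[1L]]$materials[[1L]]$quantities), 2L)
  expect_identical(serialize_actions(seq), gnarly)
})
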