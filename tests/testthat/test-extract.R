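test_that("implicit collection precedes drying of the organic layer", {
  seq <- extract_sentence("The organic layer was dried over sodium sulfate")
  expect_equal(serialize_actions(seq),
               "CollectLayer organic; DrySolution over sodium sulfate")
})

test_that("an unnamed solution subject becomes MakeSolution + Add SLN", {
  seq <- extract_sentence(
    "23 g of aluminum chloride in 30 mL of dichloroethane was heated to 50 °C.")
  expect_equal(
    serialize_actions(seq),
    paste0("MakeSolution with aluminum chloride (23 g) and ",
           "dichloroethane (30 mL); Add SLN; SetTemperature 50 °C"))
  types <- vapply(unclass(seq), `[[`, "", "type")
  expect_equal(types, c("MakeSolution", "Add", "SetTemperature"))
})

test_that("dissolution maps to two additions with trailing conditions", {
  seq <- extract_sentence(paste0(
    "3-Bromo-2-fluoroaniline (10 g, 52.63 mmol) was dissolved in DCM ",
    "(100 mL) under nitrogen atmosphere."))
  expect_equal(serialize_actions(seq),
               paste0("Add 3-Bromo-2-fluoroaniline (10 g, 52.63 mmol); ",
                      "Add DCM (100 mL) under nitrogen"))
})

test_that("pH adjustment parses the target value and the agent", {
  seq <- extract_sentence(
    "After adjusting to pH 1.5 with 10% hydrochloric acid, the mixture was stirred.")
  ph <- Filter(function(a) a$type == "PH", unclass(seq))
  expect_length(ph, 1L)
  expect_equal(ph[[1L]]$condition$ph_value, 1.5)
  expect_equal(ph[[1L]]$materials[[1L]]$name, "10% hydrochloric acid")
})

test_that("the full work-up sentence of the worked example extracts", {
  seq <- extract_sentence(paste0(
    "After adjusting to pH 1.5 with 10% hydrochloric acid, the ethyl ",
    "acetate solution was separated, washed with a saturated aqueous ",
    "sodium chloride and then dried over anhydrous magnesium sulfate."))
  expect_equal(
    serialize_actions(seq),
    paste0("PH with 10% hydrochloric acid to pH 1.5; PhaseSeparation; ",
           "CollectLayer organic; Wash with saturated aqueous sodium ",
           "chloride; DrySolution over anhydrous magnesium sulfate"))
})

test_that("context disambiguation of heat, remove and dry", {
  expect_equal(disambiguate_verb("heat", "was heated to 50 °C."),
               "SetTemperature")
  expect_equal(disambiguate_verb("heat", "heated at 80 °C for 2 h"),
               "Stir")
  expect_equal(disambiguate_verb("heat", "heated to reflux for 2 h"),
               "Reflux")
  expect_equal(disambiguate_verb("remove", "the solvent was removed"),
               "Concentrate")
  expect_equal(disambiguate_verb("remove", "removed by filtration"),
               "Filter")
  expect_equal(disambiguate_verb("dry", "dried over MgSO4"), "DrySolution")
  expect_error(disambiguate_verb("blorbify", "whatever"),
               class = "synthactions_unsupported_verb")
})

test_that("classification gates: language, cross-reference, analytics", {
  expect_equal(serialize_actions(extract_sentence(
    "Das Gemisch wurde zwei Stunden bei Raumtemperatur geruehrt.")),
    "OtherLanguage")
  expect_equal(serialize_actions(extract_sentence(
    "The title compound was prepared as described in Example 12.")),
    "FollowOtherProcedure")
  expect_equal(serialize_actions(extract_sentence(
    "1H NMR (400 MHz, CDCl3): δ 7.25 (m, 2H), 3.80 (s, 3H).")),
    "NoAction")
  expect_equal(serialize_actions(extract_sentence(
    "The mixture was vortexed with 2-chloroaniline (5 g).")),
    "InvalidAction")
  expect_length(extract_sentence(""), 0L)
})

test_that("paraphrases of addition give identical sequences", {
  a <- extract_sentence("To the mixture was added acetaldehyde (4.95 mL).")
  b <- extract_sentence("Acetaldehyde (4.95 mL) was added to the mixture.")
  expect_equal(tolower(serialize_actions(a)),
               tolower(serialize_actions(b)))
})

test_that("implicit-action insertion grows, never shrinks, a sequence", {
  base <- action_sequence(action("DrySolution",
                                 materials = "sodium sulfate"))
  out <- insert_implicit_actions(base,
                                 "The organic layer was dried over sodium sulfate")
  expect_equal(serialize_actions(out),
               "CollectLayer organic; DrySolution over sodium sulfate")
  # explicit subject: unchanged
  same <- insert_implicit_actions(base, "The mixture was dried")
  expect_equal(length(same), length(base))
  sol <- insert_implicit_actions(
    action_sequence(action("SetTemperature", temperature = "50 °C")),
    "23 g of aluminum chloride in 30 mL of dichloroethane was heated to 50 °C.")
  expect_equal(vapply(unclass(sol), `[[`, "", "type"),
               c("MakeSolution", "Add", "SetTemperature"))
})

test_that("an unspecified filtration keeps the filtrate when followed by work-up", {
  seq <- extract_procedure(
    "The solution mixture is filtered. It is then concentrated.")
  expect_equal(serialize_actions(seq), "Filter keep filtrate; Concentrate")
  # single sentence: extract_procedure equals extract_sentence
  s <- "The reaction was quenched with water."
  expect_equal(serialize_actions(extract_procedure(s)),
               serialize_actions(extract_sentence(s)))
})

test_that("the flagship worked example reproduces the reference sequence", {
  ex <- example_procedure()
  seq <- extract_procedure(ex$procedure)
  expect_length(seq, 16L)
  expect_identical(serialize_actions(seq), ex$reference)
  res <- demo_extraction(quiet = TRUE)
  expect_true(res$exact_match)
  expect_equal(res$similarity, 1)
})

test_that("extraction is total and valid on noisy fixtures", {
  corp <- generate_corpus(generator_config(n_samples = 150, seed = 99,
                                           noise = TRUE))
  for (s in corp$sentence) {
    seq <- extract_sentence(s)
    expect_s3_class(seq, "action_sequence")
    out <- serialize_actions(seq, validate = FALSE)
    expect_false(is_parse_error(parse_actions(out)), info = s)
  }
})

test_that("the lexicon is user-extensible through a JSON config", {
  tmp <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(
    list(lyophilize = list(action = "DrySolid", handler = "dry")),
    auto_unbox = TRUE), tmp)
  lex <- default_lexicon(tmp)
  expect_equal(lex[["lyophilize"]]$action, "DrySolid")
  seq <- extract_sentence("The solid was lyophilized.", lexicon = lex)
  expect_equal(serialize_actions(seq), "DrySolid")
})
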