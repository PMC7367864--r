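test_that("the action type set is closed with four non-laboratory types", {
  types <- action_types()
  expect_length(types, 28L)
  expect_setequal(setdiff(types, action_types(laboratory_only = TRUE)),
                  c("FollowOtherProcedure", "InvalidAction",
                    "OtherLanguage", "NoAction"))
})

test_that("allowed_properties is total and matches the frozen table", {
  for (ty in action_types()) {
    expect_type(allowed_properties(ty), "character")
  }
  expect_setequal(allowed_properties("Filter"), "keep_phase")
  expect_length(allowed_properties("NoAction"), 0L)
  expect_length(allowed_properties("Concentrate"), 0L)
  expect_length(allowed_properties("PhaseSeparation"), 0L)
  expect_setequal(allowed_properties("Add"),
                  c("materials", "temperature", "atmosphere", "dropwise"))
  expect_setequal(allowed_properties("Stir"),
                  c("duration", "temperature", "atmosphere"))
  expect_setequal(allowed_properties("CollectLayer"), "keep_phase")
  expect_error(allowed_properties("Blorbify"), "unknown action type")
})

test_that("quantity kinds are inferred from the unit token", {
  expect_equal(quantity("6.00 g")$kind, "mass")
  expect_equal(quantity("4.95 mL")$kind, "volume")
  expect_equal(quantity("14.7 mmol")$kind, "amount")
  expect_equal(quantity("1 M")$kind, "concentration")
  expect_equal(quantity("2.2 equiv")$kind, "equivalents")
  expect_equal(quantity("92%")$kind, "other")
  expect_error(quantity(""))
})

test_that("validation accepts allowed properties and names violations", {
  expect_true(validate_action(action("Stir", duration = "2 h"))$ok)
  expect_true(validate_action(action("Concentrate"))$ok)
  bad <- validate_action(action("Stir", materials = "water"))
  expect_false(bad$ok)
  expect_match(bad$violations, "materials not allowed on Stir")
  # phase vocabulary is per type
  expect_true(validate_action(action("Filter",
                                     keep_phase = "precipitate"))$ok)
  expect_false(validate_action(action("Filter",
                                      keep_phase = "organic"))$ok)
  expect_true(validate_action(action("CollectLayer",
                                     keep_phase = "aqueous"))$ok)
  expect_false(validate_action(action("CollectLayer",
                                      keep_phase = "filtrate"))$ok)
  # a solution is a mixture: MakeSolution needs at least two materials
  expect_false(validate_action(action("MakeSolution",
                                      materials = "water"))$ok)
  expect_true(validate_action(
    action("MakeSolution", materials = c("water", "methanol")))$ok)
  # pH bounds
  expect_false(validate_action(action("PH", materials = "HCl",
                                      ph_value = 15))$ok)
  expect_true(validate_action(action("PH", materials = "HCl",
                                     ph_value = 1.5))$ok)
  # non-laboratory types admit nothing
  expect_false(validate_action(action("NoAction",
                                      materials = "water"))$ok)
})

test_that("every printed worked-example action validates", {
  ex <- example_procedure()
  seq <- parse_actions(ex$reference)
  expect_false(is_parse_error(seq))
  expect_true(validate_sequence(seq)$ok)
})

test_that("JSON serialization round-trips action sequences", {
  set.seed(91)
  for (rep in 1:20) {
    seq <- random_valid_sequence()
    back <- actions_from_json(actions_to_json(seq))
    expect_true(sequences_equal(seq, back))
  }
  js <- actions_to_json(action_sequence(action("Filter",
                                               keep_phase = "filtrate")))
  expect_match(as.character(js), "schema_version")
})
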