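# Schema version embedded in JSON output; bump when the allowed-property
# table changes.
ACTION_SCHEMA_VERSION <- "1.0"

# The closed set of 28 action types.  The last four are phony
# (non-laboratory) types used to flag text that carries no executable
# operation.
.ACTION_TYPES <- c(
  "Add", "CollectLayer", "Concentrate", "Degas", "DrySolid", "DrySolution",
  "Extract", "Filter", "MakeSolution", "Microwave", "Partition", "PH",
  "PhaseSeparation", "Purify", "Quench", "Recrystallize", "Reflux",
  "SetTemperature", "Sonicate", "Stir", "Triturate", "Wait", "Wash",
  "Yield", "FollowOtherProcedure", "InvalidAction", "OtherLanguage",
  "NoAction"
)

.NON_LAB_TYPES <- c("FollowOtherProcedure", "InvalidAction",
                    "OtherLanguage", "NoAction")

# Allowed-property table, one row per action type.  Reconstructed from the
# printed worked examples and frozen here as a versioned table:
#  * materials_min/materials_max bound the compound list (0/0 = none),
#  * the logical columns admit the corresponding Condition field,
#  * keep_phase lists the admissible phases ("" = property not allowed).
.ACTION_SCHEMA <- list(
  Add            = list(mmin = 1L, mmax = 1L,  duration = FALSE, temperature = TRUE,  atmosphere = TRUE,  dropwise = TRUE,  repetitions = FALSE, ph_value = FALSE, phases = character()),
  CollectLayer   = list(mmin = 0L, mmax = 0L,  duration = FALSE, temperature = FALSE, atmosphere = FALSE, dropwise = FALSE, repetitions = FALSE, ph_value = FALSE, phases = c("aqueous", "organic")),
  Concentrate    = list(mmin = 0L, mmax = 0L,  duration = FALSE, temperature = FALSE, atmosphere = FALSE, dropwise = FALSE, repetitions = FALSE, ph_value = FALSE, phases = character()),
  Degas          = list(mmin = 0L, mmax = 0L,  duration = TRUE,  temperature = FALSE, atmosphere = TRUE,  dropwise = FALSE, repetitions = FALSE, ph_value = FALSE, phases = character()),
  DrySolid       = list(mmin = 0L, mmax = 0L,  duration = TRUE,  temperature = TRUE,  atmosphere = TRUE,  dropwise = FALSE, repetitions = FALSE, ph_value = FALSE, phases = character()),
  DrySolution    = list(mmin = 1L, mmax = 1L,  duration = FALSE, temperature = FALSE, atmosphere = FALSE, dropwise = FALSE, repetitions = FALSE, ph_value = FALSE, phases = character()),
  Extract        = list(mmin = 1L, mmax = 1L,  duration = FALSE, temperature = FALSE, atmosphere = FALSE, dropwise = FALSE, repetitions = TRUE,  ph_value = FALSE, phases = character()),
  Filter         = list(mmin = 0L, mmax = 0L,  duration = FALSE, temperature = FALSE, atmosphere = FALSE, dropwise = FALSE, repetitions = FALSE, ph_value = FALSE, phases = c("filtrate", "precipitate")),
  MakeSolution   = list(mmin = 2L, mmax = 99L, duration = FALSE, temperature = FALSE, atmosphere = FALSE, dropwise = FALSE, repetitions = FALSE, ph_value = FALSE, phases = character()),
  Microwave      = list(mmin = 0L, mmax = 0L,  duration = TRUE,  temperature = TRUE,  atmosphere = FALSE, dropwise = FALSE, repetitions = FALSE, ph_value = FALSE, phases = character()),
  Partition      = list(mmin = 2L, mmax = 2L,  duration = FALSE, temperature = FALSE, atmosphere = FALSE, dropwise = FALSE, repetitions = FALSE, ph_value = FALSE, phases = character()),
  PH             = list(mmin = 1L, mmax = 1L,  duration = FALSE, temperature = TRUE,  atmosphere = FALSE, dropwise = TRUE,  repetitions = FALSE, ph_value = TRUE,  phases = character()),
  PhaseSeparation= list(mmin = 0L, mmax = 0L,  duration = FALSE, temperature = FALSE, atmosphere = FALSE, dropwise = FALSE, repetitions = FALSE, ph_value = FALSE, phases = character()),
  Purify         = list(mmin = 0L, mmax = 0L,  duration = FALSE, temperature = FALSE, atmosphere = FALSE, dropwise = FALSE, repetitions = FALSE, ph_value = FALSE, phases = character()),
  Quench         = list(mmin = 1L, mmax = 1L,  duration = FALSE, temperature = TRUE,  atmosphere = FALSE, dropwise = TRUE,  repetitions = FALSE, ph_value = FALSE, phases = character()),
  Recrystallize  = list(mmin = 1L, mmax = 2L,  duration = FALSE, temperature = FALSE, atmosphere = FALSE, dropwise = FALSE, repetitions = FALSE, ph_value = FALSE, phases = character()),
  Reflux         = list(mmin = 0L, mmax = 0L,  duration = TRUE,  temperature = FALSE, atmosphere = FALSE, dropwise = FALSE, repetitions = FALSE, ph_value = FALSE, phases = character()),
  SetTemperature = list(mmin = 0L, mmax = 0L,  duration = FALSE, temperature = TRUE,  atmosphere = FALSE, dropwise = FALSE, repetitions = FALSE, ph_value = FALSE, phases = character()),
  Sonicate       = list(mmin = 0L, mmax = 0L,  duration = TRUE,  temperature = TRUE,  atmosphere = FALSE, dropwise = FALSE, repetitions = FALSE, ph_value = FALSE, phases = character()),
  Stir           = list(mmin = 0L, mmax = 0L,  duration = TRUE,  temperature = TRUE,  atmosphere = TRUE,  dropwise = FALSE, repetitions = FALSE, ph_value = FALSE, phases = character()),
  Triturate      = list(mmin = 1L, mmax = 1L,  duration = FALSE, temperature = FALSE, atmosphere = FALSE, dropwise = FALSE, repetitions = FALSE, ph_value = FALSE, phases = character()),
  Wait           = list(mmin = 0L, mmax = 0L,  duration = TRUE,  temperature = TRUE,  atmosphere = FALSE, dropwise = FALSE, repetitions = FALSE, ph_value = FALSE, phases = character()),
  Wash           = list(mmin = 1L, mmax = 1L,  duration = FALSE, temperature = FALSE, atmosphere = FALSE, dropwise = FALSE, repetitions = TRUE,  ph_value = FALSE, phases = character()),
  Yield          = list(mmin = 1L, mmax = 1L,  duration = FALSE, temperature = FALSE, atmosphere = FALSE, dropwise = FALSE, repetitions = FALSE, ph_value = FALSE, phases = character()),
  FollowOtherProcedure = list(mmin = 0L, mmax = 0L, duration = FALSE, temperature = FALSE, atmosphere = FALSE, dropwise = FALSE, repetitions = FALSE, ph_value = FALSE, phases = character()),
  InvalidAction  = list(mmin = 0L, mmax = 0L,  duration = FALSE, temperature = FALSE, atmosphere = FALSE, dropwise = FALSE, repetitions = FALSE, ph_value = FALSE, phases = character()),
  OtherLanguage  = list(mmin = 0L, mmax = 0L,  duration = FALSE, temperature = FALSE, atmosphere = FALSE, dropwise = FALSE, repetitions = FALSE, ph_value = FALSE, phases = character()),
  NoAction       = list(mmin = 0L, mmax = 0L,  duration = FALSE, temperature = FALSE, atmosphere = FALSE, dropwise = FALSE, repetitions = FALSE, ph_value = FALSE, phases = character())
)

#' Action type vocabulary
#'
#' The closed set of 28 synthesis action types.  Twenty-four correspond to
#' laboratory operations (Add, Stir, Concentrate, ...); four are phony types
#' flagging text that is unsupported (`InvalidAction`), non-operational
#' (`NoAction`), not written in English (`OtherLanguage`) or a
#' cross-reference to a procedure described elsewhere
#' (`FollowOtherProcedure`).
#'
#' @param laboratory_only if `TRUE`, drop the four non-laboratory types.
#' @return character vector of action type names.
#' @export
#' @examples
#' action_types()
#' setdiff(action_types(), action_types(laboratory_only = TRUE))
action_types <- function(laboratory_only = FALSE) {
  if (laboratory_only) setdiff(.ACTION_TYPES, .NON_LAB_TYPES) else .ACTION_TYPES
}

#' Allowed properties of an action type
#'
#' Each action type admits a fixed set of properties; everything else is a
#' validation violation.  For example `Stir` admits only a duration, a
#' temperature and an atmosphere, `Filter` admits only the phase to keep
#' (filtrate or precipitate), and `Concentrate` admits nothing.
#'
#' @param type an action type name (see [action_types()]).
#' @return character vector of allowed property names, possibly empty.
#'   Materials slots are reported as `"materials"`.
#' @export
#' @examples
#' allowed_properties("Filter")
#' allowed_properties("NoAction")
allowed_properties <- function(type) {
  sch <- .ACTION_SCHEMA[[match_action_type(type)]]
  out <- character()
  if (sch$mmax > 0L) out <- c(out, "materials")
  for (f in c("duration", "temperature", "atmosphere", "dropwise",
              "repetitions", "ph_value")) {
    if (isTRUE(sch[[f]])) out <- c(out, f)
  }
  if (length(sch$phases)) out <- c(out, "keep_phase")
  out
}

# Case-insensitive resolution of a type name to its canonical spelling;
# errors on anything outside the closed set (schema mismatch).
match_action_type <- function(type) {
  stopifnot(is.character(type), length(type) == 1L)
  i <- match(tolower(type), tolower(.ACTION_TYPES))
  if (is.na(i)) {
    stop("unknown action type: '", type, "' (schema version ",
         ACTION_SCHEMA_VERSION, ")", call. = FALSE)
  }
  .ACTION_TYPES[[i]]
}

#' Quantity attached to a chemical mention
#'
#' Quantities are kept as the raw text printed in the procedure (e.g.
#' `"6.00 g"`); only their kind is inferred from the unit token.
#'
#' @param raw non-empty quantity string.
#' @return an object of class `synth_quantity` with fields `raw` and `kind`
#'   (one of mass, volume, amount, concentration, equivalents, other).
#' @export
#' @examples
#' quantity("14.7 mmol")$kind
quantity <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(trimws(raw)))
  raw <- trimws(raw)
  structure(list(raw = raw, kind = quantity_kind(raw)),
            class = "synth_quantity")
}

quantity_kind <- function(raw) {
  unit <- regmatches(raw, regexpr("[A-Za-zμ%]+\\.?$", raw))
  if (!length(unit)) return("other")
  switch(tolower(unit),
    "g" = , "mg" = , "kg" = , "μg" = , "ug" = "mass",
    "ml" = , "l" = , "μl" = , "ul" = "volume",
    "mol" = , "mmol" = , "μmol" = , "umol" = "amount",
    "m" = , "n" = "concentration",
    "equiv" = , "eq" = , "equivalents" = "equivalents",
    "other")
}

#' Chemical mention
#'
#' A compound name with its raw quantity strings and (optionally) the
#' grammatical role it plays in the sentence.  The reserved name `"SLN"`
#' refers to the product of the most recent `MakeSolution` action.
#'
#' @param name non-empty compound name.
#' @param quantities character vector of raw quantity strings, or a list of
#'   [quantity()] objects.
#' @param role one of subject, direct_object, oblique, solvent, unknown.
#' @return an object of class `chemical_mention`.
#' @export
#' @examples
#' chemical("acetaldehyde", c("4.95 mL", "88.2 mmol"))
chemical <- function(name, quantities = character(), role = "unknown") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(trimws(name)))
  role <- match.arg(role,
                    c("unknown", "subject", "direct_object", "oblique",
                      "solvent"))
  if (is.character(quantities)) quantities <- lapply(quantities, quantity)
  stopifnot(all(vapply(quantities, inherits, TRUE, "synth_quantity")))
  structure(list(name = trimws(name), quantities = quantities, role = role),
            class = "chemical_mention")
}

#' Construct a synthesis action
#'
#' Builds one structured synthesis step: an action type plus its typed
#' properties.  Construction does not enforce the allowed-property table;
#' use [validate_action()] for that, so that malformed actions remain
#' representable data rather than exceptions.
#'
#' @param type action type name (case-insensitive).
#' @param materials list of [chemical()] mentions (a character vector of
#'   names is accepted and upgraded).
#' @param duration,temperature,atmosphere raw condition text, or `NULL`.
#' @param ph_value numeric pH, or `NULL`.
#' @param dropwise logical flag, or `NULL`.
#' @param repetitions positive integer, or `NULL`.
#' @param keep_phase one of filtrate, precipitate, aqueous, organic, or
#'   `NULL`.
#' @return an object of class `synth_action`.
#' @export
#' @examples
#' action("Stir", duration = "2 h", temperature = "0 °C")
#' action("Filter", keep_phase = "filtrate")
action <- function(type, materials = list(), duration = NULL,
                   temperature = NULL, atmosphere = NULL, ph_value = NULL,
                   dropwise = NULL, repetitions = NULL, keep_phase = NULL) {
  type <- match_action_type(type)
  if (is.character(materials)) materials <- lapply(materials, chemical)
  stopifnot(is.list(materials),
            all(vapply(materials, inherits, TRUE, "chemical_mention")))
  if (!is.null(repetitions)) {
    repetitions <- as.integer(repetitions)
    stopifnot(length(repetitions) == 1L, !is.na(repetitions),
              repetitions >= 1L)
  }
  if (!is.null(ph_value)) {
    ph_value <- as.numeric(ph_value)
    stopifnot(length(ph_value) == 1L, !is.na(ph_value))
  }
  chr1 <- function(x) {
    if (is.null(x)) return(NULL)
    stopifnot(is.character(x), length(x) == 1L, nzchar(trimws(x)))
    trimws(x)
  }
  structure(list(
    type = type,
    materials = materials,
    condition = list(duration = chr1(duration),
                     temperature = chr1(temperature),
                     atmosphere = chr1(atmosphere),
                     ph_value = ph_value,
                     dropwise = if (is.null(dropwise)) NULL else isTRUE(dropwise),
                     repetitions = repetitions),
    keep_phase = chr1(keep_phase)
  ), class = "synth_action")
}

#' Ordered sequence of synthesis actions
#'
#' @param ... `synth_action` objects, or a single list of them.
#' @return an object of class `action_sequence` (a list of actions, possibly
#'   empty, order preserved).
#' @export
#' @examples
#' action_sequence(action("Filter", keep_phase = "filtrate"),
#'                 action("Concentrate"))
action_sequence <- function(...) {
  acts <- list(...)
  if (length(acts) == 1L && is.list(acts[[1L]]) &&
      !inherits(acts[[1L]], "synth_action")) {
    acts <- acts[[1L]]
  }
  stopifnot(all(vapply(acts, inherits, TRUE, "synth_action")))
  structure(acts, class = "action_sequence")
}

#' @export
c.action_sequence <- function(...) {
  parts <- lapply(list(...), function(x) {
    if (inherits(x, "action_sequence")) unclass(x)
    else if (inherits(x, "synth_action")) list(x)
    else if (is.list(x)) x
    else stop("cannot concatenate into an action sequence")
  })
  action_sequence(do.call(c, parts))
}

#' @export
`[.action_sequence` <- function(x, i) action_sequence(unclass(x)[i])

#' Validate an action against the allowed-property table
#'
#' Checks that every populated field of the action is admissible for its
#' type.  Violations are returned as data, never thrown: a syntactically
#' representable but schema-breaking action is a normal occurrence when
#' parsing model predictions.
#'
#' @param act a [action()] object.
#' @return list with `ok` (logical) and `violations` (character vector, one
#'   human-readable entry per disallowed populated field; empty when `ok`).
#' @export
#' @examples
#' validate_action(action("Stir", duration = "2 h"))$ok
#' validate_action(action("Stir", materials = "water"))$violations
validate_action <- function(act) {
  stopifnot(inherits(act, "synth_action"))
  sch <- .ACTION_SCHEMA[[act$type]]
  v <- character()
  nm <- length(act$materials)
  if (nm > 0L && sch$mmax == 0L) {
    v <- c(v, paste0("materials not allowed on ", act$type))
  } else if (nm > sch$mmax) {
    v <- c(v, paste0(act$type, " admits at most ", sch$mmax,
                     " material(s), got ", nm))
  } else if (nm < sch$mmin &&
             (nm > 0L || act$type %in% c("MakeSolution", "Partition"))) {
    # a mixture needs its parts; for other types materials are optional
    v <- c(v, paste0(act$type, " requires at least ", sch$mmin,
                     " material(s), got ", nm))
  }
  for (f in c("duration", "temperature", "atmosphere", "dropwise",
              "repetitions")) {
    if (!is.null(act$condition[[f]]) && !isTRUE(sch[[f]]) &&
        !(f == "dropwise" && identical(act$condition$dropwise, FALSE))) {
      v <- c(v, paste0(f, " not allowed on ", act$type))
    }
  }
  if (!is.null(act$condition$ph_value)) {
    if (!isTRUE(sch$ph_value)) {
      v <- c(v, paste0("ph_value not allowed on ", act$type))
    } else if (act$condition$ph_value < 0 || act$condition$ph_value > 14) {
      v <- c(v, paste0("ph_value out of [0, 14]: ", act$condition$ph_value))
    }
  }
  if (!is.null(act$keep_phase)) {
    if (!length(sch$phases)) {
      v <- c(v, paste0("keep_phase not allowed on ", act$type))
    } else if (!act$keep_phase %in% sch$phases) {
      v <- c(v, paste0("keep_phase '", act$keep_phase, "' not in {",
                       paste(sch$phases, collapse = ", "), "} for ",
                       act$type))
    }
  }
  list(ok = length(v) == 0L, violations = v)
}

#' Validate every action of a sequence
#'
#' @param seq an [action_sequence()].
#' @return list with `ok` and per-action `violations` (named by position).
#' @export
validate_sequence <- function(seq) {
  stopifnot(inherits(seq, "action_sequence"))
  res <- lapply(seq, validate_action)
  bad <- which(!vapply(res, `[[`, TRUE, "ok"))
  list(ok = length(bad) == 0L,
       violations = stats::setNames(lapply(res[bad], `[[`, "violations"),
                                    bad))
}

#' @export
print.synth_action <- function(x, ...) {
  cat(serialize_actions(action_sequence(x), validate = FALSE), "\n")
  invisible(x)
}

#' @export
print.action_sequence <- function(x, ...) {
  if (!length(x)) {
    cat("<empty action sequence>\n")
    return(invisible(x))
  }
  txt <- vapply(seq_along(x), function(i) {
    serialize_actions(x[i], validate = FALSE)
  }, "")
  cat(sprintf("%2d  %s", seq_along(x), txt), sep = "\n")
  invisible(x)
}

#' @export
format.action_sequence <- function(x, ...) serialize_actions(x, validate = FALSE)

# ---- JSON serialization ----------------------------------------------------

action_to_list <- function(act) {
  cond <- Filter(Negate(is.null), act$condition)
  list(
    type = act$type,
    materials = lapply(act$materials, function(m) {
      list(name = m$name,
           quantities = lapply(m$quantities,
                               function(q) list(raw = q$raw, kind = q$kind)),
           role = m$role)
    }),
    condition = cond,
    keep_phase = act$keep_phase
  )
}

action_from_list <- function(x) {
  mats <- lapply(x$materials, function(m) {
    chemical(m$name,
             quantities = lapply(m$quantities, function(q) quantity(q$raw)),
             role = if (is.null(m$role)) "unknown" else m$role)
  })
  cond <- x$condition
  action(x$type, materials = mats,
         duration = cond$duration, temperature = cond$temperature,
         atmosphere = cond$atmosphere, ph_value = cond$ph_value,
         dropwise = cond$dropwise, repetitions = cond$repetitions,
         keep_phase = x$keep_phase)
}

#' JSON round-trip for action sequences
#'
#' Field names follow the type definitions (`type`, `materials`,
#' `condition`, `keep_phase`); the schema version is embedded so corpus
#' files remain auditable.
#'
#' @param seq an [action_sequence()].
#' @param json a JSON string produced by `actions_to_json()`.
#' @return `actions_to_json()` returns a JSON string; `actions_from_json()`
#'   an [action_sequence()].
#' @export
actions_to_json <- function(seq) {
  stopifnot(inherits(seq, "action_sequence"))
  jsonlite::toJSON(list(schema_version = ACTION_SCHEMA_VERSION,
                        actions = lapply(seq, action_to_list)),
                   auto_unbox = TRUE, null = "null")
}

#' @rdname actions_to_json
#' @export
actions_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  action_sequence(lapply(x$actions, action_from_list))
}
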