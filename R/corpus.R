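# Corpus construction: adapting legacy action records, combining the two
# rule-based sources, filtering pretraining pairs, splitting, and selecting
# hard sentences for annotation.
#
# The corpus unit is a paired sample: one sentence, its serialized action
# string, and a provenance tag.  Data frames with columns
# (sentence, actions, source) are the working representation throughout.

.LEGACY_TYPE_MAP <- c(
  add = "Add", heat = "__heat__", stir = "Stir", concentrate = "Concentrate",
  evaporate = "Concentrate", wash = "Wash", dry = "DrySolution",
  filter = "Filter", yield = "Yield", reflux = "Reflux", extract = "Extract",
  quench = "Quench", purify = "Purify", recrystallize = "Recrystallize",
  wait = "Wait", degas = "Degas", partition = "Partition",
  cool = "SetTemperature", settemperature = "SetTemperature",
  makesolution = "MakeSolution", collectlayer = "CollectLayer",
  phaseseparation = "PhaseSeparation", triturate = "Triturate",
  sonicate = "Sonicate", microwave = "Microwave", drysolid = "DrySolid",
  noaction = "NoAction")

.legacy_chemicals <- function(rec) {
  lapply(rec$compounds, function(cp) {
    chemical(cp$name, quantities = unlist(cp$quantities))
  })
}

#' Adapt legacy action records to the action model
#'
#' Legacy records carry a single property set common to all action types
#' (compounds with quantities, temperature, duration, atmosphere).  Mapped
#' types keep whatever the allowed-property table admits; compounds
#' attached to a heat-like record become `Add` actions prepended to the
#' resulting `Stir` (when a duration is present) or `SetTemperature`.
#' Unmappable records become `InvalidAction`.
#'
#' @param records list of legacy records, each a list with `action_name`,
#'   `compounds` (list of `list(name=, quantities=)`) and optional
#'   `temperature`, `duration`, `atmosphere`.
#' @return an [action_sequence()].
#' @export
#' @examples
#' adapt_legacy(list(list(action_name = "Heat",
#'   compounds = list(list(name = "toluene", quantities = list("5 mL"))),
#'   temperature = "50 °C")))
adapt_legacy <- function(records) {
  acts <- list()
  for (rec in records) {
    mapped <- .LEGACY_TYPE_MAP[tolower(rec$action_name)]
    if (is.na(mapped)) {
      acts <- c(acts, list(action("InvalidAction")))
      next
    }
    chems <- .legacy_chemicals(rec)
    if (mapped == "__heat__") {
      acts <- c(acts, lapply(chems, function(m) action("Add", list(m))))
      main <- if (!is.null(rec$duration)) {
        action("Stir", duration = rec$duration,
               temperature = rec$temperature,
               atmosphere = rec$atmosphere)
      } else {
        action("SetTemperature", temperature = rec$temperature)
      }
      acts <- c(acts, list(main))
      next
    }
    allowed <- allowed_properties(mapped)
    sch <- .ACTION_SCHEMA[[mapped]]
    use <- if ("materials" %in% allowed) {
      utils::head(chems, sch$mmax)
    } else {
      list()
    }
    surplus <- if ("materials" %in% allowed) {
      chems[seq_along(chems) > sch$mmax]
    } else {
      chems
    }
    acts <- c(acts, lapply(surplus, function(m) action("Add", list(m))))
    a <- tryCatch(
      action(mapped, materials = use,
             duration = if ("duration" %in% allowed) rec$duration,
             temperature = if ("temperature" %in% allowed) rec$temperature,
             atmosphere = if ("atmosphere" %in% allowed) rec$atmosphere),
      error = function(e) action("InvalidAction"))
    if (!validate_action(a)$ok) a <- action("InvalidAction")
    acts <- c(acts, list(a))
  }
  action_sequence(acts)
}

#' Combine the two rule-based extraction sources
#'
#' The sentence-level combination keeps the NLP-extracted sequence and
#' appends `Yield` actions from the legacy extraction (legacy extraction is
#' better at yields); Yields already present are not duplicated, and
#' nothing else is merged.
#'
#' @param nlp_seq [action_sequence()] from [extract_sentence()].
#' @param legacy_seq [action_sequence()] from [adapt_legacy()] on the same
#'   sentence.
#' @return an [action_sequence()] with `nlp_seq` as a prefix.
#' @export
combine_sources <- function(nlp_seq, legacy_seq) {
  stopifnot(inherits(nlp_seq, "action_sequence"),
            inherits(legacy_seq, "action_sequence"))
  have <- vapply(unclass(nlp_seq), function(a) {
    if (a$type == "Yield") serialize_actions(action_sequence(a),
                                             validate = FALSE) else ""
  }, "")
  extra <- Filter(function(a) {
    a$type == "Yield" &&
      !serialize_actions(action_sequence(a), validate = FALSE) %in% have
  }, unclass(legacy_seq))
  action_sequence(c(unclass(nlp_seq), extra))
}

.CORPUS_ANALYSIS_KEYWORDS <- c(
  "NMR", "MS", "HPLC", "LCMS", "m/z", "δ", "Hz", "IR", "mp", "m.p.",
  "anal", "calcd", "found")

.sentence_has_analysis_keyword <- function(s) {
  toks <- strsplit(s, "[^A-Za-z0-9./δ']+")[[1L]]
  any(tolower(.CORPUS_ANALYSIS_KEYWORDS) %in% tolower(toks)) ||
    grepl("m/z|m\\.p\\.", s)
}

#' Filter pairs for pretraining
#'
#' Removes biased automatic annotations before pretraining: samples whose
#' sequence contains `InvalidAction`; `NoAction` samples whose sentence
#' exceeds 30 characters and contains no compound-analysis keyword; then
#' duplicate sentences (whitespace-normalized exact match, first kept).
#' Idempotent; never increases the sample count.
#'
#' @param samples data.frame with columns `sentence`, `actions`.
#' @return the filtered data.frame.
#' @export
filter_pretraining <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("sentence", "actions") %in% names(samples)))
  if (!nrow(samples)) return(samples)
  has_invalid <- grepl("\\bInvalidAction\\b", samples$actions)
  keep <- !has_invalid
  is_noaction <- grepl("\\bNoAction\\b", samples$actions)
  too_long <- nchar(samples$sentence) > 30L
  no_kw <- !vapply(samples$sentence, .sentence_has_analysis_keyword, TRUE,
                   USE.NAMES = FALSE)
  keep <- keep & !(is_noaction & too_long & no_kw)
  out <- samples[keep, , drop = FALSE]
  norm <- gsub("\\s+", " ", trimws(out$sentence))
  out <- out[!duplicated(norm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split a corpus into train / validation / test sets
#'
#' Sentence-level, disjoint, exhaustive and seed-reproducible.
#'
#' @param samples data.frame of paired samples.
#' @param fractions length-3 non-negative numeric summing to 1.
#' @param seed integer seed.
#' @return named list `train`, `valid`, `test` of data.frames.
#' @export
#' @examples
#' sp <- split_dataset(generate_corpus(generator_config(100, seed = 1)),
#'                     c(0.8, 0.1, 0.1), seed = 7)
#' vapply(sp, nrow, 0L)
split_dataset <- function(samples, fractions = c(0.785, 0.107, 0.108),
                          seed = 1L) {
  stopifnot(is.data.frame(samples), length(fractions) == 3L,
            all(fractions >= 0), abs(sum(fractions) - 1) < 1e-8)
  n <- nrow(samples)
  if (!n) return(list(train = samples, valid = samples, test = samples))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  n_train <- round(fractions[1L] * n)
  n_valid <- round((fractions[1L] + fractions[2L]) * n) - n_train
  idx <- list(train = perm[seq_len(n_train)],
              valid = perm[n_train + seq_len(n_valid)],
              test = perm[seq_len(n - n_train - n_valid) + n_train + n_valid])
  lapply(idx, function(i) {
    out <- samples[sort(i), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

.CONTEXT_VERB_RE <- paste0(
  "\\b(heat(ed|ing|s)?|remov(e|ed|ing|es)|treat(ed|ing|s)?|",
  "warm(ed|ing|s)?|cool(ed|ing|s)?)\\b")

#' Select hard sentences for manual annotation
#'
#' Flags the sentences that rule-based extraction usually struggles with:
#' those containing highly context-dependent verbs (heat, remove, treat,
#' warm, cool), the literal phrase "followed by", or extractions where one
#' compound name occurs in multiple actions.
#'
#' @param samples data.frame with columns `sentence`, `actions` (the
#'   rule-based extractions).
#' @return the selected rows, with a `reason` column.
#' @export
select_hard_sentences <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("sentence", "actions") %in% names(samples)))
  if (!nrow(samples)) {
    samples$reason <- character(0)
    return(samples)
  }
  reasons <- character(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    r <- character()
    if (grepl(.CONTEXT_VERB_RE, tolower(samples$sentence[i]))) {
      r <- c(r, "context_verb")
    }
    if (grepl("followed by", samples$sentence[i], fixed = TRUE)) {
      r <- c(r, "followed_by")
    }
    seq <- parse_actions(samples$actions[i])
    if (!is_parse_error(seq)) {
      nms <- unlist(lapply(unclass(seq), function(a) {
        vapply(a$materials, `[[`, "", "name")
      }))
      nms <- nms[nms != "SLN"]
      if (length(nms) && any(table(nms) > 1L)) {
        r <- c(r, "repeated_compound")
      }
    }
    reasons[i] <- paste(r, collapse = "+")
  }
  out <- samples[nzchar(reasons), , drop = FALSE]
  out$reason <- reasons[nzchar(reasons)]
  rownames(out) <- NULL
  out
}

# ---- corpus I/O ------------------------------------------------------------

#' Read and write paired corpora
#'
#' TSV files carry one `sentence TAB action-string` pair per line (no
#' header); JSONL files carry one JSON object per line with fields
#' `sentence`, `actions` and optional `source`.
#'
#' @param samples data.frame with columns `sentence`, `actions` and
#'   optionally `source`.
#' @param path file path.
#' @return readers return a data.frame; writers return `path` invisibly.
#' @export
write_corpus_tsv <- function(samples, path) {
  stopifnot(all(c("sentence", "actions") %in% names(samples)))
  lines <- paste(gsub("\t", " ", samples$sentence),
                 gsub("\t", " ", samples$actions), sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus_tsv
#' @export
read_corpus_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) {
    return(data.frame(sentence = character(), actions = character(),
                      source = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(sentence = vapply(parts, `[`, "", 1L),
             actions = vapply(parts, function(p) {
               if (length(p) > 1L) p[[2L]] else ""
             }, ""),
             source = "file", stringsAsFactors = FALSE)
}

#' @rdname write_corpus_tsv
#' @export
write_corpus_jsonl <- function(samples, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(samples))) {
    rec <- list(sentence = samples$sentence[i], actions = samples$actions[i])
    if ("source" %in% names(samples)) rec$source <- samples$source[i]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_corpus_tsv
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  data.frame(
    sentence = vapply(recs, `[[`, "", "sentence"),
    actions = vapply(recs, `[[`, "", "actions"),
    source = vapply(recs, function(r) {
      if (is.null(r$source)) "file" else r$source
    }, ""),
    stringsAsFactors = FALSE)
}

#' Read legacy action records from JSONL
#'
#' One JSON object per line, each with `sentence` and `actions` (a list of
#' legacy records as consumed by [adapt_legacy()]).  This documented format
#' is the package's own; it replaces a proprietary reaction-database
#' format.
#'
#' @param path file path.
#' @return list of `list(sentence=, records=)` entries.
#' @export
read_legacy_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    list(sentence = x$sentence, records = x$actions)
  })
}
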