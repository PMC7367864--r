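# Rule-based extraction of action sequences from procedure sentences.
#
# The extractor finds operation verbs from a lexicon, carves the sentence
# into per-verb argument windows, analyzes each verb's local subject, and
# maps (verb, subject, window) to actions through per-family handlers.
# Implicit actions (MakeSolution + "Add SLN" for solution-phrase subjects,
# CollectLayer for layer subjects, Wait for "After <duration>" openers) are
# inserted where the text leaves them unstated.  Every sentence yields a
# sequence — unknown-but-relevant text degrades to InvalidAction, never to
# an error — and every emitted action passes validation, so serialized
# extractor output always re-parses (validity is 100% by construction).

# ---- verb lexicon ----------------------------------------------------------

.verb_forms <- function(lemma, extra = character()) {
  forms <- c(lemma, extra)
  if (grepl("e$", lemma)) {
    forms <- c(forms, paste0(lemma, "d"), paste0(lemma, "s"),
               paste0(sub("e$", "", lemma), "ing"))
  } else if (grepl("[^aeiou]y$", lemma)) {
    stem <- sub("y$", "", lemma)
    forms <- c(forms, paste0(stem, "ied"), paste0(stem, "ies"),
               paste0(lemma, "ing"))
  } else {
    forms <- c(forms, paste0(lemma, "ed"), paste0(lemma, "s"),
               paste0(lemma, "ing"))
  }
  unique(forms)
}

.LEXICON_SEED <- list(
  # lemma = c(default action, handler, extra irregular forms...)
  add         = c("Add", "add"),
  combine     = c("Add", "add"),
  charge      = c("Add", "add"),
  pour        = c("Add", "add"),
  treat       = c("Add", "add"),
  dilute      = c("Add", "add"),
  place       = c("Add", "add"),
  introduce   = c("Add", "add"),
  mix         = c("Add", "add"),
  dissolve    = c("Add", "dissolve"),
  suspend     = c("Add", "dissolve"),
  quench      = c("Quench", "quench"),
  wash        = c("Wash", "wash"),
  dry         = c("DrySolution", "dry"),
  filter      = c("Filter", "filter"),
  collect     = c("CollectLayer", "collect"),
  concentrate = c("Concentrate", "concentrate"),
  evaporate   = c("Concentrate", "concentrate"),
  distill     = c("Concentrate", "concentrate"),
  remove      = c("Concentrate", "remove"),
  purify      = c("Purify", "purify"),
  recrystallize = c("Recrystallize", "recrystallize"),
  crystallize = c("Recrystallize", "recrystallize"),
  reflux      = c("Reflux", "reflux"),
  stir        = c("Stir", "stir", "stirred", "stirring"),
  agitate     = c("Stir", "stir"),
  heat        = c("SetTemperature", "heat"),
  warm        = c("SetTemperature", "heat"),
  cool        = c("SetTemperature", "cool"),
  triturate   = c("Triturate", "triturate"),
  sonicate    = c("Sonicate", "sonicate"),
  degas       = c("Degas", "degas", "degassed", "degasses", "degassing"),
  purge       = c("Degas", "degas"),
  bubble      = c("Degas", "degas"),
  microwave   = c("Microwave", "microwave"),
  partition   = c("Partition", "partition"),
  extract     = c("Extract", "extract"),
  separate    = c("PhaseSeparation", "separate"),
  stand       = c("Wait", "wait", "stood"),
  age         = c("Wait", "wait"),
  give        = c("Yield", "yield", "gave", "given"),
  afford      = c("Yield", "yield"),
  obtain      = c("Yield", "yield"),
  yield       = c("Yield", "yield"),
  furnish     = c("Yield", "yield"),
  adjust      = c("PH", "ph"),
  acidify     = c("PH", "ph"),
  basify      = c("PH", "ph"),
  neutralize  = c("PH", "ph")
)

.build_lexicon <- function(seed) {
  entries <- lapply(names(seed), function(lemma) {
    spec <- seed[[lemma]]
    list(lemma = lemma, action = spec[[1L]], handler = spec[[2L]],
         forms = .verb_forms(lemma, if (length(spec) > 2L) spec[-(1:2)]
                             else character()))
  })
  names(entries) <- names(seed)
  structure(entries, class = "verb_lexicon")
}

.DEFAULT_LEXICON <- NULL  # built lazily (once) below

#' The shipped verb lexicon
#'
#' Maps operation verbs (and their inflected forms) to a default action
#' type and a context handler.  The lexicon is user-extensible: pass a JSON
#' file of `{"lemma": {"action": ..., "handler": ..., "forms": [...]}}`
#' entries to extend or override the shipped set — rules can never cover
#' every way to describe a synthesis, so extension is a first-class path.
#'
#' @param path optional JSON file with additional entries.
#' @return an object of class `verb_lexicon`.
#' @export
default_lexicon <- function(path = NULL) {
  lex <- .build_lexicon(.LEXICON_SEED)
  if (!is.null(path)) {
    extra <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    for (lemma in names(extra)) {
      e <- extra[[lemma]]
      lex[[lemma]] <- list(
        lemma = lemma,
        action = match_action_type(e$action),
        handler = if (is.null(e$handler)) "add" else e$handler,
        forms = unique(c(unlist(e$forms),
                         .verb_forms(lemma))))
    }
  }
  lex
}

#' @export
print.verb_lexicon <- function(x, ...) {
  cat("<verb lexicon>", length(x), "lemmas:",
      paste(utils::head(names(x), 12L), collapse = ", "), "...\n")
  invisible(x)
}

# ---- sentence-level classification gates -----------------------------------

.ENGLISH_MARKERS <- c(
  "the", "a", "an", "of", "to", "with", "in", "and", "was", "were", "is",
  "are", "at", "for", "then", "under", "over", "on", "by", "after",
  "before", "or", "from", "this", "it", "into", "mixture", "reaction",
  "solution", "residue", "resulting", "give", "layer", "layers"
)

.is_other_language <- function(s, lexicon) {
  words <- tolower(regmatches(s, gregexpr("[A-Za-zÀ-ÿ]{2,}", s))[[1L]])
  if (length(words) < 4L) return(FALSE)
  all_forms <- unlist(lapply(lexicon, `[[`, "forms"), use.names = FALSE)
  hits <- sum(words %in% c(.ENGLISH_MARKERS, all_forms))
  hits / length(words) < 0.1
}

.RE_FOLLOW_OTHER <- paste0(
  "as described in|according to (the )?(procedure|method|general)|",
  "prepared as in|in a manner (similar|analogous) to|",
  "(in the )?same manner as|following the (general )?procedure|",
  "analogously to|using the (procedure|method) (of|described)")

.ANALYSIS_FIXED <- c(
  "NMR", "MS ", "HPLC", "LCMS", "LC-MS", "m/z", "δ", " Hz", "MHz", "IR ",
  "(ESI", "ESI-", "m.p.", "anal.", "calcd", "calc'd", "found:",
  "elemental analysis", "melting point")
.ANALYSIS_RE <- c("\\bmp\\b", "\\bRf\\b")

.has_analysis_keyword <- function(s) {
  any(vapply(.ANALYSIS_FIXED, function(k) grepl(k, s, fixed = TRUE), TRUE)) ||
    any(vapply(.ANALYSIS_RE, function(k) grepl(k, s), TRUE))
}

# ---- verb event detection --------------------------------------------------

.find_events <- function(s, lexicon) {
  low <- .mask_nested(tolower(s))
  out <- NULL
  for (entry in lexicon) {
    for (f in entry$forms) {
      m <- gregexpr(paste0("\\b", f, "\\b"), low)[[1L]]
      if (m[1L] == -1L) next
      out <- rbind(out, data.frame(start = as.integer(m),
                                   end = as.integer(m) +
                                     attr(m, "match.length") - 1L,
                                   lemma = entry$lemma,
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    return(data.frame(start = integer(), end = integer(),
                      lemma = character(), stringsAsFactors = FALSE))
  }
  # at one position keep the longest match
  out <- out[order(out$start, -out$end), , drop = FALSE]
  out <- out[!duplicated(out$start), , drop = FALSE]
  # drop overlapping shorter matches ("stir" inside "stirring" variants)
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1L]) {
    if (out$start[i] <= out$end[i - 1L]) keep[i] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  # attributive participles ("the combined extracts"), nouns followed by a
  # copula ("the extracts were dried") and the noun "reflux" in "to/at/under
  # reflux" are not operation events
  keep <- vapply(seq_len(nrow(out)), function(i) {
    before <- substr(s, 1L, out$start[i] - 1L)
    after <- substr(s, out$end[i] + 1L, nchar(s))
    if (grepl("\\b(the|a|an)\\s+$", before, ignore.case = TRUE)) return(FALSE)
    if (grepl("^\\s+(was|were|is|are)\\b", after)) return(FALSE)
    if (out$lemma[i] == "reflux" &&
        grepl("\\b(to|at|under)\\s+$", before, ignore.case = TRUE)) {
      return(FALSE)
    }
    TRUE
  }, TRUE)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- chunk utilities -------------------------------------------------------

.GENERIC_CHUNK_RE <- paste0(
  "^(the |a |an )?((resulting|reaction|crude|combined|solution|cooled|",
  "cold|stirred|above|obtained|remaining|whole) )*",
  "(mixture|solution|reaction|residue|suspension|slurry|filtrate|it|",
  "this|contents|flask|product|material|oil|all)$")

.is_generic_chunk <- function(x) {
  grepl(.GENERIC_CHUNK_RE, trimws(tolower(x)))
}

# split off a trailing top-level "(...)" group that looks like quantities
.trailing_quantities <- function(item) {
  item <- trimws(item)
  quants <- character()
  if (endsWith(item, ")")) {
    depth <- .depth_map(item)
    n <- nchar(item)
    open <- which(substring(item, 1:n, 1:n) == "(" & depth == 1L)
    if (length(open)) {
      open <- open[length(open)]
      inner <- substr(item, open + 1L, n - 1L)
      if (grepl("[0-9]", inner) && !grepl("[()]", inner)) {
        quants <- trimws(strsplit(inner, ",", fixed = TRUE)[[1L]])
        item <- trimws(substr(item, 1L, open - 1L))
      }
    }
  }
  list(name = item, quantities = quants)
}

# tokens that end a material chunk (searched at top level)
# a comma belongs to a chemical name when not followed by a space ("2,6-"),
# so only comma-space/semicolon-space are clause cuts
.CHUNK_CUTS <- c(
  ", ", "; ", " and then ", " then ", " followed by ", " at ",
  " under ",
  " for ", " dropwise", " over ", " to give", " to afford", " to yield",
  " in vacuo", " maintaining", " during", " while", " whilst", " using",
  " eluting", " over a period", " portionwise", " slowly", " carefully",
  " via ", " through ", " until ", " keeping", " to provide", " to furnish",
  " overnight", " twice", " three times", " x ")

.cut_chunk <- function(txt) {
  masked <- .mask_nested(txt)
  pos <- nchar(txt) + 1L
  for (ct in .CHUNK_CUTS) {
    m <- regexpr(ct, masked, fixed = TRUE)
    if (m[1L] != -1L && m < pos) pos <- as.integer(m)
  }
  trimws(substr(txt, 1L, pos - 1L))
}

.strip_article <- function(x) {
  trimws(sub("^(the|a|an)\\s+", "", trimws(x), ignore.case = TRUE))
}

# parse free text into chemical mentions; "60 ml of X" inverts to X (60 ml)
.materials_from_text <- function(txt, multi = TRUE, keep_generic = FALSE) {
  txt <- .cut_chunk(txt)
  txt <- trimws(gsub("[.,;]+$", "", txt))
  if (!nzchar(txt)) return(list())
  items <- if (multi) .split_top_level(txt, " and ") else txt
  out <- list()
  for (item in items) {
    item <- .strip_article(gsub("[.,;]+$", "", trimws(item)))
    if (!nzchar(item) || tolower(item) %in% c("then", "it", "this")) next
    if (!keep_generic && .is_generic_chunk(item)) next
    inv <- regmatches(item, regexec(
      paste0("^((?:about )?[0-9][0-9.]*\\s?(?:kg|g|mg|mL|ml|L|mol|mmol|",
             "M|N|%|μL|uL))\\s+of\\s+(.+)$"), item))[[1L]]
    if (length(inv) == 3L) {
      out[[length(out) + 1L]] <- chemical(.strip_article(inv[3L]),
                                          quantities = inv[2L])
      next
    }
    tq <- .trailing_quantities(item)
    if (!nzchar(tq$name)) next
    out[[length(out) + 1L]] <- chemical(tq$name, quantities = tq$quantities)
  }
  out
}

.GAS_WORDS <- c("nitrogen", "argon", "hydrogen", "air", "n2", "ar", "h2",
                "co", "inert")

.window_conditions <- function(w) {
  w_norm <- normalize_text(w)
  cond <- list(duration = NULL, temperature = NULL, atmosphere = NULL,
               dropwise = FALSE, repetitions = NULL, ph_value = NULL,
               reflux = FALSE, microwave = FALSE)
  if (!nzchar(w_norm)) return(cond)
  tags <- tag_entities(w_norm)
  dur <- tags$value[tags$label == "DURATION"]
  if (length(dur)) {
    cond$duration <- sub("^(about|approximately)\\s+", "", dur[1L])
  }
  tmp <- tags$value[tags$label == "TEMPERATURE"]
  if (length(tmp)) {
    v <- tmp[1L]
    if (tolower(v) %in% c("rt", "r.t.", "r.t", "rt.")) v <- "room temperature"
    cond$temperature <- v
  }
  am <- regexpr(.RE_ATMOSPHERE, w_norm, perl = TRUE)
  if (am[1L] != -1L) {
    frag <- tolower(regmatches(w_norm, am))
    gas <- regmatches(frag, regexpr(
      paste0("(", paste(.GAS_WORDS, collapse = "|"), ")"), frag))
    if (length(gas)) {
      cond$atmosphere <- switch(gas, n2 = "nitrogen", h2 = "hydrogen",
                                ar = "argon", gas)
    }
  }
  cond$dropwise <- grepl("\\bdropwise\\b", w_norm)
  masked <- .mask_nested(w_norm)
  if (grepl("\\btwice\\b", masked)) {
    cond$repetitions <- 2L
  } else if (grepl("\\b(thrice|three times)\\b", masked)) {
    cond$repetitions <- 3L
  } else {
    rm_ <- regmatches(masked, regexec("\\b([0-9]+)\\s*(?:times|x)\\b",
                                      masked))[[1L]]
    if (length(rm_) == 2L) cond$repetitions <- as.integer(rm_[2L])
    xm <- regmatches(masked, regexec("\\bx\\s*([0-9]+)\\b", masked))[[1L]]
    if (length(xm) == 2L) cond$repetitions <- as.integer(xm[2L])
  }
  ph <- tags$value[tags$label == "PH_VALUE"]
  if (length(ph)) cond$ph_value <- as.numeric(ph[1L])
  cond$reflux <- grepl("\\b(to|at|under)\\s+reflux\\b", tolower(w_norm))
  cond$microwave <- grepl("\\bmicrowave\\b", tolower(w_norm))
  cond
}

# material chunk introduced by a preposition inside a window
.prep_chunk <- function(w, prep) {
  masked <- .mask_nested(paste0(" ", w))
  m <- regexpr(paste0(" ", prep, " "), masked, fixed = TRUE)
  if (m[1L] == -1L) return(NULL)
  substr(paste0(" ", w), as.integer(m) + nchar(prep) + 2L,
         nchar(w) + 1L)
}

# ---- subject analysis ------------------------------------------------------

.RE_LAYER <- paste0(
  "^(the |a |an )?((combined|separated|resulting) )*",
  "(organic|aqueous|water|ether(eal)?)\\s+(layer|layers|phase|phases|",
  "fraction|fractions|extract|extracts|solution)")

.analyze_subject <- function(txt) {
  txt <- trimws(sub("^To\\s+", "", trimws(txt), ignore.case = FALSE))
  txt <- trimws(gsub(",+$", "", txt))
  res <- list(kind = "generic", materials = list(), phase = NULL,
              text = txt, solid = FALSE)
  if (!nzchar(txt)) return(res)
  low <- tolower(txt)
  if (grepl(.RE_LAYER, low)) {
    res$kind <- "layer"
    res$phase <- if (grepl("aqueous|water", sub("\\s+(layer|layers|phase|phases|fraction|fractions|extract|extracts|solution).*$", "", low)))
      "aqueous" else "organic"
    return(res)
  }
  # "<solvent> solution/layer" (e.g. "the ethyl acetate solution")
  body <- .strip_article(low)
  if (grepl("(layer|solution|phase|extracts?)$", body)) {
    head <- trimws(sub("(layer|solution|phase|extracts?)$", "", body))
    if (nzchar(head) && any(tolower(.SOLVENT_DICT) == head)) {
      res$kind <- "layer"
      res$phase <- if (head %in% c("water")) "aqueous" else "organic"
      return(res)
    }
  }
  if (grepl("^(the |a |an )?(precipitate|solid|solids|crystals|filter cake|cake|crude solid)\\b", low)) {
    res$kind <- "solid"
    res$solid <- TRUE
    return(res)
  }
  if (.is_generic_chunk(txt)) return(res)
  # solution phrase: "a solution|suspension|mixture of X [and Y] in Z"
  sol <- regmatches(txt, regexec(
    "^(?:a|the)\\s+(?:solution|suspension|mixture)\\s+of\\s+(.+)$",
    txt, ignore.case = TRUE))[[1L]]
  if (length(sol) == 2L) {
    rest <- sol[2L]
    parts <- .split_top_level(rest, " in ")
    if (length(parts) >= 2L) {
      solvent <- parts[length(parts)]
      solutes <- paste(parts[-length(parts)], collapse = " in ")
      mats <- c(.materials_from_text(solutes, multi = TRUE),
                .materials_from_text(solvent, multi = FALSE))
      if (length(mats) >= 2L) {
        res$kind <- "solution"
        res$materials <- mats
        return(res)
      }
    }
    mats <- .materials_from_text(rest, multi = TRUE)
    if (length(mats)) {
      res$kind <- "compound"
      res$materials <- mats
      return(res)
    }
  }
  # bare "X (q) in Y (v)" subject: an unnamed solution
  parts <- .split_top_level(txt, " in ")
  if (length(parts) >= 2L) {
    solvent <- parts[length(parts)]
    solutes <- paste(parts[-length(parts)], collapse = " in ")
    m1 <- .materials_from_text(solutes, multi = TRUE)
    m2 <- .materials_from_text(solvent, multi = FALSE)
    if (length(m1) && length(m2)) {
      res$kind <- "solution"
      res$materials <- c(m1, m2)
      return(res)
    }
  }
  mats <- .materials_from_text(txt, multi = TRUE)
  if (length(mats)) {
    res$kind <- "compound"
    res$materials <- mats
  }
  res
}

# ---- handlers --------------------------------------------------------------

.INVALID_MARK <- structure(list(), class = "sa_invalid_marker")

.cond_action <- function(type, materials = list(), cond = NULL, ...) {
  allowed <- allowed_properties(type)
  action(type,
         materials = materials,
         duration = if ("duration" %in% allowed) cond$duration,
         temperature = if ("temperature" %in% allowed) cond$temperature,
         atmosphere = if ("atmosphere" %in% allowed) cond$atmosphere,
         dropwise = if ("dropwise" %in% allowed && isTRUE(cond$dropwise)) TRUE,
         repetitions = if ("repetitions" %in% allowed) cond$repetitions,
         ph_value = if ("ph_value" %in% allowed) cond$ph_value,
         ...)
}

.leading_materials <- function(w) {
  # window that starts directly with a material (inverted passive object)
  w <- trimws(sub("^(dropwise|slowly|carefully|portionwise)\\s+", "", w))
  if (grepl(paste0("^(to|with|in|into|onto|over|at|under|for|by|and|",
                   "then|a|an|the)\\b"), tolower(w))) {
    return(list())
  }
  .materials_from_text(w, multi = TRUE)
}

.handler_add <- function(ev, subj, w, cond, first) {
  mats <- NULL
  wm <- .prep_chunk(w, "with")
  if (!is.null(wm)) mats <- .materials_from_text(wm, multi = TRUE)
  if (!length(mats) && ev$inverted) mats <- .leading_materials(w)
  if (!length(mats) && first && subj$kind == "compound") {
    mats <- subj$materials
  }
  if (!length(mats) && first && subj$kind == "solution") {
    # subject solution already covered by the implicit MakeSolution/Add SLN
    return(list())
  }
  if (!length(mats)) return(list())
  lapply(mats, function(m) .cond_action("Add", list(m), cond))
}

.handler_dissolve <- function(ev, subj, w, cond, first) {
  mats <- if (first && subj$kind %in% c("compound", "solution")) {
    subj$materials
  } else if (ev$inverted) {
    .leading_materials(w)
  } else {
    list()
  }
  solv <- .prep_chunk(w, "in")
  smats <- if (!is.null(solv)) .materials_from_text(solv, multi = FALSE)
           else list()
  acts <- c(lapply(mats, function(m) action("Add", list(m))),
            lapply(smats, function(m) action("Add", list(m))))
  if (!length(acts)) return(list())
  # conditions attach to the last addition
  last <- acts[[length(acts)]]
  acts[[length(acts)]] <- .cond_action("Add", last$materials, cond)
  acts
}

.handler_quench <- function(ev, subj, w, cond, first) {
  wm <- .prep_chunk(w, "with")
  mats <- if (!is.null(wm)) .materials_from_text(wm, multi = TRUE) else list()
  if (length(mats) > 1L) mats <- mats[1L]
  list(.cond_action("Quench", mats, cond))
}

.handler_wash <- function(ev, subj, w, cond, first) {
  wm <- .prep_chunk(w, "with")
  mats <- if (!is.null(wm)) .materials_from_text(wm, multi = TRUE) else list()
  if (!length(mats)) return(list(.cond_action("Wash", list(), cond)))
  lapply(mats, function(m) .cond_action("Wash", list(m), cond))
}

.handler_extract <- function(ev, subj, w, cond, first) {
  wm <- .prep_chunk(w, "with")
  if (is.null(wm)) wm <- .prep_chunk(w, "into")
  mats <- if (!is.null(wm)) .materials_from_text(wm, multi = TRUE) else list()
  if (!length(mats)) return(list(.cond_action("Extract", list(), cond)))
  lapply(mats, function(m) .cond_action("Extract", list(m), cond))
}

.handler_dry <- function(ev, subj, w, cond, first) {
  om <- .prep_chunk(w, "over")
  if (is.null(om)) om <- .prep_chunk(w, "with")
  mats <- if (!is.null(om)) .materials_from_text(om, multi = FALSE) else list()
  if (length(mats)) {
    return(list(action("DrySolution", mats[1L])))
  }
  if (first && (subj$solid || subj$kind == "solid")) {
    return(list(.cond_action("DrySolid", list(), cond)))
  }
  if (first && subj$kind == "layer") return(list(action("DrySolution")))
  list(.cond_action("DrySolid", list(), cond))
}

.handler_filter <- function(ev, subj, w, cond, first) {
  phase <- NULL
  if (grepl("^\\s*off\\b", w) ||
      (first && (subj$solid || subj$kind == "solid"))) {
    phase <- "precipitate"
  }
  list(action("Filter", keep_phase = phase))
}

.handler_collect <- function(ev, subj, w, cond, first) {
  if (grepl("by\\s+(suction\\s+)?filtration", w, ignore.case = TRUE)) {
    phase <- if (first && subj$kind == "layer" &&
                 identical(subj$phase, "aqueous")) "filtrate" else "precipitate"
    return(list(action("Filter", keep_phase = phase)))
  }
  if (first && subj$kind == "layer") {
    return(list(action("CollectLayer", keep_phase = subj$phase)))
  }
  wm <- .prep_chunk(w, "of")
  if (!is.null(wm) && grepl("organic", wm, ignore.case = TRUE)) {
    return(list(action("CollectLayer", keep_phase = "organic")))
  }
  list(.INVALID_MARK)
}

.handler_concentrate <- function(ev, subj, w, cond, first) {
  list(action("Concentrate"))
}

.handler_remove <- function(ev, subj, w, cond, first) {
  ctx <- paste(subj$text, w)
  if (grepl("by\\s+(suction\\s+)?filtration|\\bfiltered\\b", ctx,
            ignore.case = TRUE)) {
    return(list(action("Filter", keep_phase = "filtrate")))
  }
  solventish <- grepl("\\bsolvents?\\b", ctx, ignore.case = TRUE) ||
    any(vapply(tolower(.SOLVENT_DICT), function(sv)
      grepl(paste0("\\b", sv, "\\b"), tolower(subj$text), fixed = FALSE),
      TRUE))
  if (solventish) return(list(action("Concentrate")))
  list(.INVALID_MARK)
}

.handler_purify <- function(ev, subj, w, cond, first) list(action("Purify"))

.handler_recrystallize <- function(ev, subj, w, cond, first) {
  fm <- .prep_chunk(w, "from")
  mats <- if (!is.null(fm)) .materials_from_text(fm, multi = TRUE) else list()
  if (length(mats) > 2L) mats <- mats[1:2]
  list(action("Recrystallize", mats))
}

.handler_reflux <- function(ev, subj, w, cond, first) {
  list(.cond_action("Reflux", list(), cond))
}

.handler_stir <- function(ev, subj, w, cond, first) {
  list(.cond_action("Stir", list(), cond))
}

.handler_heat <- function(ev, subj, w, cond, first) {
  if (cond$reflux) return(list(.cond_action("Reflux", list(), cond)))
  if (cond$microwave) return(list(.cond_action("Microwave", list(), cond)))
  if (!is.null(cond$duration)) return(list(.cond_action("Stir", list(), cond)))
  if (!is.null(cond$temperature)) {
    return(list(action("SetTemperature", temperature = cond$temperature)))
  }
  list(action("Stir"))
}

.handler_cool <- function(ev, subj, w, cond, first) {
  if (!is.null(cond$temperature)) {
    return(list(action("SetTemperature", temperature = cond$temperature)))
  }
  if (!is.null(cond$duration)) return(list(.cond_action("Wait", list(), cond)))
  list()
}

.handler_wait <- function(ev, subj, w, cond, first) {
  list(.cond_action("Wait", list(), cond))
}

.handler_triturate <- function(ev, subj, w, cond, first) {
  wm <- .prep_chunk(w, "with")
  mats <- if (!is.null(wm)) .materials_from_text(wm, multi = FALSE) else list()
  list(action("Triturate", mats))
}

.handler_sonicate <- function(ev, subj, w, cond, first) {
  list(.cond_action("Sonicate", list(), cond))
}

.handler_degas <- function(ev, subj, w, cond, first) {
  if (is.null(cond$atmosphere)) {
    wm <- .prep_chunk(w, "with")
    if (!is.null(wm)) {
      gas <- tolower(trimws(.cut_chunk(wm)))
      gas <- sub("\\s+gas$", "", gas)
      if (gas %in% .GAS_WORDS) {
        cond$atmosphere <- switch(gas, n2 = "nitrogen", h2 = "hydrogen",
                                  ar = "argon", gas)
      }
    }
  }
  list(.cond_action("Degas", list(), cond))
}

.handler_microwave <- function(ev, subj, w, cond, first) {
  list(.cond_action("Microwave", list(), cond))
}

.handler_partition <- function(ev, subj, w, cond, first) {
  bm <- .prep_chunk(w, "between")
  mats <- if (!is.null(bm)) .materials_from_text(bm, multi = TRUE) else list()
  if (length(mats) != 2L) return(list(.INVALID_MARK))
  list(action("Partition", mats))
}

.handler_separate <- function(ev, subj, w, cond, first) {
  if (first && subj$kind == "layer") {
    return(list(action("PhaseSeparation"),
                action("CollectLayer", keep_phase = subj$phase)))
  }
  list(action("PhaseSeparation"))
}

.handler_yield <- function(ev, subj, w, cond, first) {
  chunk <- if (ev$passive && first && subj$kind %in% c("compound", "generic") &&
               nzchar(subj$text)) {
    paste(subj$text, w)
  } else {
    w
  }
  chunk <- trimws(gsub("[.;]+$", "", trimws(chunk)))
  tq <- .trailing_quantities(chunk)
  name <- tq$name
  name <- .split_top_level(name, " as ")[1L]
  name <- .cut_chunk(name)
  name <- .strip_article(name)
  name <- trimws(gsub("[.,;]+$", "", name))
  if (!nzchar(name)) return(list())
  list(action("Yield", list(chemical(name, quantities = tq$quantities))))
}

.handler_ph <- function(ev, subj, w, cond, first) {
  wm <- .prep_chunk(w, "with")
  if (is.null(wm)) wm <- .prep_chunk(w, "by addition of")
  mats <- if (!is.null(wm)) .materials_from_text(wm, multi = FALSE) else list()
  if (is.null(cond$ph_value)) return(list(.INVALID_MARK))
  list(.cond_action("PH", mats, cond))
}

.HANDLERS <- list(
  add = .handler_add, dissolve = .handler_dissolve, quench = .handler_quench,
  wash = .handler_wash, extract = .handler_extract, dry = .handler_dry,
  filter = .handler_filter, collect = .handler_collect,
  concentrate = .handler_concentrate, remove = .handler_remove,
  purify = .handler_purify, recrystallize = .handler_recrystallize,
  reflux = .handler_reflux, stir = .handler_stir, heat = .handler_heat,
  cool = .handler_cool, wait = .handler_wait, triturate = .handler_triturate,
  sonicate = .handler_sonicate, degas = .handler_degas,
  microwave = .handler_microwave, partition = .handler_partition,
  separate = .handler_separate, yield = .handler_yield, ph = .handler_ph
)

# ---- verb disambiguation (exported surface) --------------------------------

#' Resolve a verb lemma to an action type in context
#'
#' Context-dependent verbs map to different actions: "heat" with a duration
#' is a `Stir` (heat for some time), without one a punctual
#' `SetTemperature`; "remove" with a solvent is `Concentrate`, in a
#' filtration context `Filter`.  More specific readings win over plain
#' `Add` (Quench > PH > Partition > Add), preserving the intent of the
#' original text.
#'
#' @param lemma a verb lemma present in the lexicon.
#' @param context the sentence (or window) the verb occurs in.
#' @param lexicon a [default_lexicon()].
#' @return an action type name.  An unknown lemma signals an error of class
#'   `synthactions_unsupported_verb` (callers emit `InvalidAction`).
#' @export
#' @examples
#' disambiguate_verb("heat", "the mixture was heated to 50 °C.")
#' disambiguate_verb("heat", "heated at 80 °C for 2 h")
disambiguate_verb <- function(lemma, context, lexicon = default_lexicon()) {
  entry <- lexicon[[tolower(lemma)]]
  if (is.null(entry)) {
    stop(structure(class = c("synthactions_unsupported_verb", "error",
                             "condition"),
                   list(message = paste0("verb not in lexicon: ", lemma),
                        call = sys.call())))
  }
  cond <- .window_conditions(context)
  switch(entry$handler,
    heat = {
      if (cond$reflux) "Reflux"
      else if (cond$microwave) "Microwave"
      else if (!is.null(cond$duration)) "Stir"
      else "SetTemperature"
    },
    cool = "SetTemperature",
    remove = {
      if (grepl("filtration|filtered", context, ignore.case = TRUE)) "Filter"
      else "Concentrate"
    },
    dry = {
      if (grepl("\\bover\\b", context, ignore.case = TRUE)) "DrySolution"
      else if (grepl("solid|precipitate|cake", context, ignore.case = TRUE))
        "DrySolid"
      else "DrySolution"
    },
    entry$action)
}

# ---- sentence extraction ---------------------------------------------------

.RE_WAIT_PREFIX <- paste0(
  "^After\\s+((?:about\\s+|approximately\\s+)?[0-9][0-9.]*\\s?",
  "(?:min(?:utes?)?|h(?:ours?)?|hrs?|days?|weeks?)|overnight|",
  "an? (?:further )?(?:hour|minute|day|while))\\b[,;]?\\s*")

# local subject of an event: the noun phrase between the previous clause
# boundary and the copula directly before the verb (if any)
.local_subject <- function(pre_text) {
  # match on the masked text so commas inside quantity parentheses do not
  # truncate the subject, then slice the original at the same offsets
  masked <- .mask_nested(pre_text)
  m <- regexec(paste0("(?:^|, |; | and | then )\\s*",
                      "((?:[^,;]|[,;](?!\\s))*?)\\s+",
                      "(?:was|were|is|are)(?:\\s+(?:then|also|",
                      "subsequently))?\\s*$"),
               masked, perl = TRUE)[[1L]]
  if (m[1L] == -1L || length(m) < 2L) {
    return(list(passive = FALSE, subject = NA_character_))
  }
  st <- m[2L]
  len <- attr(m, "match.length")[2L]
  list(passive = TRUE, subject = substr(pre_text, st, st + len - 1L))
}

.apply_filter_phase_rule <- function(acts) {
  if (length(acts) < 2L) return(acts)
  for (i in seq_len(length(acts) - 1L)) {
    if (acts[[i]]$type == "Filter" && is.null(acts[[i]]$keep_phase)) {
      nxt <- acts[[i + 1L]]$type
      if (nxt %in% c("Concentrate", "DrySolution", "Purify")) {
        acts[[i]]$keep_phase <- "filtrate"
      }
    }
  }
  acts
}

#' Extract the action sequence of one sentence
#'
#' The core rule-based model.  Classification fallbacks: non-English text
#' maps to `OtherLanguage`, cross-reference phrases ("as described in ...")
#' to `FollowOtherProcedure`, analytical or descriptive text to `NoAction`,
#' and recognized-but-unsupported constructs to `InvalidAction`.  Every
#' sentence yields a sequence and every returned action passes
#' [validate_action()].
#'
#' @param sentence one sentence of procedure text.
#' @param lexicon a [default_lexicon()].
#' @return an [action_sequence()].
#' @export
#' @examples
#' extract_sentence("The organic layer was dried over sodium sulfate.")
extract_sentence <- function(sentence, lexicon = default_lexicon()) {
  stopifnot(is.character(sentence), length(sentence) == 1L)
  s <- normalize_text(sentence)
  if (!nzchar(s)) return(action_sequence(list()))
  if (.is_other_language(s, lexicon)) {
    return(action_sequence(action("OtherLanguage")))
  }
  if (grepl(.RE_FOLLOW_OTHER, s, ignore.case = TRUE)) {
    return(action_sequence(action("FollowOtherProcedure")))
  }

  prefix_actions <- list()
  body <- s
  wp <- regexpr(.RE_WAIT_PREFIX, body, perl = TRUE)
  if (wp[1L] != -1L) {
    dur <- sub(.RE_WAIT_PREFIX, "\\1", regmatches(body, wp), perl = TRUE)
    dur <- sub("^(about|approximately)\\s+", "", dur)
    if (grepl("^an? ", dur)) {
      dur <- sub("^an?\\s+(further\\s+)?", "1 ", dur)
    }
    prefix_actions <- list(action("Wait", duration = dur))
    body <- substr(body, attr(wp, "match.length") + 1L, nchar(body))
  }

  ev <- .find_events(body, lexicon)
  if (!nrow(ev)) {
    if (.has_analysis_keyword(body)) {
      return(action_sequence(action("NoAction")))
    }
    tags <- tag_entities(body)
    if (any(tags$label %in% c("QUANTITY", "COMPOUND"))) {
      return(action_sequence(c(prefix_actions, list(action("InvalidAction")))))
    }
    return(action_sequence(action("NoAction")))
  }

  acts <- prefix_actions
  invalid_seen <- FALSE
  n <- nrow(ev)
  for (i in seq_len(n)) {
    pre_start <- if (i == 1L) 1L else ev$end[i - 1L] + 1L
    pre_text <- substr(body, pre_start, ev$start[i] - 1L)
    loc <- .local_subject(pre_text)
    w_end <- if (i < n) ev$start[i + 1L] - 1L else nchar(body)
    w <- substr(body, ev$end[i] + 1L, w_end)
    # the next event's subject (if any) does not belong to this window
    if (i < n) {
      nxt_pre <- substr(body, ev$end[i] + 1L, ev$start[i + 1L] - 1L)
      nloc <- .local_subject(nxt_pre)
      if (nloc$passive && !is.na(nloc$subject) && nzchar(nloc$subject)) {
        cutpos <- regexpr(nloc$subject, w, fixed = TRUE)
        if (cutpos[1L] != -1L) w <- substr(w, 1L, cutpos - 1L)
      }
    }
    subj_text <- if (i == 1L) {
      if (loc$passive && !is.na(loc$subject)) loc$subject
      else trimws(gsub("(was|were|is|are)\\s*$", "", pre_text))
    } else {
      if (loc$passive && !is.na(loc$subject)) loc$subject else ""
    }
    first <- i == 1L || (loc$passive && nzchar(subj_text))
    subj <- .analyze_subject(subj_text)
    # sentence-initial recipient "To X ..." keeps solution phrasing
    if (i == 1L && grepl("^To\\s", trimws(pre_text))) {
      recip <- sub("\\s+(was|were|is|are)(\\s+(then|also))?\\s*$", "",
                   trimws(pre_text))
      subj_to <- .analyze_subject(recip)
      if (subj_to$kind == "solution") subj <- subj_to
    }
    # implicit prepends from the event's own subject
    lemma <- ev$lemma[i]
    handler_id <- lexicon[[lemma]]$handler
    if (first && subj$kind == "solution" &&
        !handler_id %in% c("dissolve")) {
      acts <- c(acts, list(action("MakeSolution", subj$materials),
                           action("Add", list(chemical("SLN")))))
    }
    if (first && subj$kind == "layer" &&
        !handler_id %in% c("separate", "collect")) {
      acts <- c(acts, list(action("CollectLayer", keep_phase = subj$phase)))
    }
    cond <- .window_conditions(w)
    evi <- list(lemma = lemma, passive = loc$passive,
                inverted = loc$passive && i == 1L &&
                  !is.na(loc$subject) == FALSE)
    # inversion: copula directly before the verb and material text after it
    prev_tok_copula <- grepl("(was|were|is|are)(\\s+(then|also))?\\s*$",
                             pre_text)
    evi$inverted <- prev_tok_copula
    evi$passive <- prev_tok_copula || loc$passive
    out <- .HANDLERS[[handler_id]](evi, subj, w, cond, first)
    for (a in out) {
      if (inherits(a, "sa_invalid_marker")) {
        invalid_seen <- TRUE
      } else {
        acts <- c(acts, list(a))
      }
    }
  }
  if (invalid_seen) acts <- c(acts, list(action("InvalidAction")))
  if (!length(acts)) acts <- list(action("InvalidAction"))
  # keep only actions that pass validation (handlers should guarantee this;
  # the filter is a safety net preserving the validity contract)
  ok <- vapply(acts, function(a) validate_action(a)$ok, TRUE)
  acts <- acts[ok]
  if (!length(acts)) acts <- list(action("InvalidAction"))
  action_sequence(.apply_filter_phase_rule(acts))
}

#' Insert implicit actions implied by a sentence's subject
#'
#' Solution-phrase subjects ("23 g of X in 30 mL of Y was ...") prepend
#' `MakeSolution` + `Add SLN`; bare layer subjects ("the organic layer was
#' ...") prepend the implicit `CollectLayer`.  Output length is never
#' smaller than input length.
#'
#' @param seq an [action_sequence()] from the verb mapping.
#' @param sentence the originating sentence (context).
#' @return an [action_sequence()].
#' @export
insert_implicit_actions <- function(seq, sentence) {
  stopifnot(inherits(seq, "action_sequence"))
  s <- normalize_text(sentence)
  m <- regexpr("^(.*?)\\s+(?:was|were|is|are)\\b", s, perl = TRUE)
  subj_text <- if (m[1L] != -1L) {
    sub("^(.*?)\\s+(?:was|were|is|are)\\b.*$", "\\1", s, perl = TRUE)
  } else {
    ""
  }
  subj <- .analyze_subject(subj_text)
  has_ms <- any(vapply(seq, function(a) a$type == "MakeSolution", TRUE))
  first_type <- if (length(seq)) seq[[1L]]$type else ""
  if (subj$kind == "solution" && !has_ms && first_type != "MakeSolution") {
    return(c(action_sequence(action("MakeSolution", subj$materials),
                             action("Add", list(chemical("SLN")))), seq))
  }
  if (subj$kind == "layer" && first_type != "CollectLayer" &&
      first_type %in% c("DrySolution", "Wash", "Extract", "Concentrate",
                        "Filter")) {
    return(c(action_sequence(action("CollectLayer",
                                    keep_phase = subj$phase)), seq))
  }
  seq
}

#' Extract the action sequence of a whole procedure
#'
#' Splits the procedure into sentences, extracts each, concatenates in
#' order, then post-processes across sentences: a `Filter` with no phase
#' followed by `Concentrate`, `DrySolution` or `Purify` keeps the filtrate
#' (the continuation tells which phase mattered).
#'
#' @param procedure free text, possibly many sentences.
#' @param lexicon a [default_lexicon()].
#' @return an [action_sequence()].
#' @export
#' @examples
#' extract_procedure("The solution mixture is filtered. It is then concentrated.")
extract_procedure <- function(procedure, lexicon = default_lexicon()) {
  sents <- split_sentences(procedure)
  if (!nrow(sents)) return(action_sequence(list()))
  seqs <- lapply(sents$text, extract_sentence, lexicon = lexicon)
  acts <- do.call(c, lapply(seqs, unclass))
  action_sequence(.apply_filter_phase_rule(acts))
}
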