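# Text normalization, sentence splitting and entity tagging for
# experimental-procedure prose.  Everything here is deterministic and
# pattern-based; offsets are 0-based half-open character intervals on the
# normalized sentence.

# Lightweight normalization: unify the unicode variants that actually occur
# in procedure text (degree signs, minus signs, exotic spaces), collapse
# whitespace.  Values stay as raw text — the textual action representation
# prints them verbatim.
#' Normalize procedure text
#'
#' Collapses whitespace and unifies the unicode variants commonly found in
#' patent text (degree signs, dashes, non-breaking spaces).
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_text <- function(x) {
  x <- gsub("[\u00a0\u2000-\u200b\u202f\u205f\u3000]", " ", x)
  x <- gsub("[\u2218\u00ba\u02da]", "\u00b0", x) # ring/ordinal variants -> degree
  x <- gsub("\u00b0\\s*C", "\u00b0C", x)
  x <- gsub("\u2212", "-", x)                  # unicode minus
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# Tokens that end with a period without ending a sentence.
.ABBREVIATIONS <- c(
  "aq", "conc", "e.g", "i.e", "ca", "approx", "vs", "cf", "wt", "vol",
  "eq", "equiv", "sat", "satd", "anhyd", "dil", "m.p", "b.p", "anal",
  "calcd", "no", "fig", "ref", "temp", "min"
)

#' Split a procedure into sentences
#'
#' Deterministic, abbreviation-aware splitter: breaks after `.`, `!` or `?`
#' followed by whitespace and an upper-case letter, digit or opening
#' bracket, unless the preceding token is a known abbreviation
#' (`aq.`, `conc.`, `e.g.`, ...).  Decimal points and mid-sentence `°C.`
#' followed by lower-case text never split.
#'
#' @param procedure a single character string (may be empty).
#' @return data.frame with columns `index` (1-based sentence position) and
#'   `text`; zero rows for empty input.
#' @export
#' @examples
#' split_sentences("A. Then B.")
split_sentences <- function(procedure) {
  stopifnot(is.character(procedure), length(procedure) == 1L)
  txt <- normalize_text(procedure)
  empty <- data.frame(index = integer(), text = character(),
                      stringsAsFactors = FALSE)
  if (!nzchar(txt)) return(empty)
  cand <- gregexpr("[.!?](?=\\s+[A-Z0-9(\\[\"'])", txt, perl = TRUE)[[1L]]
  breaks <- integer()
  if (cand[1L] != -1L) {
    for (p in cand) {
      before <- substr(txt, 1L, p - 1L)
      tok <- tolower(sub("^.*?([A-Za-z][A-Za-z.]*)$", "\\1", before))
      if (!tok %in% .ABBREVIATIONS) breaks <- c(breaks, p)
    }
  }
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, nchar(txt))
  sents <- trimws(substring(txt, starts, ends))
  sents <- sents[nzchar(sents)]
  data.frame(index = seq_along(sents), text = sents,
             stringsAsFactors = FALSE)
}

# -- entity patterns ---------------------------------------------------------

.NUM <- "[0-9]+(?:\\.[0-9]+)?"
.RANGE <- paste0(.NUM, "(?:\\s*[–-]\\s*", .NUM, ")?")

.QUANTITY_UNITS <- "(?:kg|g|mg|μg|ug|mL|ml|L|μL|uL|mol|mmol|μmol|umol|M|N|equiv|eq)"

.RE_QUANTITY <- paste0("(?<![\\w.])", .RANGE, "\\s?", .QUANTITY_UNITS,
                       "(?![\\w])")
.RE_PERCENT <- paste0("(?<![\\w.])", .RANGE, "\\s?%")
.RE_TEMPERATURE <- paste0(
  "(?:-?", .NUM, "(?:\\s*[–-]\\s*-?", .NUM, ")?\\s?°C",
  "|room temperature|ambient temperature|\\bRT\\b|\\br\\.?t\\.?\\b)")
.RE_DURATION <- paste0(
  "(?:(?:about\\s+|approximately\\s+)?", .RANGE,
  "\\s?(?:min(?:utes?)?|h(?:ours?)?|hrs?|sec(?:onds?)?|s\\b|days?|weeks?)",
  "(?![\\w])|overnight)")
.ATMOSPHERE_GASES <- "(?:nitrogen|argon|hydrogen|air|N2|Ar|H2|CO|an inert atmosphere|inert gas)"
.RE_ATMOSPHERE <- paste0("under (?:an?\\s+)?(?:atmosphere of\\s+)?",
                         .ATMOSPHERE_GASES,
                         "(?:\\s+(?:atmosphere|gas))?")
.RE_PH <- paste0("pH\\s*(?:of\\s*)?=?\\s*(", .NUM, ")")

# Common solvents / reagents recognized without further context.
.SOLVENT_DICT <- c(
  "water", "brine", "ice water", "methanol", "ethanol", "isopropanol",
  "MeOH", "EtOH", "IPA", "dichloromethane", "DCM", "chloroform",
  "ethyl acetate", "EtOAc", "tetrahydrofuran", "THF", "diethyl ether",
  "ether", "hexane", "n-hexane", "heptane", "pentane", "toluene",
  "benzene", "xylene", "acetonitrile", "MeCN", "acetone", "DMF", "DMSO",
  "dioxane", "1,4-dioxane", "dichloroethane", "pyridine",
  "sodium sulfate", "sodium sulphate", "magnesium sulfate",
  "anhydrous magnesium sulfate", "anhydrous sodium sulfate", "Na2SO4",
  "MgSO4", "sodium bicarbonate", "saturated sodium bicarbonate",
  "sodium hydroxide", "aqueous sodium hydroxide", "potassium carbonate",
  "hydrochloric acid", "HCl", "acetic acid", "brine solution", "celite",
  "silica gel", "petroleum ether", "ammonium chloride",
  "saturated ammonium chloride"
)

.match_all <- function(re, s, perl = TRUE) {
  m <- gregexpr(re, s, perl = perl)[[1L]]
  if (m[1L] == -1L) return(NULL)
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + attr(m, "match.length"),
             stringsAsFactors = FALSE)
}

.drop_overlaps <- function(tags, against) {
  if (!nrow(tags) || !nrow(against)) return(tags)
  keep <- vapply(seq_len(nrow(tags)), function(i) {
    !any(tags$start[i] < against$end & against$start < tags$end[i])
  }, TRUE)
  tags[keep, , drop = FALSE]
}

# Words that cannot belong to a compound name; they delimit the
# name-preceding-parenthesis heuristic.
.NAME_STOPWORDS <- c(
  "a", "an", "the", "of", "with", "in", "on", "by", "to", "and", "or",
  "was", "were", "is", "are", "then", "into", "onto", "over", "under",
  "at", "for", "from", "as", "after", "before", "added", "using",
  "containing", "give", "gave", "afford", "afforded", "obtain",
  "obtained", "yield", "yielded", "via", "followed", "between"
)

.tag_compounds <- function(s) {
  out <- NULL
  # (a) name immediately preceding a parenthesized quantity group
  pm <- gregexpr("\\(([^()]*[0-9][^()]*)\\)", s)[[1L]]
  if (pm[1L] != -1L) {
    for (k in seq_along(pm)) {
      p0 <- as.integer(pm[k])
      prefix <- substr(s, 1L, p0 - 1L)
      words_m <- gregexpr("[^ ]+", prefix)
      if (words_m[[1L]][1L] == -1L) next
      wstart <- as.integer(words_m[[1L]])
      wtext <- regmatches(prefix, words_m)[[1L]]
      take <- integer()
      for (i in rev(seq_along(wtext))) {
        w <- gsub("[,;.]$", "", tolower(wtext[i]))
        if (w %in% .NAME_STOPWORDS || grepl("[,;]$", wtext[i])) break
        take <- c(i, take)
      }
      if (!length(take)) next
      st <- wstart[take[1L]] - 1L
      en <- wstart[take[length(take)]] - 1L +
        nchar(gsub("[,;.]+$", "", wtext[take[length(take)]]))
      if (en > st) out <- rbind(out, data.frame(start = st, end = en))
    }
  }
  # (b) dictionary of common solvents/reagents
  for (w in .SOLVENT_DICT) {
    re <- paste0("(?<![\\w-])", gsub("([.()\\[\\]])", "\\\\\\1", w),
                 "(?![\\w-])")
    hit <- .match_all(re, s)
    if (!is.null(hit)) out <- rbind(out, hit)
  }
  # (c) chemical-looking tokens (digits + hyphens + letters)
  hit <- .match_all(
    "(?<![\\w-])[0-9]+(?:,[0-9]+)*-[A-Za-z][\\w\\[\\]()',-]*[a-z]{2}(?![\\w-])",
    s)
  if (!is.null(hit)) out <- rbind(out, hit)
  if (is.null(out) || !nrow(out)) return(out)
  # merge: drop spans contained in (or overlapping) a longer span
  out <- out[order(out$start, -out$end), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(out))) {
      if (i == j || !keep[j]) next
      if (out$start[j] < out$end[i] && out$start[i] < out$end[j]) {
        # overlap: keep the longer
        li <- out$end[i] - out$start[i]
        lj <- out$end[j] - out$start[j]
        if (lj > li) keep[i] <- FALSE else keep[j] <- FALSE
      }
    }
  }
  out[keep, , drop = FALSE]
}

#' Tag chemical entities in one sentence
#'
#' Finds compounds, quantities, temperatures, durations, atmospheres, pH
#' values and yield percentages.  Compound recognition is pattern- and
#' dictionary-based (tokens preceding quantity parentheses, common
#' solvents, chemical-looking hyphenated tokens), deliberately not a
#' trained chemical named-entity model.
#'
#' @param sentence a single character string (normalized internally).
#' @return data.frame with columns `start`, `end` (0-based half-open
#'   offsets on the normalized sentence), `label` (COMPOUND, QUANTITY,
#'   TEMPERATURE, DURATION, ATMOSPHERE, PH_VALUE, YIELD_PCT) and `value`
#'   (surface text; the parsed number for PH_VALUE).  Sorted by `start`.
#' @export
#' @examples
#' tag_entities("acetaldehyde (4.95 mL, 88.2 mmol) at 0 °C")
tag_entities <- function(sentence) {
  stopifnot(is.character(sentence), length(sentence) == 1L)
  s <- normalize_text(sentence)
  res <- NULL
  add <- function(tags, label, res) {
    if (is.null(tags) || !nrow(tags)) return(res)
    tags$label <- label
    tags$value <- substring(s, tags$start + 1L, tags$end)
    rbind(res, tags)
  }
  res <- add(.match_all(.RE_TEMPERATURE, s), "TEMPERATURE", res)
  dur <- .match_all(.RE_DURATION, s)
  if (!is.null(dur) && !is.null(res)) {
    dur <- .drop_overlaps(dur, res[res$label == "TEMPERATURE", ])
  }
  res <- add(dur, "DURATION", res)
  res <- add(.match_all(.RE_ATMOSPHERE, s), "ATMOSPHERE", res)
  qty <- .match_all(.RE_QUANTITY, s)
  if (!is.null(qty) && !is.null(res)) {
    qty <- .drop_overlaps(qty,
                          res[res$label %in% c("TEMPERATURE", "DURATION"), ])
  }
  res <- add(qty, "QUANTITY", res)
  # percentages: inside parentheses or right before a compound word they are
  # quantities/name parts; a bare percent near "yield" is a yield figure
  pct <- .match_all(.RE_PERCENT, s)
  if (!is.null(pct)) {
    depth <- .depth_map(s)
    for (i in seq_len(nrow(pct))) {
      inside <- depth[pct$start[i] + 1L] > 0L
      after <- substr(s, pct$end[i] + 1L, pct$end[i] + 2L)
      if (inside) {
        res <- rbind(res, data.frame(start = pct$start[i], end = pct$end[i],
                                     label = "QUANTITY",
                                     value = substring(s, pct$start[i] + 1L,
                                                       pct$end[i])))
      } else if (!grepl("^ [A-Za-z]", after)) {
        res <- rbind(res, data.frame(start = pct$start[i], end = pct$end[i],
                                     label = "YIELD_PCT",
                                     value = substring(s, pct$start[i] + 1L,
                                                       pct$end[i])))
      }
    }
  }
  phm <- regexpr(.RE_PH, s, perl = TRUE)
  if (phm[1L] != -1L) {
    cap <- regmatches(s, phm)
    num <- sub(.RE_PH, "\\1", cap, perl = TRUE)
    res <- rbind(res, data.frame(start = as.integer(phm) - 1L,
                                 end = as.integer(phm) - 1L +
                                   attr(phm, "match.length"),
                                 label = "PH_VALUE", value = num))
  }
  comp <- .tag_compounds(s)
  if (!is.null(comp) && nrow(comp)) {
    comp$label <- "COMPOUND"
    comp$value <- substring(s, comp$start + 1L, comp$end)
    if (!is.null(res)) {
      comp <- .drop_overlaps(comp, res[res$label %in%
                                         c("ATMOSPHERE", "TEMPERATURE",
                                           "DURATION"), ])
    }
    res <- rbind(res, comp)
  }
  if (is.null(res)) {
    return(data.frame(start = integer(), end = integer(),
                      label = character(), value = character(),
                      stringsAsFactors = FALSE))
  }
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Relationships between compounds in a sentence
#'
#' Emits `SOLUTE_IN` relations for solution phrases ("a solution of X in
#' Z") and a direction-normalized `ADDED_TO` relation: "To X is added Y"
#' and "Y is added to X" both resolve to `ADDED_TO(Y, X)`.  Ambiguous
#' attachments yield no relation.
#'
#' @param sentence a single character string.
#' @param tags entity tags from [tag_entities()] on the same sentence
#'   (recomputed when omitted).
#' @return data.frame with columns `from`, `relation`, `to`.
#' @export
#' @examples
#' compound_relationships("To X2 is added Y2")
compound_relationships <- function(sentence, tags = tag_entities(sentence)) {
  s <- normalize_text(sentence)
  out <- data.frame(from = character(), relation = character(),
                    to = character(), stringsAsFactors = FALSE)
  clean <- function(x) {
    x <- gsub("\\([^()]*\\)", "", x)        # drop quantity parens
    trimws(gsub("\\s+", " ", x))
  }
  # SOLUTE_IN from solution phrases
  sol_re <- "(?i:a|the)\\s+(?i:solution|suspension|mixture)\\s+of\\s+(.*?)\\s+in\\s+([A-Za-z][\\w ,()\\[\\]'-]*?)(?=$|\\s+(?:was|were|is|are|at|under|to)\\b|[,;.])"
  m <- gregexpr(sol_re, s, perl = TRUE)[[1L]]
  if (m[1L] != -1L) {
    for (k in seq_along(m)) {
      frag <- substr(s, m[k], m[k] + attr(m, "match.length")[k] - 1L)
      solutes <- clean(sub(sol_re, "\\1", frag, perl = TRUE))
      solvent <- clean(sub(sol_re, "\\2", frag, perl = TRUE))
      for (sol in strsplit(solutes, "\\s+and\\s+")[[1L]]) {
        if (nzchar(sol) && nzchar(solvent)) {
          out <- rbind(out, data.frame(from = clean(sol),
                                       relation = "SOLUTE_IN",
                                       to = solvent))
        }
      }
    }
  }
  # ADDED_TO, both formulations normalized to (added material, recipient)
  re1 <- "^To\\s+(.+?)\\s+(?:was|were|is|are)\\s+added\\s+(.+?)(?:[,;.]|$)"
  re2 <- "^(.+?)\\s+(?:was|were|is|are)\\s+added\\s+to\\s+(.+?)(?:[,;.]|$)"
  if (grepl(re1, s, perl = TRUE)) {
    to <- clean(sub(re1, "\\1", regmatches(s, regexpr(re1, s, perl = TRUE)),
                    perl = TRUE))
    from <- clean(sub(re1, "\\2",
                      regmatches(s, regexpr(re1, s, perl = TRUE)),
                      perl = TRUE))
    out <- rbind(out, data.frame(from = from, relation = "ADDED_TO",
                                 to = to))
  } else if (grepl(re2, s, perl = TRUE)) {
    frag <- regmatches(s, regexpr(re2, s, perl = TRUE))
    from <- clean(sub(re2, "\\1", frag, perl = TRUE))
    to <- clean(sub(re2, "\\2", frag, perl = TRUE))
    out <- rbind(out, data.frame(from = from, relation = "ADDED_TO",
                                 to = to))
  }
  rownames(out) <- NULL
  out
}
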