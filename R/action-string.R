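# Textual representation of action sequences.
#
# One action sequence <-> one single-line string, clauses joined by "; ",
# e.g. "Filter keep filtrate; Concentrate".  The surface grammar per type is
# keyword-based (with/and/over/from/keep/for/at/under/to pH/x/dropwise);
# compound names may contain spaces and internal parentheses, so quantity
# parentheses and the next keyword delimit them.  Serialization and parsing
# are mutual inverses on the canonical form; parsing accepts arbitrary text
# and returns a structured failure instead of throwing (this underpins the
# validity metric).

# Per-character parenthesis/bracket depth; used to mask nested material
# names so keyword search only sees top-level text.
.depth_map <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  depth <- integer(length(ch))
  d <- 0L
  for (i in seq_along(ch)) {
    if (ch[i] %in% c("(", "[")) {
      d <- d + 1L
      depth[i] <- d
    } else if (ch[i] %in% c(")", "]")) {
      depth[i] <- d
      d <- max(0L, d - 1L)
    } else {
      depth[i] <- d
    }
  }
  depth
}

# Replace every character at depth > 0 (including the brackets) by \x01 so
# that regex keyword search cannot match inside parenthesized groups.
.mask_nested <- function(s) {
  if (!nzchar(s)) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  ch[.depth_map(s) > 0L] <- "\x01"
  paste(ch, collapse = "")
}

# Split s on a literal separator, only at top-level (depth 0) occurrences.
.split_top_level <- function(s, sep) {
  m <- gregexpr(sep, .mask_nested(s), fixed = TRUE)[[1L]]
  if (m[1L] == -1L) return(s)
  starts <- c(1L, m + attr(m, "match.length"))
  ends <- c(m - 1L, nchar(s))
  vapply(seq_along(starts),
         function(i) substr(s, starts[i], ends[i]), "")
}

.MATERIAL_INTRO <- c(
  Add = "", Yield = "", MakeSolution = "with", Quench = "with",
  Wash = "with", Extract = "with", Triturate = "with", Partition = "with",
  PH = "with", DrySolution = "over", Recrystallize = "from"
)

.format_material <- function(m) {
  if (length(m$quantities)) {
    paste0(m$name, " (",
           paste(vapply(m$quantities, `[[`, "", "raw"), collapse = ", "),
           ")")
  } else {
    m$name
  }
}

.serialize_clause <- function(act) {
  parts <- act$type
  if (length(act$materials)) {
    intro <- .MATERIAL_INTRO[[act$type]]
    mats <- paste(vapply(act$materials, .format_material, ""),
                  collapse = " and ")
    parts <- c(parts, if (nzchar(intro)) intro, mats)
  }
  cond <- act$condition
  if (!is.null(cond$ph_value)) {
    parts <- c(parts, "to pH", format(cond$ph_value, trim = TRUE))
  }
  if (isTRUE(cond$dropwise)) parts <- c(parts, "dropwise")
  if (!is.null(cond$duration)) {
    parts <- c(parts,
               if (act$type != "Wait") "for",
               cond$duration)
  }
  if (!is.null(cond$temperature)) {
    parts <- c(parts,
               if (act$type != "SetTemperature") "at",
               cond$temperature)
  }
  if (!is.null(cond$atmosphere)) parts <- c(parts, "under", cond$atmosphere)
  if (!is.null(cond$repetitions)) parts <- c(parts, "x", cond$repetitions)
  if (!is.null(act$keep_phase)) {
    parts <- c(parts,
               if (act$type == "Filter") "keep",
               act$keep_phase)
  }
  paste(parts, collapse = " ")
}

#' Serialize an action sequence to its textual representation
#'
#' Produces the canonical single-line form, clauses joined by `"; "`, with
#' no terminal period (the canonical form must be unique for the
#' serialize/parse pair to be bijective; a trailing period is accepted on
#' input).
#'
#' @param seq an [action_sequence()] (a single `synth_action` is accepted).
#' @param validate check every action against the allowed-property table
#'   first and error, naming the violating field, if any check fails.
#' @return single character string; `""` for an empty sequence.
#' @export
#' @examples
#' serialize_actions(action_sequence(
#'   action("Filter", keep_phase = "filtrate"), action("Concentrate")))
serialize_actions <- function(seq, validate = TRUE) {
  if (inherits(seq, "synth_action")) seq <- action_sequence(seq)
  stopifnot(inherits(seq, "action_sequence"))
  if (!length(seq)) return("")
  if (validate) {
    for (i in seq_along(seq)) {
      chk <- validate_action(seq[[i]])
      if (!chk$ok) {
        stop("invalid action at position ", i, ": ",
             paste(chk$violations, collapse = "; "), call. = FALSE)
      }
    }
  }
  paste(vapply(seq, .serialize_clause, ""), collapse = "; ")
}

.parse_failure <- function(clause_index, token, message, input) {
  structure(list(ok = FALSE, clause = clause_index, token = token,
                 message = message, input = input),
            class = "action_parse_error")
}

#' Is an object a structured parse failure?
#'
#' @param x any object.
#' @return `TRUE` for parse failures returned by [parse_actions()].
#' @export
is_parse_error <- function(x) inherits(x, "action_parse_error")

#' @export
print.action_parse_error <- function(x, ...) {
  cat("<action string parse error> clause ", x$clause, ": ", x$message,
      "\n", sep = "")
  invisible(x)
}

# Parse the material chunk of a clause.  Multi-material types split on
# top-level " and "; a trailing balanced parenthesis group containing a
# digit is read as the comma-separated quantity list, anything else stays
# part of the name.
.parse_materials <- function(chunk, multi) {
  items <- if (multi) .split_top_level(chunk, " and ") else chunk
  out <- vector("list", length(items))
  for (i in seq_along(items)) {
    item <- trimws(items[i])
    if (!nzchar(item)) return(NULL)
    quants <- character()
    if (endsWith(item, ")")) {
      depth <- .depth_map(item)
      n <- nchar(item)
      open <- which(substring(item, 1:n, 1:n) == "(" & depth == 1L)
      open <- if (length(open)) open[length(open)] else NA_integer_
      if (!is.na(open)) {
        inner <- substr(item, open + 1L, n - 1L)
        # a quantity group closes the item and contains at least one digit
        if (grepl("[0-9]", inner) && !grepl("[()]", inner)) {
          quants <- trimws(strsplit(inner, ",", fixed = TRUE)[[1L]])
          item <- trimws(substr(item, 1L, open - 1L))
        }
      }
    }
    if (!nzchar(item) || !all(nzchar(quants))) return(NULL)
    out[[i]] <- chemical(item, quantities = quants)
  }
  out
}

.COND_KEYWORDS <- c(dropwise = " dropwise", ph_value = " to pH ",
                    duration = " for ", temperature = " at ",
                    atmosphere = " under ", repetitions = " x ")

.parse_clause <- function(clause, idx, input) {
  clause <- trimws(clause)
  if (!nzchar(clause)) {
    return(.parse_failure(idx, "", "empty clause", input))
  }
  head_tok <- sub("\\s.*$", "", clause)
  type <- tryCatch(match_action_type(head_tok), error = function(e) NULL)
  if (is.null(type)) {
    return(.parse_failure(idx, head_tok,
                          paste0("unknown action name '", head_tok, "'"),
                          input))
  }
  rest <- trimws(sub("^\\S+\\s*", "", clause))

  # fixed-form types first
  if (type == "SetTemperature") {
    if (!nzchar(rest)) {
      return(.parse_failure(idx, "", "SetTemperature needs a temperature",
                            input))
    }
    return(action(type, temperature = rest))
  }
  if (type == "CollectLayer") {
    if (!nzchar(rest)) return(action(type))
    if (!rest %in% c("aqueous", "organic")) {
      return(.parse_failure(idx, rest,
                            "CollectLayer phase must be aqueous or organic",
                            input))
    }
    return(action(type, keep_phase = rest))
  }

  # locate condition keywords at top level, leftmost occurrence each
  padded <- paste0(" ", rest)
  masked <- .mask_nested(padded)
  hits <- list()
  for (f in names(.COND_KEYWORDS)) {
    kw <- .COND_KEYWORDS[[f]]
    pat <- if (f == "dropwise") " dropwise(?= |$)" else kw
    m <- regexpr(pat, masked, perl = (f == "dropwise"))
    if (m[1L] != -1L) {
      hits[[f]] <- c(pos = as.integer(m),
                     len = attr(m, "match.length"))
    }
  }
  ord <- order(vapply(hits, `[[`, 0L, "pos"))
  hits <- hits[ord]
  first_pos <- if (length(hits)) hits[[1L]]["pos"] else nchar(padded) + 1L
  head_chunk <- trimws(substr(padded, 1L, first_pos - 1L))

  # per-keyword value segments (text up to the next keyword)
  vals <- list()
  if (length(hits)) {
    pos <- vapply(hits, `[[`, 0L, "pos")
    len <- vapply(hits, `[[`, 0L, "len")
    ends <- c(pos[-1L] - 1L, nchar(padded))
    for (i in seq_along(hits)) {
      f <- names(hits)[i]
      v <- trimws(substr(padded, pos[i] + len[i], ends[i]))
      if (f == "dropwise") {
        if (nzchar(v)) {
          return(.parse_failure(idx, v, "unexpected text after 'dropwise'",
                                input))
        }
        vals[[f]] <- TRUE
      } else {
        if (!nzchar(v)) {
          return(.parse_failure(idx, trimws(.COND_KEYWORDS[[f]]),
                                paste0("missing value after '",
                                       trimws(.COND_KEYWORDS[[f]]), "'"),
                                input))
        }
        vals[[f]] <- v
      }
    }
  }
  if (!is.null(vals$repetitions)) {
    n <- suppressWarnings(as.integer(vals$repetitions))
    if (is.na(n) || n < 1L) {
      return(.parse_failure(idx, vals$repetitions,
                            "repetitions must be a positive integer", input))
    }
    vals$repetitions <- n
  }
  if (!is.null(vals$ph_value)) {
    p <- suppressWarnings(as.numeric(vals$ph_value))
    if (is.na(p)) {
      return(.parse_failure(idx, vals$ph_value, "pH value is not numeric",
                            input))
    }
    vals$ph_value <- p
  }

  materials <- list()
  keep_phase <- NULL
  if (type == "Filter") {
    if (nzchar(head_chunk)) {
      phase <- sub("^keep\\s+", "", head_chunk)
      if (identical(phase, head_chunk) ||
          !phase %in% c("filtrate", "precipitate")) {
        return(.parse_failure(idx, head_chunk,
                              "Filter admits only 'keep filtrate' or 'keep precipitate'",
                              input))
      }
      keep_phase <- phase
    }
  } else if (type %in% names(.MATERIAL_INTRO)) {
    intro <- .MATERIAL_INTRO[[type]]
    chunk <- head_chunk
    if (nzchar(intro) && nzchar(chunk)) {
      stripped <- sub(paste0("^", intro, "\\s+"), "", chunk)
      if (identical(stripped, chunk)) {
        return(.parse_failure(idx, chunk,
                              paste0("expected '", intro, "' after ", type),
                              input))
      }
      chunk <- stripped
    }
    if (nzchar(chunk)) {
      multi <- type %in% c("MakeSolution", "Partition", "Recrystallize")
      materials <- .parse_materials(chunk, multi)
      if (is.null(materials)) {
        return(.parse_failure(idx, chunk, "malformed material list", input))
      }
    } else if (type %in% c("MakeSolution", "Partition")) {
      return(.parse_failure(idx, "", paste0(type, " needs materials"),
                            input))
    }
  } else if (type == "Wait") {
    if (nzchar(head_chunk)) vals$duration <- head_chunk
  } else if (nzchar(head_chunk)) {
    return(.parse_failure(idx, head_chunk,
                          paste0("unexpected text after ", type, ": '",
                                 head_chunk, "'"),
                          input))
  }

  act <- tryCatch(
    action(type, materials = materials, duration = vals$duration,
           temperature = vals$temperature, atmosphere = vals$atmosphere,
           ph_value = vals$ph_value, dropwise = vals$dropwise,
           repetitions = vals$repetitions, keep_phase = keep_phase),
    error = function(e) NULL)
  if (is.null(act)) {
    return(.parse_failure(idx, clause, "malformed clause", input))
  }
  chk <- validate_action(act)
  if (!chk$ok) {
    return(.parse_failure(idx, clause,
                          paste(chk$violations, collapse = "; "), input))
  }
  act
}

#' Parse the textual representation back into an action sequence
#'
#' Accepts arbitrary text: clauses are split on semicolons, a trailing
#' period is tolerated, action names are matched case-insensitively
#' (`"ADD X"` and `"Add X"` parse identically).  An unparseable clause
#' yields a structured failure object (see [is_parse_error()]) carrying the
#' clause index and offending token — parsing never throws, which is what
#' the validity metric relies on.
#'
#' @param s a single character string.
#' @return an [action_sequence()] on success, otherwise an
#'   `action_parse_error` object.
#' @export
#' @examples
#' parse_actions("Quench with water; Concentrate")
#' is_parse_error(parse_actions("Blorbify at 5 °C"))
parse_actions <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  if (is.na(s)) return(.parse_failure(1L, NA_character_, "NA input", s))
  txt <- trimws(s)
  txt <- sub("\\.\\s*$", "", txt)
  if (!nzchar(txt)) return(action_sequence(list()))
  clauses <- strsplit(txt, ";", fixed = TRUE)[[1L]]
  acts <- vector("list", length(clauses))
  for (i in seq_along(clauses)) {
    res <- .parse_clause(clauses[i], i, s)
    if (is_parse_error(res)) return(res)
    acts[[i]] <- res
  }
  action_sequence(acts)
}

#' Count the actions in an action string
#'
#' @param s a single character string in the textual representation.
#' @return non-negative integer count of actions.  A parse failure is
#'   propagated as an error.
#' @export
#' @examples
#' count_actions("Filter keep filtrate; Concentrate")
count_actions <- function(s) {
  res <- parse_actions(s)
  if (is_parse_error(res)) {
    stop("cannot count actions: clause ", res$clause, ": ", res$message,
         call. = FALSE)
  }
  length(res)
}

#' Are two action sequences identical?
#'
#' Equality is defined on the canonical textual form, which carries every
#' populated property.
#'
#' @param a,b [action_sequence()] objects.
#' @return logical.
#' @export
sequences_equal <- function(a, b) {
  identical(serialize_actions(a, validate = FALSE),
            serialize_actions(b, validate = FALSE))
}
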