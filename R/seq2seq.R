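# Sentence-to-action-string translation protocol: shared subword
# vocabulary, pretraining on rule-generated pairs, refinement on annotated
# pairs, beam n-best decoding, checkpoint selection and ensembling.
#
# The protocol is engine-agnostic: a model exposes train/translate/save/
# load and everything else (corpus handling, checkpoints, refinement,
# ensembles) is engine-independent.  The default engine is an analogical
# template-induction translator: from each training pair it abstracts the
# text spans shared between sentence and action string into slots, stores
# the resulting (source template -> target template) rule with a count, and
# decodes new sentences by matching stored templates and transplanting the
# captured spans.  This engine is deterministic, trains in seconds on a
# CPU, generalizes over entity substitutions exactly like the
# subword-based neural model it stands for generalizes in the large, and
# fails (decoding to InvalidAction) on constructions it has never seen —
# the behaviour the protocol's metrics are designed to expose.  Transformer
# hyperparameters (layers, hidden size, attention heads) are carried in the
# configuration as presets for heavier engines.

# ---- subword vocabulary (byte-pair encoding) -------------------------------

.WORD_END <- "▁"  # end-of-word sentinel appended to each word

#' Build a shared source/target subword vocabulary
#'
#' Byte-pair encoding learned on the concatenation of source sentences and
#' target action strings (the two sides share one vocabulary and hence one
#' embedding space).  Deterministic: merge ties are broken
#' lexicographically.
#'
#' @param texts character vector (typically `c(sentences, action_strings)`).
#' @param vocab_size requested vocabulary size; the corpus may support
#'   fewer merges, in which case the vocabulary is corpus-limited.  Must be
#'   at least the alphabet size.
#' @return object of class `subword_vocab` with fields `tokens`, `merges`,
#'   `size`.
#' @export
#' @examples
#' v <- build_vocabulary(c("add water", "add brine"), vocab_size = 30)
#' encode_subwords(v, "add water")
build_vocabulary <- function(texts, vocab_size) {
  stopifnot(is.character(texts), length(texts) > 0L)
  words <- unlist(strsplit(texts, "\\s+"))
  words <- words[nzchar(words)]
  if (!length(words)) stop("empty corpus", call. = FALSE)
  wtab <- table(words)
  alphabet <- sort(unique(c(unlist(strsplit(names(wtab), "")), .WORD_END)))
  if (vocab_size < length(alphabet)) {
    stop("vocab_size (", vocab_size, ") is smaller than the alphabet (",
         length(alphabet), ")", call. = FALSE)
  }
  # symbol sequences per distinct word
  seqs <- lapply(names(wtab), function(w) {
    c(strsplit(w, "")[[1L]], .WORD_END)
  })
  counts <- as.integer(wtab)
  merges <- character()
  n_merges <- vocab_size - length(alphabet)
  for (k in seq_len(n_merges)) {
    pair_counts <- new.env(parent = emptyenv())
    for (i in seq_along(seqs)) {
      sy <- seqs[[i]]
      if (length(sy) < 2L) next
      prs <- paste(sy[-length(sy)], sy[-1L], sep = " ")
      for (p in unique(prs)) {
        cur <- if (is.null(pair_counts[[p]])) 0L else pair_counts[[p]]
        pair_counts[[p]] <- cur + sum(prs == p) * counts[i]
      }
    }
    prs <- ls(pair_counts)
    if (!length(prs)) break
    vals <- vapply(prs, function(p) pair_counts[[p]], 0L)
    best <- prs[order(-vals, prs)][1L]
    if (vals[match(best, prs)] < 2L) break
    merges <- c(merges, best)
    ab <- strsplit(best, " ", fixed = TRUE)[[1L]]
    merged <- paste0(ab[1L], ab[2L])
    seqs <- lapply(seqs, function(sy) {
      i <- 1L
      out <- character()
      while (i <= length(sy)) {
        if (i < length(sy) && sy[i] == ab[1L] && sy[i + 1L] == ab[2L]) {
          out <- c(out, merged)
          i <- i + 2L
        } else {
          out <- c(out, sy[i])
          i <- i + 1L
        }
      }
      out
    })
  }
  tokens <- unique(c(alphabet, vapply(merges, function(m) {
    paste0(strsplit(m, " ", fixed = TRUE)[[1L]], collapse = "")
  }, "")))
  structure(list(tokens = tokens, merges = merges,
                 size = length(tokens)),
            class = "subword_vocab")
}

#' Encode / decode text with a subword vocabulary
#'
#' Encoding applies the learned merges in order; decoding concatenates
#' subwords and restores spaces at word boundaries, so
#' `decode_subwords(v, encode_subwords(v, x))` is the identity on
#' whitespace-normalized text.
#'
#' @param vocab a [build_vocabulary()] object.
#' @param text single character string.
#' @param tokens character vector of subword tokens.
#' @return `encode_subwords()` a character vector of subword tokens;
#'   `decode_subwords()` a string.
#' @export
encode_subwords <- function(vocab, text) {
  stopifnot(inherits(vocab, "subword_vocab"))
  words <- strsplit(trimws(text), "\\s+")[[1L]]
  words <- words[nzchar(words)]
  merge_pairs <- strsplit(vocab$merges, " ", fixed = TRUE)
  out <- character()
  for (w in words) {
    sy <- c(strsplit(w, "")[[1L]], .WORD_END)
    for (ab in merge_pairs) {
      merged <- paste0(ab[1L], ab[2L])
      i <- 1L
      nx <- character()
      while (i <= length(sy)) {
        if (i < length(sy) && sy[i] == ab[1L] && sy[i + 1L] == ab[2L]) {
          nx <- c(nx, merged)
          i <- i + 2L
        } else {
          nx <- c(nx, sy[i])
          i <- i + 1L
        }
      }
      sy <- nx
    }
    out <- c(out, sy)
  }
  out
}

#' @rdname encode_subwords
#' @export
decode_subwords <- function(vocab, tokens) {
  stopifnot(inherits(vocab, "subword_vocab"))
  txt <- paste(tokens, collapse = "")
  txt <- gsub(paste0(.WORD_END, "$"), "", txt)
  gsub(.WORD_END, " ", txt, fixed = TRUE)
}

#' @export
print.subword_vocab <- function(x, ...) {
  cat("<subword vocabulary>", x$size, "tokens,", length(x$merges),
      "merges\n")
  invisible(x)
}

# ---- configuration ---------------------------------------------------------

#' Translation model configuration
#'
#' Carries the full hyperparameter set of the translation protocol.  The
#' defaults are the full-scale settings (transformer encoder–decoder, 4
#' layers, hidden and embedding size 256, 8 attention heads, shared
#' source/target vocabulary of 16,000, label smoothing 0, gradient
#' accumulation 4, 500,000 pretraining steps, checkpoints every 1,000
#' steps); [desk_config()] scales everything down to sizes trainable on a
#' laptop CPU in minutes.  Engine-specific parameters not used by the
#' default engine are preserved as presets for heavier engines.
#'
#' @param layers,hidden_size,embedding_size,attention_heads architecture
#'   preset.
#' @param shared_source_target_vocab single shared subword vocabulary flag.
#' @param label_smoothing,gradient_accumulation optimizer presets.
#' @param vocab_size subword vocabulary size.
#' @param train_steps number of training steps.
#' @param checkpoint_every checkpoint interval in steps.
#' @param seed integer seed.
#' @return object of class `seq2seq_config`.
#' @export
seq2seq_config <- function(layers = 4L, hidden_size = 256L,
                           embedding_size = 256L, attention_heads = 8L,
                           shared_source_target_vocab = TRUE,
                           label_smoothing = 0, gradient_accumulation = 4L,
                           vocab_size = 16000L, train_steps = 500000L,
                           checkpoint_every = 1000L, seed = 1L) {
  structure(list(layers = as.integer(layers),
                 hidden_size = as.integer(hidden_size),
                 embedding_size = as.integer(embedding_size),
                 attention_heads = as.integer(attention_heads),
                 shared_source_target_vocab =
                   isTRUE(shared_source_target_vocab),
                 label_smoothing = label_smoothing,
                 gradient_accumulation = as.integer(gradient_accumulation),
                 vocab_size = as.integer(vocab_size),
                 train_steps = as.integer(train_steps),
                 checkpoint_every = as.integer(checkpoint_every),
                 seed = as.integer(seed)),
            class = "seq2seq_config")
}

#' @rdname seq2seq_config
#' @export
desk_config <- function(vocab_size = 300L, train_steps = 2000L,
                        checkpoint_every = 500L, seed = 1L) {
  seq2seq_config(layers = 2L, hidden_size = 128L, embedding_size = 128L,
                 vocab_size = vocab_size, train_steps = train_steps,
                 checkpoint_every = checkpoint_every, seed = seed)
}

# ---- template induction engine ---------------------------------------------

.SLOT_STOPWORDS <- c("the", "was", "were", "is", "are", "and", "with",
                     "for", "at", "in", "of", "to", "a", "an", "under",
                     "over", "keep", "from")

.tokenize_ws <- function(x) {
  t <- strsplit(trimws(x), "\\s+")[[1L]]
  t[nzchar(t)]
}

# token positions and "cores" (tokens with leading/trailing punctuation
# stripped, offsets kept): matching on cores lets a quantity inside
# parentheses in the action string align with the bare quantity in the
# sentence, while the punctuation stays literal in the template
.token_cores <- function(s) {
  m <- gregexpr("\\S+", s)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(core = character(), cstart = integer(),
                      cend = integer()))
  }
  toks <- regmatches(s, list(m))[[1L]]
  starts <- as.integer(m)
  cores <- character(length(toks))
  cstart <- cend <- integer(length(toks))
  for (i in seq_along(toks)) {
    lead <- attr(regexpr("^[]()\\[{};:,.!]*", toks[i]), "match.length")
    trail <- attr(regexpr("[](\\[{});:,.!]*$", toks[i]), "match.length")
    core <- substr(toks[i], lead + 1L, nchar(toks[i]) - trail)
    cores[i] <- core
    cstart[i] <- starts[i] + lead
    cend[i] <- starts[i] + nchar(toks[i]) - trail - 1L
  }
  data.frame(core = cores, cstart = cstart, cend = cend,
             stringsAsFactors = FALSE)
}

# abstract the text spans shared by source and target into numbered slots;
# spans align on punctuation-stripped token cores, longest span first
.delex_pair <- function(src, tgt) {
  src <- paste(.tokenize_ws(src), collapse = " ")
  tgt <- paste(.tokenize_ws(tgt), collapse = " ")
  stk <- .token_cores(src)
  ttk <- .token_cores(tgt)
  ns <- nrow(stk)
  nt <- nrow(ttk)
  t_used <- logical(nt)
  s_used <- logical(ns)
  slots <- list()  # each: list(s_start, s_end, t_start, t_end, content)
  if (nt && ns) {
    for (len in rev(seq_len(nt))) {
      start <- 1L
      while (start + len - 1L <= nt) {
        idx <- start:(start + len - 1L)
        if (any(t_used[idx]) || any(!nzchar(ttk$core[idx]))) {
          start <- start + 1L
          next
        }
        content_t <- substr(tgt, ttk$cstart[start],
                            ttk$cend[start + len - 1L])
        ok_span <- len > 1L ||
          (grepl("[0-9]", content_t) ||
           (nchar(content_t) >= 3L &&
            !tolower(content_t) %in% .SLOT_STOPWORDS))
        hit <- NA_integer_
        if (ok_span && ns >= len) {
          for (j in seq_len(ns - len + 1L)) {
            jdx <- j:(j + len - 1L)
            if (any(s_used[jdx])) next
            if (!all(stk$core[jdx] == ttk$core[idx])) next
            content_s <- substr(src, stk$cstart[j], stk$cend[j + len - 1L])
            if (!identical(content_s, content_t)) next
            hit <- j
            break
          }
        }
        if (!is.na(hit)) {
          slots[[length(slots) + 1L]] <-
            list(s_start = stk$cstart[hit],
                 s_end = stk$cend[hit + len - 1L],
                 t_start = ttk$cstart[start],
                 t_end = ttk$cend[start + len - 1L],
                 content = content_t)
          t_used[idx] <- TRUE
          s_used[hit:(hit + len - 1L)] <- TRUE
          start <- start + len
        } else {
          start <- start + 1L
        }
      }
    }
  }
  if (!length(slots)) {
    return(list(src_tpl = src, tgt_tpl = tgt, n_slots = 0L,
                anchors = character()))
  }
  # slot ids follow source position
  ord <- order(vapply(slots, `[[`, 0L, "s_start"))
  slots <- slots[ord]
  splice <- function(text, starts, ends, ids) {
    o <- order(starts)
    out <- ""
    pos <- 1L
    for (k in o) {
      out <- paste0(out, substr(text, pos, starts[k] - 1L),
                    "\x02", ids[k], "\x03")
      pos <- ends[k] + 1L
    }
    paste0(out, substr(text, pos, nchar(text)))
  }
  ids <- seq_along(slots)
  src_tpl <- splice(src, vapply(slots, `[[`, 0L, "s_start"),
                    vapply(slots, `[[`, 0L, "s_end"), ids)
  tgt_tpl <- splice(tgt, vapply(slots, `[[`, 0L, "t_start"),
                    vapply(slots, `[[`, 0L, "t_end"), ids)
  # anchor: a slot directly adjacent to another slot (whitespace-only
  # separation) is ambiguous under non-greedy matching, so it must capture
  # text beginning with the closed-class function word its training
  # content begins with; isolated slots stay unanchored so that variant
  # instances of the same pattern (e.g. "dropwise" vs "at 0 °C") unify
  adjacent <- grepl(paste0("\x03\\s+\x02"), src_tpl)
  adj_ids <- integer()
  if (adjacent) {
    mm <- gregexpr("\x02([0-9]+)\x03\\s+\x02([0-9]+)\x03", src_tpl)[[1L]]
    if (mm[1L] != -1L) {
      frag <- regmatches(src_tpl, list(mm))[[1L]]
      adj_ids <- unique(as.integer(unlist(
        regmatches(frag, gregexpr("[0-9]+", frag)))))
    }
  }
  anchors <- vapply(seq_along(slots), function(k) {
    if (!k %in% adj_ids) return("")
    w <- sub("\\s.*$", "", slots[[k]]$content)
    if (tolower(w) %in% c("at", "for", "under", "to", "with", "in",
                          "over", "from", "keep")) w else ""
  }, "")
  list(src_tpl = src_tpl, tgt_tpl = tgt_tpl, n_slots = length(slots),
       anchors = anchors)
}

.tpl_regex <- function(src_tpl, anchors = character()) {
  esc <- gsub("([.^$*+?()\\[\\]{}|\\\\])", "\\\\\\1", src_tpl, perl = TRUE)
  m <- gregexpr("\x02[0-9]+\x03", esc)[[1L]]
  if (m[1L] != -1L) {
    marks <- regmatches(esc, list(m))[[1L]]
    for (mk in marks) {
      id <- as.integer(gsub("[\x02\x03]", "", mk))
      anc <- if (id <= length(anchors)) anchors[id] else ""
      cap <- if (nzchar(anc)) paste0("(", anc, " .+?)") else "(.+?)"
      esc <- sub(mk, cap, esc, fixed = TRUE)
    }
  }
  paste0("^", esc, "$")
}

.tpl_slot_order <- function(tpl) {
  m <- gregexpr("\x02([0-9]+)\x03", tpl)[[1L]]
  if (m[1L] == -1L) return(integer())
  as.integer(gsub("[\x02\x03]", "", regmatches(tpl, list(m))[[1L]]))
}

.fill_tpl <- function(tgt_tpl, captures_by_id) {
  out <- tgt_tpl
  for (id in seq_along(captures_by_id)) {
    out <- gsub(paste0("\x02", id, "\x03"), captures_by_id[[id]], out,
                fixed = TRUE)
  }
  out
}

.new_store <- function() list()

.store_update <- function(store, src_tpl, tgt_tpl, anchors, step) {
  cur <- store[[src_tpl]]
  if (is.null(cur)) {
    store[[src_tpl]] <- list(tgt = tgt_tpl, count = 1L, step = step,
                             anchors = anchors)
  } else if (identical(cur$tgt, tgt_tpl)) {
    cur$count <- cur$count + 1L
    # instances with conflicting slot anchors unify to an unanchored slot
    if (length(cur$anchors) == length(anchors)) {
      cur$anchors[cur$anchors != anchors] <- ""
    }
    store[[src_tpl]] <- cur
  } else {
    # conflicting target for the same source pattern: later, more frequent
    # evidence wins (refinement overrides pretraining)
    cur$count <- cur$count - 1L
    if (cur$count <= 0L) {
      store[[src_tpl]] <- list(tgt = tgt_tpl, count = 1L, step = step,
                               anchors = anchors)
    } else {
      store[[src_tpl]] <- cur
    }
  }
  store
}

# ---- training --------------------------------------------------------------

.train_on <- function(store, corpus, steps, step_offset, checkpoint_every,
                      valid = NULL) {
  n <- nrow(corpus)
  stopifnot(n > 0L)
  losses <- numeric(steps)
  checkpoints <- list()
  delex <- vector("list", n)  # cache per-sample delexicalization
  for (s in seq_len(steps)) {
    i <- (s - 1L) %% n + 1L
    if (is.null(delex[[i]])) {
      delex[[i]] <- .delex_pair(corpus$sentence[i], corpus$actions[i])
    }
    d <- delex[[i]]
    # prequential sequence loss: does the current model already produce
    # this pair's target pattern?
    cur <- store[[d$src_tpl]]
    losses[s] <- as.numeric(is.null(cur) || !identical(cur$tgt, d$tgt_tpl))
    store <- .store_update(store, d$src_tpl, d$tgt_tpl, d$anchors,
                           step_offset + s)
    if (checkpoint_every > 0L &&
        (s %% checkpoint_every == 0L || s == steps)) {
      acc <- NA_real_
      if (!is.null(valid) && nrow(valid)) {
        preds <- .decode_store(store, valid$sentence, n_best = 1L)
        acc <- mean(preds == valid$actions)
      }
      checkpoints[[length(checkpoints) + 1L]] <-
        list(step = step_offset + s, accuracy = acc, store = store)
    }
  }
  list(store = store, losses = losses, checkpoints = checkpoints)
}

.decode_candidates <- function(store, sentence, beam_size = 10L) {
  s <- paste(.tokenize_ws(sentence), collapse = " ")
  cands <- list()
  for (src_tpl in names(store)) {
    re <- .tpl_regex(src_tpl, store[[src_tpl]]$anchors)
    m <- regexec(re, s, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    g <- regmatches(s, list(m))[[1L]]
    caps <- if (length(g) > 1L) g[-1L] else character()
    if (any(!nzchar(caps))) next
    order_ids <- .tpl_slot_order(src_tpl)
    caps_by_id <- character(max(c(order_ids, 0L)))
    if (length(order_ids)) caps_by_id[order_ids] <- caps
    out <- .fill_tpl(store[[src_tpl]]$tgt, as.list(caps_by_id))
    n_lit <- nchar(gsub("\x02[0-9]+\x03", "", src_tpl))
    cnt <- store[[src_tpl]]$count
    score <- n_lit + cnt / (cnt + 1)
    cands[[length(cands) + 1L]] <- list(text = out, score = score)
  }
  if (!length(cands)) {
    return(data.frame(text = "InvalidAction", score = -Inf,
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(text = vapply(cands, `[[`, "", "text"),
                   score = vapply(cands, `[[`, 0, "score"),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$text), , drop = FALSE]
  df <- df[!duplicated(df$text), , drop = FALSE]
  utils::head(df, beam_size)
}

.decode_store <- function(store, sentences, n_best = 1L, beam_size = 10L) {
  vapply(sentences, function(s) {
    .decode_candidates(store, s, beam_size)$text[1L]
  }, "", USE.NAMES = FALSE)
}

#' Pretrain a translation model on rule-generated pairs
#'
#' Trains the default engine for `config$train_steps` steps (one paired
#' sample per step, cycling through the corpus), logging a prequential
#' sequence loss and saving checkpoints every `config$checkpoint_every`
#' steps.  A shared subword vocabulary of `config$vocab_size` is built from
#' both sides of the training corpus.
#'
#' @param corpus data.frame with columns `sentence`, `actions`.
#' @param config a [seq2seq_config()]; use [desk_config()] for
#'   laptop-scale runs.
#' @param valid optional validation data.frame; checkpoint accuracies are
#'   computed on it.
#' @return object of class `seq2seq_model`.
#' @export
pretrain <- function(corpus, config = desk_config(), valid = NULL) {
  stopifnot(is.data.frame(corpus))
  if (!nrow(corpus)) stop("empty training corpus", call. = FALSE)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config$seed)
  vocab <- build_vocabulary(c(corpus$sentence, corpus$actions),
                            vocab_size = config$vocab_size)
  fit <- .train_on(.new_store(), corpus, config$train_steps, 0L,
                   config$checkpoint_every, valid)
  structure(list(engine = "template-induction",
                 store = fit$store, vocab = vocab, config = config,
                 steps_done = config$train_steps,
                 losses = fit$losses,
                 checkpoints = lapply(fit$checkpoints, function(ck) {
                   ck["store"] <- NULL
                   ck
                 }),
                 phase = "pretrained"),
            class = "seq2seq_model")
}

#' Refine a pretrained model on annotated pairs
#'
#' Continues training from the final state of the pretrained model on
#' (typically hand-annotated, possibly augmented) pairs, checkpointing
#' every `checkpoint_every` steps and computing validation exact-match
#' accuracy at each checkpoint.  The returned model is the checkpoint with
#' the highest validation accuracy (ties resolved towards the latest
#' step); all checkpoint statistics are kept in `$checkpoints`.
#'
#' @param model a pretrained `seq2seq_model`.
#' @param annotated_corpus data.frame with `sentence`, `actions`.
#' @param valid validation data.frame used for checkpoint selection.
#' @param train_steps,checkpoint_every overrides of the model's config.
#' @return a refined `seq2seq_model`.
#' @export
refine <- function(model, annotated_corpus, valid = NULL,
                   train_steps = NULL, checkpoint_every = NULL) {
  stopifnot(inherits(model, "seq2seq_model"), is.data.frame(annotated_corpus))
  if (!nrow(annotated_corpus)) stop("empty refinement corpus", call. = FALSE)
  cfg <- model$config
  steps <- if (is.null(train_steps)) cfg$train_steps else
    as.integer(train_steps)
  ck_every <- if (is.null(checkpoint_every)) cfg$checkpoint_every else
    as.integer(checkpoint_every)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(cfg$seed + 1L)
  fit <- .train_on(model$store, annotated_corpus, steps, model$steps_done,
                   ck_every, valid)
  ckpts <- fit$checkpoints
  accs <- vapply(ckpts, function(ck) ck$accuracy, 0)
  best_store <- fit$store
  best_step <- model$steps_done + steps
  if (length(ckpts) && !all(is.na(accs))) {
    # argmax validation accuracy; ties -> latest step
    best_i <- which(accs >= max(accs, na.rm = TRUE) - 1e-12)
    best_i <- best_i[length(best_i)]
    best_store <- ckpts[[best_i]]$store
    best_step <- ckpts[[best_i]]$step
  }
  out <- model
  out$store <- best_store
  out$steps_done <- best_step
  out$losses <- c(model$losses, fit$losses)
  out$checkpoints <- c(model$checkpoints,
                       lapply(ckpts, function(ck) {
                         ck["store"] <- NULL
                         ck
                       }))
  out$phase <- "refined"
  out
}

#' Translate sentences to ranked action strings
#'
#' Beam-search style n-best decoding: for each sentence, up to `n_best`
#' candidate action strings are returned, score-sorted and deterministic.
#' A sentence no stored pattern matches decodes to `InvalidAction` with
#' score `-Inf`.
#'
#' @param model a `seq2seq_model`.
#' @param sentences character vector.
#' @param beam_size beam width (`n_best <= beam_size`).
#' @param n_best number of ranked candidates per sentence.
#' @return data.frame with columns `sentence_index`, `rank`, `text`,
#'   `score`.
#' @export
translate <- function(model, sentences, beam_size = 10L, n_best = 1L) {
  stopifnot(inherits(model, "seq2seq_model"), n_best <= beam_size)
  out <- lapply(seq_along(sentences), function(i) {
    df <- .decode_candidates(model$store, sentences[i], beam_size)
    df <- utils::head(df, n_best)
    data.frame(sentence_index = i, rank = seq_len(nrow(df)),
               text = df$text, score = df$score,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
predict.seq2seq_model <- function(object, newdata, ...) {
  .decode_store(object$store, as.character(newdata))
}

#' Ensemble decoding over several models
#'
#' Models must share a vocabulary.  Candidates are pooled across models and
#' rescored by the mean of per-model scores (a model that cannot produce a
#' candidate contributes zero), then the best candidate per sentence is
#' returned.
#'
#' @param models list of `seq2seq_model` objects sharing a vocabulary.
#' @param sentences character vector.
#' @param beam_size per-model beam width.
#' @return character vector of best action strings.
#' @export
ensemble_translate <- function(models, sentences, beam_size = 10L) {
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, TRUE, "seq2seq_model")))
  ref <- models[[1L]]$vocab$tokens
  for (m in models[-1L]) {
    if (!identical(m$vocab$tokens, ref)) {
      stop("ensemble members use different vocabularies", call. = FALSE)
    }
  }
  vapply(sentences, function(s) {
    pool <- new.env(parent = emptyenv())
    for (m in models) {
      df <- .decode_candidates(m$store, s, beam_size)
      for (k in seq_len(nrow(df))) {
        if (!is.finite(df$score[k])) next
        key <- df$text[k]
        cur <- if (is.null(pool[[key]])) 0 else pool[[key]]
        pool[[key]] <- cur + df$score[k] / length(models)
      }
    }
    keys <- ls(pool)
    if (!length(keys)) return("InvalidAction")
    scores <- vapply(keys, function(k) pool[[k]], 0)
    keys[order(-scores, keys)][1L]
  }, "", USE.NAMES = FALSE)
}

#' Exact-sequence accuracy of a model on a paired corpus
#'
#' @param model a `seq2seq_model`.
#' @param corpus data.frame with `sentence`, `actions`.
#' @return fraction of sentences whose best decode equals the reference.
#' @export
seq2seq_accuracy <- function(model, corpus) {
  preds <- predict(model, corpus$sentence)
  mean(preds == corpus$actions)
}

#' @export
print.seq2seq_model <- function(x, ...) {
  cat("<seq2seq model> engine:", x$engine, "| phase:", x$phase,
      "| steps:", x$steps_done,
      "| patterns:", length(x$store),
      "| vocab:", x$vocab$size, "\n")
  invisible(x)
}

#' Save / load a translation model
#'
#' Models serialize to JSON (templates, counts, vocabulary, configuration),
#' so checkpoints are plain text and portable.
#'
#' @param model a `seq2seq_model`.
#' @param path file path.
#' @return `load_seq2seq()` returns the model; `save_seq2seq()` the path,
#'   invisibly.
#' @export
save_seq2seq <- function(model, path) {
  stopifnot(inherits(model, "seq2seq_model"))
  payload <- list(
    engine = model$engine, phase = model$phase,
    steps_done = model$steps_done,
    config = unclass(model$config),
    vocab = unclass(model$vocab),
    store = lapply(model$store, function(e) {
      list(tgt = e$tgt, count = e$count, step = e$step,
           anchors = as.list(e$anchors))
    }),
    store_keys = names(model$store))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_seq2seq
#' @export
load_seq2seq <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  store <- lapply(x$store, function(e) {
    list(tgt = e$tgt, count = as.integer(e$count), step = as.integer(e$step),
         anchors = as.character(unlist(e$anchors)))
  })
  names(store) <- unlist(x$store_keys)
  cfg <- do.call(seq2seq_config, x$config[names(x$config) %in%
                                            names(formals(seq2seq_config))])
  vocab <- structure(list(tokens = unlist(x$vocab$tokens),
                          merges = as.character(unlist(x$vocab$merges)),
                          size = as.integer(x$vocab$size)),
                     class = "subword_vocab")
  structure(list(engine = x$engine, store = store, vocab = vocab,
                 config = cfg, steps_done = as.integer(x$steps_done),
                 losses = numeric(), checkpoints = list(),
                 phase = x$phase),
            class = "seq2seq_model")
}
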