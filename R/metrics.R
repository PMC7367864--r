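# Evaluation metrics for predicted action strings: validity, adapted
# corpus BLEU, normalized Levenshtein similarity, threshold accuracies,
# and the per-action-type confusion ledger.

#' Validity of predicted action strings
#'
#' The fraction of predictions that can be converted back to actions
#' without error, i.e. for which [parse_actions()] succeeds.  Computed on
#' the raw strings, before any normalization.
#'
#' @param predictions character vector of action strings.
#' @return fraction in `[0, 1]`.
#' @export
#' @examples
#' validity(c("Concentrate", "garbage!!"))
validity <- function(predictions) {
  stopifnot(is.character(predictions))
  if (!length(predictions)) return(NaN)
  ok <- vapply(predictions,
               function(s) !is_parse_error(parse_actions(s)), TRUE,
               USE.NAMES = FALSE)
  mean(ok)
}

#' Normalized Levenshtein similarity
#'
#' One minus the character-level edit distance divided by the longer
#' string's length; two empty strings are identical (similarity 1).
#'
#' @param pred,ref character vectors (recycled to common length).
#' @return numeric vector of similarities in `[0, 1]`.
#' @export
#' @examples
#' levenshtein_similarity("abc", "abd")
levenshtein_similarity <- function(pred, ref) {
  n <- max(length(pred), length(ref))
  pred <- rep_len(as.character(pred), n)
  ref <- rep_len(as.character(ref), n)
  vapply(seq_len(n), function(i) {
    mx <- max(nchar(pred[i]), nchar(ref[i]))
    if (mx == 0L) return(1)
    d <- utils::adist(pred[i], ref[i])[1L, 1L]
    1 - d / mx
  }, 0)
}

#' Threshold accuracies over a set of similarities
#'
#' The 100%, 90% and 75% accuracies: fractions of sentences whose
#' normalized Levenshtein similarity is at least 1.0, 0.9 and 0.75.  By
#' construction `acc100 <= acc90 <= acc75`.
#'
#' @param similarities numeric vector of values in `[0, 1]` (non-empty).
#' @return named numeric vector `c(acc100=, acc90=, acc75=)`.
#' @export
#' @examples
#' threshold_accuracies(c(1.0, 0.95, 0.80, 0.50))
threshold_accuracies <- function(similarities) {
  if (!length(similarities)) {
    stop("threshold accuracies are undefined for an empty set",
         call. = FALSE)
  }
  stopifnot(all(similarities >= -1e-9 & similarities <= 1 + 1e-9))
  eps <- 1e-9
  c(acc100 = mean(similarities >= 1 - eps),
    acc90 = mean(similarities >= 0.9 - eps),
    acc75 = mean(similarities >= 0.75 - eps))
}

.ngram_counts <- function(tokens, n) {
  if (length(tokens) < n) return(integer(0))
  grams <- vapply(seq_len(length(tokens) - n + 1L), function(i) {
    paste(tokens[i:(i + n - 1L)], collapse = "\x1f")
  }, "")
  table(grams)
}

#' Adapted corpus BLEU
#'
#' Corpus-level BLEU on whitespace tokens with the usual geometric mean of
#' modified n-gram precisions (orders 1–4) and brevity penalty, adapted so
#' that short references are not penalized: for each sentence pair, n-gram
#' orders above `min(4, length of the shorter side)` are skipped for that
#' pair.  When every pair has at least four words on both sides, standard
#' BLEU is recovered.  A single-word exact pair scores 1, not 0.
#'
#' @param pred_corpus,ref_corpus aligned character vectors.
#' @return BLEU score in `[0, 1]`.
#' @export
#' @examples
#' adapted_bleu("Filter keep filtrate", "Filter keep filtrate")
adapted_bleu <- function(pred_corpus, ref_corpus) {
  if (length(pred_corpus) != length(ref_corpus)) {
    stop("prediction and reference corpora differ in length", call. = FALSE)
  }
  if (!length(pred_corpus)) return(NaN)
  num <- den <- numeric(4L)
  pred_len <- ref_len <- 0
  for (i in seq_along(pred_corpus)) {
    pt <- strsplit(trimws(pred_corpus[i]), "\\s+")[[1L]]
    rt <- strsplit(trimws(ref_corpus[i]), "\\s+")[[1L]]
    pt <- pt[nzchar(pt)]
    rt <- rt[nzchar(rt)]
    pred_len <- pred_len + length(pt)
    ref_len <- ref_len + length(rt)
    cap <- min(4L, length(pt), length(rt))
    if (cap < 1L) next
    for (n in seq_len(cap)) {
      pg <- .ngram_counts(pt, n)
      rg <- .ngram_counts(rt, n)
      if (!length(pg)) next
      clipped <- sum(pmin(pg, rg[match(names(pg), names(rg))]),
                     na.rm = TRUE)
      num[n] <- num[n] + clipped
      den[n] <- den[n] + sum(pg)
    }
  }
  used <- which(den > 0)
  if (!length(used)) return(0)
  precisions <- num[used] / den[used]
  if (any(precisions == 0)) return(0)
  bp <- if (pred_len >= ref_len || pred_len == 0) 1 else
    exp(1 - ref_len / pred_len)
  bp * exp(mean(log(precisions)))
}

# deterministic edit-script alignment of two action-type sequences:
# prefer matches, then substitutions, leftmost-first
.align_types <- function(ptypes, rtypes) {
  np <- length(ptypes)
  nr <- length(rtypes)
  D <- matrix(0L, nr + 1L, np + 1L)
  D[1L, ] <- 0L:np
  D[, 1L] <- 0L:nr
  for (i in seq_len(nr)) {
    for (j in seq_len(np)) {
      sub_cost <- D[i, j] + (rtypes[i] != ptypes[j])
      D[i + 1L, j + 1L] <- min(sub_cost, D[i, j + 1L] + 1L,
                               D[i + 1L, j] + 1L)
    }
  }
  ops <- list()
  i <- nr
  j <- np
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        D[i + 1L, j + 1L] == D[i, j] + (rtypes[i] != ptypes[j])) {
      ops[[length(ops) + 1L]] <-
        list(op = if (rtypes[i] == ptypes[j]) "match" else "sub",
             ref = i, pred = j)
      i <- i - 1L
      j <- j - 1L
    } else if (i > 0L && D[i + 1L, j + 1L] == D[i, j + 1L] + 1L) {
      ops[[length(ops) + 1L]] <- list(op = "del", ref = i, pred = NA)
      i <- i - 1L
    } else {
      ops[[length(ops) + 1L]] <- list(op = "ins", ref = NA, pred = j)
      j <- j - 1L
    }
  }
  rev(ops)
}

#' Per-action-type confusion ledger
#'
#' For each aligned sentence, predicted and reference actions are aligned
#' by a minimal edit script over action types (ties broken by preferring
#' matches, then substitutions, leftmost-first).  Type-equal aligned pairs
#' increment `type_match`; pairs equal in every property additionally
#' increment `full_match`; insertions count as `only_in_prediction`,
#' deletions as `only_in_ground_truth`, and substitutions populate the
#' off-diagonal confusion matrix.
#'
#' @param pred_seqs,ref_seqs aligned lists of [action_sequence()] objects
#'   or action strings (unparseable predictions count as `InvalidAction`).
#' @return object of class `confusion_ledger`: a list with `table` (one row
#'   per action type: `type_match`, `full_match`, `only_in_prediction`,
#'   `only_in_ground_truth`) and `substitutions` (reference x prediction
#'   count matrix).
#' @export
confusion_ledger <- function(pred_seqs, ref_seqs) {
  stopifnot(length(pred_seqs) == length(ref_seqs))
  as_seq <- function(x) {
    if (inherits(x, "action_sequence")) return(x)
    p <- parse_actions(as.character(x))
    if (is_parse_error(p)) action_sequence(action("InvalidAction")) else p
  }
  types <- action_types()
  tab <- matrix(0L, length(types), 4L,
                dimnames = list(types, c("type_match", "full_match",
                                         "only_in_prediction",
                                         "only_in_ground_truth")))
  subs <- matrix(0L, length(types), length(types),
                 dimnames = list(ref = types, pred = types))
  for (k in seq_along(pred_seqs)) {
    pseq <- as_seq(pred_seqs[[k]])
    rseq <- as_seq(ref_seqs[[k]])
    pty <- vapply(unclass(pseq), `[[`, "", "type")
    rty <- vapply(unclass(rseq), `[[`, "", "type")
    pser <- vapply(unclass(pseq), function(a) {
      serialize_actions(action_sequence(a), validate = FALSE)
    }, "")
    rser <- vapply(unclass(rseq), function(a) {
      serialize_actions(action_sequence(a), validate = FALSE)
    }, "")
    for (op in .align_types(pty, rty)) {
      switch(op$op,
        match = {
          tab[rty[op$ref], "type_match"] <-
            tab[rty[op$ref], "type_match"] + 1L
          if (identical(pser[op$pred], rser[op$ref])) {
            tab[rty[op$ref], "full_match"] <-
              tab[rty[op$ref], "full_match"] + 1L
          }
        },
        sub = {
          subs[rty[op$ref], pty[op$pred]] <-
            subs[rty[op$ref], pty[op$pred]] + 1L
        },
        ins = {
          tab[pty[op$pred], "only_in_prediction"] <-
            tab[pty[op$pred], "only_in_prediction"] + 1L
        },
        del = {
          tab[rty[op$ref], "only_in_ground_truth"] <-
            tab[rty[op$ref], "only_in_ground_truth"] + 1L
        })
    }
  }
  structure(list(table = as.data.frame(tab), substitutions = subs),
            class = "confusion_ledger")
}

#' @export
print.confusion_ledger <- function(x, ...) {
  tab <- x$table[rowSums(x$table) > 0, , drop = FALSE]
  tab <- tab[order(-tab$type_match), , drop = FALSE]
  print(tab)
  nsub <- sum(x$substitutions)
  cat("substitutions:", nsub, "\n")
  invisible(x)
}

#' Action-type and length distributions of a corpus
#'
#' @param corpus data.frame with an `actions` column of action strings, or
#'   a list of [action_sequence()] objects.
#' @return list with `type_counts` (named integer vector, decreasing),
#'   `actions_per_sentence` and `chars_per_sentence` (when sentences are
#'   available) integer vectors.
#' @export
action_distribution <- function(corpus) {
  if (is.data.frame(corpus)) {
    seqs <- lapply(corpus$actions, function(s) {
      p <- parse_actions(s)
      if (is_parse_error(p)) action_sequence(action("InvalidAction")) else p
    })
    chars <- if ("sentence" %in% names(corpus)) nchar(corpus$sentence)
             else integer()
  } else {
    seqs <- corpus
    chars <- integer()
  }
  types <- unlist(lapply(seqs, function(sq) {
    vapply(unclass(sq), `[[`, "", "type")
  }))
  counts <- sort(table(types), decreasing = TRUE)
  list(type_counts = stats::setNames(as.integer(counts), names(counts)),
       actions_per_sentence = vapply(seqs, length, 0L),
       chars_per_sentence = chars)
}

#' Full metric report for a prediction set
#'
#' Computes validity on the raw predictions, then converts unparseable
#' predictions to `InvalidAction` (as in the deployed pipeline) and
#' computes adapted BLEU, mean normalized Levenshtein similarity and the
#' 100/90/75% threshold accuracies against the references.
#'
#' @param predictions,references aligned character vectors of action
#'   strings.
#' @return object of class `metrics_report` with fields `validity`, `bleu`,
#'   `levenshtein_similarity`, `acc100`, `acc90`, `acc75`, `n`.
#' @export
evaluate_predictions <- function(predictions, references) {
  stopifnot(length(predictions) == length(references))
  val <- validity(predictions)
  fixed <- vapply(predictions, function(s) {
    if (is_parse_error(parse_actions(s))) "InvalidAction" else s
  }, "", USE.NAMES = FALSE)
  sims <- levenshtein_similarity(fixed, references)
  accs <- threshold_accuracies(sims)
  structure(list(validity = val,
                 bleu = adapted_bleu(fixed, references),
                 levenshtein_similarity = mean(sims),
                 acc100 = accs[["acc100"]], acc90 = accs[["acc90"]],
                 acc75 = accs[["acc75"]],
                 n = length(predictions)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    paste0("action extraction metrics (n = %d)\n",
           "  validity:                %6.1f %%\n",
           "  BLEU (adapted):          %6.1f %%\n",
           "  Levenshtein similarity:  %6.1f %%\n",
           "  100%% accuracy:           %6.1f %%\n",
           "  90%% accuracy:            %6.1f %%\n",
           "  75%% accuracy:            %6.1f %%\n"),
    x$n, 100 * x$validity, 100 * x$bleu, 100 * x$levenshtein_similarity,
    100 * x$acc100, 100 * x$acc90, 100 * x$acc75))
  invisible(x)
}
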