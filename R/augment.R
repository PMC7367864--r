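# Entity-substitution data augmentation.  Compound names, quantities,
# durations and temperatures found in a sentence are each replaced, with a
# fixed probability, by a random draw from a substitution pool; the same
# replacement is applied to the paired action string, so the alignment
# between sentence and actions is preserved.  Substitution is deliberately
# not chemistry-aware: the goal is linguistic variety, not plausible
# recipes.

.POOL_FOR_LABEL <- c(COMPOUND = "compounds", QUANTITY = "quantities",
                     DURATION = "durations", TEMPERATURE = "temperatures")

#' Augment one paired sample by entity substitution
#'
#' Each taggable entity (compound, quantity, duration, temperature) is
#' independently replaced with probability `p` by a draw from the matching
#' pool.  The identical replacement is applied to the action string, so
#' every entity string appearing in the actions still appears in the
#' sentence afterwards.
#'
#' @param sample list or one-row data.frame with `sentence` and `actions`.
#' @param pools a [generate_pools()] object (or compatible list).
#' @param p substitution probability in `[0, 1]` (default 0.5, the standard
#'   setting).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (so corpus-level augmentation controls determinism).
#' @return list with `sentence`, `actions` and `n_substituted`.
#' @export
#' @examples
#' pools <- generate_pools(seed = 1)
#' s <- list(sentence = "The mixture was stirred for 2 h at 0 °C.",
#'           actions = "Stir for 2 h at 0 °C")
#' augment_sample(s, pools, p = 1, seed = 42)
augment_sample <- function(sample, pools, p = 0.5, seed = NULL) {
  stopifnot(p >= 0, p <= 1)
  sentence <- as.character(sample$sentence)[1L]
  actions <- as.character(sample$actions)[1L]
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
  }
  tags <- tag_entities(sentence)
  tags <- tags[tags$label %in% names(.POOL_FOR_LABEL), , drop = FALSE]
  n_sub <- 0L
  if (nrow(tags)) {
    # right-to-left so earlier spans stay valid while splicing
    tags <- tags[order(-tags$start), , drop = FALSE]
    for (i in seq_len(nrow(tags))) {
      pool_name <- .POOL_FOR_LABEL[[tags$label[i]]]
      pool <- pools[[pool_name]]
      if (!length(pool)) {
        stop("empty substitution pool for ", pool_name, call. = FALSE)
      }
      if (stats::runif(1L) >= p) next
      value <- tags$value[i]
      repl <- sample(pool, 1L)
      sentence <- paste0(substr(sentence, 1L, tags$start[i]),
                         repl,
                         substr(sentence, tags$end[i] + 1L,
                                nchar(sentence)))
      actions <- gsub(value, repl, actions, fixed = TRUE)
      n_sub <- n_sub + 1L
    }
  }
  list(sentence = sentence, actions = actions, n_substituted = n_sub)
}

#' Augment a corpus up to a target size
#'
#' The original samples are kept and repeatedly augmented (cycling through
#' the corpus) until `n_target` samples exist.  With `dedup = TRUE`,
#' duplicate (sentence, actions) pairs are removed afterwards — the
#' "augmented unique" variant — so the output may then be smaller than
#' `n_target`.
#'
#' @param samples data.frame with columns `sentence`, `actions`.
#' @param pools a [generate_pools()] object.
#' @param p per-entity substitution probability.
#' @param n_target total number of samples to produce (`>= nrow(samples)`).
#' @param dedup drop duplicate pairs after augmentation.
#' @param seed integer seed for the whole augmentation run.
#' @return data.frame with columns `sentence`, `actions`, `source`.
#' @export
augment_corpus <- function(samples, pools, p = 0.5, n_target = nrow(samples),
                           dedup = FALSE, seed = 1L) {
  stopifnot(is.data.frame(samples), n_target >= nrow(samples))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  n0 <- nrow(samples)
  out_sent <- samples$sentence
  out_act <- samples$actions
  i <- 0L
  while (length(out_sent) < n_target) {
    i <- i %% n0 + 1L
    aug <- augment_sample(list(sentence = samples$sentence[i],
                               actions = samples$actions[i]),
                          pools, p = p)
    out_sent <- c(out_sent, aug$sentence)
    out_act <- c(out_act, aug$actions)
  }
  res <- data.frame(sentence = out_sent, actions = out_act,
                    source = c(rep("original", n0),
                               rep("augmented", length(out_sent) - n0)),
                    stringsAsFactors = FALSE)
  if (dedup) {
    res <- res[!duplicated(paste(res$sentence, res$actions, sep = "\t")), ,
               drop = FALSE]
    rownames(res) <- NULL
  }
  res
}
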