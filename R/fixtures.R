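# Seeded grammar-based generator of synthetic experimental-procedure
# sentences with exact ground-truth action sequences, plus substitution
# pools for data augmentation.  Compound names are syntactic stand-ins
# (chemically plausible-looking, not real recipes); the generator is the
# package's no-download test and training substrate.

.POOL_PREFIXES <- c(
  "2-chloro", "3-bromo", "4-fluoro", "2,4-dichloro", "4-methoxy",
  "3-nitro", "2-methyl", "4-cyano", "3,5-dimethyl", "2-amino",
  "4-hydroxy", "3-ethyl", "2-fluoro", "4-bromo", "3-methoxy",
  "2,6-difluoro", "4-nitro", "3-chloro", "2-ethoxy", "4-methyl"
)
.POOL_CORES <- c(
  "benzaldehyde", "aniline", "phenol", "benzamide", "pyridine",
  "quinoline", "indole", "acetophenone", "toluene", "benzonitrile",
  "benzoic acid", "styrene", "naphthalene", "pyrimidine", "thiophene",
  "imidazole", "piperidine", "morpholine", "pyrazole", "benzofuran"
)
.POOL_SOLVENTS <- c(
  "methanol", "ethanol", "dichloromethane", "ethyl acetate", "THF",
  "toluene", "acetonitrile", "DMF", "diethyl ether", "n-hexane",
  "water", "dioxane", "acetone", "DMSO"
)
.POOL_WASHES <- c(
  "brine", "water", "saturated sodium bicarbonate",
  "aqueous sodium hydroxide", "saturated ammonium chloride")
.POOL_DESICCANTS <- c("sodium sulfate", "magnesium sulfate",
                      "anhydrous sodium sulfate",
                      "anhydrous magnesium sulfate")
.POOL_ACIDS <- c("hydrochloric acid", "10% hydrochloric acid",
                 "acetic acid", "aqueous sodium hydroxide")

.rand_compound <- function() {
  pre <- sample(.POOL_PREFIXES, 1L)
  core <- sample(.POOL_CORES, 1L)
  core1 <- sub("^([a-z])", "\\1", core)
  nm <- paste0(pre, core1)
  if (stats::runif(1) < 0.25) nm <- paste("methyl", nm)
  nm
}

.rand_num <- function(lo, hi, digits = 1L) {
  formatC(round(stats::runif(1L, lo, hi), digits), format = "fg")
}

.rand_mass <- function() paste0(.rand_num(0.1, 25, 2L), " g")
.rand_volume <- function() paste0(.rand_num(1, 250, 1L), " mL")
.rand_amount <- function() paste0(.rand_num(0.5, 120, 1L), " mmol")
.rand_conc <- function() paste0(sample(c(1, 2, 4, 6, 10), 1L), " M")
.rand_quantity <- function() {
  switch(sample(4L, 1L), .rand_mass(), .rand_volume(), .rand_amount(),
         .rand_conc())
}
.rand_duration <- function() {
  if (stats::runif(1) < 0.12) return("overnight")
  if (stats::runif(1) < 0.5) paste(sample(c(5, 10, 15, 20, 30, 45, 90), 1L), "min")
  else paste(sample(c(1, 2, 3, 4, 6, 12, 16, 24), 1L), "h")
}
.rand_temperature <- function() {
  if (stats::runif(1) < 0.3) return("room temperature")
  paste0(sample(c(-78, -20, 0, 5, 25, 40, 50, 60, 80, 100, 110, 120), 1L),
         " °C")
}
.rand_gas <- function() sample(c("nitrogen", "argon"), 1L)

#' Substitution pools for data augmentation
#'
#' Deterministically generates pools of compound names, raw quantity
#' strings (units g, mg, mL, mmol, mol, M), durations and temperatures.
#' These synthetic pools stand in for lists compiled from a licensed
#' reaction dataset; they are labelled synthetic and are chemically
#' superficial on purpose.
#'
#' @param seed integer seed.
#' @param n pool size per category.
#' @return an object of class `substitution_pools` with fields `compounds`,
#'   `quantities`, `durations`, `temperatures`.
#' @export
#' @examples
#' pools <- generate_pools(seed = 1)
#' lengths(unclass(pools))
generate_pools <- function(seed = 1L, n = 60L) {
  stopifnot(n >= 1L)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  pools <- list(
    compounds = unique(replicate(n, .rand_compound())),
    quantities = unique(replicate(n, .rand_quantity())),
    durations = unique(replicate(n, .rand_duration())),
    temperatures = unique(replicate(n, .rand_temperature()))
  )
  stopifnot(all(lengths(pools) > 0L))
  structure(pools, class = "substitution_pools")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# ---- sentence templates ----------------------------------------------------
# Each template returns list(sentence = ..., actions = action_sequence).
# The ground truth is constructed jointly with the sentence, so it is exact
# by construction; all templates stay within the shipped verb lexicon.

.TEMPLATES <- list(

  add_passive = function() {
    cm <- .rand_compound(); q <- c(.rand_mass(), .rand_amount())
    dw <- stats::runif(1) < 0.2
    tp <- if (stats::runif(1) < 0.4) .rand_temperature()
    sent <- paste0(cm, " (", paste(q, collapse = ", "),
                   ") was added to the reaction mixture",
                   if (dw) " dropwise",
                   if (!is.null(tp)) paste0(" at ", tp), ".")
    list(sentence = sent,
         actions = action_sequence(action("Add",
                                          list(chemical(cm, q)),
                                          dropwise = if (dw) TRUE,
                                          temperature = tp)))
  },

  add_to_solution = function() {
    a <- .rand_compound(); qa <- .rand_mass()
    s <- sample(.POOL_SOLVENTS, 1L); qs <- .rand_volume()
    b <- .rand_compound(); qb <- .rand_amount()
    tp <- if (stats::runif(1) < 0.5) .rand_temperature()
    sent <- paste0("To a solution of ", a, " (", qa, ") in ", s, " (", qs,
                   ") was added ", b, " (", qb, ")",
                   if (!is.null(tp)) paste0(" at ", tp), ".")
    list(sentence = sent,
         actions = action_sequence(
           action("MakeSolution", list(chemical(a, qa), chemical(s, qs))),
           action("Add", list(chemical("SLN"))),
           action("Add", list(chemical(b, qb)), temperature = tp)))
  },

  dissolve = function() {
    a <- .rand_compound(); q <- c(.rand_mass(), .rand_amount())
    s <- sample(.POOL_SOLVENTS, 1L); qs <- .rand_volume()
    gas <- if (stats::runif(1) < 0.3) .rand_gas()
    sent <- paste0(a, " (", paste(q, collapse = ", "),
                   ") was dissolved in ", s, " (", qs, ")",
                   if (!is.null(gas)) paste0(" under ", gas, " atmosphere"),
                   ".")
    list(sentence = sent,
         actions = action_sequence(
           action("Add", list(chemical(a, q))),
           action("Add", list(chemical(s, qs)), atmosphere = gas)))
  },

  stir = function() {
    d <- .rand_duration(); tp <- if (stats::runif(1) < 0.7) .rand_temperature()
    sent <- paste0("The mixture was stirred for ", d,
                   if (!is.null(tp)) paste0(" at ", tp), ".")
    list(sentence = sent,
         actions = action_sequence(action("Stir", duration = d,
                                          temperature = tp)))
  },

  heat_settemp = function() {
    tp <- .rand_temperature()
    sent <- paste0("The reaction mixture was heated to ", tp, ".")
    list(sentence = sent,
         actions = action_sequence(action("SetTemperature",
                                          temperature = tp)))
  },

  heat_stir = function() {
    tp <- .rand_temperature(); d <- .rand_duration()
    sent <- paste0("The mixture was heated at ", tp, " for ", d, ".")
    list(sentence = sent,
         actions = action_sequence(action("Stir", duration = d,
                                          temperature = tp)))
  },

  wait_then_add = function() {
    d <- .rand_duration(); b <- .rand_compound(); qb <- .rand_mass()
    sent <- paste0("After ", d, ", ", b, " (", qb, ") was added.")
    list(sentence = sent,
         actions = action_sequence(action("Wait", duration = d),
                                   action("Add", list(chemical(b, qb)))))
  },

  quench = function() {
    w <- sample(c("water", "saturated ammonium chloride", "methanol"), 1L)
    tp <- if (stats::runif(1) < 0.3) .rand_temperature()
    sent <- paste0("The reaction was quenched with ", w,
                   if (!is.null(tp)) paste0(" at ", tp), ".")
    list(sentence = sent,
         actions = action_sequence(action("Quench", list(chemical(w)),
                                          temperature = tp)))
  },

  wash = function() {
    n <- sample(2L, 1L)
    ws <- sample(.POOL_WASHES, n)
    sent <- paste0("The organic layer was washed with ",
                   paste(ws, collapse = " and "), ".")
    acts <- c(list(action("CollectLayer", keep_phase = "organic")),
              lapply(ws, function(w) action("Wash", list(chemical(w)))))
    list(sentence = sent, actions = action_sequence(acts))
  },

  dry = function() {
    des <- sample(.POOL_DESICCANTS, 1L)
    sent <- paste0("The combined organic layers were dried over ", des, ".")
    list(sentence = sent,
         actions = action_sequence(
           action("CollectLayer", keep_phase = "organic"),
           action("DrySolution", list(chemical(des)))))
  },

  filter_concentrate = function() {
    sent <- "The mixture was filtered and concentrated in vacuo."
    list(sentence = sent,
         actions = action_sequence(action("Filter", keep_phase = "filtrate"),
                                   action("Concentrate")))
  },

  concentrate = function() {
    sent <- sample(c("The solvent was removed under reduced pressure.",
                     "The resulting mixture was concentrated in vacuo.",
                     "The solvent was evaporated under reduced pressure."),
                   1L)
    list(sentence = sent,
         actions = action_sequence(action("Concentrate")))
  },

  purify = function() {
    sent <- sample(
      c("The residue was purified by column chromatography.",
        "The crude product was purified by column chromatography on silica gel."),
      1L)
    list(sentence = sent, actions = action_sequence(action("Purify")))
  },

  yield = function() {
    q <- c(.rand_mass(), .rand_amount())
    sent <- paste0("The title compound was obtained as a white solid (",
                   paste(q, collapse = ", "), ").")
    list(sentence = sent,
         actions = action_sequence(
           action("Yield", list(chemical("title compound", q)))))
  },

  ph = function() {
    v <- sample(c(1, 1.5, 2, 4, 7, 9, 10, 12), 1L)
    acid <- sample(.POOL_ACIDS, 1L)
    sent <- paste0("The mixture was adjusted to pH ", format(v, trim = TRUE),
                   " with ", acid, ".")
    list(sentence = sent,
         actions = action_sequence(action("PH", list(chemical(acid)),
                                          ph_value = v)))
  },

  reflux = function() {
    d <- .rand_duration()
    sent <- paste0("The mixture was heated to reflux for ", d, ".")
    list(sentence = sent,
         actions = action_sequence(action("Reflux", duration = d)))
  },

  extract = function() {
    s <- sample(c("ethyl acetate", "dichloromethane", "diethyl ether"), 1L)
    qv <- .rand_volume()
    sent <- paste0("The aqueous layer was extracted with ", s, " (", qv,
                   ").")
    list(sentence = sent,
         actions = action_sequence(
           action("CollectLayer", keep_phase = "aqueous"),
           action("Extract", list(chemical(s, qv)))))
  },

  partition = function() {
    s1 <- "ethyl acetate"; s2 <- "water"
    q1 <- .rand_volume(); q2 <- .rand_volume()
    sent <- paste0("The residue was partitioned between ", s1, " (", q1,
                   ") and ", s2, " (", q2, ").")
    list(sentence = sent,
         actions = action_sequence(
           action("Partition", list(chemical(s1, q1), chemical(s2, q2)))))
  },

  phase_separation = function() {
    sent <- "The layers were separated."
    list(sentence = sent,
         actions = action_sequence(action("PhaseSeparation")))
  },

  collect_separate = function() {
    sent <- "The organic layer was separated."
    list(sentence = sent,
         actions = action_sequence(
           action("PhaseSeparation"),
           action("CollectLayer", keep_phase = "organic")))
  },

  dry_solid = function() {
    tp <- .rand_temperature()
    sent <- paste0("The solid was dried at ", tp, ".")
    list(sentence = sent,
         actions = action_sequence(action("DrySolid", temperature = tp)))
  },

  wait_stand = function() {
    d <- .rand_duration()
    sent <- paste0("The mixture was allowed to stand for ", d, ".")
    list(sentence = sent,
         actions = action_sequence(action("Wait", duration = d)))
  },

  solution_heated = function() {
    a <- .rand_compound(); qa <- .rand_mass()
    s <- sample(.POOL_SOLVENTS, 1L); qs <- .rand_volume()
    tp <- .rand_temperature()
    sent <- paste0(qa, " of ", a, " in ", qs, " of ", s,
                   " was heated to ", tp, ".")
    list(sentence = sent,
         actions = action_sequence(
           action("MakeSolution", list(chemical(a, qa), chemical(s, qs))),
           action("Add", list(chemical("SLN"))),
           action("SetTemperature", temperature = tp)))
  },

  recrystallize = function() {
    s <- sample(c("ethanol", "methanol", "toluene"), 1L)
    qv <- .rand_volume()
    sent <- paste0("The crude product was recrystallized from ", s, " (",
                   qv, ").")
    list(sentence = sent,
         actions = action_sequence(
           action("Recrystallize", list(chemical(s, qv)))))
  },

  triturate = function() {
    s <- sample(c("diethyl ether", "n-hexane", "acetone"), 1L)
    sent <- paste0("The residue was triturated with ", s, ".")
    list(sentence = sent,
         actions = action_sequence(action("Triturate",
                                          list(chemical(s)))))
  },

  sonicate = function() {
    d <- .rand_duration()
    sent <- paste0("The mixture was sonicated for ", d, ".")
    list(sentence = sent,
         actions = action_sequence(action("Sonicate", duration = d)))
  },

  degas = function() {
    g <- .rand_gas(); d <- .rand_duration()
    sent <- paste0("The solution was purged with ", g, " for ", d, ".")
    list(sentence = sent,
         actions = action_sequence(action("Degas", atmosphere = g,
                                          duration = d)))
  },

  microwave = function() {
    tp <- .rand_temperature(); d <- .rand_duration()
    sent <- paste0("The mixture was heated in the microwave at ", tp,
                   " for ", d, ".")
    list(sentence = sent,
         actions = action_sequence(action("Microwave", duration = d,
                                          temperature = tp)))
  },

  follow_other = function() {
    sent <- paste0("The title compound was prepared as described in Example ",
                   sample(50L, 1L), ".")
    list(sentence = sent,
         actions = action_sequence(action("FollowOtherProcedure")))
  },

  no_action = function() {
    sent <- sample(c(
      "1H NMR (400 MHz, CDCl3): δ 7.25 (m, 2H), 3.80 (s, 3H).",
      "MS (ESI): m/z 312.1 [M+H]+.",
      "m.p. 120-122 °C."), 1L)
    list(sentence = sent, actions = action_sequence(action("NoAction")))
  },

  other_language = function() {
    sent <- sample(c(
      "Das Gemisch wurde zwei Stunden bei Raumtemperatur geruehrt.",
      "Le melange est agite pendant deux heures a temperature ambiante."),
      1L)
    list(sentence = sent,
         actions = action_sequence(action("OtherLanguage")))
  }
)

# Default template weights, shaped like the action-frequency profile of
# patent procedures: additions, stirring and concentration dominate;
# recrystallization, microwaving and sonication are rare.
.DEFAULT_WEIGHTS <- c(
  add_passive = 16, add_to_solution = 7, dissolve = 8, stir = 12,
  heat_settemp = 4, heat_stir = 4, wait_then_add = 6, quench = 3,
  wash = 7, dry = 6, filter_concentrate = 5, concentrate = 8, purify = 5,
  yield = 5, ph = 2, reflux = 2, extract = 3, partition = 1,
  phase_separation = 2, collect_separate = 2, dry_solid = 1.5,
  wait_stand = 2, solution_heated = 2, recrystallize = 0.8,
  triturate = 0.8, sonicate = 0.5, degas = 0.5, microwave = 0.5,
  follow_other = 1, no_action = 2, other_language = 0.5
)

.NOISE_VERBS <- c("vortexed", "centrifuged", "lyophilized", "blorbified",
                  "spin-coated")

#' Generator configuration
#'
#' @param n_samples number of paired samples to generate.
#' @param seed integer seed; same config + seed gives an identical corpus.
#' @param weights named non-negative template weights (defaults emulate the
#'   action-frequency profile of patent procedures).
#' @param noise if `TRUE`, a fraction of sentences receive out-of-lexicon
#'   verbs (ground truth `InvalidAction`) or letter-swap typos, to exercise
#'   robustness rather than correctness.
#' @param noise_rate fraction of noised sentences when `noise` is on.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_samples = 100L, seed = 1L,
                             weights = .DEFAULT_WEIGHTS, noise = FALSE,
                             noise_rate = 0.2) {
  stopifnot(n_samples >= 0L, is.numeric(weights), all(weights >= 0),
            sum(weights) > 0, all(names(weights) %in% names(.TEMPLATES)))
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("weights must be named by template")
  }
  structure(list(n_samples = as.integer(n_samples),
                 seed = as.integer(seed), weights = weights,
                 noise = isTRUE(noise), noise_rate = noise_rate),
            class = "generator_config")
}

.swap_typo <- function(word) {
  n <- nchar(word)
  if (n < 4L) return(word)
  i <- sample(seq_len(n - 1L)[-1L], 1L)
  paste0(substr(word, 1L, i - 1L), substr(word, i + 1L, i + 1L),
         substr(word, i, i), substr(word, i + 2L, n))
}

#' Generate a synthetic paired corpus
#'
#' Draws sentences from weighted templates covering every laboratory action
#' type; each sample's ground-truth action sequence is constructed jointly
#' with the sentence, so it is exact by construction.
#'
#' @param config a [generator_config()].
#' @return data.frame with columns `sentence`, `actions` (serialized action
#'   string), `template` and `source` (`"synthetic"`).
#' @export
#' @examples
#' head(generate_corpus(generator_config(n_samples = 5, seed = 7)))
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config$seed)
  w <- config$weights
  ids <- sample(names(w), config$n_samples, replace = TRUE,
                prob = w / sum(w))
  out <- vector("list", config$n_samples)
  for (i in seq_along(ids)) {
    tpl <- .TEMPLATES[[ids[i]]]()
    sent <- tpl$sentence
    astr <- serialize_actions(tpl$actions)
    if (config$noise && stats::runif(1) < config$noise_rate) {
      if (stats::runif(1) < 0.5) {
        # out-of-lexicon operation verb: relevant but unsupported
        cm <- .rand_compound()
        sent <- paste0("The mixture was ", sample(.NOISE_VERBS, 1L),
                       " with ", cm, " (", .rand_mass(), ").")
        astr <- serialize_actions(action_sequence(action("InvalidAction")))
      } else {
        words <- strsplit(sent, " ", fixed = TRUE)[[1L]]
        cand <- which(nchar(words) >= 5L & !grepl("[0-9()]", words))
        if (length(cand)) {
          j <- sample(cand, 1L)
          words[j] <- .swap_typo(words[j])
          sent <- paste(words, collapse = " ")
        }
      }
    }
    out[[i]] <- data.frame(sentence = sent, actions = astr,
                           template = ids[i], source = "synthetic",
                           stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sentence = character(), actions = character(),
               template = character(), source = character())
  rownames(res) <- NULL
  res
}
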