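# Independent oracles and generators used across the test suite.  These
# implementations are deliberately separate from the package code paths
# they check.

# plain dynamic-programming Levenshtein distance (character level)
dp_levenshtein <- function(a, b) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  n <- length(av)
  m <- length(bv)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1L] <- i
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L,
                         cur[j] + 1L,
                         prev[j] + (av[i] != bv[j]))
    }
    prev <- cur
  }
  prev[m + 1L]
}

# reference corpus BLEU with fixed 4-gram order (no short-sentence
# adaptation); written independently of the package implementation
reference_bleu4 <- function(preds, refs) {
  get_ngrams <- function(toks, n) {
    if (length(toks) < n) return(character())
    sapply(seq_len(length(toks) - n + 1L), function(i) {
      paste(toks[i:(i + n - 1L)], collapse = "|")
    })
  }
  num <- den <- rep(0, 4)
  plen <- rlen <- 0
  for (i in seq_along(preds)) {
    pt <- scan(text = preds[i], what = "", quiet = TRUE)
    rt <- scan(text = refs[i], what = "", quiet = TRUE)
    plen <- plen + length(pt)
    rlen <- rlen + length(rt)
    for (n in 1:4) {
      pg <- get_ngrams(pt, n)
      rg <- get_ngrams(rt, n)
      if (!length(pg)) next
      ptab <- table(pg)
      rtab <- table(rg)
      shared <- intersect(names(ptab), names(rtab))
      num[n] <- num[n] + sum(pmin(ptab[shared], rtab[shared]))
      den[n] <- den[n] + length(pg)
    }
  }
  if (any(den == 0) || any(num == 0)) return(0)
  bp <- if (plen > rlen) 1 else exp(1 - rlen / plen)
  bp * exp(sum(log(num / den)) / 4)
}

# ---- random valid actions over the allowed-property table ------------------

.test_names <- c(
  "water", "brine", "SLN", "acetic acid", "sodium sulfate",
  "4-methoxybenzaldehyde", "2,6-difluoroaniline", "ethyl acetate",
  "methyl 3-7-amino-2-[(2,4-dichlorophenyl)(hydroxy)methyl]-1H-benzimidazol-1-ylpropanoate",
  "aqueous sodium hydroxide", "n-hexane", "N,N-dimethylformamide")
.test_quants <- c("6.00 g", "14.7 mmol", "1 M", "92%", "0.5 mL",
                  "about 3 g", "2.2 equiv")
.test_durations <- c("30 min", "2 h", "overnight", "3 days")
.test_temperatures <- c("0 °C", "room temperature", "-78 °C", "100–105 °C")
.test_atmospheres <- c("nitrogen", "argon", "air")

random_chemical <- function() {
  chemical(sample(.test_names, 1L),
           quantities = sample(.test_quants,
                               sample(0:3, 1L, prob = c(3, 3, 2, 1))))
}

random_valid_action <- function(type = sample(action_types(), 1L)) {
  allowed <- allowed_properties(type)
  sch <- synthactions:::.ACTION_SCHEMA[[type]]
  mats <- list()
  if ("materials" %in% allowed) {
    lo <- if (type %in% c("MakeSolution", "Partition")) sch$mmin else 0L
    choices <- lo:min(sch$mmax, 3L)
    k <- choices[sample.int(length(choices), 1L)]
    mats <- replicate(k, random_chemical(), simplify = FALSE)
  }
  pick <- function(f, pool) {
    if (f %in% allowed && runif(1) < 0.6) sample(pool, 1L) else NULL
  }
  keep <- NULL
  if ("keep_phase" %in% allowed && runif(1) < 0.7) {
    keep <- sample(sch$phases, 1L)
  }
  # SetTemperature must carry its temperature
  temp <- if (type == "SetTemperature") sample(.test_temperatures, 1L)
          else pick("temperature", .test_temperatures)
  action(type, materials = mats,
         duration = pick("duration", .test_durations),
         temperature = temp,
         atmosphere = pick("atmosphere", .test_atmospheres),
         ph_value = if ("ph_value" %in% allowed && runif(1) < 0.8)
           round(runif(1, 0, 14), 1),
         dropwise = if ("dropwise" %in% allowed && runif(1) < 0.3) TRUE,
         repetitions = if ("repetitions" %in% allowed && runif(1) < 0.3)
           sample(2:4, 1L),
         keep_phase = keep)
}

random_valid_sequence <- function(max_len = 6L) {
  n <- sample(0:max_len, 1L)
  action_sequence(replicate(n, random_valid_action(), simplify = FALSE))
}

random_noise_string <- function() {
  mode <- sample(4L, 1L)
  if (mode == 1L) {
    # random printable garbage
    paste(sample(c(letters, LETTERS, 0:9, "(", ")", ";", ".", ",", "%",
                   "°", " ", "\t"), sample(1:80, 1L), replace = TRUE),
          collapse = "")
  } else if (mode == 2L) {
    # almost-valid clause with a corrupted head
    paste0(sample(c("Blorbify", "ADDD", "stirr", "Concentrat", "12345",
                    ""), 1L),
           " with stuff at 5 °C")
  } else if (mode == 3L) {
    # valid head with corrupted tail
    paste0(sample(action_types(), 1L), " ",
           paste(sample(c("with", "at", "for", "((", "))", "to pH", "x",
                          "and", "under", ";"),
                       sample(1:8, 1L), replace = TRUE),
                 collapse = " "))
  } else {
    paste(replicate(sample(1:3, 1L),
                    paste(sample(c("Add", "Wash with", "xyz", ";", "" ),
                                 sample(1:4, 1L), replace = TRUE),
                          collapse = " ")),
          collapse = "; ")
  }
}
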