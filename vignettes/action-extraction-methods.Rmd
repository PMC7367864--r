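---
title: "From procedure prose to action sequences: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From procedure prose to action sequences: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthactions)
```

## The problem

Experimental procedures for organic synthesis are reported as free prose in
patents and journals.  A bench chemist — or a robotic platform — needs the
same information as a sequence of discrete, typed operations: add this
reagent, stir for so long at such a temperature, quench, extract, dry,
filter, concentrate, purify, and so on.  `synthactions` converts prose into
such **action sequences** and provides everything around that conversion:
a typed action model, a bijective one-line text representation, a
rule-based extractor, corpus and augmentation tooling, an evaluation
suite, and a scaled-down sequence-to-sequence translation protocol.

## The action model

An action is a type plus a set of typed properties.  The vocabulary is a
closed set of 28 types: 24 laboratory operations (`Add`, `Stir`,
`Concentrate`, `MakeSolution`, `Filter`, ...) and four phony types that
flag text rather than describe work (`NoAction` for analytical or
descriptive text, `OtherLanguage` for non-English text,
`FollowOtherProcedure` for cross-references, `InvalidAction` for relevant
but unsupported constructs).  Restricting sequences to a linear order is a
deliberate simplification: branched work-ups are rare in single-step
procedures, and `MakeSolution` (prepare a mixture in a separate vessel,
then `Add SLN`) plus `CollectLayer` (select the aqueous or organic
fraction) recover the most common non-linearities.  Glassware and
apparatus are ignored on purpose — equipment does not determine the
chemistry.

Each type admits a fixed property set: `Stir` takes only a duration, a
temperature and an atmosphere; `Filter` only the phase to keep (filtrate
or precipitate); `Concentrate` nothing at all.  The full table is frozen
in code and exposed through `allowed_properties()`; `validate_action()`
reports violations as data rather than raising errors, because malformed
actions are a normal outcome of parsing model predictions and must be
countable.  Two borderline choices are worth stating.  `MakeSolution`
requires at least two materials — a solution is a mixture, and a one-entry
mixture is treated as a schema violation.  For all other material-bearing
types the material is optional (e.g. a bare `DrySolution` when no
desiccant is named), because extraction must be able to express "the verb
happened" without inventing an agent.

## The textual representation

`serialize_actions()` and `parse_actions()` convert between sequences and
a single-line string: clauses joined by `"; "`, a keyword grammar per type
(`with`/`and` for materials, `for` duration, `at` temperature, `under`
atmosphere, `to pH` value, `x` repetitions, `keep` phase), and compound
names printed verbatim — names may contain spaces, commas and nested
brackets, so quantity parentheses and the next keyword delimit them.  A
trailing period is accepted on input and omitted on output, and action
names parse case-insensitively; canonical output uses capitalized names.
The canonical form is unique, which makes the pair bijective — verified in
the test suite on 10,000 seeded random sequences drawn from the
allowed-property table.  Parsing arbitrary text never throws: failures are
structured objects carrying the clause index and offending token, which is
exactly what the validity metric counts.

```{r}
s <- "Filter keep filtrate; Concentrate"
parse_actions(s)
identical(serialize_actions(parse_actions(s)), s)
```

## The rule-based extractor

`extract_sentence()` maps one sentence to a sequence in stages:

1. **Gates.** Non-English text (detected by an English-marker token-share
   heuristic with a fixed 10% threshold — deterministic, no language
   model), cross-reference phrases, and analytics-dominated text short-cut
   to the phony types.
2. **Verb events.** A lexicon maps operation verbs and their inflections
   to handler families (`add`, `combine`, `suspend`, `charge`, `dilute`,
   `dissolve`, `mix`, `place`, `pour`, `treat` → additions;
   `concentrate`, `evaporate`, `remove`, `distill` → solvent removal; and
   so on through washing, drying, filtration, purification,
   recrystallization, refluxing, stirring, trituration, sonication,
   degassing, microwaving, partitioning, extraction, phase separation,
   waiting, yields and pH adjustment).  Attributive participles ("the
   *combined* extracts") and nouns followed by a copula ("the extracts
   *were* dried") are rejected as events.  The lexicon is extensible via a
   JSON file, because no fixed rule set covers every formulation.
3. **Windows and local subjects.** Each verb owns the text up to the next
   verb; a noun phrase directly before a copula is that verb's local
   subject.  Commas inside quantity parentheses and chemical names
   ("2,6-difluoro...") are masked before any clause splitting — a comma
   followed by a space separates clauses, a comma without one belongs to a
   name.
4. **Context disambiguation.** "heat" with a duration is a `Stir`, without
   one a punctual `SetTemperature`, with "to reflux" a `Reflux`; "remove"
   is `Concentrate` near a solvent and `Filter` in a filtration context.
   When several readings apply, the more specific action wins (Quench >
   PH > Partition > Add), preserving the intent of the original text.
5. **Implicit actions.** A solution-phrase subject ("To a suspension of X
   and Y in Z was added ...", "23 g of X in 30 mL of Y was heated ...")
   prepends `MakeSolution` + `Add SLN`; a bare layer subject ("The organic
   layer was dried ...") prepends `CollectLayer`; an "After 30 min,"
   opener prepends `Wait 30 min`.
6. **Cross-action repair.** A `Filter` with no stated phase followed by
   `Concentrate`, `DrySolution` or `Purify` keeps the filtrate — the
   continuation reveals which phase mattered.  `extract_procedure()`
   applies the same rule across sentence boundaries.

Every sentence yields a sequence and every emitted action validates, so
serialized extractor output always re-parses: the extractor's validity is
100% by construction, a property the test suite checks on noisy input as
well.  Word order is normalized where the language allows it: "To X is
added Y" and "Y is added to X" produce identical sequences.

```{r}
extract_sentence("The organic layer was dried over sodium sulfate")
demo_extraction(quiet = TRUE)$similarity
```

## The synthetic-fixture generator

`generate_corpus()` draws sentences from weighted templates covering every
laboratory action type, constructing the ground-truth sequence jointly
with the sentence, so the truth is exact by construction.  Default weights
emulate the action-frequency profile of patent procedures: additions,
stirring and concentration dominate; recrystallization, microwaving and
sonication are rare.  Compound names are chemically superficial stand-ins
(prefix + core, e.g. "4-methoxybenzaldehyde"); quantities, durations and
temperatures use realistic units and ranges.  A `noise` mode injects
out-of-lexicon verbs (ground truth `InvalidAction`) and letter-swap typos,
separating correctness tests (clean templates, where the extractor is
expected to recover ≥ 99% of sequences exactly) from robustness tests.

What the generator deliberately does **not** emulate: the long-tail
variety of human phrasing, OCR noise, cross-sentence coreference, branched
work-ups, and real chemical plausibility.  Passing tests on fixtures
therefore demonstrate the internal consistency of the pipeline and the
learnability of a patent-like grammar — not performance on real patent
text, which is known to be much harder for rule-based systems.

## Data augmentation

`augment_sample()` substitutes compound names, quantities, durations and
temperatures, each independently with probability `p` (default 0.5), with
draws from substitution pools; the identical replacement is applied to the
action string, so sentence/action alignment is preserved.  The probability
applies **per entity**, the most direct reading of a uniform substitution
rate; the empirical rate over many draws is binomial around `p`, which the
acceptance checks verify within three standard errors.  Substitution is
not chemistry-aware by design — the goal is linguistic variety for
refinement training, not plausible recipes.  Pools ship as seeded
synthetic lists (`generate_pools()`), labelled synthetic, standing in for
lists that would otherwise be compiled from a licensed reaction database.

## Metrics

* **Validity** — the fraction of predictions that parse back into actions,
  computed on raw strings before any repair.
* **Levenshtein similarity** — one minus the character edit distance over
  the longer length (base R's `adist` supplies the distance; an
  independent dynamic-programming oracle checks it in the tests).  The
  100/90/75% accuracies are the fractions of sentences at or above those
  similarity thresholds; by construction they are monotone.
* **Adapted BLEU** — corpus BLEU on whitespace tokens, except that for
  each sentence pair the n-gram order is capped at `min(4, shorter side)`
  so that short references are not penalized; with all pairs at ≥ 4 words
  the standard corpus BLEU is recovered (cross-checked in the tests
  against an independent fixed-order implementation).  This cap is the
  package's documented convention and reports should label it
  "adapted-BLEU (package convention)".
* **Confusion ledger** — per sentence, predicted and reference actions are
  aligned by a minimal edit script over action types; ties are broken by
  preferring matches, then substitutions, leftmost-first (a deterministic
  convention, since several minimal scripts can exist).  Aligned
  type-equal pairs count as type matches, property-equal pairs
  additionally as full matches; insertions/deletions are "only in
  prediction"/"only in ground truth", substitutions fill an off-diagonal
  matrix.  The ledger conserves mass: reference actions = type matches +
  substitutions + deletions.

## The translation protocol and its engine

The extraction task is formulated as sentence-level translation into the
textual action representation: pretrain on pairs generated by the
rule-based extractor, filter biased pairs first (drop `InvalidAction`
pairs and verbose keyword-free `NoAction` pairs, then duplicate
sentences), refine on a small set of exact (annotated-style) pairs,
checkpoint periodically, select the checkpoint with the best validation
exact-match accuracy (ties to the latest step), decode with beam n-best,
and optionally ensemble models sharing a vocabulary.  Invalid decodes are
converted to `InvalidAction` downstream.

The protocol is engine-agnostic behind `pretrain()` / `refine()` /
`translate()` / `save_seq2seq()`.  The default engine is an **analogical
template-induction translator**: each training pair is delexicalized by
abstracting the text spans shared between sentence and action string
(matched on punctuation-stripped token cores, longest span first) into
numbered slots; the resulting source→target template rule is stored with a
count; decoding matches stored templates against the input and transplants
the captured spans.  Two numerical details matter.  Slots directly
adjacent to another slot are ambiguous under non-greedy matching, so they
are anchored to the closed-class function word their training content
begins with ("at ...", "for ..."); isolated slots stay unanchored so
variant instances unify.  Conflicting targets for the same source pattern
resolve by majority with recency winning ties, which is what lets
refinement override pretraining errors.

This engine was chosen deliberately: it is deterministic, trains in
seconds on one CPU, generalizes over entity substitutions the way a
subword neural model generalizes at scale, and fails honestly (decoding to
`InvalidAction`) on constructions it has never seen — for example
cross-reference sentences whose only variation is a literal example
number.  The configuration object carries the full-scale transformer
hyperparameters (4 layers, hidden/embedding size 256, 8 attention heads,
shared 16,000-subword vocabulary, label smoothing 0, gradient accumulation
4, 500,000 steps, checkpoints every 1,000) as a preset for heavier
engines; `desk_config()` scales to 2 layers, hidden 128, vocabulary 300
and 2,000 steps.  The shared subword vocabulary is a real byte-pair
encoding (`build_vocabulary()`, lexicographic tie-breaks, lossless
round-trip), used by the protocol for tokenization and model metadata.
Ensembling averages candidate-level scores across members over the union
of their decodes — the package's convention, standing in for per-step
log-probability averaging, which a template decoder does not have.

Problem sizes used by the tests and reproduction script — 1,000 fixture
sentences for validity and extractor recovery, 10,000 sequences for
bijectivity, 10,000 draws for the augmentation rate, 2,000 training pairs
and 2,000 steps for the scaled protocol — were chosen so the full suite
runs in a few minutes on a single CPU while keeping every estimate's
sampling error well below its acceptance margin.

## Degenerate inputs and tie-breaks

Empty text extracts to an empty sequence; an empty action string parses to
an empty sequence; threshold accuracies over an empty set are an error
(undefined), while validity of an empty prediction set is `NaN`.
`SetTemperature` always carries its temperature (a temperature-less
punctual change is meaningless, and the extractor emits `Stir` instead
when a heat verb has neither duration nor temperature).  Sentence
splitting treats "°C." as a sentence end only before an upper-case
continuation, and a fixed abbreviation list (aq., conc., e.g., m.p., ...)
never splits.

## Known limitations

The compound recognizer is pattern- and dictionary-based, not a trained
chemical named-entity model; rare name shapes will be missed.  The
verb lexicon, though extensible, cannot cover every phrasing — that
limitation is the very motivation for the translation model.  The default
translation engine cannot produce genuinely novel target structure for an
unseen source pattern; it degrades to `InvalidAction` rather than
guessing.  Only linear action sequences are represented; state-dependent
instructions ("until the color disappears") are not expressible.
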