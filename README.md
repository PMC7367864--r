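# synthactions

Converts free-text chemical synthesis procedures — the prose found in
patent experimental sections — into structured **action sequences**: the
ordered, typed operations (Add, Stir, Concentrate, Filter, ...) a bench
chemist or a robotic platform needs to actually run the reaction.

It is aimed at cheminformatics practitioners building structured reaction
databases, training data for procedure-understanding models, or inputs for
automated synthesis platforms.

## What is inside

* **Action model** — a closed vocabulary of 28 action types (24 laboratory
  operations plus four phony types flagging non-operational, non-English,
  cross-referencing or unsupported text), each with a fixed set of allowed
  properties, and validation that reports violations as data.
* **Textual representation** — a bijective single-line serialization of
  action sequences (`Filter keep filtrate; Concentrate`), the target
  language for translation models; parsing never crashes, it returns
  structured failures that the validity metric counts.
* **Rule-based extractor** — a verb-lexicon NLP model with context
  disambiguation ("heat" + duration → Stir, otherwise SetTemperature),
  implicit-action insertion (solution-phrase subjects become
  `MakeSolution; Add SLN`; "the organic layer was dried" becomes
  `CollectLayer organic; DrySolution ...`), and cross-sentence repair.
* **Corpus tools** — legacy-record adaptation, source combination,
  pretraining filters, seeded splits, hard-sentence selection, TSV/JSONL
  I/O.
* **Augmentation** — entity substitution (compounds, quantities,
  durations, temperatures) applied consistently to sentence and actions.
* **Metrics** — validity, adapted BLEU, normalized Levenshtein similarity
  with 100/90/75% threshold accuracies, and a per-type confusion ledger.
* **Fixtures** — a seeded template grammar generating procedure sentences
  with exact ground truth, the package's no-download test and training
  substrate.
* **Seq2seq protocol** — subword vocabulary, pretrain on rule-generated
  pairs, refine on annotated pairs with checkpoint selection, beam n-best
  decoding, ensembling; exercised at desk scale on fixtures.

## The representation in one example

A sentence such as

> To a solution of benzaldehyde (5.2 g, 49 mmol) in methanol (50 mL) was
> added sodium borohydride (2.0 g, 53 mmol) at 0 °C.

extracts to

```r
library(synthactions)
extract_sentence(paste0(
  "To a solution of benzaldehyde (5.2 g, 49 mmol) in methanol (50 mL) ",
  "was added sodium borohydride (2.0 g, 53 mmol) at 0 °C."))
#>  1  MakeSolution with benzaldehyde (5.2 g, 49 mmol) and methanol (50 mL)
#>  2  Add SLN
#>  3  Add sodium borohydride (2.0 g, 53 mmol) at 0 °C
```

The one verb ("added") yields three actions: the suspension in the subject
is an implicit separate preparation (`MakeSolution`), its product (`SLN`)
enters the reactor, and only then is the reagent added.  Every sequence
round-trips through its one-line text form,
`parse_actions(serialize_actions(x))`, which is what makes the text form
usable as a translation target.

Evaluating the extractor against exact synthetic ground truth:

```r
corp  <- generate_corpus(generator_config(n_samples = 200, seed = 7))
preds <- vapply(corp$sentence,
                function(s) serialize_actions(extract_sentence(s)), "")
evaluate_predictions(preds, corp$actions)
#> action extraction metrics (n = 200)
#>   validity:                 100.0 %
#>   BLEU (adapted):           100.0 %
#>   Levenshtein similarity:   100.0 %
#>   100% accuracy:            100.0 %
#>   90% accuracy:             100.0 %
#>   75% accuracy:             100.0 %
```

Validity is the share of predictions that parse back into actions; the
threshold accuracies are the share of sentences whose normalized
Levenshtein similarity to the reference reaches 100/90/75%.  On clean
fixture sentences the rule model is exact by design; on noisy or real text
it is not, which is what the refine-a-translation-model protocol is for
(see the methods vignette, `vignettes/action-extraction-methods.Rmd`).

`demo_extraction()` runs a full multi-sentence worked example — a
reductive amination with complete work-up — and prints the extracted
16-action sequence next to its reference with their similarity.

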