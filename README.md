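# radspatial

Weakly supervised extraction of spatial relations from radiology report
sentences.

Radiology reports express clinically critical information *spatially*: a
spatial trigger — a preposition or verb such as "in", "of", "terminates" —
links a finding or device to an anatomical location, together with
contextual participants of the relation. `radspatial` extracts the trigger
and nine spatial **frame elements** (FEs) per trigger:

| FE | Example (span in bold) |
|---|---|
| Figure | There is hazy **opacity** of the lung ... |
| Ground | ... opacity of the **lung** ... |
| Hedge | ... **consistent with** hyaline membrane disease. |
| Diagnosis | ... consistent with **hyaline membrane disease**. |
| Position status | A right PIC catheter **terminates** in the mid SVC. |
| Relative position | The UV line tip is **high** in the right atrium. |
| Distance | ETT tube is **1 cm** above the carina. |
| Reason | ... could be due to a small **lacune**. |
| Associated process | During the **movement of the right foot**, ... |

The package is for clinical-NLP researchers who want frame-level spatial
labels *without* manually annotated training data. It builds its own
training set by **data programming**:

1. **Candidate generation** — dictionary longest-match entity/trigger
   tagging (with distance and vertebral-segment regexes) produces all
   {trigger, entity} pairs per sentence.
2. **Labeling functions** — a registry of 19 deterministic heuristics; each
   votes one FE label for a pair or abstains.
3. **Generative label model** — a one-coin Dawid–Skene model fitted by EM
   estimates each heuristic's unobserved accuracy α\_j and aggregates the
   votes into one probabilistic label per pair:
   P(y = k | votes) ∝ π\_k · Π\_j [α\_j if vote\_j = k, (1−α\_j)/8 if
   vote\_j ≠ k], with abstentions ignored.
4. **Filtering + BIO** — trigger-level instances keep only plausible frames
   (Figure+Ground present; no "history of"-style frequent phrase around the
   trigger) and are rendered as BIO tag sequences with the trigger masked
   as `$sptrg$`.
5. **Sequence tagger** — an averaged-perceptron baseline (BIO-constrained
   greedy decoding) trains on the weak labels; a transformer backend is
   specified as an adapter contract.
6. **Evaluation** — strict span+label scoring conditioned on triggers,
   charging FE errors for false-positive and missed triggers.

A synthetic radiology-sentence generator with exact gold frames
(`generate_corpus()`) makes the whole pipeline testable end to end without
access to restricted clinical text.

## Worked example

```r
library(radspatial)

entities <- radspatial_entities()   # packaged mini-dictionary, expanded
triggers <- radspatial_triggers()

s <- tokenize_sentence(
  "There is hazy opacity of the lung consistent with hyaline membrane disease.",
  doc_id = "report1")

run <- weak_label_corpus(list(s), entities, triggers)
run$instances[[1]]
```

```
<rs_instance> report1/0 trigger 'of' [weak]
  FIGURE             opacity (p=0.70)
  GROUND             lung (p=1.00)
  HEDGE              consistent with (p=1.00)
  DIAGNOSIS          hyaline membrane disease (p=1.00)
```

The pipeline found the trigger "of" and labeled all four participating
spans; the probabilities are posterior confidences from the label model
(0.70 for the Figure span because a single heuristic voted for it, 1.00
where several agreed). The surviving instance renders as a masked BIO
sequence ready for tagger training:

```r
writeLines(with(to_bio(run$kept[[1]]), paste(tokens, tags, sep = "\t")))
```

```
There      O
is         O
hazy       O
opacity    B-FIGURE
$sptrg$    O
the        O
lung       B-GROUND
consistent B-HEDGE
with       I-HEDGE
hyaline    B-DIAGNOSIS
membrane   I-DIAGNOSIS
disease    I-DIAGNOSIS
.          O
```

Training and applying the baseline tagger end to end:

```r
corpus <- generate_corpus(synth_config(n_sentences = 600, seed = 7))
train  <- corpus[1:500]; test <- corpus[501:600]

run    <- weak_label_corpus(lapply(train, `[[`, "sentence"), entities, triggers)
tagger <- train_tagger(lapply(run$kept, to_bio), tagger_config(seed = 1),
                       lexicon = entities)
pred   <- predict_instances(tagger, lapply(test, `[[`, "sentence"),
                            entities, triggers, run$model)
score_fes(synth_gold_instances(test), pred, mode = "predicted_triggers")
```

On the noise-free synthetic corpus this reports trigger and overall FE
precision/recall/F1 of 100 — the templates are within-distribution for the
default heuristics, so this validates the machinery, not real-report
performance (see the methods vignette,
`vignettes/weak-supervision-methods.Rmd`).

A thin command-line wrapper over the same functions ships in
`inst/cli/radspatial.R` (`synth`, `tag`, `weak-label`, `bio`, `train`,
`eval` subcommands).

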