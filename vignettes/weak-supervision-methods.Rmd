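---
title: "Weakly supervised spatial frame extraction: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised spatial frame extraction: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radspatial)
```

## The task and the model

Radiology reports describe findings and devices *spatially*: a spatial
trigger (a preposition or verb such as "in", "of", "terminates") evokes a
relation between a located object and its anatomical location. `radspatial`
extracts, per trigger, nine spatial frame elements (FEs): **Figure** (the
located finding/device), **Ground** (the anatomy), **Hedge** (uncertainty
phrasing such as "consistent with"), **Diagnosis**, **Position status**
(device placement language: "terminates", "tip"), **Relative position**
("high", "inferior"), **Distance** ("1 cm"), **Reason**, and **Associated
process**.

Manual annotation of such frames is expensive, so the package builds its
training data by *data programming*: deterministic heuristics (labeling
functions, LFs) vote an FE label — or abstain — for every candidate
{trigger, entity} pair, a generative label model reconciles the noisy votes
into one probabilistic label per pair, and a sequence tagger is trained on
the resulting weak labels. No hand-labeled sentence is needed anywhere in
the training path.

## Candidate generation

Two dictionaries drive candidate generation. The entity dictionary maps
surface forms to nine categories (finding, anatomy, device, process,
location/certainty descriptors, hedge, position status, relative position);
the trigger dictionary lists spatial prepositions and verbs. The package
ships small self-contained dictionaries (`radspatial_entities()`,
`radspatial_triggers()`); production users load their own ontology-derived
term lists with `read_term_list()`.

Dictionary expansion (`expand_lexicon()`) adds region phrases ("area(s)
of", "focus/foci of" x finding terms), descriptor products ("petechial" +
"hemorrhage"), and plural forms (rule-based with a small irregulars table:
focus/foci, vertebra/vertebrae, atrium/atria). Expansion only ever feeds
base or manually added terms into each rule, which makes it a fixed point:
re-expanding an expanded lexicon changes nothing.

Tagging is case-insensitive exact longest-match over token-aligned spans,
ties to the leftmost start. One deliberate exception: a multi-token anatomy
match whose first token is a location descriptor ("inferior cerebellar
peduncle") is split into the descriptor and the remaining anatomy span, so
that the descriptor can fill the Relative-position FE. Two regex matchers
supplement the dictionaries: distances (`\d+(\.\d+)?(-\d+(\.\d+)?)? (mm|cm|
millimeter(s)|centimeter(s))`) and vertebral segment codes
(`[CTL]\d{1,2}(-[CTL]\d{1,2})?`). No stemming or fuzzy matching is
attempted; misspelled dictionary terms are simply missed, which is the main
coverage limitation of exact matching and the reason the synthetic
generator exposes a misspelling knob (below).

Candidate pairs are the full cross product of triggers and entities in a
sentence, minus pairs whose spans overlap. Offsets are 0-based half-open
characters; `token_gap` counts whole tokens strictly between the spans, so
"0–2 words in between" means `token_gap <= 2`.

## The labeling functions

The registry (`default_lf_registry()`) holds exactly 19 LFs, each declaring
a single target label it may emit (label purity is enforced at application
time). The two Ground and two Diagnosis heuristics implement published
feature tables; the remainder are package-defined stand-ins whose design is
recorded next to each function. Shared knobs live in `lf_config()`:

* `window_len = 4` — token windows (never characters, never across
  sentence boundaries); "within the window" means at most 3 tokens between
  the spans.
* cue lists match as lowercase substrings of the joined window text, so
  the stem "indicat" hits "indicating"/"indicative".
* a "preposition-containing hedge" is a hedge dictionary entry containing
  one of *of/for/with/to* ("consistent with", "concerning for").

Two registry-level choices deserve a note. First, the Figure
"chained-frame" heuristic is defined as *anatomy left of a non-copular
trigger with a copular token in between* ("The tonsils **are** below the
foramen magnum"): the naive reading (anatomy left-adjacent to a copular
trigger followed by a second trigger) would contradict the first Ground
heuristic on sentences like "The lungs demonstrate ... of ...", where the
left-adjacent anatomy is the Ground. Second, a colon-style Ground LF covers
the "location: findings" reporting format some institutions use ("Brain
parenchyma: There are ..."), where the anatomy precedes a colon and the
trigger follows it.

## The generative label model

`fit_label_model()` implements a one-coin Dawid–Skene-style
conditional-independence model: each pair has a latent true label drawn
from class priors $\pi$, and LF $j$, when it does not abstain, votes the
truth with accuracy $\alpha_j$ and otherwise a uniformly chosen wrong label
($P = (1-\alpha_j)/8$). Fitting is EM:

* E-step: posterior over the true label per pair under current
  $(\alpha, \pi)$;
* M-step: $\alpha_j \leftarrow (\text{expected correct} + \lambda p_0
  n_j) / (n_j + \lambda n_j)$ with $\lambda$ = 0.01 (`l2`) pseudo-counts
  pulling toward $p_0$ = 0.7 (`precision_init`), where $n_j$ is the LF's
  non-abstain count.

Accuracies start at 0.7; the loop runs at most 100 iterations (`epochs`) or
until the maximum parameter change drops below `tol` = 1e-6. The penalized
log-likelihood is recorded per iteration and is non-decreasing (a property
the test suite asserts). `learning_rate` is carried in the configuration
for interface parity with SGD-trained label models but is unused by EM.

**Class priors are fixed uniform by default.** This was a genuinely open
design point resolved by implementation experience: with target-pure LFs,
an FE covered by a *single* heuristic (Distance and Relative position in
the default registry) is vulnerable to a label-switching degeneracy when
priors are re-estimated freely — the rare class's prior and its LF's
accuracy spiral jointly to zero, and every such span is relabeled to the
majority class, because for a singleton-vote row the "LF is almost always
wrong" explanation has higher likelihood than the honest one once
$\pi_{\text{rare}} < (1-\alpha)/8$. Fixing a uniform class balance (the
default of widely used data-programming label models when no balance is
supplied) removes the degeneracy; `estimate_priors = TRUE` restores free
estimation for callers whose registries cover every label with several LFs.
Argmax ties break by the fixed label enum order (Figure first), giving
fully deterministic labels; `fit_majority()` provides the majority-vote
baseline under the same tie-break, and in the symmetric equal-accuracy case
the two aggregators provably coincide.

## Instances, filtering, BIO

Labeled pairs are regrouped per trigger. Within a label, overlapping spans
keep the higher probability, then the longer span; across labels, overlap
resolves by probability then enum order (the source material is silent on
both — these are package choices). Two filters then select training
instances: (1) a frame must contain both Figure and Ground — during
*evaluation* this is relaxed to Ground-only so that trigger recall is not
sacrificed before the tagger has a chance to predict the FEs; (2) a
frequent-phrase check drops triggers embedded in non-spatial collocations
("history **of**"). The phrase lists are pure configuration with small
package-chosen defaults, since the original lists come from prior work that
is not reproducible here.

Surviving instances become BIO sequences: every trigger token is replaced
by the mask symbol `$sptrg$` (one mask token per original token, keeping
alignment — the masking granularity was unspecified, and per-token masking
preserves offsets), FE spans become `B-X`/`I-X` runs, everything else `O`.
BIO sequences round-trip: decoding recovers exactly the surviving spans.

## The baseline tagger

The shipped backend is an averaged perceptron over window features (token
identity, +/-2 context, shape, 3-char suffix, is-mask, bucketed signed
distance to the mask, optional lexicon categories) with greedy decoding
under hard BIO transition constraints — `I-X` is only reachable from
`B-X`/`I-X`. Greedy decoding with hard constraints was chosen over Viterbi
for simplicity and is documented as replaceable. Training shuffles sequence
order per epoch under the configured seed and is reproducible
bit-for-bit. Sequences longer than `max_seq_len` (128) are truncated with a
recorded warning.

A `transformer` backend id is reserved as an adapter contract: an external
masked-language-model tagger that honors the same train/predict signatures
and CoNLL files can replace the baseline (the recorded reference
fine-tuning settings are maximum sequence length 128, learning rate 2e-5, 4
epochs; a sub-word-capable adapter must document its own label-alignment
policy, e.g. first-subtoken labeling). No pretrained weights ship with the
package, and `train_tagger(backend = "transformer")` says so rather than
silently falling back.

## Evaluation protocol

Scoring is strict: exact span boundaries, exact label, exact trigger span
(near-miss triggers count as an FP/FN pair). Because FEs are predicted *per
trigger*, end-to-end scoring (`mode = "predicted_triggers"`) charges every
FE predicted under a false-positive trigger as a false positive and every
gold FE under a missed trigger as a false negative; `gold_triggers` mode
isolates FE quality from trigger quality, and the predicted-triggers score
can never exceed it. The Overall row is micro-averaged (count-weighted)
with a `macro` option, since count-weighted aggregation is what per-FE
count columns in the field's results tables imply.

## The synthetic corpus

`generate_corpus()` emulates seven radiology reporting styles: "finding in
location" (optionally with a relative-position term), the "location:
findings" colon style, device position ("The catheter is positioned in
..."; "The catheter tip is high in ..."), hedge+diagnosis ("... consistent
with pneumonia."), distance ("The drain is 2 cm above ..."), reason ("...
due to infection."), and associated process ("During swallowing, ...").
Sentences are emitted pre-tokenized (single spaces, punctuation as its own
token); gold trigger and FE spans are recorded exactly, and generation is
byte-reproducible by seed. The default style mix (25/10/15/20/10/10/10 %)
gives every FE at least 1% frame coverage at n = 1000.

Two noise knobs stress the pipeline's known weaknesses: `misspell_rate`
applies character edits (swap/drop/duplicate) to tokens *outside* gold
spans — modelling the misspelling-driven coverage loss of exact dictionary
matching while keeping gold spans well-defined — and `distractor_rate`
mixes in frame-free sentences to exercise trigger precision. The templates
are intentionally within-distribution for the default LFs: passing
end-to-end tests demonstrates that the machinery (candidates, votes,
aggregation, filtering, BIO, tagging, scoring) composes correctly, *not*
that the heuristics would reach comparable scores on real reports, whose
vocabulary coverage, sentence complexity and reporting-style variety far
exceed the generator's.

## Problem sizes and numerical choices

The package's own study sizes, chosen to exercise every code path at desk
scale: the end-to-end synthetic experiment uses 500 training and 100
held-out sentences (noise-free), the label-model recovery simulation uses
5000 rows with five LFs of accuracies 0.9/0.85/0.8/0.7/0.6 and 30%
abstention, and the law-of-large-numbers check uses 10 000 rows. EM
accuracy estimates are clipped to (1e-6, 1 - 1e-6); posterior computations
run in log space with max-subtraction. All randomness flows through
explicit seeds, and seeded helpers restore the caller's RNG state.

## Known limitations

* Exact dictionary matching: no stemming, no fuzzy match, no spelling
  correction; coverage on real text is bounded by the supplied term lists.
* The 15 non-published heuristics are package-defined; holders of the
  original supplementary material should swap in the exact rules.
* No modelling of LF correlations; the label model assumes conditional
  independence given the true label.
* Single-sentence scope: no cross-sentence frames, no section handling,
  sentence segmentation is input-provided.
* The baseline tagger is lexical; generalization to unseen vocabulary
  relies on the optional lexicon-category features.
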