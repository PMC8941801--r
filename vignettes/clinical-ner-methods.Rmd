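---
title: "Models and design choices in emrner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in emrner}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(emrner)
```

# The task

Chinese clinical notes have no word boundaries, and word segmentation errors
propagate into entity boundaries, so `emrner` treats clinical named-entity
recognition as *character-level* sequence labeling. Seven entity types are
extracted from neurosurgical EMR notes — symptom, body region, disease,
family history, surgery, medication and disease course — over four note
types per patient (current medical history, past medical history, case
characteristics, family history). Each character receives one of 15 BIO
tags (`O` plus `B-`/`I-` per type); mentions are typed spans with 0-based,
end-exclusive offsets, so `end - start` always equals the mention length.
The end-exclusive convention is the only one under which span arithmetic
and content length agree for all of our fixtures, and it is fixed
throughout the package. Whether offsets should instead count from 1 cannot
be settled from span lengths alone; 0-based indexing is used consistently
and is also what the character-index feature assumes.

Three model families are implemented, deliberately spanning the classical
difficulty ladder:

* **dictionary maximum string matching** — no context, memorizes surfaces;
* **linear-chain CRF** over windowed unigram feature templates;
* **BiLSTM-CRF** — trained character embeddings, a bidirectional peephole
  LSTM encoder, and a CRF output layer.

# The synthetic corpus generator

Hospital EMR corpora are restricted, so the generator is a first-class,
tested module that stands in for one. It emulates the statistical structure
that makes the modeling problem interesting:

* **note-type conditioning** — entity-sampling weights per (entity type,
  note type) default to the normalized token distribution observed in a
  500-patient neurosurgical corpus: symptoms dominate current-history
  notes, past histories are rich in diseases/surgeries/medications,
  family-history entities occur almost exclusively in family-history notes,
  and disease-course phrases in case texts. This is what makes the
  document-type feature informative. The weights are configuration, not
  constants.
* **hard constructions** — with probability `hardcase_rate` a body-region
  mention is emitted immediately followed by a symptom mention (双下肢 +
  水肿, adjacent spans), and diagnoses are emitted as "？"-separated
  uncertain pairs (考虑X？Y？); with probability `negation_rate` a symptom
  is negated ("无" + symptom) *and still annotated*, matching the
  annotation rule that negative symptoms are extracted (negated family
  histories, by contrast, are simply not generated, since they are not
  annotated entities).
* **open vocabulary** — each entity type has a train pool and a disjoint
  held-out pool; test-split mentions draw from the held-out pool with
  probability `oov_fraction` (default 0.1), so dictionary memorization
  fails on exactly that fraction while context models can generalize.
* **determinism** — identical `(config, seed)` yields byte-identical
  corpora; patients split 3:1:1 into train/validation/test, four notes per
  patient, so 500 patients give the 300/100/100-patient splits used by the
  end-to-end tests.

What it does **not** emulate: fluent long-form clinical prose; annotation
inconsistency between annotators; surface forms shared across entity types
(in real notes a hypertension mention may be a disease or a family history
depending on the sentence — the generator keeps the pools disjoint across
types so the dictionary-recall property is well-posed); numeric findings
and examination values. Passing tests on synthetic data therefore
demonstrates correctness of the machinery and the expected *qualitative*
ordering of the models, not clinical-grade accuracy on real EMRs.

# Feature extraction

Four observation streams per character: the POS of the enclosing word, the
radical (the indexing graphical component of a Han character, e.g. 疒 in
病/痛/瘤), the note type, and the character index counted from 0. The
template set is windowed unigrams at offsets −2…+2 (content window 5) of
the character, POS and radical streams, plus the offset-free note type:
5 + 5 + 5 + 1 = **16 templates** per position. This composition is the one
uniquely consistent with a window of 5 and a count of 16; the exact
template inventory is otherwise under-determined, so we document it as a
reconstruction. The character index is emitted bucketed (0, 1–4, 5–9,
10–19, 20+) as an optional 17th template — raw indices explode the feature
space, and the index feature is the one known to *hurt* performance, so
the buckets keep its ablation meaningful. Out-of-window offsets produce
`<BOS>`/`<EOS>` sentinels.

The segmenter is pluggable (`text -> data.frame(word, pos)` partitioning
the text). The built-in fallback treats every character as a one-character
word with POS `"X"`, so the package runs with no external models; with the
fallback the POS stream is constant and the character window carries the
signal. The radical table ships as a plain TSV covering the generator
charset plus common Han characters; unknown Han characters map to `"N"`
with a warning, as do digits, Latin letters and punctuation.

# The linear-chain CRF

The model is
\[
P(y \mid x) \propto \exp\Big(\sum_t \mathrm{emis}(t, y_t) +
\sum_t \mathrm{trans}(y_{t-1}, y_t)\Big),
\]
with emission scores summing the state weights \(\mu_k\) of the (feature
string, label) indicators active at a position, and a label-pair transition
table for the \(\lambda_j\). Realizing the pairwise feature functions as
x-independent label-pair weights is the convention of unigram-template CRF
toolkits (a unigram template file plus the default bigram template `B`);
conjoining every observation string with label pairs would multiply the
parameter space by \(|Y|^2\) for no benefit on this task. Only
feature/label combinations observed in training are instantiated; unseen
features are dropped at decode time.

Numerics and training:

* forward–backward uses per-step rescaling (sums of scaled alphas) with a
  per-position emission shift and a global transition shift, so no
  log-sum-exp is needed in the inner loop and `log Z` is exact to machine
  precision — verified against exhaustive path enumeration at `T <= 6`;
* sequences are padded-free but *batched*: all sequences are stacked into
  one sparse indicator matrix and the DP recursions run vectorized across
  sequences grouped by length;
* training maximizes the L2-penalized log-likelihood (`l2 = 1` by default,
  the toolkit-style default in the absence of a stated value) with
  deterministic batch L-BFGS (`stats::optim`), so identical runs give
  identical models and no seed is involved;
* the BIO transition mask (`I-t` only after `B-t`/`I-t` of the same type,
  never first) is always applied at decode; optionally during training
  (`constrain_train`), where forbidden transitions are pinned at −30
  rather than −∞ to keep the optimizer's objective finite. The default is
  decode-only, treating the constraint as an output-layer property;
* Viterbi ties break by label-scheme order (first maximum), which makes
  the zero-weight masked decode the all-`O` path.

The 16-run feature ablation grid (`feature_ablation_grid()`) is a single
config matrix driving `crf_fit()` per combination.

# The BiLSTM-CRF

The recurrent cell implements the peephole LSTM equations exactly as
printed, with full peephole matrices on the cell state and the output gate
peeking at the *current* cell \(C_t\):

\[
\begin{aligned}
i_t &= \sigma(W_{xi} x_t + W_{hi} h_{t-1} + W_{ci} C_{t-1} + b_i)\\
f_t &= \sigma(W_{xf} x_t + W_{hf} h_{t-1} + W_{cf} C_{t-1} + b_f)\\
C_t &= f_t \odot C_{t-1} + i_t \odot \tanh(W_{xC} x_t + W_{hC} h_{t-1} + b_C)\\
o_t &= \sigma(W_{xo} x_t + W_{ho} h_{t-1} + W_{co} C_t + b_o)\\
h_t &= o_t \odot \tanh(C_t)
\end{aligned}
\]

This requires a custom cell and hand-derived backpropagation (the output
gate's peephole feeds gradient back into \(C_t\)), both verified against an
independent scalar evaluation of the five equations (1e−10) and central
finite differences over every parameter block (1e−4). Whether the original
design really used peephole connections or only printed the general
equations is unknowable; the peephole cell is the default and a standard
cell is available via `peephole = FALSE`. Dropout placement is likewise
unstated; it is applied to both the embeddings and the encoder outputs.

Defaults follow the standard recipe: embedding 100, hidden 100, at most 30
epochs, batch 16, learning rate 0.01, gradient-norm clip 5, dropout 0.5,
Adam. Mini-batches are realized as per-sequence processing with gradient
accumulation over 16 sequences per update — mathematically identical to
padded-tensor batching, with no padding positions to mask out of the loss.
The vocabulary comes from the training corpus with a trained unknown row.
Two noising devices make the unknown row genuinely *trained*: per-character
unk replacement (`unk_replace = 0.02`, the classic singleton-dropout
device) and whole-span masking of gold mentions (`span_unk_replace =
0.15`). The second matters because out-of-vocabulary mentions at test time
are contiguous runs of unseen characters; masking whole entity spans in
training teaches the encoder to type such runs from the clause context
("伴 … ，", "其父患 …") rather than from memorized surfaces. After each
epoch the model is scored on the validation split (strict overall F1 — the
selection criterion had to be chosen, and strict F1 is the headline
metric); the best parameters are retained and training stops after
`patience` epochs without improvement. Divergence (non-finite loss or
gradient) is reported with its epoch. The CRF output layer shares the DP
kernels with the linear-chain CRF, including the decode-time mask, so
decoded sequences are always BIO-well-formed and strict mention decoding
never errors.

An optional embedding-provider hook (`model$embedder`) accepts
per-character context vectors from an external pretrained encoder, so a
BERT-style front end can be plugged in without the package shipping one;
no pretrained weights are included and the hook receives no gradients.

# Evaluation

Strict equality requires content, start, end and type all equal. The
relaxed (lenient) criterion keeps type equality and the literal overlap
inequality `max(starts) <= min(ends)`; the content-equality clause of the
lenient definition is dropped by default because literal string equality
combined with unequal boundaries is self-contradictory — "content" denotes
the semantic concept. The literal three-clause variant sits behind
`literal_content = TRUE`. Under end-exclusive spans the printed `<=`
admits *touching* spans; it is implemented literally and tested as the
adjacency edge case. Every strict match is a relaxed match, so relaxed
P/R/F1 dominate strict P/R/F1 on any input — property-tested and visible
in every model-comparison row.

Matching is one-to-one (each gold mention matches at most one prediction),
greedy in gold-span order with ties to the earliest predicted start; the
cardinality convention `P := 0` when `|S| = 0`, `R := 0` when `|G| = 0`,
`F1 := 0` when `P + R = 0`. Percentages are kept unrounded internally and
rounded to two decimals only in rendered tables. Inter-annotator agreement
follows the A1-as-gold formulation: precision is the consistent count over
A2's annotations, recall over A1's, agreement their harmonic mean.

# Problem sizes in the test suite

The end-to-end tests and the acceptance script regenerate a 500-patient
corpus (300/100/100 patients; about 4,800 training sequences of 15–80
characters) with `oov_fraction = 0.1`. At that size the CRF trains in
about a minute of L-BFGS (120 iterations) and the BiLSTM-CRF uses 8 epochs
— validation F1 saturates within the first three epochs on this synthetic
task, so the remaining epochs of the 30-epoch default add nothing the
selection criterion can see, and 8 keeps the whole suite comfortably
reproducible on a single CPU. Oracle suites run at `T <= 6`, `|Y| <= 5`
where exhaustive enumeration is feasible; structural invariants run at
1,000 documents / 10,000 decodes.

# Known limitations

* The fallback segmenter makes the POS stream uninformative; plug in a
  real Chinese segmenter through the segmenter interface to reproduce
  POS-feature ablations meaningfully.
* The radical table covers the generator charset plus common characters,
  not the full Han inventory; unknown Han characters degrade to `"N"`.
* Absolute scores on the synthetic corpus are far above what restricted
  hospital corpora yield (the synthetic task is cleaner and its lexicon
  smaller); only the qualitative ordering — dictionary < CRF, dictionary <
  BiLSTM-CRF, relaxed ≥ strict — should be read as meaningful.
* No discontinuous or nested mentions, and no attribute layer: negation is
  lexical context, not a structural flag.
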