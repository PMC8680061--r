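---
title: "Definition-enhanced span NER: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Definition-enhanced span NER: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(defner)
```

## The modelling problem

`defner` recognises typed entity mentions — chemicals normalizable to a
concept identifier (`NORMALIZABLES`), chemicals that are not
(`NO_NORMALIZABLES`), proteins and genes (`PROTEINAS`), and general
substance classes (`UNCLEAR`) — in clinical text distributed as BRAT
standoff corpora. The scientific idea is that the *meaning* of an entity
type, written down as its annotation-guideline definition, is useful input
to the recogniser rather than just documentation for annotators. The
package implements the two architectures that operationalise this idea and
every piece of plumbing needed to measure whether it works: corpus
reading/writing, sentence splitting, offset-exact token alignment, span
decoding, and strict exact-match scoring.

## Boundary prediction

Both formulations reduce NER to per-position boundary classification.
For a sentence of $n$ tokens the encoder yields a representation matrix,
and two affine heads score each position with independent 2-way softmaxes
for "is a mention start" and "is a mention end". A position joins the
start (end) index set only when its class-1 probability *strictly* exceeds
its class-0 probability; an exact tie counts as negative, reading the
argmax-equals-one extraction rule as strict preference. This per-position
two-class shape (rather than a single softmax over positions) is what the
probability tables' printed dimensions imply, and it allows several
mentions per sentence per type.

Index sets are paired into spans by **nearest-end greedy matching**: scan
the starts in order; each start takes the smallest unused end at or after
it that precedes the next start (when one exists); unmatched boundaries
are dropped and counted. The published method stops at index extraction
and never states a pairing rule, so this was a genuinely open design
point. We chose this rule because the corpora are flat (mentions never
nest or overlap), it is deterministic and linear-time, and its output is
provably non-overlapping and ordered; a probability-weighted bipartite
matcher could be slotted in behind the same interface but would change
nothing on flat gold data, where oracle probabilities already decode to
exactly the planted annotations (the end-to-end identity property in the
test suite).

The training objective is $L = L_\mathrm{start} + L_\mathrm{end}$ —
an exact decomposition, asserted as such — where each term is the mean
2-class cross-entropy over *scored* positions. Special tokens and query
positions are excluded from scoring, so they can neither contribute loss
nor ever be predicted as answers. We do not re-weight the heavily
negative class balance by default; the published work is silent on the
loss beyond its start/end decomposition, and unweighted token-level
cross-entropy is the standard choice for boundary heads.

## MRC: the definition as a query

The reading-comprehension formulation packs each type's definition text
$q^y$ with the sentence as `[CLS] q [SEP] X [SEP]` (segment 0 over the
query part, segment 1 over the context part) and runs one forward pass
per type per sentence — four packed inputs for the four types. Each type
owns a separate head; the encoder is shared across types. "Separate span
predictors" pins down the heads but not what is shared; sharing the
encoder is the standard MRC-NER arrangement and keeps the parameter count
independent of the type inventory.

Two query sources are provided, both byte-stable constants pinned by
checksum in the tests: the verbatim Spanish guideline definitions, and a
rule template `¿Qué entidades <TYPE> se mencionan en el texto?`. The
published table writes the `NO_NORMALIZABLES` template token as
`No_NORMALIZABLES`; we keep that casing verbatim rather than normalising
it.

## SOne: the definition as a vector

The one-pass formulation encodes the sentence exactly once — the forward
pass is counted and asserted to be one per sentence regardless of the
number of types — and concatenates a per-type definition vector
$e \in \mathbb{R}^{d_e}$ to every token row before that type's head
(input $[Z, E]$ with $E$ being $n$ copies of $e$). The four heads are
built by one factory with independent initialisations: same structure,
different parameters. The "multi-layer pointer network" whose depth
"depends on the number of entity types" is interpreted as one
start/end affine pair per type over the shared augmented input; no deeper
stack is described anywhere, and one layer per type is the minimal
structure consistent with the wording.

Definition sources:

* `w2v`: the arithmetic mean of word embeddings over all tokens of all
  known mentions of the type. Mentions are taken from the **training
  split only** — pooling test mentions would leak labels. Mention strings
  are whitespace-split and lowercased before lookup;
  out-of-vocabulary tokens are skipped, and a type with no in-vocabulary
  token is an error unless the caller explicitly requests a zero-vector
  fallback (the fitting function does, so rare types degrade gracefully).
* `rule_query` / `guideline`: the query text is encoded, the final layer
  mean-pooled over the query tokens, and projected to $d_e$. Neither the
  pooling nor the $d \to d_e$ map is specified in the source; mean pooling
  plus a linear projection is the simplest faithful reading. Whether the
  query encoder is fine-tuned jointly was left open; we initialise the
  definition vector from the frozen encoder and then train the *vector*
  jointly with the model (`definition_trainable = TRUE` for these two
  sources). This keeps the variant distinction — initialisation differs
  per query — without the cost of back-propagating through a second
  encoder at every step. `definition_trainable = FALSE` freezes it.
* `none`: the ablation; $d_e = 0$ and the heads see $Z$ alone.

`UNCLEAR` participates in training by default but is excluded at scoring
time, matching the challenge convention that those mentions are not
evaluated; exclusion at scoring rather than loading means the same
predictions can be re-scored with a different exclusion set.

## The encoder and its training

Both models consume an encoder through a narrow contract: token ids and
segment ids in, an $s \times d$ matrix out, padding positions masked out
of attention so they can never influence real positions. The bundled
implementation is a 2-layer single-head self-attention encoder with
residual feed-forward blocks and learned token/position/segment
embeddings, with an explicit analytic backward pass (verified against
central finite differences in the tests) and no dropout, so evaluation
determinism is structural. It exercises the same code paths a pretrained
transformer adapter would; shipping or requiring pretrained weights is
out of scope, and the `encoder.kind = "pretrained"` configuration key is
the marked extension point.

Parameters that matter, with defaults and rationale:

* `d = 32`, `n_layers = 2`: the desk-scale encoder shape; large enough to
  resolve the one genuinely contextual sub-problem in the synthetic data
  (a gazetteer word that is a whole mention in one sentence and the
  *second* token of a longer mention in another — only attention to the
  neighbouring token disambiguates its end-boundary label).
* `d_ff = 4 * d`: feed-forward width. The narrower `2 * d` block turned
  out to be the binding constraint on reliable exact recovery of small
  training corpora, so the conventional 4× ratio is the default.
* `max_len`: 250 packed positions for MRC, 230 for SOne — the MRC budget
  is larger because the packed sequence must also hold the query. These
  are wordpiece-style token counts *including* special tokens (the
  source is ambiguous about its "token" unit). Truncation drops the
  context tail, never the query, and is counted.
* `d_e = 300`: definition-vector dimension, the stated setting.
* `steps = 300`, `batch_size = 20`: the optimisation budget used
  throughout the tests; batch size is the published setting.
* `lr = 1e-2` with 5% linear warmup and cosine decay to a tenth of the
  peak: the published 2e-5 is a fine-tuning rate for a pretrained
  encoder and cannot train a randomly initialised one in this budget; a
  randomly initialised small model needs a step size two to three orders
  larger, and the schedule removes the late-training oscillation that a
  constant rate shows at this scale.

Cross-entropy probabilities are floored at $10^{-12}$ before the
logarithm; attention masking uses an additive $-10^{30}$ before the row
softmax, which is exactly zero attention weight after normalisation in
double precision.

## Corpus plumbing

BRAT offsets are 0-based half-open character offsets — the format's own
convention; the modelling source never states one. Only `T` lines are
consumed; note and normalization lines are skipped. Reading verifies
every surface string against its text slice and rejects overlapping
mentions; writing normalises mention order by start offset, so
write-read is the identity and a second write cycle is byte-identical.

Sentences are split on the five terminators `\n . ; ? !`; the delimiter
stays the final character (and, when printable, the final token) of its
window, so document offsets survive splitting and a delimiter can never
begin a mention. Abbreviation periods are *not* special-cased — the rule
is applied literally, and over-splitting at abbreviations is a documented
consequence. A gold mention that crosses a window boundary (possible only
when a mention contains a terminator) or that does not align with token
boundaries is excluded from supervision, counted, and reported through a
warning: projection failures are never silent. The whitespace-and-
punctuation tokenizer guarantees every non-whitespace character is
covered by exactly one token span, making the char → token → char label
projection invertible on aligned mentions; a mention's token range is its
first through last covering token, and its supervision marks those
positions as start/end targets.

## The synthetic generator

The generator emulates the statistical shape the models assume:
multi-sentence records terminated by the five sentence-ending symbols,
flat typed mentions of one or two pseudo-Spanish words planted at exact
character offsets, per-sentence Poisson mention rates whose defaults echo
the real corpus profile (chemicals most frequent, proteins next, the two
rare types floored at 0.01/sentence), and a sentence-length mixture in
which 95% of sentences are short and 5% exceed 230 tokens — mirroring the
reported "about 95% within 230 tokens" statistic. Each type draws from
its own disjoint gazetteer, disjoint also from the filler vocabulary, so
type identity is lexically learnable by a small model; that is precisely
what makes exact-recovery training tests meaningful. Mentions never
contain sentence delimiters under the default spec (a crossing-mention
stress case is constructed directly in the tests instead). Generation is
a pure function of (spec, seed), and a random embedding table covering
every gazetteer word is emitted alongside for the `w2v` variant.

What it deliberately does **not** emulate: Spanish morphology and syntax,
realistic mention-frequency skew, nested or discontinuous mentions,
annotation noise, and document structure. Passing tests on these corpora
therefore demonstrate that the implementations are correct and trainable
— packing, masking, gradient flow, decoding, scoring — not that the
models would reach any particular score on real clinical text; the
published corpus-level results require pretrained Spanish-capable
weights, GPU fine-tuning and the hidden test split, all outside this
package's scope.

## Evaluation conventions

Scoring is strict exact match: a prediction counts only if document,
type, start and end all coincide with a gold mention, one-to-one, with
duplicates of an already-matched prediction counted as false positives.
Any metric with a zero denominator is reported as 0, the common scorer
convention. Type labels compare case-sensitively. Reports round to 4
decimals (round-half-even) only at the formatting layer; all computation
is unrounded. Problem sizes used by the test suite — 20-sentence training
corpora, 40–500-document plumbing corpora, 10,000-case pairing-oracle
sweeps — were chosen as the smallest sizes at which each property is
meaningfully exercised.

## Known limitations

* The pairing rule is a design choice the source does not constrain;
  on non-flat predictions different rules give different spans.
* Subword ends inside a word are reported raw by default
  (no extension to the word boundary), favouring transparency over
  cosmetic fixes; a config flag for boundary extension is the natural
  extension point.
* The trainable-vector reading of the encoded-definition variants is one
  of several defensible interpretations of joint training.
* The tiny encoder is a correctness and learnability vehicle, not a
  competitive Spanish clinical encoder.
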