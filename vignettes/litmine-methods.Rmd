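---
title: "litmine: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{litmine: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litmine)
```

## The problem

Drug-target discovery leans on literature evidence: a gene or protein
("target", GP), a disease (DS) and a chemical or drug (CD) mentioned together
in a sentence is a unit of association evidence. litmine is a desk-scale,
fully testable implementation of that evidence chain:

1. **Tagging** — a gazetteer (dictionary) tagger finds GP/DS/CD/OG mentions
   as character spans;
2. **Evaluation** — strict and partial span matching against gold spans,
   with precision/recall/F1;
3. **Grounding (normalization)** — mentions are mapped to ontology-style
   identifiers (EFO-like for diseases, ChEMBL-like for chemicals,
   Ensembl-like for genes) through a lexical cascade backed by skip-gram
   embeddings;
4. **Association** — same-sentence co-occurrences of mapped mentions are
   extracted, aggregated into unique (kind, identifier pair) records, and
   ranked;
5. **Statistics** — corpus-level normalization summaries and match rates
   against a curated reference evidence set.

Everything runs offline on plain-text inputs. A synthetic-corpus generator
produces documents with planted mentions at exact offsets and a known truth,
so each stage is tested against ground truth rather than against itself.

All character offsets anywhere in the package are **0-based, half-open,
in characters**.

## Sentence splitting

The splitter is rule-based: a sentence ends at a run of `.?!` followed by
whitespace and an uppercase letter or digit. The "uppercase or digit"
requirement already protects species abbreviations ("E. coli causes…" never
splits, because "coli" is lowercase). A configurable protected-abbreviation
list (shipped as `inst/extdata/abbreviations.txt`: "et al.", "Fig.", "i.e.",
"vs.", …) suppresses the remaining false breaks. Table blocks are segmented
one sentence-unit per newline-delimited row — the simplest defensible policy
for a structure where grammatical sentence boundaries do not exist — and
figure captions are treated as paragraphs.

Sentences never overlap, always reproduce the block slice exactly, and
re-splitting a sentence returns it unchanged (idempotence). These three
properties are asserted in the test suite.

## Lexicons, term normalization and the matching policy

A lexicon is a table of `(entry_id, preferred_label, synonyms)` rows with a
fixed entity type. Terms are indexed after normalization: lowercase,
internal whitespace collapsed, leading/trailing punctuation stripped.

One class of term is special: **short all-uppercase forms** (at most 5
characters, no lowercase letters — "WAS", "T2D", gene-symbol style). These
are additionally indexed case-sensitively, and the tagger matches them *only*
case-sensitively. The motivation is the classic dictionary-tagger failure
mode: "WAS" the gene versus "was" the verb. Consequently these terms are
also exempt from the (case-insensitive) blacklist — the case requirement is
already a stronger filter, and blacklisting "was" should not silence the
gene symbol.

The tagger matches the full term index against each sentence, requires token
boundaries on both sides (a match may not start or end inside an
alphanumeric run; hyphens count as boundaries, which blocks substring hits
like "can" inside "cancer"), resolves overlaps within one entity type
longest-match-first with ties to the leftmost start, and permits overlaps
across types (the four classes are annotated independently in gold
standards). Desk-scale corpora make a per-pattern vectorized scan fast
enough that no automaton index is needed.

## Evaluation

Two of the classic span-evaluation modes are implemented:

* **strict** — a predicted mention is a true positive iff a gold mention of
  the same type has identical block-level boundaries;
* **partial** — one character of overlap with a same-type gold mention
  suffices.

Each gold mention absorbs at most one prediction; matching is greedy in
positional order, which is standard and deterministic. `P = tp/(tp+fp)`,
`R = tp/(tp+fn)`, `F1 = 2PR/(P+R)`, each defined as 0 when its denominator
is 0. Rounding, everywhere in the package, is **half away from zero** —
metrics to 2 decimals, percentages to 1 decimal — which is what published
benchmark tables use. The two omitted modes ("exact boundary regardless of
type", "type with overlap") are a documented limitation; reports carry a
`mode` column so there is never ambiguity about which mode produced a
number.

Inter-annotator agreement uses Cohen's kappa,
`kappa = (p_o - p_e)/(1 - p_e)` with `p_e = sum_c freq_a(c) freq_b(c)`.
When both annotators are constant on one label (`p_e = 1`), kappa is
undefined and reported as 1 with an `undefined` flag. The kappa
implementation is verified against a confusion-matrix brute force on random
label vectors.

## Skip-gram embeddings

`train_embeddings()` is a from-scratch skip-gram with negative sampling
(SGNS), in C++ for speed, with the classic word2vec training loop:

| parameter          | default | meaning                                   |
|--------------------|---------|-------------------------------------------|
| `dim`              | 100     | embedding dimension                        |
| `window`           | 5       | symmetric context window (dynamically reduced per position) |
| `negative_samples` | 5       | negatives per positive pair, drawn from the unigram^0.75 table |
| `epochs`           | 5       | passes over the corpus                     |
| `min_count`        | 2       | vocabulary frequency cutoff                |
| `learning_rate`    | 0.025   | initial SGD rate, linear decay             |
| `subsample`        | 1e-3    | frequent-word subsampling threshold        |
| `seed`             | 1       | drives init, window reduction, subsampling, negative draws |

Training is single-threaded by design: identical corpus, parameters and seed
give bitwise-identical vectors, which the pipeline's determinism contract
and the test suite rely on. (Multi-threaded SGNS implementations gain speed
by racing updates and are inherently non-reproducible; at desk scale the
trade is not worth it.)

Subsampling matters more than usual here: biomedical sentences are dominated
by a small set of function words, and without down-weighting them every
token's context distribution looks alike. A token with relative frequency
`f` is kept with probability `(sqrt(f/t)+1) * t/f`.

The model keeps **both** SGNS matrices. The input matrix holds the word
vectors proper: cosine between input vectors measures interchangeability
(two tokens used in the same contexts), which is what `phrase_vector()`
(mean of in-vocabulary token vectors) and association ranking use. The
output (context) matrix is what SGNS multiplies input vectors against to
predict co-occurrence, so input-against-output similarity measures
*affinity* — "do these words occur around each other" — which is the
question the grounding disambiguation tier actually asks. Both matrices are
persisted in the text model format along with vocabulary counts.

## The grounding cascade

The production systems this package emulates describe embedding-based
normalization without algorithmic detail, so the cascade here is an
explicit, documented design with every tier independently switchable:

1. **exact** — normalized surface equals a preferred label; confidence 1.0.
2. **synonym** — normalized surface is an indexed term (short all-caps
   surfaces also consult the case-sensitive index). Unambiguous: confidence
   0.9. Ambiguous: context disambiguation (below); confidence = the
   winning similarity, clamped to [0, 1].
3. **fuzzy** — a unique index term within Levenshtein distance
   `fuzzy_max_distance` (default 1) that has a single candidate identifier;
   confidence 0.7.
4. **embedding** — nearest entry by cosine between the surface phrase
   vector and preferred-label phrase vectors (input space), accepted iff
   the similarity reaches `tau` (default 0.5); confidence = similarity.

Anything else is `UNMAPPED` and lands, with its sentence text, in the failed
export — unmapped mentions are retained for further study, never silently
dropped. Raising `tau` can only shrink the mapped set (asserted as a
property test), and the fixed tier confidences are monotone in tier
reliability.

**Context disambiguation.** For an ambiguous term the cascade compares the
mention's sentence context with each candidate's preferred label. The
context vector is the *subsample-weighted* mean of the sentence tokens'
input vectors, excluding the mention's own tokens — the weights are the
trainer's own keep-probabilities, so function words contribute almost
nothing and co-mentioned entities dominate. Each candidate is represented
by the subsample-weighted mean of its label tokens' *output* vectors, and
the winner is the candidate with the highest cosine against the context
vector. This input-context-versus-output-label pairing was chosen after
measuring the plain alternative: mean-of-everything input-space cosine is
swamped by function-word mass and barely beats chance on planted two-way
ambiguity, while the weighted cross-space variant recovers the planted
identifier in >=80% of ambiguous cases (pooled over seeds) on the ambiguity
study corpus described below. When no model or no usable vectors are
available the tier falls back to the lexicographically smallest candidate at
confidence 0.5 — deterministic, and visibly low-confidence downstream.

## Association extraction and ranking

Two mapped mentions of *different* groundable types in one sentence form one
co-occurrence; kinds are GP-DS, GP-CD and DS-CD. Same-type pairs, organism
mentions, pairs sharing a span, and pairs whose endpoints ground to one
identifier are excluded. Pairs are canonicalized (type order GP < DS < CD,
then identifier order) and aggregated into one record per (kind, pair) with
sentence-level `evidence_count` and per-document `document_count`. The
per-sentence pair count always equals `g*d + g*c + d*c` for mapped mention
counts g, d, c — a law the tests check against brute-force enumeration.
Associations are strictly intra-sentence: coreference and cross-sentence
inference are out of scope, which bounds recall on real text.

The ranking score is a package convention, isolated in one function so it
can be replaced:

```
score = log10(1 + evidence_count) * max(0, cos(label_1, label_2))
```

with phrase vectors in the input space. It rises monotonically with
evidence volume, is damped for semantically unrelated endpoint labels, and
is flagged (`score_defined = FALSE`, score 0) when either label has no
in-vocabulary token.

## Corpus statistics and benchmarking

`corpus_stats()` reports, per entity type: mention count, mapped count,
distinct normalized surface strings ("unique entities"), mapped distinct
strings, and distinct identifiers mapped to. "Unique entity" deliberately
means *distinct surface string after term normalization* — in real corpora
mention counts exceed distinct-label counts by two orders of magnitude, and
the mapped-unique percentage exposes the long tail of rare variant labels
that resists normalization.

`benchmark_match_rates()` scores pipeline output against a curated reference
table of (publication, target, disease) rows at five granularities —
publications, publication/target, publication/disease,
publication/disease/target triplets, and corpus-wide disease/target pairs —
by exact identifier equality after grounding (no ontology-ancestor credit).
Triplets require an actual GP-DS co-occurrence in that publication, not just
both identifiers appearing somewhere in it.

## The synthetic corpus generator

The generator exists so every stage can be tested against known truth. It
is template-based on purpose: the acceptance surface is span-exact, so
offsets and truth must be correct *by construction*, not approximately.

Design features, and what they emulate:

* **Topic documents over a fixed association network.** Each disease entry
  is linked to 2 genes and 2 chemicals for the whole corpus; a document
  samples its topic (one DS, one partner GP, one partner CD, one OG) from
  the network and reuses it across its sentences. Real literature has
  stable association structure — the same disease keeps co-occurring with
  the same genes and drugs across papers — and that stability is exactly
  the "co-occurrence pattern" signal embedding-based normalization exploits.
* **Label-first introduction.** The first mention of an entity in a
  document uses its preferred label; later mentions may use synonyms,
  mirroring how abstracts introduce a term before abbreviating it.
  Sentence-initial slots always take the label so that the generated text
  keeps exact, splitter-compatible sentence boundaries.
* **Ambiguity knob** (`ambiguity_rate`): a generated entry adopts an earlier
  same-type entry's short all-caps synonym, which is then retired, keeping
  every planted ambiguity exactly two-way.
* **Noise knob** (`noise_rate`): appends a spurious parenthetical lexicon
  mention that is *not* recorded in gold — the classic dictionary-tagger
  false positive. Recall stays at 1; precision degrades.
* **Density knob** (`association_density`): sets the expected number of
  fully planted GP/DS/CD pairs per sentence (0–3) through the template mix.

Default study conditions: seed 42, 200 documents of 5 sentences, four
50-entry lexicons, planting rate 0.9, ambiguity 0, noise 0, density 1.5.
The ambiguity study corpus used by the disambiguation property test is
150 documents with `ambiguity_rate = 0.5` and `association_density = 2.5`:
resolvable-by-context ambiguity presupposes sentences that actually carry
co-mentions, which is what the higher density provides. The
interchangeable-token corpus (300 tokenized sentences, two planted tokens
substituted into identical context templates) backs the embedding
similarity property, measured over 20 seeds.

What the generator does **not** emulate — and therefore what green tests do
not establish about real literature: natural prose variation, discontinuous
and nested mentions, abbreviation definitions with scope, document-level
coreference, OCR/encoding noise, and realistic ambiguity far beyond two-way.
Real-corpus precision/recall will be far below the synthetic 1.0; the
synthetic corpus verifies the *machinery*, not the linguistic difficulty.

## Numerical and procedural choices

* Offsets: 0-based half-open characters, everywhere.
* Rounding: half away from zero; metrics 2 decimals, percentages 1 decimal.
* Degenerate metric inputs: P, R, F1 are 0 on empty denominators;
  `mapped_fraction()` refuses `total = 0`.
* Tie-breaks: tagger — longest match, then leftmost; disambiguation —
  first candidate in identifier order at equal similarity; ranking —
  identifier order within equal scores.
* Determinism: a single seed drives the generator, embedding training and
  hence the whole pipeline; two runs with one config are byte-identical,
  and the acceptance script asserts this.
* Test problem sizes: 200-document corpora for exact-recovery checks,
  150-document corpora for the ambiguity study, 100 randomized instances
  per oracle-equivalence property, 20 seeds for the embedding property —
  sizes at which every property is measurable in seconds on one CPU.

## Known limitations

* The gazetteer tagger is the *baseline* system by design; no model
  inference is implemented. External taggers can inject mentions through
  the same `Mention` contract.
* Only strict and partial evaluation modes; no bootstrap intervals or
  significance tests on metric differences.
* Grounding covers GP/DS/CD; organisms are tagged but never grounded.
* The ranking formula and the cascade confidences are package conventions,
  not community standards; both are isolated and documented for
  replacement.
* Relation *classification* (altered expression, genetic variation,
  regulatory modification…) is intentionally absent: co-occurrence is
  treated as the universal association set, and the kappa tooling is there
  to quantify why annotating finer relations is unreliable.
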