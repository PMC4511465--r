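---
title: "Recursive pairwise event extraction: model, features and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recursive pairwise event extraction: model, features and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The extraction model

`eventpairs` treats biomedical event extraction as multi-class
classification of *(candidate, argument)* pairs. Nine event types are
modelled, in three classes: single-theme events (SVT: Gene_expression,
Transcription, Protein_catabolism, Phosphorylation, Localization), Binding
(BIN: up to two protein themes), and regulations (REG: Regulation,
Positive_regulation, Negative_regulation; theme and optional cause may be
proteins *or events*). Within a sentence, candidate trigger entities come
from a gazetteer of stemmed token sequences harvested from the training
annotation; argument entities are the annotated proteins. Each pair gets a
linear score per label in the set Y = {nine types} ∪ {None}; the pair's
decision is the score argmax, with ties broken in a fixed label order and
None last.

Inference is a score-ordered agenda. All candidate × protein pairs are
scored up front; the globally best pair is popped, and if its label is not
None an event is created. Creating an event makes its trigger entity
available as an argument: pairs (c_i, c_α) are then added for every other
candidate c_i (once per distinct trigger entity, even when several events
share the trigger — argument features encode event-hood, not event type or
multiplicity). Pairs whose acceptance would close a cycle in the event
graph are censored, so the extracted set is a DAG at every step and the
agenda pops at most |C_S|·(|A_S| + |C_S|) pairs. When an accepted pair's
argument entity anchors several events, the created regulation takes the
first-created (highest-scoring) event with that trigger as its theme; this
keeps the event graph well-defined without enumerating combinations.

Two assumptions matter. First, events are sentence-bounded: gold events
whose trigger and arguments span sentences are dropped at read time with a
message. Second, recall is bounded by the gazetteer: a trigger whose
stemmed form never occurs in training cannot be proposed at test time.

## Features

Feature vectors are sparse binary indicators in three namespaces.
*Candidate* features (window half-width 2 by default): head-token stem,
stem with `-`/`/` stripped, substring after a hyphen, head POS, separator
position flags, special prefixes (`over`, `up`, `down`, `co`), parent and
child (dependency-label, stem/POS) conjunctions, window stems and POS with
explicit `<PAD>` slots at sentence boundaries, window separator flags, a
sentence-level `mRNA` flag, and the protein-masked coarse token when the
entity is embedded in a larger token (`PROT-expression`, `PROT-express`).
*Argument* features (half-width 1): an is-protein flag, head POS, optional
interaction labels from a local protein lookup table, window features and
the parent conjunction. The is-protein flag is what lets the classifier
enforce that only regulations take event arguments — and the scorer
additionally masks non-REG labels to −∞ for event-valued arguments.
*Joint* features: V-walks (token, label, token) and E-walks (label, token,
label) along the undirected shortest dependency path between the two head
tokens, each in stem and POS variants as a bag of walks, plus a
proteins-in-between flag and a shared-coarse-token feature (`ARG-express`
style). `punct` and `det` edges are pruned before the path search (a
config knob), and walks are emitted only for paths of at most 4 edges;
longer or absent paths simply contribute no walk features.

Walk strings encode direction with arrows: a downward edge (head first)
prints as `head LABEL ←dependent` (e.g. `regul PREP_OF ←promot`), an
upward edge as `dependent LABEL → head`; E-walk terminals use `START` and
`END` sentinels. Protein masking rewrites feature surfaces only — a token
inside a protein span becomes `PROT`, a partially overlapping token has the
overlap replaced (`LPS-activated` → `PROT-activated`) — character offsets
are never touched.

Two tokenizations feed these features: the fine layer (from the token
table, which also carries POS and the dependency parse) drives everything
path- and window-based, while a coarse whitespace layer that keeps
hyphenated compounds intact supports the shared-token and embedded-token
features. The package consumes parses as data and never runs a parser;
corpora must ship a token table per document.

## Training

For each label, a one-vs-rest linear SVM with L1 hinge loss and asymmetric
costs is fitted by dual coordinate descent (implemented in C++; the bias is
an augmented constant feature, the solver's shuffling is seeded, and
refits are bitwise reproducible). The per-type cost pair is chosen from
the grids C⁺ ∈ {0.001, 0.01, 0.1, 1, 10, 100} and
C⁻ ∈ {0.001, 0.01, 0.05, 0.1, 1, 10} by cross-validation maximizing that
type's binary F-score in isolation; folds are assigned at *document* level
(5 by default) to avoid sentence leakage, and ties go to the first grid
point in a fixed order. Training pairs are the candidate × protein sets of
every sentence, labeled from gold, *enriched* with candidate × gold-trigger
pairs for the regulation and None scorers — gold triggers, never model
predictions, stand in for event arguments, so training needs no inference
and batch solvers apply. A Binding with two themes contributes one pair
per theme. If a gold trigger is not covered by any candidate the event is
logged and skipped for labeling.

The cross-validated confusion matrix reported by `summary()` is the sum of
per-fold confusion matrices on left-out pairs, with every scorer refitted
per fold at its selected costs.

Post-processing uses two binary classifiers trained with the same cost-grid
machinery. *Binding fusion*: for triggers sharing two or more predicted
Binding singletons, each unordered theme pair is classified; accepted
merges are applied greedily by descending score, each singleton consumed at
most once (a deliberate choice — the annotation also allows one singleton
to participate in several gold merges, so a relaxation flag may be worth
adding; the greedy rule keeps the theme multiset invariant). Positives
come from gold two-theme Bindings, negatives from co-trigger theme pairs
not merged in gold. *Cause assignment*: candidate causes are the
sentence's proteins and other extracted events (excluding the event's own
theme); accepted causes attach in descending score order, one per event,
with attachments that would create a cycle censored. Features for both are
the union of the trigger's candidate features, both arguments' argument
features, both trigger–argument joint sets and an argument–argument joint
set. A classifier with no gold positives is disabled; with positives but
no negatives it accepts everything (the one-class case is unavoidable on
small corpora).

The None score accepts an additive shift δ at prediction time
(`delta`), which is how `pr_curve()` traces precision–recall trade-offs:
the sweep is computed at pair level, before post-processing.

## Evaluation

`evaluate_events()` implements approximate-span, recursive matching: a
prediction matches a gold event iff types are equal, the predicted trigger
span lies within the gold span extended by one fine token on each side
(`mode = "exact"` switches to span equality), and arguments match
recursively — proteins by identity, event arguments by a matching event
under the same criteria, Binding themes as an unordered pair, causes both
absent or both matching. Matching is computed as a greatest fixpoint over
the nesting structure followed by a greedy one-to-one assignment ordered by
the fixed type order and offsets. F1 is 2PR/(P+R) with 0/0 counted as 0;
class totals micro-aggregate the SVT/BIN/REG groups. The exact official
semantics for partially correct nested structures are a matter of
convention; the strict-recursive rule here is declared rather than derived,
and is the conservative choice.

## The synthetic corpus generator

Shared-task corpora cannot be redistributed, so the generator produces
standoff corpora from a small set of syntactic templates ("The X of P was
detected.", two-theme "of P1 to P2", cause "by P2", regulation chains "The
X of the Y of P…", and a distractor template using trigger lemmas in
non-event contexts) with hand-specified dependency parses emitted in the
token table. The default trigger lexicon assigns disjoint lemma sets to
the nine types and the default type mix is weighted toward expression and
regulation types as in real Genia-style data; Binding takes a second theme
with probability 0.4, regulation themes nest with probability 0.4 up to
depth 2, and causes occur with probability 0.3. These defaults were chosen
once as a plausible miniature of the real annotation densities.
`make_separable_corpus()` additionally verifies lemma-stem disjointness, so
the trigger stem plus local path features admit a perfect linear separator
— that is what makes the perfect-recovery test meaningful.

What passing on synthetic data does and does not show: the generator
exercises the full format and event structure (nesting, fusion, causes,
DAG constraints, id plumbing) and makes end-to-end recovery a sharp
correctness check, but its language is templated — no annotation
inconsistency, no paraphrase, no parser noise, no cross-sentence discourse.
F-scores on it say nothing quantitative about performance on real
biomedical text; the original task's scores require the official corpora
and test server.

The test suite and `scripts/acceptance.R` use 200 sentences (40 documents)
for the separable study and 500 sentences with 20% distractor noise, split
70/30 by document, for the held-out study — sizes chosen so the full cost
grid (36 points × 10 types × 5 folds) remains comfortable on one core.

## Numerical and degenerate-case choices

The DCD solver runs at most 1000 epochs to projected-gradient tolerance
0.1 with shrinking (the standard settings for this solver family); binary
problems with a single class yield constant ±1 scorers. Agenda ties on
equal scores break lexicographically by candidate offset, then argument
offset, then label order. Empty candidate sets, empty sentences,
disconnected dependency graphs and over-threshold paths are all ordinary
inputs, not errors. Sentence splitting uses provided spans verbatim when
available (the token table's sentence grouping) and a simple
terminal-punctuation rule otherwise. The Porter stemmer is implemented in
the package (idempotent on the vocabulary used, verified in tests), and
`PROT` is exempt from stemming so masked tokens stay distinguished. The
protein interaction table is a packaged synthetic snapshot
(`inst/extdata/protein_kb_synthetic.tsv`); live database queries are out
of scope for reproducibility.

## Known limitations

Cross-sentence events are dropped, not modelled. Bindings with three or
more themes are not produced (pairwise fusion only). The gazetteer is
closed-vocabulary. One cause per regulation event. The walk-string arrow
convention is one of several in circulation; it is fixed and documented
here, and only its consistency matters to the classifier.
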