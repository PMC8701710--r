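---
title: "Grammar-constrained text-to-SQL for EMR questions: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grammar-constrained text-to-SQL for EMR questions: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medsql)
```

## The problem

Clinicians ask questions like *"tell me the insurance and primary disease of
james sloan"* against an electronic-medical-record database whose answer is a
SQL query over a handful of joined tables. `medsql` translates such questions
into executable SQL for a fixed relational schema. Instead of emitting SQL as
a word sequence, the model emits a **tree-structured intermediate
representation**: a derivation under a small context-free grammar whose
terminals are schema columns, tables, and question spans. The tree renders
deterministically to SQL, so the decoder can never produce an unparseable
query, and order ambiguities of raw SQL text (join order, select-column
order) do not multiply the output space during learning.

## The grammar

The production inventory is fixed at 24 rules:

* `Z -> R` (a single query; no compound set operators exist in this query
  family),
* `R -> Select` and `R -> Select Filter` (with or without a Where clause),
* `Select -> A | A A | A A A` (one to three projected columns),
* seven aggregator rules `A -> agg C T` with
  `agg ∈ {none, max, min, count, sum, avg, count_distinct}`,
* `Filter -> and|or Filter Filter`,
* eight comparison rules `Filter -> op A V` with
  `op ∈ {=, !=, >, >=, <, <=, like, not like}`, and
* `Filter -> between A V V`.

`count(distinct …)` is its own aggregator because it appears as a distinct
surface form in the query family. The Select arity cap of three keeps the
inventory at exactly 24 while covering the observed 1–3 projected columns.
Multi-condition Where clauses nest **right-leaning**; the renderer inserts
parentheses only where a child connective binds less tightly than its
parent, so rendering followed by re-parsing is the identity on every
grammar-valid tree (a property the test suite checks on 1000 random trees).

A derivation serializes depth-first, left-to-right into four action types:
`ApplyRule` (expand a nonterminal), `SelectColumn`, `SelectTable`, and
`SelectValue` (a start/end token span of the question, 0-based inclusive).
The serialization is a bijection: `actions_to_tree()` inverts
`tree_to_actions()` exactly, and any sequence accepted step-by-step by
`valid_actions()`/`apply_action()` parses to a tree.

## Schema linking

Before encoding, question n-grams (n = 5 down to 1, left-to-right within a
length) are matched against column and table names, which are lower-cased
and underscore-split for matching. An n-gram matches a name exactly (same
word sequence) or as a **word-set subset** (so "days stay" links to
`days_stay`). A double match takes the column mark, since columns outrank
tables; once an n-gram is fixed, overlapping candidates are discarded;
every remaining token becomes its own unmarked span. Subset matching is the
weakest reading that still links partial mentions; exact matches outrank
subset matches, and ties fall back to schema declaration order, so linking
is deterministic. Linking spans partition the question exactly — a property
tested on every generated corpus.

## Encoder

The marked question and the schema are serialized into one token stream:
`[cls]`, each question span's words followed by a mark token
(`[mcol]`/`[mtab]`/`[mnone]`), `[sep]`, every column's name words each
followed by `[sep]`, then the table names. A self-attention encoder over
this stream produces per-position hidden vectors; each span's (and each
column's/table's) positions are average-pooled through a shared
fully-connected `tanh` layer into the span matrix `H_X`, column matrix
`H_C`, and table matrix `H_T`. The decoder starts from
`tanh(W · h_cls + b)` of the `[cls]` position.

Two representational choices matter:

* **Positions restart inside schema blocks.** Question positions are
  sequential (word order carries meaning there), but every column/table
  block restarts its position ids and instead carries a segment embedding
  identifying the table it belongs to. Self-attention is otherwise
  order-free, so column encodings are exactly equivariant under reordering
  columns within a table, while same-named columns of different tables
  (`subject_id` appears in all five) remain distinguishable through their
  segment.
* **The encoder backend is a contract.** Any map from the token stream to
  per-position vectors qualifies. The package trains a small transformer
  from scratch (desk defaults: width 32–48, 1–2 layers, 2 heads,
  post-layer-norm, ReLU feed-forward); a pretrained bidirectional
  transformer at width 768 with a 300-wide decoder is the documented
  large-scale configuration for users with such weights, and ablations in
  the literature show the architecture tolerates different encoders.

## Decoder

A single LSTM emits all four action types in depth-first order (the
coarse-to-fine structure is realized as this skeleton-then-leaf ordering
within one decoder, not as two networks). At each step the previous
action's embedding is the recurrent input (rule embeddings for
`ApplyRule`; the column/table/span encodings themselves for terminal
actions). The hidden state attends over `H_X` (context `v`) and over
`[H_C; H_T]` (context `u`) by scaled dot-product with learned query
projections. Heads:

* **ApplyRule** — softmax over the frontier's admissible productions of
  `e(r)·W_r[h; v; u]`.
* **SelectColumn** — a memory-enhanced pointer. A sigmoid gate over
  `[h; v]` mixes a schema branch (bilinear pointer over columns **not yet
  selected**) with a memory branch (pointer over the already-selected
  columns). Once selected, a column moves from the schema branch into
  memory; while the memory is empty the schema branch is used alone.
* **SelectTable** — a pointer over `H_T` masked to the tables containing
  the just-selected column; with schema-qualified columns this prunes to a
  single table.
* **SelectValue** — independent start and end pointers over question
  spans; the end pointer is conditioned on the chosen start (its query
  includes the start span's encoding) and masked to spans at or after it,
  so emitted spans are always well-formed. Span-level pointer mass maps to
  token positions through each span's first (start) or last (end) token.

Every head is masked to the grammar-admissible set from `valid_actions()`,
with probability exactly zero elsewhere, and each step's distribution sums
to one over that set. Greedy decoding is the default; because of the
masking, any parameter setting — including a freshly initialized model —
yields a parseable sequence and engine-accepted SQL. Near the 128-action
budget the recursive `and`/`or` productions are masked out so a completion
always exists; exceeding the budget raises an incomplete-output error.

Extracted condition values are finally snapped to database content:
for text-kind columns the stored value with the highest **ROUGE-L**
(LCS-based F1 over lower-cased word tokens) replaces the extracted span,
with exact case-insensitive matches short-circuiting and ties resolved to
the first stored value in first-seen order. Numeric values pass through
verbatim — snapping "2123" to an unrelated stored number would be worse
than leaving it.

## Rendering SQL

Select items render in child order as `table."column"` with lower-case
keywords; values are double-quoted. The From clause is reconstructed from
the tree's table leaves: the first referenced table is the origin and every
further table is connected by breadth-first shortest path over the schema's
join-key edges (declaration order breaks ties), rendered as inner joins.
Logic-form accuracy compares **canonical token sequences** (lower-cased,
whitespace- and quote-normalized, `<>` mapped to `!=`), which preserves
order everywhere — swapped select columns or join tables break a
logic-form match. Execution accuracy runs both queries on a SQLite fixture
and compares result tables with column order respected and rows as
multisets (the query family has no ORDER BY); result-column labels echo
query text and are not compared. The five-component breakdown compares, as
unordered collections per pair: aggregator multiset, aggregation-column
set, table set, (condition column, operator) pairs, and case-folded
condition values; an unparseable prediction scores zero on all five.

## Training

Training is teacher-forced maximum likelihood of gold action sequences
(value steps contribute both pointer log-probabilities), with Adam,
batches of 8, and global gradient-norm clipping at 5.0. Gold sequences are
derived by parsing the gold SQL and locating each condition value's token
span in the question. Model selection keeps the parameters with the best
validation logic-form accuracy under greedy decoding. The package's
learning-rate default for the small from-scratch backend is 5e-4; the
corpus-scale experiments use 2e-3 with a per-epoch decay of 0.85 (a large
initial rate for fast early progress, decaying so the plateau settles
rather than oscillates) over up to 12 epochs, stopping early once
validation accuracy clears 0.97. This converges in a few minutes of CPU
time on a 3000-pair corpus; the transformer layer's forward and backward
passes are compiled (RcppArmadillo), everything else is plain R matrix
algebra. (Fine-tuning a large pretrained encoder is a different regime —
order 1e-6 over ~100 epochs.) All gradients are hand-derived matrix
algebra; the test suite checks them against central finite differences on
a tiny configuration.

## The synthetic corpus

No clinical data ships with the package. The generator emulates a
template-built EMR question corpus: five tables (demographic, diagnoses,
procedures, prescriptions, lab) with 23/5/5/7/9 columns star-joined on the
admission key, synthetic patients with referential integrity, and ~30
weighted question templates covering every production of the grammar —
all aggregators, all comparison operators, `between`, `and`/`or`, one to
three select columns, and zero to three conditions. Template weights are
set so the corpus averages ≈1.05 select columns and ≈1.5 conditions per
query, near the shape reported for the kind of corpus it emulates (means
1.1 and 1.76; the generator's test asserts agreement within ±0.3). Every
condition value is inserted verbatim into the question, which guarantees
gold value spans exist — the property the pointer supervision needs.
Optional paraphrase noise (default rate 0.3) applies seeded synonym
substitution and filler-word dropout outside value spans, emulating
crowd-sourced rephrasing.

What the generator does **not** emulate: free rephrasings that drop or
alter value mentions (real crowd workers produce some), genuinely held-out
question *templates*, lexical overlap between values and schema names, and
clinical realism of the values themselves. Passing the held-out evaluation
therefore demonstrates parameter recovery under the stated conditions —
same templates, unseen values and combinations — not transfer to real
clinical text. Reproducing published results on the credentialed EMR
corpus this design targets would additionally require those data and a
fine-tuned pretrained encoder, both out of scope here.

## Numerical and degenerate-input choices

* Masked softmax assigns exact zeros outside the admissible set; the
  mixture gate is bypassed while the column memory is empty.
* Stored text values are lower-cased at load and questions are lower-cased
  at tokenization, so rendered conditions match stored content;
  execution-side string comparison is therefore effectively
  case-insensitive. Whether the original corpus matched strings
  case-sensitively at execution time is not documented; this choice is
  flagged for anyone comparing against it.
* Numeric columns are created with SQLite NUMERIC affinity, so quoted
  numeric condition values ("2123") compare numerically.
* An empty question is rejected at inference; an empty stored-value pool
  returns the extracted value unchanged with a warning.
* Ties everywhere (argmax, linking candidates, recovery scores) break to
  the first index, making every pipeline stage deterministic under fixed
  seeds.

## Problem sizes used by the shipped experiments

The test suite and acceptance script train the desk-scale model (encoder
width 32, 1 layer, 2 heads; decoder width 64) on corpora of 3000 pairs
over 300 patients, evaluating on the held-out tenth. These sizes were
chosen as the package's reference experiment: large enough that every
template appears hundreds of times and held-out accuracy is a meaningful
recovery measure, small enough to train in minutes on one CPU core.
Smaller fixtures (hundreds of pairs) back the unit and property tests.

## Known limitations

* Single schema per model; no cross-database generalization, nested
  queries, GROUP BY/ORDER BY/LIMIT, outer joins, or set operators — absent
  from the query family by construction.
* Value linking against cell content happens only after decoding (ROUGE-L
  recovery), not during linking.
* The SelectColumn universe is schema-qualified, so the name-level
  candidate count differs from implementations that deduplicate column
  names across tables.
* Beam search is not implemented; decoding is greedy.
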