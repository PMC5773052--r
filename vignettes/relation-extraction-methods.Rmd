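---
title: "Extracting protein localization relations: models, features, evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting protein localization relations: models, features, evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locrex)
```

## The task and its decomposition

Given an abstract, which protein-in-compartment relationships does it
attest to? The deliverable is a set of *document-level normalized
relations* — pairs of a UniProtKB accession and a GO Cellular Component
identifier — each linked to the sentences that support it, because a
curator will only accept an annotation they can verify against the text.

`locrex` decomposes the task in the way the field's extraction systems
do: named-entity recognition and normalization, binary classification of
candidate mention pairs, aggregation to normalized relations, and a
document-level evaluation protocol. The package treats the tagger and the
syntactic parser as *contracts*: any component that produces offset-sound
normalized mentions, or token tables with lemmas, POS tags and dependency
heads, plugs in. A naive dictionary tagger and hand-parsed fixture
sentences are shipped so that nothing external is required to run or test
the pipeline.

## Candidate instances

Candidates are all (protein mention, location mention) pairs at sentence
distance 0 (configurably 1). Labels come from gold relations at *exact
character offsets*: the same normalized relation attested three times
yields three positive instances. Pairs at larger distances produce no
instance at all; the gold relations there become irrecoverable false
negatives at evaluation time. This is a deliberate precision-first
trade-off: admitting distant pairs multiplies candidates (mostly
negative) and the package's scope is the same-sentence extractor plus the
machinery to quantify exactly what that choice costs — the recall
ceiling. With a fraction $q_0$ of unique relations in the same sentence,
a D0-only extractor's recall is bounded by $100\,q_0$ and its F-measure
by the harmonic mean of 100 and $100\,q_0$ (`recall_ceiling()`).

## Feature families

Five families, all emitted as named sparse features
(`family|stream|n|content`), binary for n-grams:

* **Entity counts** (`cnt`): mention counts in the covering sentence(s),
  divided by the per-feature maximum observed in training. Training
  values land in [0, 1]; a larger test count scales above 1 (count 11
  against a training maximum of 10 gives 1.1). The family is
  configurable; the default emits two features (protein+location count,
  total count), a compact choice documented here because count
  parameterizations in the 2-vs-4-feature range are equally defensible
  and the selector prunes redundant ones anyway.
* **Marker flag** (`dom|marker`): the protein surface, tokenized and
  lowercased, matches a reporter-protein lexicon (GFP, red fluorescent
  protein, ...). Reporter constructs are fused to the protein under
  study; their mentions are poor annotation subjects.
* **Known-annotation flag** (`dom|sp`): the pair is already in a
  protein→GO table, directly or with the mentioned term a descendant of
  a tabled term.
* **Linear n-grams** (`lin`): n = 1..3 over tokens strictly between the
  pair, in a masked-lemma stream (lowercase lemma; numerals → `NUM`;
  tokens of other entity mentions → `PROTEIN`/`LOCATION`/`ORGANISM`) and
  a POS stream. In n ≥ 2 grams the pair itself contributes `SOURCE`
  (left mention) and `TARGET` (right mention); adjacent mentions produce
  only `SOURCE|TARGET`.
* **Dependency-path n-grams** (`dep`): the unique shortest path in the
  undirected dependency tree between the two mention head tokens (the
  token of each mention whose head lies outside it), in masked-lemma,
  POS and edge-label streams. Edge direction is not encoded, and the
  path is canonicalized to run SOURCE→TARGET, so traversal order cannot
  leak into the features.

Masking precedence is total — pair endpoint > entity class > `NUM` >
lemma — so every token maps to exactly one unit. `SOURCE`/`TARGET`
assignment is by linear position by default, with a role-based switch
(`mask_mode = "role"`); by-position matches the way the linear family is
naturally read, and the tests pin the equivalence of the two conventions
on reversed-order sentences.

Word tokenization (for the tagger, marker matching and the parse-free
fallback) splits contiguous letters and digits ("P53" → "P", "53"),
which makes identifier variants comparable.

## Feature selection and the classifier

Tens of thousands of n-gram features arise from a few hundred instances;
most are correlated. Selection uses an L1-penalized linear
support-vector classifier with squared hinge loss,

$$\min_{w,b}\; \|w\|_1 + C \sum_i \max(0,\, 1 - y_i(x_i^\top w + b))^2,$$

at C = 2, solved by accelerated proximal gradient (FISTA) with
soft-thresholding; the intercept is unpenalized, the iteration starts at
zero and is fully deterministic, so no solver seed exists. Features with
nonzero weight are kept (|w| > 1e-6; the tolerance only guards against
floating-point dust, as converged FISTA zeros are exact). Kept-set size
grows with C, which the tests check on a C grid spaced by orders of
magnitude — adjacent C values can swap correlated features, so only the
coarse monotone trend is a stable property.

The final model is a separate linear-kernel SVM (libsvm via `e1071`)
refit on the kept features, not the selector itself: selection and
margin fitting are different jobs, and the two-stage design lets the
final cost constant (`c_final`, default 1) be tuned independently of the
selection trade-off. The final hyperparameters are deliberately plain
defaults — cost 1, no class weights, decision threshold 0 — all exposed
as arguments; raising the threshold trades recall for precision, the
regime curation prefers. The decision rule is strict: margin exactly at
the threshold predicts *unrelated*, a tie-break that must be pinned
somewhere and is pinned conservatively.

## Aggregation and evaluation

Mention-level predictions collapse to unique document-level (accession,
GO id) pairs, expanding ambiguous mentions over all their identifiers.
With hierarchy collapsing, a term that is a strict ancestor of another
retained term for the same protein is dropped: the child is the more
exact annotation. A unique relation's sentence distance is the minimum
over its supporting mention pairs — the easiest available evidence; a
flag switches to counting all supports, since either convention is
defensible for multi-support relations.

Matching is asymmetric by design: a predicted GO term equal to *or a
descendant of* the gold term is correct (more specific is still right);
an ancestor is not. Descent is the transitive closure over combined
`is_a` and `part_of` edges — "part of a compartment" places a protein
inside it just as subclassing does, and the closure is reflexive.
Protein equality is exact accession match by default; a pluggable
equivalence predicate accommodates near-identical database entries
(≥90% sequence identity) via a precomputed accession-pair table, because
pinning a sequence database snapshot inside the package would be worse
than exposing the hook.

Counting is per gold relation: one matched gold relation is one true
positive however many predictions match it; predictions matching nothing
are false positives; missed gold relations are false negatives. P, R
and F are percentages from pooled counts; a zero denominator reports 0
with an explicit degenerate flag (the conservative convention — an
extractor that predicts nothing on a corpus with gold relations scores
0, not undefined). Reported tables round to integer percent; raw floats
stay in the machine-readable output. Micro-averaging (pooled counts) is
the default; per-fold macro numbers are available from `tidy()` on the
cross-validation object.

Cross-validation is 5-fold over *documents* (60% train / 20% validation
/ 20% test; every document tested exactly once), because mention-level
splits would leak repeated attestations of the same relation across
folds. The bootstrap standard error resamples 15% of the test documents
without replacement, 1000 times, and reports

$$\sigma = \sqrt{\tfrac{1}{n-1}\textstyle\sum_i (x_i - \langle x\rangle)^2},
\qquad \mathrm{StdErr} = \sigma/\sqrt{n},$$

with $\langle x\rangle$ the statistic on the *entire* test set rather
than the bootstrap-sample mean. That convention is unusual — with the
sample mean substituted it reduces to the classic standard error of the
mean, which the tests verify — but it is retained as stated so the error
bars are comparable with the protocol it implements.

## The fixture corpus: what it emulates, what it does not

`generate_fixture_corpus()` builds documents from hand-parsed sentence
templates: positive templates phrase a localization relation ("X is
localized to the Y", "The Y is the final destination of X", "X
accumulates in the Y", plus two- and three-sentence variants for
distances 1 and 2), negative templates co-mention a pair without
relating it (negation, hedging, incidental co-occurrence). Each unit
draws a protein and location unused elsewhere in the document, so
document-level unique relations correspond one-to-one to planted
positives, which makes the co-mention baseline's precision exactly the
planted positive rate — an analytically known target the acceptance
tests exploit.

Defaults mirror the corpus structure the method family was developed
against: a 100-abstract scale of study, about two thirds of unique
relations in the same sentence and 15% in adjacent ones
(`distance_mix = c(D0 = .66, D1 = .15, D2 = .19)`), and roughly 47%
negatives among same-sentence candidate pairs (`negative_rate = 0.47`,
the 312-of-663 proportion such corpora show). Documents carry 2–4 units
plus an organism sentence; entity names come from small curated
dictionaries with real-looking UniProtKB/GO/taxon identifiers.

What passing on fixtures shows: every pipeline stage is wired correctly,
the features separate relational from non-relational phrasings, folds do
not leak, aggregation and scoring follow the stated rules, and the
learned extractor dominates the co-mention baseline in precision when
distractors are present. What it does not show: performance on real
abstracts. Template language has none of the lexical variety, parser
noise, nested mentions, normalization ambiguity or annotation
disagreement of a curated corpus, so fixture P/R/F values are properties
of the construction, not estimates of real-world accuracy. Runs against
a real annotated corpus require only a reader to this package's corpus
format (a documented JSON container; a converter stub is the intended
extension point).

## Numerical and degenerate-input choices

* Offsets are 0-based half-open over raw text; surfaces must equal the
  text slice or loading fails with an error naming the entity.
* Sentence spans straddled by an entity are merged (splitters err on
  abbreviations; same-sentence logic needs each entity in one sentence).
* Malformed normalization identifiers are pruned on load with a warning;
  the mention survives unnormalized.
* Unparseable sentences degrade gracefully: dependency features are
  absent, linear features fall back to raw tokenization, and the vector
  is flagged degraded.
* An empty kept-feature set (tiny C) yields an intercept-only model
  predicting the majority class rather than an error.
* GO identifiers absent from the loaded ontology fail the location
  whitelist (closed-world filtering) and never match by hierarchy.
* Problem sizes in the shipped tests and the acceptance script — fixture
  corpora of 2–120 documents, 1000 random trees for the path oracle,
  1000 bootstrap replicates — were chosen as the smallest sizes at which
  the checked properties are statistically meaningful.

## Known limitations

* No real parser or production tagger is bundled; both are contracts.
  The dictionary tagger is a fixture-scale reference implementation
  (longest match, no disambiguation beyond stopwords and taxid filters).
* Same-sentence (optionally adjacent-sentence) extraction only; the
  recall ceiling machinery quantifies, but does not lift, that bound.
* Protein equivalence beyond exact accession match depends on a
  caller-supplied predicate or pair table.
* The GO whitelist roots are this package's reading of "organelles,
  membranes, extracellular region"; they are configuration, not ground
  truth.
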