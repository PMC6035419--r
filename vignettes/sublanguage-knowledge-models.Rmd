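---
title: "Inducing knowledge models from report sublanguage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inducing knowledge models from report sublanguage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sublangr)
```

## The problem and the approach

Clinical report text in a narrow domain — radiology image reports are the
motivating case — behaves as a *sublanguage*: a restricted register with a
small inventory of semantic types and a handful of recurring syntactic
frames. That restriction is exploitable. Instead of hand-writing an ontology
or training a supervised extractor, `sublangr` mines the patterns directly:

1. **Segmentation.** Reports are reorganized into short clause segments at
   punctuation and conjunction-like words, because the frames of interest
   live at the clause level.
2. **Triple extraction.** Each segment's constituency parse is matched
   against a small set of embedded verb-phrase structures to produce
   `Subject:Relationship:Object` (SRO) triples. Entities are *maximal*
   NP/ADJP phrases; the relation keeps its surface inflection.
3. **Semantic tagging.** Each entity phrase receives exactly one semantic
   type from a pluggable lexicon, by the last-recognizable-entity rule.
4. **Network induction.** Tagged triples accumulate into a directed
   co-occurrence network over semantic types, pruned to its dominant
   nodes and edges.
5. **Knowledge model.** Fine-grained types are regrouped into 14 coarse
   semantic categories, the network is lifted to category level, and
   manually curated relationship labels are attached.

The package also implements the corresponding evaluation metrics
(one-vs-rest precision/recall/F, relationship coverage, inter-rater
agreement) and a deterministic synthetic-corpus generator so the whole
pipeline is testable offline.

## The SRO extraction model

Within a clause `(S (NP …) (VP …))` the verb phrase is classified by its
embedded structure, most specific first:

| pattern | shape | relation | example |
|---|---|---|---|
| P3 | `V + VP(V + PP(P + NP))` | verb verb prep | "A **is associated with** B" |
| P1 | `V + VP(V + NP)` | verb verb | "A **has become** B" |
| P2 | `V + PP(P + NP)` | verb prep | "A **present with** B" |
| P4 | `V + NP + PP(P + NP)` | verb | "A **demonstrated** a patient with previous history" |
| SIMPLE | `V + NP` | verb | "lesion **shows** enhancement" |
| PP_ONLY | `NP(NP + PP(P + NP))` | prep | "frontal view **of** vertebral body" |

The precedence order P3 > P1 > P2 > P4 > SIMPLE > PP_ONLY is a design
choice: P3 structurally contains both P1 and P2, so matching the most
specific shape first prevents double extraction. The test suite checks this
ordering against an exhaustive shape enumeration on randomly generated
clause trees.

Two object-span conventions are worth spelling out, because they decide how
prepositional attachment surfaces in the model:

* A PP that is a **sibling** of the object NP under the VP (the P4
  "postpositive" shape) is combined into the object: the object of
  "A demonstrated a patient with previous history" is the whole phrase
  "a patient with previous history", and the embedded "a patient : with :
  previous history" is additionally emitted as a PP_ONLY triple.
* A PP **nested inside** the object NP leaves the verb's object as the NP
  core, and the PP chain is unrolled recursively. "There are foci of
  intensely increased radiotracer uptake in T9" therefore yields exactly
  three triples — `There:are:foci`,
  `foci:of:intensely increased radiotracer uptake in T9`,
  `intensely increased radiotracer uptake:in:T9` — rather than six
  sentence-level pairings, which is the point of phrase-level extraction.

Existential "There" is kept as a literal subject; it is simply untaggable
downstream and the pair drops out of the network. Negation gets no special
semantics: "not" is an adverb and attaches to the Relationship as a
modifier. Adverbs in general attach, per triple, to the role whose token
span contains them (subject NP, object NP including its PP chain, or the
matched VP).

```{r}
tree <- read_ptb(paste0(
  "(S (NP (EX There)) (VP (VBP are) (NP (NP (NNS foci)) ",
  "(PP (IN of) (NP (NP (NN uptake)) (PP (IN in) (NP (NN T9))))))))"))[[1]]
triples_to_df(extract_sro(tree))[, c("pattern_id", "subject", "relation", "object")]
```

## Semantic tagging: one tag per phrase

Tagging all nouns in a phrase separately produces lists like
*Location + Body Part + Observation* for "right breast pain"; the model
instead assigns one type per phrase, the type of the **last recognizable
entity**. The rule is operationalized as: among all token windows matching
the lexicon, pick the window whose *last token is rightmost*, breaking ties
by window length. "Last" fixes the end; "maximal" motivates the longest
match. Because the source phrasing could also be read as scanning for the
rightmost *start*, both variants are exposed (`scan = "rightmost-end"`,
the default, or `"rightmost-start"`); they differ only on phrases where a
match begins after another match ends.

No stemming or lemmatization is applied by default — plural stripping is an
opt-in flag (`strip_plural = TRUE`) — and matching is case-insensitive on
punctuation-stripped text. The bundled `mini_lexicon()` is a synthetic,
hand-curated list of ~110 radiology terms covering all 44 semantic types of
the default category map with at least two terms each; it exists so that
tests and examples run without any licensed vocabulary, and it makes no
attempt to mirror real corpus frequencies.

```{r}
lex <- mini_lexicon()
tag_phrase("right breast pain", lex)[c("semantic_type", "matched_term")]
```

## Network induction and the knowledge model

Every tagged triple contributes one *co-occurrence incidence* to the
ordered pair (subject type, object type); edges are directed and self-loops
are legal (Pathology:Pathology pairs are common in practice). Pruning keeps
the `top_nodes` most frequent types — default 40, after which entity
coverage tends to plateau in domain corpora — plus four expert-chosen types
(Body System, Receptor, Organism Function, Biomedical or Dental Material)
that are retained regardless of frequency, then the `top_edges` heaviest
edges (default 100) plus any expert-chosen pairs. Ties at a cutoff are
broken lexicographically and logged: the tie-break is arbitrary but must be
deterministic. Entity coverage (kept frequency mass over total) is reported,
not asserted, because it is a property of the corpus at hand.

The 14-category regrouping reuses five general-purpose types as their own
categories and groups the remaining 39 into nine domain categories; the
default map is embedded and checked by the test suite (14 categories, 44
types, fixed per-category counts). Lifting the network to category level
sums contributing type-pair weights; endpoints outside the map route to a
residual bucket so total weight is conserved exactly.

Relationship labels are **loaded, never inferred**: labeling is a manual,
expert task, and the same surface preposition maps to different labels in
different category pairs ("of" is Situated_at in Location:Body Part but
Indicative_of in Observation:Pathology). The bundled default label table
carries the documented surface-to-label examples; the default expert-edge
file ships the single documented pair (Substance:Observation) plus a
commented template, since the remaining conceptually important pairs are an
empirical, corpus-specific judgment. "Significant" flags on categories and
relationships are computed as top-*N* by total occurrence with *N*
configurable (default 10), since significance is defined by occurrence
counts without a stated threshold.

## Evaluation metrics

Machine annotations are scored against a rater consensus with one-vs-rest
confusion counts per category: precision TP/(TP+FP), recall TP/(TP+FN),
F = 2PR/(P+R), with zero denominators yielding 0 under a warning. Units
whose reference label is outside the model (`OUT_OF_MODEL`) are excluded
from per-category metrics but remain in coverage denominators. For display,
percentages round half-up to one decimal and F to four decimals. Relationship
coverage is the fraction of raters' tags present in the model's label set,
and agreement is the fraction of units where two raters chose the same
label.

## The synthetic corpus: what it does and does not emulate

`generate_fixtures()` builds a corpus from clause templates — one per
pattern id — whose entity slots cycle through a seeded shuffle of the whole
mini-lexicon. Everything derives from a single PRNG stream keyed by `seed`,
so equal seeds give byte-identical bundles. Default study conditions, chosen
once as plausible for a small annotated report sample and held fixed:

* 20 documents (50 in the end-to-end checks), 3–5 clause segments each,
  uniform mix over the six patterns;
* `noise = 0.05`: one phrase in twenty is an out-of-lexicon token,
  emulating unrecognized abbreviations and rare terms;
* `disagreement = 0.08`: the second simulated rater departs from the first
  on 8% of units, consistent with initial inter-rater agreement in the
  low-90s typically reported for semantic annotation of report text;
* `ref_flip = 0.10`: the consensus departs from the machine's gold category
  on 10% of units, so machine-vs-reference metrics are non-trivial;
* `novel_tag_rate = 0.03`: raters occasionally invent relationship tags the
  model does not list, keeping relationship coverage below 1.

The generator guarantees *coverage* — all fourteen categories and all six
patterns appear at 20+ documents — but does not attempt to mimic a real
corpus's Zipfian type-frequency distribution, parse errors, coordination,
typos, or long multi-clause sentences. Passing the end-to-end identity test
(gold triples and tags recovered exactly at `noise = 0`) therefore
demonstrates the pipeline's internal correctness on clean parses, not its
robustness to real parser output; with real reports, extraction quality is
bounded by the external parser and lexicon supplied.

Gold trees are built by template rather than by running a parser, so the
tests have no parser dependency; an external-parser adapter would slot in
where `read_ptb()` consumes bracketed trees.

## Numerical and degenerate-input choices

* Character spans are 0-based half-open; token spans likewise. One stated
  convention avoids off-by-one drift between segmenter, extractor and tests.
* Segmentation protects decimal points (`2.5`), digit:digit ratios
  (`1:30` — the treatment of colons inside times is unstated in the source
  description, so protection is the default and configurable), and
  single-capital abbreviation periods; word splitters match whole
  case-folded tokens only, so "android" never splits on "and".
* Empty documents yield zero segments; trees without NP/ADJP yield no
  entities; segments matching no pattern yield no triples and are counted
  as uncovered rather than erroring.
* Duplicate conflicting lexicon rows and doubly-mapped semantic types are
  load errors, not silent overwrites.
* Problem sizes in the shipped tests (50-document end-to-end runs, 1000
  random phrases and 400 random trees for the oracle-equivalence
  properties) were chosen to exercise every code path while keeping the
  default suite fast.

## Known limitations

* One triple per VP: coordinated VPs each yield a triple, but NP
  coordination inside a slot is not split.
* No coreference, no negation/uncertainty semantics, no word-sense
  disambiguation, no spell checking or abbreviation expansion.
* Relationship labeling is manual by design; automatic labeling would be a
  separate modeling effort.
* PP chains are emitted from object slots only; a PP inside a verb's
  *subject* NP is left in place, which loses occasional relations but never
  fabricates one.
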