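# sublangr

Data-driven sublanguage pattern mining for domain-restricted report text.
`sublangr` turns a corpus of short clinical reports (the motivating case is
radiology image reports) with constituency parses and a semantic lexicon
into a *knowledge model*: a graph of coarse semantic categories linked by
labeled, weighted relationships, induced bottom-up from the text itself
rather than written top-down as an ontology.

The pipeline, for users doing clinical NLP or knowledge-base construction:

1. **Segment** reports into short clauses (period/comma/colon plus
   conjunction-like word splitters, with decimal/abbreviation protection).
2. **Extract** `Subject:Relationship:Object` (SRO) triples from
   Penn-Treebank parse trees. Entities are maximal NP/ADJP phrases; the
   relation is a verb, verb chain, verb+preposition, or bare preposition,
   matched via embedded VP/PP structures in most-specific-first order
   (P3 > P1 > P2 > P4 > SIMPLE > PP_ONLY). Adverbs become role modifiers.
3. **Tag** each entity with exactly one semantic type by the
   last-recognizable-entity rule: the lexicon window ending rightmost in
   the phrase (longest on ties) labels the whole phrase.
4. **Induce** a directed co-occurrence network: each triple contributes one
   incidence to the ordered pair (subject type, object type); prune to the
   top-40 types and top-100 edges plus expert-chosen additions.
5. **Regroup** the 44 fine-grained semantic types into 14 semantic
   categories, lift the network, attach manually curated relationship
   labels, and export the model (JSON / GraphML / DOT).
6. **Evaluate** with one-vs-rest precision / recall / F per category,
   knowledge-model relationship coverage, and inter-rater agreement:

   Precision = TP/(TP+FP), Recall = TP/(TP+FN), F = 2·P·R/(P+R),
   Coverage = #(raters' tags covered by the model)/#(tags),
   Agreement = agreed/(agreed+disagreed).

A deterministic synthetic-corpus generator (`generate_fixtures()`) with
gold trees, triples, tags and simulated raters makes the whole pipeline
testable offline; `example_corpus()` carries seven worked sentences with
hand-built gold analyses.

## Worked example

```r
library(sublangr)

tree <- read_ptb(paste0(
  "(S (NP (EX There)) (VP (VBP are) (NP (NP (NNS foci)) ",
  "(PP (IN of) (NP (NP (NN uptake)) (PP (IN in) (NP (NN T9))))))))"))[[1]]
triples_to_df(extract_sro(tree))[, c("pattern_id", "subject", "relation", "object")]
#>   pattern_id subject relation        object
#> 1     SIMPLE   There      are          foci
#> 2    PP_ONLY    foci       of  uptake in T9
#> 3    PP_ONLY  uptake       in            T9
```

Phrase-level extraction yields three tight relationships instead of six
sentence-level pairings. Tagging assigns one type to a whole phrase:

```r
lex <- mini_lexicon()
tag_phrase("right breast pain", lex)[c("semantic_type", "matched_term")]
#> $semantic_type
#> [1] "Sign or Symptom"
#>
#> $matched_term
#> [1] "breast pain"
```

"right breast pain" is one Sign-or-Symptom entity (category *Observation*
after regrouping), not a list of three tags. End to end on the synthetic
corpus:

```r
cfg <- pipeline_config(out_dir = "run",
                       fixture = fixture_spec(seed = 1, n_documents = 10))
run_pipeline(cfg)
jsonlite::fromJSON("run/metrics.json")$overall
#> $precision
#> [1] 0.9042553
#>
#> $recall
#> [1] 0.9042553
#>
#> $f_score
#> [1] 0.9042553
```

which writes `segments.tsv`, `triples.tsv`, `tagged_triples.tsv`, network
exports, `model.json` and `metrics.json` under `run/`. The same stages are
available from a shell via `inst/cli/sublang.R`:

```sh
Rscript inst/cli/sublang.R all --config cfg.yaml --out run
```

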