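# ordbench

Benchmarking structured reaction extraction against ORD-style records.

## What this is for

Synthetic organic chemistry records most of its knowledge as free-text
procedure paragraphs. Structured repositories such as the Open Reaction
Database (ORD) represent the same content as nested, typed records —
`inputs` holding compounds with identifiers, amounts and reaction roles,
`conditions`, an ordered list of `workups`, and `outcomes` with products and
yields. Tools that extract the latter from the former (fine-tuned LLMs,
rule-based parsers, NER pipelines) need corpora to train on and a scoring
scheme that understands nested objects. `ordbench` provides that loop for
tool builders and evaluators:

* **Corpus preparation** under explicit admission rules (every input has
  components; a procedure paragraph exists), *implicit-information
  scrubbing* (product names and yield values not literally stated in the
  text are removed, by logged path), prompt/completion rendering through an
  instruction template, prompt-keyed deduplication, an inclusive
  2048-token length filter and a seeded 8:1:1 train/validation/test split.
* **Heuristic JSON repair** for almost-valid model completions (missing
  quotes/commas/brackets, trailing commas), as a forgiving parser with a
  logged action list; valid input is a byte-identical fixed point.
* **Schema validation** against a declarative, versioned vocabulary of the
  modeled ORD subset (enum strictness, scalar types, unknown fields).
* **Evaluation metrics.** Messages (whole compounds, workups, conditions,
  products) and leaf fields (individual scalars) are each classified as
  Accurate / Removal / Addition / Alteration. Message lists are matched by
  a padded minimal-cost bijection under a nested edit distance
  *d*(a, b) = #(leaf paths in exactly one tree) + #(shared paths with
  unequal values), with repeated sub-lists aligned recursively and
  *d*(x, EMPTY) = #leaves(x). A lenient routine treats compound-like
  messages as equal when identifiers and amounts agree, isolating
  entity/relation quality from implicit-field errors.
* **Name recognition scoring** (normalized-edit-distance matching of name
  multisets) and **reaction-role classification** evaluation with a
  seeded popularity baseline, confusion matrices with MISSING/ERROR
  columns, and macro-F1.
* **A synthetic fixture generator** producing USPTO-register (procedure
  text, record) pairs, plus a perturbation engine that injects *logged*
  corruptions — the known-answer oracle behind the test suite.

Everything is tidyverse-shaped: corpora and tallies are tibbles,
evaluations have `tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

```r
library(ordbench)

# a 20-reaction synthetic corpus, deterministic under the seed
corpus <- gen_corpus(gen_config(n_reactions = 20, seed = 7,
                                compounds_range = c(2, 4)))
cat(substr(corpus$procedure_text[1], 1, 130), "...\n")
#> A solution of methyl iodide (43.46 g) in diethyl ether (40 mL) was stirred
#> at 110 °C. The solid was recrystallized from hot ethano ...

# corrupt each prediction with logged perturbations
pred <- corpus
for (i in seq_len(nrow(corpus))) {
  pred$record[[i]] <- perturb(
    corpus$record[[i]],
    list(compound = c(alter = 1), workup = c(remove = 1)),
    seed = 100 + i
  )$record
}

report <- aggregate_report(evaluate_records(corpus, pred))
td <- tidy(report)
td[td$variant == "strict",
   c("message_type", "accurate", "removal", "alteration", "total",
     "accurate_pct")]
#> # A tibble: 4 × 6
#>   message_type       accurate removal alteration total accurate_pct
#>   <chr>                 <int>   <int>      <int> <int>        <dbl>
#> 1 Compound                 42       0         20    62         67.7
#> 2 ProductCompound          20       0          0    20        100
#> 3 ReactionConditions       20       0          0    20        100
#> 4 ReactionWorkup           45      20          0    65         69.2
glance(report)
#> # A tibble: 1 × 4
#>   n_reactions message_mean_accuracy_pct message_mean_accuracy_strict_pct
#> 1          20                      87.0                             84.2
```

Each perturbed record lost one workup (20 removals over 65 ground-truth
workups) and had one compound leaf altered (20 alterations over 62
compounds); the tallies recover the injected corruption counts exactly, and
the lenient mean (87.0) exceeds the strict one (84.2) because some compound
alterations touched only the reaction role, which the lenient routine
ignores.

Report arithmetic utilities reproduce printed-table conventions:

```r
tally_percentages(tibble::tibble(accurate = 38470, removal = 2242,
                                 addition = 1015, alteration = 4242,
                                 total = 44954))$accurate_pct
#> [1] 85.6
format_param_count(adapter_param_count(10, 30, 4096))
#> [1] "1.2 million"
```

## Package layout

* `R/` — schema model, record parsing/validation, nested distance and
  matching, evaluation and reports, name/role scoring, corpus prep, JSON
  repair, synthetic fixtures, pipeline.
* `inst/extdata/` — schema vocabulary (JSON) and the prompt template.
* `inst/scripts/ordbench.R` — thin command-line wrapper
  (generate / perturb / repair / validate / evaluate).
* `vignettes/ordbench-methods.Rmd` — the methods vignette: metric
  definitions, design decisions, generator assumptions, limitations.
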