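---
title: "Scoring structured reaction extraction: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring structured reaction extraction: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordbench)
```

## The problem

Organic synthesis procedures are written as free-text paragraphs; structured
databases such as the Open Reaction Database (ORD) store the same content as
nested, typed records. Extraction systems — fine-tuned language models,
rule-based parsers, NER pipelines — translate the former into the latter, and
benchmarking them requires (a) training/evaluation corpora built under
well-defined admission and scrubbing rules, and (b) a scoring scheme that
works on *nested objects* rather than flat label sequences. `ordbench`
implements both sides of this loop at desk scale, together with a synthetic
data generator that makes every metric testable against a known answer.

## The record model

We model the subset of the ORD `Reaction` message exercised by its four
chemically central members: `inputs` (a map of `ReactionInput`, each with
`Compound` components), `conditions` (a single `ReactionConditions` message),
`workups` (an ordered list of `ReactionWorkup`) and `outcomes` (with
`ProductCompound` products). The subset is declared in a versioned JSON
vocabulary (`inst/extdata/ord_schema_subset.json`) listing each field path,
its kind and, for enum fields, the admitted strings — the full ORD schema has
over 600 fields, and a data-driven subset keeps the differ generic while
allowing extension. Validation is syntactic in the ORD sense: enum fields are
matched case-sensitively against their vocabulary (mirroring protobuf enum
strictness), scalar kinds are type-checked, and unknown fields are flagged.
Unpopulated fields are *absent* (explicit nulls are stripped at parse), which
makes "populated leaf count" — the backbone of the distance below —
well defined.

Leaves are addressed by dotted paths with zero-based bracketed list indices
and quoted map keys, e.g. `inputs["m1"].components[0].identifiers[0].value`.

## The evaluation metrics

Two granularities are scored, both with the same four-way taxonomy
(*Accurate / Removal / Addition / Alteration*):

* **Message level.** For each message type, how many whole messages were
  extracted exactly, dropped, invented, or changed?
* **Leaf level.** The same question for individual scalar fields, bucketed
  by field type (identifiers, amount, reaction role, condition, workup,
  other).

The distance between two messages is a nested edit distance: the number of
leaf paths present in exactly one tree plus the number of shared paths with
unequal values, where repeated sub-lists are first aligned by the
minimal-cost pairing of their items (recursively). The distance from any
message to the empty message equals its number of populated leaves. Scalars
compare numerically after parse (`5 == 5.0`) and strings exactly after
trimming, so serialization dialects cannot create spurious alterations.
Numeric tolerance is deliberately not used: for extraction tasks a missing
or misplaced number is the dominant failure mode, and exact match keeps the
metric interpretable.

Lists of messages are compared by padding the shorter list with empty
messages and finding the bijection minimizing the summed distance. The
assignment is solved by an O(n^3) augmenting-path Hungarian algorithm
written in the package (no assignment solver is available among our
dependencies), and the test suite cross-checks it against exhaustive
enumeration of all bijections for every list length up to six. Because only
the shorter side is padded, pad–pad pairings cannot occur. Ties among
equal-cost bijections are canonicalized deterministically (the lower
ground-truth index takes the lower prediction index whenever the swap is
cost-neutral), so reports are byte-reproducible.

Mode attribution follows the assignment: a pair with a ground-truth pad is
an Addition, with a prediction pad a Removal, distance zero is Accurate and
anything else an Alteration. Leaf attribution inherits from it: every leaf
of a Removed message is a removed leaf, every leaf of an Added message an
added leaf, and Accurate/Altered pairs classify each aligned leaf
individually. Totals count ground-truth messages only
(`accurate + removal + alteration = total`), with additions reported over
the same denominator, so percentages conserve. The message level is strictly
more stringent: an Accurate message has zero leaf-level failures.

`ReactionConditions` is a single message, never a list, so only Accurate
and Alteration apply to it; an unparseable prediction counts as the total
removal of all ground-truth messages (and an alteration of the conditions).

**A structural property worth knowing.** Under this distance,
`d(a, b) <= leaves(a) + leaves(b)`, with strict inequality whenever the two
messages share any leaf path (two compounds always share
`identifiers[0].type`). Pairing a dropped ground-truth message with an
invented predicted message is therefore never more expensive than giving
each a pad. Consequently, when a removal and an addition of the same message
type occur in the *same* list comparison they surface as a single
Alteration; Removals and Additions arise from length differences between
the lists. The synthetic perturbation oracle respects this: it never injects
adds and removes of one message type into the same record, which is exactly
the regime in which the logged corruption counts are provably recoverable.

**Lenient equivalence.** Much of the error mass in product extraction comes
from *implicit* fields: calculated yields, texture, isolated color — content
derived rather than stated. The lenient routine treats two compound-like
messages as identical when their identifier multisets (type/value pairs)
and all amount-bearing leaves agree, ignoring everything else; for input
compounds this also ignores the reaction role, which is an inference task
rather than extraction. Lenient tallies upgrade qualifying Alterations to
Accurate and are reported alongside the strict ones.

Report percentages are printed at one decimal with half-up rounding
(`round()`'s banker's rounding disagrees with how such tables are
conventionally printed), and the headline message-level figure is the
unweighted mean of per-type accuracies using the lenient variants.

## Corpus preparation

A record is admitted when every `ReactionInput` has at least one component
and a non-empty procedure paragraph is attached. Two scrubbing rules then
remove *unlearnable* implicit information: a NAME identifier whose value
does not occur in the paragraph, and a YIELD measurement whose integer
percentage is not stated there. Name matching is a case-insensitive
substring search after whitespace normalization; yield matching searches
the integer part as a decimal string under word boundaries. These are the
simplest faithful readings of "explicitly stated"; both rules are
idempotent, and removals are logged by path. The whole YIELD measurement
message is dropped rather than its bare value leaf, so no dangling
measurement without a value survives.

Prompt/completion pairs are rendered through an Alpaca-style instruction
template; the completion is the record's canonical JSON. Deduplication keys
on the prompt string only (completion conflicts are logged, not resolved).
The token limit defaults to an inclusive 2048 under a deterministic
word-plus-punctuation tokenizer — counts are tokenizer-dependent, and a
subword tokenizer can be substituted; we read "limit" inclusively as the
conventional meaning. Splitting is a seeded shuffle followed by
largest-remainder apportionment of the normalized 8:1:1 ratios, recorded
in the prep report.

## JSON repair

Model completions are occasionally almost-JSON. Repair is implemented as a
forgiving recursive-descent parser that consumes the malformed text into a
structure while logging each fix (missing quotes, commas, colons, brackets;
trailing commas; trailing garbage), then re-serializes canonically. Valid
input is a byte-identical fixed point; repair of its own successful output
is the identity; and on the fuzz family used in the tests — deleting any
single quote or closing bracket from a valid record — the success rate is
asserted to be 100%. Semantic repair (wrong field names, hallucinated
fields) is deliberately out of scope: those are the evaluator's to count,
not the repairer's to hide.

## Name recognition and role classification

The compound-name task compares the multiset of NAME identifier values in
a record (referencing tokens such as "desired product" count as names)
against a prediction, pairing names by minimum-total-cost matching with the
normalized Levenshtein distance as pair cost and a pad cost of 1; zero-cost
pairs are Accurate, matched non-identical names Alterations. Names are
compared case-sensitively after whitespace normalization, since chemical
names are case-meaningful (NaH vs nah).

Role classification treats each input compound's single `reaction_role`
(REACTANT / SOLVENT / CATALYST in patent-derived corpora; products are
always PRODUCT and excluded) as a three-class problem. The confusion matrix
gains two extra prediction columns: MISSING when no predicted compound
pairs with a ground-truth compound, and ERROR when the paired compound's
name is wrong — role classification presupposes correct extraction. The
popularity baseline assigns each name its most frequent training-set role,
breaking ties and unseen names uniformly at random (seeded). Macro-F1
averages per-role F1 over the three classes, with MISSING/ERROR counted as
false negatives of the true role; a zero-support class contributes 0 to the
average (the convention is ours, stated rather than inherited, and
configurable in principle).

## The synthetic generator

The generator emulates the register of patent procedure text ("A solution
of X (a g) in Y (c mL) was stirred at T °C … The residue gave P (d g,
e%).") over a small lexicon of real solvent, catalyst and reactant names
with per-name role distributions — solvents draw SOLVENT with probability
0.90, catalysts CATALYST with 0.85, reactants REACTANT with 0.92, the rest
spread over the alternatives — so roles are context-dependent the way they
are in real corpora. Amounts are drawn without replacement from
parse-canonical decimal grids, names are distinct within a record, and
every name and integer yield appears verbatim in the text ("consistent
mode"), so scrubbing removes nothing unless `p_omit_product_name` is raised.
All generation is seed-deterministic.

The perturbation engine applies logged add/remove/alter corruptions at
uniformly sampled sites. Alterations change exactly one leaf to a fresh
value guaranteed distinct from every other value in the record, so a
corrupted message stays at distance 1 from its origin but at distance >= 2
from every other message — the optimal matching is unambiguous and the
evaluation tallies must equal the log exactly, which is what the recovery
tests assert on 500 reactions.

What the generator does *not* emulate: linguistic variety (one sentence
frame per record), chemical plausibility of the combinations, abbreviation
and alias noise, OCR artifacts, or the long-tailed length distribution of
real patent paragraphs. Passing the recovery and conservation tests
therefore demonstrates that the *metrics* are implemented correctly, not
that any particular extractor performs well on real text.

## Problem sizes and numerical choices

The test suite and the acceptance script run the matching oracle on 1000+
random instances with list lengths up to six (exhaustive enumeration tops
out at 720 bijections), the perturbation-recovery check on 500 synthetic
reactions, and the repair fuzz on every single-character deletion of quotes
and closing brackets across ten records (several hundred corruptions) —
sizes chosen to exercise every code path many times while keeping a full
run comfortable on a laptop. Degenerate inputs are defined rather than
accidental: empty lists match to empty pair sets, a zero denominator
reports `NA` rather than a number, an all-empty confusion matrix has
undefined macro-F1, and infeasible perturbation requests fail naming the
message type that is short.

## Known limitations

* The nested distance fixes one reasonable definition (unit cost per
  missing/extra/unequal leaf, recursive list alignment); parity with any
  specific external nested-diff utility is not claimed, and non-uniform
  level weighting is not supported.
* The schema vocabulary is a subset; records using ORD fields outside it
  validate as "unknown field" rather than being understood.
* Token counts from the default tokenizer are not comparable to subword
  tokenizers; corpus retention under a token limit is therefore
  tokenizer-relative.
* The popularity baseline ignores context by construction; it is a floor,
  not a competitor.
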