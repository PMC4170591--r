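---
title: "Hybrid curation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid curation: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridcurate)
```

This vignette is the package's own account of the methods it implements:
what each stage assumes, which parameters matter, what the synthetic-data
generators do and do not emulate, and the choices made where the design was
genuinely open.

## Text model

An abstract is `display_text = title + "\n" + body`. All stand-off
annotations are 0-based, half-open intervals over this string, counted in
Unicode code points, and every annotation must reproduce its slice exactly
(`validate_standoff()` enforces this everywhere). The MEDLINE reader keeps
only PMID, TI and AB; records lacking AB get an empty body and a warning,
since a title alone can still carry a mutation mention.

## Mutation extraction

Recognition is a two-step filter: a registry of named surface-form
patterns proposes matches, and a stop-list vetoes them. Both ship as
plain-text TSV tables (`inst/extdata/`) and are user-extensible; the
registry covers HGVS-like nucleotide substitutions (`c.758C>T`, `758C>T`),
one- and three-letter protein substitutions (`R117H`, `p.G12D`,
`Arg 117 His`), prose forms ("T to C at position 59", "substitution of Pro
for Ser"), and dbSNP `rs` identifiers, which are kept as semantic mentions
and never decomposed into triples. Overlapping matches resolve
longest-first, then leftmost-first, then registry order — so `c.758C>T`
always beats the shorter `758C>T` reading inside it.

Standardization yields ⟨level, wild, mutant, position⟩ with three-letter
amino acids mapped to one-letter uppercase and RNA `U` mapped to `T`. A
bare one-letter `X123Y` is read at the protein level: the one-letter amino
acid alphabet contains the nucleotide letters, and the protein reading is
the common usage in abstracts; `>`-forms and `c.` prefixes force the
nucleotide level. When a wild/mutant pair carries no in-pattern position,
the surrounding text is searched for the nearest integer within
`window_w = 200` characters per side (nearest by character distance, ties
leftward), and the concept is flagged **nonlocal**. Nonlocal positions are
the dominant source of concept-level error in this design — the window can
capture a number at the wrong coordinate level — which is why
`drop_nonlocal` exists as a first-class configuration: it trades
end-to-end recall for precision, and `score_relations()` asserts exactly
that direction.

The coding filter removes concepts with negative positions and concepts
whose mention sentence (period/semicolon split) names an intron, IVS, UTR,
untranslated region or promoter; the keyword set is a parameter.
Stop-codon and synonymous substitutions are not recognized by default — a
deliberate fidelity choice to the extractor generation being emulated, and
a known recall loss — and `mutation_patterns(include_stop = TRUE)` opts
in. Positions are kept exactly as printed; no reference-genome validation
is attempted.

## Gene tagging

The native path is a longest-match gazetteer over a human gene lexicon
(the lexicon is the species filter), with a case rule — symbols of ≤5
characters match exactly, longer names case-insensitively — because short
symbols are case-brittle (`was` vs `WAS`) while long names are not. On top
of it sits the abbreviation filter: parenthesized short forms are paired
with their spelled-out long forms by Schwartz–Hearst right-to-left
character alignment (with the pragmatic extension that unalignable
trailing digits are dropped, so `ESR1` pairs with "estrogen receptor
alpha"), and a gene mention equal to a defined short form survives only if
the long form — whole, or by default any contiguous word subsequence of it
— is a lexicon name for the same gene id. The subsequence interpretation
of "part of the long form" is configurable to whole-match-only
(`partial = FALSE`). The filter never touches mentions that are not
defined short forms, and never removes a concept that has one. The
fidelity path, `ingest_external_genes()`, accepts stand-off output of an
external normalizer unchanged.

## Candidates and controls

Candidates are the per-abstract cross product of distinct gene and
mutation concepts; the item id is the readable composite key
`pmid|entrez|level|wild|position|mutant`, which is deterministic and
auditable. dbSNP-only mutation concepts are excluded by default because an
rs identifier already names its gene. Controls are drawn **with
replacement** from the control pool and interleaved uniformly at random so
that the expected control share equals `fraction` (default 0.2); with
1078 test items this gives streams of ≈1350 slots. Injection is per item
stream rather than per worker stream — equivalent in expectation and much
simpler to audit; the simulator routes the shared stream to workers.

## The crowd simulator

The simulator emulates the *structure* of a crowd experiment: a worker is
(sensitivity, specificity, inconsistent-rate, volume); ability is a
two-component Beta mixture (default 80% competent, mean 0.85; 20%
below-chance, mean 0.35), volumes are log-uniform on 1…stream-length
(matching the observed "one worker did everything, one did a single item"
heavy tail), and a 5-item qualifier passed at 4 correct gates entry. The
third response ("Inconsistent annotation") is modeled truth-independent at
1.4%, its observed rate. Latent truths come from the scenario ledger; the
default positive rate is 371/1078 ≈ 34%. Because log-uniform volumes can
undershoot the k×items capacity a stream needs, `simulate_crowd()` tops up
the population until qualified capacity covers the stream with slack — a
crowd platform has an open worker supply — while `simulate_judgments()`
itself refuses shortfalls loudly.

What the simulator does **not** emulate: item difficulty (errors are
i.i.d. given the worker), learning and fatigue, payment-sensitive
behavior, and correlated errors between workers. Tests that pass on
simulated crowds therefore establish the correctness and qualitative
behavior of the aggregation machinery, not the accuracy a real crowd
would achieve; real headline accuracies depend on a real corpus and real
workers.

## Aggregation

Each worker is one Naïve Bayes feature. From control items only,
`profile_workers()` tallies response counts by control truth
(Inconsistent excluded) and forms add-α-smoothed likelihoods (α = 1);
an item's posterior log-odds is `log(prior/(1−prior)) + Σ log
P(r|true)/P(r|false)`, label YES iff strictly positive. Choices worth
stating:

* **Prior 0.5** by default (configurable): the judged class rate is not
  known upstream of judging. Evaluation code accepts any prior, so
  sensitivity to `prior ∈ {0.3, 0.5, class rate}` is one call away.
* **Ties go to NO**: conservative for database deposit, where a false
  deposit is costlier than a miss.
* **Two-sided profiles** (separate likelihoods per response) strictly
  generalize a single "control accuracy" and reduce to it on balanced
  controls; a worker at exactly 50% on balanced controls has unit Bayes
  factors and contributes nothing, and with α = 0 this is exact.
* **Inconsistent = abstention** (likelihood 1 under both classes);
  `inconsistent = "as_no"` is available since the response is rare (1.4%).
* Workers with no countable controls get a flagged uniform profile rather
  than an error: they contribute nothing, which is the defensible default
  for an unknown worker.

Redundancy ablation (`truncate_to_n()`) keeps the *n* earliest judgments
per slot by timestamp (ties by worker id), simulating having asked for
less redundancy. Dynamic firing (`dynamic_fire()`) removes every judgment
of workers whose **final** control accuracy is below chance — the post-hoc
simulation the design calls for — with an online variant (running
accuracy, `min_controls`) behind a flag. Firing can raise aggregate
accuracy because Naïve Bayes still gives poor workers nonzero weight,
while firing ignores them entirely.

## Evaluation

Entity concepts score by membership: genes on (pmid, EntrezGene id),
mutations on (pmid, triple). Entity precision is reported but approximate
by construction — the gold standard only lists entities involved in a
curated relation — so recall is the primary entity metric. Relation
scoring splits YES decisions into tp/fp and NO decisions into judged-fn/tn
by gold membership, and reports precision, accuracy, HIT recall
tp/(tp+fn_judged), and end-to-end recall tp/|gold|; the two recalls differ
exactly by the relations the extractors never surfaced. `drop_nonlocal`
changes only the item set, never the gold denominator. Mention-span
scoring is deliberately not implemented; the stand-off slice invariant is
the only span-level check.

Pairwise agreement uses Cohen's κ with per-rater marginals over the shared
items and three categories (Inconsistent included); κ is undefined (NA
with a note) when both raters are constant and identical. Surface
rescoring overrides the gold-derived truth of an item only when a
three-annotator expert panel is unanimous.

Report rounding mirrors the conventions of the tables this framework
reproduces: ratios to 3 decimals, percentages to 1 decimal, and money
*truncated* to the cent (521.29/275 = 1.8956 displays as $1.89) —
truncation, not rounding, is what the published cost cells follow (with a
single one-cent exception at n = 1 that no consistent rule reproduces).

## Problem sizes

The test suite runs its property checks on crowds of 100–300 items and
8–15 workers over 20–100 seeds, and the acceptance script simulates one
full-scale stream (1078 test items, ~20% controls, 5-fold redundancy) plus
200 template sentences for extractor recall; these sizes give stable
statistics for every asserted ordering while keeping a full run in the
low minutes on one CPU.

## Known limitations

* The pattern registry targets point substitutions only: insertions,
  deletions, frameshifts and fusions are out of scope, as is mapping rs
  identifiers to triples.
* The gazetteer path has no disambiguation beyond the lexicon and the
  abbreviation filter; ambiguous symbols shared by two human genes resolve
  to the first lexicon entry.
* The gold-standard TSV schema is package-defined (the reference corpus
  format is unpublished); a documented example ships as a fixture.
* Simulated accuracies are optimistic relative to real crowds (see the
  simulator section); only orderings and gains should be read across.
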