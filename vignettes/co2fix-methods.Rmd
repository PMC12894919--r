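---
title: "Marker-rule prediction of CO2 fixation pathways: model, design and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-rule prediction of CO2 fixation pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(co2fix)
```

## The prediction model

`co2fix` decides presence or absence of the seven known natural CO2
fixation pathways from a genome's KO profile — the set of KEGG Orthology
identifiers assigned to its proteins. The decision procedure is a
three-level boolean formula per pathway:

* a **clause** is a quantifier over a KO set: `all_of` (every KO required;
  multi-subunit complexes such as ATP-citrate lyase or the archaeal
  CODH/ACS complex), `one_of` (any KO suffices; evolutionarily distinct
  enzymes catalysing the same reaction, such as the three fumarate
  hydratase classes), or `at_least(k)` (a subunit quorum; used only where
  per-subunit essentiality is uncertain, namely the glycine cleavage
  system, 3 of 4, and the seven-subunit glycine reductase, 5 of 7);
* a **variant** is the conjunction of its clauses (a mechanistic type of
  the pathway, e.g. rTCA-I vs rTCA-II, bacterial WL-I vs archaeal WL-II);
* a **pathway** is the disjunction of its variants.

The model assumes presence/absence only: copy number is discarded, because
no rule uses multiplicity. All three quantifiers are monotone in the
profile, so the whole predictor is monotone — a superset of annotation can
only add calls, never remove them. This property is tested directly
(1,000 nested profile pairs) and is also what makes the synthetic recall
analysis below exact.

Marker choice embeds several discriminations worth knowing about:
ribulose-phosphate 3-epimerase is required alongside RubisCO and
phosphoribulokinase so that the archaeal RHP route is not called CBB;
succinyl-CoA:L-malate CoA-transferase separates the 3HP bicycle from
3HP/4HB; PEP carboxylase and fumarate hydratase separate DC/4HB from
3HP/4HB, whose dehydratase KO (K14534) both share. The validator reports
such cross-pathway KOs rather than rejecting them. Organisms whose rTCA
runs on oxidative-TCA citrate synthase have no discriminating marker and
are out of scope by design, as are hybrid bacterial/archaeal WL forms.

## Rule set encoding

Rules are data, not code: `builtin_ruleset()` returns the curated set (42
distinct marker KOs; 3/5/7/3/7/7/11 per pathway), and any rule set
round-trips through a canonical JSON dialect (`serialize_ruleset()` /
`load_ruleset()`) with stable key and list order, so serialization is
byte-deterministic. Design choices that were genuinely open:

* Marker-table rows of one variant are interpreted as a conjunction of
  clauses — each row is a required marker enzyme — while the "or"/"and"
  wording within a row maps to `one_of`/`all_of`.
* Pathways with a single mechanistic form are modelled as one variant
  whose id equals the pathway id.
* Machine-readable pathway ids are slash-free tokens (`3HP4HB`, `DC4HB`);
  display names keep the slashes. Variant ids keep their conventional
  form (`3HP/4HB-I`).
* Evaluation is order-independent; authored order is preserved purely for
  reproducible serialization and stable matrix column order.
* Per-variant evidence (`rTCA-I` vs `rTCA-II`) and matched-KO diagnostics
  are reported with every call; the binary matrix collapses variants. This
  is an extension beyond a bare presence/absence output, flagged as such
  in the documentation.

## KofamScan ingestion

The supported input is the KofamScan detail-TSV (significance mark, gene,
KO, adaptive threshold, bit score, E-value, definition) — the only
KofamScan tabular format carrying the score and per-family threshold the
assignment rule needs. Per gene, every significant hit contributes its KO;
a gene with hits but no significant one contributes exactly one fallback
KO, that of its top-scoring hit. Numerical conventions:

* The asterisk column is trusted when present. If a file carries no
  asterisks at all, significance is recomputed as `score > threshold`;
  hits whose family has no adaptive threshold (`-`) are treated as
  never-significant and hence fallback-eligible.
* Fallback ties on score break by lowest E-value, then lexicographically
  smallest KO id. The choice is arbitrary but total, so assignment is
  deterministic and invariant under row permutation (tested by property).
* No score floor is applied to the fallback.
* Manual curation of off-target KOs is a human step we do not automate;
  `assign_kos(exclude = ...)` is the mechanical hook for it.

Degenerate inputs: empty files yield empty profiles; short rows and
unparseable numerics fail with the line number; KO-list tokens that do not
match `K#####` are skipped with a warning rather than aborting a whole
genome.

## Benchmarking conventions

Predictions and curated labels meet as binary genome-by-pathway matrices,
joined by genome id (never by row position); genomes present on one side
only are dropped and counted. Per pathway, precision = TP/(TP+FP), recall
= TP/(TP+FN), F1 their harmonic mean. Zero denominators score 0 rather
than NaN, the same convention used for pathways outside a tool's
prediction scope (`supported = FALSE`, all metrics 0). True negatives are
computed although the headline metrics ignore them; they cost nothing and
enable specificity extensions. Mapping other tools' native outputs (e.g.
MetaCyc pathway ids) onto the seven columns is left to user-prepared
matrices.

## What the synthetic corpus emulates — and what it does not

`generate_corpus()` stands in for a curated benchmark corpus with known
composition. Per pathway it emits positive genomes carrying the **full KO
complement of one variant** plus `background_k` decoy KOs, then deletes
each marker KO independently with probability `dropout_p`; near-miss
negatives are minimal satisfying profiles with one critical KO removed
(one `all_of` member, the only included `one_of` member, or one `at_least`
member so the count falls to `min_count - 1`). Truth labels record the
intended pathway *before* dropout, so dropout degrades recall but never
precision — the two metrics are isolated on purpose. Decoys are drawn from
`K90000`–`K90999`, outside real KOfam space, so false positives are
impossible in a clean corpus and precision 1 is an exact expectation, not
a statistical one.

Positives carry the full variant complement (not the minimal profile)
because that makes the detection probability under dropout a clean closed
form: `(1-p)^m` per `all_of` clause over *m* KOs, `1 - p^r` per `one_of`
over *r* alternatives, and `P[Binomial(n, 1-p) >= k]` per `at_least(k of
n)`; a variant's detection probability is the product over its clauses
(their KO sets are disjoint within a variant). `variant_detection_prob()`
exposes the closed form, and the test suite checks it against exhaustive
subset enumeration (up to 2^11 subsets for rGly) as an independent oracle.

Defaults were fixed once as desk-scale study conditions: `n_per_pathway =
50`, `variant_choice = "all"` (so rTCA-II, WL-II and 3HP/4HB-II are
exercised, not just first variants), `dropout_p = 0`, `background_k = 20`,
`negatives_per_pathway = 10`, and multi-pathway genomes at the observed
co-occurrence counts among chemolithoautotroph genomes (3 CBB+WL, 2
WL+rGly). Validation runs use explicit sizes: 10,000 random subsets of
the 42 marker KOs for oracle equivalence, 1,000 nested pairs for
monotonicity, and 500 positives per variant at `dropout_p = 0.1` for the
recall analysis, where observed recall must fall within 3 binomial
standard errors of the closed form.

The corpus does **not** emulate real genomes: no protein sequences, no
realistic HMM score distributions, no phylogenetic correlation between
markers, no genome incompleteness beyond independent per-KO dropout, and
background KOs that are guaranteed-disjoint decoys rather than genuine
off-pathway annotation. Passing these tests therefore demonstrates that
the engine implements its stated logic exactly and behaves as the closed
forms predict under independent dropout — not that real-world precision
or recall will match, since real error comes from annotation quality and
the biological ambiguities above.

## Known limitations

* Binary calls only; no partial-pathway or completeness scoring.
* No flux directionality or activity inference; reversible pathways (WL
  in particular) may be present without autotrophic function.
* rTCA running on shared oxidative-TCA enzymes, and hybrid WL subunit
  combinations, are undetectable by marker logic and excluded.
* The rGly definition rests on the glycine cleavage and glycine reductase
  quorums; route-specific downstream markers are not included.
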