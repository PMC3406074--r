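---
title: "Methods: comparative XME profiling from label-free proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative XME profiling from label-free proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xmeprofiler)
```

## The problem and the shape of the pipeline

Human skin metabolises xenobiotics, but the enzymes responsible
(xenobiotic-metabolising enzymes, XMEs) are present at much lower levels
than in liver, which makes a broad, unbiased inventory difficult.
`xmeprofiler` implements the downstream half of a GeLC-MS/MS profiling
workflow for this problem: starting from per-sample peptide
identification tables (peptide sequence, charge, score, ion intensity,
gel region, subcellular fraction) and a protein database in FASTA, it

1. digests database sequences in silico and maps every observed peptide
   to all proteins containing it (exact substring matching);
2. selects putative XMEs from protein *names* with accept/reject keyword
   lists and whole-word filters;
3. consolidates proteins that the peptide evidence cannot distinguish
   into groups reported under a root description;
4. applies the detection criterion (two distinct tryptic peptides, at
   least two donors), resolves a reporting gel region and subcellular
   fraction per group;
5. quantifies groups between tissues by summed peptide ion intensity,
   substituting the limit of detection for non-detections, and tests
   differences with an exact Mann–Whitney test;
6. calibrates limits of detection from spike-in dilution series and
   performs the bounded-ratio arithmetic that places undetected proteins
   in context.

The repository is organised as an analysis: the numbered drivers under
`analysis/` narrate a complete simulated study, while every computation
lives in the package so it is unit-tested and reusable. The drivers plus
the exported functions are the interface; no shell wrapper is shipped
because each stage is one function call.

## Keyword selection

Selection operates on protein *descriptions*, not sequences. Evaluation
order is fixed and deliberate:

1. **word filters** (`hypothetical`, `like`) on word boundaries — a
   boundary match means `"...member C3-like protein"` is filtered while
   `"ligase"` never is;
2. **reject list** by substring containment — rejects override accepts,
   so `"protein-glutamine gamma-glutamyltransferase"` cannot survive via
   a transferase fragment and `"carbohydrate sulfotransferase 1"` is
   eliminated despite containing `"sulfotransferase"`;
3. **accept list** by substring containment; the first fragment in list
   order is recorded in the audit table.

Names are normalized first (case folding, unicode dashes and primes to
ASCII, whitespace collapsing). Hyphenated and space-separated spellings
are *not* conflated: the accept list itself carries both spellings of
catechol O-methyltransferase, which documents that the matcher treats
them as distinct. Whether the original selection was substring-based or
token-anchored is not knowable from the outputs alone; substring
containment is assumed, and the audit table records every decision with
its matched fragment so discrepancies stay visible.

One consequence worth stating: published comparative tables usually
print hand-curated root descriptions (e.g. "glutathione S-transferase
alpha"), and a curated name need not contain any accept fragment (the
list has `"glutathione transferase"`, without the "S-"). Selection is
therefore defined on raw database descriptions, upstream of any
curation; curated display names should not be fed back through the
selector and are not guaranteed to pass it.

## Digestion and peptide mapping

Trypsin cleaves C-terminal to K or R except before proline (Keil rule)
— the rule ion-trap search engines of the period applied, adopted here
as a design decision since identification output does not state it.
With `missed_cleavages = k`, all concatenations of up to `k + 1`
adjacent fully-tryptic fragments are emitted; the default of 2 and the
6–30-residue observability window used by the generator are typical for
ion-trap identification. Mapping is exact substring containment of the
peptide in each database sequence; isoleucine and leucine are not
merged, because the lookup is a database text search, not a spectral
match. Peptides matching nothing are dropped with a warning rather than
failing a run. Uniqueness classes (`unique-to-protein`,
`unique-to-family`, `shared-across-families`) are a pure function of
the match set and the family partition.

## Consolidation and detection

Two accepted proteins merge when neither has at least `min_unique = 2`
supporting peptides that distinguish it from the other; groups are the
connected components of merged pairs. The threshold mirrors the
two-peptide identification standard (the principle is stated in the
field; the number is our choice). Root names are derived mechanically —
longest common prefix, trailing digits/punctuation trimmed, falling
back to the alphabetically first member — so consolidation is
deterministic and auditable, where the original reporting curated names
by hand. Supporting peptides whose matches span two final groups are
excluded from both support sets, so support sets partition the
evidence.

Detection in a tissue requires `min_peptides = 2` distinct peptides in
at least `min_donors = 2` samples; the detection rate is the percentage
of the tissue's samples meeting the peptide threshold. The rule is
applied after combining fractions (whether the original applied it per
fraction is unstated; combined-first is assumed and both knobs are
configurable). Gel-region resolution precedes quantification: only the
region with the greatest total distinct-peptide count is used, ties
going to the lowest region index with a logged note. Fraction
resolution compares summed intensities; within a 2-fold ratio both
fractions are reported (the "similar levels" threshold is ours — none
is published).

## Quantification and testing

Per sample, a group's abundance is the sum of its supporting peptide
intensities in the resolved region. Non-detections are replaced by an
intensity equivalent to the limit of detection — by default the
smallest observed peptide intensity in the dataset, which
operationalizes "equivalent to the limit of detection" without external
calibration and can be overridden from the spike-in module. The fold
difference is the ratio of tissue means of the substituted sums (mean
rather than median or total is our choice; the aggregation is not fully
specified in the original reporting, and it is configurable in
principle because the substitution and ratio are separate functions).
When one tissue has no detections at all the ratio is a bound, rendered
`>x` or `<x`.

Group differences are tested with a two-sided Mann–Whitney test. For
combined `n <= 25` — which covers the 10-vs-5 donor design — the
p-value is exact: the rank-sum distribution over all `choose(n1+n2,
n1)` labellings is computed by dynamic programming over doubled
mid-ranks (doubling makes tied mid-ranks integral), and the two-sided p
doubles the smaller tail, capped at 1. `stats::wilcox.test` is *not*
used for this because it abandons exactness under ties; it serves as an
independent cross-check in the tests for tie-free cases, alongside a
full-enumeration oracle for tied cases. A consequence asserted as a
property: at 10 vs 5 the smallest achievable two-sided exact p is
`2/3003 ≈ 6.7e-4`, so a `"<0.001"` rendering is attainable and
`"<0.0001"` is not. P-values display as `"<0.001"` below 0.001 and at
two significant figures otherwise; no multiple-testing correction is
applied by default (none was applied originally; `stats::p.adjust` is
available to callers who want one).

Peptide-count profiles (distinct peptides per group per column) are the
relative measure used for model comparisons; the Spearman correlation
summary attached to them is a convenience output, not part of the
original reporting.

## Spike-in calibration and bounded-ratio arithmetic

The limit of detection of an analyte is the smallest spike amount at
which at least two distinct peptides are detected *and remain detected
at every larger amount* — the first sustained crossing, a rule chosen
to be robust to non-monotone noise (published panels report single
values without stating a rule). Conversion to a concentration bound
divides by the analysed protein mass, which is always an explicit
parameter: the published fmol-to-pmol/mg panel is internally consistent
only with roughly 13 µg effectively analysed, while the accompanying
text cites 75 µg, and the module does not resolve that discrepancy — it
exposes the mass and lets the caller decide. Bounded ratios are
rendered at one significant figure with round-half-away-from-zero
(which reproduces `<0.003` from 0.0032 and `<0.002` from 0.00219; R's
`signif` would round halves to even). The minimum comparator/bound
ratio across a panel gives an "at least x-fold" separation statement.

## What the generator emulates — and what it does not

The synthetic-data module exists so every stage is testable with known
ground truth and no external downloads. It emulates:

- the study design: 10 skin vs 5 liver donors, cytosol/microsome
  fractions, 20 gel regions;
- protein families that literally share tryptic peptides (sequences are
  concatenations of synthetic fully-tryptic peptides, so
  zero-missed-cleavage digestion recovers them exactly);
- names covering all four selection outcomes, including reject-list
  hits and `hypothetical`/`like` names;
- intensities as abundance × a fixed per-peptide response factor ×
  log-normal noise (`sigma = 0.3` by default), censored at the
  observation level below the detection limit, with a 0.9
  per-observation detection probability. The multiplicative model is
  the simplest one consistent with the reported ~3-order-of-magnitude
  linearity between ion intensity and quantity; the log-normal choice
  is a modelling decision, not a claim about the original data.

It does **not** simulate spectra, retention times, chromatography, or
real tryptic-peptide detectability, and no real proteome is bundled —
sequences are random strings with planted shared peptides, and
accessions carry a `SYN_` prefix. Passing tests on this generator
demonstrate that the pipeline's logic implements its stated rules and
recovers known truth under the stated noise model; they cannot certify
behaviour on real LC-MS/MS output, where intensity distributions,
peptide response and censoring are all messier.

Default problem sizes are deliberately small — a 20-protein database
with 8 peptides per protein and 15 samples for the study simulation,
and 100 seeded replicates for the noise-calibration check — which keeps
any full run of the analysis scripts and test suite in the
seconds-to-minutes range while still exercising every rule (families,
censoring, bounds, ties).

## Numerical and degenerate-input choices

- Seeds fully determine outputs; reruns are byte-identical. Derived
  seeds are small integer offsets of the configured seed.
- Censoring uses `intensity >= detection_limit`; a zero-abundance
  protein yields no observations; an infinite limit yields empty
  tables.
- `fold_difference` requires a positive substitution intensity and
  errors on a non-positive one; identical samples give a Mann–Whitney
  p of exactly 1 (no signal), not an error.
- Region ties resolve to the lowest region index, with a message.
- Rank-sum counts are held in doubles; the largest count at the exact
  limit (`choose(25, 12)`) is far below 2^53, so the enumeration is
  exact.
- The word filters apply before consolidation, mirroring an automated
  pre-filter; note the accept list itself contains one `-like 1`
  fragment, which the word filter therefore shadows — kept as-is for
  list fidelity.

## Known limitations

- Exact substring matching may be stricter than the original
  "BLAST-type" peptide lookup; near-exact matches are not found.
- Keyword selection is only as good as the lists; the audit table is
  the mitigation.
- The evidence-graph consolidation is not a parsimony (minimal
  explanation) inference and is not meant to be.
- Fold differences from summed intensities inherit all label-free
  caveats (no between-run normalization, no match-between-runs); these
  are out of scope here as they were in the original workflow.
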