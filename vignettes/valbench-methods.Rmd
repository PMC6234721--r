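---
title: "Site-level benchmarking of germline variant callsets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site-level benchmarking of germline variant callsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valbench)
```

## The evaluation model

`valbench` scores a variant-calling pipeline against a truth catalog of
orthogonally validated sites. Each site belongs to one sample and is
either *positive* (a specific variant, with expected REF/ALT alleles,
confirmed present by the orthogonal assay) or *negative* (a variant call
once made at the locus, confirmed absent). Sites fall in four top-level
classes — positive substitutions, positive indels (deletions,
insertions, complex indels), negative substitution sites and negative
indel sites — and each class has its own scoring rule:

- **Positive substitution**: true positive iff a substitution call with
  exactly the expected REF/ALT exists at exactly the expected position.
  A different substitution at that position is evidence the variant was
  processed but mis-called; it scores as a false negative with the flag
  `incorrect_call_present`.
- **Negative substitution**: false positive iff *any* substitution call
  sits at the exact position, whatever its allele. (An alternative
  reading would require the specific absent allele; we follow the
  broader rule because a negative site attests that no substitution is
  present there at all.)
- **Positive indel-type**: the *detection count* is the number of
  indel-type calls whose normalized position falls in a 200 bp window
  centred on the site. The site is detected (TP) if the count is
  positive, and *accurately represented* if at least one in-window call
  equals the truth alleles exactly after normalization. Detection and
  representation are deliberately separated: a deletion reported as two
  shorter frameshifting deletions is detected but misrepresented, and
  the clinical interpretation of the two spellings can differ
  radically.
- **Negative indel-type**: false positive iff the windowed detection
  count is positive.

Substitution calls never count toward indel detection and vice versa;
the window rule exists precisely because indel coordinates are
representation-dependent while substitution coordinates are not.

### The 200 bp window

The window is `[pos − 100, pos + 99]`, clamped at chromosome start: 200
positions, centred up to the one-base asymmetry that an even width
forces (we bias one base left and document it; `indel_window()` is the
single source of this arithmetic). Window membership uses the call's
*normalized* position so that padding never moves a call in or out of a
window. Truth sites are required (and synthetically generated) to be
more than 200 bp apart, so a call is attributable to at most one site.

### Minimal representation and matching

Both truth alleles and calls are reduced to minimal representation: the
longest shared allele suffix is stripped, then the longest shared
prefix (advancing the position), always retaining at least one base per
allele. Exact indel matching compares `(chrom, pos, ref, alt)` of the
two minimal forms. Because *both* sides are normalized identically,
matching is well defined without a reference genome. Left-alignment
through repetitive reference context is additionally available when a
reference context is supplied to `normalize_record()`, but the default
pipeline does not assume one; two spellings that only left-alignment
can reconcile (e.g. a deletion shifted within a repeat tract) are
treated as different representations of a detected variant, which is
the conservative choice for representation accuracy.

Ties in trimming are resolved suffix-first. This matters for anchored
deletions such as `ACGA/A`: trimming the shared suffix first and
retaining one base per allele leaves the conventional anchored form,
and the property suite checks the implementation against an exhaustive
enumeration oracle over all prefix/suffix trims.

### Missing data

A site is a *no-call* when it cannot be assessed: its callset is
absent, a record overlapping the position carries a missing genotype
(`./.`), or — for gVCF-derived callsets — the position lies under
neither a variant record nor an END-tagged reference block. No-calls
score FN at positive sites and TN at negative sites, but carry a flag
so reports can state that missing data prevented assessment rather than
claiming a clean negative. Any reference block counts as assessable
coverage regardless of its quality annotations; we note the alternative
reading (discounting low-quality blocks) but do not implement it, as
block quality conventions differ across callers.

## Metrics and rounding

Sensitivity TP/(TP+FN), specificity TN/(TN+FP) and false detection rate
FP/(FP+TP) are computed overall and per class; overall counts are the
sums of the two class counts by construction. Cells print as
`n/d (p%)` with `p` rounded to the nearest integer, ties to even (base
R's `round()`). Ties-to-even is the convention that reproduces the
published benchmark tables this format follows — e.g. 7/280 = 2.5%
prints as 2% while 20/301 = 6.64% prints as 7% — and the worked-example
tests pin every such cell. A zero denominator prints `NA`; no division
by zero ever occurs.

## Baselines, regression, filter sweeps

**Group A/B benchmarking.** Given full results from one or more
baseline pipelines over the same catalog, Group A is the set of
positive sites *every* baseline detects and Group B the set of negative
sites *every* baseline leaves clean — status TN with detection count 0
and no missing-data flag. A no-call negative is excluded from Group B:
a site a baseline could not assess is no evidence that calls there are
wrong. A new pipeline is then summarized by the Group A sites it
misses and the Group B sites where it calls a variant, both of which
indicate substandard performance worth investigating.

**Regression comparison.** `compare_runs()` classifies each site whose
verdict differs between two runs: gained/lost detection (FN↔TP),
gained/lost false call (TN↔FP), same-status changes in windowed
detection count, and same-status changes in representation accuracy.
The classification is anti-symmetric under swapping the runs, which the
invariant suite checks.

**QUAL sweeps.** `sweep_quality_threshold()` re-derives every site's
verdict from the stored per-site call records, keeping only calls of
the filtered class with QUAL ≥ t. Re-deriving from records (rather
than adjusting summary counts) is what makes sites holding both high-
and low-quality calls behave correctly, and gives the monotonicity
guarantee that false positives and true positives are non-increasing in
t. Calls without a QUAL are treated as failing every threshold, with a
warning.

## The synthetic scenario generator

`scenario_spec()` / `generate_scenario()` produce a truth catalog,
per-sample VCF (or gVCF) callsets and a *ledger* — the expected
verdict of every site. The generator emulates the statistical structure
of a real validation series:

- the default layout is 142 samples and 704 sites: 123 positive
  substitutions, 293 positive indels, 41 negative substitution sites
  and 247 negative indel sites. The deletion/insertion/complex split of
  the 293 indels is not published as such; we allocate 203/80/10
  following the published composition of the baseline-detected subset
  (186:74:9), which is the best available estimate of the class mix;
- planted error processes, each an independent per-site Bernoulli draw:
  missed variants (`fn_rate`), false calls at negative sites
  (`fp_rate_negative`), misrepresentation of detected variants
  (`misrepresentation_rate`: wrong ALT at substitution sites — which
  scores as a miss — and split or garbled spellings at indel sites),
  missing data (`missing_rate`), and clustered in-window secondary
  calls (`cluster_probability`), mirroring phenomena observed in real
  callsets (split frameshifting deletions, universally misrepresented
  complex indels, proximal call clusters, a negative site unassessable
  for missing data);
- planted QUAL scores: true calls from `qual_true` (default mean 50,
  sd 10) and false calls from `qual_false` (default mean 15, sd 5),
  normal with a floor at 0.1, reflecting that false calls
  concentrate at low quality — the premise of QUAL filtering;
- exact calls are emitted padded with probability `pad_probability`
  (default 0.3) so that normalization is exercised on every run, not
  only in dedicated tests.

Sites are placed 500 bp apart on one simulated contig, so detection
windows never overlap and every planted outcome is independent —
making the ledger *exact*, not probabilistic. The central
test property is ledger fidelity: across randomized scenarios,
`evaluate_all()` must equal the ledger row for row. All randomness
flows from the single spec seed; identical specs give byte-identical
files.

What the generator does **not** emulate: read-level evidence (no
FASTQ/BAM), realistic allele frequencies or genotype mixtures,
multi-allelic records, overlapping variants, homopolymer- or
repeat-context error enrichment, and reference-context-dependent indel
placement. Passing tests therefore demonstrate that the *evaluation
engine* is correct under the stated contracts, not that any particular
caller performs well on real data.

## Numerical and degenerate-input choices

- Percent rounding: ties to even, as above.
- `format_rate(0, 0)` returns `"NA"`; empty categories never divide by
  zero.
- Multi-allelic ALT fields are rejected, not auto-split: the evaluation
  contract requires one call per record, and silently decomposing
  genotypes would blur which sample carries which allele. gVCF variant
  rows are the one exception — their trailing `<NON_REF>` alternative
  is stripped before the contract is applied, because it is notation
  for the surrounding reference block, not a second call.
- Symbolic, breakend and non-ACGTN alleles raise errors naming the
  line; structural-variant evaluation is out of scope.
- Records on chromosomes absent from the catalog are retained but can
  never match a site; they are ignored rather than treated as errors.
- An absent callset downgrades to a warning and no-calls for that
  sample only, so one missing file does not invalidate a 142-sample
  run.
- Tab-delimited parsing of VCF bodies preserves each record's verbatim
  source line, which the true/false-positive output files must quote;
  field-level agreement with an independent VCF parser is checked in
  the test suite.

## Problem sizes used in the test suite

The property suites run on deliberately small scenarios: ledger
fidelity on 100 random scenarios of up to ~50 sites over up to 5
samples; oracle equivalence on 1,000 windowed-count configurations and
1,000 random allele pairs; rate recovery on 25 scenarios of 40 positive
sites. These sizes give exact bookkeeping (fidelity, oracles) or
standard-error margins (rate recovery, tolerance four standard errors)
while keeping the default test run fast; the evaluation engine itself
is size-agnostic and the generator's default 704-site, 142-sample
layout is exercised in the census and acceptance tests.

## Known limitations

- Genotype-level concordance (het/hom agreement) is not assessed; the
  unit of evaluation is the site.
- Exact matching gives no partial credit for complex indels; a complex
  truth variant reported as a nearby cluster of simpler events is
  detected-but-misrepresented even when the net edit is equivalent, if
  minimal representations differ.
- Without a reference context, two left-shiftable spellings of the same
  event in a repeat tract are counted as misrepresentation; supplying a
  context to `normalize_record()` reconciles them but the bundled
  pipeline does not wire a genome in.
- Phasing is not interpreted: a cluster of indel calls that would
  cancel on one haplotype still counts each call separately, which is
  the behaviour the regression-comparison workflow is designed to
  surface for manual review.
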