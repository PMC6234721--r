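# valbench

Benchmarking germline variant calling against a catalog of orthogonally
validated truth sites.

## The problem

Clinical, commercial and academic sequencing pipelines all need a
consistent, transparent way to measure how well they call germline
variants. The gold standard is a truth catalog built by an independent
assay (Sanger sequencing): a set of **positive sites**, where a specific
variant is confirmed present in a specific sample, and **negative
sites**, where a variant that some caller once reported is confirmed
absent. Given such a catalog and one VCF callset per sample, `valbench`
scores every site and aggregates the verdicts into the three standard
site-level metrics:

- **sensitivity** = TP / (TP + FN)
- **specificity** = TN / (TN + FP)
- **false detection rate (FDR)** = FP / (FP + TP)

computed overall and separately for base substitutions and indels, and
printed as `n/d (p%)` cells.

## How sites are scored

Substitutions and indels are scored differently, because indel calls
rarely land on the exact annotated coordinate:

- A **positive substitution** site is a true positive only if the exact
  alternate allele is called at the exact position; a different
  substitution at that position is flagged and scored as a miss. A
  **negative substitution** site is a false positive if *any*
  substitution is called at the position.
- An **indel-type** site counts every indel call inside a 200 bp window
  centred on the site (`[pos − 100, pos + 99]`). A positive indel site
  is *detected* if the count is positive, and additionally *accurately
  represented* if some call reproduces the truth alleles exactly after
  both are reduced to minimal representation (shared suffix stripped,
  then shared prefix, keeping at least one base per allele — so
  `GTCA/ATCA` at 100 and `G/A` at 100 are the same call). A negative
  indel site with any in-window indel call is a false positive.
- Missing genotypes (`./.`) and loci outside every gVCF reference block
  are **no-calls**: false negatives at positive sites, flagged true
  negatives at negative sites.

On top of the per-site verdicts the package provides baseline
benchmarking (Group A: positive sites every reference pipeline detects;
Group B: negative sites every reference pipeline leaves clean),
site-level regression comparison between two runs of a pipeline, and
QUAL-threshold sweeps for filter design. A seeded scenario generator
produces truth catalogs and VCF callsets with fully known planted error
structure, so the entire pipeline is testable without any external data.

## Worked example

```r
library(valbench)

sp <- scenario_spec(n_samples = 6, n_substitution = 20, n_deletion = 12,
                    n_insertion = 8, n_complex = 2,
                    n_negative_substitution = 8, n_negative_indel = 15,
                    fn_rate = 0.1, fp_rate_negative = 0.2,
                    misrepresentation_rate = 0.15, missing_rate = 0.05,
                    seed = 7)
gen <- generate_scenario(sp, "demo")

catalog  <- load_truth(gen$truth_path)
callsets <- load_callsets(read_sample_map(gen$sample_map_path))
results  <- evaluate_all(catalog, callsets)
results
#> Site evaluation: 65 sites
#>   TP 31  FN 11  TN 16  FP 7  (no-call 6)
compute_summary(results)
#> Performance summary
#>   overall        sensitivity 31/42 (74%)      specificity 16/23 (70%)      FDR 7/38 (18%)
#>   substitutions  sensitivity 11/20 (55%)      specificity 7/8 (88%)        FDR 1/12 (8%)
#>   indels         sensitivity 20/22 (91%)      specificity 9/15 (60%)       FDR 6/26 (23%)
```

The evaluation found 31 of the 42 planted variants (the rest were
planted as misses, wrong-allele calls or no-calls), 7 false calls among
the 23 negative sites, and 6 sites where missing data
prevented assessment — exactly what the generator's ledger
(`gen$ledger`) says it planted. `write_result_tables(results, outdir =
"out")` writes the `Summary.txt`, `FullResults.txt`,
`TruePositives.txt`, `FalsePositives.txt` and `ColumnHeaders.txt`
tables, and `render_report()` builds the one-page Markdown report.

A thin command-line wrapper is installed in `exec/`:

```sh
valbench evaluate --truth truth.tsv --sample-map map.tsv --outdir out
valbench compare out_v1 out_v2
valbench sweep --truth truth.tsv --sample-map map.tsv --class substitution --thresholds 0,10,20,30
valbench simulate --spec scenario.yaml --outdir sim --seed 1
```

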