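# mbsomatic — tumor-only somatic mutation discovery for mouse medulloblastoma exomes

`mbsomatic` is an R implementation of a tumor-only somatic SNV/indel
discovery workflow for mouse medulloblastoma (MB) models, for researchers
who sequence tumors from engineered or orthotopic mouse cohorts without
banked matched-normal DNA. It covers the full path from per-read pileup
evidence to a cross-species mutation comparison:

1. **Candidate calling** against a public reference normal, with read-level
   quality/mismatch gates and a one-sided Fisher's exact test on the 2×2
   allele-count table
   `[[alt_tumor, ref_tumor], [alt_normal, ref_normal]]`. A candidate is
   somatic-putative iff tumor VAF ≥ 10% and *P* < 0.10, with significance
   tiers *P* < 0.05 (high) and 0.05 < *P* < 0.10 (low), crossed with a
   base-quality tier into the four-way substitution classification.
2. **Germline filtering** in fixed order: public SNP-database site lists →
   raw weak evidence in any of 18 laboratory-strain normals (a panel of
   normals) → realignment review of alt reads (paralogs, slippage) and
   mutant-template review of indels → validation against non-tumor mice of
   the common ancestors at amplicon depth. Every decision is logged in a
   per-variant filter trail.
3. **Consequence annotation** (silent / missense / nonsense / frameshift /
   in-frame / splice / noncoding) by strand-aware codon translation, with
   per-tumor burden, non-silent counts and the missense-to-silent ratio.
4. **Cross-species comparison**: mouse→human ortholog symbol mapping,
   mRNA-space coordinate lifting through local alignment, and a parser for
   the compact human-MB mutation-catalog notation
   (`SHH,U,WNT (12: F6,M4,N2)`) with subgroup-concordance and per-gene
   loss-of-function/missense tallies.
5. **Cohort statistics**: exact permutation comparison of subgroup burdens,
   exact hypergeometric enrichment tail, and a deterministic
   machine-readable report.

A seeded synthetic-cohort generator (`sim_config()`, `generate_reference()`,
`generate_cohort_truth()`, `render_pileups()`) emulates the study design —
18 strain haplotypes partially represented in SNP databases, 12 tumors in
three subgroups, ancestor controls, realistic qualities and depths — so the
entire cascade is testable against known truth.

## Worked example

End-to-end discovery on a freshly simulated default cohort, then the
catalog comparison:

```r
library(mbsomatic)

res <- run_pipeline(list(seed = 1), out_dir = "scratch/demo")
m   <- recovery_metrics(res)
cat(sprintf("validated %d | precision %.2f | stratum recall %.2f | mean burden %.1f\n",
            m$n_validated, m$precision, m$recall_stratum,
            res$report$burden$mean_1dp))

catalog <- read_mutation_catalog(
  system.file("extdata", "human_mb_catalog.tsv", package = "mbsomatic"),
  system.file("extdata", "human_mb_studies.tsv", package = "mbsomatic"))
conc <- subgroup_concordant_genes(catalog_mouse_records(catalog), catalog)
cat(length(conc), "concordant genes:", paste(conc, collapse = ", "), "\n")
print(tally_gene(catalog, "KMT2D"))
```

```
validated 60 | precision 1.00 | stratum recall 1.00 | mean burden 5.0
7 concordant genes: BAI3, DOCK7, KMT2C, KMT2D, LRFN2, PIWIL4, WDR11
   total      lof missense 
      30       21        9 
```

The pipeline recovered all 60 seeded somatic mutations of this cohort with
no false validated calls (precision 1.00), at a mean of 5.0 mutations per
tumor; the catalog comparison finds 7 genes whose mouse mutation recurs in
the same MB subgroup in a human study, and tallies 30 `KMT2D` mutations
across the human cohorts, 21 of them loss-of-function (nonsense or
frameshift) and 9 missense.

## The analysis workflow

The numbered drivers under `analysis/` run the same study as a file-based
pipeline (large intermediates under `scratch/`, small tables under
`results/`):

```sh
Rscript analysis/01_simulate.R        # cohort, pileups, truth VCF, SNP DBs
Rscript analysis/02_call.R            # candidates, Fisher P, four-way classes
Rscript analysis/03_filter_validate.R # db -> strain -> review -> ancestors
Rscript analysis/04_annotate.R        # consequences, missense/silent
Rscript analysis/05_crossmap.R        # ortholog map, catalog concordance
Rscript analysis/06_report.R          # burdens, subgroup tests, report
```

`run_pipeline()` executes the same stages in one call (with `--dry-run`
semantics via `dry_run = TRUE`), and reruns with the same configuration
are byte-identical.

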