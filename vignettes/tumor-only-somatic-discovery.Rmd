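---
title: "Tumor-only somatic mutation discovery: models, parameters and design choices"
author: "mbsomatic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-only somatic mutation discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Mouse models of medulloblastoma (MB) — spontaneous WNT and SHH tumors and
orthotopic MYC-driven Group 3 (G3) tumors — acquire somatic mutations whose
overlap with human MB mutations is of direct biological interest. When no
matched germline DNA was banked, somatic discovery from tumor exomes must
work *tumor-only*: each tumor is compared against a public reference normal
(C57BL/6-style whole-genome data), and the germline background — which for
outbred colony mice is far more complex than the reference strain — must be
removed by orthogonal evidence: public SNP databases, raw sequencing data
of 18 common laboratory strains (a panel of normals), and finally targeted
re-sequencing of the tumors together with non-tumor mice from the common
ancestor colony.

`mbsomatic` implements that discovery procedure end to end, together with
coding-consequence annotation, cross-species comparison against a human MB
mutation catalog, and cohort statistics, and ships a seeded synthetic
cohort generator that emulates the study design so the whole cascade is
testable against known truth.

## Candidate calling

### Read gates

Every counting step uses the same per-read gate, with thresholds from the
discovery caller's parameter set: mapping quality ≥ 1, base quality ≥ 10
(`broad_min_quality`), flanking quality ≥ 15, at most 20 mismatches on the
read of which at most 15 are high-quality (base quality ≥ 15). Flanking
quality models the minimum base quality in a short window around the
called base, so a confident call inside a sloppy read neighborhood is
still discounted.

A candidate needs ≥ 2 filtered alt reads (`min_alt_allele_count`) coming
from ≥ 2 distinct reads of evidence (`unique_filter_coverage`). The pileup
dialect used here carries no read start coordinate, so "distinct evidence"
is operationalized as distinct `readId` values among the passing alt
reads; with duplicate-marked data this is the guard against PCR-duplicate
stacks. `min_minor_frequency` (default 0) is honored as a configurable
no-op threshold on the filtered VAF.

### Somatic criteria and the four-way class

For tumor counts $(a_t, r_t)$ and normal counts $(a_n, r_n)$ of alt and
reference reads, the caller computes the one-sided Fisher exact
probability of the tumor carrying at least $a_t$ alt reads with all
margins of the 2×2 table fixed:

$$P = \sum_{x \ge a_t} \frac{\binom{a_t+r_t}{x}\,\binom{a_n+r_n}{m-x}}{\binom{N}{\,a_t+r_t\,}}, \qquad m = a_t + a_n .$$

The sum is evaluated exactly over the hypergeometric support
(`stats::dhyper` supplies the mass terms; the test suite checks the tail
against an independent `choose()`-based enumeration over every table with
margins up to 30, at $10^{-12}$).

A candidate is *somatic-putative* iff its filtered tumor VAF
($a_t/(a_t+r_t)$) is ≥ 0.10 **and** $P < 0.10$. Significance tiers follow
the workflow's boundaries — HIGH for $P < 0.05$, LOW for $0.05 < P < 0.10$ —
and candidates at $P \ge 0.10$ are rejected outright, since only two tiers
below 0.10 are defined. All thresholds are inclusive on the passing side
exactly as stated ("≥ 10%", "P < 0.05"). The quality tier of the
four-way class is decided by the median base quality of the filtered
alt-supporting reads at a default cut of 25: a simple, monotone statistic
of exactly the reads that made the call, exposed as
`quality_tier_threshold`. All four classes are retained and labeled;
dropping any of them is left to configuration, since their downstream fate
is a policy question, not an algorithmic one.

Degenerate input: an all-zero 2×2 table yields $P = 1$ with a warning.

## The germline filter cascade

Stage order is fixed — databases → strain panel → sequence review →
ancestor validation — and each stage touches only candidates still in
play, which makes every stage idempotent. Every decision appends a
`(stage, decision, reason)` row to the per-variant filter trail.

1. **SNP databases.** Matching is on `(contig, pos, alt)` — the full
   normalized allele, with indels left-aligned — not on position alone,
   so a novel allele at a known tri-allelic site survives.
2. **Strain-panel weak evidence.** A candidate is germline if any single
   strain shows ≥ `min_evidence_reads` (default 1) alt reads of any
   quality ≥ `broad_min_quality` at the locus. This is deliberately
   aggressive — it is the "check the raw data for weak evidence" step
   that removes germline variants hiding in low-coverage or poor-quality
   panel regions. Loci with no panel coverage at all are flagged
   `panel_uncovered` and retained.
3. **Realignment review (SNVs).** Alt-supporting read sequences are
   re-examined: each read's original (ungapped) placement score against
   the reference is compared with (a) a gapped local realignment to the
   same window and (b) local alignments to every other reference window
   sharing a k-mer seed (k = 13) with the read. A read is *explained
   away* if some alternative reaches the original score without the alt
   base. The call becomes an artifact only when a **majority** of alt
   reads are explained away — a single ambiguous read never kills a call,
   because the review's purpose is to catch systematic mapping artifacts
   (paralogs, homopolymer slippage), not to re-litigate every read.
4. **Mutant-template review (indels).** A template is built by applying
   the indel to the reference window; every tumor and normal read is
   scored against both the wild-type window and the template (local
   alignment, affine gaps). A read "covers the mutant allele" when it
   aligns strictly better to the template *and* spans the indel with
   anchored bases on both sides — reads too short to span count for
   neither side. One covering normal read makes the call germline;
   retention requires ≥ `min_alt_allele_count` covering tumor reads.
5. **Ancestor validation.** At amplicon depth over the control mice:
   `not_covered` when no control covers the locus (excluded from the
   validation-rate denominator); germline when any control shows the alt
   at ≥ 2 reads and VAF ≥ 0.05 (a floor approximating Sanger/MiSeq
   detectability, both exposed in configuration); validated-somatic when
   the tumor amplicon confirms the alt and every covered control is
   negative.

The pileup interchange format carries per-read qualities and mismatch
counts but no read sequences, so inside `run_pipeline()` the two
sequence-level reviews flag survivors `unreviewed` and pass them to
validation; both reviews are fully exercised on constructed read-sequence
fixtures in the test suite. The manual-curation step that sits between
filtering and validation in the original workflow is inherently human; it
is represented by optional allow/deny id lists (`manual_curation()`),
which default to empty — denial rejects a surviving candidate, and an
allow entry is the one mechanism permitted to override an automated
removal, with the override recorded in the trail.

## Consequence annotation

Strand-aware codon lookup against the transcript models using the standard
nuclear genetic code: CDS substitutions become silent / missense /
nonsense by translating the mutated codon (reverse-strand variants are
complemented before substitution); CDS indels become frameshift when the
length change is not a multiple of 3, in-frame otherwise; substitutions in
the 2 bp of intron flanking an exon boundary (canonical donor/acceptor,
window configurable) are splice; everything else is noncoding. With
multiple overlapping transcripts one record is produced per variant on the
longest-CDS transcript — a deterministic policy chosen because no
multi-transcript rule is specified for the original analysis. Stop-loss is
folded into missense (with a note) and start-loss is not separately
modeled. The missense-to-silent ratio is reported as undefined — never as
infinity — when no silent mutation exists.

## Cross-species comparison

Mouse symbols map to human ortholog symbols by exact lookup with a
case-normalized fallback (mouse title-case vs human upper-case); duplicate
mouse symbols in the orthology table are a configuration error. Mutation
positions lift through a local mRNA-vs-mRNA alignment (affine gaps; match
+2, mismatch −3, gap open 5, gap extend 2 — conventional nucleotide
local-alignment scoring — with a score floor of 40 below which the pair is
unmapped). The alignment traceback becomes an explicit column map
`mouse_pos → human_pos`; positions in unaligned gaps or tails are reported
unmapped, and the human codon number is `ceiling(pos / 3)`.

The human-MB mutation catalog is shipped as a packaged TSV in the compact
cell notation `SUBGROUPS (TOTAL: TYPELIST)` (e.g. `WNT (3: M2,N)`); a
cell whose total disagrees with the sum of its type tokens is a parse
error naming the cell. The type letters are treated as opaque codes; only
the loss-of-function set `{N, F}` (nonsense, frameshift) and the missense
set `{M}` are given semantics, and both are configurable.

**Concordance matches on subgroup only.** A gene counts as concordant when
the mouse tumor's subgroup label appears among the subgroup labels of at
least one human study entry for that gene. Matching additionally on the
mutation-type letter fails to reproduce the catalog's own concordant set
(e.g. the PIWIL4 mouse entry carries type `D`, the human entries type
`M`), so subgroup-only matching is adopted and the discrepancy documented
here.

## Cohort statistics

Per-tumor burden includes zero-mutation tumors and reports the mean at one
decimal place alongside the exact value. Subgroup burden comparisons use
an exact permutation test — full enumeration of all
$\binom{n_A+n_B}{n_A}$ group assignments of the rank-sum statistic
(midranks for ties), with a difference-of-means statistic available
alongside; at the cohort sizes in play (3–5 tumors per subgroup) the
enumeration is exact, and larger inputs fall back to the asymptotic test.
The hypergeometric upper tail $P(X \ge k)$ is summed exactly via
log-binomial coefficients. No multiple-testing correction is applied
anywhere, matching the original analysis. The terminal report is
deterministic (fixed key order, no timestamps), so identical
configurations reproduce it byte for byte.

## The synthetic cohort generator

The generator's defaults encode the study design being emulated:

* **Cohort structure:** 12 tumors — 4 WNT, 4 SHH, 4 G3 — over 18 panel
  strains and 4 ancestor controls. Per-tumor somatic burden is Poisson
  with subgroup means (WNT 10, SHH 2, G3 4), capped at 31: expected total
  64 (5.3 per tumor) with the WNT > G3 > SHH ordering of the modeled
  cohort.
* **Somatic variants:** VAF uniform on [0.10, 0.90] (the somatic VAF
  criterion is satisfiable by construction); 5% of events are 1–3 bp
  indels, left-aligned at generation time so truth-vs-call matching is
  exact after the caller's own left alignment.
* **Germline model:** two levels plus a colony layer — founder variants
  shared by every strain, line and ancestor; strain-private variants
  (homozygous: panel strains are inbred); and ancestral-line variants for
  the tumor colony, heterozygous in tumors and ancestors, of which 70%
  (`panel_representation`) are also carried by some panel strain. The
  remaining 30% are invisible to the panel and databases — they are what
  makes ancestor validation load-bearing rather than ornamental. The true
  strain-background complexity of outbred colonies is not quantitatively
  known; this sharing model is an explicit assumption and every piece of
  it is configuration.
* **Databases** cover 80% of all germline variants (`db_coverage`), split
  across two site lists.
* **Depths:** tumor 60×, reference normal 40×, strains 30×, ancestors
  200× (amplicon-scale). 2% of capture sites are low-efficiency
  (`lowcov_factor` 0.2) — a *site* property shared by all samples, as
  capture efficiency is locus-specific; per-sample depth is Poisson
  around the scaled mean, and a zero draw simply leaves the site absent
  from that sample's stream.
* **Error model:** per-read substitution errors at $10^{-4}$ with
  calibrated low base qualities (mean ≈ 8, so most miscalls fail the
  broad quality gate), i.e. quality-filtered consensus-grade pileup
  evidence. This choice is structural, not cosmetic: the strain
  weak-evidence filter accepts a single alt read of any broad quality
  across ~540 panel reads per locus, so its false-removal rate on true
  somatic variants is roughly
  $\text{panel reads} \times \text{error rate} / 3 \times P(\text{pass}\mid\text{error})$.
  At raw-base error rates (~$10^{-3}$ with ordinary qualities) that
  filter removes ~15% of true somatic variants — the over-filtering
  regime the tumor-only design explicitly risks — whereas the original
  workflow applied this check with human review of the raw evidence. The
  generator therefore defaults to the regime in which the automated
  1-read threshold is meaningful; `base_error` and `min_evidence_reads`
  are both exposed for studying the over-filtering trade-off directly.

What the generator does **not** emulate: read-level FASTQ/BAM artifacts,
alignment and mapping biases (the realignment review is exercised on
constructed fixtures instead), copy-number and structural variation, UTRs
(transcript exons are fully coding), depth loss over deletions, germline
indels, and the real — unknown — haplotype structure of outbred colonies.
Recovery results on synthetic cohorts therefore demonstrate the internal
consistency of the cascade (candidates are conserved across terminal
categories; database- or panel-visible germline is removed with logged
reasons; well-covered, well-supported somatic truth is recovered with
precision 1), not calling performance on real alignments.

## Problem sizes and numerical choices

The default synthetic exome is deliberately small — 6 genes × 150 codons
on two contigs (~3 kb of capture footprint), ~345 germline and ~64
somatic truth variants, ~36 samples — sized so a full
simulate-call-filter-validate cycle completes in well under a minute and
the acceptance analyses re-run it from scratch across several seeds. All
randomness flows from a single integer seed through fixed per-stage
derived seeds, so every artifact is reproducible byte for byte.

Tie-breaking and edge conventions, in one place: thresholds are inclusive
on the passing side; equal-scoring alternative placements count
against a reviewed read (`≥` in the artifact rule) while the gapped
self-realignment must strictly beat the mismatch placement; the
longest-CDS transcript wins annotation; catalog entries normalize to
sorted subgroups and letter-sorted type tokens; the all-zero Fisher table
is defined as $P = 1$ with a warning; `hypergeometric_tail(k = 0)` is 1;
an empty silent class makes the missense/silent ratio undefined rather
than infinite.

## Known limitations

Validation rates on synthetic cohorts run far above the ~30% of the
modeled study, because the simulator's germline is mostly removed before
validation and no manual-curation stage contributes false positives.
Study-scale discovery numbers (hundreds of putative calls from real
alignments) depend on raw sequencing data that is not modeled here; the
package reproduces the *procedure* and the catalog-derived results, not
the raw-data call set.
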