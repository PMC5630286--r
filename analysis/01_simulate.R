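#!/usr/bin/env Rscript
# Stage 1 — simulate the cohort.
#
# Generates the default synthetic mouse-MB cohort: a small exome on two
# contigs, 18 inbred strain haplotypes, 12 tumors (4 WNT / 4 SHH / 4 G3)
# with seeded somatic SNVs/indels, 4 ancestor controls, SNP databases
# covering 80% of the germline, and per-read pileups for every sample.
# Large pileups go to scratch/pipeline/; small summaries to results/.

suppressPackageStartupMessages({
  library(mbsomatic)
  library(data.table)
})

seed <- as.integer(Sys.getenv("MBSOMATIC_SEED", "1"))
sim_dir <- "scratch/pipeline/sim"
dir.create(sim_dir, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = seed)
ref <- generate_reference(cfg)
truth <- generate_cohort_truth(ref, cfg)
roster <- cohort_roster(truth, cfg)

write_reference_fasta(ref, file.path(sim_dir, "reference.fa"))
write_transcripts(ref$transcripts, file.path(sim_dir, "transcripts.tsv"))
write_truth_vcf(truth, file.path(sim_dir, "truth.vcf"), ref)
for (nm in names(truth$db))
  write_snp_db(truth$db[[nm]], file.path(sim_dir, paste0(nm, ".tsv")))

for (role in c("tumor", "normal", "strain", "ancestor")) {
  pu <- render_pileups(truth, ref, cfg, roster$sample[roster$role == role])
  write_pileup(pu, file.path(sim_dir, paste0(role, "s.pileup.tsv")))
}

summary <- data.table(
  item = c("seed", "tumors", "strains", "ancestors", "contigs",
           "genes", "truth_germline_variants", "truth_somatic_variants",
           "db_known_fraction", "placement_retries"),
  value = c(seed, cfg$n_tumors, cfg$n_strains, length(truth$ancestors),
            length(ref$contigs), nrow(ref$transcripts),
            nrow(truth$germline), nrow(truth$somatic),
            round(mean(truth$germline$in_db), 3), truth$retries))
fwrite(summary, "results/01_cohort_summary.tsv", sep = "\t")

cat(sprintf(
  "Simulated cohort (seed %d): %d tumors carrying %d somatic truth variants\n",
  seed, cfg$n_tumors, nrow(truth$somatic)))
cat(sprintf("  germline background: %d variants, %.0f%% database-known\n",
            nrow(truth$germline), 100 * mean(truth$germline$in_db)))
cat("  artifacts under", sim_dir, "; summary in results/01_cohort_summary.tsv\n")
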