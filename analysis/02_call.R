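#!/usr/bin/env Rscript
# Stage 2 — candidate calling.
#
# Detects candidate SNVs/indels in every tumor against the reference
# normal with the discovery parameter set (read gates, >=2 alt reads from
# distinct evidence), computes the one-sided Fisher exact P per candidate,
# applies the somatic criteria (VAF >= 10%, P < 0.10) and assigns the
# four-way quality/significance class.

suppressPackageStartupMessages({
  library(mbsomatic)
  library(data.table)
})

sim_dir <- "scratch/pipeline/sim"
call_dir <- "scratch/pipeline/call"
dir.create(call_dir, recursive = TRUE, showWarnings = FALSE)

ref <- ref_bundle(read_reference_fasta(file.path(sim_dir, "reference.fa")),
                  read_transcripts(file.path(sim_dir, "transcripts.tsv")))
pu_tumor <- read_pileup(file.path(sim_dir, "tumors.pileup.tsv"))
pu_normal <- read_pileup(file.path(sim_dir, "normals.pileup.tsv"))

cfg <- caller_config()
cs <- call_cohort(pu_tumor, pu_normal, cfg, ref)

fwrite(cs$calls, file.path(call_dir, "candidates.tsv"), sep = "\t")
fwrite(filter_trail(cs), file.path(call_dir, "trail.tsv"), sep = "\t")

cls <- table(four_way_class(cs))
summary <- data.table(
  item = c("candidates", "somatic_putative", "rejected",
           paste0("class_", names(cls))),
  value = c(nrow(cs$calls), sum(cs$calls$status == "somatic_putative"),
            sum(cs$calls$status == "rejected"), as.integer(cls)))
fwrite(summary, "results/02_calling_summary.tsv", sep = "\t")

cat(sprintf("Candidates: %d; somatic-putative after criteria: %d\n",
            nrow(cs$calls), sum(cs$calls$status == "somatic_putative")))
cat("Four-way (quality/significance) classes:\n")
print(cls)
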