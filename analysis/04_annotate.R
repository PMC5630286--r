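#!/usr/bin/env Rscript
# Stage 4 — consequence annotation.
#
# Strand-aware codon classification of the validated somatic mutations
# (silent / missense / nonsense / frameshift / in-frame / splice /
# noncoding), the non-silent count and the missense-to-silent ratio.

suppressPackageStartupMessages({
  library(mbsomatic)
  library(data.table)
})

sim_dir <- "scratch/pipeline/sim"
val_dir <- "scratch/pipeline/validate"
ann_dir <- "scratch/pipeline/annotate"
dir.create(ann_dir, recursive = TRUE, showWarnings = FALSE)

ref <- ref_bundle(read_reference_fasta(file.path(sim_dir, "reference.fa")),
                  read_transcripts(file.path(sim_dir, "transcripts.tsv")))
calls <- fread(file.path(val_dir, "validated.tsv"),
               colClasses = list(character = c("id", "sample_id", "contig",
                                               "ref", "alt", "var_type",
                                               "status")))

ann <- annotate_calls(calls, ref$transcripts, ref)

# subgroup roster recovered from the sample naming scheme
roster <- data.table(sample = unique(calls$sample_id))
roster[, subgroup := c(MBW = "WNT", MBS = "SHH",
                       MBM = "G3")[substr(sample, 1, 3)]]
records <- mutation_records(ann, roster)
write_mutation_records(records, file.path(ann_dir, "mutation_records.tsv"))

s <- summarize_consequences(records)
fwrite(data.table(class = names(s$class_counts),
                  n = as.integer(s$class_counts)),
       "results/04_consequence_classes.tsv", sep = "\t")

cat(sprintf("Validated mutation records: %d\n", nrow(records)))
cat(sprintf("Non-silent (amino-acid-changing): %d\n", s$n_nonsilent))
cat(sprintf("Missense-to-silent ratio: %s\n",
            if (s$ratio_defined) sprintf("%.1f", s$missense_silent_ratio)
            else "undefined (no silent mutations)"))
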