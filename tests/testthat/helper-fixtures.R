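# Fixtures built in code: a fast small cohort configuration, a hand-built
# two-exon transcript with known codons, pileup-site constructors, and a
# synthetic stand-in for a validated-mutation table.

small_sim_config <- function(seed = 1L, ...) {
  args <- list(seed = seed,
               n_strains = 6L,
               subgroup_sizes = c(WNT = 1L, SHH = 1L, G3 = 1L),
               burden_mean = c(WNT = 4, SHH = 2, G3 = 3),
               n_genes = 2L, codons_per_gene = 60L, exons_per_gene = 2L,
               intron_length = 60L, intergenic = 120L,
               depth_tumor = 40, depth_normal = 40, depth_strain = 25,
               depth_ancestor = 80,
               n_founder = 8L, n_strain_private = 4L, n_line_private = 4L)
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

# One plus-strand gene, two exons of 30 codons each, intron of 52 bp.
# Codon 46 is ATT (Ile); codons 2-45 GCT (Ala), 47-59 GGA (Gly), 60 TAA.
tiny_ref <- function(pad = 20L) {
  cds <- paste0("ATG", strrep("GCT", 44), "ATT", strrep("GGA", 13), "TAA")
  stopifnot(nchar(cds) == 180L)
  exon1 <- substr(cds, 1L, 90L)
  exon2 <- substr(cds, 91L, 180L)
  intron <- strrep("TTCA", 13L)          # 52 bp, no ATT context
  left <- strrep("CA", pad / 2)
  right <- strrep("GT", pad / 2)
  contig <- paste0(left, exon1, intron, exon2, right)
  e1s <- pad + 1L; e1e <- pad + 90L
  e2s <- e1e + nchar(intron) + 1L; e2e <- e2s + 89L
  tx <- data.table::data.table(
    gene = "Tiny1", tx_id = "TXT01", contig = "ctgA", strand = "+",
    exon_starts = paste(c(e1s, e2s), collapse = ","),
    exon_ends = paste(c(e1e, e2e), collapse = ","),
    cds_start = e1s, cds_end = e2e)
  structure(list(contigs = c(ctgA = contig), transcripts = tx),
            class = "ref_bundle")
}

# genomic position of (codon, within-codon offset 1..3) in tiny_ref
tiny_cds_gpos <- function(ref, codon, offset = 1L) {
  cdsp <- (codon - 1L) * 3L + offset
  ex <- exon_table(ref$transcripts[1])
  if (cdsp <= 90L) ex$start[1] + cdsp - 1L
  else ex$start[2] + (cdsp - 90L) - 1L
}

# mirrored bundle: reverse-complemented contig with the minus-strand
# transcript occupying the mirrored coordinates
mirror_bundle <- function(ref) {
  contig <- ref$contigs[[1]]
  L <- nchar(contig)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(contig)))
  tx <- data.table::copy(ref$transcripts)
  ex <- exon_table(tx[1])
  new_starts <- rev(L - ex$end + 1L)
  new_ends <- rev(L - ex$start + 1L)
  tx[1, `:=`(strand = ifelse(strand == "+", "-", "+"),
             exon_starts = paste(new_starts, collapse = ","),
             exon_ends = paste(new_ends, collapse = ","),
             cds_start = new_starts[1], cds_end = new_ends[length(new_ends)])]
  structure(list(contigs = setNames(rc, names(ref$contigs)),
                 transcripts = tx), class = "ref_bundle")
}

# pileup-site constructor for caller/filter unit tests
make_site <- function(alleles, ref = "A", baseQ = 35L, mapQ = 60L,
                      flankQ = 30L, mismatches = 0L, hqMismatches = 0L,
                      sample = "T1", contig = "chr1", pos = 100L,
                      readId = NULL) {
  n <- length(alleles)
  data.table::data.table(
    sample = sample, contig = contig, pos = as.integer(pos), ref = ref,
    allele = alleles,
    baseQ = as.integer(rep_len(baseQ, n)),
    mapQ = as.integer(rep_len(mapQ, n)),
    flankQ = as.integer(rep_len(flankQ, n)),
    mismatches = as.integer(rep_len(mismatches, n)),
    hqMismatches = as.integer(rep_len(hqMismatches, n)),
    readId = readId %||% paste0(sample, ".", seq_len(n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# candidate_set with a single synthetic candidate row (status/fields set
# directly, for stage-level unit tests)
make_candidate <- function(id = "T1:chr1:100:A>G", sample_id = "T1",
                           contig = "chr1", pos = 100L, ref = "A", alt = "G",
                           tumor_ref = 20L, tumor_alt = 10L,
                           normal_ref = 30L, normal_alt = 0L,
                           vaf = tumor_alt / (tumor_ref + tumor_alt),
                           fisher_p = NA_real_, status = "somatic_putative",
                           median_alt_baseq = 35) {
  calls <- data.table::data.table(
    id = id, sample_id = sample_id, contig = contig, pos = as.integer(pos),
    ref = ref, alt = alt, var_type = variant_type(ref, alt),
    tumor_ref = as.integer(tumor_ref), tumor_alt = as.integer(tumor_alt),
    normal_ref = as.integer(normal_ref), normal_alt = as.integer(normal_alt),
    vaf = vaf, distinct_reads = as.integer(tumor_alt),
    median_alt_baseq = median_alt_baseq, fisher_p = fisher_p,
    sig_tier = NA_character_, quality_tier = NA_character_, status = status)
  candidate_set(calls)
}

# SYNTHETIC stand-in for a validated-mutation table: 64 records over 12
# tumors with the aggregate structure of the study cohort (62 SNVs + 2
# frameshift indels, per-tumor burdens 0..31 summing to 64, 40 non-silent,
# missense:silent = 34:20). Class counts within the printed aggregates are
# not published; these are fixed so that every printed summary is a
# function of a single consistent record set.
synthetic_validated_records <- function() {
  burdens <- c(MBW01 = 31L, MBW02 = 10L, MBW03 = 7L, MBW04 = 6L,
               MBS01 = 0L, MBS02 = 1L, MBS03 = 1L, MBS04 = 2L,
               MBM01 = 2L, MBM02 = 1L, MBM03 = 2L, MBM04 = 1L)
  stopifnot(sum(burdens) == 64L)
  classes <- c(rep("missense", 34L), rep("silent", 20L),
               rep("nonsense", 2L), rep("splice", 2L),
               rep("frameshift", 2L), rep("noncoding", 4L))
  stopifnot(length(classes) == 64L)
  sample_id <- rep(names(burdens), burdens)
  sg <- c(MBW = "WNT", MBS = "SHH", MBM = "G3")
  data.table::data.table(
    sample_id = sample_id,
    subgroup = unname(sg[substr(sample_id, 1L, 3L)]),
    gene = sprintf("GeneS%02d", seq_len(64L)),
    class = classes,
    var_type = ifelse(classes == "frameshift", "DEL", "SNV"))
}

tumor_roster_12 <- function() {
  data.table::data.table(
    sample = c(paste0("MBW0", 1:4), paste0("MBS0", 1:4), paste0("MBM0", 1:4)),
    subgroup = rep(c("WNT", "SHH", "G3"), each = 4L))
}
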