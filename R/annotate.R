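# Coding-consequence annotation.
#
# Strand-aware codon lookup against the transcript models using the
# standard nuclear genetic code: CDS SNVs become silent / missense /
# nonsense by codon translation, CDS indels become frameshift (length not
# a multiple of 3) or in-frame, and SNVs within the splice window of an
# exon/intron boundary become splice. Variants outside any transcript (or
# deep intronic) are noncoding. One record per variant, taken on the
# longest-CDS overlapping transcript.

AA_CODE <- Biostrings::GENETIC_CODE

translate_codon <- function(codon) unname(AA_CODE[codon])

# per-transcript CDS geometry: genomic exon table and CDS sequence
transcript_geometry <- function(tx_row, ref) {
  ex <- exon_table(tx_row)
  chunks <- vapply(seq_len(nrow(ex)), function(j)
    substr(ref$contigs[[tx_row$contig]], ex$start[j], ex$end[j]), "")
  cds <- paste(chunks, collapse = "")
  if (tx_row$strand == "-") cds <- reverse_complement(cds)
  list(exons = ex, cds = cds, strand = tx_row$strand, contig = tx_row$contig)
}

# 1-based CDS position of a genomic position (NA when not exonic)
cds_position <- function(geom, gpos) {
  ex <- geom$exons
  inside <- gpos >= ex$start & gpos <= ex$end
  if (!any(inside)) return(NA_integer_)
  j <- which(inside)[1]
  before <- if (j > 1L) sum(ex$end[seq_len(j - 1L)] - ex$start[seq_len(j - 1L)] + 1L) else 0L
  fwd <- before + (gpos - ex$start[j] + 1L)
  if (geom$strand == "+") fwd else nchar(geom$cds) - fwd + 1L
}

# distance to the nearest intronic splice boundary; 0 when exonic
splice_distance <- function(geom, gpos) {
  ex <- geom$exons
  if (any(gpos >= ex$start & gpos <= ex$end)) return(0L)
  k <- nrow(ex)
  if (k < 2L) return(NA_integer_)
  d <- NA_integer_
  for (j in seq_len(k - 1L)) {
    if (gpos > ex$end[j] && gpos < ex$start[j + 1L]) {
      d <- min(gpos - ex$end[j], ex$start[j + 1L] - gpos)
    }
  }
  d
}

overlapping_transcripts <- function(transcripts, contig_, lo, hi, flank = 0L) {
  transcripts[contig == contig_ & cds_start - flank <= hi &
                cds_end + flank >= lo]
}

#' Annotate one variant with its coding consequence
#'
#' @param contig,pos,ref_allele,alt_allele normalized variant (VCF
#'   conventions, indels anchored).
#' @param transcripts transcript model table.
#' @param ref a `ref_bundle`.
#' @param splice_window intronic bp around exon boundaries treated as
#'   splice-disrupting for SNVs (canonical donor/acceptor = 2).
#' @return list: gene, tx_id, class (silent, missense, nonsense,
#'   frameshift, inframe_indel, splice, noncoding), protein_change (e.g.
#'   "I46T", "Q12*"; NA otherwise), note.
#' @export
annotate_variant <- function(contig, pos, ref_allele, alt_allele,
                             transcripts, ref, splice_window = 2L) {
  if (!contig %in% names(ref$contigs))
    stop("annotate_variant: unknown contig ", contig)
  span_hi <- pos + nchar(ref_allele) - 1L
  cand <- overlapping_transcripts(transcripts, contig, pos, span_hi,
                                  flank = splice_window + 50L)
  none <- list(gene = NA_character_, tx_id = NA_character_,
               class = "noncoding", protein_change = NA_character_,
               note = NA_character_)
  if (!nrow(cand)) return(none)
  # longest-CDS policy over transcripts whose exon structure the variant touches
  geoms <- lapply(seq_len(nrow(cand)), function(i)
    transcript_geometry(cand[i], ref))
  ord <- order(-vapply(geoms, function(g) nchar(g$cds), 1L))
  vt <- variant_type(ref_allele, alt_allele)
  for (i in ord) {
    g <- geoms[[i]]
    tx <- cand[i]
    if (vt == "SNV") {
      cp <- cds_position(g, pos)
      if (!is.na(cp)) {
        codon_idx <- (cp - 1L) %/% 3L + 1L
        within <- (cp - 1L) %% 3L + 1L
        codon <- substr(g$cds, (codon_idx - 1L) * 3L + 1L, codon_idx * 3L)
        alt_base <- if (g$strand == "+") alt_allele else
          reverse_complement(alt_allele)
        mut <- codon
        substr(mut, within, within) <- alt_base
        aa_ref <- translate_codon(codon)
        aa_alt <- translate_codon(mut)
        if (aa_ref == aa_alt) {
          return(list(gene = tx$gene, tx_id = tx$tx_id, class = "silent",
                      protein_change = NA_character_, note = NA_character_))
        }
        if (aa_alt == "*") {
          return(list(gene = tx$gene, tx_id = tx$tx_id, class = "nonsense",
                      protein_change = paste0(aa_ref, codon_idx, "*"),
                      note = NA_character_))
        }
        note <- if (aa_ref == "*") "stop_loss_folded_into_missense" else NA_character_
        return(list(gene = tx$gene, tx_id = tx$tx_id, class = "missense",
                    protein_change = paste0(aa_ref, codon_idx, aa_alt),
                    note = note))
      }
      sd <- splice_distance(g, pos)
      if (!is.na(sd) && sd <= splice_window) {
        return(list(gene = tx$gene, tx_id = tx$tx_id, class = "splice",
                    protein_change = NA_character_, note = NA_character_))
      }
    } else {
      # indel: altered genomic bases are those after the anchor (deletion)
      # or the insertion point between pos and pos+1
      if (vt == "DEL") {
        touched <- seq(pos + 1L, pos + nchar(ref_allele) - 1L)
      } else {
        touched <- c(pos, pos + 1L)
      }
      in_cds <- any(!is.na(vapply(touched, function(p) cds_position(g, p),
                                  1L)))
      if (in_cds) {
        shift <- abs(nchar(ref_allele) - nchar(alt_allele)) %% 3L
        cls <- if (shift != 0L) "frameshift" else "inframe_indel"
        return(list(gene = tx$gene, tx_id = tx$tx_id, class = cls,
                    protein_change = NA_character_, note = NA_character_))
      }
      sd <- min(vapply(touched, function(p) {
        d <- splice_distance(g, p); if (is.na(d)) Inf else d
      }, 1))
      if (is.finite(sd) && sd <= splice_window) {
        return(list(gene = tx$gene, tx_id = tx$tx_id, class = "splice",
                    protein_change = NA_character_, note = NA_character_))
      }
    }
  }
  none
}

#' Annotate a table of variants
#'
#' @param variants data.table with contig, pos, ref, alt columns (e.g.
#'   `candidate_set$calls`).
#' @param transcripts,ref,splice_window see [annotate_variant()].
#' @return the table with gene, tx_id, class, protein_change, note columns
#'   appended.
#' @export
annotate_calls <- function(variants, transcripts, ref, splice_window = 2L) {
  v <- copy(as.data.table(variants))
  ann <- lapply(seq_len(nrow(v)), function(i)
    annotate_variant(v$contig[i], v$pos[i], v$ref[i], v$alt[i],
                     transcripts, ref, splice_window))
  v[, `:=`(gene = vapply(ann, `[[`, "", "gene"),
           tx_id = vapply(ann, `[[`, "", "tx_id"),
           class = vapply(ann, `[[`, "", "class"),
           protein_change = vapply(ann, `[[`, "", "protein_change"),
           note = vapply(ann, `[[`, "", "note"))]
  v[]
}

#' Build mutation records from validated calls
#'
#' Only `validated_somatic` candidates become records; each carries the
#' sample, its subgroup, the variant and the consequence call.
#'
#' @param annotated annotated calls table (from [annotate_calls()] on
#'   `candidate_set$calls`).
#' @param roster data.table(sample, subgroup) for the tumors.
#' @return data.table of mutation records.
#' @export
mutation_records <- function(annotated, roster) {
  rec <- as.data.table(annotated)[status == "validated_somatic"]
  bad <- setdiff(rec$sample_id, roster$sample)
  if (length(bad)) stop("mutation_records: samples absent from roster: ",
                        paste(bad, collapse = ", "))
  rec[as.data.table(roster), on = c(sample_id = "sample"),
      subgroup := i.subgroup]
  rec[]
}

#' Summarize consequence classes
#'
#' @param records mutation-record table with a `class` column.
#' @return list: class_counts (named), n_records, n_nonsilent (classes
#'   other than silent and noncoding), n_missense, n_silent,
#'   missense_silent_ratio (NA with `ratio_defined = FALSE` when no silent
#'   mutations exist).
#' @export
summarize_consequences <- function(records) {
  classes <- c("silent", "missense", "nonsense", "frameshift",
               "inframe_indel", "splice", "noncoding")
  cc <- setNames(integer(length(classes)), classes)
  if (nrow(records)) {
    tab <- table(factor(records$class, levels = classes))
    cc[names(tab)] <- as.integer(tab)
  }
  n_nonsilent <- sum(cc[setdiff(classes, c("silent", "noncoding"))])
  defined <- cc[["silent"]] > 0L
  list(class_counts = cc,
       n_records = if (nrow(records)) nrow(records) else 0L,
       n_nonsilent = n_nonsilent,
       n_missense = cc[["missense"]],
       n_silent = cc[["silent"]],
       missense_silent_ratio = if (defined) cc[["missense"]] / cc[["silent"]]
       else NA_real_,
       ratio_defined = defined)
}

#' Write mutation records as TSV
#'
#' Mirrors the validated-mutation table layout: sample, subgroup, gene,
#' position, alleles, protein change, consequence class.
#'
#' @param records mutation-record table.
#' @param path output path.
#' @export
write_mutation_records <- function(records, path) {
  cols <- intersect(c("sample_id", "subgroup", "gene", "contig", "pos",
                      "ref", "alt", "var_type", "protein_change", "class",
                      "vaf", "fisher_p"), names(records))
  fwrite(records[, ..cols], path, sep = "\t")
  invisible(path)
}
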