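# Candidate SNV/indel calling with Fisher's-exact somatic criteria.
#
# Detection compares each tumor's per-read evidence with a reference normal
# (here the public C57BL/6-style sample), applies the caller's read-level
# quality/mismatch gates, and emits one candidate per non-reference allele
# with enough filtered support. Somatic criteria: one-sided Fisher's exact
# P for alt enrichment in tumor below 0.10 and tumor VAF >= 10%; candidates
# are then placed in the four-way (quality tier x significance tier) class.

#' Caller configuration
#'
#' Defaults mirror the variation-detection parameter set used for discovery:
#' reads contribute only with mapping quality >= 1, base quality >= 10,
#' flanking quality >= 15, at most 20 mismatches of which at most 15 are
#' high-quality (base quality >= 15); candidates need >= 2 filtered alt
#' reads from >= 2 distinct reads of evidence. Somatic criteria: tumor VAF
#' >= 0.10 and one-sided Fisher P < 0.10, with P < 0.05 the high
#' significance tier and 0.05 < P < 0.10 the low tier. `min_minor_frequency`
#' is honored as a (default no-op) threshold on the filtered tumor VAF.
#'
#' @param min_flanking_quality,min_alt_allele_count,min_minor_frequency
#'   read-gate and support thresholds.
#' @param broad_min_quality minimum base quality for a read to count at all.
#' @param mmf_max_hq_mismatches,mmf_min_quality,mmf_max_any_mismatches
#'   mismatch-filter thresholds (hq = mismatches at base quality >=
#'   `mmf_min_quality`).
#' @param unique_filter_coverage minimum distinct reads of alt evidence.
#' @param min_mapq minimum mapping quality.
#' @param vaf_min minimum tumor variant allele fraction.
#' @param p_high,p_low significance-tier boundaries (`P < p_high` HIGH,
#'   `p_high < P < p_low` LOW, `P >= p_low` rejected).
#' @param quality_tier_threshold median alt-read base quality at or above
#'   which a candidate is quality-tier HIGH.
#' @return object of class `caller_config`.
#' @export
caller_config <- function(min_flanking_quality = 15,
                          min_alt_allele_count = 2,
                          min_minor_frequency = 0,
                          broad_min_quality = 10,
                          mmf_max_hq_mismatches = 15,
                          mmf_min_quality = 15,
                          mmf_max_any_mismatches = 20,
                          unique_filter_coverage = 2,
                          min_mapq = 1,
                          vaf_min = 0.10,
                          p_high = 0.05,
                          p_low = 0.10,
                          quality_tier_threshold = 25) {
  cfg <- as.list(environment())
  if (!(p_high > 0 && p_high < p_low && p_low <= 1))
    stop("caller_config: need 0 < p_high < p_low <= 1")
  if (vaf_min < 0 || vaf_min > 1)
    stop("caller_config: vaf_min must lie in [0, 1]")
  counts <- c(min_flanking_quality, min_alt_allele_count, broad_min_quality,
              mmf_max_hq_mismatches, mmf_min_quality, mmf_max_any_mismatches,
              unique_filter_coverage, min_mapq, quality_tier_threshold)
  if (any(counts < 0)) stop("caller_config: count thresholds must be >= 0")
  class(cfg) <- "caller_config"
  cfg
}

#' Read-level gate used by all allele counting
#'
#' A read contributes iff mapQ >= min_mapq, baseQ >= broad_min_quality,
#' flankQ >= min_flanking_quality, mismatches <= mmf_max_any_mismatches and
#' high-quality mismatches <= mmf_max_hq_mismatches.
#'
#' @param reads data.table of read observations (pileup dialect).
#' @param cfg a [caller_config()].
#' @return logical vector, one element per read.
#' @export
read_passes_gates <- function(reads, cfg) {
  reads$mapQ >= cfg$min_mapq &
    reads$baseQ >= cfg$broad_min_quality &
    reads$flankQ >= cfg$min_flanking_quality &
    reads$mismatches <= cfg$mmf_max_any_mismatches &
    reads$hqMismatches <= cfg$mmf_max_hq_mismatches
}

#' Filtered allele counts at one site
#'
#' @param site data.table of read observations for one sample at one locus.
#' @param cfg a [caller_config()].
#' @return named integer vector of per-allele read counts after the read
#'   gates (empty site gives an empty vector).
#' @export
collect_allele_counts <- function(site, cfg) {
  if (is.null(site) || nrow(site) == 0L) return(setNames(integer(0), character(0)))
  keep <- read_passes_gates(site, cfg)
  if (!any(keep)) return(setNames(integer(0), character(0)))
  tab <- table(site$allele[keep])
  setNames(as.integer(tab), names(tab))
}

#' One-sided Fisher's exact P for alt enrichment in tumor
#'
#' Exact upper-tail probability over the 2x2 table
#' `[[t_alt, t_ref], [n_alt, n_ref]]`: the chance, with all margins fixed,
#' of the tumor carrying at least the observed number of alt reads. The
#' tail is summed exactly over the hypergeometric support. Vectorized.
#'
#' @param t_alt,t_ref tumor alt/ref read counts.
#' @param n_alt,n_ref normal alt/ref read counts.
#' @return P in (0, 1]; an all-zero table is defined as P = 1 with a warning.
#' @export
fisher_one_sided <- function(t_alt, t_ref, n_alt, n_ref) {
  n <- length(t_alt)
  stopifnot(length(t_ref) == n, length(n_alt) == n, length(n_ref) == n)
  if (any(c(t_alt, t_ref, n_alt, n_ref) < 0))
    stop("fisher_one_sided: counts must be non-negative")
  tot <- t_alt + t_ref + n_alt + n_ref
  if (any(tot == 0)) warning("fisher_one_sided: all-zero table, P defined as 1")
  m <- t_alt + n_alt          # alt margin
  k <- t_alt + t_ref          # tumor margin (draws)
  p <- numeric(n)
  for (i in seq_len(n)) {
    if (tot[i] == 0) { p[i] <- 1; next }
    hi <- min(m[i], k[i])
    if (t_alt[i] > hi) { p[i] <- 0; next }  # unreachable for consistent counts
    xs <- t_alt[i]:hi
    p[i] <- min(1, sum(dhyper(xs, m[i], tot[i] - m[i], k[i])))
  }
  p
}

candidate_cols <- function() {
  data.table(id = character(), sample_id = character(), contig = character(),
             pos = integer(), ref = character(), alt = character(),
             var_type = character(), tumor_ref = integer(), tumor_alt = integer(),
             normal_ref = integer(), normal_alt = integer(), vaf = numeric(),
             distinct_reads = integer(), median_alt_baseq = numeric(),
             fisher_p = numeric(), sig_tier = character(),
             quality_tier = character(), status = character())
}

empty_trail <- function() {
  data.table(id = character(), stage = character(), decision = character(),
             reason = character())
}

#' A set of candidate variants with a filter trail
#'
#' Container pairing the candidate table with the append-only per-variant
#' filter trail; every pipeline stage records (stage, decision, reason) for
#' each variant it touches.
#'
#' @param calls candidate data.table.
#' @param trail trail data.table.
#' @return object of class `candidate_set`.
#' @export
candidate_set <- function(calls = candidate_cols(), trail = empty_trail()) {
  structure(list(calls = calls, trail = trail), class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("candidate_set:", nrow(x$calls), "candidates\n")
  if (nrow(x$calls)) print(table(x$calls$status))
  invisible(x)
}

add_trail <- function(cs, ids, stage, decision, reason) {
  if (!length(ids)) return(cs)
  cs$trail <- rbindlist(list(cs$trail, data.table(
    id = ids, stage = stage, decision = decision, reason = reason)))
  cs
}

#' Trail rows for a candidate set
#' @param cs candidate_set.
#' @return data.table(id, stage, decision, reason), append order preserved.
#' @export
filter_trail <- function(cs) cs$trail

normalize_indel_token <- function(contig_seq, pos, ref_base, token) {
  if (startsWith(token, "+")) {
    out <- left_align_variant(contig_seq, pos, ref_base,
                              paste0(ref_base, substring(token, 2L)))
  } else {
    del <- substring(token, 2L)
    out <- left_align_variant(contig_seq, pos,
                              paste0(ref_base, del), ref_base)
  }
  out
}

#' Detect candidate variants at one locus
#'
#' Contract-level single-site detection: emits one candidate per
#' non-reference allele whose filtered alt count reaches
#' `min_alt_allele_count` with evidence from at least
#' `unique_filter_coverage` distinct reads. A site absent from the normal
#' yields normal counts {0, 0} and a `low_normal_coverage` flag in the
#' trail. For cohort-scale calling use [call_cohort()], which applies the
#' identical rules vectorized.
#'
#' @param tumor_site,normal_site read observations at one locus (the normal
#'   may be NULL/empty).
#' @param cfg a [caller_config()].
#' @param ref optional `ref_bundle` for indel left-alignment.
#' @return a [candidate_set()].
#' @export
detect_candidates <- function(tumor_site, normal_site, cfg, ref = NULL) {
  if (!nrow(tumor_site)) return(candidate_set())
  locus <- unique(tumor_site[, .(contig, pos, ref)])
  if (nrow(locus) != 1L)
    stop("detect_candidates: tumor_site must cover exactly one locus")
  if (!is.null(normal_site) && nrow(normal_site)) {
    nl <- unique(normal_site[, .(contig, pos)])
    if (nrow(nl) != 1L || nl$contig != locus$contig || nl$pos != locus$pos)
      stop("detect_candidates: tumor and normal sites refer to different loci")
  }
  keep <- read_passes_gates(tumor_site, cfg)
  ts <- tumor_site[keep]
  counts <- collect_allele_counts(tumor_site, cfg)
  ncounts <- if (!is.null(normal_site) && nrow(normal_site))
    collect_allele_counts(normal_site, cfg) else setNames(integer(0), character(0))
  ref_base <- locus$ref
  ref_n <- if (ref_base %in% names(counts)) counts[[ref_base]] else 0L
  n_ref_n <- if (ref_base %in% names(ncounts)) ncounts[[ref_base]] else 0L
  alts <- setdiff(names(counts), ref_base)
  cs <- candidate_set()
  smp <- tumor_site$sample[1]
  for (a in alts) {
    a_n <- counts[[a]]
    uniq <- length(unique(ts$readId[ts$allele == a]))
    if (a_n < cfg$min_alt_allele_count || uniq < cfg$unique_filter_coverage) next
    vaf <- a_n / (ref_n + a_n)
    if (vaf < cfg$min_minor_frequency) next
    if (grepl("^[+-]", a)) {
      if (is.null(ref)) {
        norm <- if (startsWith(a, "+"))
          list(pos = locus$pos, ref = ref_base,
               alt = paste0(ref_base, substring(a, 2L)))
        else list(pos = locus$pos,
                  ref = paste0(ref_base, substring(a, 2L)), alt = ref_base)
      } else {
        norm <- normalize_indel_token(ref$contigs[[locus$contig]], locus$pos,
                                      ref_base, a)
      }
      v_ref <- norm$ref; v_alt <- norm$alt; v_pos <- norm$pos
    } else {
      v_ref <- ref_base; v_alt <- a; v_pos <- locus$pos
    }
    id <- sprintf("%s:%s:%d:%s>%s", smp, locus$contig, v_pos, v_ref, v_alt)
    n_alt_n <- if (a %in% names(ncounts)) ncounts[[a]] else 0L
    row <- data.table(
      id = id, sample_id = smp, contig = locus$contig, pos = as.integer(v_pos),
      ref = v_ref, alt = v_alt, var_type = variant_type(v_ref, v_alt),
      tumor_ref = as.integer(ref_n), tumor_alt = as.integer(a_n),
      normal_ref = as.integer(n_ref_n), normal_alt = as.integer(n_alt_n),
      vaf = vaf, distinct_reads = as.integer(uniq),
      median_alt_baseq = median(ts$baseQ[ts$allele == a]),
      fisher_p = NA_real_, sig_tier = NA_character_,
      quality_tier = NA_character_, status = "candidate")
    cs$calls <- rbindlist(list(cs$calls, row))
    cs <- add_trail(cs, id, "detect", "emit",
                    sprintf("alt=%d distinct=%d", a_n, uniq))
    if ((n_ref_n + n_alt_n) == 0L)
      cs <- add_trail(cs, id, "detect", "flag", "low_normal_coverage")
  }
  cs
}

#' Call candidates across a whole tumor pileup
#'
#' Vectorized cohort-scale detection applying exactly the per-site rules of
#' [detect_candidates()]: read gates, per-allele counting, alt-count and
#' distinct-read thresholds, indel normalization (left alignment), Fisher P
#' against the normal, somatic criteria and the four-way classification.
#'
#' @param tumor_pileup pileup data.table for one or more tumor samples.
#' @param normal_pileup pileup data.table for the reference normal.
#' @param cfg a [caller_config()].
#' @param ref `ref_bundle` used for indel left-alignment.
#' @return a [candidate_set()] with `fisher_p`, tiers and status filled in.
#' @export
call_cohort <- function(tumor_pileup, normal_pileup, cfg, ref) {
  tp <- tumor_pileup[read_passes_gates(tumor_pileup, cfg)]
  np <- normal_pileup[read_passes_gates(normal_pileup, cfg)]
  if (!nrow(tp)) return(candidate_set())
  counts <- tp[, .(n = .N, distinct_reads = data.table::uniqueN(readId),
                   median_alt_baseq = as.numeric(median(baseQ))),
               by = .(sample = sample, contig, pos, ref, allele)]
  refc <- counts[allele == ref, .(sample, contig, pos, tumor_ref = n)]
  altc <- counts[allele != ref]
  altc <- altc[n >= cfg$min_alt_allele_count &
                 distinct_reads >= cfg$unique_filter_coverage]
  if (!nrow(altc)) return(candidate_set())
  altc[refc, on = c("sample", "contig", "pos"), tumor_ref := i.tumor_ref]
  altc[is.na(tumor_ref), tumor_ref := 0L]
  altc[, vaf := n / (tumor_ref + n)]
  altc <- altc[vaf >= cfg$min_minor_frequency]
  if (!nrow(altc)) return(candidate_set())
  # normal counts for the same allele token and the reference allele
  nref <- np[allele == ref, .(normal_ref = .N), by = .(contig, pos)]
  nalt <- np[, .(normal_alt = .N), by = .(contig, pos, allele)]
  altc[nref, on = c("contig", "pos"), normal_ref := i.normal_ref]
  altc[nalt, on = c("contig", "pos", "allele"), normal_alt := i.normal_alt]
  altc[is.na(normal_ref), normal_ref := 0L]
  altc[is.na(normal_alt), normal_alt := 0L]
  # normalize alleles (indel tokens -> anchored, left-aligned ref/alt)
  is_indel <- grepl("^[+-]", altc$allele)
  v_pos <- altc$pos; v_ref <- altc$ref; v_alt <- altc$allele
  if (any(is_indel)) {
    for (i in which(is_indel)) {
      nm <- normalize_indel_token(ref$contigs[[altc$contig[i]]], altc$pos[i],
                                  altc$ref[i], altc$allele[i])
      v_pos[i] <- nm$pos; v_ref[i] <- nm$ref; v_alt[i] <- nm$alt
    }
  }
  calls <- data.table(
    id = sprintf("%s:%s:%d:%s>%s", altc$sample, altc$contig, v_pos, v_ref, v_alt),
    sample_id = altc$sample, contig = altc$contig, pos = as.integer(v_pos),
    ref = v_ref, alt = v_alt, var_type = variant_type(v_ref, v_alt),
    tumor_ref = altc$tumor_ref, tumor_alt = altc$n,
    normal_ref = altc$normal_ref, normal_alt = altc$normal_alt,
    vaf = altc$vaf, distinct_reads = altc$distinct_reads,
    median_alt_baseq = altc$median_alt_baseq,
    fisher_p = NA_real_, sig_tier = NA_character_,
    quality_tier = NA_character_, status = "candidate")
  setorder(calls, sample_id, contig, pos, alt)
  cs <- candidate_set(calls)
  cs <- add_trail(cs, calls$id, "detect", "emit",
                  sprintf("alt=%d distinct=%d", calls$tumor_alt,
                          calls$distinct_reads))
  lown <- calls$id[calls$normal_ref + calls$normal_alt == 0L]
  cs <- add_trail(cs, lown, "detect", "flag", "low_normal_coverage")
  cs <- apply_somatic_criteria(cs, cfg)
  cs <- classify_quality(cs, cfg)
  cs
}

#' Apply the somatic criteria and significance tiers
#'
#' Computes the one-sided Fisher P where missing, then sets status
#' `somatic_putative` iff VAF >= `vaf_min` and P < `p_low`; the
#' significance tier is HIGH for P < `p_high`, LOW for `p_high` < P <
#' `p_low`, else NONE with status `rejected`. Decisions are appended to the
#' filter trail.
#'
#' @param cs a [candidate_set()].
#' @param cfg a [caller_config()].
#' @return the updated candidate_set.
#' @export
apply_somatic_criteria <- function(cs, cfg) {
  calls <- cs$calls
  if (!nrow(calls)) return(cs)
  need <- is.na(calls$fisher_p)
  if (any(need)) {
    calls$fisher_p[need] <- fisher_one_sided(
      calls$tumor_alt[need], calls$tumor_ref[need],
      calls$normal_alt[need], calls$normal_ref[need])
  }
  p <- calls$fisher_p
  calls$sig_tier <- ifelse(p < cfg$p_high, "HIGH",
                           ifelse(p < cfg$p_low, "LOW", "NONE"))
  pass_vaf <- calls$vaf >= cfg$vaf_min
  pass_p <- p < cfg$p_low
  upd <- calls$status == "candidate"
  calls$status[upd & pass_vaf & pass_p] <- "somatic_putative"
  calls$status[upd & !(pass_vaf & pass_p)] <- "rejected"
  cs$calls <- calls
  cs <- add_trail(cs, calls$id[upd & pass_vaf & pass_p], "somatic_criteria",
                  "pass", sprintf("p=%.4g vaf=%.3f",
                                  p[upd & pass_vaf & pass_p],
                                  calls$vaf[upd & pass_vaf & pass_p]))
  rej <- upd & !(pass_vaf & pass_p)
  cs <- add_trail(cs, calls$id[rej], "somatic_criteria", "reject",
                  ifelse(!pass_vaf[rej], "vaf_below_min", "p_above_low"))
  cs
}

#' Assign the quality tier (four-way classification)
#'
#' Quality tier is HIGH iff the median base quality of the filtered
#' alt-supporting reads reaches `quality_tier_threshold`; the four-way
#' class of a substitution is the pair (quality tier, significance tier).
#' Pure function of its inputs.
#'
#' @param cs a [candidate_set()] (after [apply_somatic_criteria()]).
#' @param cfg a [caller_config()].
#' @return the updated candidate_set.
#' @export
classify_quality <- function(cs, cfg) {
  if (!nrow(cs$calls)) return(cs)
  cs$calls$quality_tier <- ifelse(
    cs$calls$median_alt_baseq >= cfg$quality_tier_threshold, "HIGH", "LOW")
  cs <- add_trail(cs, cs$calls$id, "quality_tier", cs$calls$quality_tier,
                  sprintf("median_alt_baseq=%.1f", cs$calls$median_alt_baseq))
  cs
}

#' Four-way class labels
#' @param cs candidate_set after tier assignment.
#' @return character vector like "HIGH/LOW" (quality tier / significance
#'   tier) per candidate.
#' @export
four_way_class <- function(cs) {
  paste(cs$calls$quality_tier, cs$calls$sig_tier, sep = "/")
}

#' Write candidate calls as annotated VCF
#'
#' FILTER reflects terminal status (PASS for validated somatic); INFO
#' carries Fisher P, VAF and the two tiers.
#'
#' @param cs candidate_set.
#' @param path output path.
#' @param ref optional ref_bundle for contig headers.
#' @export
write_calls_vcf <- function(cs, path, ref = NULL) {
  calls <- cs$calls
  status_filter <- c(candidate = "rejected", somatic_putative = "PASS",
                     rejected = "rejected", germline = "germline_db",
                     artifact = "artifact", validated_somatic = "PASS",
                     not_covered = "not_covered")
  filt <- status_filter[calls$status]
  # refine germline filter labels from the trail
  g <- cs$trail[stage %in% c("db_filter", "strain_filter", "ancestor_validate") &
                  decision == "germline"]
  if (nrow(g)) {
    lab <- c(db_filter = "germline_db", strain_filter = "germline_strain",
             ancestor_validate = "germline_ancestor")
    filt[match(g$id, calls$id)] <- lab[g$stage]
  }
  dt <- data.table(contig = calls$contig, pos = calls$pos, id = calls$id,
                   ref = calls$ref, alt = calls$alt, filter = unname(filt),
                   info = sprintf("FISHERP=%.6g;VAF=%.4f;SIGTIER=%s;QUALTIER=%s",
                                  calls$fisher_p, calls$vaf, calls$sig_tier,
                                  calls$quality_tier))
  setorder(dt, contig, pos, alt)
  cl <- if (!is.null(ref)) nchar(ref$contigs) else NULL
  write_simple_vcf(dt, path, contig_lengths = cl)
}
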