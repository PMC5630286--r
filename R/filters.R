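# Germline filter cascade, realignment/indel review, ancestor validation.
#
# Stage order is fixed: SNP databases -> strain-panel raw evidence ->
# realignment / mutant-template review -> ancestor-panel validation. Each
# stage only touches candidates still in play (status somatic_putative), so
# every stage is idempotent, and every decision lands in the filter trail.

#' A germline SNP database
#'
#' @param name database name used in removal reasons.
#' @param sites data.table(contig, pos, alt), 1-based; duplicates dropped.
#' @return object of class `snp_db`.
#' @export
snp_db <- function(name, sites) {
  sites <- unique(as.data.table(sites)[, .(contig, pos = as.integer(pos), alt)])
  structure(list(name = name, sites = sites), class = "snp_db")
}

#' Remove candidates found in germline SNP databases
#'
#' Matching is on (contig, pos, alt) — full normalized alt string, so
#' indels match on their left-aligned (pos, ref, alt) identity and a
#' different alt allele at a known position is retained (tri-allelic sites
#' are not over-filtered). Matches get status `germline` with reason
#' `db:<name>`.
#'
#' @param cs a [candidate_set()].
#' @param dbs list of [snp_db()] objects (possibly empty).
#' @return updated candidate_set.
#' @export
filter_known_snps <- function(cs, dbs) {
  if (!nrow(cs$calls) || !length(dbs)) return(cs)
  live <- cs$calls$status == "somatic_putative"
  for (db in dbs) {
    if (!inherits(db, "snp_db")) stop("filter_known_snps: dbs must contain snp_db objects")
    key <- paste(db$sites$contig, db$sites$pos, db$sites$alt)
    hit <- live & paste(cs$calls$contig, cs$calls$pos, cs$calls$alt) %in% key
    if (any(hit)) {
      cs$calls$status[hit] <- "germline"
      cs <- add_trail(cs, cs$calls$id[hit], "db_filter", "germline",
                      paste0("db:", db$name))
      live <- live & !hit
    }
  }
  cs
}

#' Remove candidates with raw alt evidence in any panel strain
#'
#' Implements the weak-evidence check against the raw strain data: a
#' candidate is germline (reason `strain:<id>`) if at least
#' `min_evidence_reads` alt-supporting reads of any quality >=
#' `broad_min_quality` exist at the locus in any panel strain. Loci with no
#' panel coverage at all are retained and flagged `panel_uncovered`.
#'
#' @param cs a [candidate_set()].
#' @param strain_pileup pileup data.table covering the panel strains (the
#'   `sample` column identifies the strain).
#' @param cfg a [caller_config()] (for `broad_min_quality`).
#' @param min_evidence_reads minimum alt reads in a single strain.
#' @return updated candidate_set.
#' @export
strain_evidence_filter <- function(cs, strain_pileup, cfg,
                                   min_evidence_reads = 1L) {
  calls <- cs$calls
  if (!nrow(calls)) return(cs)
  live <- which(calls$status == "somatic_putative")
  if (!length(live)) return(cs)
  sp <- strain_pileup[baseQ >= cfg$broad_min_quality]
  cov <- sp[, .N, by = .(contig, pos)]
  for (i in live) {
    token <- allele_token(calls$ref[i], calls$alt[i])
    here <- sp[contig == calls$contig[i] & pos == calls$pos[i]]
    if (!nrow(cov[contig == calls$contig[i] & pos == calls$pos[i]])) {
      cs <- add_trail(cs, calls$id[i], "strain_filter", "flag", "panel_uncovered")
      next
    }
    hits <- here[allele == token, .N, by = sample]
    hits <- hits[N >= min_evidence_reads]
    if (nrow(hits)) {
      cs$calls$status[i] <- "germline"
      cs <- add_trail(cs, calls$id[i], "strain_filter", "germline",
                      paste0("strain:", hits$sample[1]))
    } else {
      cs <- add_trail(cs, calls$id[i], "strain_filter", "pass", "no_strain_evidence")
    }
  }
  cs
}

# pileup allele token for a normalized variant
allele_token <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, alt,
         ifelse(nchar(alt) > nchar(ref), paste0("+", substring(alt, 2L)),
                paste0("-", substring(ref, 2L))))
}

local_align_score <- function(pattern, subject, scoring = align_scoring()) {
  BiocGenerics::score(pairwise_local(pattern, subject, scoring))
}

#' Nucleotide alignment scoring scheme
#'
#' Typical local-alignment defaults: match +2, mismatch -3, affine gaps
#' costing `gap_open + L * gap_ext` for a gap of length L.
#'
#' @param match,mismatch,gap_open,gap_ext scoring parameters (gap costs
#'   are positive penalties).
#' @return a list used by the alignment-based operations.
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = 5, gap_ext = 2) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_ext = gap_ext)
}

pairwise_local <- function(pattern, subject, scoring = align_scoring()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
}

# ungapped score of a read placed at a fixed reference offset
placement_score <- function(read, window, offset, scoring = align_scoring()) {
  n <- nchar(read)
  if (offset < 1L || offset + n - 1L > nchar(window)) return(-Inf)
  r <- strsplit(read, "")[[1]]
  w <- strsplit(substr(window, offset, offset + n - 1L), "")[[1]]
  sum(ifelse(r == w, scoring$match, scoring$mismatch))
}

# positions (1-based) in `seq` sharing any k-mer with `read`, outside [lo, hi]
kmer_hits <- function(read, seq, k, lo, hi) {
  n <- nchar(read)
  if (n < k) return(integer(0))
  kmers <- unique(vapply(seq_len(n - k + 1L),
                         function(i) substr(read, i, i + k - 1L), ""))
  hits <- integer(0)
  for (km in kmers) {
    m <- gregexpr(km, seq, fixed = TRUE)[[1]]
    m <- m[m > 0]
    hits <- c(hits, m[m < lo - k | m > hi])
  }
  unique(hits)
}

#' Realignment review of an SNV candidate
#'
#' Re-examines the alt-supporting reads: each read is scored at its
#' original placement against the reference (ungapped), then against (a)
#' gapped local alignment to the same reference window and (b) local
#' alignments to every other reference window sharing a k-mer seed with the
#' read. A read is "explained away" when some alternative scores at least
#' as well as the original placement without invoking the alt base; the
#' candidate becomes an `artifact` when a majority of alt reads are
#' explained away (single ambiguous reads never kill a call). Without read
#' sequences the review is skipped and the call flagged `unreviewed`.
#'
#' @param cs a [candidate_set()] (the call at `call_id` must be an SNV).
#' @param call_id id of the candidate under review.
#' @param alt_reads data.frame(seq, start): alt-supporting read sequences
#'   and their 1-based mapped start positions, or NULL.
#' @param ref a `ref_bundle`.
#' @param window reference window half-width around the call.
#' @param k k-mer seed length for alternative placements.
#' @param scoring an [align_scoring()] list.
#' @return updated candidate_set.
#' @export
realign_review_snv <- function(cs, call_id, alt_reads, ref,
                               window = 200L, k = 13L,
                               scoring = align_scoring()) {
  i <- match(call_id, cs$calls$id)
  if (is.na(i)) stop("realign_review_snv: unknown call id ", call_id)
  if (cs$calls$status[i] != "somatic_putative") return(cs)
  if (is.null(alt_reads) || !nrow(alt_reads)) {
    return(add_trail(cs, call_id, "snv_review", "flag", "unreviewed"))
  }
  ctg <- cs$calls$contig[i]; p <- cs$calls$pos[i]
  seq <- ref$contigs[[ctg]]
  lo <- max(1L, p - window); hi <- min(nchar(seq), p + window)
  win <- substr(seq, lo, hi)
  away <- logical(nrow(alt_reads))
  for (r in seq_len(nrow(alt_reads))) {
    rd <- alt_reads$seq[r]
    off <- alt_reads$start[r] - lo + 1L
    s_orig <- placement_score(rd, win, off, scoring)
    s_gap <- local_align_score(rd, win, scoring)
    s_other <- -Inf
    for (h in kmer_hits(rd, seq, k, lo, hi)) {
      wlo <- max(1L, h - window); whi <- min(nchar(seq), h + window)
      s_other <- max(s_other, local_align_score(rd, substr(seq, wlo, whi),
                                                scoring))
    }
    # the gapped self-alignment only counts when it re-explains the read
    # without the alt mismatch, i.e. beats the mismatch-bearing placement
    away[r] <- (s_gap > s_orig) || (s_other >= s_orig)
  }
  if (mean(away) > 0.5) {
    cs$calls$status[i] <- "artifact"
    cs <- add_trail(cs, call_id, "snv_review", "artifact",
                    sprintf("explained_away=%d/%d", sum(away), length(away)))
  } else {
    cs <- add_trail(cs, call_id, "snv_review", "pass",
                    sprintf("explained_away=%d/%d", sum(away), length(away)))
  }
  cs
}

#' Build the mutant allele template for an indel
#'
#' Returns the reference window centered on the indel anchor with the indel
#' applied; length is `window` minus the deletion length or plus the
#' insertion length.
#'
#' @param ref a `ref_bundle`.
#' @param contig,pos,ref_allele,alt_allele normalized anchored indel.
#' @param window total wild-type window length (bp).
#' @return list(template, wild, win_start, indel_at): sequences plus the
#'   1-based template position of the first altered base.
#' @export
build_mutant_template <- function(ref, contig, pos, ref_allele, alt_allele,
                                  window = 100L) {
  seq <- ref$contigs[[contig]]
  half <- window %/% 2L
  lo <- pos - half
  hi <- lo + window - 1L
  if (lo < 1L || hi > nchar(seq))
    stop("build_mutant_template: window extends outside contig")
  wild <- substr(seq, lo, hi)
  anchor_off <- pos - lo + 1L
  left <- substr(wild, 1L, anchor_off - 1L)
  right <- substr(wild, anchor_off + nchar(ref_allele), nchar(wild))
  template <- paste0(left, alt_allele, right)
  list(template = template, wild = wild, win_start = lo,
       indel_at = anchor_off + 1L)
}

read_covers_mutant <- function(read, tmpl, scoring = align_scoring()) {
  a_t <- pairwise_local(read, tmpl$template, scoring)
  a_w <- pairwise_local(read, tmpl$wild, scoring)
  if (BiocGenerics::score(a_t) <= BiocGenerics::score(a_w)) return(FALSE)
  # must span the altered bases with at least one anchored base each side
  n_changed <- max(0L, nchar(tmpl$template) - nchar(tmpl$wild))
  st <- IRanges::start(Biostrings::subject(a_t))
  en <- IRanges::end(Biostrings::subject(a_t))
  st <= tmpl$indel_at - 1L && en >= tmpl$indel_at + n_changed
}

#' Mutant-template review of an indel candidate
#'
#' Scores every tumor and normal read at the indel site against both the
#' wild-type window and the mutant template (local alignment, affine gaps).
#' A read "covers the mutant allele" when it aligns strictly better to the
#' template and spans the indel. Any normal read covering the mutant allele
#' makes the call `germline`; otherwise the call is retained only with at
#' least `min_alt_allele_count` tumor mutant-covering reads. Reads too
#' short to span the indel count for neither side. Without read sequences
#' the review is skipped and flagged `unreviewed`.
#'
#' @param cs a [candidate_set()].
#' @param call_id id of the indel candidate.
#' @param tumor_reads,normal_reads character vectors of read sequences at
#'   the site (either may be NULL).
#' @param ref a `ref_bundle`.
#' @param cfg a [caller_config()].
#' @param window wild-type window length for [build_mutant_template()].
#' @param scoring an [align_scoring()] list.
#' @return updated candidate_set.
#' @export
indel_review <- function(cs, call_id, tumor_reads, normal_reads, ref, cfg,
                         window = 100L, scoring = align_scoring()) {
  i <- match(call_id, cs$calls$id)
  if (is.na(i)) stop("indel_review: unknown call id ", call_id)
  if (cs$calls$status[i] != "somatic_putative") return(cs)
  if (!cs$calls$var_type[i] %in% c("INS", "DEL"))
    stop("indel_review: call is not an indel")
  if (is.null(tumor_reads) || !length(tumor_reads)) {
    return(add_trail(cs, call_id, "indel_review", "flag", "unreviewed"))
  }
  tmpl <- build_mutant_template(ref, cs$calls$contig[i], cs$calls$pos[i],
                                cs$calls$ref[i], cs$calls$alt[i], window)
  t_cov <- sum(vapply(tumor_reads, read_covers_mutant, TRUE, tmpl = tmpl,
                      scoring = scoring))
  n_cov <- if (length(normal_reads))
    sum(vapply(normal_reads, read_covers_mutant, TRUE, tmpl = tmpl,
               scoring = scoring)) else 0L
  if (n_cov >= 1L) {
    cs$calls$status[i] <- "germline"
    cs <- add_trail(cs, call_id, "indel_review", "germline",
                    sprintf("normal_mutant_reads=%d", n_cov))
  } else if (t_cov >= cfg$min_alt_allele_count) {
    cs <- add_trail(cs, call_id, "indel_review", "pass",
                    sprintf("tumor_mutant_reads=%d", t_cov))
  } else {
    cs$calls$status[i] <- "rejected"
    cs <- add_trail(cs, call_id, "indel_review", "reject",
                    sprintf("tumor_mutant_reads=%d", t_cov))
  }
  cs
}

#' Flag calls that cannot be sequence-reviewed
#'
#' When per-read sequences are unavailable (the pileup dialect carries
#' qualities and mismatch counts only), the realignment and indel reviews
#' cannot run; surviving candidates are flagged `unreviewed` and proceed to
#' validation.
#'
#' @param cs a [candidate_set()].
#' @return updated candidate_set.
#' @export
flag_unreviewed <- function(cs) {
  live <- cs$calls$id[cs$calls$status == "somatic_putative"]
  stage <- ifelse(cs$calls$var_type[match(live, cs$calls$id)] == "SNV",
                  "snv_review", "indel_review")
  for (st in unique(stage)) {
    cs <- add_trail(cs, live[stage == st], st, "flag", "unreviewed")
  }
  cs
}

#' Manual curation lists
#'
#' The human review step between filtering and validation is represented
#' as optional allow/deny lists of candidate ids. Denied candidates still
#' in play are rejected (`manual_deny`); allowed candidates are asserted
#' past the automated pre-validation removals — an allowed candidate that
#' a filter removed is reinstated to `somatic_putative` with an explicit
#' override entry in the trail. This is the only stage permitted to
#' override automated decisions; it defaults to doing nothing.
#'
#' @param cs a [candidate_set()].
#' @param allow,deny character vectors of candidate ids (may be NULL).
#' @return updated candidate_set.
#' @export
manual_curation <- function(cs, allow = NULL, deny = NULL) {
  deny <- intersect(deny %||% character(0), cs$calls$id)
  hit <- cs$calls$id %in% deny & cs$calls$status == "somatic_putative"
  if (any(hit)) {
    cs$calls$status[hit] <- "rejected"
    cs <- add_trail(cs, cs$calls$id[hit], "manual_curation", "reject",
                    "manual_deny")
  }
  allow <- intersect(allow %||% character(0), cs$calls$id)
  back <- cs$calls$id %in% allow &
    cs$calls$status %in% c("germline", "artifact", "rejected")
  if (any(back)) {
    cs$calls$status[back] <- "somatic_putative"
    cs <- add_trail(cs, cs$calls$id[back], "manual_curation", "pass",
                    "manual_allow_override")
  }
  cs
}

#' Ancestor-panel validation
#'
#' For each surviving candidate: `not_covered` when no control covers the
#' locus; `germline` (reason `ancestor:<id>`) when any control shows the
#' alt allele at >= `min_reads` reads and VAF >= `vaf_floor`;
#' `validated_somatic` when the tumor amplicon confirms the alt (>=
#' `min_reads` reads at VAF >= `vaf_floor`) and every covered control is
#' negative. A tumor amplicon that fails to confirm rejects the call.
#'
#' @param cs a [candidate_set()].
#' @param ancestor_pileup pileup data.table over the control mice (`sample`
#'   column identifies the control).
#' @param tumor_pileup pileup data.table with the tumors' amplicon
#'   observations at the tested loci.
#' @param cfg a [caller_config()].
#' @param vaf_floor detectability floor for the ancestor/tumor evidence.
#' @param min_reads minimum alt reads above the floor.
#' @return updated candidate_set.
#' @export
ancestor_validate <- function(cs, ancestor_pileup, tumor_pileup, cfg,
                              vaf_floor = 0.05, min_reads = 2L) {
  calls <- cs$calls
  live <- which(calls$status == "somatic_putative")
  if (!length(live)) return(cs)
  ap <- ancestor_pileup[baseQ >= cfg$broad_min_quality]
  tp <- tumor_pileup[baseQ >= cfg$broad_min_quality]
  for (i in live) {
    token <- allele_token(calls$ref[i], calls$alt[i])
    here <- ap[contig == calls$contig[i] & pos == calls$pos[i]]
    if (!nrow(here)) {
      cs$calls$status[i] <- "not_covered"
      cs <- add_trail(cs, calls$id[i], "ancestor_validate", "not_covered",
                      "no_control_coverage")
      next
    }
    ctrl <- here[, .(depth = .N, alt_n = sum(allele == token)), by = sample]
    ctrl[, vaf := alt_n / depth]
    pos_ctrl <- ctrl[alt_n >= min_reads & vaf >= vaf_floor]
    if (nrow(pos_ctrl)) {
      cs$calls$status[i] <- "germline"
      cs <- add_trail(cs, calls$id[i], "ancestor_validate", "germline",
                      paste0("ancestor:", pos_ctrl$sample[1]))
      next
    }
    th <- tp[sample == calls$sample_id[i] & contig == calls$contig[i] &
               pos == calls$pos[i]]
    t_alt <- sum(th$allele == token)
    t_vaf <- if (nrow(th)) t_alt / nrow(th) else 0
    if (t_alt >= min_reads && t_vaf >= vaf_floor) {
      cs$calls$status[i] <- "validated_somatic"
      cs <- add_trail(cs, calls$id[i], "ancestor_validate", "validated",
                      sprintf("tumor_amplicon_vaf=%.3f controls_negative=%d",
                              t_vaf, nrow(ctrl)))
    } else {
      cs$calls$status[i] <- "rejected"
      cs <- add_trail(cs, calls$id[i], "ancestor_validate", "reject",
                      "amplicon_unconfirmed")
    }
  }
  cs
}
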