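#' @importFrom data.table data.table setDT setkey rbindlist fread fwrite := .N .SD setorder copy as.data.table setnames
#' @importFrom stats rpois rbinom rnorm runif median setNames dhyper
#' @importFrom utils head tail
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "allele", "alt", "alt_count", "baseQ", "contig", "depth", "flankQ",
  "gene", "hqMismatches", "id", "mapQ", "mismatches", "n_alt", "n_ref",
  "pos", "readId", "ref", "ref_count", "sample_id", "status", "study",
  "vaf", "var_type", "stage", "decision", "reason", "J", "N_", "distinct_reads",
  "median_alt_baseq", "is_alt", "class_", "subgroup", "total", "species",
  "site_factor", "origin", "owner", "type", "in_db"
))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generation inside the package
#' never disturbs the caller's RNG stream.
#'
#' @param seed integer seed (kept below 2^31 by callers).
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  eval.parent(substitute(expr))
}

#' Classify a normalized variant as SNV, insertion or deletion
#'
#' @param ref,alt reference and alternate allele strings (VCF conventions,
#'   indels anchored on the preceding base).
#' @return character vector in `c("SNV","INS","DEL")`.
#' @export
variant_type <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
         ifelse(nchar(alt) > nchar(ref), "INS", "DEL"))
}

#' Left-align an anchored indel against the reference sequence
#'
#' Shifts an insertion or deletion to its leftmost equivalent placement
#' (identical alternate haplotype), the normalization both the simulator and
#' the caller apply so truth-vs-call matching is exact. SNVs are returned
#' unchanged.
#'
#' @param seq reference contig sequence (single character string).
#' @param pos 1-based anchor position.
#' @param ref,alt allele strings in VCF convention.
#' @return list with elements `pos`, `ref`, `alt`.
#' @export
left_align_variant <- function(seq, pos, ref, alt) {
  if (nchar(ref) == 1L && nchar(alt) == 1L) {
    return(list(pos = pos, ref = ref, alt = alt))
  }
  base_at <- function(p) substr(seq, p, p)
  if (nchar(ref) > nchar(alt)) {         # deletion: ref = anchor + D
    d <- substr(ref, 2L, nchar(ref))
    dl <- nchar(d)
    # shift left while the base entering the deletion from the left equals
    # the base leaving it on the right
    while (pos > 1L && base_at(pos) == base_at(pos + dl)) {
      pos <- pos - 1L
      d <- substr(seq, pos + 1L, pos + dl)
    }
    list(pos = pos, ref = paste0(base_at(pos), d), alt = base_at(pos))
  } else {                               # insertion: alt = anchor + I
    ins <- substr(alt, 2L, nchar(alt))
    while (pos > 1L && base_at(pos) == substr(ins, nchar(ins), nchar(ins))) {
      ins <- paste0(substr(ins, nchar(ins), nchar(ins)),
                    substr(ins, 1L, nchar(ins) - 1L))
      pos <- pos - 1L
    }
    list(pos = pos, ref = base_at(pos), alt = paste0(base_at(pos), ins))
  }
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write a minimal VCF 4.2 file
#'
#' @param dt data.table with columns contig, pos, id, ref, alt, info
#'   (semicolon-joined INFO strings).
#' @param path output path.
#' @param contig_lengths named integer vector for `##contig` headers.
#' @keywords internal
write_simple_vcf <- function(dt, path, contig_lengths = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mbsomatic",
    '##INFO=<ID=SOMATIC,Number=0,Type=Flag,Description="Somatic variant">',
    '##INFO=<ID=GERMLINE,Number=0,Type=Flag,Description="Germline variant">',
    '##INFO=<ID=ORIGIN,Number=1,Type=String,Description="Simulator origin class">',
    '##INFO=<ID=SAMPLE,Number=1,Type=String,Description="Carrying tumor sample">',
    '##INFO=<ID=VAF,Number=1,Type=Float,Description="Target variant allele fraction">',
    '##INFO=<ID=FISHERP,Number=1,Type=Float,Description="One-sided Fisher exact P">',
    '##INFO=<ID=SIGTIER,Number=1,Type=String,Description="Significance tier">',
    '##INFO=<ID=QUALTIER,Number=1,Type=String,Description="Quality tier">',
    '##FILTER=<ID=germline_db,Description="Matched a germline SNP database">',
    '##FILTER=<ID=germline_strain,Description="Alt evidence in a panel strain">',
    '##FILTER=<ID=germline_ancestor,Description="Alt evidence in an ancestor control">',
    '##FILTER=<ID=artifact,Description="Failed realignment review">',
    '##FILTER=<ID=not_covered,Description="No validation-panel coverage">',
    '##FILTER=<ID=rejected,Description="Failed somatic criteria">'
  )
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(dt)) {
    filt <- if ("filter" %in% names(dt)) dt$filter else "PASS"
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t%s\t%s",
                    dt$contig, as.integer(dt$pos), dt$id, dt$ref, dt$alt,
                    filt, dt$info)
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a minimal VCF back into a data.table
#'
#' Parses CHROM/POS/ID/REF/ALT/FILTER/INFO from a VCF body; used for
#' round-tripping the simulator truth file and pipeline outputs.
#'
#' @param path VCF path.
#' @return data.table with one row per record.
#' @export
read_simple_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    return(data.table(contig = character(), pos = integer(), id = character(),
                      ref = character(), alt = character(),
                      filter = character(), info = character()))
  }
  parts <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  data.table(contig = parts[[1]], pos = as.integer(parts[[2]]),
             id = parts[[3]], ref = parts[[4]], alt = parts[[5]],
             filter = parts[[7]], info = parts[[8]])
}

#' Test whether a VCF INFO string carries a flag
#' @param info character vector of INFO fields.
#' @param flag flag name (e.g. "SOMATIC").
#' @return logical vector.
#' @export
vcf_info_flag <- function(info, flag) {
  vapply(strsplit(info, ";", fixed = TRUE),
         function(x) flag %in% x, logical(1))
}
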