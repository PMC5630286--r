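# Cohort-level statistics: burden summaries, subgroup comparisons by exact
# permutation, hypergeometric enrichment, and the terminal report.

#' Per-tumor mutation burden summary
#'
#' Counts include tumors with zero records; the mean is also reported at
#' one decimal, matching how per-tumor burden is conventionally quoted.
#'
#' @param records mutation-record table (may be empty).
#' @param roster data.table(sample, subgroup) including zero-mutation
#'   tumors; a record whose sample is absent from the roster is an error.
#' @return list: per_tumor (named integer), per_subgroup (list of integer
#'   vectors), mean, mean_1dp, range.
#' @export
mutation_burden <- function(records, roster) {
  roster <- as.data.table(roster)
  records <- as.data.table(records)
  if (nrow(records)) {
    bad <- setdiff(records$sample_id, roster$sample)
    if (length(bad)) stop("mutation_burden: records for samples absent from roster: ",
                          paste(bad, collapse = ", "))
  }
  counts <- setNames(integer(nrow(roster)), roster$sample)
  if (nrow(records)) {
    tab <- table(records$sample_id)
    counts[names(tab)] <- as.integer(tab)
  }
  per_sg <- split(unname(counts), roster$subgroup)
  m <- mean(counts)
  list(per_tumor = counts, per_subgroup = per_sg,
       mean = m, mean_1dp = round(m, 1),
       range = c(min(counts), max(counts)))
}

#' Exact permutation comparison of two burden groups
#'
#' Exact P by full enumeration of group assignments (all
#' `choose(nA + nB, nA)` relabelings) of either the Wilcoxon rank-sum
#' statistic (ties handled by midranks) or the difference-of-means
#' statistic. Enumeration is exact for the cohort sizes in play (a few
#' samples per subgroup); larger groups fall back to the asymptotic
#' rank-sum test.
#'
#' @param a,b numeric burden vectors (both nonempty).
#' @param alternative "greater" (A tends larger) or "two.sided".
#' @param statistic "ranksum" or "meandiff".
#' @param max_enum largest number of assignments to enumerate.
#' @return P value.
#' @export
compare_burden <- function(a, b, alternative = c("greater", "two.sided"),
                           statistic = c("ranksum", "meandiff"),
                           max_enum = 2e5) {
  alternative <- match.arg(alternative)
  statistic <- match.arg(statistic)
  if (!length(a) || !length(b)) stop("compare_burden: both groups must be nonempty")
  pooled <- c(a, b)
  nA <- length(a); n <- length(pooled)
  if (choose(n, nA) > max_enum) {
    wt <- stats::wilcox.test(a, b, alternative = if (alternative == "greater")
      "greater" else "two.sided", exact = FALSE, correct = TRUE)
    return(unname(wt$p.value))
  }
  stat_of <- function(idx) {
    if (statistic == "ranksum") sum(rank(pooled)[idx])
    else mean(pooled[idx]) - mean(pooled[-idx])
  }
  obs <- stat_of(seq_len(nA))
  combs <- utils::combn(n, nA)
  stats_all <- apply(combs, 2L, stat_of)
  eps <- 1e-9
  if (alternative == "greater") {
    mean(stats_all >= obs - eps)
  } else {
    center <- mean(stats_all)
    mean(abs(stats_all - center) >= abs(obs - center) - eps)
  }
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X hypergeometric: `n` draws without replacement from a
#' population of `N` containing `K` successes. Summed exactly over the
#' support via log-binomial coefficients.
#'
#' @param N population size.
#' @param K successes in the population.
#' @param n draws.
#' @param k observed successes.
#' @return exact tail probability.
#' @export
hypergeometric_tail <- function(N, K, n, k) {
  ok <- N >= 0 && K >= 0 && n >= 0 && k >= 0 && K <= N && n <= N && k <= n
  if (!ok) stop("hypergeometric_tail: need 0 <= k <= n <= N and K <= N")
  lo <- max(k, max(0, n + K - N))
  hi <- min(K, n)
  if (k <= max(0, n + K - N)) return(1)
  if (lo > hi) return(0)
  xs <- lo:hi
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

#' Assemble the terminal cohort report
#'
#' Machine-readable account of the whole cascade: per-stage candidate
#' counts (with conservation across terminal categories), validation rate
#' computed with not-covered calls excluded from the denominator, per-tumor
#' and per-subgroup burdens, the consequence summary, and (when supplied)
#' the cross-species concordance list and gene tallies.
#'
#' @param cs terminal [candidate_set()].
#' @param records mutation-record table.
#' @param roster data.table(sample, subgroup).
#' @param concordant optional character vector of concordant genes.
#' @param tallies optional named list of [tally_gene()] results.
#' @return object of class `cohort_report` (a nested list).
#' @export
cohort_report <- function(cs, records, roster, concordant = NULL,
                          tallies = NULL) {
  calls <- cs$calls
  status_levels <- c("somatic_putative", "rejected", "germline", "artifact",
                     "not_covered", "validated_somatic")
  stage_counts <- setNames(as.integer(table(factor(calls$status,
                                                   levels = status_levels))),
                           status_levels)
  total <- nrow(calls)
  trail <- cs$trail
  removal <- trail[decision == "germline",
                   .N, by = stage]
  reached_validation <- sum(calls$status %in%
                              c("validated_somatic", "not_covered")) +
    nrow(trail[stage == "ancestor_validate" &
                 decision %in% c("germline", "reject")])
  tested <- reached_validation - stage_counts[["not_covered"]]
  validated <- stage_counts[["validated_somatic"]]
  burden <- mutation_burden(records, roster)
  consequences <- summarize_consequences(records)
  rep <- list(
    candidates_total = total,
    stage_counts = as.list(stage_counts),
    germline_removals_by_stage = if (nrow(removal))
      setNames(as.list(removal$N), removal$stage) else list(),
    validation = list(tested = tested, validated = validated,
                      rate = if (tested > 0) validated / tested else NA_real_),
    burden = list(per_tumor = as.list(burden$per_tumor),
                  per_subgroup = lapply(burden$per_subgroup, as.integer),
                  mean = burden$mean, mean_1dp = burden$mean_1dp,
                  range = as.integer(burden$range)),
    consequences = list(class_counts = as.list(consequences$class_counts),
                        n_nonsilent = consequences$n_nonsilent,
                        missense_silent_ratio = consequences$missense_silent_ratio,
                        ratio_defined = consequences$ratio_defined),
    concordant_genes = concordant %||% character(0),
    gene_tallies = lapply(tallies %||% list(), as.list))
  class(rep) <- "cohort_report"
  rep
}

#' Write a cohort report as JSON, TSV and plain text
#'
#' Output is deterministic for identical inputs (no timestamps, fixed key
#' order and formatting), so reruns of the same configuration are
#' byte-identical.
#'
#' @param report a [cohort_report()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  tsv_path <- file.path(dir, "burden.tsv")
  bt <- data.table(sample = names(report$burden$per_tumor),
                   burden = unlist(report$burden$per_tumor))
  fwrite(bt, tsv_path, sep = "\t")
  txt_path <- file.path(dir, "report.txt")
  lines <- c(
    "Somatic mutation discovery report",
    sprintf("Candidates: %d", report$candidates_total),
    sprintf("  validated somatic: %d", report$stage_counts$validated_somatic),
    sprintf("  germline: %d | artifact: %d | rejected: %d | not covered: %d",
            report$stage_counts$germline, report$stage_counts$artifact,
            report$stage_counts$rejected, report$stage_counts$not_covered),
    sprintf("Validation rate (not-covered excluded): %s",
            if (is.na(report$validation$rate)) "NA"
            else sprintf("%.0f%% (%d/%d)", 100 * report$validation$rate,
                         report$validation$validated, report$validation$tested)),
    sprintf("Burden: mean %.1f per tumor, range %d-%d",
            report$burden$mean_1dp, report$burden$range[1],
            report$burden$range[2]),
    sprintf("Non-silent mutations: %d | missense/silent ratio: %s",
            report$consequences$n_nonsilent,
            if (isTRUE(report$consequences$ratio_defined))
              sprintf("%.1f", report$consequences$missense_silent_ratio)
            else "undefined"),
    if (length(report$concordant_genes))
      sprintf("Subgroup-concordant genes: %s",
              paste(report$concordant_genes, collapse = ", "))
    else "Subgroup-concordant genes: none computed")
  writeLines(lines, txt_path)
  invisible(c(json = json_path, tsv = tsv_path, txt = txt_path))
}
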