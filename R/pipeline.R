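# End-to-end pipeline: simulate -> call -> filter -> validate -> annotate
# -> crossmap -> report. Stages communicate through files under the output
# directory; the effective configuration is echoed there; rerunning the
# same configuration reproduces the terminal report byte for byte.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    sim = formals(sim_config)[-1L],
    caller = formals(caller_config),
    filters = list(min_evidence_reads = 1L, vaf_floor = 0.05, min_reads = 2L,
                   allow = character(0), deny = character(0)),
    annotation = list(splice_window = 2L),
    crossmap = list(score_floor = 40),
    output = list(write_pileups = TRUE))
}

merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(defaults))
      stop("pipeline_config: unknown key '", full, "'")
    if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], full)
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Pipeline configuration
#'
#' Nested sections (sim, caller, filters, annotation, crossmap, output)
#' over a global seed. Unknown keys are rejected; the effective
#' configuration is echoed into every output directory.
#'
#' @param config NULL (defaults), a nested list of overrides, or a path to
#'   a YAML file of overrides.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(config = NULL) {
  user <- if (is.null(config)) list()
  else if (is.character(config)) yaml::read_yaml(config)
  else if (is.list(config)) config
  else stop("pipeline_config: config must be NULL, a list or a YAML path")
  defaults <- pipeline_defaults()
  # formals come through as language objects; force-evaluate
  defaults$sim <- lapply(defaults$sim, function(x) if (is.language(x)) eval(x) else x)
  defaults$caller <- lapply(defaults$caller, function(x) if (is.language(x)) eval(x) else x)
  cfg <- merge_config(defaults, user)
  class(cfg) <- "pipeline_config"
  cfg
}

resolve_configs <- function(cfg) {
  sim <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
  caller <- do.call(caller_config, cfg$caller)
  list(sim = sim, caller = caller)
}

#' Run the full discovery pipeline
#'
#' Executes simulate -> call -> filter -> validate -> annotate -> crossmap
#' -> report against a synthetic cohort, writing each stage's outputs and a
#' log under `out_dir`. Deterministic: identical configuration yields a
#' byte-identical terminal report. With `dry_run` the stage plan is printed
#' and nothing is written.
#'
#' @param config see [pipeline_config()].
#' @param out_dir output directory.
#' @param dry_run logical; print the plan only.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the truth, candidate set, records,
#'   report and output paths.
#' @export
run_pipeline <- function(config = NULL, out_dir, dry_run = FALSE,
                         quiet = TRUE) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  stages <- c("simulate", "call", "filter", "validate", "annotate",
              "crossmap", "report")
  if (dry_run) {
    cat("pipeline plan:", paste(stages, collapse = " -> "), "\n")
    return(invisible(stages))
  }
  say <- function(...) if (!quiet) message(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "pipeline.log")
  log_lines <- character(0)
  log_add <- function(...) log_lines <<- c(log_lines, sprintf(...))
  rc <- resolve_configs(cfg)
  yaml::write_yaml(rapply(unclass(cfg), function(x) x, how = "replace"),
                   file.path(out_dir, "config.yaml"))

  # --- simulate ---------------------------------------------------------
  say("simulate")
  ref <- generate_reference(rc$sim)
  truth <- generate_cohort_truth(ref, rc$sim)
  roster <- cohort_roster(truth, rc$sim)
  sim_dir <- file.path(out_dir, "sim")
  dir.create(sim_dir, showWarnings = FALSE)
  write_reference_fasta(ref, file.path(sim_dir, "reference.fa"))
  write_transcripts(ref$transcripts, file.path(sim_dir, "transcripts.tsv"))
  write_truth_vcf(truth, file.path(sim_dir, "truth.vcf"), ref)
  for (nm in names(truth$db))
    write_snp_db(truth$db[[nm]], file.path(sim_dir, paste0(nm, ".tsv")))
  tumor_samples <- roster$sample[roster$role == "tumor"]
  pu_tumor <- render_pileups(truth, ref, rc$sim, tumor_samples)
  pu_normal <- render_pileups(truth, ref, rc$sim, "normalC57")
  pu_strain <- render_pileups(truth, ref, rc$sim,
                              roster$sample[roster$role == "strain"])
  if (isTRUE(cfg$output$write_pileups)) {
    write_pileup(pu_tumor, file.path(sim_dir, "tumors.pileup.tsv"))
    write_pileup(pu_normal, file.path(sim_dir, "normal.pileup.tsv"))
    write_pileup(pu_strain, file.path(sim_dir, "strains.pileup.tsv"))
  }
  log_add("simulate: %d tumors, %d strains, %d truth somatic, %d germline, %d retries",
          length(tumor_samples), rc$sim$n_strains, nrow(truth$somatic),
          nrow(truth$germline), truth$retries)

  # --- call -------------------------------------------------------------
  say("call")
  cs <- call_cohort(pu_tumor, pu_normal, rc$caller, ref)
  # filtered tumor depth at every truth somatic locus (for recovery strata)
  tp_pass <- pu_tumor[read_passes_gates(pu_tumor, rc$caller)]
  dcounts <- tp_pass[, .(depth_f = .N), by = .(sample, contig, pos)]
  somatic_depth <- merge(truth$somatic, dcounts,
                         by.x = c("sample_id", "contig", "pos"),
                         by.y = c("sample", "contig", "pos"), all.x = TRUE)
  somatic_depth[is.na(depth_f), depth_f := 0L]
  call_dir <- file.path(out_dir, "call")
  dir.create(call_dir, showWarnings = FALSE)
  fwrite(cs$calls, file.path(call_dir, "candidates.tsv"), sep = "\t")
  log_add("call: %d candidates, %d somatic-putative", nrow(cs$calls),
          sum(cs$calls$status == "somatic_putative"))

  # --- filter (db -> strain -> review) ----------------------------------
  say("filter")
  dbs <- lapply(names(truth$db), function(nm) snp_db(nm, truth$db[[nm]]))
  cs <- filter_known_snps(cs, dbs)
  cs <- strain_evidence_filter(cs, pu_strain, rc$caller,
                               min_evidence_reads = cfg$filters$min_evidence_reads)
  # pileups carry no read sequences: realignment/indel reviews are
  # sequence-level and flag the survivors unreviewed here
  cs <- flag_unreviewed(cs)
  cs <- manual_curation(cs, allow = cfg$filters$allow,
                        deny = cfg$filters$deny)
  filt_dir <- file.path(out_dir, "filter")
  dir.create(filt_dir, showWarnings = FALSE)
  fwrite(cs$calls, file.path(filt_dir, "filtered.tsv"), sep = "\t")
  log_add("filter: %d still somatic-putative, %d germline",
          sum(cs$calls$status == "somatic_putative"),
          sum(cs$calls$status == "germline"))

  # --- validate ---------------------------------------------------------
  say("validate")
  live <- cs$calls[status == "somatic_putative", .(contig, pos)]
  anc_samples <- roster$sample[roster$role == "ancestor"]
  pu_anc <- if (nrow(live)) render_pileups(truth, ref, rc$sim, anc_samples,
                                           sites = unique(live))
  else pu_tumor[0]
  cs <- ancestor_validate(cs, pu_anc, pu_tumor, rc$caller,
                          vaf_floor = cfg$filters$vaf_floor,
                          min_reads = cfg$filters$min_reads)
  val_dir <- file.path(out_dir, "validate")
  dir.create(val_dir, showWarnings = FALSE)
  fwrite(cs$calls, file.path(val_dir, "validated.tsv"), sep = "\t")
  fwrite(cs$trail, file.path(val_dir, "filter_trail.tsv"), sep = "\t")
  write_calls_vcf(cs, file.path(val_dir, "calls.vcf"), ref)
  log_add("validate: %d validated somatic, %d not covered",
          sum(cs$calls$status == "validated_somatic"),
          sum(cs$calls$status == "not_covered"))

  # --- annotate ---------------------------------------------------------
  say("annotate")
  ann <- annotate_calls(cs$calls, ref$transcripts, ref,
                        splice_window = cfg$annotation$splice_window)
  tumor_roster <- roster[roster$role == "tumor", .(sample)]
  tumor_roster[, subgroup := truth$subgroups[sample]]
  records <- mutation_records(ann, tumor_roster)
  ann_dir <- file.path(out_dir, "annotate")
  dir.create(ann_dir, showWarnings = FALSE)
  write_mutation_records(records, file.path(ann_dir, "mutation_records.tsv"))
  log_add("annotate: %d mutation records", nrow(records))

  # --- crossmap ---------------------------------------------------------
  say("crossmap")
  # synthetic ortholog table: human symbol is the upper-cased mouse symbol,
  # human mRNA identical to the mouse CDS (identity coordinate map)
  ortho <- data.table(mouse_symbol = ref$transcripts$gene,
                      human_symbol = toupper(ref$transcripts$gene))
  cm <- copy(records)[!is.na(gene)]
  if (nrow(cm)) {
    cm[, human_gene := map_ortholog(gene, ortho)]
  } else cm[, human_gene := character(0)]
  cm_dir <- file.path(out_dir, "crossmap")
  dir.create(cm_dir, showWarnings = FALSE)
  fwrite(if (nrow(cm)) cm[, .(sample_id, gene, human_gene, class)] else
    data.table(sample_id = character(), gene = character(),
               human_gene = character(), class = character()),
    file.path(cm_dir, "ortholog_map.tsv"), sep = "\t")

  # --- report -----------------------------------------------------------
  say("report")
  report <- cohort_report(cs, records, tumor_roster)
  paths <- write_report(report, file.path(out_dir, "report"))
  writeLines(log_lines, logf)
  invisible(list(config = cfg, ref = ref, truth = truth, candidates = cs,
                 records = records, report = report, paths = paths,
                 roster = tumor_roster, somatic_depth = somatic_depth))
}

#' Recovery metrics against simulator truth
#'
#' Compares the terminal candidate set with the cohort truth:
#' * `precision`: fraction of validated-somatic calls matching a truth
#'   somatic variant of the same tumor (exact id match on sample, contig,
#'   left-aligned pos/ref/alt);
#' * `recall_stratum`: recall over truth somatic variants with filtered
#'   tumor depth >= `min_depth` and truth VAF >= `min_vaf`;
#' * `germline_removal_recall`: among truth germline variants that became
#'   candidates and are represented in a SNP database or carried by a panel
#'   strain, the fraction no longer somatic-putative after the
#'   pre-validation cascade (i.e. rejected by the paired criteria or
#'   removed as germline), with every removal carrying a logged reason.
#'
#' @param result a [run_pipeline()] result (or compatible list with
#'   `candidates`, `truth` elements).
#' @param min_depth,min_vaf stratum bounds for recall.
#' @return list of metrics plus the matched tables.
#' @export
recovery_metrics <- function(result, min_depth = 30L, min_vaf = 0.15) {
  cs <- result$candidates
  truth <- result$truth
  calls <- cs$calls
  som <- copy(truth$somatic)
  som[, key := paste(sample_id, contig, pos, ref, alt)]
  calls_key <- paste(calls$sample_id, calls$contig, calls$pos, calls$ref,
                     calls$alt)
  validated <- calls[calls$status == "validated_somatic"]
  vkey <- paste(validated$sample_id, validated$contig, validated$pos,
                validated$ref, validated$alt)
  precision <- if (nrow(validated)) mean(vkey %in% som$key) else NA_real_

  # stratum: filtered tumor depth at the truth locus (carried from the
  # rendered pileup when available, else from the call's filtered counts)
  som[, validated := key %in% vkey]
  if (!is.null(result$somatic_depth)) {
    sd <- result$somatic_depth
    som[, depth_f := sd$depth_f[match(key, paste(sd$sample_id, sd$contig,
                                                 sd$pos, sd$ref, sd$alt))]]
  } else {
    idx <- match(som$key, calls_key)
    som[, depth_f := ifelse(is.na(idx), 0L,
                            calls$tumor_ref[idx] + calls$tumor_alt[idx])]
  }
  stratum <- som[vaf >= min_vaf & depth_f >= min_depth]
  recall <- if (nrow(stratum)) mean(stratum$validated) else NA_real_

  # germline removal: candidates matching a truth germline variant that is
  # visible to the databases or the strain panel must leave the
  # somatic-putative pool before ancestor validation
  germ <- copy(truth$germline)
  germ[, in_panel := origin %in% c("founder", "strain_private") |
         !is.na(panel_carrier)]
  germ[, represented := in_db | in_panel]
  rep_key <- germ[represented == TRUE, paste(contig, pos, alt)]
  cand_gkey <- paste(calls$contig, calls$pos, calls$alt)
  sel <- which(cand_gkey %in% rep_key)
  if (length(sel)) {
    pre_stages <- c("somatic_criteria", "db_filter", "strain_filter",
                    "snv_review", "indel_review")
    removed_pre <- cs$trail[stage %in% pre_stages &
                              decision %in% c("reject", "germline", "artifact")]
    pre_val_removed <- calls$id[sel] %in% removed_pre$id
    g_recall <- mean(pre_val_removed)
    g_ids <- calls$id[sel][calls$status[sel] == "germline"]
    reasons_logged <- all(g_ids %in% cs$trail$id[cs$trail$decision == "germline" &
                                                   nzchar(cs$trail$reason)])
  } else {
    g_recall <- NA_real_
    reasons_logged <- TRUE
  }
  list(precision = precision,
       recall_stratum = recall,
       n_stratum = nrow(stratum),
       n_validated = nrow(validated),
       n_truth_somatic = nrow(som),
       germline_removal_recall = g_recall,
       germline_reasons_logged = reasons_logged,
       somatic_table = som)
}
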