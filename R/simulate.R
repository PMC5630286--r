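# Synthetic cohort generator
#
# Emulates the data structure the discovery pipeline assumes: a small exome
# (a few multi-exon genes on both strands), 18 inbred laboratory-strain
# germline haplotypes partially represented in SNP databases, 12 tumors in
# three molecular subgroups carrying inherited germline variants plus seeded
# somatic SNVs/indels (VAF >= 10% by default), deep ancestor controls
# sharing each tumor's germline background, and per-read pileup evidence
# with realistic base/mapping/flanking qualities and sequencing error.

SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

#' Simulation configuration
#'
#' Defaults encode the study design being emulated: 18 panel strains, 12
#' tumors in three subgroups (4 WNT, 4 SHH, 4 G3) with subgroup burden means
#' (10, 2, 4) giving an expected 64 somatic mutations (5.3 per tumor) and
#' the WNT > G3 > SHH burden ordering, somatic VAFs drawn uniformly on
#' [0.10, 0.90], and a germline background only partially visible to the
#' SNP databases and strain panel so that ancestor validation carries real
#' weight.
#'
#' @param seed integer; fully determines all generated output.
#' @param n_strains number of panel strains (inbred, homozygous haplotypes).
#' @param subgroup_sizes named integer vector of tumors per subgroup.
#' @param burden_mean named numeric vector, Poisson mean somatic burden per
#'   subgroup (counts are capped at `burden_max`).
#' @param burden_max hard cap on per-tumor somatic burden.
#' @param n_genes,codons_per_gene,exons_per_gene,intron_length,intergenic
#'   exome geometry of the synthetic reference.
#' @param flank intronic flank (bp) around each exon included in the capture
#'   footprint (also where splice-region variants can fall).
#' @param depth_tumor,depth_normal,depth_strain,depth_ancestor mean
#'   sequencing depths (reads/site). Ancestor depth is amplicon-scale.
#' @param lowcov_fraction,lowcov_factor fraction of capture sites with poor
#'   efficiency and the factor applied to their mean depth (a site property
#'   shared by all samples, as capture efficiency is locus-specific).
#' @param base_error per-read substitution error rate. The default models
#'   quality-filtered, consensus-grade pileup evidence (Q40-equivalent
#'   residual miscall rate) with calibrated qualities: miscalled bases
#'   carry low base qualities (mean ~8), so most fail the caller's broad
#'   quality gate. This is the operating regime the strain weak-evidence
#'   filter presupposes: it admits a single alt read of any broad quality
#'   across all 18 strains (~hundreds of panel reads per locus), so its
#'   false-removal rate on true somatic variants is roughly
#'   `panel_reads * base_error / 3 * P(pass | error)` and raw-base error
#'   rates (~1e-3) would put the generator in the over-filtering regime by
#'   construction.
#' @param n_founder founder germline variants shared by every strain, line
#'   and ancestor.
#' @param n_strain_private germline variants private to each panel strain.
#' @param n_line_private germline variants private to each tumor ancestral
#'   line (the colony background the tumors inherit).
#' @param panel_representation probability that a line-private variant is
#'   also carried by some panel strain (shared ancestry), hence removable
#'   by the strain filter; the remainder are only catchable by databases or
#'   ancestor validation.
#' @param db_coverage fraction of all germline variants present in the SNP
#'   database files.
#' @param germline_vaf heterozygous allele fraction in tumors/ancestors
#'   (panel strains are inbred and homozygous, VAF 1).
#' @param somatic_vaf_min,somatic_vaf_max somatic VAF range (uniform draw).
#' @param somatic_indel_fraction fraction of somatic events simulated as
#'   small (1-3 bp) insertions/deletions.
#' @param max_retries maximum position re-draws when a somatic position
#'   collides with a germline variant.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_strains = 18L,
                       subgroup_sizes = c(WNT = 4L, SHH = 4L, G3 = 4L),
                       burden_mean = c(WNT = 10, SHH = 2, G3 = 4),
                       burden_max = 31L,
                       n_genes = 6L,
                       codons_per_gene = 150L,
                       exons_per_gene = 3L,
                       intron_length = 120L,
                       intergenic = 300L,
                       flank = 12L,
                       depth_tumor = 60,
                       depth_normal = 40,
                       depth_strain = 30,
                       depth_ancestor = 200,
                       lowcov_fraction = 0.02,
                       lowcov_factor = 0.2,
                       base_error = 1e-4,
                       n_founder = 30L,
                       n_strain_private = 15L,
                       n_line_private = 15L,
                       panel_representation = 0.7,
                       db_coverage = 0.8,
                       germline_vaf = 0.5,
                       somatic_vaf_min = 0.10,
                       somatic_vaf_max = 0.90,
                       somatic_indel_fraction = 0.05,
                       max_retries = 100L) {
  cfg <- as.list(environment())
  rates <- c(lowcov_fraction = lowcov_fraction, lowcov_factor = lowcov_factor,
             base_error = base_error, panel_representation = panel_representation,
             db_coverage = db_coverage, germline_vaf = germline_vaf,
             somatic_vaf_min = somatic_vaf_min, somatic_vaf_max = somatic_vaf_max,
             somatic_indel_fraction = somatic_indel_fraction)
  if (any(rates < 0 | rates > 1)) {
    stop("sim_config: rate parameters must lie in [0, 1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  }
  if (somatic_vaf_min > somatic_vaf_max)
    stop("sim_config: somatic_vaf_min must not exceed somatic_vaf_max")
  counts <- c(n_strains, n_genes, codons_per_gene, exons_per_gene,
              n_founder, n_strain_private, n_line_private, burden_max)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("sim_config: count parameters must be non-negative integers")
  if (length(seed) != 1L || is.na(seed))
    stop("sim_config: seed must be a single integer")
  if (is.null(names(subgroup_sizes)) ||
      !all(names(subgroup_sizes) %in% names(burden_mean)))
    stop("sim_config: burden_mean must name every subgroup in subgroup_sizes")
  cfg$seed <- as.integer(seed)
  cfg$n_tumors <- sum(subgroup_sizes)
  class(cfg) <- "sim_config"
  cfg
}

derived_seed <- function(cfg, k) (as.numeric(cfg$seed) * 1009 + 97 * k) %% 2147483647

#' Generate the synthetic reference bundle
#'
#' Builds a small exome: `n_genes` genes with in-frame CDS (ATG start, TAA
#' stop, no internal stops), `exons_per_gene` exons each, alternating
#' strands, spread over two contigs with random intergenic/intronic
#' sequence. Coordinates are 1-based closed throughout.
#'
#' @param cfg a [sim_config()].
#' @return object of class `ref_bundle`: `contigs` (named character vector
#'   of sequences) and `transcripts` (data.table: gene, tx_id, contig,
#'   strand, exon_starts, exon_ends (comma-joined), cds_start, cds_end).
#' @export
generate_reference <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop("generate_reference: cfg must be a sim_config")
  with_seed(derived_seed(cfg, 1L), {
    n_contigs <- 2L
    contig_names <- paste0("chr", seq_len(n_contigs))
    seqs <- setNames(vector("list", n_contigs), contig_names)
    for (nm in contig_names) seqs[[nm]] <- character(0)
    cursor <- setNames(rep(0L, n_contigs), contig_names)
    rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                  collapse = "")
    tx <- vector("list", cfg$n_genes)
    for (i in seq_len(max(cfg$n_genes, 0L))) {
      ctg <- contig_names[((i - 1L) %% n_contigs) + 1L]
      strand <- if (i %% 2L == 1L) "+" else "-"
      cds <- paste0("ATG",
                    paste(sample(SENSE_CODONS, cfg$codons_per_gene - 2L,
                                 replace = TRUE), collapse = ""),
                    "TAA")
      cds_len <- nchar(cds)
      k <- cfg$exons_per_gene
      base_len <- cds_len %/% k
      exon_len <- rep(base_len, k)
      exon_len[k] <- exon_len[k] + cds_len %% k
      chunks <- character(k)
      off <- 0L
      for (j in seq_len(k)) {
        chunks[j] <- substr(cds, off + 1L, off + exon_len[j])
        off <- off + exon_len[j]
      }
      # genomic exon order left-to-right; minus-strand genes store the
      # reverse complement with exon order reversed
      gchunks <- if (strand == "+") chunks else rev(vapply(chunks, reverse_complement, ""))
      glens <- nchar(gchunks)
      # intergenic spacer, then exon/intron layout
      seqs[[ctg]] <- c(seqs[[ctg]], rand_seq(cfg$intergenic))
      cursor[ctg] <- cursor[ctg] + cfg$intergenic
      starts <- integer(k); ends <- integer(k)
      for (j in seq_len(k)) {
        starts[j] <- cursor[ctg] + 1L
        ends[j] <- cursor[ctg] + glens[j]
        seqs[[ctg]] <- c(seqs[[ctg]], gchunks[j])
        cursor[ctg] <- ends[j]
        if (j < k) {
          seqs[[ctg]] <- c(seqs[[ctg]], rand_seq(cfg$intron_length))
          cursor[ctg] <- cursor[ctg] + cfg$intron_length
        }
      }
      tx[[i]] <- data.table(
        gene = sprintf("Gene%d", i), tx_id = sprintf("TX%03d", i),
        contig = ctg, strand = strand,
        exon_starts = paste(starts, collapse = ","),
        exon_ends = paste(ends, collapse = ","),
        cds_start = starts[1L], cds_end = ends[k])
    }
    for (ctg in contig_names) {
      seqs[[ctg]] <- c(seqs[[ctg]], rand_seq(cfg$intergenic))
    }
    transcripts <- if (cfg$n_genes > 0L) rbindlist(tx) else
      data.table(gene = character(), tx_id = character(), contig = character(),
                 strand = character(), exon_starts = character(),
                 exon_ends = character(), cds_start = integer(),
                 cds_end = integer())
    structure(list(contigs = vapply(seqs, paste, "", collapse = ""),
                   transcripts = transcripts),
              class = "ref_bundle")
  })
}

#' Assemble a reference bundle from contig sequences and transcript models
#'
#' @param contigs named character vector of contig sequences (A/C/G/T).
#' @param transcripts transcript model table (see [generate_reference()]).
#' @return object of class `ref_bundle`.
#' @export
ref_bundle <- function(contigs, transcripts) {
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    stop("ref_bundle: contigs must be named")
  if (!all(grepl("^[ACGT]*$", contigs)))
    stop("ref_bundle: contig sequences may contain only A/C/G/T")
  structure(list(contigs = contigs,
                 transcripts = as.data.table(transcripts)),
            class = "ref_bundle")
}

#' Exon intervals of one transcript row
#' @param tx_row single row of a transcripts table.
#' @return data.table(start, end), genomic order.
#' @export
exon_table <- function(tx_row) {
  data.table(start = as.integer(strsplit(tx_row$exon_starts, ",")[[1]]),
             end = as.integer(strsplit(tx_row$exon_ends, ",")[[1]]))
}

contig_base <- function(ref, contig, pos) {
  substring(ref$contigs[[contig]], pos, pos)
}

# capture footprint: exonic positions +/- flank
footprint_sites <- function(ref, cfg) {
  if (!nrow(ref$transcripts)) return(data.table(contig = character(), pos = integer()))
  rows <- lapply(seq_len(nrow(ref$transcripts)), function(i) {
    tr <- ref$transcripts[i]
    ex <- exon_table(tr)
    len <- nchar(ref$contigs[[tr$contig]])
    pos <- unlist(lapply(seq_len(nrow(ex)), function(j) {
      seq(max(1L, ex$start[j] - cfg$flank), min(len, ex$end[j] + cfg$flank))
    }))
    data.table(contig = tr$contig, pos = pos)
  })
  st <- unique(rbindlist(rows))
  setorder(st, contig, pos)
  st
}

#' Generate cohort ground truth
#'
#' Draws the germline structure (founder variants shared by all strains,
#' strain-private variants, ancestral-line variants partially represented in
#' the panel), the SNP-database subset, per-tumor somatic variants with
#' target VAFs, and the ancestor controls. Somatic positions are re-drawn on
#' collision with germline positions (up to `max_retries`; retries are
#' recorded in `$retries`).
#'
#' @param ref a [generate_reference()] bundle.
#' @param cfg the same [sim_config()].
#' @return object of class `cohort_truth`.
#' @export
generate_cohort_truth <- function(ref, cfg) {
  if (!inherits(ref, "ref_bundle")) stop("generate_cohort_truth: ref must be a ref_bundle")
  with_seed(derived_seed(cfg, 2L), {
    sites <- footprint_sites(ref, cfg)
    if (!nrow(sites)) stop("generate_cohort_truth: reference has no capture footprint")
    sites[, ref := mapply(contig_base, contig, pos, MoreArgs = list(ref = ref))]
    sites[, site_factor := ifelse(runif(.N) < cfg$lowcov_fraction,
                                  cfg$lowcov_factor, 1)]

    subgroups <- rep(names(cfg$subgroup_sizes), cfg$subgroup_sizes)
    prefix <- c(WNT = "MBW", SHH = "MBS", G3 = "MBM")
    tumor_ids <- unlist(lapply(names(cfg$subgroup_sizes), function(sg) {
      sprintf("%s%02d", if (sg %in% names(prefix)) prefix[[sg]] else sg,
              seq_len(cfg$subgroup_sizes[[sg]]))
    }))
    lines <- paste0("L_", names(cfg$subgroup_sizes))
    tumor_line <- setNames(paste0("L_", subgroups), tumor_ids)

    other_base <- function(b) vapply(b, function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1L), "")

    n_lines <- length(lines)
    n_germ <- cfg$n_founder + cfg$n_strains * cfg$n_strain_private +
      n_lines * cfg$n_line_private
    if (n_germ > nrow(sites))
      stop("generate_cohort_truth: footprint too small for requested germline variants")
    gidx <- sample(nrow(sites), n_germ)
    gv <- sites[gidx, .(contig, pos, ref)]
    gv[, alt := other_base(ref)]
    gv[, type := "SNV"]
    origin <- c(rep("founder", cfg$n_founder),
                rep("strain_private", cfg$n_strains * cfg$n_strain_private),
                rep("line_private", n_lines * cfg$n_line_private))
    owner <- c(rep("all", cfg$n_founder),
               rep(sprintf("strain%02d", seq_len(cfg$n_strains)),
                   each = cfg$n_strain_private),
               rep(lines, each = cfg$n_line_private))
    gv[, `:=`(origin = origin, owner = owner)]
    # shared-ancestry: some line variants also sit in a random panel strain
    gv[, panel_carrier := NA_character_]
    is_line <- gv$origin == "line_private"
    carried <- is_line & runif(nrow(gv)) < cfg$panel_representation
    gv$panel_carrier[carried] <- sprintf("strain%02d",
                                         sample(cfg$n_strains, sum(carried),
                                                replace = TRUE))
    gv[, in_db := runif(.N) < cfg$db_coverage]
    gv[, db := ifelse(in_db, sample(c("snpdb_common", "snpdb_strains"),
                                    .N, replace = TRUE), NA_character_)]
    gv[, id := sprintf("g%04d", seq_len(.N))]

    strain_ids <- sprintf("strain%02d", seq_len(cfg$n_strains))
    strains <- setNames(lapply(strain_ids, function(s) {
      hap <- gv[origin == "founder" | (origin == "strain_private" & owner == s) |
                  (!is.na(panel_carrier) & panel_carrier == s)]
      hap[, .(contig, pos, ref, alt, type, vaf = 1.0)]
    }), strain_ids)

    line_germ <- setNames(lapply(lines, function(l) {
      gv[origin == "founder" | (origin == "line_private" & owner == l),
         .(contig, pos, ref, alt, type, vaf = cfg$germline_vaf)]
    }), lines)

    germ_pos <- paste(gv$contig, gv$pos)
    contig_len <- nchar(ref$contigs)
    retries <- 0L
    tumors <- setNames(vector("list", length(tumor_ids)), tumor_ids)
    som_list <- list()
    for (ti in seq_along(tumor_ids)) {
      tid <- tumor_ids[ti]
      sg <- subgroups[ti]
      burden <- min(rpois(1L, cfg$burden_mean[[sg]]), cfg$burden_max)
      som <- list()
      used <- character(0)
      for (m in seq_len(burden)) {
        ok <- FALSE
        for (try in seq_len(cfg$max_retries)) {
          i <- sample(nrow(sites), 1L)
          ctg <- sites$contig[i]; p <- sites$pos[i]
          is_indel <- runif(1) < cfg$somatic_indel_fraction
          if (is_indel) {
            len <- sample(1:3, 1L)
            if (runif(1) < 0.5 && p + len <= contig_len[[ctg]]) {   # deletion
              refa <- substring(ref$contigs[[ctg]], p, p + len)
              alta <- substring(ref$contigs[[ctg]], p, p)
            } else {                                               # insertion
              refa <- substring(ref$contigs[[ctg]], p, p)
              alta <- paste0(refa, paste(sample(c("A", "C", "G", "T"), len,
                                                replace = TRUE), collapse = ""))
            }
            la <- left_align_variant(ref$contigs[[ctg]], p, refa, alta)
            p <- la$pos; refa <- la$ref; alta <- la$alt
          } else {
            refa <- sites$ref[i]
            alta <- other_base(refa)
          }
          key <- paste(ctg, p)
          span <- paste(ctg, seq(p, p + nchar(refa) - 1L))
          if (!any(span %in% germ_pos) && !any(span %in% used)) {
            som[[length(som) + 1L]] <- data.table(
              contig = ctg, pos = p, ref = refa, alt = alta,
              type = variant_type(refa, alta),
              vaf = runif(1, cfg$somatic_vaf_min, cfg$somatic_vaf_max))
            used <- c(used, span)
            ok <- TRUE
            break
          }
          retries <- retries + 1L
        }
        if (!ok) stop("generate_cohort_truth: could not place somatic variant after max_retries")
      }
      som_dt <- if (length(som)) rbindlist(som) else
        data.table(contig = character(), pos = integer(), ref = character(),
                   alt = character(), type = character(), vaf = numeric())
      tumors[[tid]] <- list(subgroup = sg, line = tumor_line[[tid]],
                            germline = line_germ[[tumor_line[[tid]]]],
                            somatic = som_dt)
      if (nrow(som_dt)) som_list[[tid]] <- copy(som_dt)[, sample_id := tid]
    }
    somatic_all <- if (length(som_list)) rbindlist(som_list) else
      data.table(contig = character(), pos = integer(), ref = character(),
                 alt = character(), type = character(), vaf = numeric(),
                 sample_id = character())

    ancestor_line <- c(ancestor1 = lines[1L],
                       ancestor2 = lines[min(2L, n_lines)],
                       ancestor3 = lines[min(3L, n_lines)],
                       ancestor4 = lines[n_lines])
    ancestors <- setNames(lapply(ancestor_line, function(l) line_germ[[l]]),
                          names(ancestor_line))

    dbs <- lapply(split(gv[in_db == TRUE, .(contig, pos, alt)],
                        gv[in_db == TRUE]$db), unique)

    structure(list(
      sites = sites, germline = gv, strains = strains, lines = line_germ,
      tumors = tumors, somatic = somatic_all, ancestors = ancestors,
      ancestor_line = ancestor_line,
      subgroups = setNames(subgroups, tumor_ids),
      db = dbs, retries = retries, normal_strain = "strain01"),
      class = "cohort_truth")
  })
}

#' Sample roster for a cohort
#'
#' @param truth a [generate_cohort_truth()] object.
#' @param cfg the [sim_config()].
#' @return data.table(sample, role, depth) covering tumors, the reference
#'   normal (the strain-01 haplotype, standing for public C57BL/6 data),
#'   panel strains and ancestor controls.
#' @export
cohort_roster <- function(truth, cfg) {
  rbindlist(list(
    data.table(sample = names(truth$tumors), role = "tumor",
               depth = cfg$depth_tumor),
    data.table(sample = "normalC57", role = "normal", depth = cfg$depth_normal),
    data.table(sample = names(truth$strains), role = "strain",
               depth = cfg$depth_strain),
    data.table(sample = names(truth$ancestors), role = "ancestor",
               depth = cfg$depth_ancestor)))
}

sample_variants <- function(truth, sample) {
  if (sample %in% names(truth$tumors)) {
    t <- truth$tumors[[sample]]
    rbindlist(list(t$germline, t$somatic), use.names = TRUE)
  } else if (sample == "normalC57") {
    truth$strains[[truth$normal_strain]]
  } else if (sample %in% names(truth$strains)) {
    truth$strains[[sample]]
  } else if (sample %in% names(truth$ancestors)) {
    truth$ancestors[[sample]]
  } else stop("sample_variants: unknown sample ", sample)
}

#' Render per-read pileup observations
#'
#' Emits one row per read observation with the caller-facing evidence
#' columns. Per-site depth is Poisson around the sample's mean scaled by the
#' shared site capture factor; at a variant site the expected alt fraction
#' equals the truth VAF; substitution errors are injected at `base_error`
#' with low base qualities; flanking quality models the minimum base quality
#' in a short window around the call (never above the base quality itself).
#'
#' @param truth,ref,cfg cohort truth, reference bundle, configuration.
#' @param samples character vector of sample ids (default: full roster).
#' @param sites optional data.table(contig, pos) restriction (e.g. amplicon
#'   panels rendered only at tested loci).
#' @return data.table(sample, contig, pos, ref, allele, baseQ, mapQ, flankQ,
#'   mismatches, hqMismatches, readId). Indel-supporting reads carry allele
#'   tokens `+SEQ` (insertion) / `-SEQ` (deletion) at the anchor position.
#' @export
render_pileups <- function(truth, ref, cfg, samples = NULL, sites = NULL) {
  roster <- cohort_roster(truth, cfg)
  if (is.null(samples)) samples <- roster$sample
  missing <- setdiff(samples, roster$sample)
  if (length(missing)) stop("render_pileups: unknown samples: ",
                            paste(missing, collapse = ", "))
  site_tab <- truth$sites
  if (!is.null(sites)) {
    site_tab <- site_tab[sites[, .(contig, pos)], on = c("contig", "pos"),
                         nomatch = NULL]
  }
  render_sample <- function(s, mean_depth) {
      depth <- rpois(nrow(site_tab), mean_depth * site_tab$site_factor)
      keep <- depth > 0L
      if (!any(keep)) return(NULL)
      st <- site_tab[keep]
      d <- depth[keep]
      n <- sum(d)
      reads <- data.table(
        sample = s,
        contig = rep(st$contig, d),
        pos = rep(st$pos, d),
        ref = rep(st$ref, d))
      vars <- sample_variants(truth, s)
      reads[, allele := ref]
      if (nrow(vars)) {
        vkey <- vars[, .(contig, pos, v_ref = ref, v_alt = alt,
                         v_type = type, v_vaf = vaf)]
        reads[vkey, on = c("contig", "pos"),
              `:=`(v_alt = i.v_alt, v_ref = i.v_ref, v_type = i.v_type,
                   v_vaf = i.v_vaf)]
        u <- runif(n)
        hit <- !is.na(reads$v_vaf) & u < reads$v_vaf
        tok <- reads$v_alt
        ins <- hit & reads$v_type == "INS"
        del <- hit & reads$v_type == "DEL"
        snv <- hit & reads$v_type == "SNV"
        reads$allele[snv] <- reads$v_alt[snv]
        reads$allele[ins] <- paste0("+", substring(reads$v_alt[ins], 2L))
        reads$allele[del] <- paste0("-", substring(reads$v_ref[del], 2L))
        reads[, c("v_alt", "v_ref", "v_type", "v_vaf") := NULL]
        is_var <- hit
      } else is_var <- rep(FALSE, n)
      err <- !is_var & runif(n) < cfg$base_error
      if (any(err)) {
        bases <- c("A", "C", "G", "T")
        cur <- reads$allele[err]
        reads$allele[err] <- vapply(cur, function(b)
          sample(setdiff(bases, b), 1L), "")
      }
      bq <- pmin(41L, pmax(2L, as.integer(round(rnorm(n, 32, 4)))))
      bq[err] <- pmin(41L, pmax(2L, as.integer(round(rnorm(sum(err), 8, 4)))))
      reads[, baseQ := bq]
      reads[, mapQ := sample(c(60L, 30L, 0L), n, replace = TRUE,
                             prob = c(0.97, 0.02, 0.01))]
      reads[, flankQ := pmax(2L, baseQ - rpois(n, 2))]
      mm <- rpois(n, 1.2) + as.integer(err | is_var)
      reads[, mismatches := mm]
      reads[, hqMismatches := rbinom(n, mm, 0.5)]
      reads[, readId := paste0(s, ".", seq_len(n))]
      reads
  }
  out <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    s <- samples[si]
    ridx <- match(s, roster$sample)
    out[[si]] <- with_seed(derived_seed(cfg, 1000L + ridx),
                           render_sample(s, roster$depth[ridx]))
  }
  res <- rbindlist(out[!vapply(out, is.null, TRUE)])
  res[]
}

#' Write the truth VCF
#'
#' VCF 4.2, 1-based, indels left-aligned and anchored; INFO carries a
#' SOMATIC or GERMLINE flag, the simulator origin class, and for somatic
#' records the carrying tumor and target VAF.
#'
#' @param truth cohort truth.
#' @param path output path.
#' @param ref optional reference bundle for `##contig` headers.
#' @export
write_truth_vcf <- function(truth, path, ref = NULL) {
  g <- unique(truth$germline[, .(contig, pos, ref, alt, origin)])
  grec <- if (nrow(g)) data.table(
    contig = g$contig, pos = g$pos,
    id = sprintf("g:%s:%d:%s>%s", g$contig, g$pos, g$ref, g$alt),
    ref = g$ref, alt = g$alt,
    info = paste0("GERMLINE;ORIGIN=", g$origin)) else NULL
  s <- truth$somatic
  srec <- if (nrow(s)) data.table(
    contig = s$contig, pos = s$pos,
    id = sprintf("s:%s:%s:%d:%s>%s", s$sample_id, s$contig, s$pos, s$ref, s$alt),
    ref = s$ref, alt = s$alt,
    info = sprintf("SOMATIC;ORIGIN=somatic;SAMPLE=%s;VAF=%.4f",
                   s$sample_id, s$vaf)) else NULL
  recs <- rbindlist(list(grec, srec))
  if (nrow(recs)) setorder(recs, contig, pos, alt)
  cl <- if (!is.null(ref)) nchar(ref$contigs) else NULL
  write_simple_vcf(recs, path, contig_lengths = cl)
}

#' @rdname io_helpers
#' @name io_helpers
#' @title Plain-text I/O for the pipeline's external formats
#' @description FASTA via Biostrings; refFlat-style transcript TSV, pileup
#'   TSV and SNP-database site lists via data.table. Pileup and database
#'   files use 1-based closed coordinates, matching the VCF convention used
#'   everywhere else.
#' @param ref,tx,dt object to write.
#' @param path file path.
#' @param name database name recorded on read.
NULL

#' @rdname io_helpers
#' @export
write_reference_fasta <- function(ref, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$contigs), path)
  invisible(path)
}

#' @rdname io_helpers
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname io_helpers
#' @export
write_transcripts <- function(tx, path) {
  fwrite(tx, path, sep = "\t")
  invisible(path)
}

#' @rdname io_helpers
#' @export
read_transcripts <- function(path) {
  fread(path, sep = "\t", colClasses = list(
    character = c("gene", "tx_id", "contig", "strand",
                  "exon_starts", "exon_ends")))
}

#' @rdname io_helpers
#' @export
write_pileup <- function(dt, path) {
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname io_helpers
#' @export
read_pileup <- function(path) {
  fread(path, sep = "\t",
        colClasses = list(character = c("sample", "contig", "ref",
                                        "allele", "readId")))
}

#' @rdname io_helpers
#' @export
write_snp_db <- function(dt, path) {
  fwrite(dt[, .(contig, pos, alt)], path, sep = "\t")
  invisible(path)
}

#' @rdname io_helpers
#' @export
read_snp_db <- function(path, name = basename(path)) {
  dt <- unique(fread(path, sep = "\t",
                     colClasses = list(character = c("contig", "alt"))))
  snp_db(name, dt)
}
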