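test_that("reference geometry: CDS lengths, strand layout, degenerate gene count", {
  cfg <- sim_config(seed = 1, n_genes = 5L, codons_per_gene = 300L)
  ref <- generate_reference(cfg)
  expect_length(ref$contigs, 2L)
  expect_equal(nrow(ref$transcripts), 5L)
  for (i in seq_len(5L)) {
    tr <- ref$transcripts[i]
    ex <- exon_table(tr)
    expect_true(all(diff(ex$start) > 0))
    expect_true(all(ex$end >= ex$start))
    expect_true(all(ex$start[-1] > ex$end[-nrow(ex)]))  # non-overlapping
    cds_len <- sum(ex$end - ex$start + 1L)
    expect_equal(cds_len, 900L)
    expect_equal(cds_len %% 3L, 0L)
    expect_true(tr$cds_start >= ex$start[1] && tr$cds_end <= ex$end[nrow(ex)])
    expect_true(tr$cds_end <= nchar(ref$contigs[[tr$contig]]))
  }
  # sequences contain only ACGT
  expect_true(all(grepl("^[ACGT]+$", ref$contigs)))
  # both strands represented
  expect_setequal(unique(ref$transcripts$strand), c("+", "-"))

  empty <- generate_reference(sim_config(seed = 1, n_genes = 0L))
  expect_equal(nrow(empty$transcripts), 0L)
  expect_true(all(nchar(empty$contigs) > 0L))
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- small_sim_config(seed = 9)
  r1 <- generate_reference(cfg); r2 <- generate_reference(cfg)
  expect_identical(r1, r2)
  t1 <- generate_cohort_truth(r1, cfg); t2 <- generate_cohort_truth(r2, cfg)
  expect_identical(t1$germline, t2$germline)
  expect_identical(t1$somatic, t2$somatic)
  p1 <- render_pileups(t1, r1, cfg, c("MBW01", "strain01"))
  p2 <- render_pileups(t2, r2, cfg, c("MBW01", "strain01"))
  expect_identical(p1, p2)
  # and a different seed changes the output
  cfg3 <- small_sim_config(seed = 10)
  expect_false(identical(generate_reference(cfg3)$contigs, r1$contigs))
})

test_that("cohort truth honors the sharing model, db coverage and burden cap", {
  cfg <- small_sim_config(seed = 7)
  ref <- generate_reference(cfg)
  truth <- generate_cohort_truth(ref, cfg)

  # somatic disjoint from germline, burdens within [0, burden_max]
  gkey <- paste(truth$germline$contig, truth$germline$pos)
  skey <- paste(truth$somatic$contig, truth$somatic$pos)
  expect_length(intersect(gkey, skey), 0L)
  burdens <- vapply(truth$tumors, function(t) nrow(t$somatic), 1L)
  expect_true(all(burdens >= 0L & burdens <= cfg$burden_max))
  expect_true(all(truth$somatic$vaf > 0 & truth$somatic$vaf <= 1))
  expect_true(all(truth$somatic$vaf >= cfg$somatic_vaf_min))

  # founder variants are present in every strain haplotype
  founders <- truth$germline[origin == "founder"]
  fkey <- paste(founders$contig, founders$pos, founders$alt)
  for (s in names(truth$strains)) {
    hkey <- paste(truth$strains[[s]]$contig, truth$strains[[s]]$pos,
                  truth$strains[[s]]$alt)
    expect_true(all(fkey %in% hkey))
  }

  # every tumor germline variant is carried by at least one ancestor
  anc_key <- unique(unlist(lapply(truth$ancestors, function(a)
    paste(a$contig, a$pos, a$alt))))
  for (tid in names(truth$tumors)) {
    tg <- truth$tumors[[tid]]$germline
    expect_true(all(paste(tg$contig, tg$pos, tg$alt) %in% anc_key))
  }

  # conservation: emitted germline variant count matches the request
  n_lines <- length(unique(truth$ancestor_line))
  expect_equal(nrow(truth$germline),
               cfg$n_founder + cfg$n_strains * cfg$n_strain_private +
                 n_lines * cfg$n_line_private)
  expect_true(truth$retries >= 0L)

  # db coverage endpoints force membership
  t_all <- generate_cohort_truth(ref, small_sim_config(seed = 7, db_coverage = 1))
  expect_true(all(t_all$germline$in_db))
  t_none <- generate_cohort_truth(ref, small_sim_config(seed = 7, db_coverage = 0))
  expect_false(any(t_none$germline$in_db))
  expect_length(t_none$db, 0L)
})

test_that("pileups concentrate at the truth VAF and respect depth/error settings", {
  cfg <- small_sim_config(seed = 3, depth_tumor = 1000)
  ref <- generate_reference(cfg)
  truth <- generate_cohort_truth(ref, cfg)
  # force one somatic variant to VAF 0.5 and inspect its site
  tid <- names(truth$tumors)[1]
  expect_gt(nrow(truth$tumors[[tid]]$somatic), 0L)
  truth$tumors[[tid]]$somatic[1, vaf := 0.5]
  v <- truth$tumors[[tid]]$somatic[1]
  pu <- render_pileups(truth, ref, cfg, tid)
  site <- pu[contig == v$contig & pos == v$pos]
  tok <- if (v$type == "SNV") v$alt else if (v$type == "INS")
    paste0("+", substring(v$alt, 2)) else paste0("-", substring(v$ref, 2))
  expect_gt(nrow(site), 700)
  expect_lt(abs(mean(site$allele == tok) - 0.5), 0.05)

  # error rate 0 and no variants: every read matches the reference allele
  cfg0 <- small_sim_config(seed = 4, base_error = 0, n_founder = 0L,
                           n_strain_private = 0L, n_line_private = 0L,
                           burden_mean = c(WNT = 0, SHH = 0, G3 = 0))
  ref0 <- generate_reference(cfg0)
  truth0 <- generate_cohort_truth(ref0, cfg0)
  pu0 <- render_pileups(truth0, ref0, cfg0, "MBW01")
  expect_true(all(pu0$allele == pu0$ref))

  # degenerate depth 0: no sites rendered at all
  cfgz <- small_sim_config(seed = 5, depth_tumor = 0)
  refz <- generate_reference(cfgz)
  truthz <- generate_cohort_truth(refz, cfgz)
  puz <- render_pileups(truthz, refz, cfgz, "MBW01")
  expect_equal(nrow(puz), 0L)
})

test_that("truth VCF round-trips and anchors indels on the preceding base", {
  cfg <- small_sim_config(seed = 21, somatic_indel_fraction = 0.5)
  ref <- generate_reference(cfg)
  truth <- generate_cohort_truth(ref, cfg)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_truth_vcf(truth, path, ref)
  back <- read_simple_vcf(path)

  som <- truth$somatic
  expect_equal(sum(vcf_somatic <- vcf_info_flag(back$info, "SOMATIC")),
               nrow(som))
  skey <- sort(paste(som$contig, som$pos, som$ref, som$alt))
  bkey <- sort(paste(back$contig[vcf_somatic], back$pos[vcf_somatic],
                     back$ref[vcf_somatic], back$alt[vcf_somatic]))
  expect_equal(bkey, skey)
  gl <- back[!vcf_somatic]
  gkey <- unique(paste(truth$germline$contig, truth$germline$pos,
                       truth$germline$ref, truth$germline$alt))
  expect_setequal(paste(gl$contig, gl$pos, gl$ref, gl$alt), gkey)

  # insertions: REF is the anchor base at POS
  ins <- back[nchar(back$alt) > nchar(back$ref), ]
  if (nrow(ins)) {
    for (i in seq_len(nrow(ins))) {
      expect_identical(ins$ref[i],
                       substr(ref$contigs[[ins$contig[i]]], ins$pos[i], ins$pos[i]))
      expect_identical(substr(ins$alt[i], 1L, 1L), ins$ref[i])
    }
  }

  # empty truth: header-only VCF
  empty_path <- withr::local_tempfile(fileext = ".vcf")
  truth_empty <- truth
  truth_empty$germline <- truth$germline[0]
  truth_empty$somatic <- truth$somatic[0]
  write_truth_vcf(truth_empty, empty_path)
  lines <- readLines(empty_path)
  expect_true(all(startsWith(lines, "#")))

  # external cross-check with an independent VCF parser
  skip_if_not_installed("vcfR")
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  expect_equal(nrow(v@fix), nrow(back))
  expect_equal(as.integer(v@fix[, "POS"]), back$pos)
})

test_that("pileup and refFlat TSVs round-trip through their readers", {
  cfg <- small_sim_config(seed = 2)
  ref <- generate_reference(cfg)
  truth <- generate_cohort_truth(ref, cfg)
  pu <- render_pileups(truth, ref, cfg, "MBW01")
  pp <- withr::local_tempfile(fileext = ".tsv")
  write_pileup(pu, pp)
  expect_equal(as.data.frame(read_pileup(pp)), as.data.frame(pu))
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_transcripts(ref$transcripts, tp)
  expect_equal(as.data.frame(read_transcripts(tp)),
               as.data.frame(ref$transcripts))
  fp <- withr::local_tempfile(fileext = ".fa")
  write_reference_fasta(ref, fp)
  expect_identical(read_reference_fasta(fp), ref$contigs)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(db_coverage = 1.5), "rate")
  expect_error(sim_config(base_error = -0.1), "rate")
  expect_error(sim_config(seed = NA), "seed")
  expect_error(sim_config(n_genes = -1), "count")
  expect_error(sim_config(somatic_vaf_min = 0.5, somatic_vaf_max = 0.2),
               "somatic_vaf_min")
  expect_error(generate_reference(list()), "sim_config")
})
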