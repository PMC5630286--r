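test_that("SNP database filtering matches on position AND allele", {
  db <- snp_db("dbSNP128", data.table::data.table(
    contig = "chr1", pos = 100L, alt = "G"))

  hit <- filter_known_snps(make_candidate(alt = "G"), list(db))
  expect_equal(hit$calls$status, "germline")
  expect_true(any(filter_trail(hit)$reason == "db:dbSNP128"))

  # same position, different alt allele: retained (tri-allelic safety)
  other <- filter_known_snps(make_candidate(alt = "T", id = "T1:chr1:100:A>T"),
                             list(db))
  expect_equal(other$calls$status, "somatic_putative")

  # empty database list: unchanged
  none <- filter_known_snps(make_candidate(alt = "G"), list())
  expect_equal(none$calls$status, "somatic_putative")

  # already-terminal candidates are left alone (idempotence/stage order)
  done <- filter_known_snps(make_candidate(alt = "G", status = "rejected"),
                            list(db))
  expect_equal(done$calls$status, "rejected")

  # indels match on their normalized identity
  dbi <- snp_db("indeldb", data.table::data.table(
    contig = "chr1", pos = 100L, alt = "ACG"))
  ins <- filter_known_snps(make_candidate(alt = "ACG",
                                          id = "T1:chr1:100:A>ACG"),
                           list(dbi))
  expect_equal(ins$calls$status, "germline")
})

test_that("strain panel weak evidence removes candidates; coverage gaps are flagged", {
  cfg <- caller_config()
  cand <- make_candidate()   # chr1:100 A>G

  # one alt read in one strain suffices at the default threshold
  panel <- make_site(c(rep("A", 20), "G"), sample = "C3H")
  g <- strain_evidence_filter(cand, panel, cfg)
  expect_equal(g$calls$status, "germline")
  expect_true(any(filter_trail(g)$reason == "strain:C3H"))

  # the evidence read must clear broad-min-quality
  weak <- make_site(c(rep("A", 20), "G"), sample = "C3H",
                    baseQ = c(rep(35L, 20), 5L))
  keep <- strain_evidence_filter(make_candidate(), weak, cfg)
  expect_equal(keep$calls$status, "somatic_putative")

  # zero panel coverage at the locus: retained and flagged
  empty_panel <- make_site(rep("A", 10), sample = "C3H", pos = 999L)
  flagged <- strain_evidence_filter(make_candidate(), empty_panel, cfg)
  expect_equal(flagged$calls$status, "somatic_putative")
  expect_true(any(filter_trail(flagged)$reason == "panel_uncovered"))

  # raising min_evidence_reads to 3 with only 2 alt reads: retained
  panel2 <- make_site(c(rep("A", 20), "G", "G"), sample = "C3H")
  kept <- strain_evidence_filter(make_candidate(), panel2, cfg,
                                 min_evidence_reads = 3L)
  expect_equal(kept$calls$status, "somatic_putative")
  expect_equal(strain_evidence_filter(make_candidate(), panel2, cfg,
                                      min_evidence_reads = 2L)$calls$status,
               "germline")
})

test_that("realignment review kills paralog and slippage artifacts, passes unique loci", {
  # contig: unique left half; variant region; then an EXACT duplicate of the
  # variant region carrying the alt base (the paralog)
  set.seed(5)
  uniq <- paste(sample(c("A", "C", "G", "T"), 160, TRUE), collapse = "")
  core <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  p_rel <- 30L
  core_alt <- core
  substr(core_alt, p_rel, p_rel) <- "T"
  stopifnot(substr(core, p_rel, p_rel) != "T")

  # unique locus: clean mismatch read passes review
  ref_u <- structure(list(contigs = c(c1 = paste0(uniq, core)),
                          transcripts = data.table::data.table()),
                     class = "ref_bundle")
  vpos <- nchar(uniq) + p_rel
  read <- substr(paste0(uniq, core_alt), vpos - 15L, vpos + 15L)
  cand <- make_candidate(id = "T1:c1:v:A>T", contig = "c1", pos = vpos,
                         ref = substr(core, p_rel, p_rel), alt = "T")
  cs <- realign_review_snv(cand, "T1:c1:v:A>T",
                           data.frame(seq = read, start = vpos - 15L),
                           ref_u, window = 60L)
  expect_equal(cs$calls$status, "somatic_putative")
  expect_true(any(filter_trail(cs)$decision == "pass"))

  # paralog: a second exact copy carrying the alt explains every read
  ref_p <- structure(list(contigs = c(c1 = paste0(uniq, core, strrep("A", 30),
                                                  core_alt)),
                          transcripts = data.table::data.table()),
                     class = "ref_bundle")
  cs2 <- realign_review_snv(cand, "T1:c1:v:A>T",
                            data.frame(seq = c(read, read),
                                       start = c(vpos - 15L, vpos - 15L)),
                            ref_p, window = 25L)
  expect_equal(cs2$calls$status, "artifact")

  # homopolymer slippage: a one-base insertion shifts the tail, so the
  # ungapped placement pays several mismatches while one gap explains all
  left <- "ACGTACGTACGTGGTCCATG"
  right <- "CTAGCTAGCATGCATGCTTG"
  hp_ref <- paste0(left, "AAAAAA", right)
  ref_h <- structure(list(contigs = c(c1 = hp_ref),
                          transcripts = data.table::data.table()),
                     class = "ref_bundle")
  # read carries an extra A in the run: downstream bases shift by one
  read_h <- paste0(substr(left, 6L, 20L), "AAAAAAA", substr(right, 1L, 14L))
  hp_pos <- nchar(left) + 6L    # called "variant" at the run boundary
  cand_h <- make_candidate(id = "T1:c1:hp:C>A", contig = "c1", pos = hp_pos,
                           ref = substr(hp_ref, hp_pos, hp_pos), alt = "A")
  cs3 <- realign_review_snv(cand_h, "T1:c1:hp:C>A",
                            data.frame(seq = read_h, start = 6L),
                            ref_h, window = 40L)
  expect_equal(cs3$calls$status, "artifact")

  # no read sequences: review skipped with an unreviewed flag
  cs4 <- realign_review_snv(make_candidate(), "T1:chr1:100:A>G", NULL,
                            ref_u)
  expect_equal(cs4$calls$status, "somatic_putative")
  expect_true(any(filter_trail(cs4)$reason == "unreviewed"))
})

test_that("mutant templates apply the indel to the reference window", {
  set.seed(8)
  contig <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  ref <- structure(list(contigs = c(c1 = contig),
                        transcripts = data.table::data.table()),
                   class = "ref_bundle")
  pos <- 200L
  anchor <- substr(contig, pos, pos)

  # 3-bp deletion with a 50-bp window: template is 3 shorter
  del_ref <- substr(contig, pos, pos + 3L)
  t_del <- build_mutant_template(ref, "c1", pos, del_ref, anchor, window = 50L)
  expect_equal(nchar(t_del$wild), 50L)
  expect_equal(nchar(t_del$template), 47L)

  # insertion: template contains the anchor followed by the inserted bases
  t_ins <- build_mutant_template(ref, "c1", pos, anchor,
                                 paste0(anchor, "ACG"), window = 50L)
  expect_equal(nchar(t_ins$template), 53L)
  expect_identical(substr(t_ins$template, t_ins$indel_at - 1L,
                          t_ins$indel_at + 2L), paste0(anchor, "ACG"))

  # empty indel (ref == alt) reproduces the wild-type window
  t_id <- build_mutant_template(ref, "c1", pos, anchor, anchor, window = 50L)
  expect_identical(t_id$template, t_id$wild)

  # window outside the contig is an error
  expect_error(build_mutant_template(ref, "c1", 5L, anchor, anchor,
                                     window = 50L), "outside")
})

test_that("indel review scores reads against the mutant template", {
  cfg <- caller_config()
  set.seed(9)
  contig <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  ref <- structure(list(contigs = c(c1 = contig),
                        transcripts = data.table::data.table()),
                   class = "ref_bundle")
  pos <- 200L
  anchor <- substr(contig, pos, pos)
  del_ref <- substr(contig, pos, pos + 2L)   # 2-bp deletion
  cand <- make_candidate(id = "T1:c1:del", contig = "c1", pos = pos,
                         ref = del_ref, alt = anchor)
  # reads matching the deleted haplotype: anchor context minus the deletion
  mut_read <- paste0(substr(contig, pos - 18L, pos), substr(contig, pos + 3L,
                                                            pos + 20L))
  wt_read <- substr(contig, pos - 18L, pos + 20L)

  # tumor support with clean normal: retained
  cs <- indel_review(cand, "T1:c1:del", rep(mut_read, 5L),
                     rep(wt_read, 8L), ref, cfg)
  expect_equal(cs$calls$status, "somatic_putative")

  # one normal read covering the mutant allele: germline
  cs2 <- indel_review(make_candidate(id = "T1:c1:del", contig = "c1",
                                     pos = pos, ref = del_ref, alt = anchor),
                      "T1:c1:del", rep(mut_read, 5L),
                      c(rep(wt_read, 8L), mut_read), ref, cfg)
  expect_equal(cs2$calls$status, "germline")

  # reads too short to span the indel count for neither side
  stub <- substr(contig, pos - 18L, pos - 4L)
  cs3 <- indel_review(make_candidate(id = "T1:c1:del", contig = "c1",
                                     pos = pos, ref = del_ref, alt = anchor),
                      "T1:c1:del", rep(stub, 5L), character(0), ref, cfg)
  expect_equal(cs3$calls$status, "rejected")

  # no sequences: unreviewed flag
  cs4 <- indel_review(make_candidate(id = "T1:c1:del", contig = "c1",
                                     pos = pos, ref = del_ref, alt = anchor),
                      "T1:c1:del", NULL, NULL, ref, cfg)
  expect_true(any(filter_trail(cs4)$reason == "unreviewed"))
})

test_that("ancestor validation separates germline, somatic and uncovered calls", {
  cfg <- caller_config()
  tumor_amp <- make_site(c(rep("A", 60), rep("G", 40)), sample = "T1")

  # alt in one ancestor at VAF 0.5: germline
  anc_pos <- make_site(c(rep("A", 40), rep("G", 40)), sample = "anc1")
  g <- ancestor_validate(make_candidate(), anc_pos, tumor_amp, cfg)
  expect_equal(g$calls$status, "germline")
  expect_true(any(filter_trail(g)$reason == "ancestor:anc1"))

  # locus uncovered in every control: not_covered
  anc_off <- make_site(rep("A", 50), sample = "anc1", pos = 999L)
  nc <- ancestor_validate(make_candidate(), anc_off, tumor_amp, cfg)
  expect_equal(nc$calls$status, "not_covered")

  # negative controls + confirming tumor amplicon: validated
  anc_neg <- make_site(rep("A", 80), sample = "anc1")
  v <- ancestor_validate(make_candidate(), anc_neg, tumor_amp, cfg)
  expect_equal(v$calls$status, "validated_somatic")

  # sub-floor ancestor evidence (1 read) does not kill the call
  anc_low <- make_site(c(rep("A", 79), "G"), sample = "anc1")
  v2 <- ancestor_validate(make_candidate(), anc_low, tumor_amp, cfg)
  expect_equal(v2$calls$status, "validated_somatic")

  # tumor amplicon that cannot confirm: rejected
  tum_neg <- make_site(rep("A", 100), sample = "T1")
  r <- ancestor_validate(make_candidate(), anc_neg, tum_neg, cfg)
  expect_equal(r$calls$status, "rejected")
})

test_that("cascade stages are idempotent and only touch live candidates", {
  cfg <- caller_config()
  db <- snp_db("d1", data.table::data.table(contig = "chr1", pos = 100L,
                                            alt = "G"))
  cs <- filter_known_snps(make_candidate(), list(db))
  once <- cs$calls$status
  cs2 <- filter_known_snps(cs, list(db))
  expect_identical(cs2$calls$status, once)
  panel <- make_site(c(rep("A", 20), "G"), sample = "S1")
  cs3 <- strain_evidence_filter(cs2, panel, cfg)
  expect_identical(cs3$calls$status, once)   # already germline: untouched
  # trail is append-only
  expect_gte(nrow(filter_trail(cs3)), nrow(filter_trail(cs)))
})

test_that("manual curation lists deny survivors and can override removals", {
  cs <- make_candidate()
  denied <- manual_curation(cs, deny = cs$calls$id)
  expect_equal(denied$calls$status, "rejected")
  expect_true(any(filter_trail(denied)$reason == "manual_deny"))

  removed <- make_candidate(status = "germline")
  restored <- manual_curation(removed, allow = removed$calls$id)
  expect_equal(restored$calls$status, "somatic_putative")
  expect_true(any(filter_trail(restored)$reason == "manual_allow_override"))

  # empty lists are a no-op
  same <- manual_curation(make_candidate())
  expect_equal(same$calls$status, "somatic_putative")
})
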