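test_that("read gates enforce the caller's quality and mismatch thresholds", {
  cfg <- caller_config()
  # 10 clean ref + 3 clean alt reads count directly
  site <- make_site(c(rep("A", 10), rep("G", 3)))
  counts <- collect_allele_counts(site, cfg)
  expect_equal(counts[["A"]], 10L)
  expect_equal(counts[["G"]], 3L)

  # mapQ 0 is excluded (min-mapq 1)
  site$mapQ[11] <- 0L
  expect_equal(collect_allele_counts(site, cfg)[["G"]], 2L)

  # 21 total mismatches excluded (mmf-max-any-mismatches 20); 20 kept
  site <- make_site(c("A", "G"), mismatches = c(0L, 21L))
  expect_false("G" %in% names(collect_allele_counts(site, cfg)))
  site$mismatches[2] <- 20L
  expect_equal(collect_allele_counts(site, cfg)[["G"]], 1L)

  # 16 high-quality mismatches excluded (mmf-max-hq-mismatches 15)
  site <- make_site(c("A", "G"), mismatches = 16L, hqMismatches = c(0L, 16L))
  expect_false("G" %in% names(collect_allele_counts(site, cfg)))

  # flanking quality below 15 excluded; base quality below 10 excluded
  site <- make_site(c("G", "G"), flankQ = c(14L, 15L))
  expect_equal(collect_allele_counts(site, cfg)[["G"]], 1L)
  site <- make_site(c("G", "G"), baseQ = c(9L, 10L))
  expect_equal(collect_allele_counts(site, cfg)[["G"]], 1L)

  # empty site: zero counts
  expect_length(collect_allele_counts(make_site(character(0)), cfg), 0L)
})

test_that("candidate emission needs min alt count and distinct evidence", {
  cfg <- caller_config()
  normal <- make_site(rep("A", 30), sample = "N1")

  # a single alt read is below min-alt-allele-count 2
  cs1 <- detect_candidates(make_site(c(rep("A", 20), "G")), normal, cfg)
  expect_equal(nrow(cs1$calls), 0L)

  # exactly 2 clean alt reads at the threshold boundary are emitted
  cs2 <- detect_candidates(make_site(c(rep("A", 20), "G", "G")), normal, cfg)
  expect_equal(nrow(cs2$calls), 1L)
  expect_equal(cs2$calls$tumor_alt, 2L)
  expect_equal(cs2$calls$vaf, 2 / 22)

  # 2 alt observations from a single read identity fail unique evidence
  dup <- make_site(c(rep("A", 20), "G", "G"),
                   readId = c(paste0("r", 1:20), "rx", "rx"))
  cs3 <- detect_candidates(dup, normal, cfg)
  expect_equal(nrow(cs3$calls), 0L)

  # site absent in normal: {0,0} counts and low_normal_coverage flag
  cs4 <- detect_candidates(make_site(c(rep("A", 10), rep("G", 5))), NULL, cfg)
  expect_equal(cs4$calls$normal_ref + cs4$calls$normal_alt, 0L)
  tr <- filter_trail(cs4)
  expect_true(any(tr$reason == "low_normal_coverage"))

  # locus mismatch is a usage error
  expect_error(detect_candidates(make_site("G", pos = 100L),
                                 make_site("A", pos = 101L), cfg),
               "different loci")
})

test_that("one-sided Fisher P matches brute-force tail enumeration", {
  # spec worked examples
  expect_equal(fisher_one_sided(0L, 20L, 0L, 20L), 1.0)
  p <- fisher_one_sided(10L, 10L, 0L, 20L)
  expect_equal(p, fisher_tail_oracle(10, 10, 0, 20), tolerance = 1e-14)
  expect_gt(fisher_one_sided(2L, 18L, 2L, 18L), 0.5)
  expect_warning(p0 <- fisher_one_sided(0L, 0L, 0L, 0L), "all-zero")
  expect_equal(p0, 1)
  expect_error(fisher_one_sided(-1L, 1L, 1L, 1L), "non-negative")

  # random spot grid against the enumeration oracle
  set.seed(42)
  a <- sample(0:15, 200, TRUE); b <- sample(0:15, 200, TRUE)
  c_ <- sample(0:15, 200, TRUE); d <- sample(0:15, 200, TRUE)
  keep <- (a + b + c_ + d) > 0
  expect_equal(fisher_one_sided(a[keep], b[keep], c_[keep], d[keep]),
               fisher_tail_oracle_vec(a[keep], b[keep], c_[keep], d[keep]),
               tolerance = 1e-12)
})

test_that("Fisher P is monotone decreasing in the tumor alt count", {
  set.seed(7)
  for (i in 1:25) {
    t_ref <- sample(0:30, 1); n_alt <- sample(0:10, 1); n_ref <- sample(0:30, 1)
    ps <- fisher_one_sided(0:20, rep(t_ref, 21), rep(n_alt, 21), rep(n_ref, 21))
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("somatic criteria apply the VAF and P-value cuts as printed", {
  cfg <- caller_config()
  # VAF exactly 0.10 passes (inclusive) with a small P
  cs <- make_candidate(tumor_ref = 90L, tumor_alt = 10L, vaf = 0.10,
                       fisher_p = 0.01, status = "candidate")
  cs <- apply_somatic_criteria(cs, cfg)
  expect_equal(cs$calls$status, "somatic_putative")
  expect_equal(cs$calls$sig_tier, "HIGH")

  # P = 0.04 -> HIGH tier; P = 0.07 -> LOW tier; P = 0.20 -> rejected
  tiers <- vapply(c(0.04, 0.07, 0.20), function(p) {
    x <- apply_somatic_criteria(make_candidate(fisher_p = p,
                                               status = "candidate"), cfg)
    paste(x$calls$status, x$calls$sig_tier)
  }, "")
  expect_equal(tiers, c("somatic_putative HIGH", "somatic_putative LOW",
                        "rejected NONE"))

  # VAF below 0.10 is rejected regardless of P
  cs <- apply_somatic_criteria(
    make_candidate(tumor_ref = 95L, tumor_alt = 5L, vaf = 0.05,
                   fisher_p = 0.001, status = "candidate"), cfg)
  expect_equal(cs$calls$status, "rejected")
  expect_true(any(filter_trail(cs)$reason == "vaf_below_min"))
})

test_that("quality tier is the median alt base quality cut and is pure", {
  cfg <- caller_config()
  hi <- classify_quality(make_candidate(median_alt_baseq = 30,
                                        fisher_p = 0.01), cfg)
  expect_equal(hi$calls$quality_tier, "HIGH")
  lo <- classify_quality(make_candidate(median_alt_baseq = 12,
                                        fisher_p = 0.07), cfg)
  expect_equal(lo$calls$quality_tier, "LOW")
  # four-way class pairs quality and significance tiers
  x <- apply_somatic_criteria(make_candidate(median_alt_baseq = 30,
                                             fisher_p = 0.01,
                                             status = "candidate"), cfg)
  x <- classify_quality(x, cfg)
  expect_equal(four_way_class(x), "HIGH/HIGH")
  y <- apply_somatic_criteria(make_candidate(median_alt_baseq = 12,
                                             fisher_p = 0.07,
                                             status = "candidate"), cfg)
  y <- classify_quality(y, cfg)
  expect_equal(four_way_class(y), "LOW/LOW")
  # pure: identical inputs give identical classification
  expect_identical(classify_quality(x, cfg)$calls$quality_tier,
                   classify_quality(x, cfg)$calls$quality_tier)
})

test_that("candidate emission is invariant to read order within a site", {
  cfg <- caller_config()
  set.seed(11)
  site <- make_site(sample(c(rep("A", 25), rep("T", 6))),
                    baseQ = sample(20:40, 31, TRUE))
  normal <- make_site(rep("A", 35), sample = "N1")
  base <- detect_candidates(site, normal, cfg)
  for (k in 1:5) {
    perm <- site[sample(nrow(site))]
    again <- detect_candidates(perm, normal, cfg)
    expect_equal(again$calls$tumor_alt, base$calls$tumor_alt)
    expect_equal(again$calls$vaf, base$calls$vaf)
    expect_equal(again$calls$median_alt_baseq, base$calls$median_alt_baseq)
  }
})

test_that("vectorized cohort calling agrees with per-site detection", {
  cfg <- caller_config()
  scfg <- small_sim_config(seed = 13)
  ref <- generate_reference(scfg)
  truth <- generate_cohort_truth(ref, scfg)
  pu_t <- render_pileups(truth, ref, scfg, "MBW01")
  pu_n <- render_pileups(truth, ref, scfg, "normalC57")
  cs <- call_cohort(pu_t, pu_n, cfg, ref)
  expect_gt(nrow(cs$calls), 0L)
  # re-derive a handful of candidates through the single-site contract path
  picks <- head(seq_len(nrow(cs$calls)), 5L)
  for (i in picks) {
    row <- cs$calls[i]
    ts <- pu_t[contig == row$contig & pos == row$pos]
    ns <- pu_n[contig == row$contig & pos == row$pos]
    single <- detect_candidates(ts, ns, cfg, ref)
    j <- match(row$id, single$calls$id)
    expect_false(is.na(j))
    expect_equal(single$calls$tumor_alt[j], row$tumor_alt)
    expect_equal(single$calls$normal_alt[j], row$normal_alt)
    expect_equal(single$calls$vaf[j], row$vaf)
  }
  # every truth somatic variant observed at >= 0.15 filtered VAF and
  # >= 20 filtered depth is somatic-putative (per-seed recall 1)
  calls <- cs$calls
  sk <- paste(truth$somatic[sample_id == "MBW01"]$contig,
              truth$somatic[sample_id == "MBW01"]$pos)
  stratum <- calls[paste(contig, pos) %in% sk &
                     vaf >= 0.15 & (tumor_ref + tumor_alt) >= 20L]
  expect_true(all(stratum$status == "somatic_putative"))
})
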