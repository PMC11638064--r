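# Allele assignment, purity, the allele-swap control, isoform
# classification, demultiplexing and the methylation contrast.

test_that("allele assignment reads the base through the alignment", {
  # variant at 0-based 114 (1-based 115)
  aln <- tibble::tibble(
    qname = c("risk", "ends_before", "n_base", "skipped", "lowmapq"),
    flag = 0L, rname = "ctg",
    pos = c(110L, 105L, 110L, 110L, 110L),
    mapq = c(60L, 60L, 60L, 60L, 10L),
    cigar = c("10M", "10M", "10M", "4M4N6M", "10M"),
    seq = c("AAAAAGAAAA", "AAAAAAAAAA", "AAAAANAAAA", "AAAAAAAAAA", "AAAAAGAAAA"),
    qual = strrep("I", 10)
  )
  calls <- assign_allele(aln, variant_pos = 114L, risk = "G", nonrisk = "T")
  expect_false("lowmapq" %in% calls$read_id)  # retention profile drops MAPQ < 40
  got <- setNames(calls$allele, calls$read_id)
  expect_equal(got[["risk"]], "risk")
  expect_equal(got[["ends_before"]], "uncovered")
  expect_equal(got[["n_base"]], "other")
  expect_equal(got[["skipped"]], "other")  # base under the splice gap
})

test_that("haplotype purity is 1 at zero error and degrades with the error rate", {
  pair <- make_paper_pair()
  regions <- build_region_set(pair$model)
  run_purity <- function(err, seed) {
    spec <- cohort_spec(n_per_genotype = c(GG = 0L, GT = 4L, TT = 0L),
                        error_rate = err, depth_per_sample = 300, seed = seed)
    sim <- simulate_cohort_reads(pair, spec)
    cls <- classify_isoform(sim$alignments, regions)
    ret <- cls$read_id[cls$class %in% c("partial_retention", "full_retention")]
    calls <- assign_allele(sim$alignments, pair$model$variant$pos)
    haplotype_purity(calls[calls$read_id %in% ret, ])
  }
  p0 <- run_purity(0, 21)
  expect_true(p0$defined)
  expect_equal(p0$purity, 1)
  expect_gt(p0$n_covered, 20)
  # purity on truth labels equals purity on assigned alleles at zero error
  spec <- cohort_spec(n_per_genotype = c(GG = 0L, GT = 4L, TT = 0L),
                      error_rate = 0, depth_per_sample = 300, seed = 21)
  sim <- simulate_cohort_reads(pair, spec)
  truth_ret <- sim$truth[sim$truth$isoform != "canonical" & sim$truth$covers_variant, ]
  expect_equal(mean(truth_ret$haplotype == "risk"), p0$purity)

  p1 <- run_purity(0.01, 22)
  expect_gte(p1$purity, 0.97)  # one percent per-base error at one site

  # zero covered retention reads -> undefined, flagged
  empty <- haplotype_purity(tibble::tibble(read_id = character(),
                                           base = character(),
                                           baseq = integer(),
                                           allele = character()))
  expect_false(empty$defined)
})

test_that("forced retention on the nonrisk allele yields purity near zero", {
  pair <- make_paper_pair()
  spec <- cohort_spec(
    n_per_genotype = c(GG = 0L, GT = 0L, TT = 3L),
    retention_rates = list(risk = c(partial = 0, full = 0),
                           nonrisk = c(partial = 0.2, full = 0.05)),
    error_rate = 0, depth_per_sample = 300, seed = 13
  )
  sim <- simulate_cohort_reads(pair, spec)
  regions <- build_region_set(pair$model)
  cls <- classify_isoform(sim$alignments, regions)
  ret <- cls$read_id[cls$class %in% c("partial_retention", "full_retention")]
  calls <- assign_allele(sim$alignments, pair$model$variant$pos)
  pur <- haplotype_purity(calls[calls$read_id %in% ret, ])
  expect_equal(pur$purity, 0)
})

test_that("pairwiseAlignment scoring agrees with a hand-rolled DP oracle", {
  set.seed(55)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (rep in 1:10) {
    read <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE), collapse = "")
    ref <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
    got <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(read), Biostrings::DNAString(ref), type = "local",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 2, scoreOnly = TRUE
    )
    expect_equal(got, oracle_local_align(read, ref))
  }
})

test_that("allele swap leaves gene/paralog assignment unchanged on compliant pairs", {
  for (seed in c(3, 4, 5)) {
    pair <- build_paralog_pair(seed = seed)
    spec <- cohort_spec(n_per_genotype = c(GG = 1L, GT = 1L, TT = 0L),
                        depth_per_sample = 120, error_rate = 0.01, seed = seed)
    sim <- simulate_cohort_reads(pair, spec)
    sw <- allele_swap_control(sim$alignments, pair, max_reads = 20)
    expect_equal(sw$concordance, 1)
    expect_gt(sw$n_informative, 0)
    expect_true(all(sw$per_read$assigned_original[sw$per_read$informative] == "gene"))
  }
})

test_that("an adversarial pair distinguished only at the variant site is flagged", {
  pair <- build_paralog_pair(seed = 3)
  m <- pair$model
  # rebuild the pseudogene as an exact copy except at the variant homolog
  gene <- substr(pair$chrom_seq, pair$gene_start + 1, pair$gene_end)
  var_rel <- m$variant$pos - pair$gene_start
  para <- gene
  substr(para, var_rel + 1, var_rel + 1) <- m$variant$alt  # paralog carries G
  adv <- pair
  adv$chrom_seq <- paste0(
    substr(pair$chrom_seq, 1, pair$gene_end),
    substr(pair$chrom_seq, pair$gene_end + 1, pair$paralog_start),
    para,
    substr(pair$chrom_seq, pair$paralog_end + 1, nchar(pair$chrom_seq))
  )
  adv$diff_sites <- m$variant$pos
  spec <- cohort_spec(n_per_genotype = c(GG = 2L, GT = 0L, TT = 0L),
                      depth_per_sample = 150, error_rate = 0, seed = 4)
  sim <- simulate_cohort_reads(pair, spec)
  expect_warning(
    sw <- allele_swap_control(sim$alignments, adv, max_reads = 15),
    "variant-driven"
  )
  expect_lt(sw$concordance, 1)
})

test_that("isoform classification follows the region-overlap rules", {
  pair <- make_paper_pair()
  m <- pair$model
  regions <- build_region_set(pair$model)
  iv <- m$introns[2, ]                      # focal intron, genomic [480, 580)
  down <- regions[regions$role == "exon_down", ]
  up <- regions[regions$role == "exon_up", ]

  aln <- tibble::tibble(
    qname = c("junction", "partial39", "full"),
    flag = 16L, rname = m$chrom,
    pos = c(down$end - 19, iv$start - 49, down$end - 9),
    cigar = c("20M100N20M", "89M", sprintf("%dM", 10 + 100 + 10)),
    mapq = 60L, seq = "*", qual = "*"
  )
  # junction: 20 exon_down bases, N over the intron, 20 exon_up bases
  # partial39: 50 exon_down bases then the 39-nt retained segment
  cls <- classify_isoform(aln, regions)
  got <- setNames(cls$class, cls$read_id)
  expect_equal(got[["junction"]], "canonical")
  expect_equal(got[["partial39"]], "partial_retention")
  expect_equal(got[["full"]], "full_retention")
})

test_that("classification matches the per-base oracle on simulated truth reads", {
  pair <- make_paper_pair()
  spec <- cohort_spec(seed = 17, error_rate = 0, depth_per_sample = 60)
  sim <- simulate_cohort_reads(pair, spec, with_seq = FALSE)
  regions <- build_region_set(pair$model)
  cls <- classify_isoform(sim$alignments, regions)
  aln <- sim$alignments[match(cls$read_id, sim$alignments$qname), ]
  want <- vapply(seq_len(nrow(aln)), function(i) {
    oracle_classify(aln$cigar[i], aln$pos[i], regions)
  }, character(1))
  expect_equal(cls$class, want)
  # determinism and permutation invariance
  shuffled <- sim$alignments[sample(nrow(sim$alignments)), ]
  cls2 <- classify_isoform(shuffled, regions)
  expect_equal(cls2$class[match(cls$read_id, cls2$read_id)], cls$class)
})

test_that("barcode demultiplexing allows one mismatch and keeps ambiguity explicit", {
  wl <- c("AAAAAAAA", "TTTTTTTT", "GGGGCCCC")
  dm <- demux_barcodes(c("AAAAAAAA", "AAAAAAAT", "AAAATTTT", "GGGGCCCA"), wl)
  expect_equal(dm$assignments$assigned,
               c("AAAAAAAA", "AAAAAAAA", "unassigned", "GGGGCCCC"))
  expect_equal(dm$barcode_ratio, 2 / 3)

  # equidistant between two entries -> unassigned
  wl2 <- c("AAAA", "AATT")
  dm2 <- demux_barcodes("AAAT", wl2)
  expect_equal(dm2$assignments$assigned, "unassigned")
  expect_equal(dm2$assignments$n_at_min, 2)

  expect_error(demux_barcodes("AAAA", c("AAAA", "AAAA")), "duplicate")

  # generated whitelists honor the pairwise-distance guarantee
  wl3 <- generate_barcode_whitelist(n = 6, len = 16, min_dist = 5, seed = 2)
  d <- outer(wl3, wl3, Vectorize(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))))
  expect_true(all(d[upper.tri(d)] >= 5))

  # end to end: truth barcodes demultiplex to their own groups
  pair <- make_paper_pair()
  sim <- simulate_cohort_reads(pair, cohort_spec(seed = 2, depth_per_sample = 50),
                               with_seq = FALSE)
  dm3 <- demux_barcodes(sim$truth[, c("read_id", "barcode")],
                        sim$spec$barcode_whitelist)
  expect_true(all(dm3$assignments$assigned == dm3$assignments$barcode))
  expect_equal(dm3$barcode_ratio, 1)
})

test_that("methylation contrast recovers allele fractions and exact p-values", {
  # 10/10 vs 0/10: the most extreme table with both margins 10/10
  calls <- simulate_methylation_calls(p_meth = c(G = 1, T = 0),
                                      calls_per_allele = c(G = 10, T = 10),
                                      seed = 1)
  res <- methylation_by_allele(calls)
  expect_equal(sort(res$per_allele$frac_meth), c(0, 1))
  expect_equal(res$test$p, oracle_fisher_p(res$table))
  expect_equal(res$test$p, 2 / choose(20, 10), tolerance = 1e-12)

  # identical fractions -> p = 1
  even <- tibble::tibble(allele = rep(c("G", "T"), each = 4),
                         methylated = rep(c(1, 1, 0, 0), 2))
  expect_equal(methylation_by_allele(even)$test$p, 1)

  # generator recovery within 3 binomial sd
  big <- simulate_methylation_calls(p_meth = c(G = 0.9, T = 0.1),
                                    calls_per_allele = c(G = 500, T = 500),
                                    seed = 6)
  res2 <- methylation_by_allele(big)
  fr <- setNames(res2$per_allele$frac_meth, res2$per_allele$allele)
  expect_lt(abs(fr[["G"]] - 0.9), 3 * sqrt(0.9 * 0.1 / 500))
  expect_lt(abs(fr[["T"]] - 0.1), 3 * sqrt(0.9 * 0.1 / 500))
  expect_true(res2$test$p < 1e-10)

  # a single allele present: fractions reported, test undefined
  solo <- methylation_by_allele(tibble::tibble(allele = "G", methylated = 1))
  expect_false(solo$test$defined)
})
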