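# The synthetic-data generators: reference pair, cohort reads, activity and
# methylation tables, fixture bundle.

test_that("paralog identity lands within one point of the target", {
  for (seed in c(1, 5, 9)) {
    pair <- build_paralog_pair(seed = seed)
    # count matches through the known mutation mask
    gene <- substr(pair$chrom_seq, pair$gene_start + 1, pair$gene_end)
    para <- substr(pair$chrom_seq, pair$paralog_start + 1, pair$paralog_end)
    mm <- sum(strsplit(gene, "")[[1]] != strsplit(para, "")[[1]])
    ident <- 1 - mm / nchar(gene)
    expect_gte(ident, 0.95)
    expect_lte(ident, 0.97)
    expect_equal(ident, pair$identity)
    expect_equal(mm, length(pair$diff_sites))
  }
})

test_that("every 250-nt window overlapping the focal intron has >= 3 distinguishing sites", {
  pair <- make_paper_pair()
  m <- pair$model
  iv <- m$introns[nrow(m$introns) + 1 - m$focal_intron, ]
  d <- pair$diff_sites
  for (ws in seq(iv$start - 249, iv$end - 1, by = 10)) {
    expect_gte(sum(d >= ws & d < ws + 250), 3)
  }
  # the paralog carries a fixed non-reference base at the variant homolog
  hom <- m$paralog$variant_homolog
  expect_false(substr(pair$chrom_seq, hom + 1, hom + 1) ==
                 substr(pair$chrom_seq, m$variant$pos + 1, m$variant$pos + 1))
})

test_that("reference construction is deterministic and warns when identity is infeasible", {
  p1 <- build_paralog_pair(seed = 42)
  p2 <- build_paralog_pair(seed = 42)
  expect_identical(p1$chrom_seq, p2$chrom_seq)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_reference_fasta(p1, f1); write_reference_fasta(p2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_false(identical(p1$chrom_seq, build_paralog_pair(seed = 43)$chrom_seq))

  expect_warning(
    build_paralog_pair(target_identity = 0.999, seed = 1),
    "distinguishing sites"
  )
})

test_that("nonrisk homozygotes emit no intron-overlapping reads at zero error", {
  pair <- make_paper_pair()
  spec <- cohort_spec(n_per_genotype = c(GG = 0L, GT = 0L, TT = 4L),
                      error_rate = 0, seed = 5)
  sim <- simulate_cohort_reads(pair, spec)
  expect_true(all(sim$truth$isoform == "canonical"))
  regions <- build_region_set(pair$model)
  intron <- regions[regions$role == "intron_full", ]
  for (i in seq_len(nrow(sim$alignments))) {
    cov <- oracle_covered_pos(sim$alignments$cigar[i], sim$alignments$pos[i])
    expect_length(intersect(cov, (intron$start + 1):intron$end), 0)
  }
})

test_that("retention reads come only from risk haplotypes in heterozygotes", {
  pair <- make_paper_pair()
  spec <- cohort_spec(n_per_genotype = c(GG = 0L, GT = 4L, TT = 0L),
                      error_rate = 0, seed = 8)
  sim <- simulate_cohort_reads(pair, spec)
  ret <- sim$truth[sim$truth$isoform != "canonical", ]
  expect_gt(nrow(ret), 0)
  expect_true(all(ret$haplotype == "risk"))
})

test_that("isoform class fractions match the spec within 3 binomial sd", {
  pair <- make_paper_pair()
  spec <- cohort_spec(n_per_genotype = c(GG = 1L, GT = 0L, TT = 0L),
                      depth_per_sample = 10000, seed = 31)
  sim <- simulate_cohort_reads(pair, spec, with_seq = FALSE)
  n <- nrow(sim$truth)
  for (cls in c("partial_retention", "full_retention")) {
    p <- c(partial_retention = 0.15, full_retention = 0.05)[[cls]]
    k <- sum(sim$truth$isoform == cls)
    expect_lt(abs(k - n * p), 3 * sqrt(n * p * (1 - p)))
  }
})

test_that("truth SAM alignments are coordinate-exact against the reference", {
  pair <- make_paper_pair()
  spec <- cohort_spec(seed = 4, error_rate = 0, depth_per_sample = 40)
  sim <- simulate_cohort_reads(pair, spec)
  # at zero error every aligned base must match the reference except the
  # risk allele patch at the variant site
  var1 <- pair$model$variant$pos + 1
  for (i in seq_len(min(nrow(sim$alignments), 100))) {
    a <- sim$alignments[i, ]
    cov <- oracle_covered_pos(a$cigar, a$pos)
    ref <- strsplit(substr(pair$chrom_seq, min(cov), max(cov)), "")[[1]]
    q <- strsplit(a$seq, "")[[1]]
    mism <- 0
    qi <- 0
    for (p in cov) {
      qi <- qi + 1
      if (q[qi] != ref[p - min(cov) + 1]) mism <- mism + 1
    }
    truth_i <- sim$truth[sim$truth$read_id == a$qname, ]
    expected <- as.integer(truth_i$covers_variant && truth_i$haplotype == "risk")
    expect_equal(mism, expected)
  }
})

test_that("long-mode reads are 3'-anchored and short-mode lengths follow the model", {
  pair <- make_paper_pair()
  long <- simulate_cohort_reads(pair, cohort_spec(seed = 6, depth_per_sample = 150),
                                mode = "long", with_seq = FALSE)
  lens <- vapply(split(long$truth$tx_end, long$truth$isoform), max, numeric(1))
  expect_true(all(long$truth$tx_end == lens[long$truth$isoform]))
  short <- simulate_cohort_reads(pair, cohort_spec(seed = 6, depth_per_sample = 150),
                                 mode = "short", with_seq = FALSE)
  fl <- short$truth$tx_end - short$truth$tx_start + 1
  expect_true(all(fl >= 50))
  expect_lt(abs(mean(fl) - 300), 30)
})

test_that("activity generator: noise-free limit, calibration and determinism", {
  noise_free <- simulate_gcase_cohort(sizes = c(TT = 5, GT = 5, GG = 5),
                                      slope = -0.449, intercept = 10,
                                      sigma = 0, seed = 1)
  mg <- tapply(noise_free$activity, noise_free$dosage, mean)
  expect_equal(as.numeric(mg), c(10, 10 - 0.449, 10 - 2 * 0.449))

  # closed-form sigma for the printed group sizes and slope s.e.
  sigma <- calibrate_activity_noise(0.205, c(TT = 97, GT = 99, GG = 9))
  expect_equal(sigma, 1.6933, tolerance = 1e-4)
  # verified by simulation: the average estimated s.e. matches
  ses <- vapply(1:200, function(s) {
    d <- simulate_gcase_cohort(seed = s)
    ols_dosage(d$activity, d$dosage)$se
  }, numeric(1))
  expect_equal(mean(ses), 0.205, tolerance = 0.02)

  expect_identical(simulate_gcase_cohort(seed = 9), simulate_gcase_cohort(seed = 9))
})

test_that("methylation generator hits exact and stochastic targets", {
  exact <- simulate_methylation_calls(p_meth = c(G = 1, T = 0),
                                      calls_per_allele = c(G = 10, T = 10), seed = 1)
  frac <- tapply(exact$methylated, exact$allele, mean)
  expect_equal(as.numeric(frac[c("G", "T")]), c(1, 0))

  big <- simulate_methylation_calls(p_meth = c(G = 0.9, T = 0.1),
                                    calls_per_allele = c(G = 1000, T = 1000), seed = 2)
  fr <- tapply(big$methylated, big$allele, mean)
  expect_lt(abs(fr[["G"]] - 0.9), 3 * sqrt(0.9 * 0.1 / 1000))
  expect_lt(abs(fr[["T"]] - 0.1), 3 * sqrt(0.9 * 0.1 / 1000))

  none <- simulate_methylation_calls(p_meth = c(G = 0.5, T = 0.5),
                                     calls_per_allele = c(G = 10, T = 0), seed = 3)
  expect_false("T" %in% none$allele)
})

test_that("fixture bundle is complete, reproducible and seed-scoped", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir(); d4 <- withr::local_tempdir()
  small <- list(cohort = list(depth_per_sample = 40))
  m1 <- write_fixture_bundle(d1, pipeline_config(seed = 5, cohort = small$cohort))
  m2 <- write_fixture_bundle(d2, pipeline_config(seed = 5, cohort = small$cohort))
  expect_gte(nrow(m1), 8)
  expect_identical(m1$md5, m2$md5)
  expect_true(file.exists(file.path(d1, "manifest.tsv")))

  # different run seed with a pinned reference seed: reads change, the
  # reference FASTA does not
  m3 <- write_fixture_bundle(d3, pipeline_config(seed = 6, ref_seed = 99,
                                                 cohort = small$cohort))
  m4 <- write_fixture_bundle(d4, pipeline_config(seed = 7, ref_seed = 99,
                                                 cohort = small$cohort))
  md5_of <- function(m, f) m$md5[m$file == f]
  expect_identical(md5_of(m3, "reference.fasta"), md5_of(m4, "reference.fasta"))
  expect_false(identical(md5_of(m3, "reads.fastq"), md5_of(m4, "reads.fastq")))
})

test_that("cohort spec rejects impossible retention rates", {
  expect_error(cohort_spec(retention_rates = list(
    risk = c(partial = 0.8, full = 0.4), nonrisk = c(partial = 0, full = 0)
  )), "sum")
  expect_error(cohort_spec(retention_rates = list(
    risk = c(partial = -0.1, full = 0), nonrisk = c(partial = 0, full = 0)
  )))
})
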