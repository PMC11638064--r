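# Regional mean-depth computation and genotype-dosage association.
#
# Two independent filter profiles are deliberately kept apart: the depth
# profile (MAPQ >= 5, base quality >= 20, excluding unmapped / secondary /
# qcfail / duplicate records - the samtools-coverage style filter used for
# regional depth) and the retention profile (MAPQ >= 40, primary only - the
# read-retention filter applied before allele or isoform analysis).

#' Filter profiles
#'
#' @return Named list of filter settings.
#' @export
depth_profile <- function() {
  list(min_mapq = 5L, min_baseq = 20L,
       exclude = c("unmapped", "secondary", "qcfail", "duplicate"))
}

#' @rdname depth_profile
#' @export
retention_profile <- function() {
  list(min_mapq = 40L, primary_only = TRUE)
}

apply_flag_filters <- function(aln, exclude) {
  keep <- rep(TRUE, nrow(aln))
  for (w in exclude) keep <- keep & !flag_has(aln$flag, w)
  aln[keep, ]
}

# covered reference ranges per alignment: M/=/X and D advance coverage
# (deletions count as covered by the span dialect), N does not.
covered_ranges <- function(cigar, pos) {
  GenomicAlignments::extractAlignmentRangesOnReference(
    cigar, pos = pos, drop.D.ranges = FALSE
  )
}

# covered 1-based reference positions of one read after dropping aligned
# bases below `min_baseq` (deletions carry no base and are kept)
covered_pos_baseq <- function(cigar, pos, qual, min_baseq) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  q <- as.integer(charToRaw(qual)) - 33L
  ref <- pos; qi <- 1L
  keep <- integer(0)
  for (k in seq_along(ops)) {
    op <- ops[k]; len <- lens[k]
    if (op %in% c("M", "=", "X")) {
      ok <- q[qi:(qi + len - 1L)] >= min_baseq
      keep <- c(keep, (ref:(ref + len - 1L))[ok])
      ref <- ref + len; qi <- qi + len
    } else if (op %in% c("I", "S")) {
      qi <- qi + len
    } else if (op == "D") {
      keep <- c(keep, ref:(ref + len - 1L))
      ref <- ref + len
    } else if (op == "N") {
      ref <- ref + len
    }
  }
  keep
}

#' Mean per-base depth over a region
#'
#' Pileup depth from alignments passing the depth-profile filters,
#' averaged over every base of the region (zero-depth positions
#' included). A read contributes to each reference base its aligned
#' blocks cover; splice gaps (CIGAR N) do not cover, deletions (D) do.
#' Bases with quality below `min_baseq` are excluded for reads that carry
#' qualities.
#'
#' @param alignments Alignment tibble.
#' @param region One-row tibble or list with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param min_mapq,min_baseq,exclude Depth-profile filters.
#' @return Mean depth (numeric scalar).
#' @export
mean_region_depth <- function(alignments, region,
                              min_mapq = 5L, min_baseq = 20L,
                              exclude = c("unmapped", "secondary", "qcfail",
                                          "duplicate")) {
  width <- region$end - region$start
  if (is.na(width) || width <= 0) abort("empty region")
  aln <- alignments[alignments$rname == region$chrom, ]
  aln <- apply_flag_filters(aln, exclude)
  aln <- aln[aln$mapq >= min_mapq, ]
  if (nrow(aln) == 0) return(0)

  has_qual <- !is.na(aln$qual) & aln$qual != "*"
  # fast path: reads whose worst base passes need no per-base masking
  min_q <- rep(Inf, nrow(aln))
  if (any(has_qual)) {
    min_q[has_qual] <- vapply(aln$qual[has_qual], function(q) {
      min(as.integer(charToRaw(q))) - 33L
    }, numeric(1))
  }
  easy <- !has_qual | min_q >= min_baseq

  ir <- IRanges::IRanges()
  if (any(easy)) {
    rl <- covered_ranges(aln$cigar[easy], aln$pos[easy])
    ir <- unlist(rl, use.names = FALSE)
  }
  if (any(!easy)) {
    hard <- which(!easy)
    pos_list <- lapply(hard, function(i) {
      covered_pos_baseq(aln$cigar[i], aln$pos[i], aln$qual[i], min_baseq)
    })
    extra <- IRanges::IRanges(start = unlist(pos_list), width = 1L)
    ir <- c(ir, extra)
  }
  if (length(ir) == 0) return(0)
  cov <- IRanges::coverage(ir, width = max(region$end + 1L, max(IRanges::end(ir))))
  v <- IRanges::Views(cov, start = region$start + 1L, end = region$end)
  sum(IRanges::viewSums(v)) / width
}

#' Count primary mapped reads (the per-million denominator)
#'
#' @param alignments Alignment tibble.
#' @return Integer count of mapped, primary (non-secondary,
#'   non-supplementary) records.
#' @export
total_mapped_reads <- function(alignments) {
  sum(!flag_has(alignments$flag, "unmapped") & is_primary(alignments$flag))
}

#' Normalize a mean depth to coverage per million mapped reads
#'
#' `mean_depth / (total_mapped_reads / 1e6)`; zero total reads is an
#' error, not zero.
#'
#' @param mean_depth Mean regional depth.
#' @param total_mapped_reads Genome-wide primary mapped read count.
#' @return Normalized coverage (numeric).
#' @export
normalized_coverage <- function(mean_depth, total_mapped_reads) {
  if (total_mapped_reads <= 0) abort("total_mapped_reads must be positive")
  mean_depth / (total_mapped_reads / 1e6)
}

#' Regional coverage table for one sample
#'
#' @param alignments Alignment tibble (one sample).
#' @param regions Region tibble from [build_region_set()].
#' @param total Per-million denominator; defaults to
#'   [total_mapped_reads()] of `alignments`.
#' @param profile Depth filter profile, see [depth_profile()].
#' @return Tibble with `name`, `role`, `mean_depth`,
#'   `total_mapped_reads`, `normalized`.
#' @export
region_coverage <- function(alignments, regions, total = NULL,
                            profile = depth_profile()) {
  total <- total %||% total_mapped_reads(alignments)
  depth <- vapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    if (r$end - r$start <= 0) return(NA_real_)
    mean_region_depth(alignments, r, min_mapq = profile$min_mapq,
                      min_baseq = profile$min_baseq, exclude = profile$exclude)
  }, numeric(1))
  tibble(
    name = regions$name, role = regions$role, mean_depth = depth,
    total_mapped_reads = total,
    normalized = ifelse(is.na(depth), NA_real_,
                        vapply(depth, normalized_coverage, numeric(1),
                               total_mapped_reads = total))
  )
}

#' Per-sample regional coverage for a simulated (or loaded) cohort
#'
#' @param sim A `cohort_sim`, or an alignment tibble carrying `sample`
#'   and `genotype` columns.
#' @param regions Region tibble.
#' @param profile Depth filter profile.
#' @return Tibble with one row per sample x region, including `genotype`
#'   and `normalized`.
#' @export
quantify_cohort <- function(sim, regions, profile = depth_profile()) {
  aln <- if (inherits(sim, "cohort_sim")) sim$alignments else sim
  bind_rows(lapply(split(aln, aln$sample), function(a) {
    out <- region_coverage(a, regions, profile = profile)
    out$sample <- a$sample[1]
    out$genotype <- a$genotype[1]
    out
  }))
}

#' Genotype-dosage association of normalized coverage
#'
#' Applies the published grouping rule: when more than `gg_threshold`
#' samples are homozygous risk (GG), regress on the three-level dosage
#' (TT = 0, GT = 1, GG = 2); otherwise pool carriers and regress on the
#' binary contrast (GG + GT) vs TT. Returns the closed-form OLS fit with
#' the two-sided p and unadjusted r-squared.
#'
#' @param samples Tibble with one row per sample.
#' @param value Column holding the outcome (normalized coverage).
#' @param genotype Column holding genotypes coded `GG`/`GT`/`TT`.
#' @param gg_threshold GG count above which the dosage coding is used.
#' @return A `dosage_fit` whose `grouping` records the path taken.
#' @export
coverage_genotype_association <- function(samples, value = "normalized",
                                          genotype = "genotype",
                                          gg_threshold = 5L) {
  y <- samples[[value]]
  gt <- samples[[genotype]]
  if (length(y) < 3) abort("need at least 3 samples")
  if (length(unique(gt)) < 2) abort("no contrast: a single genotype level")
  if (sum(gt == "GG") > gg_threshold) {
    g <- c(TT = 0, GT = 1, GG = 2)[gt]
    ols_dosage(y, g, grouping = "dosage")
  } else {
    g <- as.numeric(gt %in% c("GG", "GT"))
    ols_dosage(y, g, grouping = "binary")
  }
}
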