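# Allele-of-origin assignment, haplotype purity, the allele-swap mapping
# control, isoform classification, barcode demultiplexing, and the
# per-allele methylation contrast.

# read base (and query index / base quality) at a 1-based reference
# position, walking the CIGAR; returns base NA for positions under D/N
read_base_at <- function(cigar, pos, seq, qual, gpos1) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  ref <- pos; qi <- 1L
  for (k in seq_along(ops)) {
    op <- ops[k]; len <- lens[k]
    if (op %in% c("M", "=", "X")) {
      if (gpos1 >= ref && gpos1 < ref + len) {
        q <- qi + (gpos1 - ref)
        bq <- if (!is.na(qual) && qual != "*") {
          as.integer(charToRaw(substr(qual, q, q))) - 33L
        } else NA_integer_
        return(list(base = substr(seq, q, q), qpos = q, baseq = bq))
      }
      ref <- ref + len; qi <- qi + len
    } else if (op %in% c("I", "S")) {
      qi <- qi + len
    } else if (op %in% c("D", "N")) {
      if (gpos1 >= ref && gpos1 < ref + len) {
        return(list(base = NA_character_, qpos = NA_integer_, baseq = NA_integer_))
      }
      ref <- ref + len
    }
  }
  NULL  # position outside the aligned span
}

#' Assign each read an allele of origin at the variant site
#'
#' Reports the read base observed at the variant site, mapped through the
#' alignment, for every primary alignment at or above the retention
#' MAPQ threshold. Alleles are called on the sense strand: `risk` for the
#' risk base, `nonrisk` for the nonrisk base, `other` for anything else
#' (including N or a deleted/skipped base), `uncovered` when the aligned
#' span excludes the site.
#'
#' @param alignments Alignment tibble.
#' @param variant_pos 0-based genomic position of the variant.
#' @param risk,nonrisk Sense-strand alleles (defaults G / T).
#' @param min_mapq Retention-profile MAPQ threshold.
#' @return Tibble with `read_id`, `base`, `baseq`, `allele`.
#' @export
assign_allele <- function(alignments, variant_pos, risk = "G", nonrisk = "T",
                          min_mapq = 40L) {
  aln <- alignments[is_primary(alignments$flag) &
                      !flag_has(alignments$flag, "unmapped") &
                      alignments$mapq >= min_mapq, ]
  gpos1 <- variant_pos + 1L
  n <- nrow(aln)
  base <- character(n); baseq <- integer(n); allele <- character(n)
  for (i in seq_len(n)) {
    hit <- read_base_at(aln$cigar[i], aln$pos[i], aln$seq[i], aln$qual[i], gpos1)
    if (is.null(hit)) {
      base[i] <- NA_character_; baseq[i] <- NA_integer_; allele[i] <- "uncovered"
    } else if (is.na(hit$base)) {
      base[i] <- "-"; baseq[i] <- NA_integer_; allele[i] <- "other"
    } else {
      base[i] <- hit$base; baseq[i] <- hit$baseq %||% NA_integer_
      allele[i] <- if (hit$base == risk) "risk"
                   else if (hit$base == nonrisk) "nonrisk"
                   else "other"
    }
  }
  tibble(read_id = aln$qname, base = base, baseq = baseq, allele = allele)
}

#' Haplotype purity of a read class
#'
#' Fraction of covered reads (typically retention-class reads) assigned
#' the risk allele, with a Clopper-Pearson interval. Calls whose base
#' quality at the site falls below `min_baseq` are excluded and counted.
#'
#' @param calls Output of [assign_allele()], restricted by the caller to
#'   the read class of interest.
#' @param min_baseq Base-quality floor at the variant site.
#' @param conf Confidence level for the interval.
#' @return One-row tibble with `n_covered`, `n_risk`, `purity`,
#'   `ci_lower`, `ci_upper`, `n_excluded_baseq`, `defined`.
#' @export
haplotype_purity <- function(calls, min_baseq = 20L, conf = 0.95) {
  covered <- calls[calls$allele != "uncovered", ]
  low_q <- !is.na(covered$baseq) & covered$baseq < min_baseq
  n_excl <- sum(low_q)
  covered <- covered[!low_q, ]
  n <- nrow(covered)
  if (n == 0) {
    return(tibble(
      n_covered = 0L, n_risk = 0L, purity = NA_real_,
      ci_lower = NA_real_, ci_upper = NA_real_,
      n_excluded_baseq = n_excl, defined = FALSE
    ))
  }
  k <- sum(covered$allele == "risk")
  ci <- clopper_pearson(k, n, conf)
  tibble(
    n_covered = n, n_risk = k, purity = k / n,
    ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
    n_excluded_baseq = n_excl, defined = TRUE
  )
}

#' Allele-swap mapping-artifact control
#'
#' Flips the variant base in every read covering the site (risk to
#' nonrisk and vice versa), then assigns each original and flipped read
#' to the gene or the paralog by best full dynamic-programming alignment
#' score (match +1, mismatch -1, gap -2) against both reference
#' sequences. If assignment is driven by paralog-distinguishing sites
#' rather than by the variant itself, the assignment is concordant before
#' and after the flip. Reads overlapping no distinguishing site are
#' flagged ambiguous and excluded from the rate, as are score ties.
#'
#' @param alignments Alignment tibble with materialized sequences.
#' @param pair A `paralog_pair` (paralog required).
#' @param max_reads Cap on reads tested (alignment is quadratic).
#' @param min_mapq Retention-profile MAPQ threshold.
#' @return List with `per_read` (tibble), `concordance`,
#'   `n_informative`.
#' @export
allele_swap_control <- function(alignments, pair, max_reads = 100L,
                                min_mapq = 40L) {
  model <- pair$model
  if (is.null(model$paralog)) abort("reference pair carries no paralog")
  var_pos <- model$variant$pos
  gene_ref <- substr(pair$chrom_seq, pair$gene_start + 1, pair$gene_end)
  para_ref <- substr(pair$chrom_seq, pair$paralog_start + 1, pair$paralog_end)

  aln <- alignments[is_primary(alignments$flag) & alignments$mapq >= min_mapq, ]
  if (nrow(aln) == 0 || all(aln$seq == "*")) {
    abort("allele_swap_control() needs reads with sequences")
  }
  gpos1 <- var_pos + 1L
  hits <- lapply(seq_len(nrow(aln)), function(i) {
    read_base_at(aln$cigar[i], aln$pos[i], aln$seq[i], aln$qual[i], gpos1)
  })
  covering <- vapply(hits, function(h) !is.null(h) && !is.na(h$base), logical(1))
  aln <- aln[covering, ]
  hits <- hits[covering]
  if (nrow(aln) == 0) abort("no reads cover the variant site")
  if (nrow(aln) > max_reads) {
    keep <- seq_len(max_reads)
    aln <- aln[keep, ]; hits <- hits[keep]
  }

  swap <- c(setNames(model$variant$ref, model$variant$alt),
            setNames(model$variant$alt, model$variant$ref))
  flipped <- vapply(seq_len(nrow(aln)), function(i) {
    s <- aln$seq[i]; q <- hits[[i]]$qpos
    b <- substr(s, q, q)
    repl <- unname(swap[b])
    if (!is.na(repl)) substr(s, q, q) <- repl  # error bases stay untouched
    s
  }, character(1))

  # informative = aligned span overlaps >= 1 paralog-distinguishing site
  span_w <- GenomicAlignments::cigarWidthAlongReferenceSpace(aln$cigar)
  span_lo <- aln$pos - 1L
  span_hi <- span_lo + span_w
  informative <- vapply(seq_len(nrow(aln)), function(i) {
    any(pair$diff_sites >= span_lo[i] & pair$diff_sites < span_hi[i])
  }, logical(1))

  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  score_vs <- function(reads, ref) {
    Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(reads), Biostrings::DNAString(ref),
      type = "local", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2, scoreOnly = TRUE
    )
  }
  assign_to <- function(reads) {
    sg <- score_vs(reads, gene_ref)
    sp <- score_vs(reads, para_ref)
    dplyr::case_when(sg > sp ~ "gene", sp > sg ~ "paralog", TRUE ~ "tie")
  }
  a_orig <- assign_to(aln$seq)
  a_flip <- assign_to(flipped)

  per_read <- tibble(
    read_id = aln$qname, informative = informative,
    assigned_original = a_orig, assigned_flipped = a_flip,
    concordant = a_orig == a_flip & a_orig != "tie"
  )
  usable <- per_read$informative & a_orig != "tie" & a_flip != "tie"
  conc <- if (any(usable)) mean(per_read$concordant[usable]) else NA_real_
  if (!is.na(conc) && conc < 1) {
    warn("gene/paralog assignment changes under the allele swap: assignment is variant-driven")
  }
  list(per_read = per_read, concordance = conc, n_informative = sum(usable))
}

#' Classify long reads into retention isoform classes
#'
#' Interval-arithmetic classification against the quantification regions:
#' `full_retention` when a read covers at least `min_intron_frac` of the
#' focal intron contiguously with at least one flanking exon base;
#' `partial_retention` when it covers at least `min_overlap` of the short
#' 3'-terminal intron window plus downstream-exon bases, but less than
#' `min_intron_frac` of the intron remainder; `canonical` when it spans
#' the exon-exon junction with at most `max_intron_bases` intronic
#' bases; otherwise `ambiguous`. Thresholds are exposed because they are
#' analysis choices, not measured quantities.
#'
#' @param alignments Alignment tibble.
#' @param regions Region tibble from [build_region_set()].
#' @param min_overlap Minimum short-window coverage fraction for the
#'   partial class.
#' @param min_intron_frac Minimum full-intron coverage fraction for the
#'   full class.
#' @param max_intron_bases Intronic bases tolerated in a canonical read.
#' @param min_mapq Retention-profile MAPQ threshold.
#' @return Tibble with `read_id`, `class` and the overlap diagnostics.
#' @export
classify_isoform <- function(alignments, regions, min_overlap = 0.8,
                             min_intron_frac = 0.9, max_intron_bases = 2L,
                             min_mapq = 40L) {
  reg <- function(role) {
    r <- regions[regions$role == role, ][1, ]
    IRanges::IRanges(start = r$start + 1L, end = r$end)
  }
  intron <- reg("intron_full"); short <- reg("intron_short_window")
  rest <- reg("intron_rest"); e_up <- reg("exon_up"); e_down <- reg("exon_down")

  aln <- alignments[is_primary(alignments$flag) &
                      !flag_has(alignments$flag, "unmapped") &
                      alignments$mapq >= min_mapq, ]
  rl <- covered_ranges(aln$cigar, aln$pos)
  ov <- function(ir, target) {
    if (IRanges::width(target) == 0) return(0L)
    sum(IRanges::width(IRanges::intersect(ir, target)))
  }
  n <- nrow(aln)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ir <- rl[[i]]
    w_int <- ov(ir, intron)
    w_short <- ov(ir, short)
    w_rest <- ov(ir, rest)
    w_up <- ov(ir, e_up)
    w_down <- ov(ir, e_down)
    f_int <- w_int / IRanges::width(intron)
    f_short <- if (IRanges::width(short) > 0) w_short / IRanges::width(short) else 0
    f_rest <- if (IRanges::width(rest) > 0) w_rest / IRanges::width(rest) else 0
    contiguous <- length(IRanges::reduce(IRanges::intersect(ir, intron))) <= 1
    cls <- if (f_int >= min_intron_frac && contiguous && (w_up > 0 || w_down > 0)) {
      "full_retention"
    } else if (f_short >= min_overlap && w_down > 0 && f_rest < min_intron_frac) {
      "partial_retention"
    } else if (w_up > 0 && w_down > 0 && w_int <= max_intron_bases) {
      "canonical"
    } else {
      "ambiguous"
    }
    out[[i]] <- tibble(
      read_id = aln$qname[i], class = cls,
      frac_intron = f_int, frac_short = f_short, frac_rest = f_rest,
      intron_bases = w_int, exon_up_bases = w_up, exon_down_bases = w_down
    )
  }
  bind_rows(out)
}

#' Demultiplex reads by cell barcode
#'
#' Assigns each observed barcode to the unique whitelist barcode within
#' `max_mismatch` substitutions; reads matching none, or equally close to
#' two or more entries, go to the `unassigned` bucket (never silently
#' dropped). Also reports per-group counts and the observed/whitelist
#' barcode diversity ratio.
#'
#' @param barcodes Tibble with `read_id` and `barcode`, or a character
#'   vector of observed barcodes.
#' @param whitelist Character vector of equal-length barcodes, no
#'   duplicates.
#' @param max_mismatch Maximum Hamming distance for an assignment.
#' @return List with `assignments` (tibble: `read_id`, `barcode`,
#'   `assigned`, `min_dist`, `n_at_min`), `counts`, `barcode_ratio`.
#' @export
demux_barcodes <- function(barcodes, whitelist, max_mismatch = 1L) {
  if (anyDuplicated(whitelist)) abort("whitelist contains duplicate barcodes")
  if (length(unique(nchar(whitelist))) != 1) {
    abort("whitelist barcodes must have equal length")
  }
  if (is.character(barcodes)) {
    barcodes <- tibble(read_id = sprintf("read%06d", seq_along(barcodes)),
                       barcode = barcodes)
  }
  obs <- barcodes$barcode
  dist <- vapply(whitelist, function(wl) {
    vapply(obs, function(b) {
      if (nchar(b) != nchar(wl)) Inf else hamming(b, wl)
    }, numeric(1))
  }, numeric(length(obs)))
  dist <- matrix(dist, nrow = length(obs))
  min_d <- apply(dist, 1, min)
  n_min <- rowSums(dist == min_d)
  assigned <- ifelse(
    min_d <= max_mismatch & n_min == 1,
    whitelist[apply(dist, 1, which.min)],
    "unassigned"
  )
  assignments <- tibble(
    read_id = barcodes$read_id, barcode = obs, assigned = assigned,
    min_dist = min_d, n_at_min = n_min
  )
  counts <- count(assignments, .data$assigned, name = "n_reads")
  ratio <- length(setdiff(unique(assigned), "unassigned")) / length(whitelist)
  list(assignments = assignments, counts = counts, barcode_ratio = ratio)
}

#' Per-allele methylation contrast
#'
#' Builds the 2x2 allele-by-methylation table from per-read calls and
#' tests it with the exact test. With a single allele present the
#' fractions are still reported but the p-value is undefined and
#' flagged.
#'
#' @param calls Tibble with `allele` and `methylated` (0/1), e.g. from
#'   [simulate_methylation_calls()].
#' @return List with `per_allele` (tibble: `allele`, `n`, `n_meth`,
#'   `frac_meth`), `table` (2x2 matrix or NULL), `test` (tibble from
#'   [fisher_2x2()], `defined = FALSE` when untestable).
#' @export
methylation_by_allele <- function(calls) {
  if (nrow(calls) == 0) abort("no methylation calls")
  per_allele <- summarise(
    group_by(calls, .data$allele),
    n = n(), n_meth = sum(.data$methylated), .groups = "drop"
  )
  per_allele <- mutate(per_allele, frac_meth = .data$n_meth / .data$n)
  if (nrow(per_allele) < 2) {
    return(list(
      per_allele = per_allele, table = NULL,
      test = tibble(odds_ratio = NA_real_, p = NA_real_, defined = FALSE)
    ))
  }
  tab <- as.matrix(cbind(per_allele$n_meth, per_allele$n - per_allele$n_meth))
  dimnames(tab) <- list(per_allele$allele, c("methylated", "unmethylated"))
  list(per_allele = per_allele, table = tab, test = fisher_2x2(tab))
}
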