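# Synthetic reference construction: a minus-strand gene with a designed
# retention-prone intron and a downstream pseudogene at controlled identity.

#' Build the transcript-orientation sequence of the focal intron
#'
#' Deterministically places the splice elements the branchpoint analysis
#' expects - donor GT, acceptor AG, a perfect yUnAy branchpoint context at
#' `bp_offset`, and a single upstream AG whose G sits `cryptic_gap` nt
#' above the branchpoint - on an all-pyrimidine background, so the
#' branchpoint at `bp_offset` is the unique top-scoring candidate and the
#' placed AG is the nearest upstream acceptor. The defaults reproduce the
#' geometry of the locus that motivated the package: branchpoint A 34 nt
#' before the downstream exon and a cryptic AG 6 nt further upstream,
#' giving a 39-nt retained segment.
#'
#' @param len Intron length in nt.
#' @param bp_offset Acceptor-side offset of the branchpoint adenosine.
#' @param cryptic_gap Distance in nt from the branchpoint to the G of the
#'   cryptic AG (must be at least 4 so the AG clears the scored context).
#' @return Character string (5' to 3' on the transcript).
#' @export
focal_intron_seq <- function(len = 100L, bp_offset = 34L, cryptic_gap = 6L) {
  stopifnot(cryptic_gap >= 4, bp_offset >= 18,
            bp_offset + cryptic_gap + 4 < len)
  bases <- sample(c("C", "T"), len, replace = TRUE)
  put <- function(offset, b) bases[len - offset + 1L] <<- b
  bases[1:2] <- c("G", "T")                    # donor
  put(2L, "A"); put(1L, "G")                   # canonical acceptor AG
  put(bp_offset + 3L, "C")                     # y (-3)
  put(bp_offset + 2L, "T")                     # U (-2)
  put(bp_offset + 1L, "C")                     # n (-1), kept non-A/G
  put(bp_offset, "A")                          # the branchpoint
  put(bp_offset - 1L, "T")                     # y (+1)
  put(bp_offset + cryptic_gap + 1L, "A")       # cryptic AG ...
  put(bp_offset + cryptic_gap, "G")            # ... G is its 3'-most base
  paste(bases, collapse = "")
}

#' Build a synthetic gene/pseudogene pair
#'
#' Constructs a chromosome holding a multi-exon gene (minus strand by
#' default, mirroring a gene transcribed from the antisense strand) and,
#' downstream, a pseudogene copy mutated to a target global identity
#' (default 96%, the level at which read mapping between the two becomes
#' genuinely confusable). The pseudogene placement guarantees at least 3
#' distinguishing substitutions in every 250-nt window overlapping the
#' focal intron, so reads from that region remain assignable, and carries
#' a fixed non-reference base at the position homologous to the variant
#' site (so assignment never hinges on the variant itself). The gene's
#' focal intron follows [focal_intron_seq()]; the variant (sense-strand
#' ref T = intact branchpoint A on the transcript, alt G = disrupting C)
#' is placed at `bp_offset`.
#'
#' @param exon_lens Exon lengths in transcript order.
#' @param intron_lens Intron lengths in transcript order.
#' @param focal_intron Transcript-order index of the retention-prone intron.
#' @param bp_offset,cryptic_gap Focal intron geometry, see
#'   [focal_intron_seq()].
#' @param strand Gene strand.
#' @param target_identity Target gene/pseudogene identity in (0.5, 1).
#' @param chrom Chromosome name.
#' @param pad,spacer Random-sequence padding before the gene and between
#'   gene and pseudogene.
#' @param seed RNG seed; the same seed reproduces the sequence byte for
#'   byte.
#' @return An object of class `paralog_pair`: a list with `model` (a
#'   [gene_model()] whose `genome_seq` is the full chromosome and whose
#'   `paralog` field records span, coordinate offset and distinguishing
#'   sites), `chrom_seq`, `identity`, and `diff_sites` (gene-coordinate,
#'   0-based).
#' @export
build_paralog_pair <- function(exon_lens = c(150L, 120L, 140L, 160L),
                               intron_lens = c(90L, 100L, 80L),
                               focal_intron = 2L,
                               bp_offset = 34L, cryptic_gap = 6L,
                               strand = "-",
                               target_identity = 0.96,
                               chrom = "chrSyn",
                               pad = 100L, spacer = 300L,
                               seed = 1L) {
  stopifnot(length(intron_lens) == length(exon_lens) - 1)
  if (target_identity <= 0.5 || target_identity >= 1) {
    abort("target_identity must be in (0.5, 1)")
  }
  with_seed(seed, {
    # --- gene in transcript orientation ---
    n_ex <- length(exon_lens)
    seg_seq <- character(2 * n_ex - 1)
    seg_kind <- rep(c("exon", "intron"), length.out = 2 * n_ex - 1)
    for (k in seq_along(seg_seq)) {
      if (seg_kind[k] == "exon") {
        seg_seq[k] <- rand_dna(exon_lens[(k + 1) / 2])
      } else {
        i <- k / 2
        if (i == focal_intron) {
          seg_seq[k] <- focal_intron_seq(intron_lens[i], bp_offset, cryptic_gap)
        } else {
          s <- strsplit(rand_dna(intron_lens[i]), "")[[1]]
          s[1:2] <- c("G", "T")
          s[(length(s) - 1):length(s)] <- c("A", "G")
          seg_seq[k] <- paste(s, collapse = "")
        }
      }
    }
    tx_seq <- paste(seg_seq, collapse = "")
    glen <- nchar(tx_seq)
    gene_seq <- if (strand == "-") revcomp(tx_seq) else tx_seq

    # segment boundaries in transcript coords -> genomic exon intervals
    ends <- cumsum(nchar(seg_seq))
    starts <- c(1L, head(ends, -1) + 1L)
    gene_start <- pad
    to_genomic <- function(a, b) {
      if (strand == "-") {
        c(gene_start + glen - b, gene_start + glen - a + 1L)
      } else {
        c(gene_start + a - 1L, gene_start + b)
      }
    }
    ex_iv <- lapply(which(seg_kind == "exon"), function(k) to_genomic(starts[k], ends[k]))
    exons <- arrange(tibble(
      start = vapply(ex_iv, `[`, numeric(1), 1),
      end = vapply(ex_iv, `[`, numeric(1), 2)
    ), .data$start)

    # --- pseudogene copy with controlled divergence ---
    gene_end <- gene_start + glen
    para_start <- gene_end + spacer
    gseq <- strsplit(gene_seq, "")[[1]]

    # focal intron (gene coords, relative to gene start)
    fi_k <- which(seg_kind == "intron")[focal_intron]
    fi <- to_genomic(starts[fi_k], ends[fi_k]) - gene_start
    # variant: transcript offset bp_offset inside the focal intron
    var_rel <- if (strand == "-") fi[1] + bp_offset - 1L else fi[2] - bp_offset
    var_pos <- gene_start + var_rel

    n_target <- round((1 - target_identity) * glen)
    tiles_lo <- max(0L, fi[1] - 250L)
    tiles_hi <- min(glen, fi[2] + 250L)
    tile_starts <- seq.int(tiles_lo, tiles_hi - 1L, by = 125L)
    min_required <- 3L * length(tile_starts)
    if (min_required > (1 - target_identity + 0.01) * glen) {
      warn(paste(
        "target identity too high to guarantee >= 3 distinguishing sites",
        "in every 250-nt window overlapping the focal intron"
      ))
    }

    diff <- sort(sample.int(glen, n_target) - 1L)
    diff <- union(diff, var_rel)
    for (ts in tile_starts) {
      te <- min(ts + 125L, glen)
      have <- sum(diff >= ts & diff < te)
      if (have < 3) {
        pool <- setdiff(seq.int(ts, te - 1L), diff)
        diff <- union(diff, sample_safe(pool, min(3 - have, length(pool))))
      }
    }
    # keep realized identity within +/- 1 percentage point of target
    lo_n <- ceiling((1 - target_identity - 0.01) * glen)
    if (length(diff) > round((1 - target_identity + 0.01) * glen)) {
      removable <- setdiff(diff, var_rel)
      in_tile <- removable[removable >= tiles_lo & removable < tiles_hi]
      free <- setdiff(removable, in_tile)
      drop_n <- length(diff) - n_target
      diff <- setdiff(diff, sample_safe(free, min(drop_n, length(free))))
    }
    if (length(diff) < lo_n) {
      pool <- setdiff(seq_len(glen) - 1L, diff)
      diff <- union(diff, sample_safe(pool, lo_n - length(diff)))
    }
    diff <- sort(diff)

    pseq <- gseq
    for (d in diff) {
      pseq[d + 1L] <- sample(setdiff(c("A", "C", "G", "T"), gseq[d + 1L]), 1)
    }
    # fixed non-reference base at the variant-homologous position
    pseq[var_rel + 1L] <- "C"

    chrom_seq <- paste0(
      rand_dna(pad), paste(gseq, collapse = ""), rand_dna(spacer),
      paste(pseq, collapse = ""), rand_dna(pad)
    )
    identity <- 1 - length(diff) / glen

    model <- gene_model(
      chrom = chrom, strand = strand, exons = exons,
      genome_seq = chrom_seq,
      # sense-strand alleles: the reference carries the intact branchpoint
      # (A on the transcript), the alt allele destroys it (C on transcript)
      variant = if (strand == "-") {
        list(pos = var_pos, ref = "T", alt = "G")
      } else {
        list(pos = var_pos, ref = "A", alt = "C")
      },
      focal_intron = focal_intron,
      paralog = list(
        start = para_start, end = para_start + glen,
        offset = para_start - gene_start,
        diff_sites = gene_start + diff,
        variant_homolog = para_start + var_rel
      )
    )
    structure(
      list(
        model = model, chrom_seq = chrom_seq, identity = identity,
        diff_sites = gene_start + diff,
        gene_start = gene_start, gene_end = gene_end,
        paralog_start = para_start, paralog_end = para_start + glen,
        seed = seed
      ),
      class = "paralog_pair"
    )
  })
}

#' @export
print.paralog_pair <- function(x, ...) {
  cat(sprintf(
    "<paralog_pair> gene %d-%d, paralog %d-%d, identity %.3f (%d distinguishing sites)\n",
    x$gene_start, x$gene_end, x$paralog_start, x$paralog_end,
    x$identity, length(x$diff_sites)
  ))
  invisible(x)
}

#' Write the synthetic chromosome as FASTA
#'
#' @param pair A `paralog_pair` (or any object with `chrom_seq` and a
#'   model carrying `chrom`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(pair, path) {
  ss <- Biostrings::DNAStringSet(pair$chrom_seq)
  names(ss) <- pair$model$chrom
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
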