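# Rule-based branchpoint window analysis.
# All offsets are acceptor-side intronic offsets in transcript orientation:
# offset 1 is the last intron base (adjacent to the downstream exon), larger
# offsets are further upstream (5') within the intron.

base_at_offset <- function(intron_seq, offset) {
  len <- nchar(intron_seq)
  if (offset < 1 || offset > len) return(NA_character_)
  substr(intron_seq, len - offset + 1, len - offset + 1)
}

is_pyrimidine <- function(b) !is.na(b) & b %in% c("C", "T", "U")

#' Enumerate and score branchpoint candidates in an intron
#'
#' Every adenosine whose acceptor-side offset falls inside the search
#' window is scored against the yUnAy branchpoint consensus (pyrimidine,
#' U, any, A, pyrimidine; the A is the branchpoint). Matched positions
#' contribute fixed weights - U immediately 5' of the "any" slot 0.5, each
#' pyrimidine 0.25 - so scores live in \[0, 1\]. Candidates are ranked by
#' score, ties broken by proximity to the 3' splice site (smaller offset
#' wins). The default window, 18-44 nt upstream of the 3' splice site, is
#' the standard human branchpoint positioning range and can be widened.
#'
#' @param intron_seq Intron sequence in transcript orientation (DNA
#'   alphabet; must end with the acceptor dinucleotide AG).
#' @param window Integer vector `c(min_offset, max_offset)`.
#' @return A tibble with `offset`, `score`, `rank` (empty when the window
#'   holds no A).
#' @examples
#' enumerate_branchpoints(paste0("GT", strrep("C", 60), "TTTCTACTTT",
#'   strrep("C", 20), "AG"))
#' @export
enumerate_branchpoints <- function(intron_seq, window = c(18L, 44L)) {
  intron_seq <- toupper(intron_seq)
  len <- nchar(intron_seq)
  if (substr(intron_seq, len - 1, len) != "AG") {
    abort("intron must end with the acceptor dinucleotide AG")
  }
  if (window[1] < 1 || window[2] > len) abort("window outside intron")
  offsets <- seq.int(window[1], window[2])
  bases <- vapply(offsets, function(o) base_at_offset(intron_seq, o), character(1))
  a_off <- offsets[bases == "A"]
  if (length(a_off) == 0) {
    return(tibble(offset = integer(), score = numeric(), rank = integer()))
  }
  score1 <- function(o) {
    s <- 0
    if (is_pyrimidine(base_at_offset(intron_seq, o + 3L))) s <- s + 0.25
    if (identical(base_at_offset(intron_seq, o + 2L), "T")) s <- s + 0.5
    if (is_pyrimidine(base_at_offset(intron_seq, o - 1L))) s <- s + 0.25
    s
  }
  out <- tibble(offset = a_off, score = vapply(a_off, score1, numeric(1)))
  out <- arrange(out, desc(.data$score), .data$offset)
  out$rank <- seq_len(nrow(out))
  out
}

#' Call whether a variant disrupts the branchpoint
#'
#' The branchpoint is disrupted when the variant converts the top-ranked
#' candidate adenosine to a non-A base (for the locus that motivated this
#' package: A to C on the transcript, i.e. T to G on the sense strand of a
#' minus-strand gene). When disrupted, the best remaining candidate (the
#' destroyed position excluded) is reported as the alternative branchpoint.
#'
#' @param candidates Output of [enumerate_branchpoints()].
#' @param variant_offset Acceptor-side offset of the variant.
#' @param ref,alt Transcript-orientation alleles.
#' @return List with `disrupted` (logical) and `alt_bp` (one-row tibble or
#'   `NULL`).
#' @export
assess_variant_effect <- function(candidates, variant_offset, ref, alt) {
  if (nrow(candidates) == 0) {
    return(list(disrupted = FALSE, alt_bp = NULL))
  }
  top <- candidates[1, ]
  disrupted <- top$offset == variant_offset && ref == "A" && alt != "A"
  alt_bp <- NULL
  if (disrupted) {
    rest <- filter(candidates, .data$offset != variant_offset)
    if (nrow(rest) > 0) alt_bp <- rest[1, ]
  }
  list(disrupted = disrupted, alt_bp = alt_bp)
}

#' Scan upstream of a disrupted branchpoint for a cryptic 3' acceptor
#'
#' Walks from the disrupted branchpoint toward the intron 5' end
#' (increasing offsets) and reports the nearest AG dinucleotide; splicing
#' at that AG leaves every intronic base 3' of it - through the intron end
#' - retained in the message. The retained segment therefore abuts the
#' downstream exon and never includes the cryptic AG itself. No minimal
#' branchpoint-to-acceptor spacing is enforced: the spacing is reported
#' and callers may filter.
#'
#' @param intron_seq Intron sequence in transcript orientation.
#' @param bp_offset Offset of the disrupted branchpoint adenosine.
#' @return A tibble with `acceptor_offset` (offset of the 3'-most base,
#'   the G, of the cryptic AG; `NA` when no upstream AG exists),
#'   `retained_len`, and `gap` (acceptor minus branchpoint offset).
#' @export
scan_cryptic_acceptor <- function(intron_seq, bp_offset) {
  intron_seq <- toupper(intron_seq)
  len <- nchar(intron_seq)
  absent <- tibble(acceptor_offset = NA_integer_, retained_len = NA_integer_,
                   gap = NA_integer_)
  if (bp_offset + 1L > len - 1L) return(absent)
  for (o in seq.int(bp_offset + 1L, len - 1L)) {
    if (identical(base_at_offset(intron_seq, o), "G") &&
        identical(base_at_offset(intron_seq, o + 1L), "A")) {
      return(tibble(
        acceptor_offset = o, retained_len = o - 1L, gap = o - bp_offset
      ))
    }
  }
  absent
}

#' Run the full branchpoint analysis on a gene model
#'
#' Enumerates branchpoint candidates in the focal intron, calls the
#' variant's effect, scans for the cryptic acceptor when the branchpoint
#' is disrupted, and predicts the resulting isoform set: canonical only
#' when splicing is intact; canonical plus partial and full retention when
#' the branchpoint is lost and a cryptic AG exists; canonical plus full
#' retention when no upstream AG can rescue splicing.
#'
#' @param model A [gene_model()] carrying sequence and a variant.
#' @param window Branchpoint search window (offsets).
#' @return An object of class `splice_call`: a list with `candidates`,
#'   `primary_bp`, `variant_offset`, `disrupted`, `alt_bp`,
#'   `cryptic_acceptor`, `retained_len`, `acceptor_gap`,
#'   `predicted_isoforms`.
#' @export
splice_scan <- function(model, window = c(18L, 44L)) {
  if (is.null(model$variant)) abort("gene model carries no variant")
  iseq <- intron_seq_tx(model, model$focal_intron)
  loc <- to_transcript_coords(model, model$variant$pos)
  if (loc$type != "intronic" || loc$index != model$focal_intron) {
    abort("variant not in the analyzed intron")
  }
  ref_tx <- if (model$strand == "-") revcomp(model$variant$ref) else model$variant$ref
  alt_tx <- if (model$strand == "-") revcomp(model$variant$alt) else model$variant$alt

  cands <- enumerate_branchpoints(iseq, window = window)
  eff <- assess_variant_effect(cands, loc$offset, ref_tx, alt_tx)
  acceptor <- tibble(acceptor_offset = NA_integer_, retained_len = NA_integer_,
                     gap = NA_integer_)
  isoforms <- "canonical"
  if (eff$disrupted) {
    acceptor <- scan_cryptic_acceptor(iseq, loc$offset)
    isoforms <- if (is.na(acceptor$acceptor_offset)) {
      c("canonical", "full_retention")
    } else {
      c("canonical", "partial_retention", "full_retention")
    }
  }
  structure(
    list(
      candidates = cands,
      primary_bp = if (nrow(cands) > 0) cands[1, ] else NULL,
      variant_offset = loc$offset,
      ref_tx = ref_tx, alt_tx = alt_tx,
      disrupted = eff$disrupted, alt_bp = eff$alt_bp,
      cryptic_acceptor = acceptor$acceptor_offset,
      retained_len = acceptor$retained_len,
      acceptor_gap = acceptor$gap,
      predicted_isoforms = isoforms
    ),
    class = "splice_call"
  )
}

#' @export
print.splice_call <- function(x, ...) {
  cat(sprintf(
    "<splice_call> variant offset %d, disrupted: %s\n", x$variant_offset,
    x$disrupted
  ))
  if (x$disrupted) {
    cat(sprintf(
      "  cryptic acceptor at offset %s (gap %s nt), retained segment %s nt\n",
      x$cryptic_acceptor, x$acceptor_gap, x$retained_len
    ))
  }
  cat("  predicted isoforms:", paste(x$predicted_isoforms, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn splice_scan Candidate table plus call columns as a tibble.
#' @param x A `splice_call`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.splice_call <- function(x, ...) {
  mutate(
    x$candidates,
    is_variant_site = .data$offset == x$variant_offset,
    disrupted = x$disrupted
  )
}

#' Predicted isoform interval models
#'
#' Expands a splice call into genomic exon-block models for each predicted
#' isoform: `canonical` (the annotated exons), `partial_retention` (the
#' retained 3'-terminal intron segment fused to the downstream exon) and
#' `full_retention` (the whole focal intron retained, fusing the flanking
#' exons). Retention isoforms are emitted only when the call is disrupted.
#'
#' @param model A [gene_model()].
#' @param call A `splice_call` from [splice_scan()].
#' @return A tibble of exon blocks with `isoform`, `chrom`, `start`,
#'   `end` (0-based half-open, ascending within isoform).
#' @export
predict_isoforms <- function(model, call) {
  canonical <- mutate(model$exons, isoform = "canonical")
  out <- canonical
  iv <- intron_interval_tx(model, model$focal_intron)
  if (call$disrupted) {
    if (!is.na(call$retained_len)) {
      ret <- if (model$strand == "-") {
        list(start = iv$start, end = iv$start + call$retained_len)
      } else {
        list(start = iv$end - call$retained_len, end = iv$end)
      }
      partial <- merge_adjacent_blocks(bind_rows(
        model$exons, tibble(start = ret$start, end = ret$end)
      ))
      out <- bind_rows(out, mutate(partial, isoform = "partial_retention"))
    }
    full <- merge_adjacent_blocks(bind_rows(
      model$exons, tibble(start = iv$start, end = iv$end)
    ))
    out <- bind_rows(out, mutate(full, isoform = "full_retention"))
  }
  out <- select(out, "isoform", "start", "end")
  out$chrom <- model$chrom
  arrange(out[, c("isoform", "chrom", "start", "end")], .data$isoform, .data$start)
}

merge_adjacent_blocks <- function(blocks) {
  blocks <- arrange(blocks, .data$start)
  ir <- IRanges::reduce(IRanges::IRanges(blocks$start + 1L, blocks$end))
  tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Write predicted isoforms as GTF
#'
#' @param isoforms Tibble from [predict_isoforms()].
#' @param path Output path.
#' @param strand Strand of the gene.
#' @param gene_id `gene_id` attribute value.
#' @return `path`, invisibly.
#' @export
write_isoforms_gtf <- function(isoforms, path, strand = "-", gene_id = "GENE") {
  gr <- GenomicRanges::GRanges(
    seqnames = isoforms$chrom,
    ranges = IRanges::IRanges(isoforms$start + 1L, isoforms$end),
    strand = strand
  )
  gr$type <- "exon"
  gr$gene_id <- gene_id
  gr$transcript_id <- paste0(gene_id, ".", isoforms$isoform)
  rtracklayer::export(gr, path, format = "GTF")
  invisible(path)
}
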