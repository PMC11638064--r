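# Alignment and read I/O. Reading goes through Rsamtools/GenomicAlignments
# (SAM text is converted with asBam first); SAM text writing is done here
# because Bioconductor offers no SAM text writer.

#' Write alignments as SAM
#'
#' @param alignments Tibble with `qname`, `flag`, `rname`, `pos`
#'   (1-based), `mapq`, `cigar`, `seq`, `qual`.
#' @param sq Named integer vector of reference lengths (name = contig).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, sq, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (nm in names(sq)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, as.integer(sq[[nm]])), con)
  }
  if (nrow(alignments) > 0) {
    writeLines(sprintf(
      "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
      alignments$qname, alignments$flag, alignments$rname, alignments$pos,
      alignments$mapq, alignments$cigar, alignments$seq, alignments$qual
    ), con)
  }
  invisible(path)
}

#' Read alignments from SAM or BAM into a tibble
#'
#' @param path SAM or BAM file.
#' @return Tibble with `qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`,
#'   `seq`, `qual`.
#' @export
read_alignments <- function(path) {
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else {
    path
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
  )
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  tibble(
    qname = x$qname,
    flag = as.integer(x$flag),
    rname = as.character(x$rname),
    pos = as.integer(x$pos),
    mapq = as.integer(x$mapq),
    cigar = x$cigar,
    seq = as.character(x$seq),
    qual = as.character(x$qual)
  )
}

#' Write reads as FASTQ
#'
#' Read sequences are emitted as sequenced (transcript orientation):
#' reverse-strand alignments are reverse-complemented out of reference
#' orientation.
#'
#' @param alignments Alignment tibble with materialized `seq`/`qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(alignments, path) {
  if (any(alignments$seq == "*")) {
    abort("alignments carry no sequences (simulated with with_seq = FALSE?)")
  }
  seqs <- Biostrings::DNAStringSet(alignments$seq)
  rev <- bitwAnd(alignments$flag, 16L) != 0L
  seqs[rev] <- Biostrings::reverseComplement(seqs[rev])
  q <- Biostrings::BStringSet(alignments$qual)
  q[rev] <- Biostrings::reverse(q[rev])
  out <- Biostrings::QualityScaledDNAStringSet(
    seqs, Biostrings::PhredQuality(q)
  )
  names(out) <- alignments$qname
  Biostrings::writeQualityScaledXStringSet(out, path)
  invisible(path)
}

# decode SAM flag bits into the named filters used by the coverage profile
flag_has <- function(flag, what) {
  bit <- c(unmapped = 4L, secondary = 256L, qcfail = 512L, duplicate = 1024L,
           supplementary = 2048L)[[what]]
  bitwAnd(flag, bit) != 0L
}

is_primary <- function(flag) {
  !flag_has(flag, "secondary") & !flag_has(flag, "supplementary")
}
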