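# Genomic coordinate system for a gene/pseudogene pair.
# Internal convention: 0-based half-open genomic intervals; HGVS and VCF I/O
# are 1-based; BED is 0-based half-open. All splice logic runs on the
# transcript-orientation sequence (reverse complement for minus-strand genes).

#' Construct a gene model
#'
#' Holds the exon/intron structure of a single-isoform gene, the candidate
#' intronic variant, and (optionally) the coordinates of a paralogous
#' pseudogene sharing the same chromosome. Exons are 0-based half-open
#' genomic intervals in ascending order; for a minus-strand gene the
#' transcript order is the reverse of the genomic order.
#'
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with `start`, `end` (0-based half-open),
#'   non-overlapping and sorted by `start`.
#' @param genome_seq Optional chromosome sequence (single character string)
#'   used to validate splice dinucleotides and drive sequence-based steps.
#' @param variant Optional list `list(pos =, ref =, alt =)` with the
#'   0-based genomic position and the sense-strand ref/alt bases.
#' @param focal_intron Transcript-order index of the retention-prone intron.
#' @param paralog Optional list describing the pseudogene:
#'   `list(start =, end =, diff_sites =, variant_homolog =)` (0-based).
#' @param validate Check invariants (exon ordering, GT..AG intron ends in
#'   transcript orientation, variant inside the focal intron).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(chrom, strand, exons, genome_seq = NULL, variant = NULL,
                       focal_intron = 1L, paralog = NULL, validate = TRUE) {
  strand <- match.arg(strand, c("+", "-"))
  exons <- as_tibble(exons)[, c("start", "end")]
  n <- nrow(exons)
  if (n < 2) abort("a gene model needs at least two exons")
  introns <- tibble(
    start = exons$end[-n],
    end = exons$start[-1]
  )
  model <- structure(
    list(
      chrom = chrom, strand = strand, exons = exons, introns = introns,
      genome_seq = genome_seq, variant = variant,
      focal_intron = as.integer(focal_intron), paralog = paralog
    ),
    class = "gene_model"
  )
  if (validate) validate_gene_model(model)
  model
}

validate_gene_model <- function(model) {
  ex <- model$exons
  if (any(ex$end <= ex$start)) abort("exons must have positive width")
  if (is.unsorted(ex$start, strictly = TRUE) || any(ex$start[-1] < ex$end[-nrow(ex)])) {
    abort("exons must be sorted and non-overlapping")
  }
  ni <- nrow(model$introns)
  if (model$focal_intron < 1 || model$focal_intron > ni) {
    abort("focal_intron out of range")
  }
  if (!is.null(model$genome_seq)) {
    for (i in seq_len(ni)) {
      s <- intron_seq_tx(model, i)
      if (substr(s, 1, 2) != "GT" || substr(s, nchar(s) - 1, nchar(s)) != "AG") {
        abort(sprintf("intron %d does not start GT / end AG in transcript orientation", i))
      }
    }
  }
  if (!is.null(model$variant)) {
    iv <- intron_interval_tx(model, model$focal_intron)
    if (model$variant$pos < iv$start || model$variant$pos >= iv$end) {
      abort("variant_site must lie inside the focal intron")
    }
    if (!is.null(model$genome_seq)) {
      base <- seq_at(model, model$variant$pos, model$variant$pos + 1)
      if (base != model$variant$ref) {
        abort(sprintf("reference base %s does not match variant ref %s", base, model$variant$ref))
      }
    }
  }
  invisible(model)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf(
    "<gene_model> %s:%d-%d (%s), %d exons, focal intron %d%s\n",
    x$chrom, min(x$exons$start), max(x$exons$end), x$strand,
    nrow(x$exons), x$focal_intron,
    if (is.null(x$paralog)) "" else ", with paralog"
  ))
  invisible(x)
}

n_introns <- function(model) nrow(model$introns)

# transcript-order index -> genomic-order row
tx_to_genomic_index <- function(model, i, what = c("intron", "exon")) {
  what <- match.arg(what)
  n <- if (what == "intron") n_introns(model) else nrow(model$exons)
  if (model$strand == "+") i else n - i + 1L
}

intron_interval_tx <- function(model, i) {
  as.list(model$introns[tx_to_genomic_index(model, i, "intron"), ])
}

exon_interval_tx <- function(model, k) {
  as.list(model$exons[tx_to_genomic_index(model, k, "exon"), ])
}

seq_at <- function(model, start, end) {
  if (is.null(model$genome_seq)) abort("gene model carries no sequence")
  substr(model$genome_seq, start + 1, end)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Transcript-orientation sequence of an intron
#'
#' @param model A [gene_model()].
#' @param i Transcript-order intron index (defaults to the focal intron).
#' @return Character string, 5' to 3' on the transcript.
#' @export
intron_seq_tx <- function(model, i = model$focal_intron) {
  iv <- intron_interval_tx(model, i)
  s <- seq_at(model, iv$start, iv$end)
  if (model$strand == "-") revcomp(s) else s
}

#' Parse an HGVS-style intronic acceptor-side variant name
#'
#' Understands the `c.<exonpos>-<offset><ref>><alt>` form used for variants
#' upstream of an exon's first base (for example `"c.1225-34C>A"`). The
#' alleles are in transcript orientation. Donor-side (`+` offset) names are
#' rejected: the analysis is specific to the acceptor-side branchpoint
#' window.
#'
#' @param hgvs HGVS-like string.
#' @return A tibble with `exon_pos`, `offset`, `ref`, `alt`.
#' @examples
#' parse_hgvs_offset("c.1225-34C>A")
#' @export
parse_hgvs_offset <- function(hgvs) {
  stopifnot(is.character(hgvs), length(hgvs) == 1)
  if (grepl("^c\\.\\d+\\+", hgvs)) {
    abort(sprintf("donor-side offsets unsupported: '%s'", hgvs))
  }
  m <- stringr::str_match(hgvs, "^c\\.(\\d+)-(\\d+)([ACGT])>([ACGT])$")
  if (is.na(m[1, 1])) {
    bad <- sub("^c\\.", "", hgvs)
    abort(sprintf("malformed HGVS string: offending token '%s'", bad))
  }
  offset <- as.integer(m[1, 3])
  if (offset < 1) abort("intronic offset must be >= 1")
  tibble(
    exon_pos = as.integer(m[1, 2]), offset = offset,
    ref = m[1, 4], alt = m[1, 5]
  )
}

#' Convert a genomic position to transcript coordinates
#'
#' For an intronic position, returns the HGVS-style acceptor-side offset:
#' the 1-based distance upstream of the downstream exon's first base, in
#' transcript orientation (offset 1 is the intron base adjacent to the
#' exon). Strand-aware: minus-strand genes count toward genomically lower
#' coordinates.
#'
#' @param model A [gene_model()].
#' @param pos 0-based genomic position inside the gene span.
#' @return A one-row tibble with `type` (`"exonic"`/`"intronic"`), `index`
#'   (transcript-order exon or intron number) and `offset` (`NA` for
#'   exonic positions).
#' @export
to_transcript_coords <- function(model, pos) {
  span <- c(min(model$exons$start), max(model$exons$end))
  if (pos < span[1] || pos >= span[2]) abort("position outside gene span")
  for (k in seq_len(nrow(model$exons))) {
    e <- exon_interval_tx(model, k)
    if (pos >= e$start && pos < e$end) {
      return(tibble(type = "exonic", index = k, offset = NA_integer_))
    }
  }
  for (i in seq_len(n_introns(model))) {
    iv <- intron_interval_tx(model, i)
    if (pos >= iv$start && pos < iv$end) {
      offset <- if (model$strand == "-") pos - iv$start + 1L else iv$end - pos
      return(tibble(type = "intronic", index = i, offset = as.integer(offset)))
    }
  }
  abort("position not located")  # unreachable for contiguous models
}

#' Convert an intronic offset back to a genomic position
#'
#' Inverse of [to_transcript_coords()] for intronic positions.
#'
#' @param model A [gene_model()].
#' @param offset 1-based intronic offset (distance upstream of the
#'   downstream exon in transcript orientation).
#' @param intron Transcript-order intron index.
#' @return 0-based genomic position.
#' @export
offset_to_genomic <- function(model, offset, intron = model$focal_intron) {
  iv <- intron_interval_tx(model, intron)
  len <- iv$end - iv$start
  if (offset < 1 || offset > len) abort("offset outside intron")
  if (model$strand == "-") iv$start + offset - 1L else iv$end - offset
}

#' Build the quantification region set
#'
#' Emits the named regions the coverage analysis is run on: the exons
#' flanking the focal intron (`exon_up` upstream in transcript
#' orientation, `exon_down` downstream), the full focal intron, the short
#' 3'-terminal window of the intron adjacent to the downstream exon, the
#' remainder of the intron, the whole gene span and (when present) the
#' paralog span. `intron_short_window` and `intron_rest` partition
#' `intron_full`.
#'
#' @param model A [gene_model()].
#' @param short_window_len Length in nt of the short window. Defaults to
#'   the retained-segment length predicted by [splice_scan()] when the
#'   model carries sequence and a variant, else 40.
#' @return A tibble with `name`, `chrom`, `start`, `end`, `role`.
#' @export
build_region_set <- function(model, short_window_len = NULL) {
  if (is.null(short_window_len)) {
    short_window_len <- tryCatch({
      call <- splice_scan(model)
      if (!is.na(call$retained_len)) call$retained_len else 40L
    }, error = function(e) 40L)
  }
  short_window_len <- as.integer(short_window_len)
  if (short_window_len <= 0) abort("short_window_len must be positive")
  iv <- intron_interval_tx(model, model$focal_intron)
  ilen <- iv$end - iv$start
  if (short_window_len > ilen) abort("short_window_len exceeds the focal intron length")

  up <- exon_interval_tx(model, model$focal_intron)
  down <- exon_interval_tx(model, model$focal_intron + 1L)
  if (model$strand == "-") {
    sw <- list(start = iv$start, end = iv$start + short_window_len)
    rest <- list(start = sw$end, end = iv$end)
  } else {
    sw <- list(start = iv$end - short_window_len, end = iv$end)
    rest <- list(start = iv$start, end = sw$start)
  }
  regions <- tibble(
    name = c("exon_up", "exon_down", "intron_full", "intron_short_window",
             "intron_rest", "gene"),
    chrom = model$chrom,
    start = c(up$start, down$start, iv$start, sw$start, rest$start,
              min(model$exons$start)),
    end = c(up$end, down$end, iv$end, sw$end, rest$end, max(model$exons$end)),
    role = c("exon_up", "exon_down", "intron_full", "intron_short_window",
             "intron_rest", "gene")
  )
  if (!is.null(model$paralog)) {
    regions <- bind_rows(regions, tibble(
      name = "paralog", chrom = model$chrom,
      start = model$paralog$start, end = model$paralog$end, role = "paralog"
    ))
  }
  regions
}

#' Write / read a region set as BED
#'
#' Round-trips the tibble produced by [build_region_set()] through the
#' standard 0-based half-open BED format (names preserved in column 4).
#'
#' @param regions Region tibble.
#' @param path Output path.
#' @return `path`, invisibly (writer); the region tibble (reader).
#' @export
write_regions_bed <- function(regions, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    name = regions$name
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_regions_bed
#' @export
read_regions_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble(
    name = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    role = gr$name
  )
}

#' Write / read a gene model's exon structure as GTF
#'
#' @param model A [gene_model()].
#' @param path Output path.
#' @param gene_id Value of the `gene_id` attribute.
#' @return `path`, invisibly (writer); a [gene_model()] without sequence
#'   or variant (reader).
#' @export
write_gene_gtf <- function(model, path, gene_id = "GENE") {
  n <- nrow(model$exons)
  gr <- GenomicRanges::GRanges(
    seqnames = model$chrom,
    ranges = IRanges::IRanges(start = model$exons$start + 1L, end = model$exons$end),
    strand = model$strand
  )
  gr$type <- "exon"
  gr$gene_id <- gene_id
  gr$transcript_id <- paste0(gene_id, ".t1")
  rtracklayer::export(gr, path, format = "GTF")
  invisible(path)
}

#' @rdname write_gene_gtf
#' @param focal_intron Focal intron index to set on the imported model.
#' @export
read_gene_gtf <- function(path, focal_intron = 1L) {
  gr <- rtracklayer::import(path, format = "GTF")
  gr <- gr[gr$type == "exon"]
  ord <- order(GenomicRanges::start(gr))
  gr <- gr[ord]
  gene_model(
    chrom = as.character(GenomicRanges::seqnames(gr))[1],
    strand = as.character(GenomicRanges::strand(gr))[1],
    exons = tibble(
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr)
    ),
    focal_intron = focal_intron,
    validate = FALSE
  )
}

#' Write / read the candidate variant as a one-record VCF
#'
#' @param model A [gene_model()] carrying a variant.
#' @param path Output path.
#' @param id Variant identifier.
#' @return `path` invisibly (writer); a tibble with `chrom`, `pos`
#'   (0-based), `ref`, `alt` (reader).
#' @export
write_variant_vcf <- function(model, path, id = "variant") {
  if (is.null(model$variant)) abort("gene model carries no variant")
  v <- model$variant
  vr <- VariantAnnotation::VRanges(
    seqnames = model$chrom,
    ranges = IRanges::IRanges(start = v$pos + 1L, width = 1L),
    ref = v$ref, alt = v$alt, sampleNames = "synthetic"
  )
  names(vr) <- id
  suppressWarnings(VariantAnnotation::writeVcf(vr, path))
  invisible(path)
}

#' @rdname write_variant_vcf
#' @export
read_variant_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  tibble(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr) - 1L,
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = vapply(VariantAnnotation::alt(vcf), function(a) as.character(a)[1], character(1))
  )
}
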