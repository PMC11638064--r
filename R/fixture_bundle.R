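# One-call generation of a complete on-disk fixture bundle.

#' Configuration for a fixture bundle or pipeline run
#'
#' Collects the per-stage parameters of the synthetic world. Every
#' argument defaults to the stated analysis conditions (see the
#' individual generators). Randomness is seed-scoped: each stage draws
#' from a sub-seed derived from `seed`, and the reference gets its own
#' `ref_seed` (derived from `seed` unless pinned), so changing `seed`
#' changes reads but can leave the reference untouched.
#'
#' @param seed Master seed.
#' @param ref_seed Optional pinned seed for the reference pair.
#' @param reference List of [build_paralog_pair()] arguments.
#' @param cohort List of [cohort_spec()] arguments.
#' @param mode Read mode, `"long"` or `"short"`.
#' @param short_window_len Short-window length for [build_region_set()].
#' @param gcase List of [simulate_gcase_cohort()] arguments.
#' @param methylation List of [simulate_methylation_calls()] arguments.
#' @param swap_max_reads Read cap for the allele-swap control stage.
#' @param window Branchpoint search window.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, ref_seed = NULL, reference = list(),
                            cohort = list(), mode = "long",
                            short_window_len = NULL, gcase = list(),
                            methylation = list(), swap_max_reads = 50L,
                            window = c(18L, 44L)) {
  structure(
    list(
      seed = as.integer(seed), ref_seed = ref_seed, reference = reference,
      cohort = cohort, mode = mode, short_window_len = short_window_len,
      gcase = gcase, methylation = methylation,
      swap_max_reads = swap_max_reads, window = window
    ),
    class = "pipeline_config"
  )
}

config_stages <- function(config) {
  seed <- config$seed
  ref_seed <- config$ref_seed %||% derive_seed(seed, 11L)
  pair <- do.call(build_paralog_pair, c(config$reference, list(seed = ref_seed)))
  cohort_args <- config$cohort
  if (is.null(cohort_args$seed)) cohort_args$seed <- derive_seed(seed, 12L)
  spec <- do.call(cohort_spec, cohort_args)
  list(pair = pair, spec = spec, ref_seed = ref_seed)
}

#' Write a complete synthetic fixture bundle
#'
#' Generates and writes every input the analysis consumes - reference
#' FASTA, gene model GTF, region BED, variant VCF, reads FASTQ, truth
#' SAM, truth/sample/activity/methylation TSVs - plus a manifest of md5
#' checksums. Regeneration with the same configuration reproduces the
#' checksums byte for byte.
#'
#' @param outdir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return The manifest tibble (`file`, `md5`), invisibly written to
#'   `manifest.tsv`.
#' @export
write_fixture_bundle <- function(outdir, config = pipeline_config()) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (file.access(outdir, 2) != 0) abort(sprintf("directory not writable: %s", outdir))
  st <- config_stages(config)
  pair <- st$pair
  model <- pair$model
  sim <- simulate_cohort_reads(pair, st$spec, mode = config$mode)
  regions <- build_region_set(model, config$short_window_len)
  activity <- do.call(simulate_gcase_cohort,
                      c(config$gcase, list(seed = derive_seed(config$seed, 13L))))
  meth <- do.call(simulate_methylation_calls,
                  c(config$methylation, list(seed = derive_seed(config$seed, 14L))))

  p <- function(f) file.path(outdir, f)
  wrote <- character(0)
  put <- function(f, writer) {
    tryCatch(writer(p(f)), error = function(e) {
      abort(sprintf("failed writing %s: %s", p(f), conditionMessage(e)))
    })
    wrote <<- c(wrote, f)
  }
  sq <- setNames(nchar(pair$chrom_seq), model$chrom)
  put("reference.fasta", function(f) write_reference_fasta(pair, f))
  put("gene.gtf", function(f) write_gene_gtf(model, f, gene_id = "SYNGENE"))
  put("regions.bed", function(f) write_regions_bed(regions, f))
  put("variant.vcf", function(f) write_variant_vcf(model, f, id = "synvar"))
  put("reads.fastq", function(f) write_fastq(sim$alignments, f))
  put("truth.sam", function(f) write_sam(sim$alignments, sq, f))
  put("truth_reads.tsv", function(f) readr::write_tsv(sim$truth, f))
  put("samples.tsv", function(f) readr::write_tsv(sim$samples, f))
  put("activity.tsv", function(f) readr::write_tsv(activity, f))
  put("methylation.tsv", function(f) readr::write_tsv(meth, f))

  manifest <- tibble(
    file = wrote,
    md5 = unname(tools::md5sum(file.path(outdir, wrote)))
  )
  readr::write_tsv(manifest, p("manifest.tsv"))
  manifest
}
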