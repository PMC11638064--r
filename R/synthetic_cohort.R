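# Diploid cohort read simulation with genotype-dependent intron retention.
# Risk allele = G on the sense strand (C on the transcript, disrupting the
# branchpoint); nonrisk = T (intact branchpoint A). Retention-class reads are
# drawn only from haplotypes whose allele has non-zero retention rates, which
# is what makes haplotype purity on retention reads an end-to-end check.

#' Specify a synthetic cohort
#'
#' Defaults state the world the analysis was designed for: the genotype
#' counts of the eight-sample discovery cohort (1 GG, 4 GT, 3 TT), risk
#' haplotypes emitting partial- and full-retention transcripts at 0.15 and
#' 0.05 (placeholders chosen for comfortable desk-scale power, not
#' measured tissue values), nonrisk haplotypes fully canonical, a mean of
#' 200 reads over the gene per sample, a 1% per-base substitution error
#' rate, and 0.2/kb 5' truncation in long mode (3'-biased coverage, as in
#' degraded poly(A)-anchored long reads).
#'
#' @param n_per_genotype Named counts for `GG`, `GT`, `TT`.
#' @param retention_rates List with `risk` and `nonrisk` elements, each
#'   `c(partial =, full =)` with `partial + full <= 1`.
#' @param depth_per_sample Mean reads per sample over the gene (Poisson).
#' @param read_length `c(mean =, sd =)` fragment length for short mode.
#' @param trunc_per_kb 5' truncation probability per kb of transcript
#'   (long mode).
#' @param error_rate Per-base substitution probability.
#' @param barcode_whitelist Character vector of equal-length cell
#'   barcodes; generated (8 barcodes of 16 nt) when `NULL`.
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_genotype = c(GG = 1L, GT = 4L, TT = 3L),
                        retention_rates = list(
                          risk = c(partial = 0.15, full = 0.05),
                          nonrisk = c(partial = 0, full = 0)
                        ),
                        depth_per_sample = 200,
                        read_length = c(mean = 300, sd = 60),
                        trunc_per_kb = 0.2,
                        error_rate = 0.01,
                        barcode_whitelist = NULL,
                        seed = 1L) {
  stopifnot(all(c("GG", "GT", "TT") %in% names(n_per_genotype)),
            all(n_per_genotype >= 0))
  for (al in c("risk", "nonrisk")) {
    r <- retention_rates[[al]]
    if (any(r < 0) || sum(r) > 1) {
      abort(sprintf("retention rates for '%s' must be >= 0 and sum to <= 1", al))
    }
  }
  if (is.null(barcode_whitelist)) {
    barcode_whitelist <- generate_barcode_whitelist(seed = derive_seed(seed, 99))
  }
  structure(
    list(
      n_per_genotype = n_per_genotype, retention_rates = retention_rates,
      depth_per_sample = depth_per_sample, read_length = read_length,
      trunc_per_kb = trunc_per_kb, error_rate = error_rate,
      barcode_whitelist = barcode_whitelist, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Generate a cell-barcode whitelist
#'
#' Random equal-length barcodes kept pairwise at Hamming distance of at
#' least `min_dist`, so one-mismatch demultiplexing is unambiguous.
#'
#' @param n Number of barcodes.
#' @param len Barcode length in nt.
#' @param min_dist Minimum pairwise Hamming distance.
#' @param seed RNG seed (`NULL` uses the current RNG state).
#' @return Character vector of barcodes.
#' @export
generate_barcode_whitelist <- function(n = 8L, len = 16L, min_dist = 5L, seed = NULL) {
  gen <- function() {
    out <- character(0)
    while (length(out) < n) {
      cand <- rand_dna(len)
      if (all(vapply(out, function(b) hamming(b, cand) >= min_dist, logical(1)))) {
        out <- c(out, cand)
      }
    }
    out
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# --- isoform block layout helpers (transcript <-> genomic) ---

iso_layout <- function(blocks, strand) {
  blocks <- arrange(as_tibble(blocks), .data$start)
  if (strand == "-") blocks <- blocks[rev(seq_len(nrow(blocks))), ]
  w <- blocks$end - blocks$start
  cum <- cumsum(w)
  list(
    start = blocks$start, end = blocks$end, w = w,
    cum_before = c(0, head(cum, -1)), len = sum(w), strand = strand
  )
}

# genomic blocks (ascending, 0-based half-open matrix) covered by tx [a, b]
tx_to_genomic_blocks <- function(lay, a, b) {
  gs <- ge <- numeric(0)
  for (k in seq_along(lay$w)) {
    lo <- lay$cum_before[k] + 1
    hi <- lay$cum_before[k] + lay$w[k]
    aa <- max(a, lo); bb <- min(b, hi)
    if (aa > bb) next
    qa <- aa - lay$cum_before[k]; qb <- bb - lay$cum_before[k]
    if (lay$strand == "-") {
      gs <- c(gs, lay$end[k] - qb); ge <- c(ge, lay$end[k] - qa + 1)
    } else {
      gs <- c(gs, lay$start[k] + qa - 1); ge <- c(ge, lay$start[k] + qb)
    }
  }
  ord <- order(gs)
  cbind(start = gs[ord], end = ge[ord])
}

genomic_pos_to_tx <- function(lay, gpos) {
  for (k in seq_along(lay$w)) {
    if (gpos >= lay$start[k] && gpos < lay$end[k]) {
      q <- if (lay$strand == "-") lay$end[k] - gpos else gpos - lay$start[k] + 1
      return(lay$cum_before[k] + q)
    }
  }
  NA_real_
}

cigar_from_blocks <- function(bl) {
  w <- bl[, "end"] - bl[, "start"]
  if (nrow(bl) == 1) return(paste0(w, "M"))
  gaps <- bl[-1, "start"] - bl[-nrow(bl), "end"]
  paste0(paste0(w[-length(w)], "M", gaps, "N", collapse = ""), w[length(w)], "M")
}

#' Simulate cohort reads with genotype-dependent retention
#'
#' Draws, per sample, reads from the canonical, partial-retention and
#' full-retention isoforms with allele-conditional proportions; the
#' retention geometry comes from the package's own branchpoint analysis
#' ([splice_scan()] then [predict_isoforms()]), so the generator and the
#' caller share one definition of the retained segment. Every read records
#' its truth (sample, haplotype, isoform class, cell barcode) both in the
#' truth table and in its structured name
#' (`sample|haplotype|isoform|barcode|serial`). Alignments are error-free
#' in coordinates (substitution errors touch bases only), primary, and
#' MAPQ 60, so downstream stages run without an external aligner.
#'
#' @param pair A `paralog_pair` (or a [gene_model()] with sequence and
#'   variant).
#' @param spec A [cohort_spec()].
#' @param mode `"long"` (full-length with 5' truncation) or `"short"`
#'   (fragments).
#' @param with_seq Materialize read sequences and qualities; `FALSE`
#'   skips them (SAM `*`), leaving coordinates identical for the same
#'   seed - useful for coverage-only simulations.
#' @return An object of class `cohort_sim`: list with `alignments`
#'   (tibble: qname, flag, rname, pos, mapq, cigar, seq, qual, sample,
#'   genotype), `truth`, `samples`, `model`, `call`, `spec`, `mode`.
#' @export
simulate_cohort_reads <- function(pair, spec, mode = c("long", "short"),
                                  with_seq = TRUE) {
  mode <- match.arg(mode)
  model <- if (inherits(pair, "paralog_pair")) pair$model else pair
  call <- splice_scan(model)
  isoforms <- predict_isoforms(model, call)
  classes <- unique(isoforms$isoform)
  needs_partial <- any(vapply(spec$retention_rates, function(r) r[["partial"]] > 0, logical(1)))
  needs_full <- any(vapply(spec$retention_rates, function(r) r[["full"]] > 0, logical(1)))
  if ((needs_partial && !"partial_retention" %in% classes) ||
      (needs_full && !"full_retention" %in% classes)) {
    abort("retention requested but the splice call predicts no retention isoform")
  }
  lays <- lapply(split(isoforms, isoforms$isoform), function(d) {
    iso_layout(d[, c("start", "end")], model$strand)
  })
  var_tx <- lapply(lays, function(l) genomic_pos_to_tx(l, model$variant$pos))

  genos <- rep(c("GG", "GT", "TT"),
               times = c(spec$n_per_genotype[["GG"]], spec$n_per_genotype[["GT"]],
                         spec$n_per_genotype[["TT"]]))
  samples <- tibble(
    sample = sprintf("S%02d", seq_along(genos)), genotype = genos
  )
  hap_alleles <- list(
    GG = c("risk", "risk"), GT = c("risk", "nonrisk"), TT = c("nonrisk", "nonrisk")
  )

  # phase 1: structural draws (counts, haplotypes, classes, intervals)
  structure_draws <- with_seed(derive_seed(spec$seed, 1L), {
    purrr::map2(samples$sample, samples$genotype, function(sm, gt) {
      n <- rpois(1, spec$depth_per_sample)
      if (n == 0) return(NULL)
      allele <- sample(hap_alleles[[gt]], n, replace = TRUE)
      u <- runif(n)
      cls <- character(n)
      for (i in seq_len(n)) {
        r <- spec$retention_rates[[allele[i]]]
        cls[i] <- if (u[i] < r[["partial"]] && "partial_retention" %in% classes) {
          "partial_retention"
        } else if (u[i] < r[["partial"]] + r[["full"]] && "full_retention" %in% classes) {
          "full_retention"
        } else "canonical"
      }
      L <- vapply(cls, function(cl) lays[[cl]]$len, numeric(1))
      if (mode == "long") {
        p_tr <- pmin(1, spec$trunc_per_kb * L / 1000)
        trunc <- runif(n) < p_tr
        a <- ifelse(trunc, floor(runif(n, 1, L + 1)), 1)
        b <- L
      } else {
        fl <- pmax(50, pmin(L, round(rnorm(n, spec$read_length[["mean"]],
                                           spec$read_length[["sd"]]))))
        a <- floor(runif(n, 1, L - fl + 2))
        b <- a + fl - 1
      }
      bc <- sample(spec$barcode_whitelist, n, replace = TRUE)
      tibble(sample = sm, genotype = gt, haplotype = allele, isoform = cls,
             barcode = bc, tx_start = a, tx_end = b)
    })
  })
  truth <- bind_rows(structure_draws)
  if (nrow(truth) > 0) {
    truth$read_id <- sprintf(
      "%s|%s|%s|%s|%06d", truth$sample, truth$haplotype, truth$isoform,
      truth$barcode, seq_len(nrow(truth))
    )
  } else {
    truth$read_id <- character(0)
  }

  # coordinates
  n_reads <- nrow(truth)
  pos <- integer(n_reads); cigar <- character(n_reads)
  blocks_list <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    bl <- tx_to_genomic_blocks(lays[[truth$isoform[i]]], truth$tx_start[i], truth$tx_end[i])
    blocks_list[[i]] <- bl
    pos[i] <- bl[1, "start"] + 1L
    cigar[i] <- cigar_from_blocks(bl)
  }
  truth$covers_variant <- vapply(seq_len(n_reads), function(i) {
    v <- var_tx[[truth$isoform[i]]]
    !is.na(v) && v >= truth$tx_start[i] && v <= truth$tx_end[i]
  }, logical(1))

  seqs <- rep("*", n_reads); quals <- rep("*", n_reads)
  if (with_seq && n_reads > 0) {
    chrom_seq <- model$genome_seq
    risk_base <- model$variant$alt       # sense-strand risk allele (G)
    seqs <- with_seed(derive_seed(spec$seed, 2L), {
      vapply(seq_len(n_reads), function(i) {
        bl <- blocks_list[[i]]
        s <- paste(substr(rep(chrom_seq, nrow(bl)), bl[, "start"] + 1, bl[, "end"]),
                   collapse = "")
        # patch the haplotype allele at the variant site (ref carries nonrisk)
        if (truth$covers_variant[i] && truth$haplotype[i] == "risk") {
          off <- 0
          for (k in seq_len(nrow(bl))) {
            if (model$variant$pos >= bl[k, "start"] && model$variant$pos < bl[k, "end"]) {
              qpos <- off + model$variant$pos - bl[k, "start"] + 1
              substr(s, qpos, qpos) <- risk_base
              break
            }
            off <- off + bl[k, "end"] - bl[k, "start"]
          }
        }
        if (spec$error_rate > 0) {
          L <- nchar(s)
          nerr <- rbinom(1, L, spec$error_rate)
          if (nerr > 0) {
            ep <- sample.int(L, nerr)
            for (p in ep) {
              substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                                substr(s, p, p)), 1)
            }
          }
        }
        s
      }, character(1))
    })
    quals <- strrep("I", nchar(seqs))
  }

  aln <- tibble(
    qname = truth$read_id,
    flag = if (model$strand == "-") 16L else 0L,
    rname = model$chrom,
    pos = pos, mapq = 60L, cigar = cigar, seq = seqs, qual = quals,
    sample = truth$sample, genotype = truth$genotype
  )
  counts <- count(truth, .data$sample, name = "n_reads")
  samples <- left_join(samples, counts, by = "sample")
  samples$n_reads[is.na(samples$n_reads)] <- 0L

  structure(
    list(alignments = aln, truth = truth, samples = samples,
         model = model, call = call, spec = spec, mode = mode),
    class = "cohort_sim"
  )
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf(
    "<cohort_sim> %d samples, %d reads (%s mode)\n",
    nrow(x$samples), nrow(x$truth), x$mode
  ))
  invisible(x)
}

#' Analytic noise calibration for the activity generator
#'
#' Inverts the closed-form OLS slope standard error
#' `se = sigma / sqrt(sum((g - mean(g))^2))` to find the residual sd that
#' yields a stated slope s.e. at given genotype group sizes.
#'
#' @param target_se Desired analytic slope standard error.
#' @param sizes Named group sizes `c(TT =, GT =, GG =)`.
#' @return Residual standard deviation `sigma`.
#' @examples
#' calibrate_activity_noise(0.205, c(TT = 97, GT = 99, GG = 9))
#' @export
calibrate_activity_noise <- function(target_se, sizes = c(TT = 97L, GT = 99L, GG = 9L)) {
  g <- rep(c(0, 1, 2), times = c(sizes[["TT"]], sizes[["GT"]], sizes[["GG"]]))
  target_se * sqrt(sum((g - mean(g))^2))
}

#' Simulate an enzyme-activity cohort
#'
#' Generates one activity value per individual from the linear dosage
#' model `y = intercept + slope * g + N(0, sigma^2)` with `g` the
#' risk-allele dosage. Defaults are the published comparison: group sizes
#' 97 TT / 99 GT / 9 GG, generative slope -0.449 activity units per risk
#' allele, and noise calibrated so the analytic slope s.e. equals 0.205
#' (`sigma` about 1.69). The intercept, 10 umol/l/h, is a typical normal
#' glucocerebrosidase activity on dried blood spots.
#'
#' @param sizes Named genotype group sizes.
#' @param slope Generative dosage slope (activity units per risk allele).
#' @param intercept Mean activity at dosage 0.
#' @param sigma Residual sd; when `NULL`, calibrated from `target_se`.
#' @param target_se Slope s.e. used for calibration when `sigma` is `NULL`.
#' @param seed RNG seed.
#' @return Tibble with `sample_id`, `genotype`, `dosage`, `activity`;
#'   attribute `sigma` records the noise used.
#' @export
simulate_gcase_cohort <- function(sizes = c(TT = 97L, GT = 99L, GG = 9L),
                                  slope = -0.449, intercept = 10,
                                  sigma = NULL, target_se = 0.205,
                                  seed = 1L) {
  stopifnot(all(sizes >= 1))
  sigma <- sigma %||% calibrate_activity_noise(target_se, sizes)
  if (sigma < 0) abort("sigma must be >= 0")
  g <- rep(c(0L, 1L, 2L), times = c(sizes[["TT"]], sizes[["GT"]], sizes[["GG"]]))
  gt <- rep(c("TT", "GT", "GG"), times = c(sizes[["TT"]], sizes[["GT"]], sizes[["GG"]]))
  out <- with_seed(seed, tibble(
    sample_id = sprintf("A%03d", seq_along(g)),
    genotype = gt, dosage = g,
    activity = intercept + slope * g + rnorm(length(g), 0, sigma)
  ))
  attr(out, "sigma") <- sigma
  out
}

#' Simulate per-read methylation calls at the variant-linked CpG
#'
#' Bernoulli methylation per read with allele-specific probabilities,
#' mirroring DNA methylation present on the risk (G) allele and lost on
#' the nonrisk (T) allele.
#'
#' @param p_meth Named methylation probabilities per allele.
#' @param calls_per_allele Named call counts per allele; alleles with
#'   zero calls are absent from the output.
#' @param seed RNG seed.
#' @return Tibble with `read_id`, `allele`, `methylated` (0/1).
#' @export
simulate_methylation_calls <- function(p_meth = c(G = 0.9, T = 0.1),
                                       calls_per_allele = c(G = 500L, T = 500L),
                                       seed = 1L) {
  stopifnot(all(p_meth >= 0 & p_meth <= 1))
  alleles <- names(p_meth)
  with_seed(seed, {
    bind_rows(lapply(alleles, function(al) {
      n <- calls_per_allele[[al]] %||% 0L
      if (n == 0) return(NULL)
      tibble(
        read_id = sprintf("%s_m%05d", al, seq_len(n)),
        allele = al,
        methylated = rbinom(n, 1, p_meth[[al]])
      )
    }))
  })
}
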