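# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and the Bioconductor helpers they use): cigar strings are
# re-parsed by regex, pileups are counted base by base, alignments are
# scored by a hand-written DP, exact tests by enumeration.

# ---- pileup oracle ----

oracle_cigar_tokens <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  lapply(toks, function(t) {
    list(len = as.integer(sub(".$", "", t)), op = sub("^\\d+", "", t))
  })
}

# 1-based reference positions covered by one read (D covered, N not),
# optionally dropping aligned bases with quality below min_baseq
oracle_covered_pos <- function(cigar, pos, qual = NULL, min_baseq = 0) {
  ref <- pos; qi <- 1L; covered <- integer(0)
  for (t in oracle_cigar_tokens(cigar)) {
    if (t$op %in% c("M", "=", "X")) {
      for (j in seq_len(t$len)) {
        ok <- TRUE
        if (!is.null(qual) && qual != "*") {
          ok <- (utf8ToInt(substr(qual, qi, qi)) - 33L) >= min_baseq
        }
        if (ok) covered <- c(covered, ref)
        ref <- ref + 1L; qi <- qi + 1L
      }
    } else if (t$op %in% c("I", "S")) {
      qi <- qi + t$len
    } else if (t$op == "D") {
      covered <- c(covered, ref:(ref + t$len - 1L))
      ref <- ref + t$len
    } else if (t$op == "N") {
      ref <- ref + t$len
    }
  }
  covered
}

oracle_mean_depth <- function(aln, region, min_mapq = 5, min_baseq = 20,
                              exclude = c("unmapped", "secondary", "qcfail",
                                          "duplicate")) {
  bits <- c(unmapped = 4L, secondary = 256L, qcfail = 512L, duplicate = 1024L)
  depth <- setNames(rep(0, region$end - region$start),
                    (region$start + 1L):region$end)
  for (i in seq_len(nrow(aln))) {
    if (aln$rname[i] != region$chrom) next
    if (any(bitwAnd(aln$flag[i], bits[exclude]) != 0)) next
    if (aln$mapq[i] < min_mapq) next
    cov <- oracle_covered_pos(aln$cigar[i], aln$pos[i], aln$qual[i], min_baseq)
    hit <- cov[cov > region$start & cov <= region$end]
    for (p in hit) depth[as.character(p)] <- depth[as.character(p)] + 1
  }
  mean(depth)
}

# ---- branchpoint ranking oracle ----

oracle_rank_branchpoints <- function(intron_seq, window = c(18, 44)) {
  s <- strsplit(toupper(intron_seq), "")[[1]]
  len <- length(s)
  at <- function(o) if (o >= 1 && o <= len) s[len - o + 1] else NA
  pyr <- function(b) !is.na(b) && b %in% c("C", "T")
  rows <- list()
  for (o in window[1]:window[2]) {
    if (!identical(at(o), "A")) next
    sc <- 0
    if (pyr(at(o + 3))) sc <- sc + 0.25
    if (identical(at(o + 2), "T")) sc <- sc + 0.5
    if (pyr(at(o - 1))) sc <- sc + 0.25
    rows[[length(rows) + 1]] <- c(offset = o, score = sc)
  }
  if (length(rows) == 0) return(data.frame(offset = integer(), score = numeric()))
  df <- as.data.frame(do.call(rbind, rows))
  df[order(-df$score, df$offset), ]
}

# ---- local alignment DP oracle (match +1, mismatch -1, linear gap -2) ----

oracle_local_align <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- H[i, j] + if (a[i] == b[j]) 1 else -1
      H[i + 1, j + 1] <- max(0, sub, H[i, j + 1] - 2, H[i + 1, j] - 2)
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# ---- exact 2x2 enumeration oracle ----

oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  ks <- max(0, r1 - c2):min(r1, c1)
  prob <- vapply(ks, function(k) {
    choose(c1, k) * choose(c2, r1 - k) / choose(c1 + c2, r1)
  }, numeric(1))
  p_obs <- prob[ks == tab[1, 1]]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# ---- OLS via normal equations ----

oracle_ols <- function(y, g) {
  X <- cbind(1, g)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - 2
  sigma2 <- sum(res^2) / df
  covb <- sigma2 * solve(t(X) %*% X)
  se <- sqrt(covb[2, 2])
  tval <- beta[2] / se
  list(
    slope = beta[2], intercept = beta[1], se = se, t = tval,
    p = 2 * pt(abs(tval), df, lower.tail = FALSE),
    r2 = 1 - sum(res^2) / sum((y - mean(y))^2)
  )
}

# ---- per-base interval-arithmetic isoform classification oracle ----

oracle_classify <- function(cigar, pos, regions, min_overlap = 0.8,
                            min_intron_frac = 0.9, max_intron_bases = 2) {
  pos_set <- function(role) {
    r <- regions[regions$role == role, ][1, ]
    if (r$end <= r$start) return(integer(0))
    (r$start + 1L):r$end
  }
  cov <- oracle_covered_pos(cigar, pos)
  intron <- pos_set("intron_full"); short <- pos_set("intron_short_window")
  rest <- pos_set("intron_rest")
  up <- pos_set("exon_up"); down <- pos_set("exon_down")
  w_int <- length(intersect(cov, intron))
  f_int <- w_int / length(intron)
  f_short <- if (length(short)) length(intersect(cov, short)) / length(short) else 0
  f_rest <- if (length(rest)) length(intersect(cov, rest)) / length(rest) else 0
  w_up <- length(intersect(cov, up)); w_down <- length(intersect(cov, down))
  ci <- sort(intersect(cov, intron))
  contiguous <- length(ci) <= 1 || all(diff(ci) == 1)
  if (f_int >= min_intron_frac && contiguous && (w_up > 0 || w_down > 0)) {
    "full_retention"
  } else if (f_short >= min_overlap && w_down > 0 && f_rest < min_intron_frac) {
    "partial_retention"
  } else if (w_up > 0 && w_down > 0 && w_int <= max_intron_bases) {
    "canonical"
  } else {
    "ambiguous"
  }
}

# ---- shared fixtures ----

# the default synthetic pair reproducing the published intron geometry
make_paper_pair <- function(seed = 7L) build_paralog_pair(seed = seed)

# random toy alignments over a short contig for pileup oracle tests
random_alignments <- function(n_reads, contig_len = 120, chrom = "ctg") {
  ops_pool <- c("M", "M", "M", "D", "N", "I")  # soft clips only at read ends
  rows <- lapply(seq_len(n_reads), function(i) {
    pos <- sample.int(contig_len - 30, 1)
    n_ops <- sample(1:4, 1)
    ops <- c("M", sample(ops_pool, n_ops - 1, replace = TRUE))
    lens <- sample(1:12, n_ops, replace = TRUE)
    # ensure the last op consumes reference
    if (!ops[n_ops] %in% c("M")) { ops <- c(ops, "M"); lens <- c(lens, sample(1:12, 1)) }
    qlen <- sum(lens[ops %in% c("M", "I", "S")])
    flag <- sample(c(0L, 0L, 0L, 16L, 256L, 512L, 1024L, 4L), 1)
    qual <- paste(intToUtf8(sample(33:73, qlen, replace = TRUE), multiple = TRUE),
                  collapse = "")
    tibble::tibble(
      qname = sprintf("r%04d", i), flag = flag, rname = chrom, pos = pos,
      mapq = sample(c(0L, 5L, 20L, 60L), 1),
      cigar = paste0(lens, ops, collapse = ""),
      seq = "*", qual = qual
    )
  })
  dplyr::bind_rows(rows)
}
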