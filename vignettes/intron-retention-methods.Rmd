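---
title: "Branchpoint disruption and intron retention: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branchpoint disruption and intron retention: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(branchretain)
```

# The scientific problem

A common noncoding variant sits 34 nt upstream of an exon, inside the
branchpoint sequence of the preceding intron. On the transcript the
nonrisk allele is the branchpoint adenosine itself; the risk allele
replaces that A with a C, so the spliceosome cannot form the lariat at
the canonical branch site. The observable consequences, all of which this
package quantifies, are:

* partial retention of the 3'-terminal segment of the intron (the
  spliceosome falls back to an alternative branchpoint and a cryptic AG
  acceptor upstream of the canonical one), and full retention of the
  intron in a smaller fraction of transcripts;
* coverage over the intron that rises with risk-allele dosage and is
  absent in nonrisk homozygotes;
* retention reads that carry the risk allele essentially exclusively
  (haplotype purity);
* allele-linked CpG methylation at the variant site; and
* a dose-dependent reduction of the downstream enzyme activity.

The locus is complicated by a pseudogene of very high (~96%) sequence
identity immediately downstream, which makes read mapping genuinely
confusable and motivates both the allele-aware read assignment and the
allele-swap mapping control.

# The branchpoint model

The scan considers every adenosine whose acceptor-side offset lies in a
window of 18-44 nt upstream of the 3' splice site, the standard human
branchpoint positioning range. Each candidate is scored against the
yUnAy consensus anchored on the A: a pyrimidine three bases 5' of the A
contributes 0.25, a U (T in DNA) two bases 5' contributes 0.5, a
pyrimidine immediately 3' contributes 0.25, so scores live in [0, 1]. The
weighting is a fixed, hand-specified stand-in for trained branchpoint
predictors, which are deliberately out of scope: the claim being tested
is about the identity and position of one adenosine, which a consensus
score captures. Ties are broken toward the 3' splice site because that
choice is deterministic and testable; it is a convention, not biology.

A variant *disrupts* the branchpoint exactly when it converts the
top-ranked candidate A into a non-A base. Upon disruption the scanner
walks 5' from the destroyed branchpoint and reports the nearest AG
dinucleotide as the cryptic 3' splice site. Whether the cell selects that
AG because of the alternative branchpoint's position or simply because it
is the nearest upstream AG is not resolvable from the data the analysis
emulates; nearest-upstream-AG is implemented, and the alternative
branchpoint is reported as an annotation only. Splicing at the cryptic AG
retains every intronic base 3' of it through the intron end, so

```
retained_len = (offset of the cryptic AG's G) - 1
```

and the retained segment abuts the downstream exon without ever including
the AG itself. In the default synthetic geometry (branchpoint at offset
34, AG ending 6 nt further upstream) this yields a 39-nt retained
segment. No minimal branchpoint-to-acceptor spacing is enforced for the
cryptic acceptor: the observed product violates typical spacing, so the
spacing is reported and left to the caller to filter.

# Coverage quantification and the dosage association

Regional depth is a per-base pileup averaged over the region, under the
depth filter profile (MAPQ >= 5, base quality >= 20, excluding unmapped,
secondary, QC-fail and duplicate records). A second, stricter retention
profile (MAPQ >= 40, primary alignments only) gates which reads enter
allele assignment and isoform classification. The two profiles are kept
as separate objects because they serve different steps and must not be
conflated. Two pileup dialect choices are documented rather than hidden:
splice gaps (CIGAR `N`) never count as coverage, while deletions (`D`)
count as covered, since the span - not the aligned base - is the quantity
of interest at desk scale.

Normalization divides the mean depth by the number of genome-wide
primary mapped reads in millions; the denominator excludes secondary and
supplementary records. Whether a published per-million denominator counts
reads passing the depth filters or all primary mapped reads is
under-specified in the field; all-primary-mapped is the default here and
the denominator is an explicit argument.

The genotype association follows a pre-registered grouping rule: with
more than five homozygous-risk samples the regression is on the
three-level dosage (TT = 0, GT = 1, GG = 2); otherwise carriers are
pooled against nonrisk homozygotes. The fit is closed-form OLS with the
two-sided p from the t distribution and the unadjusted r². The binary
path is numerically identical to the pooled-variance two-sample t-test,
and the test suite pins that identity. "One-sided" group comparisons are
implemented as the directional version of the same two-group OLS; the
test family is not named in the source material, so the choice is pinned
by the t-test equivalence instead. No multiple-testing correction is
applied anywhere, matching how such raw p-values are reported.

# The synthetic world

The generator is a stated world, not a tuning knob. Its defaults:

| parameter | default | why |
|---|---|---|
| genotype counts | 1 GG, 4 GT, 3 TT | the discovery cohort's composition |
| gene/pseudogene identity | 0.96 | the published homology level |
| retention rates (risk allele) | 0.15 partial, 0.05 full | not measured in any tissue by the source; chosen once as a desk-scale placeholder with comfortable power, and documented as such |
| retention rates (nonrisk) | 0 | retention is risk-haplotype-exclusive |
| reads per sample | 200 (Poisson) | a realistic per-gene yield for targeted long-read data |
| 5' truncation | 0.2 per kb | poly(A)-anchored long reads degrade from the 5' end, producing the 3'-biased coverage the retention signal rides on |
| substitution error | 0.01 per base | post-filter long-read error scale; substitution-only, since allele assignment at a point site is the quantity under test and indels are an extension |
| activity model | slope -0.449, s.e. calibrated to 0.205 at 97/99/9 | the published regression, with noise sd sigma = 0.205 * sqrt(Sxx) ~ 1.69 derived in closed form |
| activity intercept | 10 umol/l/h | a typical normal enzyme activity on dried blood spots; only the slope matters to any test |
| methylation | p = 0.9 (risk) / 0.1 (nonrisk) | "methylated vs lost" with realistic call noise |

Reads carry their truth (sample, haplotype, isoform class, cell barcode)
in structured read names, avoiding a side-channel format. The partial
isoform is built by calling the package's own splice scan, so the
generator and the analysis share one definition of the retained segment
by construction - a deliberate self-consistency, tested as such.

What the generator does *not* emulate: realistic long-read error
profiles (indels, homopolymer artifacts), basecalling, mapping ambiguity
produced by a real aligner, capped versus uncapped transcripts, more
than one isoform per gene besides the retention classes, and
expression-level differences between tissues. A green test therefore
establishes that the statistical machinery recovers what the stated
world contains - not that a wet-lab experiment would.

# Numerical and design choices

* Coordinates are 0-based half-open internally; HGVS and VCF I/O are
  1-based; BED is 0-based half-open. Splice logic always runs on the
  transcript-orientation sequence (reverse complement for minus-strand
  genes) and converts back for genomic output.
* The synthetic reference carries the *nonrisk* allele as the reference
  base. At the real locus the risk allele happens to be the genome
  reference; for a self-contained synthetic world it is cleaner for the
  reference to describe the functional (branchpoint-intact) sequence,
  and nothing downstream depends on which allele is REF.
* The "~40-bp" short quantification window is, by default, the predicted
  retained segment (39 nt in the default geometry) rather than a fixed
  40: the mechanistic quantity is the retained segment, and the length is
  an explicit argument for anyone who wants the looser convention.
* Isoform-classification thresholds (0.8 of the short window, 0.9 of the
  intron, at most 2 intronic bases for a canonical junction read) are
  analysis choices, not published values; they make the classes mutually
  exclusive on truth reads and are exposed as arguments. 5'-truncated
  reads that touch none of the informative regions fall into an explicit
  `ambiguous` class rather than being forced.
* Gene/pseudogene assignment in the allele-swap control uses full local
  dynamic-programming alignment (match +1, mismatch -1, linear gap -2)
  against both references instead of an external aligner: inputs are
  desk-scale and the control stays self-contained. Ties and reads
  overlapping no distinguishing site are excluded from the concordance
  rate and flagged, never silently dropped.
* The exact 2x2 test sums hypergeometric probabilities no larger than
  the observed table's, with a 1e-7 relative tolerance so floating-point
  noise cannot drop tied tables. Degenerate margins are flagged, not
  zeroed.
* OLS degeneracies follow fixed conventions: constant outcome gives
  slope 0, r² 0, p 1; an exact fit with nonzero slope gives se 0, p 0.
* Every random draw descends from one seed through fixed per-stage
  sub-seeds (kept below 2^31), so a pipeline run is byte-reproducible
  and the reference can be pinned independently of the reads.
* The null calibration suite runs the genotype association on the
  downstream flanking exon, not the intron window: with retention rates
  at zero the intron coverage is *identically* zero (coverage is
  span-based, substitution errors cannot create it), so the intron
  regression is degenerate by construction; the flanking exon is the
  natural genotype-null region - expressed, but mechanistically
  unaffected - and is exactly where no effect is expected in the real
  data either.

# Known limitations

* The branchpoint score is a fixed consensus, not a trained model; it
  ranks candidates sensibly in designed and random sequences but carries
  no calibrated probability.
* Allele assignment is single-site; no phasing beyond the variant site
  is attempted.
* The coverage pileup counts deleted bases as covered; data with real
  indels should switch that dialect off or pre-filter.
* The enzyme-activity model is linear with homoscedastic Gaussian noise;
  real activity assays are noisier and right-skewed, which is one reason
  the recovery tests target the slope and its standard error rather than
  distributional shape.
* `run_pipeline()` exercises synthetic cohorts end to end; applying the
  stages to real alignments is supported through the same tibble-first
  functions (`read_alignments()`, `region_coverage()`, ...) but no
  external aligner is wrapped.
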