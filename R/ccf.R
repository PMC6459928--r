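#' @include io.R
NULL

#' Cancer cell fraction from read counts, purity and copy number
#'
#' Closed-form CCF: with VAF v = alt/(alt+ref), purity p, local tumor total
#' copy number Ct and normal copy number Cn,
#' \deqn{CCF = v (p Ct + (1-p) Cn) / (p m)}
#' where m is the mutation multiplicity. When `multiplicity = NULL` it is
#' estimated as round(v (p Ct + (1-p) Cn) / p) clipped to \[1, n_major\].
#' The 95% CI is a Clopper-Pearson binomial interval on v pushed through
#' the same linear map. CCFs are clipped to \[0, 1.2\] for reporting, which
#' preserves evidence of multiplicity misestimation.
#'
#' A mutation is subclonal when the CI upper bound is below 1 (see
#' [classifyClonality()]).
#'
#' @param alt,ref Alt/ref read counts (vectors allowed).
#' @param purity Tumor purity in (0, 1].
#' @param cn_tumor Local tumor total copy number.
#' @param cn_normal Normal copy number (default 2).
#' @param multiplicity Mutation multiplicity; `NULL` = auto.
#' @param n_major Major-allele copy number bounding the auto multiplicity
#'   (default `cn_tumor`).
#' @return data.frame with columns `vaf`, `multiplicity`, `ccf`, `ci_low`,
#'   `ci_high`, `clonality`.
#' @export
computeCcf <- function(alt, ref, purity, cn_tumor, cn_normal = 2,
                       multiplicity = NULL, n_major = cn_tumor) {
  if (any(is.na(purity))) stop("purity_required")
  if (any(purity <= 0 | purity > 1)) stop("purity must lie in (0, 1]")
  n <- max(length(alt), length(ref))
  alt <- rep_len(alt, n); ref <- rep_len(ref, n)
  purity <- rep_len(purity, n); cn_tumor <- rep_len(cn_tumor, n)
  cn_normal <- rep_len(cn_normal, n); n_major <- rep_len(n_major, n)
  total <- alt + ref
  if (any(total <= 0)) stop("alt + ref must be positive")
  vaf <- alt / total
  denom <- purity * cn_tumor + (1 - purity) * cn_normal
  zeroCn <- cn_tumor == 0 & alt > 0
  if (any(zeroCn)) {
    warning("cn_tumor = 0 with alt reads present; multiplicity forced to 1")
  }
  if (is.null(multiplicity)) {
    m <- round(vaf * denom / purity)
    m <- pmin(pmax(m, 1), pmax(n_major, 1))
  } else {
    m <- rep_len(multiplicity, n)
    if (any(m < 1)) stop("multiplicity must be >= 1")
  }
  m[zeroCn] <- 1
  scale <- denom / (purity * m)
  # Clopper-Pearson 95% CI on the VAF
  lowV <- ifelse(alt == 0, 0, qbeta(0.025, alt, ref + 1))
  highV <- ifelse(alt == total, 1, qbeta(0.975, alt + 1, ref))
  clip <- function(x) pmin(pmax(x, 0), 1.2)
  ccf <- clip(vaf * scale)
  ciLow <- clip(lowV * scale)
  ciHigh <- clip(highV * scale)
  data.frame(vaf = vaf, multiplicity = m, ccf = ccf,
             ci_low = ciLow, ci_high = ciHigh,
             clonality = ifelse(ciHigh < 1, "subclonal", "clonal"),
             stringsAsFactors = FALSE)
}

#' Classify mutations as clonal or subclonal
#'
#' Subclonal iff the upper bound of the CCF 95% confidence interval is
#' strictly below 1; otherwise clonal.
#'
#' @param ccf data.frame from [computeCcf()] (needs `ci_high`).
#' @return Character vector, `"clonal"` / `"subclonal"`.
#' @export
classifyClonality <- function(ccf) {
  .requireCols(ccf, "ci_high", "clonality input")
  ifelse(ccf$ci_high < 1, "subclonal", "clonal")
}

#' Call LOH and alternate-allele loss at a gene locus
#'
#' LOH: the minor allele is clonally deleted (n_minor = 0) while the major
#' allele is retained (n_major >= 1). Alternate-allele loss is flagged
#' when, under LOH, the variant read frequency exceeds 0.7.
#'
#' @param segments data.frame of segments overlapping the locus for one
#'   sample (columns `chrom`, `start`, `end`, `n_major`, `n_minor`).
#' @param chrom,pos Locus coordinates (1-based).
#' @param vaf Variant allele frequency of the mutation at the locus
#'   (`NA` if none).
#' @return `list(loh, alt_allele_loss, n_major, n_minor)`.
#' @export
callLoh <- function(segments, chrom, pos, vaf = NA_real_) {
  .requireCols(segments, c("chrom", "start", "end", "n_major", "n_minor"),
               "LOH input")
  hit <- segments$chrom == chrom & segments$start <= pos & segments$end >= pos
  if (!any(hit)) stop("locus_uncovered")
  seg <- segments[which(hit)[1], ]
  loh <- seg$n_minor == 0 && seg$n_major >= 1
  list(loh = loh,
       alt_allele_loss = isTRUE(loh && !is.na(vaf) && vaf > 0.7),
       n_major = seg$n_major, n_minor = seg$n_minor)
}

#' CCF table for a patient's mutation set
#'
#' Convenience wrapper applying [computeCcf()] to a long mutation
#' data.frame (tumor samples only), assuming diploid loci unless a segment
#' table provides local copy numbers.
#'
#' @param mutations Long mutation data.frame (see [readMutationTable()]).
#' @param samples Sample metadata data.frame with `purity`.
#' @param segments Optional segment data.frame for local copy numbers.
#' @return Long data.frame: `mutation_id`, `sample_id`, plus the
#'   [computeCcf()] columns.
#' @export
ccfTable <- function(mutations, samples, segments = NULL) {
  tumor <- samples[samples$sample_type %in%
                     c("primary_region", "lymph_node_met"), ]
  df <- mutations[mutations$sample_id %in% tumor$sample_id, ]
  pur <- setNames(tumor$purity, tumor$sample_id)[df$sample_id]
  if (any(is.na(pur))) stop("purity_required")
  cn <- rep(2L, nrow(df))
  nmaj <- rep(1L, nrow(df))
  if (!is.null(segments)) {
    for (i in seq_len(nrow(df))) {
      seg <- segments[segments$sample_id == df$sample_id[i] &
                        segments$chrom == df$chrom[i] &
                        segments$start <= df$pos[i] &
                        segments$end >= df$pos[i], ]
      if (nrow(seg) > 0) {
        cn[i] <- seg$n_major[1] + seg$n_minor[1]
        nmaj[i] <- seg$n_major[1]
      }
    }
  }
  keep <- df$alt_reads + df$ref_reads > 0
  df <- df[keep, ]
  res <- computeCcf(df$alt_reads, df$ref_reads, pur[keep], cn[keep],
                    n_major = pmax(nmaj[keep], 1))
  cbind(df[, c("mutation_id", "sample_id")], res)
}
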