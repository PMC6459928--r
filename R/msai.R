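#' @include io.R
NULL

#' Theoretical B-allele fraction for an allele-specific copy state
#'
#' Expected BAF of the allele carried on the major (or minor) haplotype in
#' a tumor of the given purity with local copy numbers (n_major, n_minor):
#' \deqn{BAF_{major} = (p\,n_{major} + (1-p)) / (p\,(n_{major}+n_{minor}) + 2(1-p))}
#' and symmetrically with n_minor in the numerator. The two always sum
#' to 1.
#'
#' @param purity Tumor purity in (0, 1].
#' @param n_major,n_minor Allele-specific copy numbers,
#'   `n_major >= n_minor >= 0`, not both 0.
#' @param allele `"major"` or `"minor"`.
#' @return Expected BAF.
#' @export
expectedBaf <- function(purity, n_major, n_minor,
                        allele = c("major", "minor")) {
  allele <- match.arg(allele)
  if (any(purity <= 0 | purity > 1)) stop("purity must lie in (0, 1]")
  if (any(n_major < n_minor) || any(n_minor < 0)) {
    stop("need n_major >= n_minor >= 0")
  }
  if (any(n_major + n_minor == 0)) stop("total copy number is 0")
  num <- if (allele == "major") n_major else n_minor
  (purity * num + (1 - purity)) /
    (purity * (n_major + n_minor) + 2 * (1 - purity))
}

#' Patient-level consensus segmentation across samples
#'
#' Combines the breakpoints of every sample's segmentation into one
#' patient-specific partition: within each chromosome, the output pieces
#' are the intervals between consecutive breakpoints of the union,
#' restricted to regions covered by all samples, each carrying every
#' sample's copy state.
#'
#' @param segments data.frame of segments for >= 2 samples (columns
#'   `sample_id`, `chrom`, `start`, `end`, `n_major`, `n_minor`).
#' @return Long data.frame: `segment_id`, `chrom`, `start`, `end`,
#'   `sample_id`, `n_major`, `n_minor` (one row per piece x sample).
#' @export
buildConsensusSegments <- function(segments) {
  .requireCols(segments, c("sample_id", "chrom", "start", "end",
                           "n_major", "n_minor"), "consensus input")
  sampleIds <- unique(segments$sample_id)
  if (length(sampleIds) < 2) stop("need segments from at least 2 samples")
  for (s in sampleIds) {
    sub <- segments[segments$sample_id == s, ]
    if (nrow(sub) == 0) stop(sprintf("sample %s has no segments", s))
    for (ch in unique(sub$chrom)) {
      d <- sub[sub$chrom == ch, ]
      d <- d[order(d$start), ]
      if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)])) {
        stop(sprintf("overlapping segments within sample %s chrom %s", s, ch))
      }
    }
  }
  out <- list()
  for (ch in unique(segments$chrom)) {
    d <- segments[segments$chrom == ch, ]
    # 1-based closed intervals: cut at every segment start and end+1
    bps <- sort(unique(c(d$start, d$end + 1L)))
    for (i in seq_len(length(bps) - 1)) {
      s0 <- bps[i]; e0 <- bps[i + 1] - 1L
      hit <- d[d$start <= s0 & d$end >= e0, ]
      if (!setequal(hit$sample_id, sampleIds)) next   # not covered by all
      out[[length(out) + 1L]] <- data.frame(
        segment_id = sprintf("%s:%d-%d", ch, s0, e0), chrom = ch,
        start = s0, end = e0, sample_id = hit$sample_id,
        n_major = hit$n_major, n_minor = hit$n_minor,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(segment_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      sample_id = character(0), n_major = integer(0),
                      n_minor = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# log-density of a normal truncated to (0, 1)
.logTruncNorm <- function(x, mu, sigma) {
  dnorm(x, mu, sigma, log = TRUE) -
    log(pnorm(1, mu, sigma) - pnorm(0, mu, sigma))
}

#' Test a segment for mirrored subclonal allelic imbalance
#'
#' For one consensus segment with allelic imbalance in two samples, each
#' heterozygous SNP's BAF is scored under two truncated-normal densities
#' centered at the theoretical BAFs of the major and minor haplotypes
#' (scale = MAD of the BAFs folded about the nearer center, floored at
#' 0.01) and assigned to the higher-likelihood haplotype per sample. The
#' per-SNP reversal log-likelihood ratios — symmetrized over sample order
#' as r_i = (-sign(L1_i) L2_i - sign(L2_i) L1_i)/2, where L_si is the
#' major-minus-minor log-likelihood in sample s — are tested against zero
#' with a one-tailed t-test. The event is mirrored when the test is
#' significant and the favored haplotype flips between the samples.
#'
#' @param snps data.frame of SNP records for exactly two samples on the
#'   segment (`sample_id`, `pos`, `a_reads`, `b_reads`); SNPs are matched
#'   across samples by position.
#' @param states Named list sample_id -> `c(n_major, n_minor)`.
#' @param purity Named numeric (or scalar) tumor purity.
#' @param alpha Significance level (default 0.05).
#' @param min_snps Minimum shared SNPs (default 10).
#' @return list: `mirrored`, `p_value`, `t_statistic`, `n_snps`,
#'   `flip_fraction`, `skipped` (`NULL` or a reason:
#'   `"no_imbalance"`, `"insufficient_snps"`).
#' @export
testMsai <- function(snps, states, purity, alpha = 0.05, min_snps = 10) {
  sampleIds <- names(states)
  if (length(sampleIds) != 2) stop("exactly two samples required")
  skip <- function(reason) list(mirrored = FALSE, p_value = NA_real_,
                                t_statistic = NA_real_, n_snps = 0L,
                                flip_fraction = NA_real_, skipped = reason)
  if (any(vapply(states, function(s) s[1] == s[2], TRUE))) {
    return(skip("no_imbalance"))
  }
  if (length(purity) == 1) purity <- setNames(rep(purity, 2), sampleIds)
  s1 <- snps[snps$sample_id == sampleIds[1], ]
  s2 <- snps[snps$sample_id == sampleIds[2], ]
  common <- intersect(s1$pos, s2$pos)
  if (length(common) < min_snps) return(skip("insufficient_snps"))
  s1 <- s1[match(common, s1$pos), ]
  s2 <- s2[match(common, s2$pos), ]
  llr <- function(d, st, p) {
    baf <- d$b_reads / (d$a_reads + d$b_reads)
    muMaj <- expectedBaf(p, st[1], st[2], "major")
    muMin <- expectedBaf(p, st[1], st[2], "minor")
    resid <- pmin(abs(baf - muMaj), abs(baf - muMin))
    sigma <- max(mad(resid, center = 0), 0.01)
    .logTruncNorm(baf, muMaj, sigma) - .logTruncNorm(baf, muMin, sigma)
  }
  L1 <- llr(s1, states[[1]], purity[sampleIds[1]])
  L2 <- llr(s2, states[[2]], purity[sampleIds[2]])
  r <- (-sign(L1) * L2 - sign(L2) * L1) / 2
  flip <- mean((L1 >= 0) != (L2 >= 0))
  if (sd(r) == 0) {
    p <- if (mean(r) > 0) 0 else 1
    tstat <- sign(mean(r)) * Inf
  } else {
    tt <- t.test(r, mu = 0, alternative = "greater")
    p <- tt$p.value
    tstat <- unname(tt$statistic)
  }
  list(mirrored = p < alpha && flip > 0.5, p_value = p, t_statistic = tstat,
       n_snps = length(common), flip_fraction = flip, skipped = NULL)
}

#' Scan all consensus segments and sample pairs for MSAI
#'
#' Builds the patient consensus segmentation, then applies [testMsai()]
#' to every (segment, sample pair) with imbalance in both samples. Raw
#' p-values are reported with a Benjamini-Hochberg adjusted column across
#' the tested pairs.
#'
#' @param segments Per-sample segment data.frame.
#' @param snps Per-SNP BAF data.frame (`sample_id`, `chrom`, `pos`,
#'   `a_reads`, `b_reads`).
#' @param purity Named purity vector (by sample).
#' @param alpha Significance level.
#' @return data.frame: one row per (segment, sample pair) with test
#'   fields, `p_adj` and `mirrored`.
#' @export
msaiScan <- function(segments, snps, purity, alpha = 0.05) {
  cons <- buildConsensusSegments(segments)
  out <- list()
  for (sid in unique(cons$segment_id)) {
    piece <- cons[cons$segment_id == sid, ]
    inSeg <- snps[snps$chrom == piece$chrom[1] &
                    snps$pos >= piece$start[1] & snps$pos <= piece$end[1], ]
    ids <- piece$sample_id
    for (i in seq_len(length(ids) - 1)) {
      for (j in seq(i + 1, length(ids))) {
        st <- list(unlist(piece[piece$sample_id == ids[i],
                                c("n_major", "n_minor")]),
                   unlist(piece[piece$sample_id == ids[j],
                                c("n_major", "n_minor")]))
        names(st) <- c(ids[i], ids[j])
        res <- testMsai(inSeg[inSeg$sample_id %in% names(st), ], st,
                        purity[names(st)], alpha = alpha)
        out[[length(out) + 1L]] <- data.frame(
          segment_id = sid, sample_1 = ids[i], sample_2 = ids[j],
          n_snps = res$n_snps, t_statistic = res$t_statistic,
          p_value = res$p_value,
          skipped = if (is.null(res$skipped)) "" else res$skipped,
          mirrored = res$mirrored, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(segment_id = character(0)))
  }
  res$p_adj <- NA_real_
  tested <- !is.na(res$p_value)
  res$p_adj[tested] <- stats::p.adjust(res$p_value[tested], "BH")
  rownames(res) <- NULL
  res
}
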