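#' @include io.R
NULL

#' Cumulative mutation count M(f) over a VAF window
#'
#' M(f) is the number of mutations with VAF >= f (counted over the whole
#' VAF vector), evaluated at every observed VAF inside the open window
#' (default (0.12, 0.24)), returned in descending f.
#'
#' @param vafs Numeric VAFs in (0, 1).
#' @param window Open interval of evaluation points.
#' @return data.frame with columns `f`, `M`, descending in `f`.
#' @export
cumulativeCurve <- function(vafs, window = c(0.12, 0.24)) {
  if (any(vafs <= 0 | vafs >= 1)) stop("VAFs must lie in (0, 1)")
  f <- sort(vafs[vafs > window[1] & vafs < window[2]], decreasing = TRUE)
  if (length(f) == 0) stop("empty_window")
  sorted <- sort(vafs)
  M <- length(vafs) - findInterval(f, sorted, left.open = TRUE)
  data.frame(f = f, M = M)
}

.r2 <- function(M, fitted) {
  ssTot <- sum((M - mean(M))^2)
  if (ssTot == 0) return(NA_real_)
  1 - sum((M - fitted)^2) / ssTot
}

#' Fit the neutral growth model M(f) = (mu/beta)(1/f - f/f_max)
#'
#' One-parameter least-squares fit through the origin of M(f) on
#' x = 1/f - f/f_max; the slope is the mutation rate per effective
#' division mu/beta. R-squared is computed against the mean of M (so it
#' can be negative for pathological fits); R^2 >= `r2_threshold` (0.98)
#' calls the sample neutral.
#'
#' @param curve data.frame from [cumulativeCurve()] (columns `f`, `M`).
#' @param f_max Expected clonal VAF; must exceed the largest window f.
#' @param purity Optional tumor purity, used only for the eligibility
#'   flag (purity > 0.5 and >= `min_snvs` window SNVs).
#' @param r2_threshold Neutrality threshold on R^2.
#' @param min_snvs Eligibility minimum for window SNVs (default 12).
#' @return list (fields of a neutral-fit result): `mu_over_beta`,
#'   `epsilon` (NA here), `f_max`, `r_squared`, `r_squared_adjusted` (NA
#'   here), `n_snvs_in_window`, `neutral`, `eligible`.
#' @export
fitNeutral <- function(curve, f_max, purity = NA_real_,
                       r2_threshold = 0.98, min_snvs = 12) {
  if (f_max <= max(curve$f)) stop("f_max must exceed the window maximum")
  if (nrow(curve) < 2) stop("need at least 2 points")
  if (nrow(curve) < min_snvs) {
    warning("fewer window SNVs than the eligibility minimum")
  }
  x <- 1 / curve$f - curve$f / f_max
  slope <- sum(x * curve$M) / sum(x * x)
  r2 <- .r2(curve$M, slope * x)
  eligible <- !is.na(purity) && purity > 0.5 && nrow(curve) >= min_snvs
  list(mu_over_beta = slope, epsilon = NA_real_, f_max = f_max,
       r_squared = r2, r_squared_adjusted = NA_real_,
       n_snvs_in_window = nrow(curve),
       neutral = isTRUE(r2 >= r2_threshold), eligible = eligible)
}

#' Purity-corrected neutral fit with a contamination parameter
#'
#' Fallback model applied when the plain fit fails the neutrality
#' threshold. Normal contamination epsilon >= 0 dilutes observed VAFs by
#' 1/(1+epsilon); substituting f(1+epsilon) for f in the neutral model
#' gives
#' \deqn{M(f) = s/f - s (1+\epsilon)^2 f / f_{max}, \quad
#'       s = \mu / (\beta (1+\epsilon)),}
#' a two-parameter constrained least-squares problem solved by profiling:
#' the slope is closed-form at fixed epsilon and epsilon is optimized on
#' \[0, `eps_max`\]. `r_squared_adjusted` >= `r2_threshold` calls the
#' sample neutral; `mu_over_beta` reports s(1+epsilon).
#'
#' @inheritParams fitNeutral
#' @param eps_max Upper bound of the contamination search (default 2).
#' @return list with the same fields as [fitNeutral()] plus fitted
#'   `epsilon`; `converged` records optimizer sanity.
#' @export
fitNeutralCorrected <- function(curve, f_max, purity = NA_real_,
                                r2_threshold = 0.98, min_snvs = 12,
                                eps_max = 2) {
  if (f_max <= max(curve$f)) stop("f_max must exceed the window maximum")
  if (nrow(curve) < 2) stop("need at least 2 points")
  f <- curve$f; M <- curve$M
  sse <- function(eps) {
    x <- 1 / f - (1 + eps)^2 * f / f_max
    sxx <- sum(x * x)
    if (sxx == 0) return(sum(M^2))
    s <- sum(x * M) / sxx
    sum((M - s * x)^2)
  }
  opt <- optimize(sse, c(0, eps_max))
  eps <- opt$minimum
  # the boundary eps = 0 may beat the interior optimum candidate
  if (sse(0) <= opt$objective) eps <- 0
  x <- 1 / f - (1 + eps)^2 * f / f_max
  s <- sum(x * M) / sum(x * x)
  r2 <- .r2(M, s * x)
  converged <- is.finite(r2) && s >= 0
  eligible <- !is.na(purity) && purity > 0.5 && nrow(curve) >= min_snvs
  list(mu_over_beta = s * (1 + eps), epsilon = eps, f_max = f_max,
       r_squared = NA_real_, r_squared_adjusted = r2,
       n_snvs_in_window = nrow(curve),
       neutral = isTRUE(converged && r2 >= r2_threshold),
       eligible = eligible, converged = converged)
}

#' Classify a cohort of samples under the neutral evolution model
#'
#' Applies the eligibility rule (purity > 0.5 and at least 12 SNVs with
#' VAF inside the window), fits the plain model, falls back to the
#' purity-corrected model when R^2 < 0.98, and reports per-sample calls
#' and the neutral fraction among eligible samples. `f_max` defaults to
#' purity/2, the expected clonal heterozygous VAF in a diploid region.
#'
#' @param reads data.frame with columns `sample_id`, `alt`, `total`.
#' @param purity Named numeric vector, sample_id -> purity.
#' @param window VAF window (default `c(0.12, 0.24)`).
#' @param f_max Optional fixed f_max; `NULL` = purity/2 per sample.
#' @param r2_threshold Neutrality threshold.
#' @return list: `table` (one row per sample: n window SNVs, eligibility,
#'   R^2s, epsilon, neutral call, model used), `fraction_neutral` among
#'   eligible samples, `n_eligible`.
#' @export
classifyNeutralCohort <- function(reads, purity, window = c(0.12, 0.24),
                                  f_max = NULL, r2_threshold = 0.98) {
  rows <- list()
  for (s in unique(reads$sample_id)) {
    d <- reads[reads$sample_id == s & reads$total > 0, ]
    vafs <- d$alt / d$total
    vafs <- vafs[vafs > 0 & vafs < 1]
    p <- unname(purity[s])
    nWin <- sum(vafs > window[1] & vafs < window[2])
    eligible <- !is.na(p) && p > 0.5 && nWin >= 12
    row <- data.frame(sample_id = s, purity = p, n_snvs_in_window = nWin,
                      eligible = eligible, r_squared = NA_real_,
                      r_squared_adjusted = NA_real_, epsilon = NA_real_,
                      mu_over_beta = NA_real_, model = NA_character_,
                      neutral = NA, stringsAsFactors = FALSE)
    if (eligible) {
      fm <- if (is.null(f_max)) p / 2 else f_max
      curve <- cumulativeCurve(vafs, window)
      fit <- fitNeutral(curve, fm, purity = p, r2_threshold = r2_threshold)
      row$r_squared <- fit$r_squared
      row$mu_over_beta <- fit$mu_over_beta
      row$model <- "plain"
      row$neutral <- fit$neutral
      if (!fit$neutral) {
        fit2 <- fitNeutralCorrected(curve, fm, purity = p,
                                    r2_threshold = r2_threshold)
        row$r_squared_adjusted <- fit2$r_squared_adjusted
        row$epsilon <- fit2$epsilon
        row$model <- "corrected"
        row$neutral <- fit2$neutral
        if (fit2$neutral) row$mu_over_beta <- fit2$mu_over_beta
      }
    }
    rows[[length(rows) + 1L]] <- row
  }
  tab <- do.call(rbind, rows)
  elig <- tab[tab$eligible, ]
  list(table = tab,
       fraction_neutral = if (nrow(elig) > 0) mean(elig$neutral) else
         NA_real_,
       n_eligible = nrow(elig))
}
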