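#' @include channels.R classes.R
NULL

#' Build a 96-channel mutational spectrum
#'
#' Counts SNVs into the 96 pyrimidine-standardized trinucleotide channels.
#' Indels and records without a usable context are skipped (with a
#' message naming how many), so the spectrum total equals the number of
#' contributing SNVs.
#'
#' @param snvs data.frame with columns `ref`, `alt`, `tri_context` (and
#'   optionally `variant_type`, used to drop non-SNVs). Pass unique
#'   mutations, not mutation x sample rows, unless per-sample counting is
#'   intended.
#' @return Named numeric vector of length 96 (catalog channel order).
#' @export
buildSpectrum <- function(snvs) {
  ch <- substitutionChannels()
  spec <- setNames(numeric(96), ch)
  if (nrow(snvs) == 0) return(spec)
  df <- snvs
  if ("variant_type" %in% names(df)) df <- df[df$variant_type == "SNV", ]
  if (nrow(df) == 0) return(spec)
  lab <- channelOf(df$ref, df$alt, df$tri_context)
  bad <- is.na(lab)
  if (any(bad)) {
    message(sprintf("buildSpectrum: %d record(s) with malformed context skipped",
                    sum(bad)))
  }
  tab <- table(factor(lab[!bad], levels = ch))
  spec + as.numeric(tab)
}

#' Fit signature exposures by non-negative least squares
#'
#' Solves min over x >= 0 of || catalog x - spectrum ||_2 (via
#' [pracma::lsqnonneg()]); no sparsity penalty, all 30 signatures compete.
#' Proportions are contributions over their sum; the dominant signature is
#' the argmax proportion, ties broken by lowest signature index. A zero
#' spectrum yields all-zero contributions and an `NA` dominant signature.
#'
#' @param spectrum Named 96-vector (see [buildSpectrum()]).
#' @param catalog 96 x 30 probability matrix (default the packaged
#'   catalog).
#' @param id Identifier recorded on the result.
#' @return A [SignatureExposure-class].
#' @export
fitExposures <- function(spectrum, catalog = signatureCatalog(),
                         id = "sample") {
  stopifnot(length(spectrum) == nrow(catalog))
  if (!is.null(names(spectrum)) &&
      !identical(names(spectrum), rownames(catalog))) {
    spectrum <- spectrum[rownames(catalog)]
  }
  nSig <- ncol(catalog)
  if (sum(spectrum) == 0) {
    return(new("SignatureExposure", id = id,
               contributions = setNames(numeric(nSig), colnames(catalog)),
               proportions = setNames(numeric(nSig), colnames(catalog)),
               dominant = NA_character_, reconstructionError = 0,
               nMutations = 0))
  }
  fit <- pracma::lsqnonneg(catalog, as.numeric(spectrum))
  x <- setNames(pmax(fit$x, 0), colnames(catalog))
  pr <- if (sum(x) > 0) x / sum(x) else x
  dom <- if (sum(x) > 0) colnames(catalog)[which.max(pr)] else NA_character_
  new("SignatureExposure", id = id, contributions = x, proportions = pr,
      dominant = dom,
      reconstructionError = sqrt(sum((catalog %*% x - spectrum)^2)),
      nMutations = sum(spectrum))
}

#' Trunk-versus-branch signature exposures across a cohort
#'
#' For each patient, splits SNVs into the trunk phase (mutations present
#' in every tumor sample) and the branch phase (everything else) using
#' timing labels, builds the two spectra and fits exposures for each.
#' Phases with fewer than `min_snvs` SNVs (default 20) are fitted but
#' flagged low-confidence; patients lacking one phase entirely are
#' excluded from the cohort test. The cohort-level comparison of the
#' chosen signature's proportion between phases is a two-sided paired
#' t-test.
#'
#' @param mutations Long mutation data.frame for the cohort (or one
#'   patient); one spectrum entry per unique mutation.
#' @param timing Named character vector mutation_id -> label
#'   (`trunk`/`shared`/`private`), e.g. from [classifyTiming()], possibly
#'   concatenated across patients.
#' @param signature Signature whose proportion is compared (default
#'   `"Signature.3"`).
#' @param catalog Signature catalog.
#' @param min_snvs Low-confidence threshold per phase.
#' @return list: `table` (per patient and phase: n SNVs, signature
#'   proportion, low-confidence flag), `exposures` (named list of
#'   [SignatureExposure-class] pairs), `test` (paired t-test or `NULL`
#'   when fewer than 2 complete patients).
#' @export
phaseExposures <- function(mutations, timing, signature = "Signature.3",
                           catalog = signatureCatalog(), min_snvs = 20) {
  uniq <- mutations[!duplicated(mutations$mutation_id), ]
  uniq <- uniq[uniq$mutation_id %in% names(timing), ]
  phase <- ifelse(timing[uniq$mutation_id] == "trunk", "trunk", "branch")
  rows <- list(); expo <- list()
  for (p in unique(uniq$patient_id)) {
    sub <- uniq[uniq$patient_id == p, ]
    ph <- phase[uniq$patient_id == p]
    pair <- list()
    for (ws in c("trunk", "branch")) {
      snvs <- sub[ph == ws, ]
      if (nrow(snvs) == 0) {
        pair[[ws]] <- NULL
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = p, phase = ws, n_snvs = 0,
          proportion = NA_real_, low_confidence = TRUE,
          stringsAsFactors = FALSE)
        next
      }
      e <- fitExposures(buildSpectrum(snvs), catalog,
                        id = paste(p, ws, sep = "_"))
      pair[[ws]] <- e
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p, phase = ws, n_snvs = e@nMutations,
        proportion = unname(exposureProportions(e)[signature]),
        low_confidence = e@nMutations < min_snvs,
        stringsAsFactors = FALSE)
    }
    expo[[p]] <- pair
  }
  tab <- do.call(rbind, rows)
  wide <- merge(tab[tab$phase == "trunk", c("patient_id", "proportion")],
                tab[tab$phase == "branch", c("patient_id", "proportion")],
                by = "patient_id", suffixes = c("_trunk", "_branch"))
  wide <- wide[complete.cases(wide), ]
  test <- if (nrow(wide) >= 2 &&
              sd(wide$proportion_branch - wide$proportion_trunk) > 0) {
    t.test(wide$proportion_branch, wide$proportion_trunk, paired = TRUE)
  } else NULL
  list(table = tab, exposures = expo, test = test)
}

#' AUC of signature-3 activity for predicting BRCA1/2 deficiency
#'
#' Empirical area under the ROC curve via the Mann-Whitney U statistic:
#' AUC = U / (n+ n-), with ties counted 1/2. Also returns the ROC points.
#'
#' @param scores Numeric predictor (signature-3 proportion per patient).
#' @param labels Logical (or 0/1) BRCA-deficiency labels.
#' @return list: `auc`, `roc` (data.frame `fpr`, `tpr` over score
#'   thresholds).
#' @export
aucSignature3 <- function(scores, labels) {
  labels <- as.logical(labels)
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0 || nNeg == 0) stop("need both positive and negative labels")
  r <- rank(scores)
  auc <- (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  thr <- sort(unique(scores), decreasing = TRUE)
  roc <- data.frame(
    fpr = c(0, vapply(thr, function(t) mean(scores[!labels] >= t), 0), 1),
    tpr = c(0, vapply(thr, function(t) mean(scores[labels] >= t), 0), 1))
  list(auc = auc, roc = roc)
}
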