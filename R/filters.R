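#' @include io.R
NULL

#' The 25-gene homologous-recombination panel
#'
#' DNA-repair genes screened for deleterious germline variants.
#' @return Character vector of 25 gene symbols.
#' @export
hrGenePanel <- function() {
  c("BRCA1", "BRCA2", "MRE11A", "NBN", "RAD50", "RAD51C", "RAD51B",
    "RAD52", "XRCC2", "BLM", "EME1", "RPA1", "POLD1", "TOP3A", "RAD54B",
    "TOP3B", "BARD1", "BRIP1", "MLH1", "MSH2", "PALB2", "CHEK2",
    "FAM175A", "MSH6", "RAD51D")
}

.filterResult <- function(df, reasons) {
  fail <- vapply(reasons, function(r) nchar(r) > 0, TRUE)
  rejected <- df[fail, , drop = FALSE]
  rejected$reason <- reasons[fail]
  list(passed = df[!fail, , drop = FALSE], rejected = rejected)
}

#' Filter somatic SNVs on tumor/normal read support
#'
#' Keeps SNVs with tumor alt reads >= `t_alt_min` (default 4), tumor
#' coverage >= `t_cov_min` (14), matched-normal alt reads <= `n_alt_max`
#' (2) and normal coverage >= `n_cov_min` (10). Rejection reasons
#' enumerate every violated rule, semicolon-separated.
#'
#' @param df data.frame with columns `t_alt`, `t_cov`, `n_alt`, `n_cov`
#'   (one row per SNV x tumor sample).
#' @param t_alt_min,t_cov_min,n_alt_max,n_cov_min Thresholds.
#' @return `list(passed, rejected)`; `rejected` gains a `reason` column.
#' @export
filterSomaticSnvs <- function(df, t_alt_min = 4, t_cov_min = 14,
                              n_alt_max = 2, n_cov_min = 10) {
  .requireCols(df, c("t_alt", "t_cov", "n_alt", "n_cov"), "SNV filter input")
  if (any(is.na(df$n_alt) | is.na(df$n_cov))) {
    stop("missing matched-normal counts")
  }
  reasons <- character(nrow(df))
  add <- function(reasons, bad, tag) {
    ifelse(bad, ifelse(nchar(reasons) > 0, paste(reasons, tag, sep = ";"),
                       tag), reasons)
  }
  reasons <- add(reasons, df$t_alt < t_alt_min, "tumor_support")
  reasons <- add(reasons, df$t_cov < t_cov_min, "tumor_coverage")
  reasons <- add(reasons, df$n_alt > n_alt_max, "normal_support")
  reasons <- add(reasons, df$n_cov < n_cov_min, "normal_coverage")
  .filterResult(df, reasons)
}

#' Filter somatic indels on support, coverage and VAF
#'
#' Keeps indels with alt reads >= `alt_min` (default 6), coverage >=
#' `cov_min` (20) and VAF >= `vaf_min` (0.1). Zero-coverage rows are
#' rejected with reason `no_coverage`.
#'
#' @param df data.frame with columns `alt` and `cov`.
#' @param alt_min,cov_min,vaf_min Thresholds.
#' @return `list(passed, rejected)`.
#' @export
filterSomaticIndels <- function(df, alt_min = 6, cov_min = 20,
                                vaf_min = 0.1) {
  .requireCols(df, c("alt", "cov"), "indel filter input")
  reasons <- character(nrow(df))
  noCov <- df$cov == 0
  vaf <- ifelse(noCov, 0, df$alt / df$cov)
  add <- function(reasons, bad, tag) {
    ifelse(bad, ifelse(nchar(reasons) > 0, paste(reasons, tag, sep = ";"),
                       tag), reasons)
  }
  reasons <- add(reasons, noCov, "no_coverage")
  reasons <- add(reasons, !noCov & df$alt < alt_min, "support")
  reasons <- add(reasons, !noCov & df$cov < cov_min, "coverage")
  reasons <- add(reasons, !noCov & vaf < vaf_min, "vaf")
  .filterResult(df, reasons)
}

#' Flag hypermutated patients
#'
#' A patient is hypermutated when its mutation burden is at least
#' `fold` (default 10) times the cohort median burden (median over all
#' patients, nobody excluded).
#'
#' @param burden Named numeric vector, patient -> mutation count.
#' @param fold Multiple of the median that triggers the flag.
#' @return Character vector of flagged patient ids.
#' @export
flagHypermutators <- function(burden, fold = 10) {
  if (length(burden) == 0) stop("empty burden map")
  if (length(burden) < 3) stop("need at least 3 patients")
  med <- median(burden)
  names(burden)[burden >= fold * med]
}

#' Filter germline variants in the HR gene panel for deleterious calls
#'
#' Keeps variants with coverage >= 30, VAF > 0.08, population minor allele
#' frequency <= 0.01 (absent MAF is treated as 0, i.e. rare), and either a
#' truncating consequence (nonsense, frameshift, splice) or a ClinVar
#' pathogenic annotation. Genes outside the 25-gene panel are rejected
#' with reason `gene_panel`.
#'
#' @param df data.frame with columns `gene`, `consequence`,
#'   `clinvar_pathogenic`, `coverage`, `vaf` and optional `population_maf`.
#' @param cov_min,vaf_min,maf_max Thresholds (defaults 30, 0.08, 0.01).
#' @param panel Gene panel (default [hrGenePanel()]).
#' @return `list(passed, rejected)`.
#' @export
filterGermlineHr <- function(df, cov_min = 30, vaf_min = 0.08,
                             maf_max = 0.01, panel = hrGenePanel()) {
  .requireCols(df, c("gene", "consequence", "clinvar_pathogenic",
                     "coverage", "vaf"), "germline filter input")
  maf <- if ("population_maf" %in% names(df)) df$population_maf else
    rep(NA_real_, nrow(df))
  maf[is.na(maf)] <- 0
  truncating <- df$consequence %in% c("nonsense", "frameshift", "splice")
  reasons <- character(nrow(df))
  add <- function(reasons, bad, tag) {
    ifelse(bad, ifelse(nchar(reasons) > 0, paste(reasons, tag, sep = ";"),
                       tag), reasons)
  }
  reasons <- add(reasons, !(df$gene %in% panel), "gene_panel")
  reasons <- add(reasons, df$coverage < cov_min, "coverage")
  reasons <- add(reasons, df$vaf <= vaf_min, "vaf")
  reasons <- add(reasons, maf > maf_max, "common_variant")
  reasons <- add(reasons, !truncating & !df$clinvar_pathogenic,
                 "not_deleterious")
  .filterResult(df, reasons)
}

#' Annotate putative driver mutations
#'
#' A non-silent variant in a driver-list gene is flagged as a driver when
#' (i) it matches a recorded mutation exactly (same gene and position) or
#' at least 3 recorded mutations of the gene lie within `window` bp (15)
#' of its position, or (ii) the gene is recessive, the consequence is
#' deleterious (nonsense/frameshift/splice) and the variant has
#' SIFT < 0.05 or PolyPhen > 0.995. Missing scores simply fail the score
#' clause. Recorded-mutation proximity is evaluated in genomic
#' coordinates.
#'
#' @param df data.frame with columns `gene`, `pos`, `consequence` and
#'   optional `sift`, `polyphen`.
#' @param config list: `driver_genes` (character), `cosmic_index` (named
#'   list gene -> data.frame(pos, count)), `recessive_genes` (character).
#' @param window Proximity window in bp.
#' @return `df` with an added logical `driver` column and a `driver_reason`
#'   column (`"cosmic"`, `"recessive"`, or `""`).
#' @export
annotateDrivers <- function(df, config, window = 15) {
  .requireCols(df, c("gene", "pos", "consequence"), "driver annotation input")
  sift <- if ("sift" %in% names(df)) df$sift else rep(NA_real_, nrow(df))
  poly <- if ("polyphen" %in% names(df)) df$polyphen else
    rep(NA_real_, nrow(df))
  nonSilent <- df$consequence != "silent"
  inList <- df$gene %in% config$driver_genes
  cosmicHit <- vapply(seq_len(nrow(df)), function(i) {
    idx <- config$cosmic_index[[df$gene[i]]]
    if (is.null(idx) || nrow(idx) == 0) return(FALSE)
    if (any(idx$pos == df$pos[i] & idx$count >= 1)) return(TRUE)
    sum(idx$count[abs(idx$pos - df$pos[i]) <= window]) >= 3
  }, TRUE)
  deleterious <- df$consequence %in% c("nonsense", "frameshift", "splice")
  scoreHit <- (!is.na(sift) & sift < 0.05) | (!is.na(poly) & poly > 0.995)
  recessiveHit <- df$gene %in% config$recessive_genes & deleterious & scoreHit
  df$driver <- nonSilent & inList & (cosmicHit | recessiveHit)
  df$driver_reason <- ifelse(!df$driver, "",
                             ifelse(cosmicHit, "cosmic", "recessive"))
  df
}

#' Filter neoantigen candidates on predicted MHC-I affinity
#'
#' Keeps peptides with predicted binding affinity strictly below
#' `affinity_max` nM (default 500).
#'
#' @param df data.frame with an `affinity_nM` column.
#' @param affinity_max Exclusive upper bound in nM.
#' @return The kept rows.
#' @export
filterNeoantigens <- function(df, affinity_max = 500) {
  .requireCols(df, "affinity_nM", "neoantigen filter input")
  if (any(df$affinity_nM < 0)) stop("negative affinity")
  df[df$affinity_nM < affinity_max, , drop = FALSE]
}
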