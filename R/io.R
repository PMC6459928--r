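#' @include classes.R
NULL

.requireCols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s: missing mandatory column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

.checkIntegerCol <- function(df, col, what) {
  x <- df[[col]]
  num <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & (is.na(num) | num != round(num) | num < 0))
  if (length(bad) > 0) {
    stop(sprintf("%s: column '%s' must hold non-negative integers (first bad data line: %d)",
                 what, col, bad[1] + 1L), call. = FALSE)
  }
  as.integer(num)
}

#' Build canonical mutation ids
#'
#' Mutation identity is `patient:chrom:pos:ref:alt`.
#' @param patient_id,chrom,pos,ref,alt Vectors of equal length.
#' @return Character vector of ids.
#' @export
mutationId <- function(patient_id, chrom, pos, ref, alt) {
  paste(patient_id, chrom, pos, ref, alt, sep = ":")
}

#' Read a MAF-like somatic mutation table
#'
#' Reads a TSV with one row per (mutation, sample). Mandatory columns:
#' `patient_id`, `sample_id`, `chrom`, `pos`, `ref`, `alt`, `variant_type`,
#' `alt_reads`, `ref_reads`. Optional columns (`gene`, `consequence`,
#' `sift`, `polyphen`, `tri_context`) are carried through when present;
#' unknown columns are ignored. Missing (mutation, sample) combinations
#' within a patient are completed with zero counts so that every mutation
#' carries counts for every sample of its patient.
#'
#' Coordinates are 1-based. SNVs must have single-base ref and alt.
#'
#' @param path Path to the TSV file.
#' @return A data.frame in long format with a `mutation_id` column.
#' @export
readMutationTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  mand <- c("patient_id", "sample_id", "chrom", "pos", "ref", "alt",
            "variant_type", "alt_reads", "ref_reads")
  .requireCols(df, mand, "mutation table")
  if (nrow(df) == 0) {
    df$mutation_id <- character(0)
    return(df)
  }
  df$pos <- .checkIntegerCol(df, "pos", "mutation table")
  df$alt_reads <- .checkIntegerCol(df, "alt_reads", "mutation table")
  df$ref_reads <- .checkIntegerCol(df, "ref_reads", "mutation table")
  if (any(df$pos < 1)) stop("mutation table: pos must be >= 1")
  snv <- df$variant_type == "SNV"
  if (any(snv & (nchar(df$ref) != 1 | nchar(df$alt) != 1))) {
    stop("mutation table: SNVs must have single-base ref and alt")
  }
  opt <- intersect(c("gene", "consequence", "sift", "polyphen", "tri_context"),
                   names(df))
  for (col in intersect(c("sift", "polyphen"), opt)) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df <- df[, c(mand, opt)]
  df$mutation_id <- mutationId(df$patient_id, df$chrom, df$pos, df$ref, df$alt)
  completeMutationCounts(df)
}

#' Complete a long mutation table to the full mutation x sample grid
#'
#' Within each patient, adds zero-count rows for (mutation, sample)
#' combinations absent from the table, so presence/absence is explicit.
#'
#' @param df Long mutation data.frame (see [readMutationTable()]).
#' @return The completed data.frame.
#' @export
completeMutationCounts <- function(df) {
  if (nrow(df) == 0) return(df)
  out <- lapply(split(df, df$patient_id), function(d) {
    samples <- unique(d$sample_id)
    muts <- unique(d$mutation_id)
    full <- expand.grid(mutation_id = muts, sample_id = samples,
                        stringsAsFactors = FALSE)
    key <- paste(d$mutation_id, d$sample_id)
    fullkey <- paste(full$mutation_id, full$sample_id)
    if (anyDuplicated(key)) stop("duplicate (mutation, sample) rows")
    miss <- full[!(fullkey %in% key), , drop = FALSE]
    if (nrow(miss) == 0) return(d)
    anno <- d[!duplicated(d$mutation_id),
              setdiff(names(d), c("sample_id", "alt_reads", "ref_reads"))]
    add <- merge(miss, anno, by = "mutation_id", sort = FALSE)
    add$alt_reads <- 0L
    add$ref_reads <- 0L
    rbind(d, add[, names(d)])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a sample metadata table
#'
#' TSV with columns `patient_id`, `sample_id`, `sample_type` (one of
#' `primary_region`, `lymph_node_met`, `normal_tissue`, `blood`) and
#' optionally `purity`, `ploidy`, `mean_depth`.
#'
#' @param path Path to the TSV.
#' @return data.frame of sample metadata.
#' @export
readSampleTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .requireCols(df, c("patient_id", "sample_id", "sample_type"), "sample table")
  ok <- c("primary_region", "lymph_node_met", "normal_tissue", "blood")
  if (!all(df$sample_type %in% ok)) {
    stop("sample table: unknown sample_type value")
  }
  if ("purity" %in% names(df) &&
      any(!is.na(df$purity) & (df$purity <= 0 | df$purity > 1))) {
    stop("sample table: purity must lie in (0, 1]")
  }
  df
}

#' Read an allele-specific copy-number segment table (SEG-like TSV)
#'
#' Columns: `sample_id`, `chrom`, `start`, `end`, `log_r`, `n_major`,
#' `n_minor`; 1-based closed intervals, `n_major >= n_minor`.
#'
#' @param path Path to the TSV.
#' @return data.frame of segments.
#' @export
readSegmentTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .requireCols(df, c("sample_id", "chrom", "start", "end", "log_r",
                     "n_major", "n_minor"), "segment table")
  df$chrom <- as.character(df$chrom)
  df$n_major <- .checkIntegerCol(df, "n_major", "segment table")
  df$n_minor <- .checkIntegerCol(df, "n_minor", "segment table")
  if (any(df$start > df$end)) stop("segment table: start > end")
  if (any(df$n_major < df$n_minor)) stop("segment table: n_major < n_minor")
  df
}

#' Read a per-SNP B-allele count table
#'
#' Columns: `sample_id`, `chrom`, `pos`, `a_reads`, `b_reads`, optional
#' `phase_id`. Requires `a_reads + b_reads > 0` on every row.
#'
#' @param path Path to the TSV.
#' @return data.frame of SNP BAF records with a derived `baf` column.
#' @export
readSnpBafTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .requireCols(df, c("sample_id", "chrom", "pos", "a_reads", "b_reads"),
               "SNP BAF table")
  df$chrom <- as.character(df$chrom)
  df$pos <- .checkIntegerCol(df, "pos", "SNP BAF table")
  df$a_reads <- .checkIntegerCol(df, "a_reads", "SNP BAF table")
  df$b_reads <- .checkIntegerCol(df, "b_reads", "SNP BAF table")
  if (any(df$a_reads + df$b_reads <= 0)) {
    stop("SNP BAF table: a_reads + b_reads must be positive")
  }
  df$baf <- df$b_reads / (df$a_reads + df$b_reads)
  df
}

#' Read an AIRR-style TCR clone table
#'
#' Columns: `sample_id`, `chain` (TRA/TRB), `cdr3_aa`, `v_gene`, `j_gene`,
#' `count` (positive integer), `productive` (logical).
#'
#' @param path Path to the TSV.
#' @return data.frame of TCR clone records.
#' @export
readTcrTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .requireCols(df, c("sample_id", "chain", "cdr3_aa", "v_gene", "j_gene",
                     "count", "productive"), "TCR table")
  df$count <- .checkIntegerCol(df, "count", "TCR table")
  if (any(df$count < 1)) stop("TCR table: counts must be positive")
  if (!all(df$chain %in% c("TRA", "TRB"))) {
    stop("TCR table: chain must be TRA or TRB")
  }
  df$productive <- as.logical(df$productive)
  df
}

#' Write a data.frame as TSV
#'
#' Writer used for all tabular outputs; plain `write.table` with tabs,
#' no quoting, no row names.
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a tree in newick format
#'
#' Accepts a [PhyloTree-class], an [ape::phylo], or a newick string.
#' Duplicate leaf labels are an error. Round-trips through
#' [ape::read.tree()] with identical topology and branch lengths.
#'
#' @param tree The tree.
#' @param path Output path.
#' @param collapse For `PhyloTree` input, collapse mutation-free internal
#'   edges before writing.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(tree, path, collapse = FALSE) {
  if (is(tree, "PhyloTree")) tree <- asPhylo(tree, collapse = collapse)
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) stop("tree must be a PhyloTree or ape phylo")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels are not allowed in newick output")
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch lengths")
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a newick tree file
#' @param path Path to a newick file.
#' @return An [ape::phylo] object.
#' @export
readNewick <- function(path) ape::read.tree(path)
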