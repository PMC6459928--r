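#' The 96 trinucleotide substitution channels
#'
#' Channel labels in the fixed catalog order: six pyrimidine-standardized
#' substitution classes (C>A, C>G, C>T, T>A, T>C, T>G), each crossed with the
#' 4 x 4 flanking-base combinations, 5' base varying slowest within a class
#' and 3' base fastest. Labels have the form `"A[C>A]A"`.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(substitutionChannels())
substitutionChannels <- function() {
  cls <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  b <- c("A", "C", "G", "T")
  unlist(lapply(cls, function(cl) {
    as.vector(t(outer(b, b, function(p, q) paste0(p, "[", cl, "]", q))))
  }), use.names = FALSE)
}

#' Load the packaged 30-signature catalog
#'
#' Reads the synthetic 96-channel x 30-signature probability catalog shipped
#' with the package (`inst/extdata/signature_catalog_synthetic.tsv`). The
#' catalog is a synthetic stand-in constructed for validation: signatures
#' 1, 2, 6, 13 and 22 carry the motif structure of their well-known
#' namesakes (CpG C>T aging, TpC APOBEC, T>A aristolochic acid, ...),
#' signature 3 is a broad dispersed profile standing in for the
#' homologous-recombination-deficiency signature, and the remainder are
#' sparse peaked profiles. Each column sums to 1. See the package vignette
#' for why a synthetic catalog is used and what that implies.
#'
#' @param path Optional path to an alternative catalog TSV (channels in rows,
#'   first column `channel`, one column per signature).
#' @return Numeric 96 x 30 matrix, rownames = channels, colnames =
#'   `Signature.1` ... `Signature.30`.
#' @export
signatureCatalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "signature_catalog_synthetic.tsv",
                        package = "mrith", mustWork = TRUE)
  }
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot("channel" %in% names(tab))
  m <- as.matrix(tab[, setdiff(names(tab), "channel"), drop = FALSE])
  rownames(m) <- tab$channel
  ch <- substitutionChannels()
  if (!identical(rownames(m), ch)) {
    if (!setequal(rownames(m), ch)) {
      stop("catalog channels do not match the 96-channel convention")
    }
    m <- m[ch, , drop = FALSE]
  }
  sums <- colSums(m)
  if (any(abs(sums - 1) > 1e-6)) stop("catalog columns must sum to 1")
  m
}

# complement a single base
.comp <- c(A = "T", C = "G", G = "C", T = "A")

#' Normalize a mutation to its pyrimidine-standardized channel
#'
#' Maps an SNV (ref, alt, trinucleotide context around the ref base) to one
#' of the 96 channels. Purine reference bases are reverse-complemented first,
#' so e.g. an `A[G>T]C` mutation is counted in the `G[C>A]T` channel.
#'
#' @param ref,alt Single reference/alternate bases.
#' @param context 3-mer string whose middle base equals `ref`.
#' @return Channel label, or `NA_character_` for malformed input.
#' @export
channelOf <- function(ref, alt, context) {
  n <- max(length(ref), length(alt), length(context))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  context <- rep_len(toupper(context), n)
  out <- rep(NA_character_, n)
  ok <- !is.na(ref) & !is.na(alt) & !is.na(context) &
    nchar(ref) == 1L & nchar(alt) == 1L & nchar(context) == 3L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt & substr(context, 2L, 2L) == ref &
    grepl("^[ACGT]{3}$", context)
  if (!any(ok)) return(out)
  r <- ref[ok]; a <- alt[ok]; ctx <- context[ok]
  pur <- r %in% c("A", "G")
  if (any(pur)) {
    rc3 <- function(s) {
      vapply(strsplit(s, ""), function(x) paste(.comp[rev(x)], collapse = ""), "")
    }
    ctx[pur] <- rc3(ctx[pur])
    r[pur] <- .comp[r[pur]]
    a[pur] <- .comp[a[pur]]
  }
  out[ok] <- paste0(substr(ctx, 1, 1), "[", r, ">", a, "]", substr(ctx, 3, 3))
  out
}
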