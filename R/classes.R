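#' @include mrith-package.R
NULL

# ---------------------------------------------------------------- PhyloTree

#' PhyloTree: a rooted multi-region tumor phylogeny
#'
#' Rooted sample tree for one patient. Leaves are tumor samples; the root is
#' the germline (all-zero mutation profile) and the edge from the germline
#' into the tree is the trunk. Every mutation of the patient's presence
#' matrix is assigned to exactly one edge; edge lengths are mutation counts.
#'
#' @slot patient Patient identifier.
#' @slot phylo An [ape::phylo] object over the tumor samples. `root.edge`
#'   carries the trunk length.
#' @slot trunkMutations Character vector of mutation ids on the trunk.
#' @slot edgeMutations List parallel to `phylo$edge` rows; each element a
#'   character vector of mutation ids assigned to that edge.
#' @slot score Parsimony score of the reconstruction.
#' @slot coOptimal Newick strings of all co-optimal topologies (including
#'   the reported one).
#' @slot presence The binary presence matrix the tree was inferred from
#'   (mutations x samples).
#' @export
setClass("PhyloTree", representation(
  patient = "character",
  phylo = "ANY",
  trunkMutations = "character",
  edgeMutations = "list",
  score = "numeric",
  coOptimal = "character",
  presence = "matrix"
))

setValidity("PhyloTree", function(object) {
  ph <- object@phylo
  if (!inherits(ph, "phylo")) return("phylo slot must be an ape 'phylo' object")
  if (length(object@edgeMutations) != nrow(ph$edge)) {
    return("edgeMutations must have one element per edge")
  }
  assigned <- c(object@trunkMutations, unlist(object@edgeMutations))
  if (anyDuplicated(assigned)) return("a mutation is assigned to two edges")
  if (nrow(object@presence) > 0 &&
      !setequal(assigned, rownames(object@presence))) {
    return("edge assignment does not cover the presence matrix rows exactly")
  }
  TRUE
})

#' @describeIn PhyloTree sample (leaf) labels
#' @param x,object A `PhyloTree`.
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @rdname PhyloTree
#' @export
setMethod("sampleNames", "PhyloTree", function(x) x@phylo$tip.label)

#' @describeIn PhyloTree mutation ids on the trunk edge
#' @export
setGeneric("trunkMutations", function(x) standardGeneric("trunkMutations"))

#' @rdname PhyloTree
#' @export
setMethod("trunkMutations", "PhyloTree", function(x) x@trunkMutations)

#' @describeIn PhyloTree parsimony score of the reconstruction
#' @export
setGeneric("parsimonyScore", function(x) standardGeneric("parsimonyScore"))

#' @rdname PhyloTree
#' @export
setMethod("parsimonyScore", "PhyloTree", function(x) x@score)

#' @describeIn PhyloTree convert to an [ape::phylo]; with `collapse = TRUE`
#'   internal edges carrying no mutations are collapsed into multifurcations.
#' @param collapse Collapse mutation-free internal edges.
#' @export
setGeneric("asPhylo", function(x, collapse = FALSE) standardGeneric("asPhylo"))

#' @rdname PhyloTree
#' @export
setMethod("asPhylo", "PhyloTree", function(x, collapse = FALSE) {
  ph <- x@phylo
  if (collapse) ph <- ape::di2multi(ph, tol = 0.5)
  ph
})

setMethod("show", "PhyloTree", function(object) {
  ph <- object@phylo
  cat("PhyloTree for patient", object@patient, "\n")
  cat(" ", length(ph$tip.label), "samples:",
      paste(ph$tip.label, collapse = ", "), "\n")
  cat(" ", nrow(object@presence), "mutations;",
      length(object@trunkMutations), "on the trunk\n")
  cat("  parsimony score:", object@score,
      "| co-optimal topologies:", length(object@coOptimal), "\n")
})

# ------------------------------------------------------------ TcrRepertoire

#' TcrRepertoire: productive TCR clones of one sample and chain
#'
#' Holds the productive clone frequency table of one sample for one chain
#' (TRA or TRB) after preprocessing (see [preprocessRepertoire()]). Clone
#' identity is the (CDR3 amino-acid sequence, V gene, J gene) triple.
#'
#' @slot sample Sample identifier.
#' @slot chain `"TRA"` or `"TRB"`.
#' @slot clones data.frame with columns `clone_id`, `cdr3_aa`, `v_gene`,
#'   `j_gene`, `count`, `freq`; frequencies sum to 1.
#' @slot totalReads Total productive read count the frequencies refer to.
#' @export
setClass("TcrRepertoire", representation(
  sample = "character",
  chain = "character",
  clones = "data.frame",
  totalReads = "numeric"
))

setValidity("TcrRepertoire", function(object) {
  cl <- object@clones
  need <- c("clone_id", "cdr3_aa", "v_gene", "j_gene", "count", "freq")
  if (!all(need %in% names(cl))) {
    return(paste("clones needs columns:", paste(need, collapse = ", ")))
  }
  if (!object@chain %in% c("TRA", "TRB")) return("chain must be TRA or TRB")
  if (nrow(cl) > 0 && abs(sum(cl$freq) - 1) > 1e-9) {
    return("clone frequencies must sum to 1")
  }
  if (anyDuplicated(cl$clone_id)) return("duplicate clone ids")
  TRUE
})

#' @describeIn TcrRepertoire number of distinct clones
#' @param x,object A `TcrRepertoire`.
#' @export
setGeneric("nClones", function(x) standardGeneric("nClones"))

#' @rdname TcrRepertoire
#' @export
setMethod("nClones", "TcrRepertoire", function(x) nrow(x@clones))

#' @describeIn TcrRepertoire clone frequency vector, named by clone id
#' @export
setGeneric("cloneFrequencies", function(x) standardGeneric("cloneFrequencies"))

#' @rdname TcrRepertoire
#' @export
setMethod("cloneFrequencies", "TcrRepertoire", function(x) {
  setNames(x@clones$freq, x@clones$clone_id)
})

setMethod("show", "TcrRepertoire", function(object) {
  cat("TcrRepertoire:", object@sample, "/", object@chain, "\n")
  cat(" ", nrow(object@clones), "productive clones,",
      format(object@totalReads, big.mark = ","), "reads\n")
  if (nrow(object@clones) > 0) {
    top <- object@clones[order(-object@clones$freq), ][1, ]
    cat("  top clone:", top$clone_id,
        sprintf("(%.3g%%)", 100 * top$freq), "\n")
  }
})

# -------------------------------------------------------- SignatureExposure

#' SignatureExposure: fitted contributions of the 30-signature catalog
#'
#' Result of non-negative least-squares deconvolution of a 96-channel
#' spectrum ([fitExposures()]). Contributions are on the mutation-count
#' scale; proportions are contributions divided by their total.
#'
#' @slot id Sample, patient or phase identifier.
#' @slot contributions Named non-negative numeric vector (30 signatures).
#' @slot proportions Contributions normalized to sum 1 (all-zero when the
#'   spectrum was empty).
#' @slot dominant Name of the signature with the highest proportion
#'   (`NA_character_` for an empty spectrum; ties broken by lowest index).
#' @slot reconstructionError Euclidean norm of catalog %*% x - spectrum.
#' @slot nMutations Number of SNVs in the spectrum.
#' @export
setClass("SignatureExposure", representation(
  id = "character",
  contributions = "numeric",
  proportions = "numeric",
  dominant = "character",
  reconstructionError = "numeric",
  nMutations = "numeric"
))

setValidity("SignatureExposure", function(object) {
  if (any(object@contributions < -1e-9)) return("negative contribution")
  tot <- sum(object@proportions)
  if (tot > 0 && abs(tot - 1) > 1e-6) return("proportions must sum to 1 (or 0)")
  TRUE
})

#' @describeIn SignatureExposure named proportion vector
#' @param x,object A `SignatureExposure`.
#' @export
setGeneric("exposureProportions",
           function(x) standardGeneric("exposureProportions"))

#' @rdname SignatureExposure
#' @export
setMethod("exposureProportions", "SignatureExposure",
          function(x) x@proportions)

#' @describeIn SignatureExposure dominant signature name
#' @export
setGeneric("dominantSignature",
           function(x) standardGeneric("dominantSignature"))

#' @rdname SignatureExposure
#' @export
setMethod("dominantSignature", "SignatureExposure", function(x) x@dominant)

setMethod("show", "SignatureExposure", function(object) {
  cat("SignatureExposure:", object@id,
      sprintf("(%d SNVs)\n", as.integer(object@nMutations)))
  if (is.na(object@dominant)) {
    cat("  empty spectrum\n")
    return(invisible(NULL))
  }
  pr <- sort(object@proportions, decreasing = TRUE)
  pr <- pr[pr > 0.01]
  cat("  dominant:", object@dominant, "\n")
  cat("  top contributions:",
      paste(sprintf("%s=%.2f", names(head(pr, 5)), head(pr, 5)),
            collapse = ", "), "\n")
  cat("  reconstruction error:",
      format(object@reconstructionError, digits = 4), "\n")
})
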