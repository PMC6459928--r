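#' @include classes.R io.R
NULL

#' Preprocess a TCR clone table into a repertoire
#'
#' For one sample and chain: keeps productive clones only, merges records
#' by clone identity (CDR3 amino-acid sequence + V gene + J gene), drops
#' low-frequency clones (<= `min_per_million` reads per million of the
#' sample's productive total, default 2), and — for diversity metrics —
#' downsamples to exactly `downsample_to` reads without replacement
#' (multivariate hypergeometric, seeded) when the total exceeds it.
#' Frequencies are renormalized to sum to 1.
#'
#' @param records TCR clone data.frame (see [readTcrTable()]).
#' @param sample,chain Sample id and chain (`TRA`/`TRB`) to extract.
#' @param downsample_to Read-normalization target (default one million).
#' @param min_per_million Low-frequency cutoff in reads per million.
#' @param seed Seed for the downsampling draw.
#' @return A [TcrRepertoire-class].
#' @export
preprocessRepertoire <- function(records, sample, chain,
                                 downsample_to = 1e6, min_per_million = 2,
                                 seed = 1) {
  d <- records[records$sample_id == sample & records$chain == chain &
                 records$productive, ]
  if (nrow(d) == 0) stop("no productive clones for this sample and chain")
  id <- paste(d$cdr3_aa, d$v_gene, d$j_gene, sep = "|")
  agg <- rowsum(d$count, id)
  counts <- setNames(as.numeric(agg), rownames(agg))
  total <- sum(counts)
  keep <- counts / total * 1e6 > min_per_million
  counts <- counts[keep]
  if (length(counts) == 0) stop("all clones fall below the abundance filter")
  if (sum(counts) > downsample_to) {
    set.seed(seed)
    counts <- .mvHyper(counts, downsample_to)
    counts <- counts[counts > 0]
  }
  parts <- do.call(rbind, strsplit(names(counts), "|", fixed = TRUE))
  clones <- data.frame(clone_id = names(counts), cdr3_aa = parts[, 1],
                       v_gene = parts[, 2], j_gene = parts[, 3],
                       count = as.numeric(counts),
                       freq = as.numeric(counts) / sum(counts),
                       stringsAsFactors = FALSE)
  clones <- clones[order(-clones$count, clones$clone_id), ]
  rownames(clones) <- NULL
  new("TcrRepertoire", sample = sample, chain = chain, clones = clones,
      totalReads = sum(counts))
}

# multivariate hypergeometric draw: k reads from pools `counts`
.mvHyper <- function(counts, k) {
  n <- length(counts)
  remaining <- sum(counts)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (k <= 0) break
    remaining <- remaining - counts[i]
    out[i] <- rhyper(1, counts[i], remaining, k)
    k <- k - out[i]
  }
  setNames(out, names(counts))
}

#' Diversity metrics of a TCR repertoire
#'
#' Shannon index in bits, Pielou evenness
#' (Shannon / log2(unique clone number); defined as 0 for a single-clone
#' repertoire), clonality = 1 - evenness, CR4 (summed frequency of the
#' top 4 clones) and the number of high-frequency clones (frequency
#' strictly above `high_freq_threshold`; default 1e-4, i.e. 0.01%, with
#' 1e-3 as the common alternative convention).
#'
#' @param rep A [TcrRepertoire-class].
#' @param high_freq_threshold High-frequency clone cutoff.
#' @return One-row data.frame of metrics.
#' @export
repertoireDiversity <- function(rep, high_freq_threshold = 1e-4) {
  f <- rep@clones$freq
  n <- length(f)
  shannon <- -sum(f * log2(f))
  evenness <- if (n > 1) shannon / log2(n) else 0
  data.frame(sample_id = rep@sample, chain = rep@chain,
             unique_clones = n, shannon = shannon, evenness = evenness,
             clonality = 1 - evenness,
             cr4 = sum(sort(f, decreasing = TRUE)[seq_len(min(4, n))]),
             high_freq_count = sum(f > high_freq_threshold),
             stringsAsFactors = FALSE)
}

.jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}

# Eq 5a count overlap: shared-clone reads over total reads
.countOverlap <- function(repA, repB) {
  shared <- intersect(repA@clones$clone_id, repB@clones$clone_id)
  a <- sum(repA@clones$count[repA@clones$clone_id %in% shared])
  b <- sum(repB@clones$count[repB@clones$clone_id %in% shared])
  (a + b) / (sum(repA@clones$count) + sum(repB@clones$count))
}

#' Pairwise repertoire similarity and distance between two samples
#'
#' Computes, per chain, the Jaccard index on clone identity sets and the
#' read-count overlap (shared-clone reads over total reads), then the two
#' distances with equal chain weights:
#' \deqn{D_J = 0.5 (1/J_{TRA} - 1) + 0.5 (1/J_{TRB} - 1)}
#' and the same form on the count overlap. A chain missing in either
#' sample drops out and the remaining chain takes full weight (flagged);
#' a zero Jaccard/overlap makes the distance infinite, reported as `cap`
#' with `capped = TRUE`.
#'
#' @param repsA,repsB Named lists of [TcrRepertoire-class] per chain,
#'   e.g. `list(TRA = ..., TRB = ...)`.
#' @param cap Reported value for infinite distances (default 1e6).
#' @return One-row data.frame: per-chain `jaccard_*` and `overlap_*`,
#'   `distance_jaccard`, `distance_overlap`, `chains_used`, `capped`.
#' @export
repertoireDistance <- function(repsA, repsB, cap = 1e6) {
  chains <- intersect(names(repsA), names(repsB))
  chains <- chains[!vapply(repsA[chains], is.null, TRUE) &
                     !vapply(repsB[chains], is.null, TRUE)]
  if (length(chains) == 0) stop("no chain present in both samples")
  jac <- setNames(rep(NA_real_, 2), c("TRA", "TRB"))
  ovl <- jac
  for (ch in chains) {
    jac[ch] <- .jaccard(repsA[[ch]]@clones$clone_id,
                        repsB[[ch]]@clones$clone_id)
    ovl[ch] <- .countOverlap(repsA[[ch]], repsB[[ch]])
  }
  w <- 1 / length(chains)
  dist_of <- function(v) {
    terms <- (1 / v[chains]) - 1
    if (any(!is.finite(terms))) return(structure(cap, capped = TRUE))
    structure(sum(w * terms), capped = FALSE)
  }
  dj <- dist_of(jac)
  dv <- dist_of(ovl)
  data.frame(sample_a = repsA[[chains[1]]]@sample,
             sample_b = repsB[[chains[1]]]@sample,
             jaccard_tra = jac["TRA"], jaccard_trb = jac["TRB"],
             overlap_tra = ovl["TRA"], overlap_trb = ovl["TRB"],
             distance_jaccard = as.numeric(dj),
             distance_overlap = as.numeric(dv),
             chains_used = paste(chains, collapse = "+"),
             capped = attr(dj, "capped") || attr(dv, "capped"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Neighbor-joining tree from a repertoire distance matrix
#'
#' Standard neighbor joining ([ape::nj()]); negative branch lengths are
#' clamped to 0 with the deficit moved to the sister edge, preserving
#' path lengths through the parent node.
#'
#' @param D Symmetric distance matrix with zero diagonal, >= 3 samples.
#' @return Unrooted [ape::phylo] tree.
#' @export
buildNjTree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("need at least 3 samples")
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix is not symmetric")
  if (any(abs(diag(D)) > 1e-9)) stop("nonzero diagonal")
  ph <- ape::nj(as.dist(D))
  neg <- which(ph$edge.length < 0)
  for (e in neg) {
    deficit <- -ph$edge.length[e]
    parent <- ph$edge[e, 1]
    sibs <- setdiff(which(ph$edge[, 1] == parent), e)
    if (length(sibs) > 0) {
      ph$edge.length[sibs[1]] <- ph$edge.length[sibs[1]] + deficit
    }
    ph$edge.length[e] <- 0
  }
  ph
}

#' Concordance between a genetic tree and a TCR tree
#'
#' For every nontrivial clade of the genetic tree restricted to the
#' shared primary-region samples, checks whether the clade members are
#' mutually closer in the TCR tree (mean within-clade cophenetic
#' distance) than to non-members (mean member-to-non-member distance).
#' The score is the fraction of clades satisfying this; a Spearman
#' correlation between the two cophenetic distance matrices is reported
#' alongside.
#'
#' @param genetic A [PhyloTree-class] or [ape::phylo].
#' @param tcr An [ape::phylo] (e.g. from [buildNjTree()]).
#' @param samples Optional character vector restricting the comparison
#'   (e.g. primary regions only); default = shared leaves.
#' @return list: `score` in \[0, 1\], `clades` (data.frame per clade),
#'   `spearman`.
#' @export
treeConcordance <- function(genetic, tcr, samples = NULL) {
  if (is(genetic, "PhyloTree")) genetic <- asPhylo(genetic, collapse = FALSE)
  shared <- intersect(genetic$tip.label, tcr$tip.label)
  if (!is.null(samples)) shared <- intersect(shared, samples)
  if (length(shared) < 4) stop("need at least 4 shared leaves")
  g <- ape::keep.tip(genetic, shared)
  t2 <- ape::keep.tip(tcr, shared)
  if (is.null(g$edge.length)) g$edge.length <- rep(1, nrow(g$edge))
  Dg <- ape::cophenetic.phylo(g)[shared, shared]
  Dt <- ape::cophenetic.phylo(t2)[shared, shared]
  ntip <- length(shared)
  tipsBelow <- function(ph, node) {
    if (node <= length(ph$tip.label)) return(ph$tip.label[node])
    kids <- ph$edge[ph$edge[, 1] == node, 2]
    unlist(lapply(kids, tipsBelow, ph = ph), use.names = FALSE)
  }
  clades <- lapply(seq_len(g$Nnode) + length(g$tip.label),
                   function(v) tipsBelow(g, v))
  clades <- Filter(function(cl) length(cl) >= 2 && length(cl) < ntip, clades)
  rows <- lapply(clades, function(cl) {
    outg <- setdiff(shared, cl)
    within <- mean(Dt[cl, cl][upper.tri(Dt[cl, cl])])
    between <- mean(Dt[cl, outg])
    data.frame(clade = paste(sort(cl), collapse = "|"),
               within = within, between = between,
               concordant = within < between, stringsAsFactors = FALSE)
  })
  cladeTab <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(clade = character(0), within = numeric(0),
               between = numeric(0), concordant = logical(0))
  score <- if (nrow(cladeTab) > 0) mean(cladeTab$concordant) else NA_real_
  sp <- suppressWarnings(
    cor(Dg[upper.tri(Dg)], Dt[upper.tri(Dt)], method = "spearman"))
  list(score = score, clades = cladeTab, spearman = sp)
}
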