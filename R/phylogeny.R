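#' @include classes.R tree-utils.R
NULL

#' Binary mutation presence matrix for one patient
#'
#' A mutation is present in a tumor sample when its VAF is at least
#' `vaf_min` (default 0.02) and it has at least `min_alt` supporting reads
#' (default 2; a guard against single-read presence calls at high depth).
#' Rows that end up all-zero are dropped with a warning. The VAF matrix is
#' attached as attribute `vaf`.
#'
#' @param mutations Long mutation data.frame (see [readMutationTable()]).
#' @param samples Optional sample metadata; when given, only
#'   `primary_region` and `lymph_node_met` samples enter the matrix,
#'   otherwise all samples present in `mutations` are used.
#' @param vaf_min,min_alt Presence thresholds.
#' @return Integer 0/1 matrix, mutations x samples, with attribute `vaf`.
#' @export
buildPresenceMatrix <- function(mutations, samples = NULL, vaf_min = 0.02,
                                min_alt = 2) {
  df <- mutations
  if (!is.null(samples)) {
    tumor <- samples$sample_id[samples$sample_type %in%
                                 c("primary_region", "lymph_node_met")]
    df <- df[df$sample_id %in% tumor, ]
  }
  sampleIds <- sort(unique(df$sample_id))
  if (length(sampleIds) < 2) stop("need at least 2 tumor samples")
  mutIds <- unique(df$mutation_id)
  total <- df$alt_reads + df$ref_reads
  vaf <- ifelse(total > 0, df$alt_reads / total, 0)
  V <- matrix(0, nrow = length(mutIds), ncol = length(sampleIds),
              dimnames = list(mutIds, sampleIds))
  A <- V
  V[cbind(match(df$mutation_id, mutIds), match(df$sample_id, sampleIds))] <- vaf
  A[cbind(match(df$mutation_id, mutIds), match(df$sample_id, sampleIds))] <-
    df$alt_reads
  P <- (V >= vaf_min & A >= min_alt) * 1L
  allZero <- rowSums(P) == 0
  if (any(allZero)) {
    warning(sprintf("%d mutation(s) unsupported in every sample; dropped",
                    sum(allZero)))
    P <- P[!allZero, , drop = FALSE]
    V <- V[!allZero, , drop = FALSE]
  }
  attr(P, "vaf") <- V
  P
}

.BIG <- 1e9

# Sankoff cost of one topology for all character patterns at once.
# pat: k x n 0/1 matrix (columns in leaf-label order `labels`);
# returns list(total score given counts, per-pattern cost).
.scoreTopology <- function(tree, pat, counts, labels, gain = 1, loss = 10) {
  rec <- function(node) {
    if (is.character(node)) {
      j <- match(node, labels)
      obs <- pat[, j]
      return(list(c0 = ifelse(obs == 0, 0, .BIG),
                  c1 = ifelse(obs == 1, 0, .BIG)))
    }
    c0 <- 0; c1 <- 0
    for (ch in node) {
      sub <- rec(ch)
      c0 <- c0 + pmin(sub$c0, sub$c1 + gain)
      c1 <- c1 + pmin(sub$c0 + loss, sub$c1)
    }
    list(c0 = c0, c1 = c1)
  }
  r <- rec(tree)
  perPattern <- pmin(r$c0, r$c1 + gain)   # germline state is 0
  list(score = sum(perPattern * counts), perPattern = perPattern)
}

# depth-first enumeration of rooted binary topologies; fun(tree) per tree
.enumTopologies <- function(labels, fun) {
  rec <- function(tree, remaining) {
    if (length(remaining) == 0) {
      fun(tree)
      return(invisible(NULL))
    }
    leaf <- remaining[1]
    for (t2 in .allInsertions(tree, leaf)) rec(t2, remaining[-1])
  }
  rec(labels[1], labels[-1])
  invisible(NULL)
}

# all ways to insert `leaf` above any node of `tree` (i.e. on any edge,
# including above the root)
.allInsertions <- function(tree, leaf) {
  out <- list(list(tree, leaf))
  if (is.list(tree)) {
    for (i in seq_along(tree)) {
      for (sub in .allInsertions(tree[[i]], leaf)) {
        t2 <- tree
        t2[[i]] <- sub
        out[[length(out) + 1L]] <- t2
      }
    }
  }
  out
}

# backtrack one optimal state reconstruction for every pattern on `tree`;
# returns a list of gain-edge keys per pattern (gain = parent 0, child 1),
# choosing state 1 on cost ties so gains sit as close to the root as
# possible, and reporting for each pattern the gain edge with the largest
# leaf set.
.assignGains <- function(tree, pat, labels, gain = 1, loss = 10) {
  k <- nrow(pat)
  nodes <- list(); edgesBelow <- list()
  build <- function(node) {
    if (is.character(node)) {
      j <- match(node, labels)
      obs <- pat[, j]
      return(list(node = node,
                  c0 = ifelse(obs == 0, 0, .BIG),
                  c1 = ifelse(obs == 1, 0, .BIG),
                  leaves = node, children = NULL))
    }
    kids <- lapply(node, build)
    c0 <- 0; c1 <- 0
    for (kd in kids) {
      c0 <- c0 + pmin(kd$c0, kd$c1 + gain)
      c1 <- c1 + pmin(kd$c0 + loss, kd$c1)
    }
    list(node = node, c0 = c0, c1 = c1,
         leaves = unlist(lapply(kids, `[[`, "leaves"), use.names = FALSE),
         children = kids)
  }
  root <- build(tree)
  gainEdges <- vector("list", k)
  walk <- function(nd, parentState) {
    # choose this node's state per pattern
    costIf0 <- nd$c0 + ifelse(parentState == 1, loss, 0)
    costIf1 <- nd$c1 + ifelse(parentState == 0, gain, 0)
    st <- ifelse(costIf1 <= costIf0, 1L, 0L)
    gained <- which(parentState == 0L & st == 1L)
    if (length(gained) > 0) {
      key <- .edgeKey(nd$leaves)
      nl <- length(nd$leaves)
      for (i in gained) {
        gainEdges[[i]] <<- rbind(gainEdges[[i]],
                                 data.frame(key = key, size = nl,
                                            stringsAsFactors = FALSE))
      }
    }
    if (!is.null(nd$children)) for (kd in nd$children) walk(kd, st)
  }
  walk(root, rep(0L, k))
  vapply(gainEdges, function(g) {
    if (is.null(g)) return(NA_character_)
    g$key[order(-g$size, g$key)][1]
  }, "")
}

#' Infer a maximum-parsimony sample tree from a presence matrix
#'
#' Exhaustively enumerates all rooted binary topologies over the tumor
#' samples (root = germline, all-zero profile) and scores each by discrete
#' character parsimony with asymmetric costs: a 0 to 1 gain costs
#' `gain_cost` (1) and a 1 to 0 reversal costs `loss_cost` (10, making
#' losses effectively forbidden — somatic point mutations are not undone
#' except by deletion). The minimum-score topologies are the co-optimal
#' set; the reported tree maximizes trunk length and then takes the
#' lexicographically smallest canonical newick. Each mutation is assigned
#' to the gain edge of an optimal reconstruction (the one covering the
#' most samples when a pattern needs several gains).
#'
#' Exhaustive search is bounded at 9 samples; larger patients need a
#' heuristic search, which this package does not provide.
#'
#' @param presence 0/1 matrix from [buildPresenceMatrix()].
#' @param patient Patient label for the result object.
#' @param gain_cost,loss_cost Character change costs.
#' @return A [PhyloTree-class].
#' @export
inferParsimonyTree <- function(presence, patient = "patient",
                               gain_cost = 1, loss_cost = 10) {
  n <- ncol(presence)
  if (n < 2) stop("need at least 2 samples")
  if (n > 9) {
    stop("more than 9 samples: exhaustive parsimony search is bounded at 9; ",
         "use a heuristic tree search")
  }
  labels <- colnames(presence)
  patStr <- apply(presence, 1, paste, collapse = "")
  tab <- table(patStr)
  uniqStr <- names(tab)
  counts <- as.numeric(tab)
  pat <- do.call(rbind, lapply(strsplit(uniqStr, ""), as.integer))
  if (is.null(pat)) pat <- matrix(0L, 0, n)

  best <- Inf
  bestTrees <- list()
  .enumTopologies(labels, function(tr) {
    sc <- .scoreTopology(tr, pat, counts, labels, gain_cost, loss_cost)$score
    if (sc < best - 1e-9) {
      best <<- sc
      bestTrees <<- list(tr)
    } else if (sc < best + 1e-9) {
      bestTrees[[length(bestTrees) + 1L]] <<- tr
    }
  })

  newicks <- vapply(bestTrees, .treeToNewick, "")
  dup <- duplicated(newicks)
  bestTrees <- bestTrees[!dup]
  newicks <- newicks[!dup]

  trunkCount <- vapply(bestTrees, function(tr) {
    g <- .assignGains(tr, pat, labels, gain_cost, loss_cost)
    sum(counts[g == .edgeKey(labels)])
  }, 0)
  keep <- which(trunkCount == max(trunkCount))
  sel <- keep[order(newicks[keep])][1]
  tree <- bestTrees[[sel]]

  gains <- .assignGains(tree, pat, labels, gain_cost, loss_cost)
  mutEdgeKey <- setNames(gains[match(patStr, uniqStr)], rownames(presence))

  edgeKeys <- vapply(.treeEdges(tree), .edgeKey, "")
  lengths <- setNames(vapply(edgeKeys, function(k)
    sum(mutEdgeKey == k), 0), edgeKeys)
  ph <- .nestedToApe(tree, lengths)
  if (is.null(ph$root.edge)) ph$root.edge <- 0

  phKeys <- .phyloEdgeKeys(ph)
  edgeMut <- lapply(phKeys, function(k) names(mutEdgeKey)[mutEdgeKey == k])
  trunkKey <- .edgeKey(labels)
  trunkMut <- names(mutEdgeKey)[mutEdgeKey == trunkKey]

  new("PhyloTree", patient = patient, phylo = ph,
      trunkMutations = trunkMut, edgeMutations = edgeMut,
      score = best, coOptimal = sort(newicks), presence = presence)
}

# canonical leaf-set key for every edge (row of ph$edge)
.phyloEdgeKeys <- function(ph) {
  ntip <- length(ph$tip.label)
  tipsBelow <- function(node) {
    if (node <= ntip) return(ph$tip.label[node])
    kids <- ph$edge[ph$edge[, 1] == node, 2]
    unlist(lapply(kids, tipsBelow), use.names = FALSE)
  }
  vapply(seq_len(nrow(ph$edge)), function(i)
    .edgeKey(tipsBelow(ph$edge[i, 2])), "")
}

#' Classify mutation timing: trunk, shared branch, or private
#'
#' Trunk mutations are present in every tumor sample of the patient,
#' private mutations in exactly one, shared-branch mutations in some but
#' not all.
#'
#' @param presence 0/1 presence matrix (or a [PhyloTree-class], whose
#'   stored matrix is used).
#' @return `list(labels, summary)`: per-mutation labels and a one-row
#'   data.frame of counts and proportions.
#' @export
classifyTiming <- function(presence) {
  if (is(presence, "PhyloTree")) presence <- presence@presence
  nS <- ncol(presence)
  nP <- rowSums(presence)
  labels <- ifelse(nP == nS, "trunk", ifelse(nP == 1, "private", "shared"))
  names(labels) <- rownames(presence)
  counts <- c(trunk = sum(labels == "trunk"),
              shared = sum(labels == "shared"),
              private = sum(labels == "private"))
  total <- sum(counts)
  summary <- data.frame(
    n_trunk = counts["trunk"], n_shared = counts["shared"],
    n_private = counts["private"], n_total = total,
    prop_trunk = if (total > 0) counts[["trunk"]] / total else NA_real_,
    prop_shared = if (total > 0) counts[["shared"]] / total else NA_real_,
    prop_private = if (total > 0) counts[["private"]] / total else NA_real_,
    prop_heterogeneous = if (total > 0)
      (counts[["shared"]] + counts[["private"]]) / total else NA_real_,
    row.names = NULL)
  list(labels = labels, summary = summary)
}

# edges (keys) on the root-to-leaf path of `sample` in a PhyloTree
.pathKeys <- function(tree, sample) {
  keys <- .phyloEdgeKeys(tree@phylo)
  onPath <- vapply(strsplit(keys, "|", fixed = TRUE),
                   function(lv) sample %in% lv, TRUE)
  c(.edgeKey(sampleNames(tree)), keys[onPath])
}

#' Detect intermixed clones across tumor regions
#'
#' A sample is flagged as intermixed when it carries, at CCF >=
#' `ccf_min`, a block of at least `min_block` mutations assigned to a
#' branch that is not on the sample's own root-to-leaf path — cells of a
#' foreign clade physically present in the region.
#'
#' @param tree A [PhyloTree-class].
#' @param ccf Long CCF data.frame (`mutation_id`, `sample_id`, `ccf`),
#'   e.g. from [ccfTable()].
#' @param ccf_min CCF threshold (default 0.1).
#' @param min_block Minimum number of qualifying mutations on the foreign
#'   branch.
#' @return data.frame with one row per (sample, foreign branch) flag:
#'   columns `sample_id`, `branch` (leaf-set key), `n_mutations`,
#'   `mean_ccf`.
#' @export
detectIntermixing <- function(tree, ccf, ccf_min = 0.1, min_block = 3) {
  keys <- .phyloEdgeKeys(tree@phylo)
  edgeMut <- tree@edgeMutations
  out <- list()
  for (s in sampleNames(tree)) {
    onPath <- .pathKeys(tree, s)
    ccfS <- ccf[ccf$sample_id == s, ]
    ccfMap <- setNames(ccfS$ccf, ccfS$mutation_id)
    for (i in seq_along(keys)) {
      if (keys[i] %in% onPath) next
      muts <- edgeMut[[i]]
      if (length(muts) == 0) next
      v <- ccfMap[muts]
      hit <- !is.na(v) & v >= ccf_min
      if (sum(hit) >= min_block) {
        out[[length(out) + 1L]] <- data.frame(
          sample_id = s, branch = keys[i], n_mutations = sum(hit),
          mean_ccf = mean(v[hit]), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(sample_id = character(0), branch = character(0),
                      n_mutations = integer(0), mean_ccf = numeric(0)))
  }
  do.call(rbind, out)
}

#' Classify the metastatic seeding pattern of a patient
#'
#' Operates on the mutation-collapsed tree (internal edges carrying no
#' mutations are contracted). Patterns:
#' * `monoclonal_precursor` — all lymph-node samples form a single clade
#'   attached at the trunk node, whose stem carries at least one mutation
#'   (metastasis-to-metastasis spread from one precursor);
#' * `linear` — the metastases nest inside a primary subclade, their
#'   attachment points forming an ancestor chain;
#' * `explosive` — two or more metastases attach independently at the
#'   trunk node;
#' * `unclassified` — anything else.
#'
#' @param tree A [PhyloTree-class].
#' @param samples Sample metadata data.frame (`sample_id`, `sample_type`).
#' @return One of the pattern strings above.
#' @export
classifySeeding <- function(tree, samples) {
  ph <- asPhylo(tree, collapse = TRUE)
  tips <- ph$tip.label
  mets <- intersect(tips, samples$sample_id[samples$sample_type ==
                                              "lymph_node_met"])
  if (length(mets) == 0) stop("no_metastasis")
  ntip <- length(tips)
  root <- ntip + 1L
  desc <- function(node) {
    if (node <= ntip) return(tips[node])
    kids <- ph$edge[ph$edge[, 1] == node, 2]
    unlist(lapply(kids, desc), use.names = FALSE)
  }
  allNodes <- seq_len(ntip + ph$Nnode)
  metOnly <- vapply(allNodes, function(v) all(desc(v) %in% mets), TRUE)
  parentOf <- function(v) {
    i <- which(ph$edge[, 2] == v)
    if (length(i) == 0) NA_integer_ else ph$edge[i, 1]
  }
  comps <- allNodes[metOnly & vapply(allNodes, function(v) {
    p <- parentOf(v)
    !is.na(p) && !metOnly[p]
  }, TRUE)]
  if (metOnly[root]) comps <- root   # degenerate: everything is a met
  parents <- vapply(comps, parentOf, 0L)
  stemLen <- vapply(comps, function(v) {
    i <- which(ph$edge[, 2] == v)
    if (length(i) == 0) 0 else ph$edge.length[i]
  }, 0)
  coversAll <- function(v) setequal(desc(v), mets)
  isAncestor <- function(a, b) {     # a strict-or-equal ancestor of b
    v <- b
    while (!is.na(v)) {
      if (v == a) return(TRUE)
      v <- parentOf(v)
    }
    FALSE
  }
  if (length(comps) == 1 && coversAll(comps[1])) {
    if (parents[1] == root) {
      if (stemLen[1] >= 1) return("monoclonal_precursor")
      return("unclassified")
    }
    return("linear")
  }
  if (length(comps) >= 2) {
    if (all(parents == root)) return("explosive")
    chain <- all(vapply(seq_along(parents), function(i)
      all(vapply(seq_along(parents), function(j)
        isAncestor(parents[i], parents[j]) ||
          isAncestor(parents[j], parents[i]), TRUE)), TRUE))
    if (chain) return("linear")
  }
  "unclassified"
}
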