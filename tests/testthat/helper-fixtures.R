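# shared fixtures and independent oracles used across test files

# small long-format mutation table written to a temp TSV
writeMutationFixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# brute-force parsimony score of one binary character on a nested-list
# topology: enumerate every internal-node state assignment explicitly
# (independent of the Sankoff DP used by the package)
bruteParsimonyScore <- function(tree, leafStates, gain = 1, loss = 10) {
  nInternal <- function(node) {
    if (is.character(node)) return(0L)
    1L + sum(vapply(node, nInternal, 0L))
  }
  k <- nInternal(tree)
  edgeCost <- function(s, t) if (t > s) gain else if (t < s) loss else 0
  grid <- as.matrix(expand.grid(rep(list(0:1), k)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    states <- grid[r, ]
    idx <- 0L
    walk <- function(node, parentState) {
      if (is.character(node)) {
        return(edgeCost(parentState, leafStates[[node]]))
      }
      idx <<- idx + 1L
      s <- states[idx]
      cost <- edgeCost(parentState, s)
      for (ch in node) cost <- cost + walk(ch, s)
      cost
    }
    best <- min(best, walk(tree, 0L))
  }
  best
}

# observed VAFs of a simulated read table, restricted to (0, 1)
readVafs <- function(df) {
  v <- df$alt / df$total
  v[v > 0 & v < 1]
}

# a TcrRepertoire built directly from named counts
makeRepertoire <- function(counts, sample = "S", chain = "TRB") {
  ids <- names(counts)
  new("TcrRepertoire", sample = sample, chain = chain,
      clones = data.frame(
        clone_id = ids, cdr3_aa = ids,
        v_gene = paste0(chain, "V1"), j_gene = paste0(chain, "J1"),
        count = as.numeric(counts),
        freq = as.numeric(counts) / sum(counts),
        stringsAsFactors = FALSE),
      totalReads = sum(counts))
}

# additive 4-taxon distance matrix for the split AB|CD
additiveMatrix4 <- function() {
  D <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  # tree: A:1, B:2 -- internal:2 -- C:3, D:1
  D["A", "B"] <- D["B", "A"] <- 3
  D["C", "D"] <- D["D", "C"] <- 4
  D["A", "C"] <- D["C", "A"] <- 6
  D["A", "D"] <- D["D", "A"] <- 4
  D["B", "C"] <- D["C", "B"] <- 7
  D["B", "D"] <- D["D", "B"] <- 5
  D
}

# leaf bipartitions (as sorted strings) induced by the internal edges of
# an unrooted/rooted phylo — topology comparison helper
leafSplits <- function(ph) {
  ntip <- length(ph$tip.label)
  below <- function(node) {
    if (node <= ntip) return(ph$tip.label[node])
    kids <- ph$edge[ph$edge[, 1] == node, 2]
    unlist(lapply(kids, below), use.names = FALSE)
  }
  splits <- lapply(ph$edge[, 2], below)
  splits <- Filter(function(s) length(s) >= 2 && length(s) <= ntip - 2,
                   splits)
  sort(unique(vapply(splits, function(s) {
    a <- sort(s); b <- sort(setdiff(ph$tip.label, s))
    if (paste(a, collapse = ",") < paste(b, collapse = ",")) {
      paste(paste(a, collapse = ","), paste(b, collapse = ","), sep = "|")
    } else {
      paste(paste(b, collapse = ","), paste(a, collapse = ","), sep = "|")
    }
  }, "")))
}
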