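# Internal helpers for rooted trees represented as nested lists:
# a leaf is its (character) label, an internal node is a list of children.

.treeLeaves <- function(tree) {
  if (is.character(tree)) return(tree)
  unlist(lapply(tree, .treeLeaves), use.names = FALSE)
}

# edge-centric view: one entry per edge, identified with the subtree below
# it; the first entry is the trunk (edge above the whole sample tree).
# Returns a list of character vectors (leaf sets), in preorder.
.treeEdges <- function(tree) {
  rec <- function(node) {
    out <- list(.treeLeaves(node))
    if (is.list(node)) {
      for (ch in node) out <- c(out, rec(ch))
    }
    out
  }
  rec(tree)
}

.treeToNewick <- function(tree) {
  rec <- function(node) {
    if (is.character(node)) return(node)
    parts <- sort(vapply(node, rec, ""))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(tree), ";")
}

# uniform-ish random rooted binary topology by random sequential joins
.randomBinaryTree <- function(labels) {
  nodes <- as.list(labels)
  while (length(nodes) > 1) {
    i <- sample.int(length(nodes), 2)
    joined <- list(nodes[[i[1]]], nodes[[i[2]]])
    nodes <- c(nodes[-i], list(joined))
  }
  nodes[[1]]
}

# convert a nested-list tree into an ape phylo with given edge lengths.
# lengths: named numeric, names are canonical leaf-set keys (see .edgeKey);
# the trunk length is returned via root.edge.
.edgeKey <- function(leaves) paste(sort(leaves), collapse = "|")

.nestedToApe <- function(tree, lengths = NULL) {
  leaves <- .treeLeaves(tree)
  n <- length(leaves)
  edges <- list()
  lens <- numeric(0)
  nodeCount <- n
  rec <- function(node) {
    if (is.character(node)) return(match(node, leaves))
    nodeCount <<- nodeCount + 1L
    me <- nodeCount
    for (ch in node) {
      id <- rec(ch)
      edges[[length(edges) + 1L]] <<- c(me, id)
      key <- .edgeKey(.treeLeaves(ch))
      lens <<- c(lens, if (is.null(lengths)) 1 else
        unname(lengths[key]))
    }
    me
  }
  root <- rec(tree)
  ph <- list(
    edge = do.call(rbind, edges),
    edge.length = ifelse(is.na(lens), 0, lens),
    tip.label = leaves,
    Nnode = nodeCount - n
  )
  class(ph) <- "phylo"
  ph <- ape::reorder.phylo(ph, "cladewise")
  if (!is.null(lengths) && !is.na(lengths[.edgeKey(leaves)])) {
    ph$root.edge <- unname(lengths[.edgeKey(leaves)])
  }
  ph
}
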