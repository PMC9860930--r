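# Tree input and branch bookkeeping. Trees are ape "phylo" objects
# throughout; branches are identified by the label of their child node.

#' Read a rooted phylogeny from a newick file
#'
#' Validates leaf-label uniqueness and non-negative branch lengths, and
#' assigns deterministic labels `N1, N2, ...` to unlabeled internal nodes so
#' every branch can be addressed by its child node label.
#'
#' @param path Path to a newick file.
#' @return An `ape::phylo` tree with internal node labels.
#' @export
read_tree <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("unparsable newick in '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("unparsable newick in '", path, "'", call. = FALSE)
  validate_tree(tr)
}

#' @rdname read_tree
#' @param text A newick string (alternative to `path`).
#' @export
read_tree_text <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("unparsable newick: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("unparsable newick", call. = FALSE)
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (ape::Ntip(tr) < 2)
    stop("tree must have at least 2 leaves", call. = FALSE)
  dups <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(dups) > 0)
    stop("duplicate leaf labels: ", paste(unique(dups), collapse = ", "),
         call. = FALSE)
  if (is.null(tr$edge.length))
    tr$edge.length <- rep(0, nrow(tr$edge))
  if (any(tr$edge.length < 0)) {
    bad <- which(tr$edge.length < 0)[1]
    stop("negative branch length (", tr$edge.length[bad], ") on edge ", bad,
         call. = FALSE)
  }
  if (is.null(tr$node.label) || any(!nzchar(tr$node.label)))
    tr$node.label <- paste0("N", seq_len(tr$Nnode))
  tr
}

#' Write a tree to newick
#'
#' @param tree An `ape::phylo` object.
#' @param path Output file path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# label of every node (tips then internals), in ape node-number order
node_labels <- function(tree) {
  c(tree$tip.label, tree$node.label)
}

#' Branch table of a tree
#'
#' One row per edge; branches are named by the child node's label.
#'
#' @param tree An `ape::phylo` object.
#' @return A tibble with columns `edge`, `parent`, `child`, `parent_label`,
#'   `child_label`, `length`, `is_tip`.
#' @export
tree_branches <- function(tree) {
  labs <- node_labels(tree)
  tibble::tibble(
    edge = seq_len(nrow(tree$edge)),
    parent = tree$edge[, 1],
    child = tree$edge[, 2],
    parent_label = labs[tree$edge[, 1]],
    child_label = labs[tree$edge[, 2]],
    length = tree$edge.length,
    is_tip = tree$edge[, 2] <= ape::Ntip(tree)
  )
}

# Resolve a branch spec (child-node label, or character vector of leaf
# labels defining a clade) to an edge index.
resolve_branch <- function(tree, spec) {
  br <- tree_branches(tree)
  if (length(spec) == 1 && spec %in% br$child_label)
    return(br$edge[match(spec, br$child_label)])
  if (all(spec %in% tree$tip.label)) {
    node <- if (length(spec) == 1) match(spec, tree$tip.label)
            else ape::getMRCA(tree, spec)
    e <- which(tree$edge[, 2] == node)
    if (length(e) == 1) return(e)
  }
  stop("cannot resolve branch spec: ", paste(spec, collapse = ","),
       call. = FALSE)
}

# Tip indices descending from the child node of an edge.
edge_descendant_tips <- function(tree, edge) {
  node <- tree$edge[edge, 2]
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  # breadth-first collection of descendant tips
  out <- integer(0); stack <- node
  while (length(stack) > 0) {
    nd <- stack[[1]]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  sort(out)
}
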