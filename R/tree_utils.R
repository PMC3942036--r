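# Internal helpers over ape "phylo" trees.
#
# Nodes are addressed by label: tips by their tip label, internal nodes by
# their newick label, with unlabelled internal nodes auto-named "N<id>".
# A branch is identified by the label of its child node; the notional
# branch above the root is "ROOT".

.tree_index <- function(tree, unique_labels = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  nl <- tree$node.label
  if (is.null(nl)) nl <- rep("", tree$Nnode)
  nl[is.na(nl) | nl == ""] <- paste0("N", which(is.na(nl) | nl == "") + n_tip)
  labels <- c(tree$tip.label, nl)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels in tree: ",
         tree$tip.label[duplicated(tree$tip.label)][1L])
  }
  # in gene trees internal "labels" are supports, not identities
  if (unique_labels && anyDuplicated(labels)) {
    stop("duplicate node labels in tree: ",
         labels[duplicated(labels)][1L])
  }
  parent <- integer(n_all)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  children <- vector("list", n_all)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    children[[p]] <- c(children[[p]], tree$edge[i, 2L])
  }
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  # postorder: children before parents
  post <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    post <- c(post, v)
    stack <- c(stack, children[[v]])
  }
  post <- rev(post)
  list(tree = tree, n_tip = n_tip, n_all = n_all, labels = labels,
       parent = parent, children = children, root = root, postorder = post)
}

.node_by_label <- function(idx, label) {
  i <- match(label, idx$labels)
  if (is.na(i)) stop("unknown node: ", label)
  i
}

# all ancestors of node v (excluding v), root last
.ancestors <- function(idx, v) {
  out <- integer(0)
  while (v != idx$root) {
    v <- idx$parent[v]
    out <- c(out, v)
  }
  out
}

# logical: is branch (above) node `a` ancestral to branch (above) node `b`?
# "ROOT" is ancestral to every branch.
.branch_ancestral <- function(idx, a, b) {
  if (identical(a, "ROOT")) return(!identical(b, "ROOT"))
  if (identical(b, "ROOT")) return(FALSE)
  ia <- .node_by_label(idx, a)
  ib <- .node_by_label(idx, b)
  ia %in% .ancestors(idx, ib)
}

# number of presence tips in the subtree of each node
.subtree_counts <- function(idx, present_tips) {
  cnt <- integer(idx$n_all)
  cnt[seq_len(idx$n_tip)] <- as.integer(seq_len(idx$n_tip) %in% present_tips)
  for (v in idx$postorder) {
    if (v > idx$n_tip) cnt[v] <- sum(cnt[idx$children[[v]]])
  }
  cnt
}
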