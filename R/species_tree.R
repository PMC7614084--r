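#' Species tree with branch lengths and optional WGD marks
#'
#' A `species_tree` is the coordinate system for every WGD placement in the
#' package: a rooted, strictly bifurcating phylogeny with non-negative branch
#' lengths in either time units or Ks units, plus an optional set of WGD marks.
#' Each mark sits on one branch at a relative position measured as a fraction
#' of the branch length from the branch's tipward end (0 = at the tipward node,
#' 1 = at the rootward node).
#'
#' Branches are identified by the leaf set of their tipward node, which is
#' invariant under any leaf-order permutation of the input newick. The root has
#' no branch above it, so WGD hypotheses on the root stem are rejected.
#'
#' @param phy an [ape::phylo] object (rooted, binary, with edge lengths).
#' @param units `"time"` or `"Ks"`.
#' @param wgd optional data.frame with columns `wgd_id`, `node` (tipward node
#'   id in `phy`), `pos` (fraction in `[0,1]`).
#' @return an object of class `species_tree`.
#' @export
species_tree <- function(phy, units = c("time", "Ks"), wgd = NULL) {
  units <- match.arg(units)
  assert_that(inherits(phy, "phylo"), "phy must be an ape 'phylo' object")
  assert_that(ape::is.rooted(phy), "species tree must be rooted")
  assert_that(ape::is.binary(phy), "species tree must be strictly bifurcating")
  assert_that(!is.null(phy$edge.length), "species tree must have branch lengths")
  assert_that(all(phy$edge.length >= 0), "branch lengths must be non-negative")
  assert_that(anyDuplicated(phy$tip.label) == 0L, "leaf labels must be unique")
  if (is.null(wgd)) {
    wgd <- data.frame(wgd_id = character(), node = integer(), pos = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    assert_that(all(c("wgd_id", "node", "pos") %in% names(wgd)),
                "wgd marks need columns wgd_id, node, pos")
    assert_that(anyDuplicated(wgd$wgd_id) == 0L, "wgd_ids must be unique tree-wide")
    assert_that(is_prob(wgd$pos), "WGD mark positions must lie in [0,1]")
    root <- ape::Ntip(phy) + 1L
    assert_that(!any(wgd$node == root),
                "WGD hypotheses on the root stem cannot be tested: the root has no branch above it")
    assert_that(all(wgd$node %in% phy$edge[, 2L]), "WGD mark node not found in tree")
  }
  structure(list(phy = phy, units = units, wgd = wgd), class = "species_tree")
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("species_tree: %d leaves, units = %s, %d WGD mark(s)\n",
              ape::Ntip(x$phy), x$units, nrow(x$wgd)))
  invisible(x)
}

#' Leaf set of the clade below a node
#' @param tree a `species_tree`.
#' @param node internal or tip node id.
#' @return sorted character vector of leaf labels.
#' @export
branch_leafset <- function(tree, node) {
  phy <- tree$phy
  if (node <= ape::Ntip(phy)) return(phy$tip.label[node])
  sort(phy$tip.label[unlist(phangorn::Descendants(phy, node, "tips"))])
}

#' Find the branch whose tipward node subtends a given leaf set
#'
#' @param tree a `species_tree`.
#' @param leaves character vector of species ids; must form a clade.
#' @return the tipward node id of the branch.
#' @export
branch_by_leafset <- function(tree, leaves) {
  phy <- tree$phy
  unknown <- setdiff(leaves, phy$tip.label)
  assert_that(length(unknown) == 0L, "unknown species in leaf set: %s",
              paste(unknown, collapse = ", "))
  if (length(leaves) == 1L) return(match(leaves, phy$tip.label))
  node <- ape::getMRCA(phy, leaves)
  clade <- branch_leafset(tree, node)
  assert_that(setequal(clade, leaves),
              "leaf set {%s} is not a clade (MRCA subtends {%s})",
              paste(sort(leaves), collapse = ","), paste(clade, collapse = ","))
  assert_that(node != ape::Ntip(phy) + 1L,
              "leaf set spans the whole tree: the root has no branch above it")
  node
}

#' Add a WGD mark to a species tree
#'
#' @param tree a `species_tree`.
#' @param wgd_id unique identifier for the event.
#' @param leaves leaf set defining the branch (tipward clade).
#' @param position fraction of the branch length from the tipward end, in
#'   `[0,1]`.
#' @return the updated `species_tree`.
#' @export
add_wgd <- function(tree, wgd_id, leaves, position = 0.5) {
  node <- branch_by_leafset(tree, leaves)
  wgd <- rbind(tree$wgd, data.frame(wgd_id = as.character(wgd_id), node = node,
                                    pos = position, stringsAsFactors = FALSE))
  species_tree(tree$phy, tree$units, wgd)
}

#' Read a species tree from newick, with WGD marks from a YAML sidecar
#'
#' WGD marks live in a sidecar YAML file rather than in newick comments so
#' that the tree file stays portable across toolchains. The sidecar maps each
#' `wgd_id` to `leaves` (the tipward clade of the branch carrying the mark) and
#' a `position` fraction.
#'
#' @param path newick file.
#' @param units `"time"` or `"Ks"`.
#' @param wgd_config optional path to a YAML file, or an already-parsed list.
#' @return a `species_tree`.
#' @export
read_species_tree <- function(path, units = c("time", "Ks"), wgd_config = NULL) {
  phy <- tryCatch(ape::read.tree(path),
                  error = function(e) abort_wgdc("malformed newick in %s: %s", path, conditionMessage(e)))
  if (is.null(phy)) abort_wgdc("malformed newick in %s", path)
  tree <- species_tree(phy, match.arg(units))
  if (!is.null(wgd_config)) {
    cfg <- if (is.character(wgd_config)) yaml::read_yaml(wgd_config) else wgd_config
    for (id in names(cfg)) {
      tree <- add_wgd(tree, id, unlist(cfg[[id]]$leaves), cfg[[id]]$position %||% 0.5)
    }
  }
  tree
}

#' Write a species tree (and optionally its WGD sidecar) to disk
#'
#' @param tree a `species_tree`.
#' @param path newick output file.
#' @param wgd_config_path optional path for the YAML sidecar holding WGD marks.
#' @return `path`, invisibly.
#' @export
write_species_tree <- function(tree, path, wgd_config_path = NULL) {
  ape::write.tree(tree$phy, file = path)
  if (!is.null(wgd_config_path)) {
    cfg <- list()
    for (i in seq_len(nrow(tree$wgd))) {
      cfg[[tree$wgd$wgd_id[i]]] <- list(
        leaves = as.list(branch_leafset(tree, tree$wgd$node[i])),
        position = tree$wgd$pos[i])
    }
    yaml::write_yaml(cfg, wgd_config_path)
  }
  invisible(path)
}

## ---- internal topology helpers ----------------------------------------------

# children of each node: list indexed by node id (empty for tips)
tree_children <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  ch <- vector("list", n)
  for (i in seq_len(nrow(phy$edge))) {
    ch[[phy$edge[i, 1L]]] <- c(ch[[phy$edge[i, 1L]]], phy$edge[i, 2L])
  }
  ch
}

# length of the branch above each node (NA for root)
branch_lengths_above <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  len <- rep(NA_real_, n)
  len[phy$edge[, 2L]] <- phy$edge.length
  len
}

# parent of each node (NA for root)
tree_parents <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  par <- rep(NA_integer_, n)
  par[phy$edge[, 2L]] <- phy$edge[, 1L]
  par
}

# node depths measured as time from the root (edge-length weighted)
node_depths <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  par <- tree_parents(phy)
  len <- branch_lengths_above(phy)
  depth <- rep(NA_real_, n)
  root <- ape::Ntip(phy) + 1L
  depth[root] <- 0
  for (nd in preorder_nodes(phy)) {
    if (nd != root) depth[nd] <- depth[par[nd]] + len[nd]
  }
  depth
}

preorder_nodes <- function(phy) {
  root <- ape::Ntip(phy) + 1L
  ch <- tree_children(phy)
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    out <- c(out, nd)
    stack <- c(ch[[nd]], stack)
  }
  out
}

postorder_nodes <- function(phy) rev(preorder_nodes(phy))
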