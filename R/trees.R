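#' @importFrom ape read.tree write.tree
#' @importFrom stats runif
#' @importFrom utils head tail
NULL

## ---------------------------------------------------------------------------
## Internal tree representations
##
## Rooted trees (species trees and rooted gene trees) are stored as flat
## parent/children vectors with stable integer node identifiers.  Unrooted
## gene trees are stored as adjacency lists; every internal node must have
## degree exactly 3.  Node identity is preserved across rooting operations so
## that plateau and class results computed on an unrooted tree can be reported
## on any of its rootings.
## ---------------------------------------------------------------------------

postorder_of <- function(children, root) {
  n <- length(children)
  out <- integer(n)
  k <- 0L
  stack <- c(root)
  visit <- integer(0)
  # iterative postorder: push node, expand children, reverse at the end
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    visit <- c(visit, v)
    kids <- children[[v]]
    if (length(kids)) stack <- c(stack, kids)
  }
  rev(visit)
}

depths_of <- function(parent, children, root) {
  n <- length(children)
  depth <- integer(n)
  queue <- c(root)
  depth[root] <- 0L
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    for (k in children[[v]]) {
      depth[k] <- depth[v] + 1L
      queue <- c(queue, k)
    }
  }
  depth
}

new_rooted_tree <- function(parent, children, label, root,
                            orig = NULL, class = "me_rooted_tree") {
  n <- length(children)
  is_leaf <- lengths(children) == 0L
  structure(list(
    n = n, parent = parent, children = children, label = label,
    root = root, is_leaf = is_leaf,
    postorder = postorder_of(children, root),
    depth = depths_of(parent, children, root),
    orig = if (is.null(orig)) seq_len(n) else orig
  ), class = class)
}

#' Number of leaves of a tree
#' @param tree a rooted, unrooted or species tree.
#' @return integer count of leaves.
#' @export
n_leaves <- function(tree) sum(tree$is_leaf)

#' Species names occurring in a tree
#' @param tree a rooted, unrooted or species tree.
#' @return sorted character vector of distinct species labels.
#' @export
tree_species <- function(tree) sort(unique(tree$label[tree$is_leaf]))

## Convert an ape "phylo" object into the flat rooted representation.
phylo_to_rooted <- function(phy) {
  ntip <- length(phy$tip.label)
  n <- ntip + phy$Nnode
  parent <- rep(NA_integer_, n)
  children <- vector("list", n)
  for (i in seq_len(n)) children[[i]] <- integer(0)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    c <- phy$edge[i, 2]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
  }
  root <- ntip + 1L
  label <- rep(NA_character_, n)
  label[seq_len(ntip)] <- phy$tip.label
  new_rooted_tree(parent, children, label, root)
}

## Convert back to "phylo" for writing.
rooted_to_phylo <- function(tree) {
  leaves <- which(tree$is_leaf)
  internals <- which(!tree$is_leaf)
  ntip <- length(leaves)
  id <- integer(tree$n)
  id[leaves] <- seq_len(ntip)
  # ape requires the root to be node ntip+1
  internals <- c(tree$root, setdiff(internals, tree$root))
  id[internals] <- ntip + seq_along(internals)
  edges <- NULL
  for (v in seq_len(tree$n)) {
    for (k in tree$children[[v]]) edges <- rbind(edges, c(id[v], id[k]))
  }
  phy <- list(edge = edges, tip.label = tree$label[leaves],
              Nnode = length(internals))
  class(phy) <- "phylo"
  phy
}

validate_binary <- function(tree, what) {
  bad <- which(!tree$is_leaf & lengths(tree$children) != 2L)
  if (length(bad))
    stop(sprintf("%s must be binary: node %d has %d children", what,
                 bad[1], length(tree$children[[bad[1]]])))
  invisible(tree)
}

## ---------------------------------------------------------------------------
## Species tree
## ---------------------------------------------------------------------------

as_species_tree <- function(tree) {
  validate_binary(tree, "species tree")
  labs <- tree$label[tree$is_leaf]
  if (anyDuplicated(labs))
    stop("species tree leaf labels must be unique: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  if (sum(tree$is_leaf) < 2L)
    stop("species tree must have at least 2 leaves")
  cluster <- vector("list", tree$n)
  for (v in tree$postorder) {
    cluster[[v]] <- if (tree$is_leaf[v]) tree$label[v] else
      sort(c(cluster[[tree$children[[v]][1]]], cluster[[tree$children[[v]][2]]]))
  }
  tree$cluster <- cluster
  leaf_ids <- which(tree$is_leaf)
  tree$leaf_of <- stats::setNames(leaf_ids, tree$label[leaf_ids])
  class(tree) <- c("me_species_tree", "me_rooted_tree")
  tree
}

## ---------------------------------------------------------------------------
## Unrooted gene trees: adjacency representation
## ---------------------------------------------------------------------------

new_unrooted_tree <- function(adj, label, orig = NULL) {
  n <- length(adj)
  is_leaf <- lengths(adj) == 1L
  bad <- which(!is_leaf & lengths(adj) != 3L)
  if (length(bad))
    stop(sprintf("unrooted tree internal node %d has degree %d (must be 3)",
                 bad[1], length(adj[[bad[1]]])))
  if (sum(is_leaf) < 3L)
    stop("unrooted gene tree must have at least 3 leaves")
  edges <- NULL
  for (u in seq_len(n)) {
    for (v in adj[[u]]) if (u < v) edges <- rbind(edges, c(u, v))
  }
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  structure(list(n = n, adj = adj, label = label, is_leaf = is_leaf,
                 edges = edges,
                 orig = if (is.null(orig)) seq_len(n) else orig),
            class = "me_unrooted_tree")
}

## Dissolve the root of a rooted binary representation into an undirected
## edge, shifting identifiers above the removed root down by one.
rooted_to_unrooted <- function(tree) {
  if (sum(tree$is_leaf) < 3L)
    stop("cannot unroot a tree with fewer than 3 leaves")
  validate_binary(tree, "gene tree")
  r <- tree$root
  shift <- function(v) ifelse(v > r, v - 1L, v)
  n <- tree$n - 1L
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  for (v in seq_len(tree$n)) {
    p <- tree$parent[v]
    if (is.na(p) || p == r) next
    a <- shift(v); b <- shift(p)
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  rk <- tree$children[[r]]
  a <- shift(rk[1]); b <- shift(rk[2])
  adj[[a]] <- c(adj[[a]], b)
  adj[[b]] <- c(adj[[b]], a)
  adj <- lapply(adj, sort)
  label <- tree$label[-r]
  new_unrooted_tree(adj, label)
}

#' Parse a newick string into a species, rooted, or unrooted tree
#'
#' Parsing is delegated to [ape::read.tree()]; the resulting topology is
#' converted into the package's flat node representation with deterministic
#' identifiers.  Branch lengths, if present, are ignored.  In `unrooted` mode a
#' rooted binary newick has its root dissolved into an undirected edge, while a
#' top-level trifurcation is taken as-is.
#'
#' @param text a newick string (terminated by `;`).
#' @param mode one of `"rooted"`, `"unrooted"`, `"species"`.
#' @return a tree object of the requested kind.
#' @examples
#' S <- parse_newick("(((a,b),(c,d)),e);", "species")
#' U <- parse_newick("(d,e,(c,(((a,b),b),((c,d),d))));", "unrooted")
#' @export
parse_newick <- function(text, mode = c("rooted", "unrooted", "species")) {
  mode <- match.arg(mode)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || length(phy$tip.label) < 2L)
    stop("failed to parse newick (or trivial tree): ", text)
  tree <- phylo_to_rooted(phy)
  if (mode == "species") return(as_species_tree(tree))
  if (mode == "rooted") {
    validate_binary(tree, "rooted gene tree")
    return(tree)
  }
  # unrooted mode
  kids <- tree$children[[tree$root]]
  if (length(kids) == 2L) return(rooted_to_unrooted(tree))
  if (length(kids) == 3L) {
    # validate the rest is binary, then take the trifurcation as the
    # display center of the unrooted tree
    bad <- which(!tree$is_leaf & lengths(tree$children) != 2L &
                   seq_len(tree$n) != tree$root)
    if (length(bad)) stop("multifurcation in unrooted newick at node ", bad[1])
    adj <- vector("list", tree$n)
    for (i in seq_len(tree$n)) adj[[i]] <- integer(0)
    for (v in seq_len(tree$n)) {
      p <- tree$parent[v]
      if (is.na(p)) next
      adj[[v]] <- c(adj[[v]], p)
      adj[[p]] <- c(adj[[p]], v)
    }
    adj <- lapply(adj, sort)
    return(new_unrooted_tree(adj, tree$label))
  }
  stop("multifurcation beyond a top-level trifurcation in unrooted newick")
}

#' Read one tree per line from a newick file
#' @param path file with `;`-terminated newick strings, one per line.
#' @param mode tree kind passed to [parse_newick()].
#' @return a list of trees.
#' @export
read_newick_file <- function(path, mode = "unrooted") {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  lapply(lines, parse_newick, mode = mode)
}

#' Write a tree as newick
#'
#' An unrooted tree is displayed as a trifurcation centered at its lowest-id
#' internal node, which makes parse/write round trips bit-stable.
#'
#' @param tree a species, rooted, or unrooted tree.
#' @return a newick string.
#' @export
write_newick <- function(tree) {
  if (inherits(tree, "me_unrooted_tree")) {
    center <- min(which(!tree$is_leaf))
    sub <- function(v, from) {
      if (tree$is_leaf[v]) return(tree$label[v])
      kids <- setdiff(tree$adj[[v]], from)
      paste0("(", paste(vapply(kids, sub, "", from = v), collapse = ","), ")")
    }
    kids <- tree$adj[[center]]
    return(paste0("(", paste(vapply(kids, sub, "", from = center),
                             collapse = ","), ");"))
  }
  sub <- function(v) {
    if (tree$is_leaf[v]) return(tree$label[v])
    paste0("(", paste(vapply(tree$children[[v]], sub, ""), collapse = ","), ")")
  }
  paste0(sub(tree$root), ";")
}

## ---------------------------------------------------------------------------
## Rooting and unrooting
## ---------------------------------------------------------------------------

find_edge <- function(U, edge) {
  e <- sort(as.integer(edge))
  hit <- which(U$edges[, 1] == e[1] & U$edges[, 2] == e[2])
  if (!length(hit)) stop("edge (", e[1], ",", e[2], ") not in unrooted tree")
  e
}

#' Root an unrooted gene tree on an edge
#'
#' A new root node (id `n+1`) subdivides the chosen edge; all other nodes keep
#' their identifiers, so results computed on the rooting map back to the
#' unrooted tree.
#'
#' @param U an unrooted gene tree.
#' @param edge integer pair: the edge to subdivide.
#' @return a rooted gene tree; its `orig` field maps nodes back to `U`
#'   (`NA` for the synthetic root).
#' @export
root_at <- function(U, edge) {
  e <- find_edge(U, edge)
  n <- U$n
  root <- n + 1L
  parent <- rep(NA_integer_, root)
  children <- vector("list", root)
  for (i in seq_len(root)) children[[i]] <- integer(0)
  children[[root]] <- c(e[1], e[2])
  parent[e[1]] <- root
  parent[e[2]] <- root
  queue <- c(e[1], e[2])
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    from <- parent[v]
    nb <- U$adj[[v]]
    # when coming through the subdivided edge, exclude the other endpoint
    excl <- if (from == root) e[e != v] else from
    kids <- setdiff(nb, excl)
    children[[v]] <- kids
    for (k in kids) {
      parent[k] <- v
      queue <- c(queue, k)
    }
  }
  label <- c(U$label, NA_character_)
  out <- new_rooted_tree(parent, children, label, root,
                         orig = c(U$orig, NA_integer_))
  out$source_edge <- e
  out
}

#' Dissolve the root of a rooted gene tree
#'
#' Inverse of [root_at()]: removes the root node and joins its two children by
#' an undirected edge.  Identifiers above the removed root shift down by one,
#' so `unroot(root_at(U, e))` returns a tree identical to `U`.
#'
#' @param G a rooted binary gene tree with at least 3 leaves.
#' @return an unrooted gene tree.
#' @export
unroot <- function(G) rooted_to_unrooted(G)

## ---------------------------------------------------------------------------
## Species-tree services: lca, clusters, subtree copies
## ---------------------------------------------------------------------------

#' Least common ancestor of two species-tree nodes
#' @param S a species tree.
#' @param a,b node ids in `S`.
#' @return the node id of the lca under the ancestor order.
#' @export
tree_lca <- function(S, a, b) {
  if (a < 1 || a > S$n || b < 1 || b > S$n) stop("node not in species tree")
  while (a != b) {
    if (S$depth[a] < S$depth[b]) b <- S$parent[b]
    else if (S$depth[b] < S$depth[a]) a <- S$parent[a]
    else { a <- S$parent[a]; b <- S$parent[b] }
  }
  a
}

#' Cluster (species set) below a species-tree node
#' @param S a species tree.
#' @param v node id.
#' @return sorted character vector of species below `v`.
#' @export
node_cluster <- function(S, v) {
  if (v < 1 || v > S$n) stop("node not in species tree")
  S$cluster[[v]]
}

#' Is `a` a descendant of (or equal to) `b` in the species tree?
#' @param S a species tree.
#' @param a,b node ids.
#' @return logical.
#' @export
is_desc <- function(S, a, b) {
  while (!is.na(a)) {
    if (a == b) return(TRUE)
    a <- S$parent[a]
  }
  FALSE
}

#' Copy the species subtree below a node as a rooted gene tree
#'
#' Returns a fresh rooted gene tree whose topology and leaf labels copy the
#' species tree below `v`.  Used as padding when building reduced trees in the
#' unrooted decomposition; nodes carry `orig = NA` to mark them as synthetic.
#'
#' @param S a species tree.
#' @param v node id in `S`.
#' @return a rooted gene tree.
#' @export
species_subtree <- function(S, v) {
  if (v < 1 || v > S$n) stop("node not in species tree")
  nodes <- integer(0)
  stack <- c(v)
  while (length(stack)) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nodes <- c(nodes, x)
    stack <- c(stack, S$children[[x]])
  }
  # postorder ids: reverse preorder collection keeps children before parents
  nodes <- rev(nodes)
  id <- stats::setNames(seq_along(nodes), nodes)
  m <- length(nodes)
  parent <- rep(NA_integer_, m)
  children <- vector("list", m)
  for (i in seq_len(m)) children[[i]] <- integer(0)
  for (x in nodes) {
    for (k in S$children[[x]]) {
      parent[id[as.character(k)]] <- id[as.character(x)]
      children[[id[as.character(x)]]] <-
        c(children[[id[as.character(x)]]], id[as.character(k)])
    }
  }
  label <- S$label[nodes]
  new_rooted_tree(parent, children, label, id[as.character(v)],
                  orig = rep(NA_integer_, m))
}

## Rooted subtree of an unrooted tree: root at `v`, growing away from the
## neighbors listed in `exclude`.  Node identifiers are freshly assigned but
## `orig` maps back to the unrooted tree.
unrooted_subtree <- function(U, v, exclude) {
  ids <- integer(0)
  par_of <- list()
  queue <- list(list(node = v, from = NA_integer_))
  order_nodes <- integer(0)
  parent_orig <- c()
  while (length(queue)) {
    it <- queue[[1]]
    queue <- queue[-1]
    order_nodes <- c(order_nodes, it$node)
    parent_orig <- c(parent_orig, it$from)
    nb <- U$adj[[it$node]]
    excl <- if (is.na(it$from)) exclude else it$from
    for (k in setdiff(nb, excl)) {
      queue <- c(queue, list(list(node = k, from = it$node)))
    }
  }
  m <- length(order_nodes)
  id <- stats::setNames(seq_len(m), order_nodes)
  parent <- rep(NA_integer_, m)
  children <- vector("list", m)
  for (i in seq_len(m)) children[[i]] <- integer(0)
  for (i in seq_len(m)) {
    if (!is.na(parent_orig[i])) {
      p <- id[as.character(parent_orig[i])]
      parent[i] <- p
      children[[p]] <- c(children[[p]], i)
    }
  }
  label <- U$label[order_nodes]
  new_rooted_tree(parent, children, label, 1L, orig = U$orig[order_nodes])
}

## ---------------------------------------------------------------------------
## Canonical forms (for topology comparison with repeated leaf labels)
## ---------------------------------------------------------------------------

#' Canonical string of a rooted tree
#'
#' Children are recursively sorted by their canonical strings, making the
#' result invariant under child order; two rooted trees are topologically
#' identical (as labeled trees) iff their canonical strings are equal.
#'
#' @param tree a rooted gene or species tree.
#' @return a canonical newick-like string (no trailing `;`).
#' @export
canonical_rooted <- function(tree) {
  sub <- function(v) {
    if (tree$is_leaf[v]) return(tree$label[v])
    paste0("(", paste(sort(vapply(tree$children[[v]], sub, "")),
                      collapse = ","), ")")
  }
  sub(tree$root)
}

#' Canonical string of an unrooted tree
#'
#' The minimum of the canonical rooted strings over all edge rootings; equal
#' strings characterize unrooted topological identity.
#'
#' @param U an unrooted gene tree.
#' @return a canonical string.
#' @export
canonical_unrooted <- function(U) {
  min(vapply(seq_len(nrow(U$edges)), function(i)
    canonical_rooted(root_at(U, U$edges[i, ])), ""))
}

#' @export
print.me_rooted_tree <- function(x, ...) {
  cat(sprintf("rooted gene tree: %d leaves, %d nodes\n  %s\n",
              n_leaves(x), x$n, write_newick(x)))
  invisible(x)
}

#' @export
print.me_species_tree <- function(x, ...) {
  cat(sprintf("species tree: %d species\n  %s\n", n_leaves(x),
              write_newick(x)))
  invisible(x)
}

#' @export
print.me_unrooted_tree <- function(x, ...) {
  cat(sprintf("unrooted gene tree: %d leaves, %d nodes\n  %s\n",
              n_leaves(x), x$n, write_newick(x)))
  invisible(x)
}
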