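## ---------------------------------------------------------------------------
## Equivalence classes on plateau edges and the unrooted decomposition
## ---------------------------------------------------------------------------

#' Speciation frontier of a rooted gene tree
#'
#' The set of ancestor-maximal non-root speciation nodes: traversing from the
#' root, the first speciation met on every root-to-leaf path (the root itself
#' excluded).  For a rooting produced by [root_at()] the returned ids are node
#' ids of the underlying unrooted tree, so frontiers of different rootings are
#' directly comparable.
#'
#' @param G a rooted gene tree.
#' @param S a species tree.
#' @param map optional precomputed [lca_map()] of `G`.
#' @return sorted integer vector of node ids.
#' @export
frontier <- function(G, S, map = NULL) {
  if (is.null(map)) map <- lca_map(G, S)
  out <- integer(0)
  stack <- G$children[[G$root]]
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (map$event[v] == "speciation") out <- c(out, v)
    else stack <- c(stack, G$children[[v]])
  }
  sort(out)
}

edge_key <- function(e) paste(sort(e), collapse = "-")

## Component of `a` after removing edge {a, via}: plateau edges fully inside.
component_edges <- function(U, a, via, edges) {
  seen <- logical(U$n)
  seen[a] <- TRUE
  queue <- a
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in U$adj[[v]]) {
      if (v == a && w == via) next
      if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  keep <- seen[edges[, 1]] & seen[edges[, 2]]
  edges[keep, , drop = FALSE]
}

#' Equivalence classes of plateau edges
#'
#' Two plateau edges are equivalent when their rootings share the same
#' speciation frontier.  The classes are built structurally: with no empty
#' edge the whole plateau is one class; with an empty edge the empty edge is a
#' singleton plain class and every plateau single edge of an S2 star defines
#' one complex class (the star edge together with the plateau edges beyond
#' it), yielding 1, 3 or 5 classes.
#'
#' @param U an unrooted gene tree.
#' @param S a species tree.
#' @param pl optional precomputed [plateau()] result.
#' @return an object of class `me_classes`: list with `classes` (each a list
#'   with `edges` matrix, `kind` `"plain"`/`"complex"`, `id`), `k_contributes`
#'   (tree has an S2 star and more than one class), and `plateau`.
#' @export
equiv_classes <- function(U, S, pl = NULL) {
  if (is.null(pl)) pl <- plateau(U, S)
  pe <- pl$plateau_edges
  classes <- list()
  if (is.null(pl$empty_edge)) {
    classes[[1]] <- list(edges = pe, kind = "complex", id = "whole-plateau")
  } else {
    e <- sort(pl$empty_edge)
    classes[[1]] <- list(edges = matrix(e, 1), kind = "plain", id = "plain")
    if (nrow(pe) > 1L) {
      # plateau single edges sharing an endpoint with the empty edge
      others <- pe[!(pe[, 1] == e[1] & pe[, 2] == e[2]), , drop = FALSE]
      touch <- others[, 1] %in% e | others[, 2] %in% e
      star_edges <- others[touch, , drop = FALSE]
      ord <- order(star_edges[, 1], star_edges[, 2])
      star_edges <- star_edges[ord, , drop = FALSE]
      for (i in seq_len(nrow(star_edges))) {
        f <- star_edges[i, ]
        ctr <- if (f[1] %in% e) f[1] else f[2]
        a <- setdiff(f, ctr)
        inner <- component_edges(U, a, ctr, others)
        # drop star edges of the *other* S2 center that ended up in the
        # component scan (they touch e, hence belong to their own class)
        inner <- inner[!(inner[, 1] %in% e | inner[, 2] %in% e), , drop = FALSE]
        cls_edges <- rbind(f, inner)
        rownames(cls_edges) <- NULL
        classes[[length(classes) + 1L]] <-
          list(edges = cls_edges, kind = "complex",
               id = paste0("E", edge_key(f)))
      }
    }
  }
  structure(list(classes = classes,
                 k_contributes = length(pl$s2_stars) > 0 && length(classes) > 1,
                 plateau = pl),
            class = "me_classes")
}

#' @export
print.me_classes <- function(x, ...) {
  sizes <- vapply(x$classes, function(cl) nrow(cl$edges), 0L)
  kinds <- vapply(x$classes, function(cl) cl$kind, "")
  cat(sprintf("%d equivalence class(es) on the plateau: sizes {%s}, kinds {%s}\n",
              length(x$classes), paste(sizes, collapse = ","),
              paste(kinds, collapse = ",")))
  invisible(x)
}

## Definitional route: partition plateau edges by frontier equality.
## Independent of the structural construction; used as its oracle in tests.
equiv_classes_frontier <- function(U, S, pl = NULL) {
  if (is.null(pl)) pl <- plateau(U, S)
  pe <- pl$plateau_edges
  keys <- vapply(seq_len(nrow(pe)), function(i) {
    G <- root_at(U, pe[i, ])
    paste(frontier(G, S), collapse = ",")
  }, "")
  split(seq_len(nrow(pe)), keys)
}

#' Decompose an unrooted gene tree along one equivalence class
#'
#' For a plain class (the one holding the empty edge) the decomposition is the
#' single rooting on that edge.  For a complex class `X` it detaches the
#' maximal rooted subtrees hanging off the leaves of the class subgraph (their
#' roots are speciations in every class rooting) and builds the reduced
#' unrooted tree in which every such leaf is replaced by a copy of the species
#' subtree below its image.  Padding nodes carry `orig = NA` so episode
#' reports can distinguish real gene-tree nodes from copies.
#'
#' @param U an unrooted gene tree.
#' @param S a species tree.
#' @param cls one class from [equiv_classes()] (a list with `edges`, `kind`).
#' @param pl optional precomputed [plateau()] result.
#' @return list with `kind`, `delta` (list of rooted trees), and for complex
#'   classes `uX` (the reduced unrooted tree), `class_edges` (edges of `uX`
#'   that are the images of the class edges, one row per class edge) and
#'   `delta_images` (species nodes whose subtree copies replaced each leaf).
#' @export
decompose_class <- function(U, S, cls, pl = NULL) {
  if (is.null(pl)) pl <- plateau(U, S)
  if (is.null(cls$edges)) stop("not a class object")
  if (cls$kind == "plain") {
    return(list(kind = "plain", delta = list(root_at(U, cls$edges[1, ])),
                uX = NULL, class_edges = NULL))
  }
  X <- cls$edges
  M <- pl$edge_maps$M
  xnodes <- sort(unique(as.integer(X)))
  xdeg <- vapply(xnodes, function(v) sum(X == v), 0L)
  xleaves <- xnodes[xdeg == 1L]
  xinternal <- xnodes[xdeg >= 2L]
  if (any(xdeg == 2L))
    stop("internal class node with degree 2: decomposition assumption violated")
  # detach the subtree hanging off each class leaf
  delta <- list()
  delta_top <- integer(0)
  xnb <- integer(0)   # the class neighbor of each leaf
  for (v in xleaves) {
    i <- which(X[, 1] == v | X[, 2] == v)[1]
    u <- setdiff(X[i, ], v)
    Tv <- unrooted_subtree(U, v, exclude = u)
    delta[[length(delta) + 1L]] <- Tv
    delta_top <- c(delta_top, M[u, v])
    xnb <- c(xnb, u)
  }
  # assemble the reduced tree: internal class nodes keep provenance, each
  # leaf is replaced by a copy of the species subtree below its image
  id_of <- stats::setNames(seq_along(xinternal), xinternal)
  n_new <- length(xinternal)
  adj <- vector("list", n_new)
  for (i in seq_len(n_new)) adj[[i]] <- integer(0)
  label <- rep(NA_character_, n_new)
  orig <- xinternal
  pad_root <- integer(length(xleaves))
  for (j in seq_along(xleaves)) {
    sub <- species_subtree(S, delta_top[j])
    off <- length(adj)
    for (i in seq_len(sub$n)) {
      adj[[off + i]] <- integer(0)
      label[off + i] <- sub$label[i]
      orig[off + i] <- NA_integer_
    }
    for (v in seq_len(sub$n)) {
      p <- sub$parent[v]
      if (is.na(p)) next
      adj[[off + v]] <- c(adj[[off + v]], off + p)
      adj[[off + p]] <- c(adj[[off + p]], off + v)
    }
    pad_root[j] <- off + sub$root
  }
  new_id <- function(v) {
    j <- match(v, xleaves)
    if (!is.na(j)) pad_root[j] else unname(id_of[as.character(v)])
  }
  class_edges <- matrix(0L, nrow(X), 2)
  for (i in seq_len(nrow(X))) {
    a <- new_id(X[i, 1]); b <- new_id(X[i, 2])
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
    class_edges[i, ] <- sort(c(a, b))
  }
  adj <- lapply(adj, sort)
  uX <- new_unrooted_tree(adj, label, orig = orig)
  list(kind = "complex", delta = delta, uX = uX, class_edges = class_edges,
       delta_images = delta_top, class_leaf_nodes = xleaves)
}
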