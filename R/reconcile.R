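## ---------------------------------------------------------------------------
## Rooted reconciliation: lca mapping, duplication cost
## Unrooted reconciliation: per-directed-edge mappings, edge types, plateau
## ---------------------------------------------------------------------------

#' LCA mapping of a rooted gene tree into the species tree
#'
#' Maps every gene-tree node to the least common ancestor of its leaf species
#' in `S` and flags each internal node as a duplication (it maps to the same
#' species node as one of its children) or a speciation.  Leaves are
#' speciations.
#'
#' @param G a rooted gene tree whose leaf species occur in `S`.
#' @param S a species tree.
#' @return a list with `map` (integer vector of species node ids) and `event`
#'   (character, `"duplication"`/`"speciation"` per node).
#' @export
lca_map <- function(G, S) {
  map <- integer(G$n)
  event <- rep("speciation", G$n)
  for (v in G$postorder) {
    if (G$is_leaf[v]) {
      sp <- G$label[v]
      leaf <- S$leaf_of[sp]
      if (is.na(leaf))
        stop("gene leaf species not present in species tree: ", sp)
      map[v] <- leaf
    } else {
      kids <- G$children[[v]]
      m <- map[kids[1]]
      for (k in kids[-1]) m <- tree_lca(S, m, map[k])
      map[v] <- m
      if (any(map[kids] == m)) event[v] <- "duplication"
    }
  }
  list(map = map, event = event)
}

#' Duplication cost of a rooted gene tree
#' @param G a rooted gene tree.
#' @param S a species tree.
#' @return integer: the number of duplication nodes under the lca mapping.
#' @export
dup_cost <- function(G, S) {
  sum(lca_map(G, S)$event == "duplication")
}

#' Per-directed-edge lca mappings of an unrooted gene tree
#'
#' For every directed edge `(u -> v)` computes the lca image of the subtree on
#' the `v` side of the edge, via two message-passing sweeps (leaf-inward, then
#' outward), in O(|U|) lca operations.  Also computes the effective top
#' `top`: the lca image of all species present in `U`, which plays the role of
#' the species root for edge classification when the family does not span all
#' species.
#'
#' @param U an unrooted gene tree.
#' @param S a species tree.
#' @return list with `M` (n x n integer matrix, `M[u, v]` = image of the `v`
#'   side of edge `{u,v}`, 0 where not adjacent) and `top` (species node id).
#' @export
edge_maps <- function(U, S) {
  n <- U$n
  M <- matrix(0L, n, n)
  leafmap <- integer(n)
  for (v in which(U$is_leaf)) {
    leaf <- S$leaf_of[U$label[v]]
    if (is.na(leaf))
      stop("gene leaf species not present in species tree: ", U$label[v])
    leafmap[v] <- leaf
  }
  r <- which(!U$is_leaf)[1]
  # BFS orientation toward r
  par <- rep(NA_integer_, n)
  order_bfs <- integer(0)
  queue <- r
  seen <- logical(n); seen[r] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order_bfs <- c(order_bfs, v)
    for (w in U$adj[[v]]) if (!seen[w]) {
      seen[w] <- TRUE; par[w] <- v; queue <- c(queue, w)
    }
  }
  # inward pass: M[par[v], v] for v in reverse BFS order
  for (v in rev(order_bfs)) {
    if (is.na(par[v])) next
    if (U$is_leaf[v]) {
      M[par[v], v] <- leafmap[v]
    } else {
      kids <- setdiff(U$adj[[v]], par[v])
      m <- M[v, kids[1]]
      for (k in kids[-1]) m <- tree_lca(S, m, M[v, k])
      M[par[v], v] <- m
    }
  }
  # outward pass: M[v, u] for every neighbor v of u, combining u's other sides
  for (u in order_bfs) {
    nb <- U$adj[[u]]
    if (U$is_leaf[u]) {
      M[nb, u] <- leafmap[u]
      next
    }
    for (v in nb) {
      if (!is.na(par[u]) && v == par[u]) next  # M[v, u] handled from v's side
      others <- setdiff(nb, v)
      m <- M[u, others[1]]
      for (w in others[-1]) m <- tree_lca(S, m, M[u, w])
      M[v, u] <- m
    }
  }
  # effective top: image of the whole tree
  e <- U$edges[1, ]
  top <- tree_lca(S, M[e[1], e[2]], M[e[2], e[1]])
  list(M = M, top = top)
}

#' Classify edges of an unrooted gene tree
#'
#' An edge `{u,v}` is `empty` when neither side maps to the effective top
#' (the rooting on it has a speciation root), `double` when both sides do,
#' and `single` otherwise.
#'
#' @param U an unrooted gene tree.
#' @param S a species tree.
#' @param em optional precomputed [edge_maps()] result.
#' @return data frame with columns `u`, `v`, `type`.
#' @export
classify_edges <- function(U, S, em = NULL) {
  if (is.null(em)) em <- edge_maps(U, S)
  top <- em$top
  a <- em$M[cbind(U$edges[, 1], U$edges[, 2])]  # image of v side
  b <- em$M[cbind(U$edges[, 2], U$edges[, 1])]  # image of u side
  type <- ifelse(a != top & b != top, "empty",
                 ifelse(a == top & b == top, "double", "single"))
  data.frame(u = U$edges[, 1], v = U$edges[, 2], type = type,
             stringsAsFactors = FALSE)
}

#' Plateau of an unrooted gene tree
#'
#' Computes the duplication cost of every edge rooting by a linear two-pass
#' dynamic program over directed edges, the argmin edge set (the plateau,
#' always a connected subtree), edge types, S2 stars (an internal center
#' incident to the empty edge, with two single edges), and node roles: plateau
#' leaves are speciations in every optimal rooting (super-speciations),
#' internal plateau nodes away from the empty edge are duplications in every
#' optimal rooting (super-duplications), and internal plateau nodes incident
#' to the empty edge are conditional (speciation exactly in the empty-edge
#' rooting when they are plateau leaves).
#'
#' @param U an unrooted gene tree.
#' @param S a species tree.
#' @return an object of class `me_plateau`: list with `edges` (data frame:
#'   `u`, `v`, `type`, `cost`, `in_plateau`), `plateau_edges` (matrix),
#'   `min_cost`, `empty_edge`, `double_edges`, `s2_stars`, `plateau_nodes`,
#'   `plateau_leaves`, `plateau_internal`, `roles`, `top`, `edge_maps`.
#' @export
plateau <- function(U, S) {
  em <- edge_maps(U, S)
  M <- em$M
  top <- em$top
  n <- U$n
  # dup indicator for directed edge (u -> v): is v a duplication when its
  # parent direction is u?
  C <- matrix(NA_integer_, n, n)
  r <- which(!U$is_leaf)[1]
  par <- rep(NA_integer_, n)
  order_bfs <- integer(0)
  queue <- r
  seen <- logical(n); seen[r] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order_bfs <- c(order_bfs, v)
    for (w in U$adj[[v]]) if (!seen[w]) {
      seen[w] <- TRUE; par[w] <- v; queue <- c(queue, w)
    }
  }
  dupflag <- function(u, v) {
    # v internal, entered from u
    kids <- setdiff(U$adj[[v]], u)
    as.integer(M[u, v] == M[v, kids[1]] || M[u, v] == M[v, kids[2]])
  }
  # inward: C[par[v], v]
  for (v in rev(order_bfs)) {
    if (is.na(par[v])) next
    if (U$is_leaf[v]) C[par[v], v] <- 0L
    else {
      kids <- setdiff(U$adj[[v]], par[v])
      C[par[v], v] <- dupflag(par[v], v) + C[v, kids[1]] + C[v, kids[2]]
    }
  }
  # outward
  for (u in order_bfs) {
    nb <- U$adj[[u]]
    if (U$is_leaf[u]) { C[nb, u] <- 0L; next }
    for (v in nb) {
      if (!is.na(par[u]) && v == par[u]) next
      others <- setdiff(nb, v)
      C[v, u] <- dupflag(v, u) + C[u, others[1]] + C[u, others[2]]
    }
  }
  ecls <- classify_edges(U, S, em)
  rootdup <- (M[cbind(ecls$u, ecls$v)] == top) |
    (M[cbind(ecls$v, ecls$u)] == top)
  cost <- C[cbind(ecls$u, ecls$v)] + C[cbind(ecls$v, ecls$u)] +
    as.integer(rootdup)
  min_cost <- min(cost)
  in_plateau <- cost == min_cost
  edges <- cbind(ecls, cost = cost, in_plateau = in_plateau)
  pe <- U$edges[in_plateau, , drop = FALSE]
  pnodes <- sort(unique(as.integer(pe)))
  pdeg <- vapply(pnodes, function(v) sum(pe == v), 0L)
  pleaves <- pnodes[pdeg == 1L]
  pinternal <- pnodes[pdeg >= 2L]
  empty_idx <- which(edges$type == "empty" & edges$in_plateau)
  empty_edge <- if (length(empty_idx)) c(edges$u[empty_idx[1]],
                                         edges$v[empty_idx[1]]) else NULL
  dbl <- edges[edges$type == "double" & edges$in_plateau, c("u", "v")]
  # S2 stars: internal endpoints of the empty edge with their three edges
  s2 <- list()
  if (!is.null(empty_edge)) {
    for (ctr in empty_edge) {
      if (U$is_leaf[ctr]) next
      star <- t(vapply(setdiff(U$adj[[ctr]], integer(0)),
                       function(w) sort(c(ctr, w)), integer(2)))
      s2[[length(s2) + 1L]] <- list(center = ctr, edges = star)
    }
  }
  roles <- rep(NA_character_, n)
  roles[pleaves] <- "super-speciation"
  if (is.null(empty_edge)) {
    roles[pinternal] <- "super-duplication"
  } else {
    for (v in pinternal) {
      roles[v] <- if (v %in% empty_edge) "conditional" else "super-duplication"
    }
  }
  structure(list(edges = edges, plateau_edges = pe, min_cost = min_cost,
                 empty_edge = empty_edge,
                 double_edges = as.matrix(dbl),
                 s2_stars = s2, plateau_nodes = pnodes,
                 plateau_leaves = pleaves, plateau_internal = pinternal,
                 roles = roles, top = top, edge_maps = em),
            class = "me_plateau")
}

#' @export
print.me_plateau <- function(x, ...) {
  cat(sprintf("plateau: %d of %d edges optimal (duplication cost %d)\n",
              nrow(x$plateau_edges), nrow(x$edges), x$min_cost))
  if (!is.null(x$empty_edge))
    cat(sprintf("  empty edge: (%d,%d)\n", x$empty_edge[1], x$empty_edge[2]))
  if (nrow(x$double_edges))
    cat(sprintf("  double edges: %d\n", nrow(x$double_edges)))
  invisible(x)
}

## Brute-force oracle: duplication cost of every rooting, computed by
## explicitly rooting each edge.  Used in tests to validate the plateau DP.
plateau_brute <- function(U, S) {
  cost <- vapply(seq_len(nrow(U$edges)), function(i)
    dup_cost(root_at(U, U$edges[i, ]), S), 0L)
  list(cost = cost, plateau = U$edges[cost == min(cost), , drop = FALSE],
       min_cost = min(cost))
}
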