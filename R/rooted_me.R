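## ---------------------------------------------------------------------------
## Rooted minimum episodes: duplication intervals, greedy linear solver,
## episode reconstruction, and a brute-force oracle
## ---------------------------------------------------------------------------

## Ancestor-or-equal matrix of S: anc[a, b] is TRUE iff a is below-or-equal b.
anc_matrix <- function(S) {
  anc <- matrix(FALSE, S$n, S$n)
  for (v in seq_len(S$n)) {
    a <- v
    while (!is.na(a)) {
      anc[v, a] <- TRUE
      a <- S$parent[a]
    }
  }
  anc
}

#' Duplication intervals of a rooted gene tree
#'
#' Every duplication `d` may be placed on the species-tree path from its
#' mapping `M(d)` up to `s`, where `s` is the child of `M(g)` towards `M(d)`
#' for `g` the lowest speciation strictly above `d` in the gene tree, or the
#' species root when no such speciation exists.
#'
#' @param G a rooted gene tree.
#' @param S a species tree.
#' @param map optional precomputed [lca_map()].
#' @return data frame with columns `node`, `bottom`, `top` (species node ids).
#' @export
intervals <- function(G, S, map = NULL) {
  if (is.null(map)) map <- lca_map(G, S)
  dups <- which(map$event == "duplication")
  bottom <- map$map[dups]
  top <- integer(length(dups))
  for (i in seq_along(dups)) {
    g <- G$parent[dups[i]]
    while (!is.na(g) && map$event[g] != "speciation") g <- G$parent[g]
    if (is.na(g)) {
      top[i] <- S$root
    } else {
      # child of M(g) on the path down to bottom
      s <- bottom[i]
      while (S$parent[s] != map$map[g]) s <- S$parent[s]
      top[i] <- s
    }
  }
  data.frame(node = dups, bottom = bottom, top = top)
}

## Preprocess one rooted tree for the episode solvers: mapping, duplications,
## intervals, and the within-tree duplication descendant lists.
prep_rooted <- function(G, S) {
  map <- lca_map(G, S)
  iv <- intervals(G, S, map)
  dups <- iv$node
  idx_of <- integer(G$n)
  idx_of[dups] <- seq_along(dups)
  # dup descendants per node, accumulated in postorder
  ddesc <- vector("list", G$n)
  for (v in G$postorder) {
    acc <- integer(0)
    for (k in G$children[[v]]) {
      acc <- c(acc, ddesc[[k]])
      if (idx_of[k] > 0L) acc <- c(acc, idx_of[k])
    }
    ddesc[[v]] <- acc
  }
  postpos <- integer(G$n)
  postpos[G$postorder] <- seq_len(G$n)
  list(tree = G, map = map, dups = dups, bottom = iv$bottom, top = iv$top,
       desc = lapply(dups, function(d) ddesc[[d]]),
       postpos = postpos[dups])
}

## Core solver on preprocessed trees.  Greedy bottom-up over species nodes:
## at each node s, force-assign every unassigned duplication whose interval
## top is s (its last chance), at the lowest level above its already-placed
## same-tree descendants; then pull still-unassigned duplications whose
## interval covers s into free levels <= lambda(s), which can never increase
## the final score.  Optimality is guarded by the brute-force oracle in the
## test suite.
rme_core <- function(preps, S, anc = NULL) {
  if (is.null(anc)) anc <- anc_matrix(S)
  nt <- length(preps)
  tree_id <- integer(0); node <- integer(0)
  bottom <- integer(0); top <- integer(0); postpos <- integer(0)
  desc <- list()
  for (t in seq_len(nt)) {
    p <- preps[[t]]
    off <- length(node)
    tree_id <- c(tree_id, rep(t, length(p$dups)))
    node <- c(node, p$dups)
    bottom <- c(bottom, p$bottom)
    top <- c(top, p$top)
    postpos <- c(postpos, p$postpos)
    desc <- c(desc, lapply(p$desc, function(d) d + off))
  }
  nd <- length(node)
  lambda <- integer(S$n)
  as_s <- rep(NA_integer_, nd)
  as_lev <- rep(NA_integer_, nd)
  if (nd) {
    bdepth <- S$depth[bottom]
    for (s in S$postorder) {
      if (S$is_leaf[s] && !any(bottom == s)) { next }
      lam <- 0L
      lev_of <- function(d) {
        dd <- desc[[d]]
        at_s <- dd[!is.na(as_s[dd]) & as_s[dd] == s]
        if (length(at_s)) max(as_lev[at_s]) + 1L else 1L
      }
      forced <- which(is.na(as_s) & top == s)
      if (length(forced)) {
        forced <- forced[order(tree_id[forced], postpos[forced])]
        for (d in forced) {
          lev <- lev_of(d)
          as_s[d] <- s; as_lev[d] <- lev
          if (lev > lam) lam <- lev
        }
      }
      if (lam > 0L) {
        repeat {
          cand <- which(is.na(as_s) & anc[bottom, s] & anc[s, top] & top != s)
          if (length(cand)) {
            cand <- cand[vapply(cand, function(d)
              all(!is.na(as_s[desc[[d]]])), TRUE)]
          }
          if (!length(cand)) break
          cand <- cand[order(-bdepth[cand], tree_id[cand], node[cand])]
          any_new <- FALSE
          for (d in cand) {
            lev <- lev_of(d)
            if (lev <= lam) {
              as_s[d] <- s; as_lev[d] <- lev
              any_new <- TRUE
            }
          }
          if (!any_new) break
        }
      }
      lambda[s] <- lam
    }
  }
  assignment <- data.frame(tree = tree_id, node = node,
                           species = as_s, level = as_lev)
  build_me_result(sum(lambda), lambda, assignment, preps, S)
}

## Shared result assembly: episodes grouped by (species node, level), with
## member duplications mapped back to source-tree node ids where available.
build_me_result <- function(score, lambda, assignment, preps, S) {
  episodes <- list()
  if (nrow(assignment)) {
    key <- paste(assignment$species, assignment$level)
    for (k in unique(key)) {
      rows <- assignment[key == k, , drop = FALSE]
      s <- rows$species[1]
      orig_node <- vapply(seq_len(nrow(rows)), function(i) {
        tr <- preps[[rows$tree[i]]]$tree
        if (is.null(tr$orig)) rows$node[i] else tr$orig[rows$node[i]]
      }, 0L)
      src_tree <- vapply(rows$tree, function(t) {
        if (is.null(preps[[t]]$src)) t else preps[[t]]$src
      }, 0L)
      episodes[[length(episodes) + 1L]] <- list(
        species = s,
        cluster = paste(S$cluster[[s]], collapse = ","),
        level = rows$level[1],
        members = data.frame(tree = src_tree, node = rows$node,
                             orig_node = orig_node))
    }
    ord <- order(vapply(episodes, function(e) e$species, 0L),
                 vapply(episodes, function(e) e$level, 0L))
    episodes <- episodes[ord]
  }
  structure(list(score = score, lambda = lambda, assignment = assignment,
                 episodes = episodes), class = "me_rme")
}

#' Minimum episodes score for rooted gene trees
#'
#' Computes the minimum over all feasible interval assignments of
#' `sum_s lambda(s)`, where `lambda(s)` is the maximum over trees of the
#' longest chain of comparable duplications placed at species node `s`.
#' Duplications from different trees placed at the same slot share an episode.
#'
#' @param trees list of rooted gene trees.
#' @param S a species tree.
#' @return an object of class `me_rme`: list with `score`, `lambda` (episode
#'   count per species node), `assignment` (one row per duplication: tree,
#'   node, species, level), and `episodes`.
#' @examples
#' S <- parse_newick("(((a,b),(c,d)),e);", "species")
#' G <- parse_newick("(e,(d,(c,(((a,b),b),((c,d),d)))));", "rooted")
#' rme_score(list(G), S)$score
#' @export
rme_score <- function(trees, S) {
  rme_core(lapply(trees, prep_rooted, S = S), S)
}

#' @export
print.me_rme <- function(x, ...) {
  cat(sprintf("minimum episodes score: %d (%d episode(s))\n",
              x$score, length(x$episodes)))
  for (e in x$episodes)
    cat(sprintf("  {%s} level %d: %d duplication(s)\n",
                e$cluster, e$level, nrow(e$members)))
  invisible(x)
}

#' Brute-force minimum episodes for rooted gene trees
#'
#' Exhaustively enumerates every placement of each duplication inside its
#' interval, keeps the placements in which comparable duplications of one
#' tree are placed at comparable species nodes in ancestor order, and
#' minimizes the episode count.  Exponential; the independent optimality
#' oracle for [rme_score()].
#'
#' @param trees list of rooted gene trees.
#' @param S a species tree.
#' @param limit maximum total number of duplications (default 8).
#' @return list with `score` and `nodes` (an optimal species-node placement).
#' @export
brute_force_rme <- function(trees, S, limit = 8L) {
  preps <- lapply(trees, prep_rooted, S = S)
  anc <- anc_matrix(S)
  tree_id <- integer(0); bottom <- integer(0); top <- integer(0)
  postpos <- integer(0); desc <- list()
  for (t in seq_along(preps)) {
    p <- preps[[t]]
    off <- length(tree_id)
    tree_id <- c(tree_id, rep(t, length(p$dups)))
    bottom <- c(bottom, p$bottom)
    top <- c(top, p$top)
    postpos <- c(postpos, p$postpos)
    desc <- c(desc, lapply(p$desc, function(d) d + off))
  }
  nd <- length(tree_id)
  if (nd == 0L) return(list(score = 0L, nodes = integer(0)))
  if (nd > limit) stop("too many duplications for brute force: ", nd)
  choices <- lapply(seq_len(nd), function(d) {
    s <- bottom[d]; path <- s
    while (s != top[d]) { s <- S$parent[s]; path <- c(path, s) }
    path
  })
  score_nodes <- function(nodes) {
    # feasibility: descendants at ancestor-or-equal... descendants must sit
    # at nodes below-or-equal their ancestors' nodes
    for (d in seq_len(nd)) {
      dd <- desc[[d]]
      if (length(dd) && !all(anc[nodes[dd], nodes[d]])) return(NA_integer_)
    }
    tot <- 0L
    for (s in unique(nodes)) {
      at_s <- which(nodes == s)
      lam <- 0L
      for (t in unique(tree_id[at_s])) {
        ds <- at_s[tree_id[at_s] == t]
        ds <- ds[order(postpos[ds])]
        len <- stats::setNames(integer(length(ds)), ds)
        for (d in ds) {
          dd <- intersect(desc[[d]], ds)
          len[as.character(d)] <- if (length(dd))
            max(len[as.character(dd)]) + 1L else 1L
        }
        lam <- max(lam, max(len))
      }
      tot <- tot + lam
    }
    tot
  }
  best <- Inf; best_nodes <- NULL
  idx <- rep(1L, nd)
  sizes <- lengths(choices)
  repeat {
    nodes <- vapply(seq_len(nd), function(d) choices[[d]][idx[d]], 0L)
    sc <- score_nodes(nodes)
    if (!is.na(sc) && sc < best) { best <- sc; best_nodes <- nodes }
    # increment mixed-radix counter
    d <- 1L
    while (d <= nd) {
      idx[d] <- idx[d] + 1L
      if (idx[d] <= sizes[d]) break
      idx[d] <- 1L; d <- d + 1L
    }
    if (d > nd) break
  }
  list(score = as.integer(best), nodes = best_nodes)
}
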