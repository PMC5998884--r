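## ---------------------------------------------------------------------------
## Unrooted / general minimum episodes: naive oracle, exact class-enumeration
## solver, linear-time bounds, and a heuristic for hard instances
## ---------------------------------------------------------------------------

is_unrooted <- function(x) inherits(x, "me_unrooted_tree")

## Preprocess a mixed rooted/unrooted input collection once for all solvers.
## For every unrooted tree: plateau, equivalence classes, per-class
## decomposition, and preprocessed rootings for every class edge.
prepare_ume <- function(trees, S) {
  lapply(seq_along(trees), function(i) {
    G <- trees[[i]]
    if (!is_unrooted(G)) {
      p <- prep_rooted(G, S)
      p$src <- i
      return(list(kind = "rooted", prep = p, tree = G))
    }
    pl <- plateau(G, S)
    ec <- equiv_classes(G, S, pl)
    classes <- lapply(ec$classes, function(cl) {
      dc <- decompose_class(G, S, cl, pl)
      if (dc$kind == "plain") {
        rp <- prep_rooted(root_at(G, cl$edges[1, ]), S)
        rp$src <- i
        list(kind = "plain", id = cl$id, edges = cl$edges,
             rooting_prep = rp)
      } else {
        dpreps <- lapply(dc$delta, function(d) {
          p <- prep_rooted(d, S); p$src <- i; p
        })
        epreps <- lapply(seq_len(nrow(dc$class_edges)), function(j) {
          p <- prep_rooted(root_at(dc$uX, dc$class_edges[j, ]), S)
          p$src <- i
          p
        })
        list(kind = "complex", id = cl$id, edges = cl$edges,
             delta_preps = dpreps, edge_preps = epreps, uX = dc$uX)
      }
    })
    list(kind = "unrooted", tree = G, plateau = pl, classes = classes,
         src = i)
  })
}

new_ume_result <- function(score, method, result, rootings = NULL,
                           classes = NULL, bounds = NULL, exact = NA) {
  structure(list(score = score, method = method, result = result,
                 rootings = rootings, classes = classes, bounds = bounds,
                 exact = exact), class = "me_ume")
}

#' @export
print.me_ume <- function(x, ...) {
  cat(sprintf("ME score: %d (method: %s%s)\n", x$score, x$method,
              if (isTRUE(x$exact)) ", exact" else ""))
  if (!is.null(x$bounds))
    cat(sprintf("  bounds: [%d, %d]\n", x$bounds[1], x$bounds[2]))
  invisible(x)
}

#' Naive exhaustive solver for mixed rooted/unrooted inputs
#'
#' Runs the rooted solver for every combination of plateau rootings of the
#' unrooted input trees and returns the minimum.  The primary oracle for the
#' class-based exact solver.
#'
#' @param trees list of rooted and/or unrooted gene trees.
#' @param S a species tree.
#' @param limit maximum number of rooting combinations (default 1e4).
#' @return an `me_ume` object.
#' @export
naive_ume <- function(trees, S, limit = 1e4) {
  rooted_preps <- list()
  unrooted <- list()
  for (i in seq_along(trees)) {
    G <- trees[[i]]
    if (is_unrooted(G)) {
      pl <- plateau(G, S)
      pe <- pl$plateau_edges
      preps <- lapply(seq_len(nrow(pe)), function(j) {
        p <- prep_rooted(root_at(G, pe[j, ]), S); p$src <- i; p
      })
      unrooted[[length(unrooted) + 1L]] <-
        list(src = i, edges = pe, preps = preps)
    } else {
      p <- prep_rooted(G, S); p$src <- i
      rooted_preps[[length(rooted_preps) + 1L]] <- p
    }
  }
  anc <- anc_matrix(S)
  sizes <- vapply(unrooted, function(u) nrow(u$edges), 0L)
  if (prod(sizes) > limit)
    stop("rooting combination count ", prod(sizes), " exceeds limit ", limit)
  if (!length(unrooted)) {
    res <- rme_core(rooted_preps, S, anc)
    return(new_ume_result(res$score, "naive", res))
  }
  idx <- rep(1L, length(unrooted))
  best <- NULL; best_idx <- NULL
  repeat {
    preps <- c(rooted_preps,
               lapply(seq_along(unrooted), function(j)
                 unrooted[[j]]$preps[[idx[j]]]))
    res <- rme_core(preps, S, anc)
    if (is.null(best) || res$score < best$score) {
      best <- res; best_idx <- idx
    }
    d <- 1L
    while (d <= length(idx)) {
      idx[d] <- idx[d] + 1L
      if (idx[d] <= sizes[d]) break
      idx[d] <- 1L; d <- d + 1L
    }
    if (d > length(idx)) break
  }
  rootings <- lapply(seq_along(trees), function(i) NULL)
  for (j in seq_along(unrooted))
    rootings[[unrooted[[j]]$src]] <- unrooted[[j]]$edges[best_idx[j], ]
  new_ume_result(best$score, "naive", best, rootings = rootings, exact = TRUE)
}

#' Minimum over the rootings of one complex class against a rooted background
#'
#' Returns `min` over the class edges of the rooted minimum-episodes score of
#' the background plus the reduced tree rooted on that edge, together with the
#' per-edge extra-root-episode counts `m` (score minus background score minus
#' the obligatory root duplication episode).
#'
#' @param uX reduced unrooted tree of a complex class ([decompose_class()]).
#' @param class_edges matrix of `uX` edges forming the class image.
#' @param background list of rooted gene trees.
#' @param S a species tree.
#' @return list with `score`, `per_edge`, `m`, `best_edge`, `background_score`.
#' @export
gnaw <- function(uX, class_edges, background, S) {
  bg_preps <- lapply(background, prep_rooted, S = S)
  anc <- anc_matrix(S)
  r <- rme_core(bg_preps, S, anc)$score
  per_edge <- vapply(seq_len(nrow(class_edges)), function(j) {
    rme_core(c(bg_preps, list(prep_rooted(root_at(uX, class_edges[j, ]), S))),
             S, anc)$score
  }, 0L)
  best <- which.min(per_edge)
  list(score = min(per_edge), per_edge = per_edge, m = per_edge - r - 1L,
       best_edge = class_edges[best, ], background_score = r)
}

## Score one fixed choice of classes: background preps plus, for every chosen
## complex class, the best joint rooting of its reduced tree.  Evaluates the
## joint product of class-edge rootings when small enough; otherwise combines
## per-tree minima at the root, which is exact when the background has no
## root-level episodes (all background roots are speciations).
score_class_combo <- function(bg_preps, complex_list, S, anc,
                              edge_budget = 1e4) {
  if (!length(complex_list)) {
    res <- rme_core(bg_preps, S, anc)
    return(list(score = res$score, result = res, edge_idx = integer(0)))
  }
  sizes <- vapply(complex_list, function(cl) length(cl$edge_preps), 0L)
  if (prod(sizes) <= edge_budget) {
    idx <- rep(1L, length(sizes))
    best <- NULL; best_idx <- NULL
    repeat {
      preps <- c(bg_preps, lapply(seq_along(complex_list), function(j)
        complex_list[[j]]$edge_preps[[idx[j]]]))
      res <- rme_core(preps, S, anc)
      if (is.null(best) || res$score < best$score) { best <- res; best_idx <- idx }
      d <- 1L
      while (d <= length(idx)) {
        idx[d] <- idx[d] + 1L
        if (idx[d] <= sizes[d]) break
        idx[d] <- 1L; d <- d + 1L
      }
      if (d > length(idx)) break
    }
    return(list(score = best$score, result = best, edge_idx = best_idx))
  }
  # separated evaluation: per-tree best rooting, extra chains meet only in
  # shared root-level episodes
  r <- rme_core(bg_preps, S, anc)$score
  edge_idx <- integer(length(complex_list))
  extras <- integer(length(complex_list))
  for (j in seq_along(complex_list)) {
    per_edge <- vapply(complex_list[[j]]$edge_preps, function(p)
      rme_core(c(bg_preps, list(p)), S, anc)$score, 0L)
    edge_idx[j] <- which.min(per_edge)
    extras[j] <- min(per_edge) - r
  }
  preps <- c(bg_preps, lapply(seq_along(complex_list), function(j)
    complex_list[[j]]$edge_preps[[edge_idx[j]]]))
  result <- rme_core(preps, S, anc)
  list(score = r + max(extras), result = result, edge_idx = edge_idx)
}

#' Exact minimum episodes for mixed rooted/unrooted inputs
#'
#' Enumerates the product of plateau equivalence-class choices over the
#' unrooted input trees (at most `5^k` combinations, `k` the number of trees
#' with an S2 star and more than one class).  Every combination is scored on
#' its decomposition: rooted inputs, plain-class rootings and detached
#' subtrees form a rooted background, and each chosen complex class
#' contributes the best rooting of its reduced tree.
#'
#' @param trees list of rooted and/or unrooted gene trees.
#' @param S a species tree.
#' @param budget maximum number of class combinations (default 1e5).
#' @param edge_budget maximum joint class-edge product evaluated exhaustively
#'   per combination (default 1e4).
#' @return an `me_ume` object with per-tree chosen class and rooting edge.
#' @export
exact_ume <- function(trees, S, budget = 1e5, edge_budget = 1e4) {
  prepped <- prepare_ume(trees, S)
  exact_ume_prepped(prepped, trees, S, budget, edge_budget)
}

exact_ume_prepped <- function(prepped, trees, S, budget = 1e5,
                              edge_budget = 1e4) {
  anc <- anc_matrix(S)
  rooted_preps <- lapply(Filter(function(p) p$kind == "rooted", prepped),
                         function(p) p$prep)
  un <- Filter(function(p) p$kind == "unrooted", prepped)
  sizes <- vapply(un, function(u) length(u$classes), 0L)
  if (prod(sizes) > budget)
    stop("class combination count ", prod(sizes), " exceeds budget ",
         budget, "; use heuristic_ume()")
  if (!length(un)) {
    res <- rme_core(rooted_preps, S, anc)
    return(new_ume_result(res$score, "exact", res, exact = TRUE))
  }
  idx <- rep(1L, length(un))
  best <- NULL
  repeat {
    bg <- rooted_preps
    complex_list <- list()
    complex_src <- integer(0)
    for (j in seq_along(un)) {
      cl <- un[[j]]$classes[[idx[j]]]
      if (cl$kind == "plain") {
        bg <- c(bg, list(cl$rooting_prep))
      } else {
        bg <- c(bg, cl$delta_preps)
        complex_list <- c(complex_list, list(cl))
        complex_src <- c(complex_src, j)
      }
    }
    sc <- score_class_combo(bg, complex_list, S, anc, edge_budget)
    if (is.null(best) || sc$score < best$score) {
      best <- sc
      best$class_idx <- idx
      best$complex_src <- complex_src
    }
    d <- 1L
    while (d <= length(idx)) {
      idx[d] <- idx[d] + 1L
      if (idx[d] <= sizes[d]) break
      idx[d] <- 1L; d <- d + 1L
    }
    if (d > length(idx)) break
  }
  rootings <- vector("list", length(trees))
  classes <- vector("list", length(trees))
  for (j in seq_along(un)) {
    cl <- un[[j]]$classes[[best$class_idx[j]]]
    classes[[un[[j]]$src]] <- cl$id
    if (cl$kind == "plain") {
      rootings[[un[[j]]$src]] <- cl$edges[1, ]
    } else {
      jj <- which(best$complex_src == j)
      rootings[[un[[j]]$src]] <- cl$edges[best$edge_idx[jj], ]
    }
  }
  new_ume_result(best$score, "exact", best$result, rootings = rootings,
                 classes = classes, exact = TRUE)
}

#' Lower bound on the minimum episodes score
#'
#' Trees with several equivalence classes contribute only the duplications
#' outside their plateau (the rooted subtrees hanging off plateau leaves);
#' single-class trees are incorporated in full through their class
#' decomposition, with the class rootings minimized jointly.  The resulting
#' score can never exceed the exact ME score.
#'
#' @param trees list of rooted and/or unrooted gene trees.
#' @param S a species tree.
#' @param edge_budget maximum joint class-edge product minimized exhaustively;
#'   above it single-class plateau duplications are discarded as well, which
#'   keeps the bound valid (default 1e4).
#' @return an `me_ume` object with `method = "lower"`.
#' @export
lower_bound <- function(trees, S, edge_budget = 1e4) {
  prepped <- prepare_ume(trees, S)
  lower_bound_prepped(prepped, S, edge_budget)
}

off_plateau_preps <- function(u, S) {
  U <- u$tree
  pl <- u$plateau
  out <- list()
  for (v in pl$plateau_leaves) {
    pe <- pl$plateau_edges
    i <- which(pe[, 1] == v | pe[, 2] == v)[1]
    w <- setdiff(pe[i, ], v)
    Tv <- unrooted_subtree(U, v, exclude = w)
    p <- prep_rooted(Tv, S)
    p$src <- u$src
    out[[length(out) + 1L]] <- p
  }
  out
}

lower_bound_prepped <- function(prepped, S, edge_budget = 1e4) {
  anc <- anc_matrix(S)
  bg <- lapply(Filter(function(p) p$kind == "rooted", prepped),
               function(p) p$prep)
  un <- Filter(function(p) p$kind == "unrooted", prepped)
  single <- Filter(function(u) length(u$classes) == 1L, un)
  multi <- Filter(function(u) length(u$classes) > 1L, un)
  for (u in multi) bg <- c(bg, off_plateau_preps(u, S))
  complex_list <- list()
  for (u in single) {
    cl <- u$classes[[1]]
    if (cl$kind == "plain") bg <- c(bg, list(cl$rooting_prep))
    else {
      bg <- c(bg, cl$delta_preps)
      complex_list <- c(complex_list, list(cl))
    }
  }
  sizes <- vapply(complex_list, function(cl) length(cl$edge_preps), 0L)
  if (length(sizes) && prod(sizes) > edge_budget) {
    # too large to minimize jointly: discard those plateau duplications too
    bg <- lapply(Filter(function(p) p$kind == "rooted", prepped),
                 function(p) p$prep)
    for (u in multi) bg <- c(bg, off_plateau_preps(u, S))
    for (u in single) {
      cl <- u$classes[[1]]
      if (cl$kind == "plain") bg <- c(bg, list(cl$rooting_prep))
      else bg <- c(bg, cl$delta_preps, off_plateau_preps(u, S))
    }
    res <- rme_core(bg, S, anc)
    return(new_ume_result(res$score, "lower", res, exact = FALSE))
  }
  sc <- score_class_combo(bg, complex_list, S, anc, edge_budget)
  new_ume_result(sc$score, "lower", sc$result, exact = FALSE)
}

#' Upper bound on the minimum episodes score
#'
#' Commits every unrooted tree to its largest equivalence class (ties broken
#' towards the plain class, then the lowest class id), roots each committed
#' complex class greedily against the accumulated background, and scores the
#' resulting fully rooted instance.  A feasible configuration, hence never
#' below the exact ME score.
#'
#' @param trees list of rooted and/or unrooted gene trees.
#' @param S a species tree.
#' @return an `me_ume` object with `method = "upper"`.
#' @export
upper_bound <- function(trees, S) {
  prepped <- prepare_ume(trees, S)
  upper_bound_prepped(prepped, S)
}

upper_bound_prepped <- function(prepped, S) {
  anc <- anc_matrix(S)
  bg <- lapply(Filter(function(p) p$kind == "rooted", prepped),
               function(p) p$prep)
  un <- Filter(function(p) p$kind == "unrooted", prepped)
  chosen <- list()
  for (u in un) {
    sizes <- vapply(u$classes, function(cl) nrow(cl$edges), 0L)
    cl <- u$classes[[which.max(sizes)]]  # first max: plain precedes complex
    if (cl$kind == "plain") bg <- c(bg, list(cl$rooting_prep))
    else {
      bg <- c(bg, cl$delta_preps)
      chosen[[length(chosen) + 1L]] <- cl
    }
  }
  for (cl in chosen) {
    per_edge <- vapply(cl$edge_preps, function(p)
      rme_core(c(bg, list(p)), S, anc)$score, 0L)
    bg <- c(bg, list(cl$edge_preps[[which.min(per_edge)]]))
  }
  res <- rme_core(bg, S, anc)
  new_ume_result(res$score, "upper", res, exact = FALSE)
}

#' Heuristic solver for the minimum episodes score
#'
#' Computes the lower and upper bounds first; when they coincide the common
#' value is the exact score.  Otherwise, when the number of multi-class trees
#' `k` stays within `k_budget`, the exact class-enumeration solver is run;
#' beyond that a greedy pass repeatedly commits the tree/class pair with the
#' smallest score against the accumulated background.
#'
#' @param trees list of rooted and/or unrooted gene trees.
#' @param S a species tree.
#' @param k_budget largest `k` for which exact enumeration is attempted
#'   (default 7).
#' @param budget,edge_budget enumeration caps passed to [exact_ume()].
#' @return an `me_ume` object with `method = "heuristic"`, bounds attached,
#'   and `exact` set when the result is provably optimal.
#' @export
heuristic_ume <- function(trees, S, k_budget = 7L, budget = 1e5,
                          edge_budget = 1e4) {
  prepped <- prepare_ume(trees, S)
  anc <- anc_matrix(S)
  lo <- lower_bound_prepped(prepped, S, edge_budget)
  up <- upper_bound_prepped(prepped, S)
  bounds <- c(lo$score, up$score)
  if (lo$score == up$score) {
    return(new_ume_result(up$score, "heuristic", up$result, bounds = bounds,
                          exact = TRUE))
  }
  un <- Filter(function(p) p$kind == "unrooted", prepped)
  k <- sum(vapply(un, function(u) length(u$classes) > 1L, TRUE))
  if (k <= k_budget) {
    res <- exact_ume_prepped(prepped, trees, S, budget, edge_budget)
    return(new_ume_result(res$score, "heuristic", res$result,
                          rootings = res$rootings, classes = res$classes,
                          bounds = bounds, exact = TRUE))
  }
  # greedy commit: tree/class pair with the minimal score against the
  # current background; ties resolved by input order, then class order
  bg <- lapply(Filter(function(p) p$kind == "rooted", prepped),
               function(p) p$prep)
  remaining <- seq_along(un)
  while (length(remaining)) {
    best <- NULL
    for (j in remaining) {
      for (ci in seq_along(un[[j]]$classes)) {
        cl <- un[[j]]$classes[[ci]]
        if (cl$kind == "plain") {
          sc <- rme_core(c(bg, list(cl$rooting_prep)), S, anc)$score
          add <- list(cl$rooting_prep)
        } else {
          per_edge <- vapply(cl$edge_preps, function(p)
            rme_core(c(bg, cl$delta_preps, list(p)), S, anc)$score, 0L)
          sc <- min(per_edge)
          add <- c(cl$delta_preps, list(cl$edge_preps[[which.min(per_edge)]]))
        }
        if (is.null(best) || sc < best$sc)
          best <- list(sc = sc, j = j, add = add)
      }
    }
    bg <- c(bg, best$add)
    remaining <- setdiff(remaining, best$j)
  }
  res <- rme_core(bg, S, anc)
  new_ume_result(res$score, "heuristic", res, bounds = bounds,
                 exact = res$score == lo$score)
}
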