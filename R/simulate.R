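## ---------------------------------------------------------------------------
## Duplication-loss simulator: synthetic gene families along a species tree
## with optional injected multi-family duplication episodes
## ---------------------------------------------------------------------------

#' Simulate gene families under a duplication-loss model
#'
#' Gene lineages traverse the species tree from the root.  On entering a
#' branch a lineage is lost with probability `loss_prob` (recorded as a loss
#' leaf carrying the branch's cluster) or duplicated with probability
#' `dup_prob` (one trial per branch per lineage).  At an episode node every
#' surviving lineage additionally duplicates with that node's participation
#' probability, which plants a shared multi-family duplication at a known
#' species-tree location.  At the species-tree leaves surviving lineages
#' become gene sequences; internal nodes emit speciations.  Families whose
#' extracted gene tree has fewer than 3 leaves are resampled (bounded
#' retries), so every family yields a valid unrooted tree.
#'
#' @param S a species tree.
#' @param n_families number of gene families to simulate.
#' @param dup_prob per-branch duplication probability in `[0, 1]`.
#' @param loss_prob per-branch per-lineage loss probability in `[0, 1]`.
#' @param episodes list of injected episodes, each `list(node =, prob =)`:
#'   a species node id and a participation probability.
#' @param seed integer seed for the single pseudo-random stream of the run.
#' @param max_retries resampling attempts per family before failing.
#' @return an object of class `me_sim`: list of families, each with `dls`
#'   (the scenario), `rooted` and `unrooted` (the extracted gene tree in both
#'   forms), plus the call parameters as attributes.
#' @examples
#' S <- parse_newick("(((a,b),(c,d)),e);", "species")
#' fams <- simulate_gene_families(S, 5, dup_prob = 0, loss_prob = 0, seed = 1)
#' @export
simulate_gene_families <- function(S, n_families, dup_prob = 0.1,
                                   loss_prob = 0.1, episodes = list(),
                                   seed = 1L, max_retries = 100L) {
  stopifnot(dup_prob >= 0, dup_prob <= 1, loss_prob >= 0, loss_prob <= 1)
  ep_prob <- rep(0, S$n)
  for (e in episodes) {
    if (e$node < 1 || e$node > S$n) stop("episode node not in species tree")
    stopifnot(e$prob >= 0, e$prob <= 1)
    ep_prob[e$node] <- e$prob
  }
  if (!is.null(seed)) set.seed(seed)

  enter_branch <- function(v) {
    if (stats::runif(1) < loss_prob)
      return(list(kind = "loss", species = S$cluster[[v]]))
    if (stats::runif(1) < dup_prob)
      return(list(kind = "dup", kids = list(at_node(v), at_node(v))))
    at_node(v)
  }
  at_node <- function(v) {
    if (ep_prob[v] > 0 && stats::runif(1) < ep_prob[v])
      return(list(kind = "dup", kids = list(settle(v), settle(v))))
    settle(v)
  }
  settle <- function(v) {
    if (S$is_leaf[v]) return(list(kind = "gene", label = S$label[v]))
    kids <- S$children[[v]]
    list(kind = "spec", kids = list(enter_branch(kids[1]),
                                    enter_branch(kids[2])))
  }

  fams <- vector("list", n_families)
  for (i in seq_len(n_families)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      nested <- enter_branch(S$root)
      if (nested$kind == "loss") next
      dls <- validate_dls(flatten_dls(nested))
      if (!sum(dls$kind == "gene")) next
      G <- gt(dls)
      if (n_leaves(G) < 3L) next
      fams[[i]] <- list(dls = dls, rooted = G, unrooted = unroot(G))
      ok <- TRUE
      break
    }
    if (!ok)
      stop("family ", i, " degenerate after ", max_retries,
           " resampling attempts; adjust rates or use a larger species tree")
  }
  structure(fams, class = "me_sim",
            params = list(n_families = n_families, dup_prob = dup_prob,
                          loss_prob = loss_prob, episodes = episodes,
                          seed = seed))
}

#' @export
print.me_sim <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "simulated gene families: %d (dup %.3g, loss %.3g, %d episode node(s), seed %s)\n",
    length(x), p$dup_prob, p$loss_prob, length(p$episodes),
    format(p$seed)))
  invisible(x)
}
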