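## ---------------------------------------------------------------------------
## High-level runner: configuration, species-label resolution, report writing
## ---------------------------------------------------------------------------

#' Resolve gene leaf labels to species names
#'
#' `exact` leaves labels untouched; `separator` keeps the part after the last
#' separator (labels like `GENE_SPECIES`); `file` looks labels up in a
#' two-column table (gene, species).
#'
#' @param tree a rooted or unrooted gene tree.
#' @param mode one of `"exact"`, `"separator"`, `"file"`.
#' @param sep separator character for `separator` mode.
#' @param table data frame with columns gene, species for `file` mode.
#' @return the tree with species leaf labels.
#' @export
map_species_labels <- function(tree, mode = c("exact", "separator", "file"),
                               sep = "_", table = NULL) {
  mode <- match.arg(mode)
  if (mode == "exact") return(tree)
  leaves <- which(tree$is_leaf)
  labs <- tree$label[leaves]
  if (mode == "separator") {
    parts <- strsplit(labs, sep, fixed = TRUE)
    tree$label[leaves] <- vapply(parts, function(p) p[length(p)], "")
  } else {
    if (is.null(table) || ncol(table) < 2)
      stop("file mode requires a two-column gene/species table")
    hit <- match(labs, as.character(table[[1]]))
    if (anyNA(hit))
      stop("gene labels missing from the mapping table: ",
           paste(labs[is.na(hit)], collapse = ", "))
    tree$label[leaves] <- as.character(table[[2]])[hit]
  }
  tree
}

#' Score a collection of gene trees and reconstruct episodes
#'
#' The main entry point behind the command-line interface: reads or accepts
#' trees, runs the requested solver, and assembles a report with the score,
#' per-tree rooting and class decisions, reconstructed episodes with their
#' species-tree locations, per-node episode counts, and per-tree
#' decomposition statistics.
#'
#' @param species a species tree object or newick string/path.
#' @param genes a list of gene trees, or a path to a one-tree-per-line
#'   newick file.
#' @param mode `"unrooted"` or `"rooted"` parsing for gene-tree files.
#' @param method one of `"exact"`, `"lower"`, `"upper"`, `"heuristic"`,
#'   `"naive"`, `"rooted"`.
#' @param species_map,sep,map_table label resolution, see
#'   [map_species_labels()].
#' @param budget,edge_budget,k_budget solver caps, see [exact_ume()] and
#'   [heuristic_ume()].
#' @return an object of class `me_report`.
#' @export
ume_run <- function(species, genes, mode = "unrooted", method = "heuristic",
                    species_map = "exact", sep = "_", map_table = NULL,
                    budget = 1e5, edge_budget = 1e4, k_budget = 7L) {
  if (is.character(species)) {
    txt <- if (file.exists(species)) paste(readLines(species, warn = FALSE),
                                           collapse = "") else species
    species <- parse_newick(txt, "species")
  }
  if (is.character(genes)) genes <- read_newick_file(genes, mode = mode)
  genes <- lapply(genes, map_species_labels, mode = species_map, sep = sep,
                  table = map_table)
  if (!length(genes)) {
    warning("empty gene tree collection; score is 0")
    return(structure(list(score = 0L, method = method, episodes = list(),
                          lambda = integer(0), trees = list()),
                     class = "me_report"))
  }
  res <- switch(method,
    exact = exact_ume(genes, species, budget, edge_budget),
    naive = naive_ume(genes, species),
    lower = lower_bound(genes, species, edge_budget),
    upper = upper_bound(genes, species),
    heuristic = heuristic_ume(genes, species, k_budget, budget, edge_budget),
    rooted = {
      if (any(vapply(genes, is_unrooted, TRUE)))
        stop("method 'rooted' requires rooted gene trees")
      r <- rme_score(genes, species)
      new_ume_result(r$score, "rooted", r, exact = TRUE)
    },
    stop("unknown method: ", method))
  stats <- lapply(seq_along(genes), function(i) {
    G <- genes[[i]]
    if (!is_unrooted(G))
      return(data.frame(tree = i, kind = "rooted", leaves = n_leaves(G),
                        plateau = NA, empty = NA, double = NA, classes = NA))
    pl <- plateau(G, species)
    ec <- equiv_classes(G, species, pl)
    data.frame(tree = i, kind = "unrooted", leaves = n_leaves(G),
               plateau = nrow(pl$plateau_edges),
               empty = !is.null(pl$empty_edge),
               double = nrow(pl$double_edges) > 0,
               classes = length(ec$classes))
  })
  inner <- res$result
  structure(list(score = res$score, method = res$method, exact = res$exact,
                 bounds = res$bounds, rootings = res$rootings,
                 classes = res$classes,
                 lambda = inner$lambda, episodes = inner$episodes,
                 decomposition = do.call(rbind, stats),
                 species = species, trees = genes),
            class = "me_report")
}

#' @export
print.me_report <- function(x, ...) {
  cat(sprintf("ME score: %s (method %s%s)\n", format(x$score), x$method,
              if (isTRUE(x$exact)) ", exact" else ""))
  if (!is.null(x$bounds))
    cat(sprintf("bounds: [%d, %d]\n", x$bounds[1], x$bounds[2]))
  cat(sprintf("episodes: %d\n", length(x$episodes)))
  for (e in utils::head(x$episodes, 20))
    cat(sprintf("  {%s} level %d: %d duplication(s)\n", e$cluster, e$level,
                nrow(e$members)))
  invisible(x)
}

#' Convert a report to JSON
#' @param report an `me_report`.
#' @param path optional output file.
#' @return the JSON string, invisibly when written to a file.
#' @export
report_json <- function(report, path = NULL) {
  obj <- list(
    score = report$score, method = report$method,
    exact = isTRUE(report$exact),
    bounds = report$bounds,
    episodes = lapply(report$episodes, function(e)
      list(species_cluster = e$cluster, level = e$level,
           members = e$members)),
    per_node_episodes = {
      lam <- report$lambda
      idx <- which(lam > 0)
      lapply(idx, function(v)
        list(cluster = paste(report$species$cluster[[v]], collapse = ","),
             episodes = lam[v]))
    },
    decomposition = report$decomposition)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Convert a report's episodes to a data frame (TSV-ready)
#' @param report an `me_report`.
#' @return data frame with one row per episode member.
#' @export
report_episodes_df <- function(report) {
  if (!length(report$episodes))
    return(data.frame(cluster = character(0), level = integer(0),
                      tree = integer(0), node = integer(0)))
  do.call(rbind, lapply(report$episodes, function(e)
    data.frame(cluster = e$cluster, level = e$level,
               tree = e$members$tree, node = e$members$orig_node)))
}
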