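# Random instance generators and shared law checks, used by the unit and
# acceptance tests.  All randomness is driven by explicit set.seed() calls at
# the use sites, so every generated instance is reproducible from its seed.

rand_join <- function(items) {
  while (length(items) > 1) {
    i <- sample.int(length(items), 2)
    joined <- paste0("(", items[[i[1]]], ",", items[[i[2]]], ")")
    items <- c(items[-i], list(joined))
  }
  items[[1]]
}

rand_species_tree <- function(k) {
  parse_newick(paste0(rand_join(as.list(letters[seq_len(k)])), ";"), "species")
}

rand_rooted_gene <- function(S, nl) {
  labs <- sample(tree_species(S), nl, replace = TRUE)
  parse_newick(paste0(rand_join(as.list(labs)), ";"), "rooted")
}

rand_unrooted_gene <- function(S, nl) {
  unroot(rand_rooted_gene(S, max(nl, 3L)))
}

tempfile_with <- function(lines) {
  f <- tempfile(fileext = ".nwk")
  writeLines(lines, f)
  f
}

# worked-example fixtures
example_species <- function() parse_newick("(((a,b),(c,d)),e);", "species")
example_unrooted <- function()
  parse_newick("(d,e,(c,(((a,b),b),((c,d),d))));", "unrooted")
example_rooting <- function()
  parse_newick("(e,(d,(c,(((a,b),b),((c,d),d)))));", "rooted")

# locate the edge between the (first) leaf labeled `lab` and its neighbor
leaf_edge <- function(U, lab) {
  v <- which(U$is_leaf & !is.na(U$label) & U$label == lab)[1]
  c(v, U$adj[[v]][1])
}

# connectivity of an edge set inside U
edges_connected <- function(U, edges) {
  if (nrow(edges) <= 1) return(TRUE)
  nodes <- unique(as.integer(edges))
  seen <- nodes[1]
  repeat {
    nxt <- unique(c(seen, as.integer(edges[edges[, 1] %in% seen |
                                             edges[, 2] %in% seen, ])))
    if (length(nxt) == length(seen)) break
    seen <- nxt
  }
  length(seen) == length(nodes)
}

# Structural laws of the plateau (argmin oracle, empty/double dichotomy,
# role guarantees of the optimal rootings).
expect_plateau_laws <- function(U, S) {
  pl <- plateau(U, S)
  bf <- plateau_brute(U, S)
  expect_equal(pl$min_cost, bf$min_cost)
  expect_equal(pl$plateau_edges, bf$plateau, ignore_attr = TRUE)
  expect_equal(pl$edges$cost, bf$cost)
  # exactly one empty edge XOR at least one double edge on the plateau
  n_empty <- sum(pl$edges$type == "empty" & pl$edges$in_plateau)
  n_double <- sum(pl$edges$type == "double" & pl$edges$in_plateau)
  expect_true((n_empty == 1 && n_double == 0) ||
                (n_empty == 0 && n_double >= 1))
  expect_true(edges_connected(U, pl$plateau_edges))
  # role checks across every optimal rooting
  for (i in seq_len(nrow(pl$plateau_edges))) {
    e <- pl$plateau_edges[i, ]
    G <- root_at(U, e)
    map <- lca_map(G, S)
    for (v in pl$plateau_nodes) {
      role <- pl$roles[v]
      if (is.na(role) || role == "conditional") next
      expected <- if (role == "super-duplication") "duplication" else "speciation"
      expect_equal(map$event[v], expected)
    }
    # a node incident to the empty edge is a speciation in the empty-edge
    # rooting iff it is a plateau leaf
    if (!is.null(pl$empty_edge) && all(sort(e) == sort(pl$empty_edge))) {
      for (v in pl$empty_edge) {
        expect_equal(map$event[v] == "speciation",
                     v %in% pl$plateau_leaves)
      }
    }
  }
  invisible(pl)
}

# Class laws: structural construction equals the frontier-equality partition,
# class counts in {1,3,5}, plain classes are empty-edge singletons.
expect_class_laws <- function(U, S, pl = NULL) {
  if (is.null(pl)) pl <- plateau(U, S)
  ec <- equiv_classes(U, S, pl)
  expect_true(length(ec$classes) %in% c(1L, 3L, 5L))
  structural <- lapply(ec$classes, function(cl)
    sort(apply(cl$edges, 1, paste, collapse = "-")))
  pe <- pl$plateau_edges
  defn <- dupisodes:::equiv_classes_frontier(U, S, pl)
  definitional <- lapply(defn, function(idx)
    sort(apply(pe[idx, , drop = FALSE], 1, paste, collapse = "-")))
  expect_setequal(vapply(structural, paste, "", collapse = "|"),
                  vapply(definitional, paste, "", collapse = "|"))
  # partition covers the plateau
  expect_setequal(unlist(structural), apply(pe, 1, paste, collapse = "-"))
  for (cl in ec$classes) {
    if (cl$kind == "plain") {
      expect_equal(nrow(cl$edges), 1L)
      expect_equal(sort(cl$edges[1, ]), sort(pl$empty_edge))
    }
  }
  if (nrow(pl$double_edges) > 0) expect_length(ec$classes, 1L)
  invisible(ec)
}
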