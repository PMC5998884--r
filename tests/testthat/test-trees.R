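test_that("newick parsing produces valid trees and rejects malformed input", {
  S <- example_species()
  expect_equal(n_leaves(S), 5L)
  expect_setequal(tree_species(S), c("a", "b", "c", "d", "e"))
  expect_equal(node_cluster(S, S$root), c("a", "b", "c", "d", "e"))

  U <- example_unrooted()
  expect_equal(n_leaves(U), 9L)
  expect_equal(sum(!U$is_leaf), 7L)
  expect_true(all(lengths(U$adj)[!U$is_leaf] == 3L))

  expect_error(parse_newick("a;", "species"), "trivial|parse")
  expect_error(parse_newick("((a,b),(a,c));", "species"), "unique")
  expect_error(parse_newick("(a,b,c,d);", "unrooted"), "multifurcation")
  expect_error(parse_newick("((a,b,c),d);", "rooted"), "binary")
})

test_that("parse/write round trips are stable for all three tree kinds", {
  for (txt in c("(((a,b),(c,d)),e);", "((a,b),c);")) {
    S <- parse_newick(txt, "species")
    expect_equal(canonical_rooted(parse_newick(write_newick(S), "species")),
                 canonical_rooted(S))
  }
  G <- parse_newick("((a,(a,b)),(c,c));", "rooted")
  expect_equal(write_newick(parse_newick(write_newick(G), "rooted")),
               write_newick(G))
  U <- example_unrooted()
  U2 <- parse_newick(write_newick(U), "unrooted")
  expect_equal(canonical_unrooted(U2), canonical_unrooted(U))
  # a rooted binary string read in unrooted mode dissolves the root
  U3 <- parse_newick("((a,b),(c,d));", "unrooted")
  expect_equal(n_leaves(U3), 4L)
  expect_equal(sum(!U3$is_leaf), 2L)
})

test_that("root_at subdivides an edge, preserves identity, and inverts", {
  U <- parse_newick("(a,b,c);", "unrooted")
  e <- leaf_edge(U, "c")
  G <- root_at(U, e)
  expect_equal(G$n, U$n + 1L)
  expect_equal(length(G$children[[G$root]]), 2L)
  expect_equal(canonical_rooted(G), "((a,b),c)")
  expect_error(root_at(U, c(1L, 2L)), "not in")

  U9 <- example_unrooted()
  for (i in seq_len(nrow(U9$edges))) {
    G9 <- root_at(U9, U9$edges[i, ])
    back <- unroot(G9)
    expect_identical(back$adj, U9$adj)
    expect_identical(back$label, U9$label)
  }
  # rooting on the edge next to leaf e reproduces the worked-example rooting
  expect_equal(canonical_rooted(root_at(U9, leaf_edge(U9, "e"))),
               canonical_rooted(example_rooting()))
})

test_that("species-tree services: lca, clusters, subtree copies", {
  S <- example_species()
  ab <- which(vapply(S$cluster, function(x) identical(x, c("a", "b")), TRUE))
  expect_equal(tree_lca(S, S$leaf_of[["a"]], S$leaf_of[["b"]]), ab)
  expect_equal(tree_lca(S, ab, ab), ab)
  abcd <- which(vapply(S$cluster, function(x)
    identical(x, c("a", "b", "c", "d")), TRUE))
  expect_equal(canonical_rooted(species_subtree(S, abcd)), "((a,b),(c,d))")
  expect_true(all(is.na(species_subtree(S, abcd)$orig)))
  # leaf count equals root cluster size for random species trees
  set.seed(11)
  for (k in c(3, 5, 8)) {
    St <- rand_species_tree(k)
    expect_equal(n_leaves(St), length(node_cluster(St, St$root)))
  }
})

test_that("gene label resolution supports separator and table modes", {
  G <- parse_newick("((g1_a,g2_b),g3_c);", "rooted")
  Gm <- map_species_labels(G, "separator", sep = "_")
  expect_setequal(tree_species(Gm), c("a", "b", "c"))
  tab <- data.frame(gene = c("x", "y", "z"), species = c("a", "b", "c"))
  G2 <- parse_newick("((x,y),z);", "rooted")
  expect_setequal(tree_species(map_species_labels(G2, "file", table = tab)),
                  c("a", "b", "c"))
  expect_error(map_species_labels(parse_newick("((x,q),z);", "rooted"),
                                  "file", table = tab), "missing")
})
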