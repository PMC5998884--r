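test_that("lca mapping and duplication cost match hand-computed cases", {
  S <- example_species()
  # a restriction of S reconciles without duplications
  G0 <- parse_newick("((a,b),(c,d));", "rooted")
  expect_equal(dup_cost(G0, S), 0L)
  m0 <- lca_map(G0, S)
  expect_true(all(m0$event == "speciation"))
  expect_equal(m0$map[which(G0$label == "a")], unname(S$leaf_of[["a"]]))

  # one duplication at the (a,a) cherry
  expect_equal(dup_cost(parse_newick("((a,a),b);", "rooted"),
                        parse_newick("((a,b),c);", "species")), 1L)

  # the worked-example rooting has four duplications, two of them at the
  # {a,b,c,d} species node
  G1 <- example_rooting()
  m1 <- lca_map(G1, S)
  expect_equal(sum(m1$event == "duplication"), 4L)
  abcd <- which(vapply(S$cluster, function(x)
    identical(x, c("a", "b", "c", "d")), TRUE))
  expect_equal(sum(m1$map == abcd & m1$event == "duplication"), 2L)
  expect_error(lca_map(parse_newick("((a,z),b);", "rooted"), S), "species")
})

test_that("directed-edge mappings agree with rooting each edge", {
  set.seed(21)
  for (rep in 1:25) {
    S <- rand_species_tree(sample(3:7, 1))
    U <- rand_unrooted_gene(S, sample(4:9, 1))
    em <- edge_maps(U, S)
    for (i in seq_len(nrow(U$edges))) {
      e <- U$edges[i, ]
      G <- root_at(U, e)
      map <- lca_map(G, S)
      # each orientation image is the mapping of the corresponding child of
      # the root, and their lca is the root image
      expect_equal(em$M[e[1], e[2]], map$map[e[2]])
      expect_equal(em$M[e[2], e[1]], map$map[e[1]])
      expect_equal(tree_lca(S, em$M[e[1], e[2]], em$M[e[2], e[1]]),
                   map$map[G$root])
    }
  }
})

test_that("edge classification identifies empty, single and double edges", {
  S <- example_species()
  U <- example_unrooted()
  pl <- plateau(U, S)
  ed <- pl$edges
  key <- function(e) paste(sort(e), collapse = "-")
  types <- setNames(ed$type, paste(ed$u, ed$v, sep = "-"))
  expect_equal(unname(types[key(leaf_edge(U, "e"))]), "empty")
  # the single edge between the S2 center and its adjacent d leaf
  ctr <- leaf_edge(U, "e")[2]
  dleaf <- intersect(U$adj[[ctr]], which(U$is_leaf & !is.na(U$label) &
                                           U$label == "d"))
  expect_equal(unname(types[key(c(ctr, dleaf))]), "single")
  expect_equal(sum(ed$type == "empty"), 1L)

  # a quartet of two identical cherries over a two-species tree has a double
  # central edge, which is the whole plateau
  S2 <- parse_newick("(a,b);", "species")
  Q <- parse_newick("((a,b),(a,b));", "unrooted")
  plq <- plateau(Q, S2)
  central <- Q$edges[!(Q$edges[, 1] %in% which(Q$is_leaf)) &
                       !(Q$edges[, 2] %in% which(Q$is_leaf)), ]
  expect_equal(plq$plateau_edges, matrix(central, 1), ignore_attr = TRUE)
  expect_equal(plq$min_cost, 1L)
  expect_equal(plq$edges$type[plq$edges$in_plateau], "double")
})

test_that("plateau equals the brute-force argmin and satisfies its laws", {
  S <- example_species()
  U <- example_unrooted()
  pl <- expect_plateau_laws(U, S)
  expect_equal(nrow(pl$plateau_edges), 5L)
  expect_equal(pl$min_cost, 4L)

  # three-leaf tree: the zero-cost rooting next to c is the whole plateau
  S3 <- parse_newick("((a,b),c);", "species")
  U3 <- parse_newick("(a,b,c);", "unrooted")
  pl3 <- plateau(U3, S3)
  expect_equal(pl3$min_cost, 0L)
  expect_equal(pl3$plateau_edges, matrix(leaf_edge(U3, "c"), 1),
               ignore_attr = TRUE)

  set.seed(31)
  for (rep in 1:40) {
    Sr <- rand_species_tree(sample(3:8, 1))
    Ur <- rand_unrooted_gene(Sr, sample(4:10, 1))
    expect_plateau_laws(Ur, Sr)
  }
})

test_that("all plateau rootings share the minimal duplication cost", {
  set.seed(41)
  for (rep in 1:20) {
    S <- rand_species_tree(sample(3:7, 1))
    U <- rand_unrooted_gene(S, sample(4:9, 1))
    pl <- plateau(U, S)
    costs <- vapply(seq_len(nrow(U$edges)), function(i)
      dup_cost(root_at(U, U$edges[i, ]), S), 0L)
    expect_true(all(costs[pl$edges$in_plateau] == pl$min_cost))
    if (any(!pl$edges$in_plateau))
      expect_true(all(costs[!pl$edges$in_plateau] > pl$min_cost))
  }
})
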