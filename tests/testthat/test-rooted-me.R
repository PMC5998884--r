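test_that("duplication intervals follow the lowest-speciation rule", {
  S <- example_species()
  G1 <- example_rooting()
  iv <- intervals(G1, S)
  abcd <- which(vapply(S$cluster, function(x)
    identical(x, c("a", "b", "c", "d")), TRUE))
  at_abcd <- iv[iv$bottom == abcd, ]
  # the two duplications mapped to {a,b,c,d} are pinned there
  expect_equal(nrow(at_abcd), 2L)
  expect_equal(at_abcd$top, c(abcd, abcd))

  # a root duplication with no speciation ancestor reaches the species root
  S3 <- parse_newick("((a,b),c);", "species")
  Gaa <- parse_newick("(a,a);", "rooted")
  iv2 <- intervals(Gaa, S3)
  expect_equal(iv2$bottom, unname(S3$leaf_of[["a"]]))
  expect_equal(iv2$top, S3$root)

  # the cherry duplication under a speciation root is pinned to leaf a
  G <- parse_newick("((a,a),b);", "rooted")
  iv3 <- intervals(G, S3)
  expect_equal(iv3$bottom, unname(S3$leaf_of[["a"]]))
  expect_equal(iv3$top, unname(S3$leaf_of[["a"]]))

  # bottom is always below-or-equal top
  set.seed(71)
  for (rep in 1:30) {
    Sr <- rand_species_tree(sample(3:7, 1))
    Gr <- rand_rooted_gene(Sr, sample(2:9, 1))
    ivr <- intervals(Gr, Sr)
    for (i in seq_len(nrow(ivr)))
      expect_true(is_desc(Sr, ivr$bottom[i], ivr$top[i]))
  }
})

test_that("rooted solver handles base cases and shares cross-tree episodes", {
  S <- example_species()
  expect_equal(rme_score(list(), S)$score, 0L)
  expect_equal(rme_score(list(parse_newick("((a,b),(c,d));", "rooted")),
                         S)$score, 0L)
  # two trees with the same pinned duplication share one episode
  S3 <- parse_newick("((a,b),c);", "species")
  G <- parse_newick("((a,a),b);", "rooted")
  expect_equal(rme_score(list(G, G), S3)$score, 1L)
  # the worked-example rooting alone costs 4 episodes
  r <- rme_score(list(example_rooting()), S)
  expect_equal(r$score, 4L)
  expect_equal(sum(r$lambda), 4L)
  abcd_cluster <- "a,b,c,d"
  expect_equal(sum(vapply(r$episodes, function(e)
    e$cluster == abcd_cluster, TRUE)), 2L)
})

test_that("greedy solver matches the brute-force optimum on random instances", {
  set.seed(81)
  done <- 0
  while (done < 120) {
    S <- rand_species_tree(sample(3:6, 1))
    nt <- sample(1:4, 1)
    trees <- replicate(nt, rand_rooted_gene(S, sample(2:6, 1)),
                       simplify = FALSE)
    nd <- sum(vapply(trees, dup_cost, 0L, S = S))
    if (nd > 7) next
    bf <- brute_force_rme(trees, S)
    expect_equal(rme_score(trees, S)$score, bf$score)
    done <- done + 1
  }
})

test_that("score is monotone in the tree set and zero iff duplication-free", {
  set.seed(91)
  for (rep in 1:25) {
    S <- rand_species_tree(sample(3:6, 1))
    trees <- replicate(sample(1:3, 1), rand_rooted_gene(S, sample(2:7, 1)),
                       simplify = FALSE)
    extra <- rand_rooted_gene(S, sample(2:7, 1))
    base <- rme_score(trees, S)$score
    expect_gte(rme_score(c(trees, list(extra)), S)$score, base)
    expect_equal(rme_score(c(trees, trees), S)$score, base)
    nd <- sum(vapply(trees, dup_cost, 0L, S = S))
    expect_equal(base == 0L, nd == 0L)
  }
})

test_that("episode reconstruction is consistent with the score", {
  set.seed(101)
  for (rep in 1:25) {
    S <- rand_species_tree(sample(3:6, 1))
    trees <- replicate(sample(1:3, 1), rand_rooted_gene(S, sample(3:8, 1)),
                       simplify = FALSE)
    r <- rme_score(trees, S)
    expect_equal(sum(r$lambda), r$score)
    expect_equal(length(r$episodes),
                 sum(vapply(r$episodes, function(e) 1L, 0L)))
    # every duplication appears in exactly one episode
    nd <- sum(vapply(trees, dup_cost, 0L, S = S))
    members <- do.call(rbind, lapply(r$episodes, function(e) e$members))
    expect_equal(if (is.null(members)) 0L else nrow(members), nd)
    if (!is.null(members))
      expect_false(anyDuplicated(members[c("tree", "node")]) > 0)
    # within an episode, no two members of one tree are comparable
    for (e in r$episodes) {
      for (t in unique(e$members$tree)) {
        nodes <- e$members$node[e$members$tree == t]
        if (length(nodes) < 2) next
        G <- trees[[t]]
        for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
          if (i == j) next
          a <- nodes[i]
          repeat {
            a <- G$parent[a]
            if (is.na(a)) break
            expect_false(a == nodes[j])
          }
        }
      }
    }
    # interval feasibility and within-tree monotonicity of the assignment
    anc <- dupisodes:::anc_matrix(S)
    for (t in seq_along(trees)) {
      iv <- intervals(trees[[t]], S)
      rows <- r$assignment[r$assignment$tree == t, ]
      rows <- rows[match(iv$node, rows$node), ]
      expect_true(all(anc[cbind(iv$bottom, rows$species)]))
      expect_true(all(anc[cbind(rows$species, iv$top)]))
    }
  }
})
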