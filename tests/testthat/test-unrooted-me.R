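test_that("gnaw returns the minimum over class rootings against a background", {
  S <- example_species()
  U <- example_unrooted()
  ec <- equiv_classes(U, S)
  sizes <- vapply(ec$classes, function(cl) nrow(cl$edges), 0L)
  big <- ec$classes[[which.max(sizes)]]
  dc <- decompose_class(U, S, big)
  g <- gnaw(dc$uX, dc$class_edges, dc$delta, S)
  expect_equal(g$score, 4L)
  # every rooting of the largest class costs the same here
  expect_true(all(g$per_edge == 4L))
  # invariant to background order
  g2 <- gnaw(dc$uX, dc$class_edges, rev(dc$delta), S)
  expect_equal(g2$score, g$score)
  # definitional contract on random single-class instances
  set.seed(111)
  for (rep in 1:15) {
    Sr <- rand_species_tree(sample(3:6, 1))
    Ur <- rand_unrooted_gene(Sr, sample(4:8, 1))
    bg <- replicate(sample(0:2, 1), rand_rooted_gene(Sr, sample(2:5, 1)),
                    simplify = FALSE)
    ecr <- equiv_classes(Ur, Sr)
    for (cl in ecr$classes) {
      if (cl$kind != "complex") next
      dcr <- decompose_class(Ur, Sr, cl)
      gr <- gnaw(dcr$uX, dcr$class_edges, bg, Sr)
      direct <- min(vapply(seq_len(nrow(dcr$class_edges)), function(i)
        rme_score(c(bg, list(root_at(dcr$uX, dcr$class_edges[i, ]))),
                  Sr)$score, 0L))
      expect_equal(gr$score, direct)
    }
  }
})

test_that("exact solver reproduces hand-checked scores", {
  S <- example_species()
  U <- example_unrooted()
  expect_equal(exact_ume(list(U), S)$score, 4L)
  expect_equal(exact_ume(list(U, U), S)$score, 4L)
  S3 <- parse_newick("((a,b),c);", "species")
  expect_equal(exact_ume(list(parse_newick("(a,b,c);", "unrooted")),
                         S3)$score, 0L)
  # reported rooting lies on the plateau
  res <- exact_ume(list(U), S)
  pl <- plateau(U, S)
  keys <- apply(pl$plateau_edges, 1, paste, collapse = "-")
  expect_true(paste(sort(res$rootings[[1]]), collapse = "-") %in% keys)
})

test_that("exact equals the naive oracle on random mixed instances", {
  set.seed(121)
  done <- 0
  while (done < 40) {
    S <- rand_species_tree(sample(3:6, 1))
    nu <- sample(1:2, 1)
    nr <- sample(0:1, 1)
    trees <- c(replicate(nu, rand_unrooted_gene(S, sample(4:8, 1)),
                         simplify = FALSE),
               replicate(nr, rand_rooted_gene(S, sample(2:5, 1)),
                         simplify = FALSE))
    sizes <- vapply(trees, function(G) {
      if (inherits(G, "me_unrooted_tree"))
        nrow(plateau(G, S)$plateau_edges) else 1L
    }, 0L)
    if (prod(sizes) > 300) next
    expect_equal(exact_ume(trees, S)$score, naive_ume(trees, S)$score)
    done <- done + 1
  }
})

test_that("bounds sandwich the exact score and the heuristic stays inside", {
  set.seed(131)
  done <- 0
  while (done < 30) {
    S <- rand_species_tree(sample(3:6, 1))
    trees <- c(replicate(sample(1:2, 1), rand_unrooted_gene(S, sample(4:8, 1)),
                         simplify = FALSE),
               replicate(sample(0:1, 1), rand_rooted_gene(S, sample(2:5, 1)),
                         simplify = FALSE))
    sizes <- vapply(trees, function(G) {
      if (inherits(G, "me_unrooted_tree"))
        nrow(plateau(G, S)$plateau_edges) else 1L
    }, 0L)
    if (prod(sizes) > 300) next
    ex <- exact_ume(trees, S)$score
    lo <- lower_bound(trees, S)$score
    up <- upper_bound(trees, S)$score
    he <- heuristic_ume(trees, S)
    expect_lte(lo, ex)
    expect_gte(up, ex)
    expect_gte(he$score, lo)
    expect_lte(he$score, up)
    if (lo == up) expect_equal(he$score, ex)
    if (isTRUE(he$exact)) expect_equal(he$score, ex)
    done <- done + 1
  }
})

test_that("rooted-only instances collapse to the rooted solver", {
  set.seed(141)
  S <- rand_species_tree(5)
  trees <- replicate(3, rand_rooted_gene(S, 5), simplify = FALSE)
  r <- rme_score(trees, S)$score
  expect_equal(exact_ume(trees, S)$score, r)
  expect_equal(lower_bound(trees, S)$score, r)
  expect_equal(upper_bound(trees, S)$score, r)
  expect_equal(heuristic_ume(trees, S)$score, r)
  expect_equal(naive_ume(trees, S)$score, r)
})

test_that("greedy heuristic phase stays within bounds when forced", {
  set.seed(151)
  done <- 0
  while (done < 8) {
    S <- rand_species_tree(sample(4:6, 1))
    trees <- replicate(2, rand_unrooted_gene(S, sample(5:8, 1)),
                       simplify = FALSE)
    multi <- vapply(trees, function(U)
      length(equiv_classes(U, S)$classes) > 1L, TRUE)
    if (!any(multi)) next
    sizes <- vapply(trees, function(G) nrow(plateau(G, S)$plateau_edges), 0L)
    if (prod(sizes) > 300) next
    he <- heuristic_ume(trees, S, k_budget = 0L)
    ex <- exact_ume(trees, S)$score
    expect_gte(he$score, ex)
    expect_lte(he$score, upper_bound(trees, S)$score)
    done <- done + 1
  }
})

test_that("class enumeration breadth obeys the 5^k law", {
  set.seed(161)
  for (rep in 1:20) {
    S <- rand_species_tree(sample(3:6, 1))
    trees <- replicate(sample(1:3, 1), rand_unrooted_gene(S, sample(4:9, 1)),
                       simplify = FALSE)
    ncls <- vapply(trees, function(U) length(equiv_classes(U, S)$classes), 0L)
    k <- sum(ncls > 1L)
    expect_true(all(ncls %in% c(1L, 3L, 5L)))
    expect_lte(prod(ncls), 5^k)
  }
})
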