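test_that("Wagner length equals ordered-cost intuition on small cases", {
  m <- char_matrix(matrix(c(0L, 2L), 2, 1, dimnames = list(c("A", "B"), "c1")), 3)
  tr <- ape::read.tree(text = "(A,B);")
  expect_equal(wagner_length(tr, m), 2)
  m2 <- char_matrix(matrix(c(0L, 0L, 2L, 2L), 4, 1,
                           dimnames = list(LETTERS[1:4], "c1")), 3)
  tr2 <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(wagner_length(tr2, m2), brute_wagner(tr2, m2$states))
  expect_equal(wagner_length(tr2, m2), 2)
  ident <- char_matrix(matrix(1L, 4, 3, dimnames = list(LETTERS[1:4],
                                                        paste0("c", 1:3))), 3)
  expect_equal(wagner_length(tr2, ident), 0)
  expect_error(wagner_length(tr2, m), "taxa")
})

test_that("Wagner length equals the brute-force labeling minimum", {
  set.seed(19)
  for (i in 1:60) {
    nt <- sample(3:6, 1); nc <- sample(1:4, 1); k <- sample(2:4, 1)
    m <- random_char_matrix(nt, nc, k)
    tr <- ape::rtree(nt, br = NULL)
    tr$tip.label <- sample(rownames(m$states))
    expect_equal(wagner_length(tr, m), brute_wagner(tr, m$states))
  }
})

test_that("Wagner length agrees with independent Sankoff implementation", {
  skip_if_not_installed("phangorn")
  set.seed(37)
  for (i in 1:10) {
    nt <- 6; k <- 5
    m <- random_char_matrix(nt, 8, k)
    tr <- ape::rtree(nt, br = NULL)
    tr$tip.label <- sample(rownames(m$states))
    pd <- phangorn::phyDat(m$states[tr$tip.label, ], type = "USER",
                           levels = 0:(k - 1))
    cost <- outer(0:(k - 1), 0:(k - 1), function(a, b) abs(a - b))
    dimnames(cost) <- list(0:(k - 1), 0:(k - 1))
    expect_equal(wagner_length(tr, m),
                 sum(phangorn::sankoff(tr, pd, cost = cost, site = "site")))
  }
})

test_that("length is invariant under taxon relabeling (permutation)", {
  set.seed(3)
  m <- random_char_matrix(6, 5, 4)
  tr <- ape::rtree(6, br = NULL)
  tr$tip.label <- rownames(m$states)
  L <- wagner_length(tr, m)
  perm <- sample(rownames(m$states))
  st2 <- m$states[perm, , drop = FALSE]
  m2 <- char_matrix(st2, 4)
  expect_equal(wagner_length(tr, m2), L)
})

test_that("exhaustive search finds the global optimum and refuses big inputs", {
  # perfectly nested matrix: zero homoplasy, unique tree, CI = 1
  st <- rbind(t1 = c(0L, 0L, 0L, 0L), t2 = c(1L, 0L, 0L, 0L),
              t3 = c(1L, 1L, 0L, 0L), t4 = c(1L, 1L, 1L, 0L),
              t5 = c(1L, 1L, 1L, 1L))
  colnames(st) <- paste0("c", 1:4)
  m <- attach_ancestor(char_matrix(st, 2,
                                   polarity = setNames(rep("low", 4), colnames(st))))
  res <- exhaustive_search(m, g1_samples = 100)
  expect_equal(res$length, 4)
  expect_equal(length(res$trees), 1L)
  expect_equal(res$fit$ci, 1)
  expect_equal(res$fit$ri, 1)
  # two-taxon matrix: single topology, length = state differences
  m2 <- char_matrix(matrix(c(0L, 3L, 1L, 1L), 2, 2,
                           dimnames = list(c("A", "B"), c("c1", "c2"))), 4)
  r2 <- exhaustive_search(m2, g1_samples = 0)
  expect_equal(r2$length, 3)
  big <- random_char_matrix(10, 3, 4)
  expect_error(exhaustive_search(big), "refused")
})

test_that("branch and bound equals exhaustive search on random matrices", {
  set.seed(29)
  for (i in 1:12) {
    m <- attach_ancestor(char_matrix(
      matrix(sample(0:5, 7 * 8, TRUE), 7, 8,
             dimnames = list(paste0("t", 1:7), paste0("c", 1:8))), 6,
      polarity = setNames(rep("low", 8), paste0("c", 1:8))))
    ex <- exhaustive_search(m, g1_samples = 0)
    bb <- branch_and_bound(m, g1_samples = 0)
    expect_equal(bb$length, ex$length)
    expect_lte(bb$trees_examined, ex$trees_examined)
  }
})

test_that("heuristic search is deterministic and near-exact at small sizes", {
  set.seed(43)
  m <- random_char_matrix(10, 12, 10)
  h1 <- heuristic_search(m, seed = 3, restarts = 3, g1_samples = 0)
  h2 <- heuristic_search(m, seed = 3, restarts = 3, g1_samples = 0)
  expect_identical(ape::write.tree(h1$trees[[1]]), ape::write.tree(h2$trees[[1]]))
  expect_equal(h1$length, h2$length)
  # upper bound property: heuristic never beats the proven optimum
  hits <- 0
  for (i in 1:20) {
    m <- attach_ancestor(char_matrix(
      matrix(sample(0:5, 7 * 10, TRUE), 7, 10,
             dimnames = list(paste0("t", 1:7), paste0("c", 1:10))), 6,
      polarity = setNames(rep("low", 10), paste0("c", 1:10))))
    ex <- exhaustive_search(m, g1_samples = 0)
    h <- heuristic_search(m, seed = i, restarts = 10, g1_samples = 0)
    expect_gte(h$length, ex$length)
    hits <- hits + (h$length == ex$length)
  }
  expect_gte(hits / 20, 0.9)
})

test_that("a single taxon plus ancestor yields the trivial rooted tree", {
  st <- matrix(c(5L, 3L), 1, 2, dimnames = list("t1", c("c1", "c2")))
  m <- attach_ancestor(char_matrix(st, 6,
                                   polarity = c(c1 = "low", c2 = "low")))
  h <- heuristic_search(m, seed = 1, restarts = 1, g1_samples = 0)
  expect_equal(h$length, 8)  # sum |taxon - ANC|
  expect_setequal(h$trees[[1]]$tip.label, c("t1", "ANC"))
})

test_that("fit statistics satisfy their identities", {
  set.seed(53)
  for (i in 1:10) {
    m <- random_char_matrix(sample(4:9, 1), sample(3:8, 1), sample(3:8, 1))
    tr <- ape::rtree(nrow(m$states), br = NULL)
    tr$tip.label <- sample(rownames(m$states))
    f <- fit_stats(tr, m, g1_samples = 200, seed = i)
    expect_lte(f$ci, 1)
    expect_gt(f$ci, 0)
    expect_equal(f$rc, f$ci * f$ri)                 # exact by construction
    expect_gte(f$length, f$steps_min)
    expect_lte(f$length, f$steps_max)
  }
})

test_that("g1 from sampling matches complete enumeration on 5 taxa", {
  # single binary character with a 2/3 split; all 105 rooted topologies
  st <- matrix(c(0L, 0L, 1L, 1L, 1L), 5, 1,
               dimnames = list(paste0("t", 1:5), "c1"))
  m <- char_matrix(st, 2)
  tr <- ape::rtree(5, br = NULL)
  tr$tip.label <- rownames(st)
  f <- fit_stats(tr, m)  # <= 7 taxa: enumeration path
  expect_equal(f$g1_method, "enumeration")
  skip_if_not_installed("phangorn")
  all_t <- phangorn::allTrees(5, rooted = TRUE, tip.label = rownames(st))
  lens <- vapply(all_t, function(t) wagner_length(t, m), numeric(1))
  expect_equal(f$g1_samples, length(all_t))
  expect_equal(f$g1, moment_skewness(lens), tolerance = 1e-12)
})

test_that("g1 is zero for an engineered symmetric length distribution", {
  # four taxa: the three unrooted topologies score 4, 5, 6 steps (two copies
  # of the AB|CD character plus one AC|BD character), five rootings each, so
  # the length distribution is exactly symmetric
  st <- cbind(c1 = c(0L, 0L, 1L, 1L), c2 = c(0L, 0L, 1L, 1L),
              c3 = c(0L, 1L, 0L, 1L))
  rownames(st) <- LETTERS[1:4]
  m <- char_matrix(st, 2)
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  f <- fit_stats(tr, m)
  expect_equal(f$g1_method, "enumeration")
  expect_equal(f$g1, 0, tolerance = 1e-12)
  # constant matrix: zero-variance length distribution -> undefined, not 0
  con <- char_matrix(matrix(1L, 5, 2, dimnames = list(paste0("t", 1:5),
                                                      c("c1", "c2"))), 3)
  tr5 <- ape::rtree(5, br = NULL); tr5$tip.label <- paste0("t", 1:5)
  expect_true(is.na(fit_stats(tr5, con)$g1))
})

test_that("node distances count internal nodes and exclude the ancestor", {
  cherry <- ape::read.tree(text = "(A,B);")
  nd <- node_distances(cherry)
  expect_equal(nd$nd, c(1L, 1L))
  expect_equal(nd$relative_age, c(0, 0))
  cat4 <- ape::read.tree(text = "(((A,B),C),D);")
  nd4 <- node_distances(cat4)
  expect_equal(nd4$nd[match(c("A", "B", "C", "D"), nd4$taxon)], c(3L, 3L, 2L, 1L))
  expect_equal(nd4$relative_age[match(c("C", "D"), nd4$taxon)], c(1/3, 2/3))
  withanc <- ape::read.tree(text = "(ANC,((A,B),C));")
  nda <- node_distances(withanc)
  expect_false("ANC" %in% nda$taxon)
  expect_equal(max(nda$nd), 3L)        # nd_max from non-ANC leaves only
  expect_error(node_distances(ape::unroot(ape::read.tree(text = "((A,B),(C,D));"))),
               "rooted")
})

test_that("search results expose tidy/glance and Newick output", {
  set.seed(71)
  m <- attach_ancestor(char_matrix(
    matrix(sample(0:3, 6 * 6, TRUE), 6, 6,
           dimnames = list(paste0("t", 1:6), paste0("c", 1:6))), 4,
    polarity = setNames(rep("low", 6), paste0("c", 1:6))))
  res <- branch_and_bound(m, g1_samples = 100)
  g <- glance(res)
  expect_equal(g$rc, g$ci * g$ri)
  td <- tidy(res)
  expect_true(all(c("taxon", "nd", "relative_age") %in% names(td)))
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_result_trees(res, tmp)
  trees <- ape::read.tree(tmp)
  expect_gte(length(trees), 1L)
})
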