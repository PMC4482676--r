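test_that("the framework tree nests genera, families and orders", {
  d <- madagascar_fruit_traits()
  tr <- tree_from_taxonomy(d)
  expect_s3_class(tr, "phylo")
  expect_length(tr$tip.label, 56)
  expect_true(ape::is.ultrametric(tr))
  # congeneric species are each other's closest relatives
  strych <- grep("^Strychnos", tr$tip.label, value = TRUE)
  expect_length(strych, 5)
  mrca <- ape::getMRCA(tr, strych)
  expect_setequal(ape::extract.clade(tr, mrca)$tip.label, strych)
  # newick serialization round-trips topology and branch lengths
  txt <- ape::write.tree(tr)
  back <- ape::read.tree(text = txt)
  expect_true(ape::all.equal.phylo(tr, back, use.edge.length = TRUE))
  dup <- d[c(1:5, 5), ]
  expect_error(tree_from_taxonomy(dup), "duplicate")
})

test_that("linear parsimony solves the textbook cases", {
  expect_equal(parsimony_steps_continuous(tree2(), c(a = 1, b = 4)), 3)
  expect_equal(parsimony_steps_continuous(star3(), c(a = 1, b = 2, c = 3)), 2)
  # star tree cost is the absolute deviation from the median
  st <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1);")
  x <- c(a = 0.3, b = 2.5, c = -1, d = 7, e = 2.5)
  expect_equal(parsimony_steps_continuous(st, x),
               sum(abs(x - median(x))))
  expect_error(parsimony_steps_continuous(tree2(), c(a = 1)), "missing")
})

test_that("linear parsimony equals brute-force minimization on random trees", {
  set.seed(55)
  for (i in 1:12) {
    n <- sample(4:7, 1)
    tr <- ape::rtree(n)
    x <- setNames(round(rnorm(n), 2), tr$tip.label)
    expect_equal(parsimony_steps_continuous(tr, x), brute_force_steps(tr, x),
                 tolerance = 1e-9)
    # polytomies: randomly collapse internal branches
    poly <- ape::di2multi(tr, tol = quantile(tr$edge.length, 0.4))
    expect_equal(parsimony_steps_continuous(poly, x),
                 brute_force_steps(poly, x), tolerance = 1e-9)
  }
})

test_that("consistency and retention indices hit their defining bounds", {
  # trait perfectly clustered by clade: no homoplasy
  res <- ci_ri(balanced4(), c(a = 0, b = 0, c = 1, d = 1))
  expect_equal(res$ci, 1)
  expect_equal(res$ri, 1)
  # star tree: observed steps equal the worst case, so RI = 0
  st <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  x <- c(a = 1, b = 2, c = 5, d = 9)
  res2 <- ci_ri(st, x)
  expect_equal(res2$steps, res2$max_steps)
  expect_equal(res2$ri, 0)
  expect_lte(res2$ci, 1)
  expect_error(ci_ri(st, c(a = 1, b = 1, c = 1, d = 1)), "constant")
  # random data: CI in (0, 1], RI in [0, 1], CI = 1 iff steps = range
  set.seed(66)
  for (i in 1:8) {
    tr <- ape::rtree(10)
    y <- setNames(rnorm(10), tr$tip.label)
    r <- ci_ri(tr, y)
    expect_gt(r$ci, 0); expect_lte(r$ci, 1)
    expect_gte(r$ri, 0); expect_lte(r$ri, 1)
    expect_equal(r$ci == 1, abs(r$steps - r$min_steps) < 1e-12)
  }
})

test_that("Blomberg's K matches a direct matrix-formula computation", {
  set.seed(71)
  tr <- ape::rphylo(18, 1, 0)
  x <- simulate_trait_on_tree(tr, "brownian", seed = 72)
  k <- blomberg_k(tr, x, n_perm = 10, seed = 73)
  expect_equal(k$k, direct_blomberg_k(tr, x), tolerance = 1e-6)
  # affine invariance of K and lambda
  y <- 3 + 2 * x
  expect_equal(blomberg_k(tr, y, n_perm = 10, seed = 73)$k, k$k,
               tolerance = 1e-6)
  l1 <- pagel_lambda(tr, x); l2 <- pagel_lambda(tr, y)
  expect_equal(l1$lambda, l2$lambda, tolerance = 1e-4)
  expect_error(blomberg_k(star3(), c(a = 1, b = 2, c = 3)), "3 tips")
})

test_that("lambda is bounded with a nonnegative likelihood ratio", {
  set.seed(81)
  tr <- ape::rphylo(30, 1, 0)
  for (model in c("brownian", "white_noise")) {
    x <- simulate_trait_on_tree(tr, model, seed = 82)
    l <- pagel_lambda(tr, x)
    expect_gte(l$lambda, 0); expect_lte(l$lambda, 1)
    expect_gte(l$logL, l$logL0 - 1e-8)
    expect_gte(l$p, 0); expect_lte(l$p, 1)
  }
})

test_that("K and lambda separate Brownian from clade-free traits", {
  set.seed(91)
  tr <- ape::rphylo(40, 1, 0)
  k_bm <- numeric(25); k_wn <- numeric(25)
  l_bm <- numeric(25); l_wn <- numeric(25)
  for (i in 1:25) {
    xb <- simulate_trait_on_tree(tr, "brownian")
    xw <- simulate_trait_on_tree(tr, "white_noise")
    k_bm[i] <- blomberg_k(tr, xb, n_perm = 1)$k
    k_wn[i] <- blomberg_k(tr, xw, n_perm = 1)$k
    l_bm[i] <- pagel_lambda(tr, xb)$lambda
    l_wn[i] <- pagel_lambda(tr, xw)$lambda
  }
  expect_gt(mean(k_bm), 2 * mean(k_wn))
  expect_gt(median(l_bm), 0.7)
  expect_lt(median(l_wn), 0.3)
})

test_that("the signal table covers every trait with valid statistics", {
  d <- madagascar_fruit_traits()
  tab <- phylo_signal_table(d, n_perm = 99, seed = 14)
  expect_equal(tab$trait, c("voc", "uv", "blue", "green", "red"))
  expect_true(all(tab$ci > 0 & tab$ci <= 1))
  expect_true(all(tab$ri >= 0 & tab$ri <= 1))
  expect_true(all(tab$k >= 0))
  expect_true(all(tab$lambda >= 0 & tab$lambda <= 1))
  expect_true(all(tab$k_p >= 0 & tab$k_p <= 1))
  expect_true(all(tab$lambda_p >= 0 & tab$lambda_p <= 1))
})
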