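test_that("Tocher recovers two planted pairs", {
  d <- as_dmat(matrix(100, 4, 4))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 1
  d["C", "D"] <- d["D", "C"] <- 1
  tg <- tocher(d)
  expect_equal(length(tg$groups), 2)
  expect_setequal(tg$groups[[1]], c("A", "B"))
  expect_setequal(tg$groups[[2]], c("C", "D"))
  expect_equal(tg$intra_mean, c(1, 1))
})

test_that("Tocher puts everything together when all distances are equal", {
  d <- as_dmat(matrix(3, 5, 5))
  diag(d) <- 0
  tg <- tocher(d)
  expect_equal(length(tg$groups), 1)
  expect_setequal(tg$groups[[1]], LETTERS[1:5])
})

test_that("Tocher hand-traced 4-point example", {
  d <- as_dmat(matrix(50, 4, 4))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 1
  d["C", "D"] <- d["D", "C"] <- 2
  tg <- tocher(d)
  # theta = 2 (C and D's nearest neighbour); AB seeds first, CD next
  expect_equal(tg$theta, 2)
  expect_equal(tg$groups, list(c("A", "B"), c("C", "D")))
})

test_that("Tocher always returns a partition", {
  set.seed(20)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    m <- matrix(runif(n * n, 1, 10), n, n)
    d <- as_dmat((m + t(m)) / 2, paste0("g", 1:n))
    diag(d) <- 0
    tg <- tocher(d)
    expect_setequal(unlist(tg$groups), rownames(d))
    expect_equal(length(unlist(tg$groups)), n)
  }
})

test_that("UPGMA merges the worked 3-leaf example correctly", {
  d <- as_dmat(matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3))
  tree <- upgma(d)
  expect_equal(tree$height, c(2, 8))
  expect_equal(length(tree$height), 2)  # n - 1 merges
})

test_that("UPGMA heights are monotone and reproduce ultrametric inputs", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    m <- matrix(runif(n * n, 1, 10), n, n)
    d <- as_dmat((m + t(m)) / 2, paste0("g", 1:n))
    diag(d) <- 0
    tree <- upgma(d)
    expect_true(all(diff(tree$height) >= -1e-12))
    # cophenetic distances of the tree are ultrametric; UPGMA on them is exact
    u <- cophenetic_matrix(tree)
    tree2 <- upgma(u)
    expect_equal(cophenetic_matrix(tree2)[rownames(u), colnames(u)], u,
                 tolerance = 1e-12)
  }
})

test_that("Mojena cutoff follows mean + c * sd of fusion heights", {
  # chain ultrametric with fusion heights exactly 1, 2, 3, 10
  d <- as_dmat(matrix(0, 5, 5))
  d["A", "B"] <- 1
  d[c("A", "B"), "C"] <- 2
  d[c("A", "B", "C"), "D"] <- 3
  d[c("A", "B", "C", "D"), "E"] <- 10
  d <- pmax(d, t(d))
  tree <- upgma(d)
  expect_equal(tree$height, c(1, 2, 3, 10))
  cut <- mojena_cut(tree, c = 1.25)
  expect_equal(cut$cutoff, 4 + 1.25 * sd(c(1, 2, 3, 10)))
  expect_equal(cut$n_groups, 2)

  # equal heights: sd = 0, cutoff = h, single group
  de <- as_dmat(matrix(4, 4, 4))
  diag(de) <- 0
  ce <- mojena_cut(upgma(de), c = 1.25)
  expect_equal(ce$cutoff, 4)
  expect_equal(ce$n_groups, 1)

  # limits in c
  expect_equal(mojena_cut(tree, c = 1e6)$n_groups, 1)
  expect_equal(mojena_cut(tree, c = -1e6)$n_groups, 5)
})

test_that("Mojena group count is monotone non-increasing in c", {
  set.seed(22)
  m <- matrix(runif(64, 1, 10), 8, 8)
  d <- as_dmat((m + t(m)) / 2)
  diag(d) <- 0
  tree <- upgma(d)
  ns <- vapply(seq(-3, 3, by = 0.25),
               function(cc) mojena_cut(tree, c = cc)$n_groups, numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("Newick export round-trips through ape", {
  set.seed(23)
  m <- matrix(runif(36, 1, 5), 6, 6)
  d <- as_dmat((m + t(m)) / 2, paste0("g", 1:6))
  diag(d) <- 0
  tree <- upgma(d)
  nwk <- as_newick(tree)
  phy <- ape::read.tree(text = nwk)
  expect_equal(sort(phy$tip.label), paste0("g", 1:6))
  f <- tempfile(fileext = ".newick")
  as_newick(tree, f)
  expect_true(file.exists(f))
  expect_equal(sort(ape::read.tree(f)$tip.label), paste0("g", 1:6))
})
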