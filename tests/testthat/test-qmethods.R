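test_that("RF distance matches brute-force bipartition enumeration", {
  ## independent oracle: enumerate internal bipartitions directly
  bipartitions <- function(tree) {
    tree <- ape::unroot(tree)
    n <- length(tree$tip.label)
    out <- character(0)
    for (node in setdiff(unique(tree$edge[, 1]), n + 1L)) {
      tips <- ape::extract.clade(tree, node)$tip.label
      side <- sort(tips)
      other <- sort(setdiff(tree$tip.label, tips))
      key <- paste(paste(side, collapse = ","), paste(other, collapse = ","))
      if (length(side) > 1 && length(other) > 1)
        out <- c(out, paste(sort(c(paste(side, collapse = ","),
                                   paste(other, collapse = ","))),
                            collapse = "|"))
    }
    unique(out)
  }
  rf_brute <- function(t1, t2) {
    b1 <- bipartitions(t1); b2 <- bipartitions(t2)
    length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  }

  set.seed(201)
  t1 <- random_binary_tree(12)
  expect_equal(rf_distance(t1, t1), 0L)

  ## caterpillar vs balanced on 8 leaves, and random pairs
  cat8 <- ape::read.tree(text = "(t1,(t2,(t3,(t4,(t5,(t6,(t7,t8)))))));")
  bal8 <- ape::read.tree(text = "(((t1,t2),(t3,t4)),((t5,t6),(t7,t8)));")
  expect_equal(rf_distance(cat8, bal8), rf_brute(cat8, bal8))
  for (k in 1:5) {
    a <- random_binary_tree(sample(6:10, 1))
    b <- random_binary_tree(a$tip.label)
    expect_equal(rf_distance(a, b), rf_brute(a, b))
  }
  expect_error(rf_distance(cat8, random_binary_tree(7)), "leaf sets")
})

test_that("RF distance of an NNI neighbor is 2 and RF is a metric", {
  set.seed(211)
  t1 <- ape::read.tree(text = "(((t1,t2),(t3,t4)),((t5,t6),(t7,(t8,t9))));")
  ## NNI across the edge above (t7,(t8,t9)): swap t7 with the (t5,t6) cherry
  t2 <- ape::read.tree(text = "(((t1,t2),(t3,t4)),(t7,((t5,t6),(t8,t9))));")
  expect_equal(rf_distance(t1, t2), 2L)

  for (k in 1:5) {
    a <- random_binary_tree(8); b <- random_binary_tree(a$tip.label)
    cc <- random_binary_tree(a$tip.label)
    expect_equal(rf_distance(a, b), rf_distance(b, a))
    expect_gte(rf_distance(a, b) + rf_distance(b, cc), rf_distance(a, cc))
  }
})

test_that("majority-rule consensus keeps exactly the >50% splits", {
  set.seed(221)
  t1 <- random_binary_tree(8)
  expect_equal(rf_distance(mrct(rep(list(t1), 7)), t1), 0L)

  ## 50/50 conflict on one split: consensus drops it
  a <- ape::read.tree(text = "(((t1,t2),(t3,t4)),((t5,t6),(t7,t8)));")
  b <- ape::read.tree(text = "(((t1,t3),(t2,t4)),((t5,t6),(t7,t8)));")
  cons <- mrct(c(rep(list(a), 5), rep(list(b), 5)))
  na <- ape::unroot(a)$Nnode - 1L
  expect_equal(ape::unroot(cons)$Nnode - 1L, na - 2L)

  ## invariant to replicate order
  trees <- c(rep(list(a), 6), rep(list(b), 4))
  c1 <- mrct(trees); c2 <- mrct(rev(trees))
  expect_equal(rf_distance(c1, c2), 0L)
  expect_equal(rf_distance(c1, a), 0L)
})

test_that("builders recover the reference tree from correctly weighted tables", {
  set.seed(231)
  for (k in 1:4) {
    tr <- random_binary_tree(sample(8:12, 1))
    tab <- table_from_tree(tr)
    expect_equal(rf_distance(build_tree(tab, "wo", seed = k), tr), 0L)
    expect_equal(rf_distance(build_tree(tab, "qp", seed = k), tr), 0L)
    expect_equal(rf_distance(build_tree(tab, "wil", seed = k), tr), 0L)
  }
})

test_that("n = 4 builds return the max-weight quartet", {
  taxa <- paste0("t", 1:4)
  W <- matrix(c(0.2, 0.7, 0.1), 1, 3)
  tab <- asaq:::new_weight_table(taxa, matrix(1:4, 4), W, "manual", "x")
  tr <- build_tree(tab, "wo", seed = 1)
  ## split 13|24: t1 pairs with t3
  expect_equal(rf_distance(tr, ape::read.tree(text = "((t1,t3),(t2,t4));")), 0L)
})

test_that("missing quartets raise a missing-weight error", {
  set.seed(241)
  tr <- random_binary_tree(7)
  tab <- table_from_tree(tr)
  expect_error(build_tree(tab[-3, ], "wo", seed = 1), "missing weight")
})

test_that("consensus of replicate builds on correct weights is the reference tree", {
  set.seed(251)
  tr <- random_binary_tree(9)
  tab <- table_from_tree(tr)
  cons <- run_and_consense(tab, "wo", n_replicates = 15, seed = 5)
  expect_equal(rf_distance(cons, tr), 0L)
  cons1 <- run_and_consense(tab, "qp", n_replicates = 1, seed = 5)
  expect_equal(rf_distance(cons1, tr), 0L)
})

test_that("builds are equivariant under consistent relabelling of taxa and table", {
  set.seed(261)
  tr <- random_binary_tree(8)
  tab <- table_from_tree(tr)
  ## relabel taxa with a fixed bijection; the 0/1 table of the relabelled
  ## tree equals the relabelled table, so builds agree up to names
  tr2 <- tr
  map <- stats::setNames(paste0("x", sample(8)), tr$tip.label)
  tr2$tip.label <- unname(map[tr$tip.label])
  tab2 <- table_from_tree(tr2)
  out2 <- build_tree(tab2, "wo", seed = 3)
  expect_equal(rf_distance(out2, tr2), 0L)
})

test_that("WIL tolerates a single corrupted quartet on six taxa", {
  set.seed(271)
  tr <- random_binary_tree(6)
  tab <- table_from_tree(tr)
  flip <- 4L
  w <- as.numeric(tab[flip, c("w1", "w2", "w3")])
  tab[flip, c("w1", "w2", "w3")] <- w[c(2, 3, 1)]
  ok <- vapply(1:10, function(s)
    rf_distance(build_tree(tab, "wil", seed = s), tr) == 0, logical(1))
  expect_true(all(ok))
})

test_that("binarization takes the argmax with canonical tie-breaks and is idempotent", {
  taxa <- paste0("t", 1:5)
  Q <- utils::combn(5, 4)
  W <- rbind(c(0.5, 0.3, 0.2), c(1 / 3, 1 / 3, 1 / 3),
             c(0.1, 0.1, 0.8), c(0.2, 0.4, 0.4), c(0, 1, 0))
  tab <- asaq:::new_weight_table(taxa, Q, W, "manual", rep("x", 5))
  b <- binarize_weights(tab)
  expect_equal(b$w1, c(1, 1, 0, 0, 0))
  expect_equal(b$w2, c(0, 0, 0, 1, 1))
  expect_equal(b$w3, c(0, 0, 1, 0, 0))
  expect_identical(as.data.frame(binarize_weights(b)), as.data.frame(b))
})
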