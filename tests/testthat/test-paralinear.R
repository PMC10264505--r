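jc_matrix <- function(t) {
  e <- exp(-4 * t / 3)
  matrix((1 - e) / 4, 4, 4) + diag(rep(e, 4))
}

test_that("paralinear distance has the Jukes-Cantor closed form and flags degeneracy", {
  expect_equal(paralinear_distance(0.25 * diag(4)), 0)
  for (t in c(0.1, 0.5, 1.0))
    expect_equal(paralinear_distance(jc_matrix(t) / 4), t, tolerance = 1e-12)
  expect_true(is.na(paralinear_distance(matrix(1 / 16, 4, 4))))
  expect_error(paralinear_distance(matrix(1, 4, 4)), "distribution")
})

test_that("paralinear distances are exactly additive on GM quartets", {
  set.seed(21)
  for (k in 1:5) {
    pen <- runif(4, 0.05, 0.8); int <- runif(1, 0.05, 0.4)
    inst <- gm_quartet(pen, int, "12|34")
    p <- exact_pattern_dist(inst)
    d <- paralinear_matrix(p)
    ## leaves 1,2 are sisters; cross pairs pass the interior edge
    expect_equal(d[1, 2], pen[1] + pen[2], tolerance = 1e-8)
    expect_equal(d[3, 4], pen[3] + pen[4], tolerance = 1e-8)
    expect_equal(d[1, 3], pen[1] + int + pen[3], tolerance = 1e-8)
    expect_equal(d[2, 4], pen[2] + int + pen[4], tolerance = 1e-8)
  }
})

test_that("degenerate distributions give undefined or zero distances", {
  conc <- numeric(256); conc[1] <- 1
  d <- paralinear_matrix(asaq:::new_pattern_dist(conc))
  expect_true(all(is.na(d[upper.tri(d)])))
  expect_false(any(attr(d, "defined")[upper.tri(d)]))

  ## identical sequences with uniform composition: J = I/4 for every pair
  a <- aln_from_strings(rep("ACGTACGT", 4))
  p <- count_patterns(a, paste0("t", 1:4))
  d2 <- paralinear_matrix(p)
  expect_equal(max(abs(d2), na.rm = TRUE), 0)
})

test_that("pl statistic matches the additive-metric arithmetic", {
  ## quartet 12|34, pendants 0.1, interior 0.05
  d <- matrix(0, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.2; d[3, 4] <- d[4, 3] <- 0.2
  for (pr in list(c(1, 3), c(1, 4), c(2, 3), c(2, 4)))
    d[pr[1], pr[2]] <- d[pr[2], pr[1]] <- 0.25
  expect_equal(unname(pl_triple(d)), c(0.1, -0.1, -0.1))

  ## all distances equal (star tree): all three values zero
  ds <- matrix(0.3, 4, 4); diag(ds) <- 0
  expect_equal(unname(pl_triple(ds)), c(0, 0, 0))
})

test_that("pl statistic equals twice the interior edge length on exact data and both four-point sums agree", {
  set.seed(31)
  for (sp in QUARTET_SPLITS) {
    inst <- random_quartet_instance(sp)
    p <- exact_pattern_dist(inst)
    d <- paralinear_matrix(p)
    v <- pl_triple(d)
    int_len <- inst$tree$edge.length[
      inst$tree$edge[, 2] > length(inst$tree$tip.label)]
    expect_equal(names(which.max(v)), sp)
    expect_equal(unname(v[sp]), 2 * int_len, tolerance = 1e-8)
    ## both quantities inside the min of the statistic coincide
    s <- c(d[1, 2] + d[3, 4], d[1, 3] + d[2, 4], d[1, 4] + d[2, 3])
    expect_equal(sort(s)[2], sort(s)[3], tolerance = 1e-8)
  }
})

test_that("PL weights are softmax of the statistic and pick the generating split", {
  ds <- matrix(0.3, 4, 4); diag(ds) <- 0
  p_star <- structure(ds, class = c("paralinear_matrix", "matrix"))
  ## equal statistics -> uniform weights
  w0 <- asaq:::softmax(pl_triple(p_star))
  expect_equal(unname(w0), rep(1 / 3, 3))
  ## frozen softmax arithmetic for the (0.1, -0.1, -0.1) triple
  w1 <- asaq:::softmax(c(0.1, -0.1, -0.1))
  e <- exp(c(0.1, -0.1, -0.1))
  expect_equal(unname(w1), e / sum(e), tolerance = 1e-12)
  expect_equal(unname(w1), c(0.3792, 0.3104, 0.3104), tolerance = 1e-4)

  set.seed(41)
  inst <- random_quartet_instance("12|34")
  p <- exact_pattern_dist(inst)
  w <- pl_weights(p)
  expect_weight_triple(w)
  expect_equal(w$topology, "12|34")
  expect_error(pl_weights(asaq:::new_pattern_dist(c(1, rep(0, 255)))),
               "undefined")
})

test_that("four-point weights are normalized, symmetric under star data, and agree with PL on exact quartets", {
  set.seed(51)
  for (sp in QUARTET_SPLITS) {
    inst <- random_quartet_instance(sp)
    p <- exact_pattern_dist(inst)
    w <- fourpoint_weights(p)
    expect_weight_triple(w)
    expect_equal(w$topology, sp)
    expect_equal(w$topology, pl_weights(p)$topology)
  }
  ## perfectly symmetric star-like distribution
  pu <- asaq:::new_pattern_dist(rep(1 / 256, 256))
  pu$values <- 0.9 * pu$values
  pu$values[c(1, 86, 171, 256)] <- pu$values[c(1, 86, 171, 256)] + 0.1 / 4
  w <- fourpoint_weights(pu)
  expect_equal(unname(w$weights), rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("PL and 4P argmax agree on most simulated quartets with a clear interior edge", {
  set.seed(61)
  n <- 60
  agree <- logical(n)
  for (i in seq_len(n)) {
    inst <- gm_quartet(runif(4, 0.05, 0.6), runif(1, 0.05, 0.3), "12|34")
    p <- count_patterns(simulate_alignment(inst, 10000), paste0("t", 1:4))
    d <- paralinear_matrix(p)
    if (anyNA(d)) { agree[i] <- NA; next }
    agree[i] <- identical(pl_weights(p)$topology, fourpoint_weights(p)$topology)
  }
  expect_gt(mean(agree, na.rm = TRUE), 0.95)
})

test_that("alignment-level paralinear matrix feeds NJ to exact recovery on additive data", {
  set.seed(71)
  nwk <- "((a:0.1,b:0.15):0.08,(c:0.12,d:0.2):0.05,e:0.3);"
  inst <- gm_instance(nwk)
  aln <- simulate_alignment(inst, 20000)
  nj <- nj_paralinear(aln)
  expect_equal(rf_distance(nj, ape::read.tree(text = nwk)), 0)

  D <- paralinear_dist_matrix(aln)
  expect_true(isSymmetric(unname(D)))
  path <- tempfile(fileext = ".dist")
  write_phylip_dist(D, path)
  expect_equal(as.integer(trimws(readLines(path)[1])), 5L)
})
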