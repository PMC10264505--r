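## ---- simulation experiments on quartets and 12-taxon trees ---------------

#' Quartet model for the two-parameter tree space
#'
#' The Huelsenbeck-style quartet on split `12|34`: the pendant edges of the
#' two non-sister leaves 1 and 3 have length `a`, while the pendants of
#' leaves 2 and 4 and the interior edge have length `b` (substitutions per
#' site).  Large `a` with small `b` puts the tree in the Felsenstein zone
#' (two long non-sister branches, short interior).
#'
#' @param a,b branch lengths.
#' @param model `"gm"` (random transition matrices) or `"gtr"`.
#' @param gtr a `gtr_model` used when `model = "gtr"`.
#' @return a `gm_instance` generating on split `12|34`.
#' @export
huelsenbeck_quartet <- function(a, b, model = c("gm", "gtr"),
                                gtr = gtr_model()) {
  model <- match.arg(model)
  if (model == "gm")
    gm_quartet(c(a, b, a, b), b, split = "12|34")
  else
    gtr_instance(gm_tree_newick(c(a, b, a, b), b), model = gtr)
}

gm_tree_newick <- function(lengths, interior) {
  sprintf("((t3:%.10f,t4:%.10f):%.10f,t1:%.10f,t2:%.10f);",
          lengths[3], lengths[4], interior, lengths[1], lengths[2])
}

#' Tree-space success grid
#'
#' Evaluates a quartet weighting method over the `(a, b)` tree-space grid:
#' `reps` alignments per grid point, success = inferred topology equals the
#' generating split `12|34`.
#'
#' @param step,max grid step and maximum (the grid starts at `step`, since a
#'   zero-length edge is degenerate).
#' @param reps alignments per grid point.
#' @param n_sites alignment length.
#' @param method weighting method.
#' @param m mixture categories for rank-based scores.
#' @param model `"gm"` or `"gtr"`.
#' @param seed RNG seed.
#' @return data frame with columns `a`, `b`, `success` (fraction), `se`.
#' @export
huelsenbeck_grid <- function(step = 0.02, max = 1.5, reps = 100L,
                             n_sites = 1000L,
                             method = "asaq", m = 1L,
                             model = c("gm", "gtr"), seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  vals <- seq(step, max, by = step)
  grid <- expand.grid(a = vals, b = vals)
  grid$success <- NA_real_
  for (g in seq_len(nrow(grid))) {
    grid$success[g] <- mean(vapply(seq_len(reps), function(r) {
      inst <- huelsenbeck_quartet(grid$a[g], grid$b[g], model)
      aln <- simulate_alignment(inst, n_sites)
      p <- count_patterns(aln, c("t1", "t2", "t3", "t4"))
      quartet_weights_one(p, method, m)$topology == "12|34"
    }, logical(1)))
  }
  grid$se <- sqrt(grid$success * (1 - grid$success) / reps)
  grid
}

#' Random-branch-length quartet experiment
#'
#' Simulates alignments on split `12|34` with all five branch lengths drawn
#' i.i.d. uniform on an interval, applies a weighting method and records the
#' topology success and the weight triples (for ternary plotting).
#'
#' @param interval length-2 numeric, e.g. `c(0, 1)` or `c(0, 3)`.
#' @param n_align number of alignments.
#' @param n_sites alignment length.
#' @param method,m weighting method and mixture categories.
#' @param model `"gm"` or `"gtr"`.
#' @param seed RNG seed.
#' @return list with `success` (fraction correct), `se`, `weights`
#'   (n_align x 3 matrix), `tags` (ASAQ provenance), `n`.
#' @export
random_quartet_experiment <- function(interval = c(0, 1), n_align = 10000L,
                                      n_sites = 1000L, method = "asaq",
                                      m = 1L, model = c("gm", "gtr"),
                                      seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  gtr <- gtr_model()
  W <- matrix(NA_real_, n_align, 3L)
  ok <- logical(n_align)
  tags <- character(n_align)
  for (i in seq_len(n_align)) {
    len <- stats::runif(5L, interval[1], interval[2])
    inst <- if (model == "gm")
      gm_quartet(len[1:4], len[5], split = "12|34")
    else
      gtr_instance(gm_tree_newick(len[1:4], len[5]), model = gtr)
    aln <- simulate_alignment(inst, n_sites)
    p <- count_patterns(aln, c("t1", "t2", "t3", "t4"))
    w <- quartet_weights_one(p, method, m)
    W[i, ] <- w$weights
    ok[i] <- w$topology == "12|34"
    tags[i] <- w$tag
  }
  succ <- mean(ok)
  list(success = succ, se = sqrt(succ * (1 - succ) / n_align),
       weights = W, tags = tags, n = n_align)
}

#' Two-category quartet mixture experiment
#'
#' The across-site mixture benchmark: each alignment is the concatenation of
#' two equal-size halves simulated under independent GM parameter draws on
#' the *same* quartet topology `12|34`.  Category 1 has pendant lengths
#' `a = 0.05` for leaves 1, 3 and `b = 0.75` for leaves 2, 4; category 2
#' swaps them (`a = 0.75`, `b = 0.05`).  Both categories share the interior
#' length `r`, which steps through `r_values`.
#'
#' @param r_values interior branch lengths (default 0.01 to 0.4 in steps of
#'   0.05, i.e. 0.01, 0.06, ..., 0.36).
#' @param n_sites total alignment length (split equally between categories).
#' @param reps alignments per `r` value.
#' @param method,m weighting method (default ASAQ with `m = 2`).
#' @param seed RNG seed.
#' @return data frame (one row per `r`) with `r`, `success`, `se`, plus the
#'   overall average as attribute `average`.
#' @export
quartet_mixture_experiment <- function(r_values = seq(0.01, 0.36, by = 0.05),
                                       n_sites = 1000L, reps = 100L,
                                       method = "asaq", m = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  half <- n_sites %/% 2L
  res <- data.frame(r = r_values, success = NA_real_, se = NA_real_)
  for (ri in seq_along(r_values)) {
    r <- r_values[ri]
    ok <- vapply(seq_len(reps), function(k) {
      i1 <- gm_quartet(c(0.05, 0.75, 0.05, 0.75), r, split = "12|34")
      i2 <- gm_quartet(c(0.75, 0.05, 0.75, 0.05), r, split = "12|34")
      a1 <- simulate_alignment(i1, half)
      a2 <- simulate_alignment(i2, n_sites - half)
      codes <- cbind(a1$seq, a2$seq)
      aln <- alignment_from_codes(codes, a1$taxa)
      p <- count_patterns(aln, c("t1", "t2", "t3", "t4"))
      quartet_weights_one(p, method, m)$topology == "12|34"
    }, logical(1))
    res$success[ri] <- mean(ok)
    res$se[ri] <- sqrt(mean(ok) * (1 - mean(ok)) / reps)
  }
  attr(res, "average") <- mean(res$success)
  res
}

#' Exact two-category mixture distribution on a quartet
#'
#' The infinite-length limit of the mixture experiment: an equal-proportion
#' mixture of the exact pattern distributions of two independent GM draws on
#' the same split.
#'
#' @inheritParams quartet_mixture_experiment
#' @param r shared interior branch length.
#' @param split generating split.
#' @return a `pattern_dist`.
#' @export
exact_mixture_dist <- function(r, split = "12|34") {
  i1 <- gm_quartet(c(0.05, 0.75, 0.05, 0.75), r, split = split)
  i2 <- gm_quartet(c(0.75, 0.05, 0.75, 0.05), r, split = split)
  p1 <- exact_pattern_dist(i1)
  p2 <- exact_pattern_dist(i2)
  new_pattern_dist(0.5 * p1$values + 0.5 * p2$values, taxa = p1$taxa,
                   n_sites = Inf)
}

## ---- 12-taxon benchmark trees --------------------------------------------

## Branch-length multipliers (x b) of the two glued 6-leaf subtrees.  All
## internal edges have length b.  The D subtree carries the long-branch
## attraction quartet: its cherry leaf `x2` and the deep leaf `x5` have long
## pendants (9b and 8b), which puts {x2, x3, x4, x5} (= seq8, seq9, seq10,
## seq11 in CD/DD) in the Felsenstein zone, and makes the quoted path
## lengths hold: d(x3, x4) = 4b and d(x2, x5) = 20b.  The C subtree is
## balanced with one long pendant on x3 (9b), the leaf whose length the
## 2-category mixture design swaps with its cherry partner x4.
.subtree_C <- function(lab, b) {
  s <- lab
  sprintf("(((%s:%s,%s:%s):%s,(%s:%s,%s:%s):%s):%s,(%s:%s,%s:%s):%s):%s",
          s[1], fb(1.5, b), s[2], fb(1.5, b), fb(1, b),
          s[3], fb(9, b), s[4], fb(1.5, b), fb(1, b), fb(1, b),
          s[5], fb(1.5, b), s[6], fb(1.5, b), fb(1, b), fb(1, b))
}

.subtree_D <- function(lab, b) {
  s <- lab
  sprintf("(((((%s:%s,%s:%s):%s,%s:%s):%s,%s:%s):%s,%s:%s):%s,%s:%s):%s",
          s[1], fb(1.5, b), s[2], fb(9, b), fb(1, b),
          s[3], fb(1.5, b), fb(1, b),
          s[4], fb(1.5, b), fb(1, b),
          s[5], fb(8, b), fb(1, b),
          s[6], fb(1.5, b), fb(1, b))
}

fb <- function(mult, b) sprintf("%.10f", mult * b)

#' 12-taxon benchmark trees
#'
#' The three 12-taxon topologies obtained by gluing two 6-leaf subtrees
#' (a balanced one, C, and a caterpillar-like one, D) at the root:
#' `CC`, `CD` and `DD`.  All internal branches have length `b`; pendant
#' lengths are fixed multiples of `b` chosen so that in CD/DD the path
#' length seq9--seq10 is `4b` and seq8--seq11 is `20b`, creating a
#' long-branch-attraction quartet \{seq8, seq9, seq10, seq11\}.
#'
#' @param kind `"CC"`, `"CD"` or `"DD"`.
#' @param b internal branch length (substitutions/site).
#' @param swap_mixture if `TRUE`, return the second mixture system: the
#'   pendant lengths of seq3/seq4 and of seq7/seq8 are exchanged.
#' @return a rooted `phylo` with branch lengths, leaves `seq1..seq12`.
#' @export
twelve_taxon_trees <- function(kind = c("CC", "CD", "DD"), b,
                               swap_mixture = FALSE) {
  kind <- match.arg(kind)
  stopifnot(b > 0)
  first <- paste0("seq", 1:6); second <- paste0("seq", 7:12)
  sub <- function(which, lab) {
    if (which == "C") .subtree_C(lab, b) else .subtree_D(lab, b)
  }
  nwk <- sprintf("(%s,%s);", sub(substr(kind, 1, 1), first),
                 sub(substr(kind, 2, 2), second))
  tr <- ape::read.tree(text = nwk)
  if (swap_mixture) {
    for (pr in list(c("seq3", "seq4"), c("seq7", "seq8"))) {
      i <- match(pr, tr$tip.label)
      ei <- match(i, tr$edge[, 2])
      tr$edge.length[ei] <- tr$edge.length[rev(ei)]
    }
  }
  tr
}

#' 12-taxon reconstruction experiment
#'
#' Simulates alignments on a benchmark tree, computes a quartet weight table
#' and builds consensus trees with an amalgamation heuristic; reports the
#' Robinson-Foulds distance to the generating topology.
#'
#' @param tree generating `phylo` with branch lengths (e.g. from
#'   [twelve_taxon_trees()]); for mixtures, a list of `(tree, proportion)`
#'   pairs sharing one topology.
#' @param n_sites alignment length.
#' @param reps number of simulated alignments.
#' @param weighting,m weighting system for the quartet table.
#' @param qmethod amalgamation heuristic.
#' @param build_replicates replicate builds per alignment entering the
#'   majority-rule consensus.
#' @param model `"gm"` or `"gtr"`.
#' @param seed RNG seed.
#' @return data frame with one row per replicate: `rep`, `rf`,
#'   `rf_normalized`.
#' @export
twelve_taxon_experiment <- function(tree, n_sites = 600L, reps = 10L,
                                    weighting = "asaq", m = 1L,
                                    qmethod = "wo", build_replicates = 100L,
                                    model = c("gm", "gtr"), seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  systems <- if (inherits(tree, "phylo")) list(list(tree = tree, prop = 1))
             else tree
  ref <- systems[[1]]$tree
  gtr <- gtr_model()
  rf <- numeric(reps); rfn <- numeric(reps)
  for (k in seq_len(reps)) {
    parts <- lapply(systems, function(sy) {
      ns <- round(sy$prop * n_sites)
      inst <- if (model == "gm") gm_instance(sy$tree) else gtr_instance(sy$tree, gtr)
      simulate_alignment(inst, ns)$seq
    })
    codes <- do.call(cbind, parts)
    aln <- alignment_from_codes(codes, ref$tip.label)
    tab <- quartet_weights(aln, weighting, m = m)
    cons <- run_and_consense(tab, qmethod, n_replicates = build_replicates)
    rf[k] <- rf_distance(cons, ref)
    rfn[k] <- rf_distance(cons, ref, normalized = TRUE)
  }
  data.frame(rep = seq_len(reps), rf = rf, rf_normalized = rfn)
}

#' CD-tree mixture experiment
#'
#' The 2-category mixture on the CD topology: a proportion `p` of sites
#' evolves under the CD branch lengths and the rest under the system with
#' the seq3/seq4 and seq7/seq8 pendant lengths exchanged.  Reports average
#' RF distance of the reconstructed consensus trees to the CD topology.
#'
#' @param p proportion of sites in the first category (0.25, 0.5 or 0.75 in
#'   the benchmark design; `p = 1` reduces to the unmixed experiment).
#' @param b internal branch length.
#' @inheritParams twelve_taxon_experiment
#' @return as [twelve_taxon_experiment()].
#' @export
cd_mixture_experiment <- function(p = 0.5, b = 0.05, n_sites = 600L,
                                  reps = 10L, weighting = "asaq", m = 2L,
                                  qmethod = "wo", build_replicates = 100L,
                                  seed = NULL) {
  t1 <- twelve_taxon_trees("CD", b)
  systems <- if (p >= 1) t1 else
    list(list(tree = t1, prop = p),
         list(tree = twelve_taxon_trees("CD", b, swap_mixture = TRUE),
              prop = 1 - p))
  twelve_taxon_experiment(systems, n_sites = n_sites, reps = reps,
                          weighting = weighting, m = m, qmethod = qmethod,
                          build_replicates = build_replicates, seed = seed)
}
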