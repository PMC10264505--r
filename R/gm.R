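## ---- General Markov model simulation -------------------------------------
##
## Branch lengths are measured throughout in expected substitutions per site.
## A 4x4 row-stochastic transition matrix M is calibrated either through its
## determinant (det M = exp(-4 l)) or, when the distribution at the parent
## node is known, through the paralinear length of the induced pair joint,
## which makes paralinear distances exactly additive along the tree.

rdirichlet1 <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  x / rowSums(x)
}

## Paralinear length of edge with parent distribution `pi` and matrix M.
edge_paralinear_length <- function(M, pi) {
  dm <- det(M)
  if (dm <= 0) return(Inf)
  py <- as.numeric(pi %*% M)
  if (any(py <= 0) || any(pi <= 0)) return(Inf)
  -0.25 * (log(dm) + 0.5 * (sum(log(pi)) - sum(log(py))))
}

#' Sample a random GM transition matrix of a given branch length
#'
#' Draws a random 4x4 row-stochastic, diagonal-largest-in-column-free DLC
#' matrix (diagonal entry largest in each row, the standard identifiability
#' normalization) whose branch length equals `l` expected substitutions per
#' site.  The proposal is a random stochastic matrix interpolated between the
#' identity and a noisy uniform-mixing matrix; the interpolation parameter is
#' solved by bisection so that either `det M = exp(-4 l)` (default) or, if a
#' parent state distribution `pi` is supplied, the paralinear length of the
#' induced pair joint equals `l` exactly.  Non-DLC draws are rejected and
#' resampled with a tighter noise level.
#'
#' @param l target branch length (>= 0).
#' @param pi optional parent-node state distribution used for paralinear
#'   calibration.
#' @param max_tries resampling budget before giving up.
#' @return a 4x4 row-stochastic matrix.
#' @export
sample_gm_matrix <- function(l, pi = NULL, max_tries = 400L) {
  if (l < 0) stop("branch length must be non-negative")
  if (l == 0) return(diag(4))
  U <- matrix(0.25, 4, 4)
  len_of <- if (is.null(pi)) {
    function(M) { dm <- det(M); if (dm <= 0) Inf else -0.25 * log(dm) }
  } else {
    function(M) edge_paralinear_length(M, pi)
  }
  ## proposals: a product of diagonal-leaning Dirichlet-row matrices keeps
  ## rows and stationary composition heterogeneous even at substantial
  ## branch lengths; `beta` blends the proposal toward the uniform-mixing
  ## matrix only when the diagonal-largest constraint cannot be met
  ## otherwise (unavoidable for very long branches, where a determinant
  ## near zero forces nearly uniform rows).
  beta <- 1
  for (try in seq_len(max_tries)) {
    Z <- NULL
    for (j in 1:60) {
      Zi <- matrix(stats::rgamma(16L, shape = 1), 4L, 4L)
      diag(Zi) <- stats::rgamma(4L, shape = 6)
      Zi <- Zi / rowSums(Zi)
      if (det(Zi) <= 0) next
      Z <- if (is.null(Z)) Zi else Z %*% Zi
      if (len_of((1 - beta) * U + beta * Z) >= l) break
    }
    if (is.null(Z)) next
    R <- (1 - beta) * U + beta * Z
    if (len_of(R) < l) { next }
    lo <- 0; hi <- 1
    for (it in 1:100) {
      mid <- (lo + hi) / 2
      if (len_of((1 - mid) * diag(4) + mid * R) >= l) hi <- mid else lo <- mid
    }
    M <- (1 - hi) * diag(4) + hi * R
    if (abs(len_of(M) - l) > 1e-9) { beta <- beta * 0.95; next }
    if (all(diag(M) == apply(M, 1L, max))) return(M)
    beta <- beta * 0.85
  }
  stop("failed to sample a DLC matrix at branch length ", l)
}

#' Rooted GM model instance on a tree
#'
#' Equips a rooted tree having branch lengths with a root state distribution
#' and one random transition matrix per edge, each calibrated so that the
#' realized paralinear edge length equals the tree's branch length.  Pairwise
#' paralinear distances between leaves of the resulting model are therefore
#' exactly the path lengths of the tree.
#'
#' @param tree a rooted `phylo` with `edge.length` in substitutions/site, or
#'   a Newick string.
#' @param root_dist distribution at the root; default a uniform-simplex draw
#'   (the model is deliberately non-stationary).
#' @return an object of class `gm_instance`: list with `tree`, `root_dist`,
#'   `edge_matrices` (one per row of `tree$edge`), and `node_dist` (state
#'   distribution at every node).
#' @export
gm_instance <- function(tree, root_dist = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  tree <- stats::reorder(tree, "cladewise")  # parents precede children
  ntot <- max(tree$edge)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  if (is.null(root_dist)) root_dist <- as.numeric(rdirichlet1(1, rep(1, 4)))
  node_dist <- matrix(NA_real_, ntot, 4L)
  node_dist[root, ] <- root_dist
  mats <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chl <- tree$edge[e, 2]
    pp <- node_dist[par, ]
    mats[[e]] <- sample_gm_matrix(tree$edge.length[e], pi = pp)
    node_dist[chl, ] <- as.numeric(pp %*% mats[[e]])
  }
  structure(list(tree = tree, root_dist = root_dist, edge_matrices = mats,
                 node_dist = node_dist, model = "gm"),
            class = "gm_instance")
}

#' @export
print.gm_instance <- function(x, ...) {
  cat("GM model instance:", length(x$tree$tip.label), "leaves,",
      nrow(x$tree$edge), "edges\n")
  cat("  root distribution:", paste(round(x$root_dist, 3), collapse = " "), "\n")
  invisible(x)
}

#' Homogeneous GTR model
#'
#' A continuous-time general time-reversible rate matrix shared by all
#' branches, normalized to one expected substitution per unit branch length.
#'
#' @param rates the six exchangeabilities in the order AC, AG, AT, CG, CT,
#'   GT.  The package default (2, 5, 3, 4, 1, 2) with equal base frequencies
#'   is the benchmark setting used for the simulated GTR alignments.
#' @param freqs stationary base frequencies.
#' @return object of class `gtr_model` with components `Q`, `freqs` and an
#'   eigendecomposition for fast transition matrices.
#' @export
gtr_model <- function(rates = c(2, 5, 3, 4, 1, 2), freqs = rep(0.25, 4)) {
  stopifnot(length(rates) == 6L, all(rates > 0),
            length(freqs) == 4L, all(freqs > 0))
  freqs <- freqs / sum(freqs)
  Q <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  ord <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- ord[k, 1]; j <- ord[k, 2]
    Q[i, j] <- rates[k] * freqs[j]
    Q[j, i] <- rates[k] * freqs[i]
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q <- Q / scale
  ## symmetrize for the eigendecomposition: S = D^{1/2} Q D^{-1/2}
  s <- sqrt(freqs)
  S <- diag(s) %*% Q %*% diag(1 / s)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  structure(list(Q = Q, freqs = freqs, rates = rates,
                 evec = diag(1 / s) %*% es$vectors,
                 ivec = t(es$vectors) %*% diag(s), eval = es$values),
            class = "gtr_model")
}

#' Transition matrix of a GTR model
#' @param model a `gtr_model`.
#' @param t branch length (expected substitutions per site).
#' @return the 4x4 row-stochastic matrix `expm(tQ)`.
#' @export
gtr_transition <- function(model, t) {
  M <- model$evec %*% (exp(model$eval * t) * model$ivec)
  M[M < 0] <- 0
  M / rowSums(M)
}

#' GTR model instance on a tree
#'
#' Shares one rate matrix across all branches (homogeneous continuous-time
#' model); the per-edge transition matrices are `expm(t_e Q)` and the root is
#' at stationarity.
#'
#' @param tree rooted `phylo` with branch lengths, or Newick string.
#' @param model a `gtr_model`.
#' @return a `gm_instance` (the GM container is the common simulation
#'   currency; here all matrices commute and the root distribution is the
#'   stationary one).
#' @export
gtr_instance <- function(tree, model = gtr_model()) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  tree <- stats::reorder(tree, "cladewise")
  ntot <- max(tree$edge)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  node_dist <- matrix(rep(model$freqs, ntot), ntot, 4L, byrow = TRUE)
  mats <- lapply(tree$edge.length, function(t) gtr_transition(model, t))
  structure(list(tree = tree, root_dist = model$freqs, edge_matrices = mats,
                 node_dist = node_dist, model = "gtr"),
            class = "gm_instance")
}

## Vectorized categorical sampling: one draw per row of `prob[state, ]`.
sample_states <- function(parent, M, n) {
  cum <- t(apply(M, 1L, cumsum))
  cum[, 4L] <- 1
  u <- stats::runif(n)
  1L + rowSums(cum[parent, , drop = FALSE] < u)
}

#' Simulate an alignment from a model instance
#'
#' Sites are i.i.d.: the root state is drawn from the root distribution and
#' each child state from the parent's row of the edge's transition matrix.
#'
#' @param inst a `gm_instance` (GM or GTR).
#' @param n_sites number of alignment columns.
#' @return a `dna_alignment` whose rows follow `inst$tree$tip.label`.
#' @export
simulate_alignment <- function(inst, n_sites) {
  stopifnot(n_sites >= 1)
  tree <- inst$tree   # already cladewise from the instance constructors
  ntot <- max(tree$edge)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  states <- matrix(NA_integer_, ntot, n_sites)
  states[root, ] <- sample.int(4L, n_sites, replace = TRUE,
                               prob = inst$root_dist)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chl <- tree$edge[e, 2]
    states[chl, ] <- sample_states(states[par, ], inst$edge_matrices[[e]],
                                   n_sites)
  }
  ntips <- length(tree$tip.label)
  alignment_from_codes(states[seq_len(ntips), , drop = FALSE], tree$tip.label)
}

## ---- exact pattern distributions on quartets -----------------------------

#' Random GM instance on a quartet
#'
#' Builds a rooted quartet-tree GM instance for the given split, with leaves
#' labelled `t1..t4`.  The root is placed at the interior node adjacent to
#' the split's first pair.  Pendant branch lengths are given in leaf order
#' 1..4 and `interior` is the interior-edge length.
#'
#' @param lengths numeric(4) pendant branch lengths for leaves 1..4.
#' @param interior interior branch length.
#' @param split the generating split.
#' @param root_dist optional root distribution (default: uniform-simplex draw).
#' @return a `gm_instance`.
#' @export
gm_quartet <- function(lengths, interior, split = "12|34", root_dist = NULL) {
  split <- match.arg(split, QUARTET_SPLITS)
  pair <- switch(split, "12|34" = c(1, 2, 3, 4), "13|24" = c(1, 3, 2, 4),
                 "14|23" = c(1, 4, 2, 3))
  nwk <- sprintf("((t%d:%.10f,t%d:%.10f):%.10f,t%d:%.10f,t%d:%.10f);",
                 pair[3], lengths[pair[3]], pair[4], lengths[pair[4]],
                 interior, pair[1], lengths[pair[1]], pair[2], lengths[pair[2]])
  tree <- ape::read.tree(text = nwk)
  gm_instance(tree, root_dist = root_dist)
}

#' Exact site-pattern distribution of a quartet model
#'
#' Computes the theoretical 256-entry joint distribution at the leaves by
#' tensor contraction over the interior nodes -- the infinite-length limit of
#' [simulate_alignment()] followed by [count_patterns()].
#'
#' @param inst a `gm_instance` on a 4-leaf tree with leaves `t1..t4` (any
#'   labels; leaf order is taken from `tip.label` sorted by tip number).
#' @return a `pattern_dist`.
#' @export
exact_pattern_dist <- function(inst) {
  tree <- inst$tree
  ntips <- length(tree$tip.label)
  stopifnot(ntips == 4L)
  ntot <- max(tree$edge)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  ## children lists
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  ## partial likelihood "message" from node to its subtree leaves:
  ## L[[v]] is a 4 x 4^{k} matrix over states of v x patterns at its leaves,
  ## together with the leaf index order.
  rec <- function(v) {
    if (v <= ntips) {
      return(list(mat = diag(4), leaves = v))
    }
    parts <- lapply(kids[[as.character(v)]], function(e) {
      sub <- rec(tree$edge[e, 2])
      M <- inst$edge_matrices[[e]]
      list(mat = M %*% sub$mat, leaves = sub$leaves)
    })
    mat <- parts[[1]]$mat; leaves <- parts[[1]]$leaves
    for (i in seq_along(parts)[-1]) {
      ## row-wise tensor product over the state of v
      a <- mat; b <- parts[[i]]$mat
      mat <- t(vapply(1:4, function(s) as.numeric(outer(b[s, ], a[s, ])),
                      numeric(ncol(a) * ncol(b))))
      leaves <- c(leaves, parts[[i]]$leaves)
    }
    list(mat = mat, leaves = leaves)
  }
  full <- rec(root)
  pvec <- as.numeric(inst$root_dist %*% full$mat)
  ## pvec is indexed with the first leaf in full$leaves varying slowest?
  ## outer(b, a) makes a's index vary fastest; after the fold, the leaf order
  ## in `leaves` matches indices from slowest (first) to fastest (last).
  ## Reorder into canonical leaf order 1..4 with leaf 1 most significant.
  lv <- full$leaves
  a <- array(pvec, dim = rep(4, 4))
  ## dim i of `a` indexes the state of leaf rev(lv)[i] (last leaf varies
  ## fastest); the canonical layout wants dim i to index leaf 5-i.
  a <- aperm(a, match(4:1, rev(lv)))
  pv <- as.numeric(a)                   # leaf i = tip number i
  ## reorder so that leaf i of the distribution is the i-th taxon label in
  ## sorted order (t1..t4 for the quartet constructors)
  taxa_order <- sort(tree$tip.label)
  pv <- pattern_permute(pv, match(taxa_order, tree$tip.label))
  new_pattern_dist(pv, taxa = taxa_order, n_sites = Inf)
}

#' Paralinear length of each edge of a GM instance
#'
#' The per-edge paralinear lengths; by construction of [gm_instance()] these
#' match the tree's branch lengths to within 1e-8.
#'
#' @param inst a `gm_instance`.
#' @return numeric vector, one entry per row of `inst$tree$edge`.
#' @export
edge_lengths_paralinear <- function(inst) {
  vapply(seq_len(nrow(inst$tree$edge)), function(e) {
    pp <- inst$node_dist[inst$tree$edge[e, 1], ]
    edge_paralinear_length(inst$edge_matrices[[e]], pp)
  }, numeric(1))
}
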