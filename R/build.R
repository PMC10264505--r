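## ---- weighted quartet amalgamation by greedy taxon insertion --------------
##
## All three heuristics share one engine.  A growing unrooted binary tree is
## kept as an edge list over node ids; leaves carry global taxon indices.
## Candidate insertions (taxon x, edge e) are scored through the quartets
## {x, i, j, l} with i<j<l already placed: the topology such a quartet takes
## if x is attached on e is read off topological distances from the edge
## midpoint, and either the quartet weights of that topology are summed (WO,
## QP) or the agreements with the max-weight topology are counted (WIL).
## Only quartets containing the new taxon are ever evaluated, so one
## insertion step is O(k^3) in the number of placed taxa.

## position of taxon x within its sorted quartet (xrank) and the induced
## pairing (1: x with the smallest remaining, 2: middle, 3: largest) map to
## the canonical split index of the sorted quadruple:
.splitmap <- rbind(c(1L, 2L, 3L),
                   c(1L, 3L, 2L),
                   c(2L, 3L, 1L),
                   c(3L, 2L, 1L))

## adjacency + BFS distances from every node over unit-length edges
tree_dists <- function(edges, nodes) {
  nn <- max(nodes)
  adj <- vector("list", nn)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  D <- matrix(NA_real_, nn, nn)
  for (s in nodes) {
    dist <- rep(NA_real_, nn)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
    D[s, ] <- dist
  }
  D
}

## Build the n^4 row-lookup for a weight table (sorted quadruple -> row).
table_lookup <- function(table) {
  taxa <- attr(table, "taxa")
  n <- length(taxa)
  Q <- rbind(match(table$t1, taxa), match(table$t2, taxa),
             match(table$t3, taxa), match(table$t4, taxa))
  ## dense index instead of hashing: keys fit in (n+1)^4 <= 391k for n = 24
  L <- rep(NA_integer_, (n + 1)^4)
  kk <- ((Q[1, ] * (n + 1) + Q[2, ]) * (n + 1) + Q[3, ]) * (n + 1) + Q[4, ]
  L[kk] <- seq_along(kk)
  list(L = L, base = n + 1L, n = n, taxa = taxa,
       W = as.matrix(table[, c("w1", "w2", "w3")]))
}

lookup_rows <- function(lk, quad_sorted) {
  ## quad_sorted: 4 x K matrix of sorted taxon indices
  b <- lk$base
  kk <- ((quad_sorted[1, ] * b + quad_sorted[2, ]) * b +
           quad_sorted[3, ]) * b + quad_sorted[4, ]
  lk$L[kk]
}

## One greedy build.  mode: "wo" (weight sums, best taxon+edge), "qp"
## (weight sums, taxon order given), "wil" (consistency counts, best
## taxon+edge).  Randomness (initial quartet, QP order, tie breaks) comes
## from the current RNG stream.
build_once <- function(lk, mode = c("wo", "qp", "wil")) {
  mode <- match.arg(mode)
  n <- lk$n
  W <- if (mode == "wil") {
    top <- max.col(lk$W, ties.method = "first")
    Wb <- matrix(0, nrow(lk$W), 3L)
    Wb[cbind(seq_len(nrow(Wb)), top)] <- 1
    Wb
  } else lk$W
  init <- sort(sample.int(n, 4L))
  row0 <- lookup_rows(lk, matrix(init, 4L))
  if (is.na(row0)) stop("missing weight for quartet ",
                        paste(lk$taxa[init], collapse = ","))
  w0 <- W[row0, ]
  best <- which(w0 == max(w0))
  sp <- if (length(best) > 1L) sample(best, 1L) else best
  pair <- switch(sp, c(1L, 2L, 3L, 4L), c(1L, 3L, 2L, 4L), c(1L, 4L, 2L, 3L))
  ## nodes: 1..n reserved for leaves (taxon index = node id), internals after
  inA <- n + 1L; inB <- n + 2L
  edges <- rbind(c(inA, init[pair[1]]), c(inA, init[pair[2]]),
                 c(inA, inB),
                 c(inB, init[pair[3]]), c(inB, init[pair[4]]))
  nextnode <- n + 3L
  placed <- init
  unplaced <- setdiff(seq_len(n), placed)
  if (mode == "qp") unplaced <- sample(unplaced)
  while (length(unplaced)) {
    k <- length(placed)
    nodes <- c(placed, (n + 1L):(nextnode - 1L))
    D <- tree_dists(edges, nodes)
    Dll <- D[placed, placed, drop = FALSE]   # leaf-leaf (indexed by position)
    trip <- utils::combn(k, 3L)              # positions into `placed`
    i <- trip[1, ]; j <- trip[2, ]; l <- trip[3, ]
    Djl <- Dll[cbind(j, l)]; Dil <- Dll[cbind(i, l)]; Dij <- Dll[cbind(i, j)]
    cand_taxa <- if (mode == "qp") unplaced[1] else unplaced
    ne <- nrow(edges)
    ## per-candidate-taxon quartet rows and split maps (edge-independent)
    rows_l <- vector("list", length(cand_taxa))
    smap_l <- vector("list", length(cand_taxa))
    for (ci in seq_along(cand_taxa)) {
      x <- cand_taxa[ci]
      gi <- placed[i]; gj <- placed[j]; gl <- placed[l]
      xrank <- 1L + (x > gi) + (x > gj) + (x > gl)
      quad <- rbind(pmin(gi, x), pmin(gj, pmax(gi, x)),
                    pmin(gl, pmax(gj, pmax(gi, x))), pmax(gl, x))
      rows <- lookup_rows(lk, quad)
      if (anyNA(rows))
        stop("missing weight for a quartet containing ", lk$taxa[x])
      rows_l[[ci]] <- rows
      smap_l[[ci]] <- .splitmap[xrank, , drop = FALSE]
    }
    scores <- matrix(-Inf, length(cand_taxa), ne)
    for (e in seq_len(ne)) {
      u <- edges[e, 1]; v <- edges[e, 2]
      dP <- pmin(D[u, placed], D[v, placed]) + 0.5
      s1 <- dP[i] + Djl; s2 <- dP[j] + Dil; s3 <- dP[l] + Dij
      pos <- max.col(-cbind(s1, s2, s3), ties.method = "first")
      for (ci in seq_along(cand_taxa)) {
        sidx <- smap_l[[ci]][cbind(seq_along(pos), pos)]
        scores[ci, e] <- sum(W[cbind(rows_l[[ci]], sidx)])
      }
    }
    mx <- max(scores)
    hits <- which(scores == mx, arr.ind = TRUE)
    pick <- if (nrow(hits) > 1L) hits[sample.int(nrow(hits), 1L), ] else hits[1L, ]
    x <- cand_taxa[pick[1]]; e <- pick[2]
    mid <- nextnode; nextnode <- nextnode + 1L
    u <- edges[e, 1]; v <- edges[e, 2]
    edges[e, ] <- c(u, mid)
    edges <- rbind(edges, c(mid, v), c(mid, x))
    placed <- sort(c(placed, x))   # kept sorted so quartet keys stay sorted
    unplaced <- setdiff(unplaced, x)
  }
  edges_to_phylo(edges, lk$taxa)
}

## convert our edge list to an ape phylo via a Newick string
edges_to_phylo <- function(edges, taxa) {
  n <- length(taxa)
  adj <- vector("list", max(edges))
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  root <- n + 1L
  wr <- function(v, parent) {
    kids <- setdiff(adj[[v]], parent)
    if (!length(kids)) return(taxa[v])
    paste0("(", paste(vapply(kids, wr, character(1), parent = v),
                      collapse = ","), ")")
  }
  ape::read.tree(text = paste0(wr(root, NA), ";"))
}

#' Tree building from a quartet weight table
#'
#' Greedy weighted amalgamation heuristics:
#' \describe{
#'   \item{`wo` (weight optimization)}{starts from a uniformly random
#'     4-tuple resolved by its max-weight split, then repeatedly inserts the
#'     (taxon, edge) pair maximizing the summed weight, over all quartets
#'     that contain the new taxon, of the topology the candidate tree would
#'     display.  With correctly weighted (0/1) input quartets, WO provably
#'     returns the generating tree.}
#'   \item{`qp` (quartet puzzling)}{random initial 4-tuple and random
#'     insertion order; for each taxon the best edge under the same weighted
#'     objective is chosen.}
#'   \item{`wil` (consistency-count insertion)}{like `wo` but maximizing the
#'     number of quartets whose max-weight topology is displayed, rather
#'     than the weight sum.}
#' }
#' Ties in the objective are broken uniformly at random from the current RNG
#' stream, so replicate runs explore different reconstructions.
#'
#' @param table a `quartet_weight_table` covering all needed quartets.
#' @param method `"wo"`, `"qp"` or `"wil"`.
#' @param seed optional integer seed for this single build.
#' @return an unrooted binary `phylo`.
#' @export
build_tree <- function(table, method = c("wo", "qp", "wil"), seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  build_once(table_lookup(table), method)
}

#' Replicated builds with majority-rule consensus
#'
#' Runs a quartet amalgamation heuristic `n_replicates` times -- each
#' replicate re-randomizes the initial 4-tuple, the insertion order (QP) and
#' all tie breaks -- and returns the majority-rule consensus of the
#' replicate trees.
#'
#' @inheritParams build_tree
#' @param n_replicates number of replicate builds (benchmark default 100).
#' @param seed integer seed for the replicate stream.
#' @param return_trees if `TRUE`, attach the replicate trees as an attribute.
#' @return an unrooted `phylo` (possibly multifurcating).
#' @export
run_and_consense <- function(table, method = c("wo", "qp", "wil"),
                             n_replicates = 100L, seed = NULL,
                             return_trees = FALSE) {
  method <- match.arg(method)
  stopifnot(n_replicates >= 1L)
  if (!is.null(seed)) set.seed(seed)
  lk <- table_lookup(table)
  trees <- lapply(seq_len(n_replicates), function(i) build_once(lk, method))
  cons <- if (n_replicates == 1L) trees[[1]] else mrct(trees)
  if (return_trees) attr(cons, "replicates") <- trees
  cons
}
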