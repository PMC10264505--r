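#' Robinson-Foulds distance
#'
#' Size of the symmetric difference between the internal-edge bipartition
#' sets of two unrooted trees on the same leaf set.
#'
#' @param t1,t2 `phylo` trees (or Newick strings) with identical leaf sets.
#' @param normalized if `TRUE`, additionally return the distance divided by
#'   the total number of interior edges of the two trees.
#' @return integer RF distance (numeric when `normalized`).
#' @export
rf_distance <- function(t1, t2, normalized = FALSE) {
  if (is.character(t1)) t1 <- ape::read.tree(text = t1)
  if (is.character(t2)) t2 <- ape::read.tree(text = t2)
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  t1 <- ape::unroot(t1); t2 <- ape::unroot(t2)
  ## RF on multifurcating consensus trees is well-defined (symmetric
  ## difference of bipartition sets); phangorn only warns about it
  rf <- as.integer(suppressMessages(suppressWarnings(
    phangorn::RF.dist(t1, t2, check.labels = TRUE))))
  if (!normalized) return(rf)
  ie <- (t1$Nnode - 1L) + (t2$Nnode - 1L)
  rf / ie
}

#' Majority-rule consensus of replicate trees
#'
#' Retains exactly the bipartitions present in strictly more than half of the
#' input trees.
#'
#' @param trees a list of `phylo` objects (or `multiPhylo`).
#' @return a (possibly multifurcating) unrooted `phylo`.
#' @export
mrct <- function(trees) {
  if (inherits(trees, "phylo")) return(trees)
  trees <- lapply(trees, ape::unroot)
  class(trees) <- "multiPhylo"
  if (length(trees) == 1L) return(trees[[1]])
  ## p slightly above 0.5 so that exactly-half splits are excluded
  ape::consensus(trees, p = 0.5 + 1e-9, rooted = FALSE)
}

## Topological (unit-branch-length) distances between all nodes of a tree.
node_depth_dists <- function(tree) {
  tr <- tree
  tr$edge.length <- rep(1, nrow(tr$edge))
  ape::dist.nodes(tr)
}

#' Quartet topologies displayed by a tree
#'
#' For each 4-subset of the leaf labels, returns the split displayed by the
#' tree, as an index 1..3 into the canonical split order of the subset sorted
#' by label (1: first pairs with second, 2: with third, 3: with fourth).
#' Unresolved quartets (possible in multifurcating trees) get `NA`.
#'
#' @param tree a `phylo`.
#' @param quartets optional 4-row integer matrix of label indices (columns =
#'   quartets, as from `combn`); default all `C(n,4)` subsets of
#'   `sort(tree$tip.label)`.
#' @return list with `taxa` (sorted labels), `quartets` (4 x K index matrix)
#'   and `split` (length-K integer vector).
#' @export
tree_quartets <- function(tree, quartets = NULL) {
  taxa <- sort(tree$tip.label)
  tipof <- match(taxa, tree$tip.label)
  if (is.null(quartets)) quartets <- utils::combn(length(taxa), 4L)
  D <- node_depth_dists(tree)[tipof, tipof, drop = FALSE]
  a <- quartets[1, ]; b <- quartets[2, ]; cc <- quartets[3, ]; d <- quartets[4, ]
  s1 <- D[cbind(a, b)] + D[cbind(cc, d)]
  s2 <- D[cbind(a, cc)] + D[cbind(b, d)]
  s3 <- D[cbind(a, d)] + D[cbind(b, cc)]
  sp <- max.col(-cbind(s1, s2, s3), ties.method = "first")
  mn <- pmin(s1, s2, s3)
  nmin <- (s1 == mn) + (s2 == mn) + (s3 == mn)
  sp[nmin > 1L] <- NA_integer_
  list(taxa = taxa, quartets = quartets, split = sp)
}

#' Random binary unrooted tree
#'
#' Uniform over labelled topologies via random sequential leaf addition.
#'
#' @param taxa leaf labels, or a single integer (labels `t1..tn`).
#' @return an unrooted binary `phylo` without branch lengths.
#' @export
random_binary_tree <- function(taxa) {
  if (length(taxa) == 1L && is.numeric(taxa)) taxa <- paste0("t", seq_len(taxa))
  ape::rtree(length(taxa), rooted = FALSE, tip.label = sample(taxa),
             br = NULL)
}
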