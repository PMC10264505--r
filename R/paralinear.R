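#' Paralinear (log-det) distance from a pairwise joint distribution
#'
#' For a joint distribution \eqn{J} of the states at two leaves, the
#' paralinear distance is
#' \deqn{d = -\tfrac14\left[\ln|\det J| - \tfrac12 \ln(\det D_x \det D_y)\right],}
#' where \eqn{D_x, D_y} are the diagonal matrices of the row and column
#' marginals.  It is additive along tree paths under the general Markov model
#' and equals the branch length in expected substitutions per site for a
#' Jukes-Cantor branch with uniform composition.  The distance is *undefined*
#' (returned as `NA`) when \eqn{\det J = 0} or a marginal state frequency is
#' zero; it may be negative for empirical distributions, which callers must
#' handle (the ASAQ rule routes such quartets to the semi-algebraic score).
#'
#' @param J a 4x4 matrix with non-negative entries summing to 1.
#' @return a single numeric distance, or `NA_real_` if undefined.
#' @export
paralinear_distance <- function(J) {
  if (!is.matrix(J) || any(dim(J) != 4L) || any(J < 0) ||
      abs(sum(J) - 1) > 1e-8)
    stop("J must be a 4x4 joint distribution")
  rm <- rowSums(J); cm <- colSums(J)
  dj <- det(J)
  if (dj == 0 || any(rm == 0) || any(cm == 0)) return(NA_real_)
  -0.25 * (log(abs(dj)) - 0.5 * (sum(log(rm)) + sum(log(cm))))
}

#' All six pairwise paralinear distances of a quartet
#'
#' @param p a `pattern_dist`.
#' @return a symmetric 4x4 matrix of class `paralinear_matrix` with zero
#'   diagonal; undefined distances are `NA` and flagged in the logical
#'   attribute `defined`.
#' @export
paralinear_matrix <- function(p) {
  d <- matrix(0, 4L, 4L)
  def <- matrix(TRUE, 4L, 4L)
  for (x in 1:3) for (y in (x + 1):4) {
    v <- paralinear_distance(pair_joint(p, x, y))
    d[x, y] <- d[y, x] <- v
    def[x, y] <- def[y, x] <- !is.na(v)
  }
  structure(d, defined = def, class = c("paralinear_matrix", "matrix"))
}

#' @export
print.paralinear_matrix <- function(x, ...) {
  cat("Paralinear distance matrix (NA = undefined):\n")
  print(matrix(as.numeric(x), 4, 4), ...)
  invisible(x)
}

## Internal: the three interior-edge statistics from a 4x4 distance matrix.
## pl_{ij|kl} = min(d_ik + d_jl, d_il + d_jk) - d_ij - d_kl.
pl_from_dist <- function(d) {
  c(min(d[1, 3] + d[2, 4], d[1, 4] + d[2, 3]) - d[1, 2] - d[3, 4],
    min(d[1, 2] + d[3, 4], d[1, 4] + d[2, 3]) - d[1, 3] - d[2, 4],
    min(d[1, 2] + d[3, 4], d[1, 3] + d[2, 4]) - d[1, 4] - d[2, 3])
}

#' Interior-edge paralinear statistic of the three splits
#'
#' For each split `ij|kl` this computes
#' `min(d_ik + d_jl, d_il + d_jk) - d_ij - d_kl`, the classic neighborliness
#' quantity: on an additive (tree) metric it equals twice the interior-edge
#' length for the true split and is non-positive for the other two.  Whenever
#' all six distances are non-negative, at most one of the three values is
#' strictly positive.
#'
#' @param p a `pattern_dist`, or a 4x4 (paralinear) distance matrix.
#' @return named numeric triple in the canonical split order.
#' @export
pl_triple <- function(p) {
  d <- if (inherits(p, "pattern_dist")) paralinear_matrix(p) else p
  if (anyNA(d))
    stop("undefined paralinear distance: pl statistic unavailable",
         call. = FALSE)
  stats::setNames(pl_from_dist(d), QUARTET_SPLITS)
}

## Internal constructor of the normalized weight-triple object shared by all
## weighting systems.
new_quartet_weights <- function(w, method, tag = method,
                                taxa = paste0("t", 1:4)) {
  w <- as.numeric(w)
  w <- w / sum(w)
  structure(list(weights = stats::setNames(w, QUARTET_SPLITS),
                 topology = QUARTET_SPLITS[which.max(w)],
                 method = method, tag = tag, taxa = taxa),
            class = "quartet_weights")
}

#' @export
print.quartet_weights <- function(x, ...) {
  cat(sprintf("Quartet weights [%s] on (%s)\n", x$method,
              paste(x$taxa, collapse = ", ")))
  print(round(x$weights, 4))
  cat("  topology:", x$topology,
      if (!identical(x$tag, x$method)) paste0(" (via ", x$tag, ")") else "",
      "\n")
  invisible(x)
}

softmax <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

#' Paralinear (PL) quartet weights
#'
#' Weights are the normalized exponentials of the three interior-edge
#' paralinear statistics; the inferred topology is the split with the largest
#' statistic.
#'
#' @param p a `pattern_dist`.
#' @return a `quartet_weights` object.
#' @export
pl_weights <- function(p) {
  v <- pl_triple(p)
  w <- softmax(v)
  q <- new_quartet_weights(w, "pl", taxa = if (inherits(p, "pattern_dist")) p$taxa else paste0("t", 1:4))
  q$topology <- QUARTET_SPLITS[which.max(v)]
  q
}

#' Four-point-condition (4P) quartet weights
#'
#' A variant of the paralinear weighting driven purely by the four-point
#' condition: for each split the score is the second-smallest of the three
#' within-pair distance sums minus the split's own sum (positive only for the
#' minimizing split), and weights are normalized exponentials of the scores.
#' On additive distances the selected topology coincides with the PL choice.
#'
#' @param p a `pattern_dist`.
#' @return a `quartet_weights` object.
#' @export
fourpoint_weights <- function(p) {
  d <- paralinear_matrix(p)
  if (anyNA(d))
    stop("undefined paralinear distance: 4P weights unavailable", call. = FALSE)
  s <- c(d[1, 2] + d[3, 4], d[1, 3] + d[2, 4], d[1, 4] + d[2, 3])
  ss <- sort(s)[2]
  score <- ss - s
  q <- new_quartet_weights(softmax(score), "4p", taxa = p$taxa)
  q$topology <- QUARTET_SPLITS[which.max(score)]
  q
}

#' Paralinear distance matrix of a full alignment
#'
#' Pairwise paralinear distances for all taxa, with pairwise column deletion
#' of gap/ambiguity sites.
#'
#' @param aln a `dna_alignment`.
#' @return an n x n symmetric matrix (NA where undefined), with taxon labels.
#' @export
paralinear_dist_matrix <- function(aln) {
  n <- length(aln$taxa)
  D <- matrix(0, n, n, dimnames = list(aln$taxa, aln$taxa))
  for (x in seq_len(n - 1)) for (y in (x + 1):n) {
    sx <- aln$seq[x, ]; sy <- aln$seq[y, ]
    ok <- !is.na(sx) & !is.na(sy)
    if (!any(ok)) { D[x, y] <- D[y, x] <- NA_real_; next }
    J <- matrix(tabulate(4L * (sx[ok] - 1L) + sy[ok], nbins = 16L), 4L, 4L,
                byrow = TRUE) / sum(ok)
    D[x, y] <- D[y, x] <- paralinear_distance(J)
  }
  D
}

#' Neighbor joining on paralinear distances
#'
#' The global NJ baseline: standard neighbor joining (as implemented in
#' \pkg{ape}) applied to the pairwise paralinear distance matrix of the
#' alignment.
#'
#' @param aln a `dna_alignment` with at least 4 taxa.
#' @return an unrooted `phylo` tree.
#' @export
nj_paralinear <- function(aln) {
  if (length(aln$taxa) < 4L) stop("need at least 4 taxa")
  D <- paralinear_dist_matrix(aln)
  if (anyNA(D)) stop("undefined paralinear distance between ",
                     paste(aln$taxa[which(is.na(D), arr.ind = TRUE)[1, ]],
                           collapse = " and "))
  ape::nj(stats::as.dist(D))
}

#' Write a distance matrix in square PHYLIP format
#' @param D square numeric matrix with row names.
#' @param path output path.
#' @export
write_phylip_dist <- function(D, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D)))
    writeLines(paste(c(sprintf("%-10s", rownames(D)[i]),
                       sprintf("%.8f", D[i, ])), collapse = "  "), con)
  invisible(path)
}
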