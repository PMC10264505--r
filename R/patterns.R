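#' @keywords internal
#' @useDynLib asaq, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Nucleotide coding used throughout: A=1, C=2, G=3, T=4.
NUC <- c("A", "C", "G", "T")

#' Names of the three splits of a four-taxon set
#'
#' Splits are always reported in the canonical order `12|34`, `13|24`, `14|23`,
#' relative to the taxon ordering of the quartet at hand.  Ties between equal
#' weights or scores are broken deterministically in this order.
#'
#' @export
QUARTET_SPLITS <- c("12|34", "13|24", "14|23")

## Precomputed index machinery for the 256 site patterns.
##
## Patterns are indexed lexicographically over (A,C,G,T) with leaf 1 most
## significant: index(x1,x2,x3,x4) = 64(x1-1) + 16(x2-1) + 4(x3-1) + (x4-1) + 1.
## This fixes a bit-exact layout for cached pattern-count files.
.pat <- local({
  g <- expand.grid(x4 = 1:4, x3 = 1:4, x2 = 1:4, x1 = 1:4,
                   KEEP.OUT.ATTRS = FALSE)
  X <- as.matrix(g[, c("x1", "x2", "x3", "x4")])
  splits <- list(`12|34` = c(1L, 2L, 3L, 4L),
                 `13|24` = c(1L, 3L, 2L, 4L),
                 `14|23` = c(1L, 4L, 2L, 3L))
  flat_perm <- lapply(splits, function(s) {
    r <- 4L * (X[, s[1]] - 1L) + X[, s[2]]
    cc <- 4L * (X[, s[3]] - 1L) + X[, s[4]]
    perm <- integer(256)
    perm[(cc - 1L) * 16L + r] <- seq_len(256)
    perm
  })
  unflat_perm <- lapply(flat_perm, order)
  pairs <- utils::combn(4L, 2L)
  pair_perm <- vector("list", 16L)
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    grp <- 4L * (X[, b] - 1L) + X[, a]   # column-major cell of the 4x4 joint
    pair_perm[[(b - 1L) * 4L + a]] <- order(grp)
  }
  pat_string <- apply(X, 1L, function(x) paste(NUC[x], collapse = ""))
  list(X = X, flat_perm = flat_perm, unflat_perm = unflat_perm,
       pair_perm = pair_perm, pat_string = pat_string)
})

#' Site-pattern distribution of a quartet
#'
#' Counts the joint site patterns of four alignment rows into a probability
#' distribution over the 256 patterns in \eqn{\{A,C,G,T\}^4}.  Columns that
#' contain a gap or ambiguity symbol in any of the four rows are dropped, so
#' the result is a proper distribution on the nucleotide alphabet.
#'
#' @param aln an alignment, see [read_alignment()].
#' @param quartet character vector of four taxon labels (or integer indices
#'   into `aln$taxa`); the order defines the leaf numbering of the quartet.
#' @param gap_policy only `"drop_column"` is supported.
#' @return an object of class `pattern_dist`: a list with `taxa` (the four
#'   labels), `values` (length-256 numeric summing to 1) and `n_sites` (number
#'   of columns used).
#' @export
count_patterns <- function(aln, quartet, gap_policy = "drop_column") {
  gap_policy <- match.arg(gap_policy, "drop_column")
  idx <- if (is.numeric(quartet)) as.integer(quartet)
         else match(quartet, aln$taxa)
  if (length(idx) != 4L || anyNA(idx))
    stop("quartet must name four taxa present in the alignment")
  S <- aln$seq[idx, , drop = FALSE]
  ok <- colSums(is.na(S)) == 0L
  if (!any(ok))
    stop("degenerate input: no alignment column is fully resolved for this quartet")
  S <- S[, ok, drop = FALSE]
  code <- 64L * (S[1, ] - 1L) + 16L * (S[2, ] - 1L) + 4L * (S[3, ] - 1L) + S[4, ]
  cnt <- tabulate(code, nbins = 256L)
  new_pattern_dist(cnt / sum(cnt), taxa = aln$taxa[idx], n_sites = sum(cnt))
}

new_pattern_dist <- function(values, taxa = paste0("t", 1:4), n_sites = NA_real_) {
  stopifnot(length(values) == 256L)
  structure(list(taxa = taxa, values = as.numeric(values), n_sites = n_sites),
            class = "pattern_dist")
}

#' @export
print.pattern_dist <- function(x, ...) {
  cat("Quartet site-pattern distribution\n")
  cat("  taxa   :", paste(x$taxa, collapse = ", "), "\n")
  cat("  sites  :", x$n_sites, "\n")
  top <- order(x$values, decreasing = TRUE)[1:5]
  cat("  top patterns:",
      paste(sprintf("%s (%.4f)", .pat$pat_string[top], x$values[top]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Flattening matrix of a pattern distribution
#'
#' Rearranges the 256 pattern probabilities into the 16x16 flattening matrix
#' of a split: rows are indexed by the joint states of the split's first pair,
#' columns by the states of the second pair.  When the distribution arises on
#' a quartet tree under the general Markov model, the flattening of the true
#' split has rank at most 4 (at most 4m for an m-category same-tree mixture),
#' while the other two flattenings generically have full rank.
#'
#' @param p a `pattern_dist` or a length-256 numeric vector.
#' @param split one of `"12|34"`, `"13|24"`, `"14|23"`.
#' @return a 16x16 numeric matrix with a `split` attribute.
#' @export
flattening <- function(p, split = QUARTET_SPLITS) {
  split <- match.arg(split)
  v <- if (inherits(p, "pattern_dist")) p$values else as.numeric(p)
  structure(matrix(v[.pat$flat_perm[[split]]], 16L, 16L), split = split)
}

#' Inverse of [flattening()]
#' @param f a 16x16 flattening matrix.
#' @param split the split `f` was built with.
#' @return length-256 pattern probability vector.
#' @export
unflatten <- function(f, split = QUARTET_SPLITS) {
  split <- match.arg(split)
  as.numeric(f)[.pat$unflat_perm[[split]]]
}

#' Marginal joint distribution of a leaf pair
#'
#' Marginalizes a quartet pattern distribution onto two of its leaves.
#'
#' @param p a `pattern_dist` or length-256 numeric vector.
#' @param x,y distinct leaf indices in 1..4.
#' @return a 4x4 joint distribution with rows indexed by the state at leaf `x`.
#' @export
pair_joint <- function(p, x, y) {
  stopifnot(x != y, x %in% 1:4, y %in% 1:4)
  v <- if (inherits(p, "pattern_dist")) p$values else as.numeric(p)
  a <- min(x, y); b <- max(x, y)
  J <- matrix(colSums(matrix(v[.pat$pair_perm[[(b - 1L) * 4L + a]]], 16L, 16L)),
              4L, 4L)
  if (x > y) J <- t(J)
  dimnames(J) <- list(NUC, NUC)
  J
}

## Relabel the leaves of a pattern distribution: leaf i of the result is leaf
## perm[i] of the input.  Used for equivariance checks.
pattern_permute <- function(p, perm) {
  v <- if (inherits(p, "pattern_dist")) p$values else as.numeric(p)
  a <- array(v, dim = c(4, 4, 4, 4))   # dims correspond to (x4, x3, x2, x1)
  a2 <- aperm(a, 5L - rev(perm))       # new dims correspond to (y4, y3, y2, y1)
  as.numeric(a2)
}

#' Numerical rank of a matrix
#'
#' Rank at a relative singular-value tolerance (default 1e-9 times the largest
#' singular value, the double-precision noise floor for exactness checks).
#'
#' @param m a numeric matrix.
#' @param tol relative tolerance.
#' @export
numerical_rank <- function(m, tol = 1e-9) {
  d <- svd(m, nu = 0, nv = 0)$d
  if (d[1] == 0) return(0L)
  sum(d > tol * d[1])
}

#' Write / read cached pattern counts as TSV
#'
#' Two-column tab-separated layout: pattern string (e.g. `"ACGT"`, leaf 1
#' first) and probability (or count).  Patterns with probability zero are
#' omitted on write.
#'
#' @param p a `pattern_dist`.
#' @param path file path.
#' @export
write_pattern_counts <- function(p, path) {
  keep <- p$values > 0
  df <- data.frame(pattern = .pat$pat_string[keep], value = p$values[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pattern_counts
#' @param taxa taxon labels to attach on read.
#' @export
read_pattern_counts <- function(path, taxa = paste0("t", 1:4)) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "numeric"))
  i <- match(df$pattern, .pat$pat_string)
  if (anyNA(i)) stop("unrecognized pattern string in ", path)
  v <- numeric(256); v[i] <- df$value
  new_pattern_dist(v / sum(v), taxa = taxa, n_sites = sum(df$value))
}
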