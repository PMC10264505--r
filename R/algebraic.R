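#' Flattening-rank (Erik+2) scores
#'
#' For each split the 16x16 flattening is normalized to unit Frobenius norm
#' and scored by its Frobenius distance to the nearest matrix of rank at most
#' `4m` (the tail of its singular values): smaller is better.  A distribution
#' arising on a quartet under the general Markov model -- or an `m`-category
#' mixture of such distributions on the same tree -- has score 0 for the true
#' split in the exact (infinite-data) limit, while the other flattenings
#' generically have full rank.  The mixture bound `4m < 16` restricts
#' `m` to 1, 2 or 3.
#'
#' @param p a `pattern_dist`.
#' @param m number of across-site mixture categories (1, 2 or 3).
#' @return named numeric triple of scores (one per split), with attribute
#'   `m`.
#' @export
erik2_scores <- function(p, m = 1L) {
  m <- as.integer(m)
  if (!m %in% 1:3) stop("mixture category count m must be 1, 2 or 3 (4m < 16)")
  k <- 4L * m
  s <- vapply(QUARTET_SPLITS, function(sp) {
    f <- flattening(p, sp)
    nf <- sqrt(sum(f * f))
    if (nf == 0) return(0)
    d <- svd(f / nf, nu = 0, nv = 0)$d
    sqrt(max(sum(d[(k + 1L):16L]^2), 0))
  }, numeric(1))
  attr(s, "m") <- m
  s
}

## Shared score -> weight map for the rank-based systems: normalized
## exp(-score/tau) with tau the mean score.  Positive, normalized and
## order-reversing in the score; equal scores give equal weights.
score_to_weights <- function(score) {
  tau <- mean(score)
  ## scores at the numerical noise floor are ties, not evidence
  if (!is.finite(tau) || max(score) < 1e-6) return(rep(1 / 3, 3))
  softmax(-score / tau)
}

#' Erik+2 quartet weights
#'
#' Positive normalized weights monotone-decreasing in the flattening-rank
#' score; the inferred topology is the split with the smallest score (ties
#' broken in canonical split order).
#'
#' @inheritParams erik2_scores
#' @return a `quartet_weights` object.
#' @export
erik2_weights <- function(p, m = 1L) {
  s <- erik2_scores(p, m)
  q <- new_quartet_weights(score_to_weights(s), "erik2",
                           taxa = if (inherits(p, "pattern_dist")) p$taxa else paste0("t", 1:4))
  q$topology <- QUARTET_SPLITS[which.min(s)]
  q
}

#' Semi-algebraic (SAQ) scores and weights
#'
#' The semi-algebraic score of a split measures the divergence of the
#' observed pattern distribution from the *stochastic* general Markov model
#' on that split: the Kullback-Leibler divergence to the closest
#' distribution arising from row-stochastic transition matrices and a
#' non-negative root distribution (an `m`-category same-tree mixture when
#' `m > 1`), computed by a short expectation-maximization fit with random
#' restarts.  Because EM keeps all parameters non-negative, the score
#' enforces both the algebraic constraint (the flattening of the fitted
#' distribution has rank at most `4m`) and the semi-algebraic positivity
#' conditions of the stochastic model -- exactly the information that rank
#' statistics alone discard, and the reason this score stays reliable in the
#' Felsenstein zone, where the wrong split can only imitate the data with
#' non-stochastic parameters.
#'
#' For an exact distribution with stochastic parameters on split `S` the
#' score of `S` converges to 0, while the other splits retain a strictly
#' positive divergence for generic parameters.
#'
#' @param p a `pattern_dist`.
#' @param m mixture category count of the fitted class (1, 2 or 3).
#' @param iters maximum EM iterations per restart.
#' @param restarts number of random EM restarts (uses the current RNG
#'   stream).
#' @param pilot if positive, length of a short-run initialization phase:
#'   every restart runs only `pilot` iterations and the best is continued
#'   to the full budget; 0 runs every restart in full.
#' @return `saq_scores()`: named numeric triple of per-site KL divergences
#'   (smaller is better); `saq_weights()`: a `quartet_weights` object.
#' @export
saq_scores <- function(p, m = 1L, iters = 400L, restarts = 3L,
                       pilot = 80L) {
  v <- if (inherits(p, "pattern_dist")) p$values else as.numeric(p)
  ## common random numbers: all three splits share the same EM restart
  ## draws, so the scores are exactly leaf-permutation equivariant and the
  ## comparison between splits is not blurred by restart luck
  base_seed <- sample.int(2147483646L, 1L)
  s <- vapply(seq_along(QUARTET_SPLITS), function(sp) {
    perm <- list(c(1L, 2L, 3L, 4L), c(1L, 3L, 2L, 4L), c(1L, 4L, 2L, 3L))[[sp]]
    pv <- pattern_permute(v, perm)   # claimed split becomes 12|34
    set.seed(base_seed)
    em_quartet_kl(pv, as.integer(m), as.integer(iters), as.integer(restarts),
                  1e-10, as.integer(pilot))
  }, numeric(1))
  stats::setNames(s, QUARTET_SPLITS)
}

#' @rdname saq_scores
#' @export
saq_weights <- function(p, m = 1L, iters = 400L, restarts = 3L,
                        pilot = 80L) {
  s <- saq_scores(p, m = m, iters = iters, restarts = restarts, pilot = pilot)
  q <- new_quartet_weights(score_to_weights(s), "saq",
                           taxa = if (inherits(p, "pattern_dist")) p$taxa else paste0("t", 1:4))
  q$topology <- QUARTET_SPLITS[which.min(s)]
  q
}

#' ASAQ quartet weights
#'
#' ASAQ arbitrates between the flattening-rank weighting (Erik+2) and the
#' semi-algebraic weighting (SAQ) using the paralinear interior-edge
#' statistic: it computes all six pairwise paralinear distances and the
#' topology choices of the paralinear method and of Erik+2.  If every
#' distance is defined and non-negative and the two topologies agree, the
#' Erik+2 weights are returned (provenance tag `"erik2"`); if any distance is
#' negative or undefined, or the topologies disagree, the data are judged
#' inconsistent with stochastic tree parameters and the SAQ weights are
#' returned (tag `"saq"`).  Agreement is equality of topologies only, not of
#' weight values.
#'
#' @param p a `pattern_dist`.
#' @param m mixture categories passed to the Erik+2 component (1, 2 or 3).
#' @return a `quartet_weights` object with method `"asaq"` and provenance
#'   tag `"erik2"` or `"saq"`.
#' @export
asaq <- function(p, m = 1L) {
  d <- paralinear_matrix(p)
  if (anyNA(d) || any(d < 0, na.rm = TRUE)) {
    q <- saq_weights(p, m = m)
  } else {
    pl_top <- QUARTET_SPLITS[which.max(pl_from_dist(d))]
    e <- erik2_weights(p, m)
    q <- if (identical(pl_top, e$topology)) e else saq_weights(p, m = m)
  }
  q$method <- "asaq"
  q
}
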