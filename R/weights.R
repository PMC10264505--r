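#' Quartet weight tables
#'
#' The central fitting-style interface of the package: computes a normalized
#' weight triple for every 4-subset of the taxa of an alignment, under one of
#' the weighting systems consistent with the general Markov model
#' (`"asaq"`, `"erik2"`, `"saq"`, `"pl"`, `"4p"`).
#'
#' Within each table row the four taxon labels are sorted, and the three
#' weights `w1, w2, w3` refer to the splits `12|34`, `13|24`, `14|23` of the
#' sorted quartet.  For ASAQ the per-quartet provenance (`erik2` or `saq`) is
#' recorded in the `tag` column.  Quartets whose paralinear statistics are
#' undefined fall back as the weighting system prescribes (ASAQ and SAQ are
#' total; PL and 4P raise an error for such quartets).
#'
#' @param aln a `dna_alignment` with at least 4 taxa.
#' @param method weighting system.
#' @param m mixture categories for the flattening-rank component (1..3).
#' @param quartets optional 4-row matrix of taxon indices (into the sorted
#'   label vector) or 4-column data frame of labels restricting the table.
#' @return an object of class `quartet_weight_table`: a data frame with
#'   columns `t1..t4`, `w1..w3`, `method`, `tag`, plus attribute `taxa`.
#' @export
quartet_weights <- function(aln,
                            method = c("asaq", "erik2", "saq", "pl", "4p"),
                            m = 1L, quartets = NULL) {
  method <- match.arg(method)
  taxa <- sort(aln$taxa)
  n <- length(taxa)
  if (n < 4L) stop("need at least 4 taxa")
  Q <- resolve_quartet_arg(quartets, taxa)
  K <- ncol(Q)
  W <- matrix(NA_real_, K, 3L)
  tag <- character(K)
  for (k in seq_len(K)) {
    p <- count_patterns(aln, taxa[Q[, k]])
    w <- quartet_weights_one(p, method, m)
    W[k, ] <- w$weights
    tag[k] <- w$tag
  }
  new_weight_table(taxa, Q, W, method, tag, m = m)
}

## Single-quartet dispatch shared by the table builder and the CLI.
quartet_weights_one <- function(p, method, m = 1L) {
  switch(method,
         asaq  = asaq(p, m),
         erik2 = erik2_weights(p, m),
         saq   = saq_weights(p),
         pl    = pl_weights(p),
         `4p`  = fourpoint_weights(p),
         stop("unknown weighting method ", method))
}

resolve_quartet_arg <- function(quartets, taxa) {
  if (is.null(quartets)) return(utils::combn(length(taxa), 4L))
  if (is.data.frame(quartets)) quartets <- t(as.matrix(quartets))
  if (is.character(quartets)) quartets <- matrix(match(quartets, taxa), nrow = 4L)
  if (mode(quartets) == "character")
    quartets <- matrix(match(quartets, taxa), 4L, ncol(quartets))
  quartets <- apply(matrix(as.integer(quartets), 4L), 2L, sort)
  if (anyNA(quartets)) stop("quartet list names unknown taxa")
  quartets
}

new_weight_table <- function(taxa, Q, W, method, tag, m = 1L) {
  df <- data.frame(t1 = taxa[Q[1, ]], t2 = taxa[Q[2, ]],
                   t3 = taxa[Q[3, ]], t4 = taxa[Q[4, ]],
                   w1 = W[, 1], w2 = W[, 2], w3 = W[, 3],
                   method = method, tag = tag,
                   stringsAsFactors = FALSE)
  structure(df, taxa = taxa, m = m,
            class = c("quartet_weight_table", "data.frame"))
}

#' @export
print.quartet_weight_table <- function(x, ...) {
  cat(sprintf("Quartet weight table: %d quartets on %d taxa [%s]\n",
              nrow(x), length(attr(x, "taxa")), x$method[1]))
  if (x$method[1] == "asaq")
    cat(sprintf("  provenance: %d erik2, %d saq\n",
                sum(x$tag == "erik2"), sum(x$tag == "saq")))
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ... (", nrow(x) - 5, " more rows)\n", sep = "")
  invisible(x)
}

#' @export
summary.quartet_weight_table <- function(object, ...) {
  wm <- as.matrix(object[, c("w1", "w2", "w3")])
  top <- max.col(wm, ties.method = "first")
  cat("Weighting system:", object$method[1], "\n")
  cat("Quartets:", nrow(object), "  taxa:", length(attr(object, "taxa")), "\n")
  cat("Max-weight split distribution:",
      paste(sprintf("%s: %d", QUARTET_SPLITS, tabulate(top, 3)),
            collapse = ", "), "\n")
  cat("Mean top weight:", round(mean(wm[cbind(seq_len(nrow(wm)), top)]), 4), "\n")
  invisible(object)
}

#' Correctly weighted 0/1 table from a reference tree
#'
#' Gives weight 1 to the split each quartet displays on the tree and 0 to the
#' other two -- the premise of the exactness guarantee of weight
#' optimization.
#'
#' @param tree a binary `phylo` (or Newick string).
#' @return a `quartet_weight_table`.
#' @export
table_from_tree <- function(tree) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  tq <- tree_quartets(tree)
  if (anyNA(tq$split)) stop("reference tree has unresolved quartets")
  W <- matrix(0, ncol(tq$quartets), 3L)
  W[cbind(seq_len(nrow(W)), tq$split)] <- 1
  new_weight_table(tq$taxa, tq$quartets, W, "reference", rep("tree", nrow(W)))
}

#' Binarize a weight table
#'
#' Per quartet the max-weight split becomes 1 and the others 0; exact ties
#' are broken in canonical split order.  Idempotent.
#'
#' @param table a `quartet_weight_table`.
#' @export
binarize_weights <- function(table) {
  wm <- as.matrix(table[, c("w1", "w2", "w3")])
  top <- max.col(wm, ties.method = "first")
  wm[] <- 0
  wm[cbind(seq_len(nrow(wm)), top)] <- 1
  table$w1 <- wm[, 1]; table$w2 <- wm[, 2]; table$w3 <- wm[, 3]
  table
}

#' Read / write quartet weight tables as TSV
#'
#' Columns: `t1 t2 t3 t4 w1 w2 w3 method tag`, with weights in the canonical
#' split order of the sorted taxon quadruple.
#'
#' @param table a `quartet_weight_table`.
#' @param path file path.
#' @export
write_weights <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(rep("character", 4),
                                         rep("numeric", 3),
                                         rep("character", 2)))
  taxa <- sort(unique(unlist(df[, 1:4])))
  Q <- apply(matrix(match(as.matrix(df[, 1:4]), taxa), ncol = 4L), 1L, sort)
  new_weight_table(taxa, Q, as.matrix(df[, c("w1", "w2", "w3")]),
                   df$method[1], df$tag)
}

#' Export a weight table in wQFM input format
#'
#' One weighted quartet Newick per line, three lines per 4-subset (one per
#' split): `((a,b),(c,d)); w`.
#'
#' @param table a `quartet_weight_table`.
#' @param path output path.
#' @export
export_wqfm <- function(table, path) {
  pairs <- list(c(1L, 2L, 3L, 4L), c(1L, 3L, 2L, 4L), c(1L, 4L, 2L, 3L))
  tx <- as.matrix(table[, c("t1", "t2", "t3", "t4")])
  out <- character(3L * nrow(table))
  wcols <- c("w1", "w2", "w3")
  i <- 0L
  for (r in seq_len(nrow(table))) {
    for (s in 1:3) {
      pr <- pairs[[s]]
      i <- i + 1L
      out[i] <- sprintf("((%s,%s),(%s,%s)); %.10g",
                        tx[r, pr[1]], tx[r, pr[2]], tx[r, pr[3]], tx[r, pr[4]],
                        table[[wcols[s]]][r])
    }
  }
  writeLines(out, path)
  invisible(path)
}
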