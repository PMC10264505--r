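## Shared fixture builders: everything is generated in code at test time.

## small alignment from raw strings
aln_from_strings <- function(seqs, taxa = paste0("t", seq_along(seqs))) {
  asaq:::new_alignment(taxa, seqs)
}

## write a temporary FASTA and return its path
tmp_fasta <- function(seqs, taxa = paste0("t", seq_along(seqs))) {
  path <- tempfile(fileext = ".fa")
  writeLines(as.vector(rbind(paste0(">", taxa), seqs)), path)
  path
}

tmp_phylip <- function(seqs, taxa = paste0("t", seq_along(seqs))) {
  path <- tempfile(fileext = ".phy")
  writeLines(c(paste(length(seqs), nchar(seqs[1])),
               paste(taxa, seqs)), path)
  path
}

## a random (Dirichlet) pattern distribution
random_pattern_dist <- function(concentration = 1) {
  v <- stats::rgamma(256, concentration)
  asaq:::new_pattern_dist(v / sum(v))
}

## random quartet GM instance with comfortable branch lengths
random_quartet_instance <- function(split = "12|34",
                                    pendant_range = c(0.05, 1),
                                    interior_range = c(0.05, 0.5)) {
  gm_quartet(stats::runif(4, pendant_range[1], pendant_range[2]),
             stats::runif(1, interior_range[1], interior_range[2]),
             split = split)
}

expect_weight_triple <- function(w) {
  expect_s3_class(w, "quartet_weights")
  expect_length(w$weights, 3L)
  expect_true(all(w$weights > 0))
  expect_equal(sum(w$weights), 1, tolerance = 1e-12)
  expect_true(w$topology %in% QUARTET_SPLITS)
}
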