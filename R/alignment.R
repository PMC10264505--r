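#' Read a multiple sequence alignment
#'
#' Reads DNA alignments in FASTA or (relaxed sequential) PHYLIP format.
#' Sequences must all have the same length; taxon labels must be unique.
#' Characters outside `{A,C,G,T}` (case-insensitive) are kept as missing and
#' handled downstream by column dropping.
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip"`.
#' @return an object of class `dna_alignment`: list with `taxa` (character),
#'   `seq` (integer matrix, taxa x sites, codes A=1,C=2,G=3,T=4, `NA` for
#'   gaps/ambiguities), `char` (character matrix of the raw symbols) and
#'   `length` (site count).
#' @export
read_alignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("format error: empty alignment file ", path)
  if (format == "fasta") {
    hdr <- grep("^>", lines)
    if (length(hdr) == 0L) stop("format error: no FASTA headers in ", path)
    taxa <- sub("^>\\s*", "", lines[hdr])
    taxa <- sub("\\s.*$", "", taxa)
    ends <- c(hdr[-1] - 1L, length(lines))
    seqs <- vapply(seq_along(hdr), function(i) {
      if (hdr[i] + 1L > ends[i]) return("")
      paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
    }, character(1))
  } else {
    head <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
    if (length(head) < 2L || anyNA(head[1:2]))
      stop("format error: bad PHYLIP header in ", path)
    ntax <- head[1]; nsite <- head[2]
    body <- lines[-1]
    if (length(body) < ntax) stop("format error: fewer rows than taxa in ", path)
    taxa <- character(ntax); seqs <- character(ntax)
    for (i in seq_len(ntax)) {
      tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
      taxa[i] <- tok[1]
      seqs[i] <- paste(tok[-1], collapse = "")
    }
    ## sequel lines (wrapped sequences) are appended in taxon order
    extra <- body[-seq_len(ntax)]
    if (length(extra)) {
      for (k in seq_along(extra)) {
        i <- (k - 1L) %% ntax + 1L
        seqs[i] <- paste0(seqs[i], gsub("\\s+", "", extra[k]))
      }
    }
    if (any(nchar(seqs) != nsite))
      stop("format error: sequence lengths disagree with PHYLIP header in ", path)
  }
  seqs <- gsub("\\s+", "", seqs)
  new_alignment(taxa, seqs, path)
}

new_alignment <- function(taxa, seqs, origin = NULL) {
  if (anyDuplicated(taxa)) stop("format error: duplicated taxon labels")
  n <- nchar(seqs)
  if (length(unique(n)) != 1L)
    stop("format error: alignment rows have unequal lengths (",
         paste(sort(unique(n)), collapse = ", "), ")")
  if (n[1] < 1L) stop("format error: alignment has zero sites")
  ch <- matrix(unlist(strsplit(toupper(seqs), "")), nrow = length(taxa),
               byrow = TRUE)
  code <- matrix(match(ch, NUC), nrow = length(taxa))
  rownames(ch) <- rownames(code) <- taxa
  structure(list(taxa = taxa, seq = code, char = ch, length = n[1],
                 origin = origin),
            class = "dna_alignment")
}

## Build an alignment directly from an integer state matrix (simulator path).
alignment_from_codes <- function(codes, taxa) {
  rownames(codes) <- taxa
  structure(list(taxa = taxa, seq = codes,
                 char = matrix(NUC[codes], nrow = nrow(codes),
                               dimnames = list(taxa, NULL)),
                 length = ncol(codes), origin = "simulated"),
            class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("DNA alignment:", length(x$taxa), "taxa,", x$length, "sites\n")
  show <- utils::head(x$taxa, 6)
  for (t in show)
    cat(sprintf("  %-12s %s%s\n", t,
                paste(x$char[t, seq_len(min(40, x$length))], collapse = ""),
                if (x$length > 40) "..." else ""))
  if (length(x$taxa) > 6) cat("  ...\n")
  invisible(x)
}

#' Write an alignment as FASTA
#' @param aln a `dna_alignment`.
#' @param path output file path.
#' @export
write_fasta <- function(aln, path) {
  out <- character(2L * length(aln$taxa))
  out[c(TRUE, FALSE)] <- paste0(">", aln$taxa)
  out[c(FALSE, TRUE)] <- apply(aln$char, 1L, paste, collapse = "")
  writeLines(out, path)
  invisible(path)
}
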