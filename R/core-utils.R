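#' @importFrom stats cor median optimize pnorm qbinom rnorm runif sd var
#' @importFrom utils combn read.table write.table
NULL

## 20 standard amino acids, fixed order used by all scoring matrices
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Convert an amino-acid string to integer codes
#'
#' Codes index the fixed 20-letter alphabet used by the scoring matrices;
#' `X` (or any non-standard letter) maps to `NA` and scores zero.
#'
#' @param s character scalar, amino-acid sequence.
#' @return integer vector of codes in `1:20` (or `NA`).
#' @keywords internal
aa_to_int <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1]], AA20)
}

## rows = sequences (all the same length), cols = positions
aa_matrix <- function(seqs) {
  n <- length(seqs)
  L <- unique(nchar(seqs))
  stopifnot(length(L) == 1L)
  m <- matrix(match(unlist(strsplit(seqs, "", fixed = TRUE)), AA20),
              nrow = n, ncol = L, byrow = TRUE)
  m
}

#' Write a table as TSV with a seed provenance header
#'
#' All generated tables carry a `#seed=<int>` first line so every synthetic
#' input records how it was produced.
#'
#' @param df data frame.
#' @param path output path.
#' @param seed integer seed recorded in the header.
#' @param extra optional named character vector of extra `#key=value` lines.
#' @return `path`, invisibly.
#' @export
write_tsv_prov <- function(df, path, seed, extra = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("#seed=%d", as.integer(seed)), con)
  if (length(extra)) {
    writeLines(sprintf("#%s=%s", names(extra), unname(extra)), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_prov()]
#'
#' @param path input path.
#' @return data frame; `#key=value` header lines are returned in the
#'   `"provenance"` attribute.
#' @export
read_tsv_prov <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  df <- read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                   header = TRUE, stringsAsFactors = FALSE)
  kv <- sub("^#", "", hdr)
  prov <- sub("^[^=]*=", "", kv)
  names(prov) <- sub("=.*$", "", kv)
  attr(df, "provenance") <- prov
  df
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param seqs named character vector of amino-acid sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path input path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
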