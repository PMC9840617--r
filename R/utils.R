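#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange group_by summarise mutate filter select bind_rows n desc left_join
#' @importFrom stats setNames cor.test hclust cutree as.dist rnorm runif rbinom
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and maps T to U. All sequences stored by the package use the
#' RNA alphabet; DNA-alphabet inputs (annotator tables, printed motifs) are
#' normalized at the boundary.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector over A, C, G, U (other letters preserved
#'   uppercased; validation happens in the consumers that care).
#' @export
rna <- function(x) {
  x <- toupper(x)
  gsub("T", "U", x, fixed = TRUE)
}

#' Reverse-complement an RNA string
#'
#' @param x character vector of RNA strings (A/C/G/U).
#' @return reverse complements, RNA alphabet.
#' @export
rna_revcomp <- function(x) {
  vapply(x, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    comp <- c(A = "U", U = "A", G = "C", C = "G")[chars]
    if (anyNA(comp)) stop("non-RNA letters in ", s, call. = FALSE)
    paste(rev(unname(comp)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

is_rna <- function(x) grepl("^[ACGU]+$", x)

# Attach a per-row parse error log to a result, tRNAscan/GFF3/GenBank parsers
# keep going on malformed rows and report what they skipped.
set_parse_errors <- function(x, errors) {
  attr(x, "parse_errors") <- errors
  x
}

#' Retrieve the per-row parse error log of a parser result
#'
#' @param x a parser result (records or features tibble).
#' @return character vector of skipped-row messages (empty if clean).
#' @export
parse_errors <- function(x) attr(x, "parse_errors") %||% character(0)

# hamming distance between equal-length strings
str_hamming <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  sum(ca != cb)
}
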