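# Shared in-code fixtures: tiny annotation files and record sets built
# programmatically.

trnascan_text <- function(rows) {
  paste(c(
    "Sequence\t\ttRNA\tBounds\ttRNA\tAnti\tIntron Bounds\t",
    "Name    \ttRNA #\tBegin\tEnd  \tType\tCodon\tBegin\tEnd\tScore",
    "--------\t------\t-----\t-----\t----\t-----\t-----\t---\t-----",
    rows
  ), collapse = "\n")
}

scan_row <- function(name, num, begin, end, type, codon, ib = 0, ie = 0,
                     score = 60.0) {
  paste(name, num, begin, end, type, codon, ib, ie, score, sep = "\t")
}

gff3_line <- function(contig, type, start1, end1, strand, attrs) {
  paste(contig, "test", type, start1, end1, ".", strand, ".", attrs, sep = "\t")
}

# a small record set with known census: 2x Met-CAU, 1x Asn-GUU
mini_records <- function() {
  dplyr::bind_rows(
    trna_record("g1", start = 0, end = 72, isotype = "Met", anticodon = "CAU"),
    trna_record("g1", start = 100, end = 172, isotype = "Met", anticodon = "CAU"),
    trna_record("g2", start = 0, end = 72, isotype = "Asn", anticodon = "GUU")
  )
}

# random triplet records for property tests
random_records <- function(n, seed) {
  set.seed(seed)
  acs <- apply(matrix(sample(c("A", "C", "G", "U"), 3 * n, replace = TRUE), n), 1,
               paste, collapse = "")
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    trna_record(paste0("g", sample(3, 1)), start = (i - 1) * 100,
                end = (i - 1) * 100 + 72,
                isotype = anticodon_to_isotype(acs[i]), anticodon = acs[i])
  }))
}

# operon layout from constructed coordinates (the worked spacer example)
spacer_features <- function(shift = 0, strand = "+", genome = "g1") {
  if (strand == "+") {
    dplyr::bind_rows(
      feature_record(genome, start = 1000 + shift, end = 2500 + shift,
                     strand = "+", kind = "rRNA_16S", label = "16S ribosomal RNA"),
      feature_record(genome, start = 2600 + shift, end = 2680 + shift,
                     strand = "+", kind = "tRNA", label = "trnI-GAU",
                     anticodon = "GAU"),
      feature_record(genome, start = 2700 + shift, end = 2780 + shift,
                     strand = "+", kind = "tRNA", label = "trnA-UGC",
                     anticodon = "UGC"),
      feature_record(genome, start = 3000 + shift, end = 5800 + shift,
                     strand = "+", kind = "rRNA_23S", label = "23S ribosomal RNA")
    )
  } else {
    # mirrored around 10000: transcription right-to-left
    m <- function(s, e) c(10000 - e + shift, 10000 - s + shift)
    rows <- list(
      c("rRNA_16S", "16S ribosomal RNA", 1000, 2500, NA),
      c("tRNA", "trnI-GAU", 2600, 2680, "GAU"),
      c("tRNA", "trnA-UGC", 2700, 2780, "UGC"),
      c("rRNA_23S", "23S ribosomal RNA", 3000, 5800, NA)
    )
    dplyr::bind_rows(lapply(rows, function(r) {
      iv <- m(as.integer(r[3]), as.integer(r[4]))
      feature_record(genome, start = iv[1], end = iv[2], strand = "-",
                     kind = r[1], label = r[2],
                     anticodon = if (is.na(r[5])) NA_character_ else r[5])
    }))
  }
}

# brute-force longest-common-substring oracle: enumerate every substring of
# every input, intersect the sets, take the longest (leftmost on the first)
lcs_oracle <- function(xs, min_len = 10) {
  subs <- function(s) {
    n <- nchar(s)
    out <- character(0)
    for (i in seq_len(n)) for (j in i:n) out <- c(out, substr(s, i, j))
    unique(out)
  }
  common <- Reduce(intersect, lapply(xs, subs))
  common <- common[nchar(common) >= min_len]
  if (!length(common)) return(NULL)
  best_len <- max(nchar(common))
  cand <- common[nchar(common) == best_len]
  # leftmost on the first input
  pos <- vapply(cand, function(cc) regexpr(cc, xs[1], fixed = TRUE)[1], numeric(1))
  cand[which.min(pos)]
}
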