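# Normalized record model shared by every pipeline stage.
#
# Coordinates are 0-based half-open on the forward strand throughout the
# package; every parser converts at the boundary. Intron intervals are
# 0-based half-open positions in the unspliced gene, 5'->3' on the gene's
# own strand, serialized as "begin-end" joined by ";" ("" = no intron).

#' Standard tRNA isotypes
#'
#' The 20 canonical amino-acid isotypes, in alphabetical order.
#' Special isotypes handled alongside them are `fMet`, `Ile2`, `Sec`,
#' `Pyl`, `Sup` and `Undet`.
#'
#' @export
STANDARD_ISOTYPES <- c(
  "Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
  "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val"
)

SPECIAL_ISOTYPES <- c("fMet", "Ile2", "Sec", "Pyl", "Sup", "Undet")

RECORD_COLUMNS <- c(
  "genome_id", "contig", "start", "end", "strand", "isotype", "anticodon",
  "anticodon_offset", "gene_seq", "mature_seq", "introns", "source",
  "score", "supports", "discordant"
)

#' Construct a single annotated tRNA gene record
#'
#' @param genome_id,contig identifiers.
#' @param start,end 0-based half-open interval on the forward strand
#'   (`start < end`).
#' @param strand `"+"` or `"-"`.
#' @param isotype amino-acid isotype (`Ala`...`Val`, `fMet`, `Ile2`, `Sec`,
#'   `Pyl`, `Sup`, `Undet`).
#' @param anticodon RNA string of length 2-4 (anomalous lengths are allowed
#'   here and routed to [screen_records()] downstream).
#' @param anticodon_offset 0-based position of the anticodon within the
#'   mature sequence, or `NA`.
#' @param gene_seq unspliced gene sequence (RNA, gene strand), or `NA`.
#' @param mature_seq intron-free sequence (RNA), or `NA`.
#' @param introns list of `c(begin, end)` 0-based half-open intervals in the
#'   unspliced gene, or an already-serialized `"b-e;b-e"` string.
#' @param source annotator: `trnascan`, `aragorn`, `geseq` or `synthetic`.
#' @param score annotator score or `NA`.
#' @return a one-row records tibble (see [trna_records()]).
#' @export
trna_record <- function(genome_id, contig = genome_id, start, end, strand = "+",
                        isotype, anticodon, anticodon_offset = NA_integer_,
                        gene_seq = NA_character_, mature_seq = NA_character_,
                        introns = "", source = "synthetic", score = NA_real_) {
  if (is.list(introns) || is.numeric(introns)) introns <- serialize_introns(introns)
  trna_records(tibble(
    genome_id = genome_id, contig = contig,
    start = as.integer(start), end = as.integer(end), strand = strand,
    isotype = isotype, anticodon = rna(anticodon),
    anticodon_offset = as.integer(anticodon_offset),
    gene_seq = if (is.na(gene_seq)) gene_seq else rna(gene_seq),
    mature_seq = if (is.na(mature_seq)) mature_seq else rna(mature_seq),
    introns = introns, source = source, score = as.numeric(score),
    supports = source, discordant = FALSE
  ))
}

serialize_introns <- function(introns) {
  if (is.numeric(introns)) introns <- list(introns)
  if (length(introns) == 0) return("")
  paste(vapply(introns, function(iv) paste0(iv[1], "-", iv[2]), character(1)),
        collapse = ";")
}

#' Parse the serialized intron field of a record
#'
#' @param introns a `"begin-end;begin-end"` string (0-based half-open,
#'   gene-relative); `""` or `NA` means no intron.
#' @return list of integer `c(begin, end)` pairs.
#' @export
parse_introns <- function(introns) {
  if (is.na(introns) || !nzchar(introns)) return(list())
  lapply(strsplit(introns, ";", fixed = TRUE)[[1]], function(p) {
    as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
  })
}

#' Validate and canonicalize a tibble of tRNA gene records
#'
#' Checks the record invariants: `start < end`, strand symbols, anticodon
#' length 2-4 over the RNA alphabet, intron intervals disjoint and inside
#' the gene, and (when both present) that `mature_seq` carries the anticodon
#' at `anticodon_offset`.
#'
#' @param df a data frame with the record columns (missing optional columns
#'   are filled with defaults).
#' @return the canonicalized records tibble, columns in standard order.
#' @export
trna_records <- function(df) {
  df <- as_tibble(df)
  if (!"contig" %in% names(df)) df$contig <- df$genome_id
  if (!"anticodon_offset" %in% names(df)) df$anticodon_offset <- NA_integer_
  if (!"gene_seq" %in% names(df)) df$gene_seq <- NA_character_
  if (!"mature_seq" %in% names(df)) df$mature_seq <- NA_character_
  if (!"introns" %in% names(df)) df$introns <- ""
  if (!"score" %in% names(df)) df$score <- NA_real_
  if (!"supports" %in% names(df)) df$supports <- df$source
  if (!"discordant" %in% names(df)) df$discordant <- FALSE
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$anticodon_offset <- as.integer(df$anticodon_offset)
  df$score <- as.numeric(df$score)
  df$introns[is.na(df$introns)] <- ""
  df <- df[, RECORD_COLUMNS]

  if (any(df$start >= df$end)) stop("record with start >= end", call. = FALSE)
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'", call. = FALSE)
  bad_ac <- !grepl("^[ACGU]{2,4}$", df$anticodon)
  if (any(bad_ac)) {
    stop("invalid anticodon(s): ", paste(unique(df$anticodon[bad_ac]), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    ivs <- parse_introns(df$introns[i])
    if (length(ivs)) {
      m <- do.call(rbind, ivs)
      m <- m[order(m[, 1]), , drop = FALSE]
      if (any(m[, 1] >= m[, 2])) stop("degenerate intron interval in row ", i, call. = FALSE)
      if (nrow(m) > 1 && any(m[-1, 1] < m[-nrow(m), 2]))
        stop("overlapping intron intervals in row ", i, call. = FALSE)
      gene_len <- df$end[i] - df$start[i]
      if (max(m[, 2]) > gene_len)
        stop("intron interval outside gene in row ", i, call. = FALSE)
    }
    if (!is.na(df$anticodon_offset[i]) && !is.na(df$mature_seq[i])) {
      off <- df$anticodon_offset[i]
      ac <- df$anticodon[i]
      got <- substr(df$mature_seq[i], off + 1, off + nchar(ac))
      if (!identical(got, ac))
        stop("mature_seq does not carry anticodon at offset in row ", i, call. = FALSE)
    }
  }
  df
}

#' Write records to the package's normalized TSV
#'
#' Column order is the documented record order; `NA` is written as the empty
#' string for sequence fields and `NA` for numerics. [read_records_tsv()]
#' round-trips exactly.
#'
#' @param records a records tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_records_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read records from the normalized TSV
#'
#' @param path file written by [write_records_tsv()].
#' @return validated records tibble.
#' @export
read_records_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "NA",
                          colClasses = "character", check.names = FALSE)
  df <- as_tibble(df)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$anticodon_offset <- as.integer(df$anticodon_offset)
  df$score <- as.numeric(df$score)
  df$discordant <- as.logical(df$discordant)
  df$introns[is.na(df$introns)] <- ""
  trna_records(df)
}

#' Construct a genomic feature record (tRNA/rRNA/other)
#'
#' @param genome_id,contig identifiers.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @param kind one of `tRNA`, `rRNA_16S`, `rRNA_23S`, `rRNA_other`, `other`.
#' @param label free-text label (e.g. `"trnA-UGC"`, `"16S ribosomal RNA"`).
#' @param anticodon RNA anticodon when parseable from the label, else `NA`.
#' @param introns serialized intron evidence (as in records), default `""`.
#' @return one-row feature tibble.
#' @export
feature_record <- function(genome_id, contig = genome_id, start, end,
                           strand = "+", kind = "other", label = "",
                           anticodon = NA_character_, introns = "") {
  tibble(
    genome_id = genome_id, contig = contig,
    start = as.integer(start), end = as.integer(end), strand = strand,
    kind = kind, label = label,
    anticodon = if (is.na(anticodon)) anticodon else rna(anticodon),
    introns = introns
  )
}

empty_features <- function() {
  feature_record("x", start = 0, end = 1)[0, ]
}

# default label patterns classifying rRNA subtypes
RRNA_PATTERNS <- list(
  rRNA_16S = "16S|rrn16",
  rRNA_23S = "23S|rrn23"
)

classify_rrna <- function(label, patterns = RRNA_PATTERNS) {
  for (kind in names(patterns)) {
    if (grepl(patterns[[kind]], label, ignore.case = TRUE)) return(kind)
  }
  "rRNA_other"
}

# pull an anticodon out of a "trnA-UGC" / "tRNA-Asn (GUU)" style label
label_anticodon <- function(label) {
  m <- regmatches(label, regexpr("trn[A-Za-z]{1,4}[-_]([ACGTUacgtu]{2,4})", label))
  if (length(m)) {
    return(rna(sub("^trn[A-Za-z]{1,4}[-_]", "", m)))
  }
  m <- regmatches(label, regexpr("\\(([ACGTUacgtu]{2,4})\\)", label))
  if (length(m)) return(rna(gsub("[()]", "", m)))
  NA_character_
}
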