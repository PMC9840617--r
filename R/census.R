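# Pooled anticodon census and its derived classifications: truncated
# percentages, absent/rare anticodon classes, special isotypes and
# parasite-genome screens.

ALL_TRIPLETS <- {
  b <- c("A", "C", "G", "U")
  apply(expand.grid(b, b, b)[, 3:1], 1, paste, collapse = "")
}

AA_TO_ISOTYPE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val"
)

#' Default resolution of stop-codon-decoding anticodons
#'
#' UCA pairs the UGA stop codon and is read as selenocysteine, CUA pairs
#' UAG and is read as pyrrolysine, UUA pairs UAA and is read as a
#' suppressor; each of the first two is also a valid suppressor assignment,
#' which callers can select by overriding the map.
#'
#' @export
DEFAULT_SPECIAL_MAP <- c(UCA = "Sec", CUA = "Pyl", UUA = "Sup")

#' Map a triplet anticodon to its amino-acid isotype
#'
#' The anticodon is reverse-complemented to its Watson-Crick codon and
#' translated with NCBI genetic code table 11 (bacterial/plastid). Anticodons
#' pairing stop codons resolve through `special_map`. `CAU` resolves to Met
#' by default; when the annotator's own isotype call is `fMet` or `Ile2`
#' (passed as `annotated`), that call wins, since the genetic code cannot
#' distinguish the three CAU isotypes.
#'
#' @param anticodon RNA triplet (5'->3').
#' @param special_map named character vector anticodon -> isotype for
#'   stop-decoding anticodons; default [DEFAULT_SPECIAL_MAP].
#' @param annotated optional annotator-assigned isotype used to resolve CAU.
#' @return isotype string.
#' @export
anticodon_to_isotype <- function(anticodon, special_map = DEFAULT_SPECIAL_MAP,
                                 annotated = NA_character_) {
  if (!is_rna(anticodon)) stop("non-RNA letters in anticodon '", anticodon, "'", call. = FALSE)
  if (nchar(anticodon) != 3) {
    stop("anticodon '", anticodon, "' has length ", nchar(anticodon),
         "; non-triplet anticodons are handled by the anomalies module", call. = FALSE)
  }
  if (anticodon == "CAU" && !is.na(annotated) && annotated %in% c("fMet", "Ile2")) {
    return(annotated)
  }
  if (anticodon %in% names(special_map)) return(unname(special_map[[anticodon]]))
  codon <- rna_revcomp(anticodon)
  code <- Biostrings::getGeneticCode("11")
  aa <- unname(code[gsub("U", "T", codon)])
  if (is.na(aa) || aa == "*") {
    stop("anticodon ", anticodon, " decodes a stop codon with no special mapping",
         call. = FALSE)
  }
  unname(AA_TO_ISOTYPE[aa])
}

#' Build the pooled anticodon census from tRNA records
#'
#' Counts records by (isotype, anticodon). Annotator-assigned special
#' isotypes (fMet, Ile2, Sec, Pyl, Sup) are kept as distinct rows, as in a
#' pooled anticodon table; records whose isotype is missing/Undet fall back
#' to the genetic-code mapping. Records with non-triplet anticodons are
#' excluded from the census (they belong to [screen_records()]); their
#' number is available as `attr(x, "n_excluded")`.
#'
#' @param records records tibble.
#' @param special_map stop-decoding anticodon resolution, see
#'   [anticodon_to_isotype()].
#' @return an `anticodon_table`: list with `counts` (tibble isotype,
#'   anticodon, count), `total` and `genome_count`.
#' @export
build_table <- function(records, special_map = DEFAULT_SPECIAL_MAP) {
  records <- as_tibble(records)
  keep <- nchar(records$anticodon) == 3L
  n_excluded <- sum(!keep)
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec)) {
    iso <- vapply(seq_len(nrow(rec)), function(i) {
      a <- rec$isotype[i]
      if (!is.na(a) && a %in% c(STANDARD_ISOTYPES, "fMet", "Ile2", "Sec", "Pyl", "Sup")) a
      else anticodon_to_isotype(rec$anticodon[i], special_map)
    }, character(1))
    counts <- tibble(isotype = iso, anticodon = rec$anticodon) |>
      dplyr::count(isotype, anticodon, name = "count") |>
      arrange(isotype, anticodon)
  } else {
    counts <- tibble(isotype = character(), anticodon = character(),
                     count = integer())
  }
  out <- structure(
    list(counts = counts, total = sum(counts$count),
         genome_count = length(unique(rec$genome_id))),
    class = "anticodon_table"
  )
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Assemble an anticodon table from explicit counts
#'
#' @param counts tibble/data frame with columns isotype, anticodon, count.
#' @param genome_count number of genomes pooled (metadata).
#' @return `anticodon_table` object.
#' @export
anticodon_table <- function(counts, genome_count = NA_integer_) {
  counts <- as_tibble(counts)
  stopifnot(all(c("isotype", "anticodon", "count") %in% names(counts)))
  counts$anticodon <- rna(counts$anticodon)
  counts$count <- as.integer(counts$count)
  if (any(counts$count < 0)) stop("negative census count", call. = FALSE)
  structure(
    list(counts = counts[, c("isotype", "anticodon", "count")],
         total = sum(counts$count), genome_count = genome_count),
    class = "anticodon_table"
  )
}

#' @export
print.anticodon_table <- function(x, ...) {
  cat("Anticodon census:", nrow(x$counts), "(isotype, anticodon) cells,",
      "total", x$total, "tRNA genes")
  if (!is.na(x$genome_count)) cat(" across", x$genome_count, "genomes")
  cat("\n")
  print(x$counts, n = 10)
  invisible(x)
}

table_count <- function(table, isotype, anticodon) {
  hit <- table$counts$isotype == isotype & table$counts$anticodon == rna(anticodon)
  if (!any(hit)) 0L else sum(table$counts$count[hit])
}

#' Census percentage of one (isotype, anticodon) cell, truncated
#'
#' Computes `100 * count / total` and truncates (floors) at the second
#' decimal; values are *not* rounded. The denominator is the table's own
#' total (the sum of all cells).
#'
#' @param table an `anticodon_table`.
#' @param isotype,anticodon the cell key.
#' @return truncated percentage (e.g. `5.47`).
#' @export
percentage <- function(table, isotype, anticodon) {
  if (table$total == 0) stop("empty census", call. = FALSE)
  count <- table_count(table, isotype, anticodon)
  trunc2_pct(count, table$total)
}

# floor(100 * count/total, 2 decimals) without float drift: integer division
trunc2_pct <- function(count, total) {
  ((as.numeric(count) * 10000) %/% as.numeric(total)) / 100
}

#' Classify anticodons as absent, rare or abundant
#'
#' `absent` holds the anticodons (over the full 64-triplet space) whose
#' count summed over isotypes is zero. `rare` is computed per
#' (isotype, anticodon) cell — a cell with count in `[1, rare_max]` flags
#' its anticodon as rare even when another isotype uses the same anticodon
#' abundantly (the suppressor-UCA case: 2 suppressor genes are rare although
#' selenocysteine-UCA has 204). `abundant` holds the cells whose truncated
#' percentage is at least `abundant_min_pct`.
#'
#' @param table an `anticodon_table`.
#' @param rare_max largest count still called rare (default 25).
#' @param abundant_min_pct abundance threshold in percent (default 5.0).
#' @return list with `absent` (character), `rare` (named integer vector,
#'   anticodon -> rare-cell count) and `abundant` (tibble isotype,
#'   anticodon, percentage).
#' @export
rarity_report <- function(table, rare_max = 25, abundant_min_pct = 5.0) {
  by_ac <- setNames(rep(0L, length(ALL_TRIPLETS)), ALL_TRIPLETS)
  cs <- table$counts
  trip <- cs[nchar(cs$anticodon) == 3, , drop = FALSE]
  agg <- tapply(trip$count, trip$anticodon, sum)
  by_ac[names(agg)] <- as.integer(agg)
  absent <- sort(names(by_ac)[by_ac == 0L])

  rare_cells <- trip[trip$count >= 1 & trip$count <= rare_max, , drop = FALSE]
  if (nrow(rare_cells)) {
    rare <- tapply(rare_cells$count, rare_cells$anticodon, sum)
    rare <- setNames(as.integer(rare), names(rare))
    rare <- rare[order(names(rare))]
  } else {
    rare <- setNames(integer(0), character(0))
  }

  pct <- vapply(seq_len(nrow(trip)), function(i) trunc2_pct(trip$count[i], table$total),
                numeric(1))
  abundant <- trip[pct >= abundant_min_pct, c("isotype", "anticodon"), drop = FALSE]
  abundant$percentage <- pct[pct >= abundant_min_pct]
  list(absent = absent, rare = rare, abundant = as_tibble(abundant))
}

#' Union of per-species anticodon repertoires
#'
#' @param per_species named list: species -> character vector of anticodons.
#' @return sorted character vector of the union (RNA alphabet).
#' @export
anticodon_union <- function(per_species) {
  sort(unique(rna(unlist(per_species, use.names = FALSE))))
}

#' Screen genomes with few or no tRNA genes
#'
#' @param per_genome_counts named integer vector or tibble
#'   (genome_id, count).
#' @param threshold genomes with `count < threshold` are reported
#'   (default 10).
#' @return tibble (genome_id, count, total_loss), ascending by count;
#'   `total_loss` flags count-zero genomes.
#' @export
low_trna_genomes <- function(per_genome_counts, threshold = 10) {
  if (!is.data.frame(per_genome_counts)) {
    per_genome_counts <- tibble(genome_id = names(per_genome_counts),
                                count = as.integer(per_genome_counts))
  }
  out <- per_genome_counts[per_genome_counts$count < threshold, , drop = FALSE]
  out <- out[order(out$count, out$genome_id), , drop = FALSE]
  out$total_loss <- out$count == 0L
  as_tibble(out)
}

#' Per-genome tRNA gene counts from records
#'
#' @param records records tibble.
#' @param genomes optional character vector of all genome ids, so genomes
#'   with zero annotated tRNAs appear with count 0.
#' @return named integer vector genome_id -> count.
#' @export
per_genome_counts <- function(records, genomes = NULL) {
  counts <- table(records$genome_id)
  out <- setNames(as.integer(counts), names(counts))
  if (!is.null(genomes)) {
    missing <- setdiff(genomes, names(out))
    out <- c(out, setNames(rep(0L, length(missing)), missing))
    out <- out[genomes]
  }
  out
}

#' Write a census to TSV (isotype, anticodon, count, percentage)
#'
#' @param table an `anticodon_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_census_tsv <- function(table, path) {
  cs <- table$counts
  cs$percentage <- vapply(seq_len(nrow(cs)),
                          function(i) trunc2_pct(cs$count[i], table$total),
                          numeric(1))
  utils::write.table(cs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render a census and rarity summary as Markdown
#'
#' A compact, anticodon-table-shaped report: per-isotype rows of
#' `anticodon: count` cells, the total, and the absent/rare classes.
#'
#' @param table an `anticodon_table`.
#' @param rare_max,abundant_min_pct passed to [rarity_report()].
#' @return character vector of Markdown lines.
#' @export
census_report_md <- function(table, rare_max = 25, abundant_min_pct = 5.0) {
  rr <- rarity_report(table, rare_max, abundant_min_pct)
  lines <- c("# Anticodon census", "",
             sprintf("Total tRNA genes: %d", table$total), "",
             "| Isotype | Anticodon counts |", "|---|---|")
  for (iso in unique(table$counts$isotype)) {
    cells <- table$counts[table$counts$isotype == iso, , drop = FALSE]
    lines <- c(lines, sprintf("| %s | %s |", iso,
                              paste(sprintf("%s: %d", cells$anticodon, cells$count),
                                    collapse = ", ")))
  }
  lines <- c(lines, "",
             sprintf("Absent anticodons (%d): %s", length(rr$absent),
                     paste(rr$absent, collapse = ", ")),
             sprintf("Rare anticodons (count <= %d): %s", rare_max,
                     paste(sprintf("%s (%d)", names(rr$rare), rr$rare), collapse = ", ")),
             sprintf("Abundant cells (>= %.2f%%): %s", abundant_min_pct,
                     paste(sprintf("%s-%s (%.2f%%)", rr$abundant$isotype,
                                   rr$abundant$anticodon, rr$abundant$percentage),
                           collapse = ", ")))
  lines
}
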