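# Detection of putative spacer tRNAs: tRNA genes lying between the 16S and
# 23S rRNA genes of an rRNA operon, as in the bacterial-type plastid operon.

#' Detect spacer tRNAs between 16S and 23S rRNA genes
#'
#' For every same-strand 16S/23S pair whose inner gap is at most
#' `max_operon_gap`, the pair is oriented transcriptionally (16S upstream on
#' its strand) and the tRNA features wholly contained in the open gap are
#' reported in transcriptional order. A pair with zero contained tRNAs still
#' yields a call with an empty spacer list (genomes lacking spacer tRNAs are
#' informative). Both inverted-repeat operon copies are reported
#' independently. 16S genes with no same-strand 23S partner within the gap
#' limit produce no call and are logged in `attr(x, "unpaired")`.
#'
#' @param features feature tibble with classified `rRNA_16S`, `rRNA_23S`
#'   and `tRNA` rows (any genomes mixed).
#' @param max_operon_gap largest allowed inner gap in nt (default 10000).
#' @return tibble of calls: genome_id, contig, strand, 16S/23S coordinates,
#'   `n_spacers`, `spacers` (list column of tRNA feature tibbles in
#'   transcriptional order) and `gaps` (list column: 16S->first tRNA,
#'   between tRNAs, last tRNA->23S).
#' @export
detect_spacers <- function(features, max_operon_gap = 10000) {
  features <- as_tibble(features)
  calls <- list()
  unpaired <- character(0)
  keys <- split(seq_len(nrow(features)),
                paste(features$genome_id, features$contig, features$strand, sep = "\r"))
  for (idx in keys) {
    grp <- features[idx, , drop = FALSE]
    r16 <- grp[grp$kind == "rRNA_16S", , drop = FALSE]
    r23 <- grp[grp$kind == "rRNA_23S", , drop = FALSE]
    trna <- grp[grp$kind == "tRNA", , drop = FALSE]
    if (!nrow(r16)) next
    strand <- grp$strand[1]
    for (i in seq_len(nrow(r16))) {
      # transcriptional downstream: + strand -> 23S to the right of 16S end;
      # - strand -> 23S to the left of 16S start
      if (strand == "+") {
        cand <- r23[r23$start >= r16$end[i] &
                      r23$start - r16$end[i] <= max_operon_gap, , drop = FALSE]
        if (!nrow(cand)) {
          unpaired <- c(unpaired, sprintf("%s:%s 16S [%d,%d) %s has no 23S partner",
                                          r16$genome_id[i], r16$contig[i],
                                          r16$start[i], r16$end[i], strand))
          next
        }
        part <- cand[which.min(cand$start), , drop = FALSE]
        inner <- c(r16$end[i], part$start)
      } else {
        cand <- r23[r23$end <= r16$start[i] &
                      r16$start[i] - r23$end <= max_operon_gap, , drop = FALSE]
        if (!nrow(cand)) {
          unpaired <- c(unpaired, sprintf("%s:%s 16S [%d,%d) %s has no 23S partner",
                                          r16$genome_id[i], r16$contig[i],
                                          r16$start[i], r16$end[i], strand))
          next
        }
        part <- cand[which.max(cand$end), , drop = FALSE]
        inner <- c(part$end, r16$start[i])
      }
      contained <- trna[trna$start >= inner[1] & trna$end <= inner[2], , drop = FALSE]
      # transcriptional order: ascending on +, descending on -
      if (nrow(contained)) {
        contained <- contained[order(if (strand == "+") contained$start
                                     else -contained$end), , drop = FALSE]
      }
      gaps <- spacer_gaps(inner, contained, strand)
      calls[[length(calls) + 1L]] <- tibble(
        genome_id = r16$genome_id[i], contig = r16$contig[i], strand = strand,
        r16_start = r16$start[i], r16_end = r16$end[i],
        r23_start = part$start, r23_end = part$end,
        n_spacers = nrow(contained),
        spacers = list(contained), gaps = list(gaps)
      )
    }
  }
  out <- if (length(calls)) bind_rows(calls) else tibble(
    genome_id = character(), contig = character(), strand = character(),
    r16_start = integer(), r16_end = integer(), r23_start = integer(),
    r23_end = integer(), n_spacers = integer(),
    spacers = list(), gaps = list()
  )
  attr(out, "unpaired") <- unpaired
  out
}

spacer_gaps <- function(inner, contained, strand) {
  if (!nrow(contained)) return(inner[2] - inner[1])
  if (strand == "+") {
    bounds <- c(inner[1], rbind(contained$start, contained$end), inner[2])
  } else {
    bounds <- c(inner[2], rbind(contained$end, contained$start), inner[1])
  }
  gaps <- numeric(nrow(contained) + 1)
  for (k in seq_along(gaps)) {
    gaps[k] <- abs(bounds[2 * k] - bounds[2 * k - 1])
  }
  gaps
}

#' Summarise spacer tRNA usage across genomes
#'
#' @param calls output of [detect_spacers()].
#' @param records optional records tibble used to resolve isotypes for
#'   spacer tRNAs whose feature label lacks one.
#' @return list with `frequency` (tibble isotype, anticodon, n genomes) and
#'   `fraction_with_spacer` (share of called genomes with >= 1 spacer tRNA).
#' @export
spacer_summary <- function(calls, records = NULL) {
  if (!nrow(calls)) {
    return(list(frequency = tibble(isotype = character(), anticodon = character(),
                                   n = integer()),
                fraction_with_spacer = NA_real_))
  }
  per_genome <- split(calls, calls$genome_id)
  rows <- list()
  for (gid in names(per_genome)) {
    sp <- bind_rows(per_genome[[gid]]$spacers)
    if (!nrow(sp)) next
    iso <- vapply(seq_len(nrow(sp)), function(i) {
      lab <- label_isotype(sp$label[i])
      if (!is.na(lab)) return(lab)
      ac <- sp$anticodon[i]
      if (!is.na(ac) && nchar(ac) == 3) anticodon_to_isotype(ac) else "Undet"
    }, character(1))
    rows[[length(rows) + 1L]] <- unique(tibble(
      genome_id = gid, isotype = iso, anticodon = sp$anticodon
    ))
  }
  freq <- if (length(rows)) {
    bind_rows(rows) |>
      dplyr::count(isotype, anticodon, name = "n") |>
      arrange(desc(n), isotype)
  } else {
    tibble(isotype = character(), anticodon = character(), n = integer())
  }
  genomes_called <- unique(calls$genome_id)
  genomes_with <- unique(calls$genome_id[calls$n_spacers > 0])
  list(frequency = freq,
       fraction_with_spacer = length(genomes_with) / length(genomes_called))
}
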