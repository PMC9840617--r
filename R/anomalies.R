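# Detection of non-canonical anticodon lengths (duplets/quadruplets) and
# attribution of quadruplets to parent triplets by single-nucleotide
# insertion logic.

#' Classify an anticodon by length
#'
#' @param anticodon RNA string.
#' @return `"duplet"`, `"triplet"`, `"quadruplet"` or `"other"`.
#' @export
classify_length <- function(anticodon) {
  n <- nchar(anticodon)
  if (n == 2) "duplet" else if (n == 3) "triplet" else if (n == 4) "quadruplet" else "other"
}

#' Parent-triplet candidates of a quadruplet anticodon
#'
#' Enumerates all four single-base deletions of the quadruplet. Each
#' candidate records the deleted (= putatively inserted) position (1-4) and
#' base, so re-inserting that base reconstructs the quadruplet. The
#' preferred parent follows the insertion-at-position-4 model (a base
#' appended after an ancestral triplet) unless `known` — a set of anticodons
#' actually observed in the genomes at hand — singles out a different
#' candidate as the only known triplet.
#'
#' @param quadruplet RNA string of length 4.
#' @param known optional character vector of known triplet anticodons.
#' @return list with `quadruplet`, `candidates` (tibble parent,
#'   inserted_position, inserted_base) and `preferred_parent`.
#' @export
parent_triplets <- function(quadruplet, known = NULL) {
  quadruplet <- rna(quadruplet)
  if (!is_rna(quadruplet)) stop("non-RNA letters in '", quadruplet, "'", call. = FALSE)
  if (nchar(quadruplet) != 4) stop("expected a 4-mer", call. = FALSE)
  chars <- strsplit(quadruplet, "", fixed = TRUE)[[1]]
  cand <- tibble(
    parent = vapply(1:4, function(p) paste(chars[-p], collapse = ""), character(1)),
    inserted_position = 1:4,
    inserted_base = chars
  )
  preferred <- cand$parent[cand$inserted_position == 4]
  if (!is.null(known)) {
    known <- rna(known)
    in_known <- unique(cand$parent[cand$parent %in% known])
    if (length(in_known) == 1 && !preferred %in% known) preferred <- in_known
  }
  list(quadruplet = quadruplet, candidates = cand, preferred_parent = preferred)
}

#' Duplet-anticodon reconstruction candidates
#'
#' Duplet anticodons are treated as likely single-nucleotide-loss artifacts;
#' all triplets reconstructable by one insertion are reported, and no
#' preferred parent is chosen.
#'
#' @param duplet RNA string of length 2.
#' @return tibble (parent, deleted_position, deleted_base) of all triplets
#'   that yield the duplet by deleting one base.
#' @export
duplet_parents <- function(duplet) {
  duplet <- rna(duplet)
  if (nchar(duplet) != 2 || !is_rna(duplet)) stop("expected an RNA 2-mer", call. = FALSE)
  chars <- strsplit(duplet, "", fixed = TRUE)[[1]]
  rows <- list()
  for (pos in 1:3) {
    for (base in c("A", "C", "G", "U")) {
      parent <- append(chars, base, after = pos - 1)
      rows[[length(rows) + 1L]] <- tibble(
        parent = paste(parent, collapse = ""),
        deleted_position = pos, deleted_base = base
      )
    }
  }
  unique(bind_rows(rows))
}

#' Screen records for anticodon-length anomalies
#'
#' Every record with a non-triplet anticodon produces an anomaly call;
#' triplet records pass through to the census untouched. Together with
#' [build_table()] this accounts for every input record exactly once.
#'
#' @param records records tibble.
#' @param known optional known-anticodon set for parent attribution.
#' @return list with `calls` (tibble: genome_id, contig, start, anticodon,
#'   length_class, preferred_parent, candidates as a `;`-joined string) and
#'   `species_summary` (tibble: genome_id, n_duplet, n_quadruplet).
#' @export
screen_records <- function(records, known = NULL) {
  records <- as_tibble(records)
  anom <- records[nchar(records$anticodon) != 3L, , drop = FALSE]
  if (!nrow(anom)) {
    calls <- tibble(genome_id = character(), contig = character(),
                    start = integer(), anticodon = character(),
                    length_class = character(), preferred_parent = character(),
                    candidates = character())
    return(list(calls = calls,
                species_summary = tibble(genome_id = character(),
                                         n_duplet = integer(),
                                         n_quadruplet = integer())))
  }
  calls <- lapply(seq_len(nrow(anom)), function(i) {
    ac <- anom$anticodon[i]
    cls <- classify_length(ac)
    preferred <- NA_character_
    cand <- ""
    if (cls == "quadruplet") {
      pt <- parent_triplets(ac, known = known)
      preferred <- pt$preferred_parent
      cand <- paste(sprintf("%s@%d%s", pt$candidates$parent,
                            pt$candidates$inserted_position,
                            pt$candidates$inserted_base), collapse = ";")
    } else if (cls == "duplet") {
      dp <- duplet_parents(ac)
      cand <- paste(dp$parent, collapse = ";")
    }
    tibble(genome_id = anom$genome_id[i], contig = anom$contig[i],
           start = anom$start[i], anticodon = ac, length_class = cls,
           preferred_parent = preferred, candidates = cand)
  })
  calls <- bind_rows(calls)
  species_summary <- calls |>
    group_by(genome_id) |>
    summarise(n_duplet = sum(length_class == "duplet"),
              n_quadruplet = sum(length_class == "quadruplet"),
              .groups = "drop")
  list(calls = calls, species_summary = species_summary)
}
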