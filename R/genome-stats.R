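# Per-genome summaries (length, GC, tRNA count, clade) and the GC%-vs-tRNA
# correlation analysis.

CLADES <- c("Algae", "Bryophyte", "Eudicot", "Gymnosperm", "Magnoliids",
            "Monocot", "Nymphaeales", "Protist", "Pteridophyte", "Unknown")

#' GC fraction of a sequence, ambiguity codes excluded
#'
#' `GC = (G + C) / (A + C + G + T/U)`; any other letter (N and the IUPAC
#' ambiguity codes) is excluded from both numerator and denominator.
#'
#' @param seq nucleotide string (DNA or RNA).
#' @return GC fraction in `[0, 1]` (`NaN` for a fully ambiguous sequence).
#' @export
gc_fraction <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  gc <- sum(chars %in% c("G", "C"))
  at <- sum(chars %in% c("A", "T", "U"))
  gc / (gc + at)
}

#' Summarise one genome: length, GC and tRNA count
#'
#' @param genome_id identifier.
#' @param seq genome sequence string.
#' @param records records tibble (rows for other genomes are ignored).
#' @param clade clade label, default `"Unknown"`.
#' @return one-row tibble: genome_id, clade, length_bp, gc_fraction,
#'   trna_count.
#' @export
summarize_genome <- function(genome_id, seq, records, clade = "Unknown") {
  tibble(
    genome_id = genome_id, clade = clade,
    length_bp = nchar(seq),
    gc_fraction = gc_fraction(seq),
    trna_count = sum(records$genome_id == genome_id)
  )
}

#' Pearson correlation with a two-sided t-test p-value
#'
#' Thin, contract-checked wrapper around [stats::cor.test()]: requires
#' `n >= 3` and nonzero variance in both variables.
#'
#' @param x,y numeric vectors of equal length.
#' @return list: `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("degenerate input: zero variance", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Per-clade mean tRNA count and GC
#'
#' @param summaries tibble of genome summaries ([summarize_genome()] rows).
#' @return tibble: clade, n, mean_trna, mean_gc (clades absent from the
#'   input are omitted).
#' @export
clade_report <- function(summaries) {
  summaries |>
    group_by(clade) |>
    summarise(n = n(), mean_trna = mean(trna_count), mean_gc = mean(gc_fraction),
              .groups = "drop")
}
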