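# Packaged reference tables: the pooled anticodon census, the per-isotype
# intron consensus table and the parasite anticodon repertoires, used as
# fixtures by the census/introns modules and as default profiles by the
# synthetic generator.

extdata <- function(file) {
  path <- system.file("extdata", file, package = "cptrna")
  if (!nzchar(path)) path <- file.path("inst", "extdata", file)  # pre-install
  path
}

#' The pooled plastid anticodon census fixture
#'
#' The published pooled (isotype, anticodon) census of 5,959 plastid
#' genomes, packaged verbatim; its cells sum to 214,383.
#'
#' @return an `anticodon_table` (see [anticodon_table()]).
#' @export
table1_fixture <- function() {
  df <- utils::read.table(extdata("anticodon_table1.tsv"), sep = "\t",
                          header = TRUE, comment.char = "#")
  anticodon_table(df, genome_count = 5959L)
}

#' The per-isotype intron consensus fixture
#'
#' The published conserved group I intron consensus per tRNA isotype,
#' packaged in the package's run-length notation; 12 of the 20 standard
#' isotypes carry a consensus, 8 are "Not found". Isotypes printing several
#' consensus lines are stored as lists.
#'
#' @return named list isotype -> list of token tibbles (empty list for
#'   isotypes without a conserved intron).
#' @export
table2_fixture <- function() {
  df <- utils::read.table(extdata("intron_consensus_table2.tsv"), sep = "\t",
                          header = TRUE, comment.char = "#")
  out <- setNames(vector("list", length(STANDARD_ISOTYPES)), STANDARD_ISOTYPES)
  for (iso in STANDARD_ISOTYPES) {
    rows <- df[df$isotype == iso & df$consensus != "Not found", , drop = FALSE]
    out[[iso]] <- lapply(rows$consensus[order(rows$line)], parse_consensus)
  }
  out
}

#' Anticodon repertoires of the low-tRNA parasitic plastomes
#'
#' The per-species anticodon lists printed for the eight parasitic and
#' heterotrophic plastomes encoding fewer than ten tRNA genes.
#'
#' @return named list species -> character vector of anticodons (with
#'   within-species duplicates preserved).
#' @export
parasite_species_anticodons <- function() {
  df <- utils::read.table(extdata("parasite_anticodons.tsv"), sep = "\t",
                          header = TRUE, comment.char = "#")
  split(df$anticodon, df$species)
}

#' The 14 anticodons retained by parasitic plastomes
#'
#' The union of the eight parasite/heterotroph repertoires.
#'
#' @export
PARASITE_ANTICODONS <- c(
  "CAU", "CCA", "GAA", "GCA", "GCU", "GUA", "GUC", "GUG", "GUU",
  "UCC", "UCU", "UUC", "UUG", "UUU"
)
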