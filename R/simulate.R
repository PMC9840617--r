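# Seeded generator of synthetic plastome annotation bundles with full
# ground truth, emulating the statistical structure of a pooled plastome
# cohort: per-clade tRNA gene counts and GC, an anticodon profile matching
# the pooled census, a 16S-tRNA(Ile-GAU)-tRNA(Ala-UGC)-23S operon,
# per-isotype group I introns, planted anticodon-length anomalies, a
# parasite mode restricted to the 14 surviving anticodons, and planted
# tRF/tiRNA fragments with known end classes.

DEFAULT_CLADE_MIX <- c(
  Algae = 303, Bryophyte = 69, Eudicot = 3832, Gymnosperm = 153,
  Magnoliids = 182, Monocot = 1177, Nymphaeales = 34, Protist = 57,
  Pteridophyte = 139, Unknown = 13
) / 5959

DEFAULT_TRNA_MEAN <- c(
  Algae = 30.12, Bryophyte = 36, Eudicot = 36, Gymnosperm = 36,
  Magnoliids = 36, Monocot = 37.8, Nymphaeales = 36, Protist = 29.5,
  Pteridophyte = 36, Unknown = 36
)

DEFAULT_GC_TARGET <- c(
  Algae = 0.32, Bryophyte = 0.33, Eudicot = 0.37, Gymnosperm = 0.39,
  Magnoliids = 0.39, Monocot = 0.38, Nymphaeales = 0.39, Protist = 0.33,
  Pteridophyte = 0.41, Unknown = 0.37
)

#' Default fragment planting plan
#'
#' Plants the two motif-bearing fragment families reported for plastomes —
#' an internal (tRF-1) 19-mer shared by glutamate tRFs and a 5' 22-mer
#' shared by glycine tRFs — plus motif-free 3' tRFs and 5' tiRNA halves.
#'
#' @return list of plant entries (isotype, anticodon, end_class, count,
#'   motif, length_class).
#' @export
default_fragment_plan <- function() {
  list(
    list(isotype = "Glu", anticodon = "UUC", end_class = "tRF1", count = 5,
         motif = "GGCCUUAUCGUCUAGUGAU", length_class = "tRF"),
    list(isotype = "Gly", anticodon = "GCC", end_class = "five_prime", count = 5,
         motif = "GCGGGUAUAGUUUAGUGGUAAA", length_class = "tRF"),
    list(isotype = "His", anticodon = "GUG", end_class = "three_prime", count = 3,
         motif = NULL, length_class = "tRF"),
    list(isotype = "Lys", anticodon = "UUU", end_class = "five_prime", count = 3,
         motif = NULL, length_class = "tiRNA")
  )
}

#' Build a simulation configuration
#'
#' Defaults emulate the pooled-cohort conditions: clade proportions and
#' per-clade mean tRNA counts from the published cohort, plastome-typical
#' GC targets, the pooled census as anticodon profile, the spacer operon
#' present, introns drawn from the per-isotype consensus fixture, and no
#' anomalies or parasite genomes unless requested.
#'
#' @param seed RNG seed (all generator randomness flows from it).
#' @param n_genomes number of genomes.
#' @param clade_mix named proportions over clades (must sum to 1).
#' @param trna_mean named per-clade mean tRNA gene count.
#' @param trna_sd dispersion (normal, rounded) of per-genome counts.
#' @param gc_target named per-clade GC fraction.
#' @param anticodon_profile tibble (isotype, anticodon, count) used as
#'   sampling weights; default the packaged pooled census.
#' @param p_quadruplet,p_duplet per-gene anomaly rates in `[0, 1]`.
#' @param parasite_fraction proportion of genomes restricted to the
#'   14-anticodon parasite repertoire (5-9 genes, no operon).
#' @param spacer_operon place a 16S-Ile-Ala-23S operon in non-parasite
#'   genomes.
#' @param intron_profile named list isotype -> token tibble used to draw
#'   intron sequences; default derived from the consensus fixture.
#' @param intron_rate per-gene intron probability for isotypes with a
#'   profile.
#' @param fragment_plant list of fragment plant entries; default
#'   [default_fragment_plan()].
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_genomes = 10,
                       clade_mix = DEFAULT_CLADE_MIX,
                       trna_mean = DEFAULT_TRNA_MEAN, trna_sd = 3,
                       gc_target = DEFAULT_GC_TARGET,
                       anticodon_profile = NULL,
                       p_quadruplet = 0, p_duplet = 0,
                       parasite_fraction = 0,
                       spacer_operon = TRUE,
                       intron_profile = NULL, intron_rate = 0.3,
                       fragment_plant = default_fragment_plan()) {
  if (abs(sum(clade_mix) - 1) > 1e-8) stop("clade_mix must sum to 1", call. = FALSE)
  for (r in c(p_quadruplet, p_duplet, parasite_fraction, intron_rate)) {
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(anticodon_profile)) anticodon_profile <- table1_fixture()$counts
  if (is.null(intron_profile)) {
    t2 <- table2_fixture()
    intron_profile <- lapply(t2[vapply(t2, length, integer(1)) > 0], `[[`, 1)
  }
  structure(
    list(seed = seed, n_genomes = n_genomes, clade_mix = clade_mix,
         trna_mean = trna_mean, trna_sd = trna_sd, gc_target = gc_target,
         anticodon_profile = anticodon_profile,
         p_quadruplet = p_quadruplet, p_duplet = p_duplet,
         parasite_fraction = parasite_fraction, spacer_operon = spacer_operon,
         intron_profile = intron_profile, intron_rate = intron_rate,
         fragment_plant = fragment_plant),
    class = "sim_config"
  )
}

random_seq <- function(n, gc = 0.37) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# draw one concrete sequence from a consensus token tibble
instantiate_motif <- function(tokens, gc = 0.37) {
  parts <- vapply(seq_len(nrow(tokens)), function(i) {
    t <- tokens[i, ]
    if (t$type == "literal") return(t$bases)
    if (t$type == "choice") {
      return(sample(strsplit(t$bases, "/", fixed = TRUE)[[1]], 1))
    }
    run <- if (t$min == t$max) t$min else sample(seq(t$min, t$max), 1)
    random_seq(run, gc)
  }, character(1))
  paste(parts, collapse = "")
}

MATURE_LEN <- 72L
ANTICODON_OFFSET <- 34L  # 0-based; anticodon occupies positions 35-37 (1-based)
INTRON_AFTER <- 38L      # introns inserted 3' of the anticodon (after base 38)

build_mature <- function(anticodon, gc) {
  body <- strsplit(random_seq(MATURE_LEN, gc), "")[[1]]
  ac <- strsplit(anticodon, "")[[1]]
  body[(ANTICODON_OFFSET + 1):(ANTICODON_OFFSET + length(ac))] <- ac
  paste(body, collapse = "")
}

#' Generate a synthetic plastome cohort with ground truth
#'
#' Deterministic for a fixed `config$seed`. Genomes carry their tRNA genes
#' (some minus-strand), optionally the 16S-tRNA(Ile-GAU)-tRNA(Ala-UGC)-23S
#' spacer operon, per-isotype introns, planted anticodon anomalies
#' (quadruplets built by inserting a base at position 4 of a sampled
#' triplet, duplets by deleting one base), and a parasite mode drawing 5-9
#' genes from the 14-anticodon survivor set without an operon. Planted
#' fragments are embedded with their declared end relationship to a mature
#' tRNA, with reference boundaries forced apart so that motif recovery is
#' exact.
#'
#' @param config a [sim_config()].
#' @return list: `genomes` (named DNA strings), `records` (truth records
#'   tibble), `features` (feature tibble), `fragments` (tibble with true
#'   end classes), `fasta`, `gff3`, `trnascan` (file-content strings) and
#'   `truth` (per-genome counts, anomaly/spacer/intron/fragment truth,
#'   clade table).
#' @export
generate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genomes
  clades <- sample(names(config$clade_mix), n, replace = TRUE,
                   prob = config$clade_mix)
  parasite <- runif(n) < config$parasite_fraction
  gids <- sprintf("SYN%04d", seq_len(n))

  prof <- config$anticodon_profile
  prof <- prof[prof$count > 0, , drop = FALSE]
  pprof <- prof[prof$anticodon %in% PARASITE_ANTICODONS, , drop = FALSE]

  # ---- gene plan ------------------------------------------------------
  plan <- list()
  for (g in seq_len(n)) {
    gc <- config$gc_target[[clades[g]]]
    if (parasite[g]) {
      k <- sample(5:9, 1)
      rows <- pprof[sample.int(nrow(pprof), k, replace = TRUE, prob = pprof$count), ]
    } else {
      k <- max(1L, round(rnorm(1, config$trna_mean[[clades[g]]], config$trna_sd)))
      rows <- prof[sample.int(nrow(prof), k, replace = TRUE, prob = prof$count), ]
      if (config$spacer_operon) {
        # operon tRNAs are part of the genome's complement
        rows <- bind_rows(tibble(isotype = c("Ile", "Ala"),
                                 anticodon = c("GAU", "UGC"), count = 0L),
                          rows)
      }
    }
    rows$genome <- gids[g]
    is_op <- rep(FALSE, nrow(rows))
    if (config$spacer_operon && !parasite[g]) is_op[1:2] <- TRUE
    rows$operon <- is_op
    rows$gc <- gc
    plan[[g]] <- rows[, c("genome", "isotype", "anticodon", "operon", "gc")]
  }
  plan <- bind_rows(plan)
  plan$gene_id <- sprintf("%s.t%03d", plan$genome,
                          stats::ave(seq_len(nrow(plan)), plan$genome, FUN = seq_along))

  # ---- assign fragment plant references -------------------------------
  plan$plant <- NA_integer_
  plants <- config$fragment_plant
  for (pi in seq_along(plants)) {
    p <- plants[[pi]]
    cand <- which(plan$isotype == p$isotype & plan$anticodon == rna(p$anticodon) &
                    is.na(plan$plant) & !plan$operon)
    need <- p$count - length(cand)
    if (need > 0) {
      # append extra genes of the required cell to random non-parasite
      # genomes; with an all-parasite cohort planting is skipped (parasite
      # genomes must keep their < 10-gene complement)
      pool <- gids[!parasite]
      if (!length(pool)) next
      hosts <- pool[sample.int(length(pool), need, replace = TRUE)]
      extra <- tibble(genome = hosts, isotype = p$isotype,
                      anticodon = rna(p$anticodon), operon = FALSE,
                      gc = unname(config$gc_target[clades[match(hosts, gids)]]),
                      gene_id = sprintf("%s.x%02d.%d", hosts, pi, seq_len(need)),
                      plant = NA_integer_)
      plan <- bind_rows(plan, extra)
      cand <- which(plan$isotype == p$isotype & plan$anticodon == rna(p$anticodon) &
                      is.na(plan$plant) & !plan$operon)
    }
    plan$plant[cand[sample.int(length(cand), p$count)]] <- pi
  }

  # ---- anomalies (never on operon or plant genes) ---------------------
  eligible <- !plan$operon & is.na(plan$plant)
  u <- runif(nrow(plan))
  plan$anomaly <- ifelse(eligible & u < config$p_quadruplet, "quadruplet",
                         ifelse(eligible & u >= config$p_quadruplet &
                                  u < config$p_quadruplet + config$p_duplet,
                                "duplet", "none"))

  # ---- build genes ----------------------------------------------------
  ngen <- nrow(plan)
  mature <- character(ngen)
  anticodon_out <- plan$anticodon
  parent_triplet <- rep(NA_character_, ngen)
  for (i in seq_len(ngen)) {
    mature[i] <- build_mature(plan$anticodon[i], plan$gc[i])
  }
  # motif embedding with forced-distinct boundary bases per plant family
  bases4 <- c("A", "C", "G", "U")
  frag_rows <- list()
  for (pi in seq_along(plants)) {
    p <- plants[[pi]]
    refs <- which(!is.na(plan$plant) & plan$plant == pi)
    motif <- if (!is.null(p$motif)) rna(p$motif) else NULL
    for (ri in seq_along(refs)) {
      i <- refs[ri]
      m <- strsplit(mature[i], "")[[1]]
      if (!is.null(motif) && p$end_class == "five_prime") {
        mm <- strsplit(motif, "")[[1]]
        m[seq_along(mm)] <- mm
        # force the base after the motif apart across references
        m[length(mm) + 1] <- bases4[(ri - 1) %% 4 + 1]
        # restore the anticodon if the motif ran over it (it does not at
        # canonical offsets, but keep the invariant under custom plans)
        ac <- strsplit(plan$anticodon[i], "")[[1]]
        m[(ANTICODON_OFFSET + 1):(ANTICODON_OFFSET + length(ac))] <- ac
      } else if (!is.null(motif) && p$end_class == "tRF1") {
        mm <- strsplit(motif, "")[[1]]
        s <- INTRON_AFTER + 2L + ri  # interior start, varies per reference
        m[s:(s + length(mm) - 1)] <- mm
        m[s - 1] <- bases4[(ri - 1) %% 4 + 1]
        m[s + length(mm)] <- bases4[ri %% 4 + 1]
      }
      mature[i] <- paste(m, collapse = "")
      # cut the fragment
      flen_pool <- if (identical(p$length_class, "tiRNA")) 30:36 else 14:29
      if (!is.null(motif)) flen_pool <- max(nchar(motif) + 2, 16):29
      flen <- sample(flen_pool, 1)
      frag <- switch(p$end_class,
        five_prime = substr(mature[i], 1, flen),
        three_prime = substr(mature[i], nchar(mature[i]) - flen + 1, nchar(mature[i])),
        tRF1 = {
          s <- INTRON_AFTER + 2L + ri
          a <- sample(1:2, 1)
          b <- flen - nchar(motif) - a
          # keep the cut strictly interior so the fragment is neither a
          # prefix nor a suffix of its reference
          b <- max(0L, min(b, nchar(mature[i]) - 1L - (s + nchar(motif) - 1L)))
          substr(mature[i], s - a, s + nchar(motif) + b - 1)
        }
      )
      frag_rows[[length(frag_rows) + 1L]] <- tibble(
        fragment_id = sprintf("frag%02d.%d", pi, ri), seq = frag,
        length = nchar(frag), length_class = classify_length_window(nchar(frag)),
        end_class = p$end_class, parent_isotype = p$isotype,
        parent_anticodon = rna(p$anticodon), parent_gene = plan$gene_id[i]
      )
    }
  }
  fragments <- if (length(frag_rows)) bind_rows(frag_rows) else tibble()

  # anomalies mutate the anticodon inside the mature sequence
  for (i in which(plan$anomaly != "none")) {
    ac <- strsplit(plan$anticodon[i], "")[[1]]
    if (plan$anomaly[i] == "quadruplet") {
      newac <- c(ac, sample(bases4, 1))
      parent_triplet[i] <- plan$anticodon[i]
    } else {
      newac <- ac[-sample(1:3, 1)]
    }
    m <- strsplit(mature[i], "")[[1]]
    m <- c(m[1:ANTICODON_OFFSET], newac, m[(ANTICODON_OFFSET + 4):length(m)])
    mature[i] <- paste(m, collapse = "")
    anticodon_out[i] <- paste(newac, collapse = "")
  }

  # introns
  gene_seq <- mature
  introns <- rep("", ngen)
  intron_truth <- list()
  for (i in seq_len(ngen)) {
    iso <- plan$isotype[i]
    if (!is.null(config$intron_profile[[iso]]) && !plan$operon[i] &&
        runif(1) < config$intron_rate) {
      iseq <- instantiate_motif(config$intron_profile[[iso]], plan$gc[i])
      gene_seq[i] <- paste0(substr(mature[i], 1, INTRON_AFTER), iseq,
                            substr(mature[i], INTRON_AFTER + 1, nchar(mature[i])))
      introns[i] <- sprintf("%d-%d", INTRON_AFTER, INTRON_AFTER + nchar(iseq))
      intron_truth[[length(intron_truth) + 1L]] <- tibble(
        genome_id = plan$genome[i], gene_id = plan$gene_id[i], isotype = iso,
        begin = INTRON_AFTER, end = INTRON_AFTER + nchar(iseq), seq = iseq
      )
    }
  }

  # ---- assemble genomes ----------------------------------------------
  rec_rows <- list()
  feat_rows <- list()
  fasta <- character(0)
  gff3 <- c("##gff-version 3")
  scan_rows <- character(0)
  spacer_truth <- list()
  for (g in seq_len(n)) {
    gid <- gids[g]
    gc <- config$gc_target[[clades[g]]]
    idx <- which(plan$genome == gid)
    has_operon <- any(plan$operon[idx])
    op_idx <- idx[plan$operon[idx]]
    rest_idx <- idx[!plan$operon[idx]]
    rest_idx <- rest_idx[sample.int(length(rest_idx))]
    pos <- 0L
    seqparts <- character(0)
    emit <- function(s) {
      seqparts[[length(seqparts) + 1L]] <<- s
      pos <<- pos + nchar(s)
    }
    emit_gene <- function(i, strand) {
      s0 <- pos
      emit(if (strand == "+") gene_seq[i] else rna_revcomp(gene_seq[i]))
      rec_rows[[length(rec_rows) + 1L]] <<- tibble(
        genome_id = gid, contig = gid, start = s0, end = pos, strand = strand,
        isotype = plan$isotype[i], anticodon = anticodon_out[i],
        anticodon_offset = ANTICODON_OFFSET, gene_seq = gene_seq[i],
        mature_seq = mature[i], introns = introns[i], source = "synthetic",
        score = round(runif(1, 40, 110), 1), supports = "synthetic",
        discordant = FALSE, gene_id = plan$gene_id[i]
      )
      feat_rows[[length(feat_rows) + 1L]] <<- feature_record(
        gid, start = s0, end = pos, strand = strand, kind = "tRNA",
        label = paste0("tRNA-", plan$isotype[i]), anticodon = anticodon_out[i])
    }
    emit(random_seq(sample(150:300, 1), gc))
    operon_ac <- character(0)
    if (has_operon) {
      s0 <- pos
      emit(random_seq(1491, gc))
      feat_rows[[length(feat_rows) + 1L]] <- feature_record(
        gid, start = s0, end = pos, strand = "+", kind = "rRNA_16S",
        label = "16S ribosomal RNA")
      for (i in op_idx) {
        emit(random_seq(sample(30:80, 1), gc))
        emit_gene(i, "+")
        operon_ac <- c(operon_ac, anticodon_out[i])
      }
      emit(random_seq(sample(30:80, 1), gc))
      s0 <- pos
      emit(random_seq(2804, gc))
      feat_rows[[length(feat_rows) + 1L]] <- feature_record(
        gid, start = s0, end = pos, strand = "+", kind = "rRNA_23S",
        label = "23S ribosomal RNA")
    }
    for (i in rest_idx) {
      emit(random_seq(sample(100:250, 1), gc))
      emit_gene(i, sample(c("+", "-"), 1))
    }
    emit(random_seq(sample(150:300, 1), gc))
    spacer_truth[[length(spacer_truth) + 1L]] <- tibble(
      genome_id = gid, has_operon = has_operon,
      spacer_anticodons = list(operon_ac)
    )
    genome_seq <- paste(seqparts, collapse = "")
    fasta <- c(fasta, paste0(">", gid), gsub("U", "T", genome_seq))
  }
  records <- trna_records(bind_rows(rec_rows)[, RECORD_COLUMNS])
  records_gene_id <- bind_rows(rec_rows)$gene_id
  features <- bind_rows(feat_rows)

  # ---- serialized annotation outputs ---------------------------------
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    attrs <- if (f$kind == "tRNA") {
      sprintf("ID=%s.%d;product=%s;anticodon=%s", f$genome_id, i, f$label, f$anticodon)
    } else {
      sprintf("ID=%s.%d;product=%s", f$genome_id, i, f$label)
    }
    gff3 <- c(gff3, paste(f$genome_id, "cptrna_sim",
                          if (f$kind == "tRNA") "tRNA" else "rRNA",
                          f$start + 1L, f$end, ".", f$strand, ".", attrs,
                          sep = "\t"))
  }
  scan_rows <- c(
    "Sequence\t\ttRNA\tBounds\ttRNA\tAnti\tIntron Bounds\t",
    "Name    \ttRNA #\tBegin\tEnd  \tType\tCodon\tBegin\tEnd\tScore",
    "--------\t------\t-----\t-----\t----\t-----\t-----\t---\t-----"
  )
  tnum <- stats::ave(seq_len(nrow(records)), records$genome_id, FUN = seq_along)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$strand == "+") {
      b1 <- r$start + 1L; e1 <- r$end
    } else {
      b1 <- r$end; e1 <- r$start + 1L
    }
    ib <- 0L; ie <- 0L
    ivs <- parse_introns(r$introns)
    if (length(ivs)) {
      iv <- ivs[[1]]
      if (r$strand == "+") {
        ib <- b1 + iv[1]; ie <- b1 + iv[2] - 1L
      } else {
        ib <- b1 - iv[1]; ie <- b1 - iv[2] + 1L
      }
    }
    scan_rows <- c(scan_rows, paste(r$genome_id, tnum[i], b1, e1, r$isotype,
                                    gsub("U", "T", r$anticodon), ib, ie, r$score,
                                    sep = "\t"))
  }

  counts <- per_genome_counts(records, genomes = gids)
  anomaly_truth <- tibble(
    genome_id = plan$genome[plan$anomaly != "none"],
    gene_id = plan$gene_id[plan$anomaly != "none"],
    anticodon = anticodon_out[plan$anomaly != "none"],
    length_class = plan$anomaly[plan$anomaly != "none"],
    parent = parent_triplet[plan$anomaly != "none"]
  )
  list(
    genomes = setNames(vapply(gids, function(gid) {
      paste(fasta[which(fasta == paste0(">", gid)) + 1], collapse = "")
    }, character(1)), gids),
    records = records, features = features, fragments = fragments,
    fasta = paste(fasta, collapse = "\n"),
    gff3 = paste(gff3, collapse = "\n"),
    trnascan = paste(scan_rows, collapse = "\n"),
    truth = list(
      per_genome_counts = counts,
      gene_ids = records_gene_id,
      anomalies = anomaly_truth,
      spacers = bind_rows(spacer_truth),
      fragments = fragments,
      introns = if (length(intron_truth)) bind_rows(intron_truth) else tibble(),
      clades = tibble(genome_id = gids, clade = clades, parasite = parasite,
                      gc_target = unname(config$gc_target[clades]))
    ),
    config = config
  )
}

#' Write a generated cohort to disk
#'
#' @param sim output of [generate()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly. Writes `genomes.fasta`, `annotation.gff3`,
#'   `trnascan.out`, `records.tsv` and `truth.json`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(sim$fasta, file.path(dir, "genomes.fasta"))
  writeLines(sim$gff3, file.path(dir, "annotation.gff3"))
  writeLines(sim$trnascan, file.path(dir, "trnascan.out"))
  write_records_tsv(sim$records, file.path(dir, "records.tsv"))
  truth <- sim$truth
  truth$per_genome_counts <- as.list(truth$per_genome_counts)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Simulate sequence pairs with a planted transition/transversion ratio
#'
#' Each pair derives one sequence from a random ancestor by mutating every
#' site independently with probability `p_sub`; a mutation is a transition
#' with probability `ratio / (ratio + 1)`, otherwise one of the two
#' transversions. The pooled count ratio over all pairs is therefore
#' centred on `ratio`.
#'
#' @param n_pairs number of independent pairs.
#' @param n_sites sites per pair.
#' @param ratio planted Ts:Tv ratio (default 4).
#' @param p_sub per-site substitution probability.
#' @param seed RNG seed.
#' @return list of 2-element character vectors (aligned pairs).
#' @export
simulate_tstv_pairs <- function(n_pairs = 1000, n_sites = 100, ratio = 4,
                                p_sub = 0.1, seed = 1) {
  set.seed(seed)
  transitions <- c(A = "G", G = "A", C = "U", U = "C")
  transversion_sets <- list(A = c("C", "U"), G = c("C", "U"),
                            C = c("A", "G"), U = c("A", "G"))
  lapply(seq_len(n_pairs), function(k) {
    anc <- sample(c("A", "C", "G", "U"), n_sites, replace = TRUE)
    der <- anc
    mut <- which(runif(n_sites) < p_sub)
    for (i in mut) {
      if (runif(1) < ratio / (ratio + 1)) {
        der[i] <- transitions[[anc[i]]]
      } else {
        der[i] <- sample(transversion_sets[[anc[i]]], 1)
      }
    }
    c(paste(anc, collapse = ""), paste(der, collapse = ""))
  })
}

#' Pooled transition/transversion ratio over simulated pairs
#'
#' @param pairs list of aligned 2-sequence character vectors.
#' @return list as in [ts_tv_ratio()], pooled over all pairs.
#' @export
ts_tv_pooled <- function(pairs) {
  ts <- 0L; tv <- 0L
  for (p in pairs) {
    pc <- pairwise_counts(p[1], p[2])
    ts <- ts + pc[["transitions"]]
    tv <- tv + pc[["transversions"]]
  }
  if (tv == 0L) {
    list(R = NA_real_, undefined = TRUE, transitions = ts, transversions = tv)
  } else {
    list(R = ts / tv, undefined = FALSE, transitions = ts, transversions = tv)
  }
}

#' Simulate a GC-vs-tRNA-count cohort with a planted correlation
#'
#' Draws (GC fraction, tRNA count) pairs from a bivariate normal with
#' correlation `rho` (counts rounded to integers), centred on
#' plastome-typical values.
#'
#' @param n cohort size.
#' @param rho planted Pearson correlation.
#' @param seed RNG seed.
#' @return tibble (gc_fraction, trna_count).
#' @export
simulate_gc_trna_cohort <- function(n = 2000, rho = 0.35, seed = 1) {
  set.seed(seed)
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  gc <- 0.37 + 0.03 * z1
  count <- round(36 + 4 * (rho * z1 + sqrt(1 - rho^2) * z2))
  tibble(gc_fraction = gc, trna_count = count)
}

#' Generate a random additive distance matrix and its source tree
#'
#' Draws a random topology with positive branch lengths and returns its
#' path-length (cophenetic) matrix; used as the oracle for NJ recovery.
#'
#' @param n_taxa number of leaves (>= 4 for a meaningful topology check).
#' @return list: `tree` ([ape] phylo) and `d` (additive distance matrix).
#' @export
simulate_additive_matrix <- function(n_taxa) {
  tree <- ape::rtree(n_taxa, br = function(k) runif(k, 0.1, 1))
  tree <- ape::unroot(tree)
  list(tree = tree, d = ape::cophenetic.phylo(tree))
}
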