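# Parsers for the three annotation sources (tRNAscan-SE tabular output,
# GFF3, GenBank flat file) and the multi-annotator merge.
#
# All parsers convert to internal 0-based half-open forward-strand
# coordinates at the boundary and collect per-row errors instead of
# failing: a malformed line is logged (see parse_errors()) and skipped.

#' Parse tRNAscan-SE 2.0 tabular output
#'
#' Expects the standard `.out` layout: three header lines followed by
#' whitespace-delimited columns (sequence name, tRNA number, begin, end,
#' isotype, anticodon, intron begin, intron end, score). Rows with
#' `begin > end` are minus-strand genes; coordinates are normalized to
#' ascending 0-based half-open. DNA anticodons are normalized to RNA.
#' Intron bounds `0/0` mean no intron; otherwise they are converted to
#' gene-relative 0-based half-open intervals on the gene's strand.
#'
#' @param text the file contents as a single string or character vector of
#'   lines.
#' @param source source tag stored on the records (default `"trnascan"`).
#' @return a records tibble; skipped rows are reported via [parse_errors()].
#' @export
parse_trnascan_table <- function(text, source = "trnascan") {
  lines <- split_lines(text)
  errors <- character(0)
  # standard header: two title lines + a dashed rule
  body_start <- 1L
  dash <- grep("^-{4,}", lines)
  if (length(dash)) {
    body_start <- dash[1] + 1L
  } else if (length(lines) >= 1 && grepl("^Sequence|^Name", lines[1])) {
    body_start <- min(4L, length(lines) + 1L)
  }
  rows <- list()
  for (i in seq(from = body_start, length.out = max(0L, length(lines) - body_start + 1L))) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    f <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(f) < 9) {
      errors <- c(errors, sprintf("line %d: expected >= 9 fields, got %d", i, length(f)))
      next
    }
    begin <- suppressWarnings(as.integer(f[3]))
    end <- suppressWarnings(as.integer(f[4]))
    ib <- suppressWarnings(as.integer(f[7]))
    ie <- suppressWarnings(as.integer(f[8]))
    score <- suppressWarnings(as.numeric(f[9]))
    if (anyNA(c(begin, end, ib, ie))) {
      errors <- c(errors, sprintf("line %d: unparseable coordinates", i))
      next
    }
    anticodon <- rna(f[6])
    if (!grepl("^[ACGU]{2,4}$", anticodon)) {
      errors <- c(errors, sprintf("line %d: invalid anticodon '%s'", i, f[6]))
      next
    }
    strand <- if (begin > end) "-" else "+"
    start0 <- min(begin, end) - 1L
    end0 <- max(begin, end)
    introns <- ""
    if (!(ib == 0L && ie == 0L)) {
      lo <- min(ib, ie); hi <- max(ib, ie)
      rel <- if (strand == "+") c(lo - begin, hi - begin + 1L) else c(begin - hi, begin - lo + 1L)
      introns <- paste0(rel[1], "-", rel[2])
    }
    isotype <- normalize_isotype(f[5])
    rows[[length(rows) + 1L]] <- tibble(
      genome_id = f[1], contig = f[1], start = start0, end = end0,
      strand = strand, isotype = isotype, anticodon = anticodon,
      anticodon_offset = NA_integer_, gene_seq = NA_character_,
      mature_seq = NA_character_, introns = introns, source = source,
      score = score, supports = source, discordant = FALSE
    )
  }
  out <- if (length(rows)) trna_records(bind_rows(rows)) else trna_records(empty_records_df())
  set_parse_errors(out, errors)
}

empty_records_df <- function() {
  trna_record("g", start = 0, end = 1, isotype = "Ala", anticodon = "UGC")[0, ]
}

# tRNAscan-SE prints "SeC"; the package uses "Sec".
normalize_isotype <- function(x) {
  x <- ifelse(x %in% c("SeC", "SEC"), "Sec", x)
  x
}

split_lines <- function(text) {
  if (length(text) == 1L) strsplit(text, "\r?\n")[[1]] else text
}

#' Parse tRNA/rRNA features from GFF3 text
#'
#' Keeps `tRNA` and `rRNA` feature lines; 1-based inclusive GFF3 coordinates
#' are converted to 0-based half-open. rRNA subtypes are classified by a
#' label pattern list (default: "16S"/"rrn16" and "23S"/"rrn23"); tRNA
#' anticodons are taken from an `anticodon` attribute or a `trnX-NNN`-style
#' label when present.
#'
#' @param text GFF3 contents (string or lines).
#' @param genome_id genome identifier for the records; defaults to the
#'   contig of each line.
#' @param rrna_patterns named list of regexes classifying rRNA labels.
#' @return a feature tibble; malformed lines reported via [parse_errors()].
#' @export
parse_gff3 <- function(text, genome_id = NULL, rrna_patterns = RRNA_PATTERNS) {
  lines <- split_lines(text)
  errors <- character(0)
  rows <- list()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) f <- strsplit(trimws(line), "\\s{2,}|\t")[[1]]
    if (length(f) < 9) {
      # tolerate single-space-delimited toy inputs: 8 fixed columns + attrs
      g <- strsplit(trimws(line), "\\s+")[[1]]
      if (length(g) >= 9) f <- c(g[1:8], paste(g[-(1:8)], collapse = " "))
    }
    if (length(f) < 9) {
      errors <- c(errors, sprintf("line %d: expected 9 columns", i))
      next
    }
    type <- f[3]
    if (!type %in% c("tRNA", "rRNA")) next
    start1 <- suppressWarnings(as.integer(f[4]))
    end1 <- suppressWarnings(as.integer(f[5]))
    if (anyNA(c(start1, end1))) {
      errors <- c(errors, sprintf("line %d: unparseable coordinates", i))
      next
    }
    if (end1 < start1) {
      errors <- c(errors, sprintf("line %d: end < start", i))
      next
    }
    strand <- f[7]
    if (!strand %in% c("+", "-")) {
      errors <- c(errors, sprintf("line %d: missing strand", i))
      next
    }
    attrs <- parse_gff3_attributes(f[9])
    label <- attrs[["product"]] %||% attrs[["gene"]] %||% attrs[["Name"]] %||%
      attrs[["ID"]] %||% ""
    kind <- if (type == "rRNA") classify_rrna(label, rrna_patterns) else "tRNA"
    anticodon <- NA_character_
    if (kind == "tRNA") {
      anticodon <- if (!is.null(attrs[["anticodon"]])) rna(attrs[["anticodon"]]) else label_anticodon(label)
    }
    rows[[length(rows) + 1L]] <- feature_record(
      genome_id = genome_id %||% f[1], contig = f[1],
      start = start1 - 1L, end = end1, strand = strand,
      kind = kind, label = label, anticodon = anticodon
    )
  }
  out <- if (length(rows)) bind_rows(rows) else empty_features()
  set_parse_errors(out, errors)
}

parse_gff3_attributes <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    p <- trimws(p)
    if (!nzchar(p)) next
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq > 0) {
      out[[substr(p, 1, eq - 1)]] <- utils::URLdecode(substr(p, eq + 1, nchar(p)))
    }
  }
  out
}

#' Parse tRNA/rRNA features from a GenBank flat file
#'
#' Reads the FEATURES table of one or more GenBank entries. `join()`
#' locations produce a single record spanning first..last, with the gaps
#' between the joined pieces retained as intron evidence (genomic 0-based
#' half-open intervals in the feature's `introns` field);
#' `complement()` sets the minus strand.
#'
#' @param text GenBank flat-file contents (string or lines).
#' @return feature tibble; unparseable locations reported via
#'   [parse_errors()].
#' @export
parse_genbank_features <- function(text) {
  lines <- split_lines(text)
  errors <- character(0)
  rows <- list()
  genome_id <- "unknown"
  in_features <- FALSE
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- lines[i]
    if (grepl("^LOCUS\\s+", line)) {
      genome_id <- strsplit(trimws(sub("^LOCUS\\s+", "", line)), "\\s+")[[1]][1]
      in_features <- FALSE
    } else if (grepl("^FEATURES", line)) {
      in_features <- TRUE
    } else if (grepl("^(ORIGIN|//)", line)) {
      in_features <- FALSE
    } else if (in_features && grepl("^ {1,10}\\S", line) && !grepl("^ +/", line)) {
      key <- strsplit(trimws(line), "\\s+")[[1]][1]
      loc <- sub("^\\s*\\S+\\s*", "", line)
      # location strings may continue over lines (no '/' prefix)
      while (i < n && grepl("^ {10,}[^/ ]", lines[i + 1]) &&
             grepl("[,(]\\s*$", loc)) {
        i <- i + 1L
        loc <- paste0(loc, trimws(lines[i]))
      }
      quals <- list()
      while (i < n && (grepl("^ +/", lines[i + 1]) ||
                       (length(quals) && grepl("^ {15,}", lines[i + 1]) &&
                        !grepl("^ {1,10}\\S", lines[i + 1])))) {
        i <- i + 1L
        q <- trimws(lines[i])
        if (startsWith(q, "/")) {
          eq <- regexpr("=", q, fixed = TRUE)
          if (eq > 0) {
            quals[[substr(q, 2, eq - 1)]] <- gsub("\"", "", substr(q, eq + 1, nchar(q)))
          } else {
            quals[[substr(q, 2, nchar(q))]] <- TRUE
          }
        } else if (length(quals)) {
          quals[[length(quals)]] <- paste(quals[[length(quals)]], q)
        }
      }
      if (key %in% c("tRNA", "rRNA")) {
        parsed <- parse_genbank_location(loc)
        if (is.null(parsed)) {
          errors <- c(errors, sprintf("%s %s: unparseable location '%s'",
                                      genome_id, key, trimws(loc)))
        } else {
          label <- quals[["product"]] %||% quals[["gene"]] %||% ""
          kind <- if (key == "rRNA") classify_rrna(label) else "tRNA"
          anticodon <- NA_character_
          if (kind == "tRNA") {
            anticodon <- if (!is.null(quals[["anticodon"]])) {
              ac <- regmatches(quals[["anticodon"]],
                               regexpr("seq:[ACGTUacgtu]{2,4}", quals[["anticodon"]]))
              if (length(ac)) rna(sub("seq:", "", ac)) else label_anticodon(quals[["anticodon"]])
            } else {
              label_anticodon(label)
            }
          }
          rows[[length(rows) + 1L]] <- feature_record(
            genome_id = genome_id, contig = genome_id,
            start = parsed$start, end = parsed$end, strand = parsed$strand,
            kind = kind, label = label, anticodon = anticodon,
            introns = parsed$introns
          )
        }
      }
    }
    i <- i + 1L
  }
  out <- if (length(rows)) bind_rows(rows) else empty_features()
  set_parse_errors(out, errors)
}

# "complement(join(100..130,180..230))" -> span, strand and inter-piece gaps
# (genomic 0-based half-open).
parse_genbank_location <- function(loc) {
  loc <- gsub("\\s", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\(", "", loc)
    loc <- sub("\\)$", "", loc)
  }
  if (grepl("^(join|order)\\(", loc)) {
    loc <- sub("^(join|order)\\(", "", loc)
    loc <- sub("\\)$", "", loc)
  }
  pieces <- strsplit(loc, ",", fixed = TRUE)[[1]]
  m <- lapply(pieces, function(p) {
    p <- gsub("[<>]", "", p)
    xs <- suppressWarnings(as.integer(strsplit(p, "..", fixed = TRUE)[[1]]))
    if (length(xs) != 2 || anyNA(xs) || xs[1] > xs[2]) return(NULL)
    xs
  })
  if (any(vapply(m, is.null, logical(1))) || length(m) == 0) return(NULL)
  mm <- do.call(rbind, m)
  mm <- mm[order(mm[, 1]), , drop = FALSE]
  span <- c(min(mm[, 1]), max(mm[, 2]))
  introns <- character(0)
  if (nrow(mm) > 1) {
    for (k in seq_len(nrow(mm) - 1)) {
      gap <- c(mm[k, 2], mm[k + 1, 1] - 1L)  # 0-based half-open genomic gap
      if (gap[2] > gap[1]) introns <- c(introns, paste0(gap[1], "-", gap[2]))
    }
  }
  list(start = span[1] - 1L, end = span[2], strand = strand,
       introns = paste(introns, collapse = ";"))
}

#' Convert tRNA feature records to tRNA gene records
#'
#' Isotypes are resolved from the label (`tRNA-Asn`, `trnA-UGC`, `trnfM`
#' forms) falling back to the genetic-code mapping of the anticodon; feature
#' intron evidence (genomic) is converted to gene-relative intervals.
#'
#' @param features feature tibble (tRNA rows are used).
#' @param source source tag for the resulting records (default `"geseq"`).
#' @return records tibble.
#' @export
features_to_records <- function(features, source = "geseq") {
  tr <- features[features$kind == "tRNA", , drop = FALSE]
  if (!nrow(tr)) return(empty_records_df())
  rows <- lapply(seq_len(nrow(tr)), function(i) {
    label <- tr$label[i]
    ac <- tr$anticodon[i]
    iso <- label_isotype(label)
    if (is.na(iso)) {
      iso <- if (!is.na(ac) && nchar(ac) == 3) anticodon_to_isotype(ac) else "Undet"
    }
    if (is.na(ac)) ac <- "NN"  # placeholder fails validation; drop below
    introns <- ""
    if (nzchar(tr$introns[i])) {
      gaps <- parse_introns(tr$introns[i])
      rel <- lapply(gaps, function(g) {
        if (tr$strand[i] == "+") c(g[1] - tr$start[i], g[2] - tr$start[i])
        else c(tr$end[i] - g[2], tr$end[i] - g[1])
      })
      rel <- rel[order(vapply(rel, `[`, numeric(1), 1))]
      introns <- serialize_introns(rel)
    }
    tibble(
      genome_id = tr$genome_id[i], contig = tr$contig[i],
      start = tr$start[i], end = tr$end[i], strand = tr$strand[i],
      isotype = iso, anticodon = ac, anticodon_offset = NA_integer_,
      gene_seq = NA_character_, mature_seq = NA_character_,
      introns = introns, source = source, score = NA_real_,
      supports = source, discordant = FALSE
    )
  })
  out <- bind_rows(rows)
  out <- out[grepl("^[ACGU]{2,4}$", out$anticodon), , drop = FALSE]
  trna_records(out)
}

ONE_LETTER_ISOTYPE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val"
)

label_isotype <- function(label) {
  m <- regmatches(label, regexpr("tRNA-([A-Za-z]{3,5}[0-9]?)", label))
  if (length(m)) {
    iso <- sub("tRNA-", "", m)
    if (iso %in% c(STANDARD_ISOTYPES, SPECIAL_ISOTYPES)) return(iso)
    if (iso == "SeC") return("Sec")
    if (iso == "Ile2") return("Ile2")
  }
  m <- regmatches(label, regexpr("trn(fM|I2|[A-Z])", label))
  if (length(m)) {
    code <- sub("trn", "", m)
    if (code == "fM") return("fMet")
    if (code == "I2") return("Ile2")
    if (code %in% names(ONE_LETTER_ISOTYPE)) return(unname(ONE_LETTER_ISOTYPE[code]))
  }
  NA_character_
}

#' Merge multi-annotator tRNA records
#'
#' Records from different sources on the same genome, contig and strand are
#' merged when their intervals reciprocally overlap by at least
#' `overlap_fraction`. The surviving record's fields follow the source
#' precedence `trnascan > geseq > aragorn`; every merged record lists its
#' supporting sources in `supports`, and clusters whose members disagree on
#' isotype keep the precedence winner's isotype with `discordant = TRUE`.
#'
#' @param record_lists a list of records tibbles (one per annotator), or a
#'   single records tibble.
#' @param overlap_fraction reciprocal-overlap threshold in (0, 1], default
#'   0.9.
#' @return merged records tibble sorted by (genome_id, contig, start).
#' @export
merge_annotations <- function(record_lists, overlap_fraction = 0.9) {
  stopifnot(overlap_fraction > 0, overlap_fraction <= 1)
  if (is.data.frame(record_lists)) record_lists <- list(record_lists)
  all <- bind_rows(lapply(record_lists, trna_records))
  if (!nrow(all)) return(trna_records(empty_records_df()))
  prec <- c(trnascan = 1, geseq = 2, aragorn = 3, synthetic = 4)
  all$.prec <- unname(prec[all$source])
  all$.prec[is.na(all$.prec)] <- 5
  keys <- split(seq_len(nrow(all)),
                paste(all$genome_id, all$contig, all$strand, sep = "\r"))
  out_rows <- list()
  for (idx in keys) {
    grp <- all[idx, , drop = FALSE]
    grp <- grp[order(grp$start, grp$end, grp$.prec), , drop = FALSE]
    cluster_id <- integer(nrow(grp))
    clusters <- list()
    for (i in seq_len(nrow(grp))) {
      placed <- FALSE
      for (ci in rev(seq_along(clusters))) {
        members <- clusters[[ci]]
        ok <- any(vapply(members, function(j) {
          reciprocal_overlap(grp$start[i], grp$end[i], grp$start[j], grp$end[j]) >=
            overlap_fraction
        }, logical(1)))
        if (ok) {
          clusters[[ci]] <- c(members, i)
          placed <- TRUE
          break
        }
      }
      if (!placed) clusters[[length(clusters) + 1L]] <- i
    }
    for (members in clusters) {
      mem <- grp[members, , drop = FALSE]
      win <- mem[order(mem$.prec, -ifelse(is.na(mem$score), -Inf, mem$score),
                       mem$start), , drop = FALSE][1, ]
      sup <- sort(unique(unlist(strsplit(mem$supports, "+", fixed = TRUE))))
      win$supports <- paste(sup, collapse = "+")
      win$discordant <- length(unique(mem$isotype)) > 1 || any(mem$discordant)
      out_rows[[length(out_rows) + 1L]] <- win
    }
  }
  out <- bind_rows(out_rows)
  out$.prec <- NULL
  out <- out[order(out$genome_id, out$contig, out$start), , drop = FALSE]
  trna_records(out)
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- max(0L, min(e1, e2) - max(s1, s2))
  min(ov / (e1 - s1), ov / (e2 - s2))
}
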