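# Group I intron extraction, per-isotype wildcard consensus strings and
# consensus clustering.
#
# Consensus notation: tokens joined by "-"; a literal base is itself, a
# degenerate position is "A/G", a single unconstrained position is "x", a
# fixed-length wildcard run is "x_3_" and a variable run is "x_2:5_".

#' Extract intron sequences per isotype
#'
#' Substrings each record's unspliced gene over its intron intervals.
#' Records without `gene_seq` or without introns contribute nothing; every
#' isotype present in the input appears in the result (possibly with an
#' empty vector).
#'
#' @param records records tibble.
#' @return named list isotype -> character vector of intron sequences.
#' @export
extract_introns <- function(records) {
  records <- as_tibble(records)
  isotypes <- unique(records$isotype)
  out <- setNames(vector("list", length(isotypes)), isotypes)
  for (iso in isotypes) out[[iso]] <- character(0)
  for (i in seq_len(nrow(records))) {
    if (is.na(records$gene_seq[i])) next
    ivs <- parse_introns(records$introns[i])
    for (iv in ivs) {
      out[[records$isotype[i]]] <- c(out[[records$isotype[i]]],
                                     substr(records$gene_seq[i], iv[1] + 1, iv[2]))
    }
  }
  out
}

new_tokens <- function() {
  tibble(type = character(), bases = character(), min = integer(), max = integer())
}

literal_token <- function(base) tibble(type = "literal", bases = base, min = 1L, max = 1L)
choice_token <- function(bases) tibble(type = "choice",
                                       bases = paste(bases, collapse = "/"),
                                       min = 1L, max = 1L)
wildcard_token <- function(min, max) tibble(type = "wildcard", bases = "x",
                                            min = as.integer(min), max = as.integer(max))

#' Build a wildcard consensus of intron sequences
#'
#' All sequences are aligned to the longest sequence (global
#' Needleman-Wunsch via [Biostrings::pairwiseAlignment()]; match +1,
#' mismatch -1, gap -2) and read off column-wise in the reference frame
#' (insertions relative to the reference are dropped). A column whose
#' majority base reaches `identity_threshold` becomes a literal token;
#' other columns become wildcards, and consecutive wildcard columns
#' collapse into a run token whose min/max span the per-sequence non-gap
#' run lengths.
#'
#' @param seqs character vector of >= 2 RNA/DNA sequences.
#' @param identity_threshold column majority frequency needed for a literal
#'   (default 0.8).
#' @param isotype optional isotype label carried on the result.
#' @return an `intron_consensus`: list(isotype, tokens, support,
#'   identity_threshold, group).
#' @export
consensus <- function(seqs, identity_threshold = 0.8, isotype = NA_character_) {
  if (length(seqs) < 2) stop("insufficient support: need >= 2 sequences", call. = FALSE)
  seqs <- rna(seqs)
  ref <- seqs[which.max(nchar(seqs))]
  L <- nchar(ref)
  n <- length(seqs)
  cols <- matrix("-", nrow = n, ncol = L)
  for (si in seq_len(n)) {
    if (seqs[si] == ref) {
      cols[si, ] <- strsplit(ref, "")[[1]]
      next
    }
    al <- Biostrings::pairwiseAlignment(
      Biostrings::RNAString(seqs[si]), Biostrings::RNAString(ref),
      type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE, type = "RNA"),
      gapOpening = 0, gapExtension = 2
    )
    pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    ref_pos <- 0L
    for (k in seq_along(sub)) {
      if (sub[k] != "-") {
        ref_pos <- ref_pos + 1L
        cols[si, ref_pos] <- pat[k]
      }
    }
  }
  is_literal <- logical(L)
  lit_base <- character(L)
  for (j in seq_len(L)) {
    tab <- table(cols[, j][cols[, j] %in% c("A", "C", "G", "U")])
    if (length(tab) && max(tab) / n >= identity_threshold) {
      is_literal[j] <- TRUE
      lit_base[j] <- names(tab)[which.max(tab)]
    }
  }
  tokens <- new_tokens()
  j <- 1L
  while (j <= L) {
    if (is_literal[j]) {
      tokens <- bind_rows(tokens, literal_token(lit_base[j]))
      j <- j + 1L
    } else {
      j2 <- j
      while (j2 < L && !is_literal[j2 + 1L]) j2 <- j2 + 1L
      run_lens <- vapply(seq_len(n), function(si) {
        sum(cols[si, j:j2] != "-")
      }, integer(1))
      tokens <- bind_rows(tokens, wildcard_token(max(1L, min(run_lens)), max(1L, max(run_lens))))
      j <- j2 + 1L
    }
  }
  structure(
    list(isotype = isotype, tokens = tokens, support = n,
         identity_threshold = identity_threshold, group = NA_character_),
    class = "intron_consensus"
  )
}

#' Render consensus tokens in run-length notation
#'
#' @param x an `intron_consensus` or a token tibble.
#' @return a string such as `"A-G-U-x-C-x_4_-U-x_2:5_-A/G"`.
#' @export
render_consensus <- function(x) {
  tokens <- if (inherits(x, "intron_consensus")) x$tokens else x
  parts <- vapply(seq_len(nrow(tokens)), function(i) {
    t <- tokens[i, ]
    if (t$type %in% c("literal", "choice")) return(t$bases)
    if (t$min == 1 && t$max == 1) return("x")
    if (t$min == t$max) return(sprintf("x_%d_", t$min))
    sprintf("x_%d:%d_", t$min, t$max)
  }, character(1))
  paste(parts, collapse = "-")
}

#' Parse run-length consensus notation back into tokens
#'
#' Inverse of [render_consensus()].
#'
#' @param s consensus string.
#' @return token tibble.
#' @export
parse_consensus <- function(s) {
  parts <- strsplit(s, "-", fixed = TRUE)[[1]]
  rows <- lapply(parts, function(p) {
    if (grepl("^[ACGU]$", p)) return(literal_token(p))
    if (grepl("^[ACGU](/[ACGU])+$", p)) {
      return(choice_token(strsplit(p, "/", fixed = TRUE)[[1]]))
    }
    if (p == "x") return(wildcard_token(1L, 1L))
    m <- regmatches(p, regexec("^x_([0-9]+)(?::([0-9]+))?_$", p))[[1]]
    if (length(m) && nzchar(m[2])) {
      lo <- as.integer(m[2])
      hi <- if (nzchar(m[3])) as.integer(m[3]) else lo
      return(wildcard_token(lo, hi))
    }
    stop("unparseable consensus token '", p, "'", call. = FALSE)
  })
  bind_rows(rows)
}

#' @export
print.intron_consensus <- function(x, ...) {
  cat(sprintf("intron_consensus (%s, support %d, threshold %.2f%s):\n  %s\n",
              x$isotype %||% "?", x$support, x$identity_threshold,
              if (is.na(x$group)) "" else paste0(", group ", x$group),
              render_consensus(x)))
  invisible(x)
}

#' Count standard isotypes with an intron consensus
#'
#' @param consensus_map named list isotype -> `intron_consensus` (or a list
#'   of them, or consensus strings); `NULL`/empty entries mean no conserved
#'   intron for that isotype.
#' @return number of the 20 standard isotypes with a non-empty consensus.
#' @export
count_intron_isotypes <- function(consensus_map) {
  present <- vapply(STANDARD_ISOTYPES, function(iso) {
    v <- consensus_map[[iso]]
    !is.null(v) && length(v) > 0
  }, logical(1))
  sum(present)
}

# expand tokens into comparable symbols: literals as their base, choices as
# their rendered set, wildcard runs as max-length runs of "x"
expand_tokens <- function(tokens) {
  out <- character(0)
  for (i in seq_len(nrow(tokens))) {
    t <- tokens[i, ]
    if (t$type == "wildcard") out <- c(out, rep("x", t$max)) else out <- c(out, t$bases)
  }
  out
}

symbols_match <- function(a, b) {
  if (a == "x" || b == "x") return(TRUE)
  length(intersect(strsplit(a, "/", fixed = TRUE)[[1]],
                   strsplit(b, "/", fixed = TRUE)[[1]])) > 0
}

# Normalized alignment distance over expanded token symbols; wildcards are
# universal matches (consensus wildcards denote unconstrained positions).
# The similarity is the best ends-free match count (longest common
# subsequence with wildcard matching) normalized by the shorter consensus:
# printed consensus lines are truncated alignment blocks, so a consensus
# that extends another (the Glu/Thr case) should score as near-identical
# rather than be penalized for its extra columns.
consensus_distance <- function(tok_a, tok_b) {
  a <- expand_tokens(tok_a)
  b <- expand_tokens(tok_b)
  n <- length(a); m <- length(b)
  s <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s[i + 1, j + 1] <- max(
        s[i, j] + as.integer(symbols_match(a[i], b[j])),
        s[i, j + 1], s[i + 1, j]
      )
    }
  }
  1 - s[n + 1, m + 1] / min(n, m)
}

#' Cluster intron consensuses into groups
#'
#' Average-linkage hierarchical clustering on the pairwise normalized edit
#' distance between rendered consensuses (wildcards match anything), cut at
#' `k` clusters. Isotypes whose merge height exceeds the cut (singleton
#' clusters) are labelled `"ungrouped"`; the remaining clusters are
#' lettered A, B, C, ... in input order of their first member.
#'
#' @param consensuses named list isotype -> `intron_consensus`, token tibble
#'   or consensus string (lists of alternatives use their first entry).
#' @param k number of clusters to cut (default 4).
#' @return list with `groups` (tibble isotype, group) and `hclust` (the
#'   dendrogram, convertible to newick via [ape::as.phylo()]).
#' @export
cluster_consensuses <- function(consensuses, k = 4) {
  isotypes <- names(consensuses)
  toks <- lapply(consensuses, function(v) {
    if (is.list(v) && !inherits(v, "intron_consensus") && !is.data.frame(v)) v <- v[[1]]
    if (inherits(v, "intron_consensus")) return(v$tokens)
    if (is.character(v)) return(parse_consensus(v[[1]]))
    v
  })
  n <- length(toks)
  if (n < 2) stop("need >= 2 consensuses to cluster", call. = FALSE)
  k <- min(k, n)
  dm <- matrix(0, n, n, dimnames = list(isotypes, isotypes))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      dm[i, j] <- dm[j, i] <- consensus_distance(toks[[i]], toks[[j]])
    }
  }
  hc <- hclust(as.dist(dm), method = "average")
  cl <- cutree(hc, k = k)
  sizes <- table(cl)
  group <- character(n)
  letter_i <- 0L
  letter_for <- integer(0)
  for (i in seq_len(n)) {
    ci <- cl[i]
    if (sizes[as.character(ci)] == 1L) {
      group[i] <- "ungrouped"
    } else {
      if (is.na(match(ci, names(letter_for))) || !as.character(ci) %in% names(letter_for)) {
        letter_i <- letter_i + 1L
        letter_for[as.character(ci)] <- letter_i
      }
      group[i] <- LETTERS[letter_for[as.character(ci)]]
    }
  }
  list(groups = tibble(isotype = isotypes, group = group), hclust = hc)
}

#' Write per-isotype consensuses to TSV
#'
#' @param consensus_map named list isotype -> `intron_consensus` or list of
#'   them (`NULL` entries written as "Not found").
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_consensus_tsv <- function(consensus_map, path) {
  rows <- list()
  for (iso in names(consensus_map)) {
    v <- consensus_map[[iso]]
    if (is.null(v) || length(v) == 0) {
      rows[[length(rows) + 1L]] <- tibble(isotype = iso, line = 1L,
                                          consensus = "Not found", support = 0L)
      next
    }
    if (inherits(v, "intron_consensus")) v <- list(v)
    for (li in seq_along(v)) {
      cc <- v[[li]]
      rows[[length(rows) + 1L]] <- tibble(
        isotype = iso, line = li,
        consensus = if (inherits(cc, "intron_consensus")) render_consensus(cc) else as.character(cc),
        support = if (inherits(cc, "intron_consensus")) cc$support else NA_integer_
      )
    }
  }
  utils::write.table(bind_rows(rows), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
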