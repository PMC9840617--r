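# Classification of short tRNA-like sequences: tRF vs tiRNA length windows,
# 5'/3'/tRF-1 end classes against mature tRNA references, and conserved
# motif extraction.

#' Classify a fragment length as tRF, tiRNA or none
#'
#' tRFs are 14-32 nt and tiRNAs ("tRNA halves") 30-50 nt in the literature;
#' the 30-32 nt overlap between the two printed windows is resolved in
#' favour of tiRNA, since tiRNAs are defined as the longer class. The
#' effective windows are therefore 14-29 (tRF) and 30-50 (tiRNA).
#'
#' @param length fragment length in nt (vectorized).
#' @return `"tRF"`, `"tiRNA"` or `"none"`.
#' @export
classify_length_window <- function(length) {
  vapply(length, function(l) {
    if (l >= 14 && l <= 29) "tRF" else if (l >= 30 && l <= 50) "tiRNA" else "none"
  }, character(1))
}

#' Classify a fragment's end class against mature tRNA references
#'
#' A fragment matching a reference prefix within `max_mismatch`
#' substitutions is `five_prime`; a suffix match is `three_prime`. If both
#' match, the class with fewer mismatches wins and prefix wins ties. A
#' fragment with no terminal match is `tRF1` — with the containing reference
#' as parent when it occurs as an internal exact substring, otherwise with
#' no parent (precursor-derived).
#'
#' @param fragment RNA (or DNA; normalized) string.
#' @param references records tibble carrying `mature_seq` (and isotype,
#'   anticodon for the parent call).
#' @param max_mismatch allowed substitutions for terminal matches
#'   (default 0; the conserved fragments reported for plastomes are exact).
#' @return a `fragment_call` list: fragment, length, length_class,
#'   end_class, parent (isotype, anticodon) or NULL, mismatches_used.
#' @export
classify_ends <- function(fragment, references, max_mismatch = 0) {
  references <- as_tibble(references)
  references <- references[!is.na(references$mature_seq), , drop = FALSE]
  if (!nrow(references)) stop("empty reference list", call. = FALSE)
  fragment <- rna(fragment)
  flen <- nchar(fragment)

  best <- NULL  # list(end_class, mm, ref_i)
  consider <- function(end_class, mm, ref_i) {
    if (mm > max_mismatch) return()
    better <- is.null(best) || mm < best$mm ||
      (mm == best$mm && best$end_class == "three_prime" && end_class == "five_prime")
    if (better) best <<- list(end_class = end_class, mm = mm, ref_i = ref_i)
  }
  for (i in seq_len(nrow(references))) {
    ref <- references$mature_seq[i]
    if (nchar(ref) < flen) next
    consider("five_prime", str_hamming(fragment, substr(ref, 1, flen)), i)
    consider("three_prime",
             str_hamming(fragment, substr(ref, nchar(ref) - flen + 1, nchar(ref))), i)
  }
  if (is.null(best)) {
    internal <- which(vapply(references$mature_seq, function(ref) {
      grepl(fragment, ref, fixed = TRUE)
    }, logical(1)))
    parent <- if (length(internal)) {
      list(isotype = references$isotype[internal[1]],
           anticodon = references$anticodon[internal[1]])
    } else {
      NULL
    }
    call <- list(end_class = "tRF1", parent = parent, mismatches_used = 0L)
  } else {
    call <- list(end_class = best$end_class,
                 parent = list(isotype = references$isotype[best$ref_i],
                               anticodon = references$anticodon[best$ref_i]),
                 mismatches_used = best$mm)
  }
  structure(
    list(fragment = fragment, length = flen,
         length_class = classify_length_window(flen),
         end_class = call$end_class, parent = call$parent,
         mismatches_used = call$mismatches_used),
    class = "fragment_call"
  )
}

#' @export
print.fragment_call <- function(x, ...) {
  par <- if (is.null(x$parent)) "none" else paste0(x$parent$isotype, "-", x$parent$anticodon)
  cat(sprintf("fragment_call: %d nt %s, end class %s, parent %s (%d mismatches)\n",
              x$length, x$length_class, x$end_class, par, x$mismatches_used))
  invisible(x)
}

#' Classify a set of fragments and tabulate end classes
#'
#' @param fragments named character vector of fragment sequences.
#' @param references,max_mismatch as in [classify_ends()].
#' @return tibble: fragment_id, length, length_class, end_class,
#'   parent_isotype, parent_anticodon, mismatches_used.
#' @export
classify_fragments <- function(fragments, references, max_mismatch = 0) {
  ids <- names(fragments) %||% as.character(seq_along(fragments))
  if (is.null(names(fragments))) names(fragments) <- ids
  rows <- lapply(seq_along(fragments), function(i) {
    fc <- classify_ends(fragments[[i]], references, max_mismatch)
    tibble(
      fragment_id = ids[i], length = fc$length, length_class = fc$length_class,
      end_class = fc$end_class,
      parent_isotype = if (is.null(fc$parent)) NA_character_ else fc$parent$isotype,
      parent_anticodon = if (is.null(fc$parent)) NA_character_ else fc$parent$anticodon,
      mismatches_used = fc$mismatches_used
    )
  })
  bind_rows(rows)
}

#' Longest substring common to all fragments
#'
#' Returns the longest substring present in every input (the leftmost
#' occurrence on the first fragment among equals), or `NULL` when the best
#' common substring is shorter than `min_len`. Inputs are normalized to the
#' RNA alphabet, so DNA-alphabet motifs match their RNA transcripts.
#'
#' @param fragments character vector (>= 2 sequences).
#' @param min_len minimum motif length to report (default 10).
#' @return the motif string, or `NULL`.
#' @export
conserved_motif <- function(fragments, min_len = 10) {
  if (length(fragments) < 2) stop("need at least 2 fragments", call. = FALSE)
  fragments <- rna(fragments)
  first <- fragments[1]
  rest <- fragments[-1]
  n <- nchar(first)
  for (len in seq(n, 1)) {
    if (len < min_len) break
    for (startpos in seq_len(n - len + 1)) {
      cand <- substr(first, startpos, startpos + len - 1)
      if (all(vapply(rest, function(s) grepl(cand, s, fixed = TRUE), logical(1)))) {
        return(cand)
      }
    }
  }
  NULL
}
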