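# Pairwise substitution counts, transition/transversion ratio, Kimura
# two-parameter distances and neighbor-joining trees over tRNA sequences.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "U")

#' Count compared sites, transitions and transversions between two aligned
#' sequences
#'
#' Gap columns (`-` or `.` in either sequence) are skipped. Transitions are
#' A<->G and C<->U; every other differing pair is a transversion.
#'
#' @param a,b aligned RNA strings of equal length.
#' @return named integer vector: `sites`, `transitions`, `transversions`.
#' @export
pairwise_counts <- function(a, b) {
  a <- rna(a); b <- rna(b)
  if (nchar(a) != nchar(b)) stop("aligned sequences must have equal length", call. = FALSE)
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  ok <- ca %in% c("A", "C", "G", "U") & cb %in% c("A", "C", "G", "U")
  ca <- ca[ok]; cb <- cb[ok]
  diff <- ca != cb
  ts <- diff & ((ca %in% PURINES & cb %in% PURINES) |
                  (ca %in% PYRIMIDINES & cb %in% PYRIMIDINES))
  c(sites = sum(ok), transitions = sum(ts), transversions = sum(diff & !ts))
}

#' Count-based transition/transversion ratio of an alignment
#'
#' Sums transitions and transversions over all sequence pairs and reports
#' `R = sum(ts) / sum(tv)`. With zero transversions the ratio is flagged
#' undefined rather than reported as a number. This is the simple count
#' estimator, not a maximum-likelihood bias estimate.
#'
#' @param alignment character vector of >= 2 aligned sequences.
#' @return list: `R` (numeric or `NA`), `undefined` (logical),
#'   `transitions`, `transversions`, `pairs`.
#' @export
ts_tv_ratio <- function(alignment) {
  if (length(alignment) < 2) stop("need >= 2 sequences", call. = FALSE)
  ts <- 0L; tv <- 0L; np <- 0L
  for (i in seq_len(length(alignment) - 1)) {
    for (j in seq(i + 1, length(alignment))) {
      pc <- pairwise_counts(alignment[[i]], alignment[[j]])
      ts <- ts + pc[["transitions"]]
      tv <- tv + pc[["transversions"]]
      np <- np + 1L
    }
  }
  if (tv == 0L) {
    list(R = NA_real_, undefined = TRUE, transitions = ts, transversions = tv,
         pairs = np)
  } else {
    list(R = ts / tv, undefined = FALSE, transitions = ts, transversions = tv,
         pairs = np)
  }
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` with `P` and `Q` the
#' transition and transversion proportions over compared (non-gap) sites.
#' Saturated pairs (non-positive logarithm argument) raise an error rather
#' than returning infinity.
#'
#' @param a,b aligned RNA strings.
#' @return the K2P distance (>= 0).
#' @export
k2p_distance <- function(a, b) {
  pc <- pairwise_counts(a, b)
  if (pc[["sites"]] == 0) stop("no comparable sites", call. = FALSE)
  P <- pc[["transitions"]] / pc[["sites"]]
  Q <- pc[["transversions"]] / pc[["sites"]]
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) stop("saturation: K2P distance undefined", call. = FALSE)
  -0.5 * log(w1 * sqrt(w2))
}

#' K2P distance matrix of an alignment
#'
#' @param alignment named character vector of aligned sequences.
#' @return symmetric matrix with zero diagonal, labelled by sequence names.
#' @export
k2p_matrix <- function(alignment) {
  n <- length(alignment)
  labels <- names(alignment) %||% paste0("seq", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- k2p_distance(alignment[[i]], alignment[[j]])
    }
  }
  d
}

validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square", call. = FALSE)
  if (any(!is.finite(d))) stop("distance matrix has non-finite entries", call. = FALSE)
  if (any(d < 0)) stop("distance matrix has negative entries", call. = FALSE)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
    stop("distance matrix is not symmetric", call. = FALSE)
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero", call. = FALSE)
  if (is.null(rownames(d))) {
    rn <- paste0("t", seq_len(nrow(d)))
    dimnames(d) <- list(rn, rn)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: at each step the pair minimizing the
#' Q-criterion is joined (ties broken lexicographically on the smallest
#' leaf label of each cluster, so the output is deterministic), branch
#' lengths follow the standard formulas and negative branch lengths are
#' clamped to zero with a warning. The result is an unrooted `phylo` tree.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal and
#'   row/column names (>= 3 taxa).
#' @return an [ape] `phylo` object.
#' @export
nj_tree <- function(d) {
  d <- validate_distance_matrix(d)
  n <- nrow(d)
  if (n < 3) stop("need >= 3 taxa", call. = FALSE)
  labels <- rownames(d)
  newick <- labels        # newick fragment per active node
  repr <- labels          # smallest leaf label per cluster, for tie-breaks
  active <- seq_len(n)
  clamped <- FALSE
  brlen <- function(x) {
    if (x < 0) {
      clamped <<- TRUE
      x <- 0
    }
    sprintf("%.12g", x)
  }
  while (length(active) > 3) {
    r <- length(active)
    dm <- d[active, active, drop = FALSE]
    rs <- rowSums(dm)
    best <- NULL
    for (i in seq_len(r - 1)) {
      for (j in seq(i + 1, r)) {
        q <- (r - 2) * dm[i, j] - rs[i] - rs[j]
        pair <- sort(c(repr[active[i]], repr[active[j]]))
        if (is.null(best) || q < best$q - 1e-12 ||
            (abs(q - best$q) <= 1e-12 &&
             (pair[1] < best$pair[1] ||
              (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
          best <- list(q = q, i = i, j = j, pair = pair)
        }
      }
    }
    i <- best$i; j <- best$j
    ai <- active[i]; aj <- active[j]
    li <- dm[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- dm[i, j] - li
    new_nwk <- sprintf("(%s:%s,%s:%s)", newick[ai], brlen(li), newick[aj], brlen(lj))
    # distances from the new node to the remaining nodes
    others <- active[-c(i, j)]
    newd <- (d[ai, others] + d[aj, others] - d[ai, aj]) / 2
    d <- rbind(cbind(d, 0), 0)
    m <- nrow(d)
    d[m, others] <- d[others, m] <- newd
    rownames(d)[m] <- colnames(d)[m] <- paste0(".n", m)
    newick <- c(newick, new_nwk)
    repr <- c(repr, min(repr[ai], repr[aj]))
    active <- c(others, m)
  }
  x <- active[1]; y <- active[2]; z <- active[3]
  lx <- (d[x, y] + d[x, z] - d[y, z]) / 2
  ly <- (d[x, y] + d[y, z] - d[x, z]) / 2
  lz <- (d[x, z] + d[y, z] - d[x, y]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 newick[x], brlen(lx), newick[y], brlen(ly), newick[z], brlen(lz))
  if (clamped) warning("negative NJ branch length(s) clamped to 0")
  ape::read.tree(text = nwk)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree
#' (K2P distances) per replicate, and annotates each internal edge of the
#' full-data tree with the fraction of replicates containing the same leaf
#' bipartition (via [ape::prop.clades()]). Deterministic for a fixed seed.
#'
#' @param alignment named character vector of aligned sequences (>= 3).
#' @param replicates number of bootstrap replicates; 0 returns the
#'   unadorned tree.
#' @param seed RNG seed.
#' @return `phylo` tree; with `replicates > 0`, `node.label` carries
#'   support fractions in `[0, 1]`.
#' @export
bootstrap_support <- function(alignment, replicates = 100, seed = 1) {
  if (length(alignment) < 3) stop("need >= 3 sequences", call. = FALSE)
  labels <- names(alignment) %||% paste0("seq", seq_along(alignment))
  names(alignment) <- labels
  tree <- nj_tree(k2p_matrix(alignment))
  if (replicates == 0) return(tree)
  chars <- do.call(rbind, strsplit(rna(unlist(alignment)), "", fixed = TRUE))
  rownames(chars) <- labels
  L <- ncol(chars)
  set.seed(seed)
  boot_trees <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
    boot_trees[[b]] <- nj_tree(k2p_matrix(rep_aln))
  }
  counts <- ape::prop.clades(tree, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  tree$node.label <- counts / replicates
  tree
}
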