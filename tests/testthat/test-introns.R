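test_that("introns are extracted from the unspliced gene over intron intervals", {
  rec <- trna_record("g", start = 0, end = 9, isotype = "Ala", anticodon = "AAA",
                     gene_seq = "AAAGGGCCC", introns = list(c(3L, 6L)))
  ex <- extract_introns(rec)
  expect_equal(ex$Ala, "GGG")
  # records without introns contribute nothing but keep their isotype key
  rec2 <- dplyr::bind_rows(rec, trna_record("g", start = 20, end = 29,
                                            isotype = "Lys", anticodon = "UUU",
                                            gene_seq = "ACGUACGUA"))
  ex2 <- extract_introns(rec2)
  expect_equal(ex2$Lys, character(0))
})

test_that("consensus of identical sequences is all literal", {
  cc <- consensus(rep("AUUGGG", 5))
  expect_equal(render_consensus(cc), "A-U-U-G-G-G")
  expect_equal(cc$support, 5)
})

test_that("columns below the identity threshold become wildcards", {
  cc <- consensus(c("AAGA", "AACA", "AAUA"), identity_threshold = 0.8)
  expect_equal(render_consensus(cc), "A-A-x-A")
  # at a permissive threshold the majority base is emitted
  cc2 <- consensus(c("AAGA", "AAGA", "AAUA"), identity_threshold = 0.6)
  expect_equal(render_consensus(cc2), "A-A-G-A")
  expect_error(consensus("AAGA"), "insufficient support")
})

test_that("consensus is invariant to input order", {
  seqs <- c("GCGAUUACG", "GCGAUUACG", "GCGAUAACG", "GCGCUUACG")
  for (perm in list(c(2, 1, 3, 4), c(4, 3, 2, 1), c(3, 1, 4, 2))) {
    expect_equal(render_consensus(consensus(seqs[perm])),
                 render_consensus(consensus(seqs)))
  }
})

test_that("raising the identity threshold never converts wildcards to literals", {
  set.seed(8)
  seqs <- vapply(1:6, function(i) {
    base <- strsplit("GCGAUUACGGAUUACG", "")[[1]]
    mut <- sample(16, 4)
    base[mut] <- sample(c("A", "C", "G", "U"), 4, replace = TRUE)
    paste(base, collapse = "")
  }, character(1))
  lo <- consensus(seqs, identity_threshold = 0.5)$tokens
  hi <- consensus(seqs, identity_threshold = 0.9)$tokens
  # compare per-column classification (same reference, no indels here)
  expand_class <- function(tok) {
    unlist(lapply(seq_len(nrow(tok)), function(i) {
      if (tok$type[i] == "wildcard") rep("x", tok$max[i]) else tok$bases[i]
    }))
  }
  lo_c <- expand_class(lo)
  hi_c <- expand_class(hi)
  expect_equal(length(lo_c), length(hi_c))
  expect_true(all(!(lo_c == "x" & hi_c != "x")))
})

test_that("run-length consensus notation round-trips", {
  for (s in c("A-U-U-G-G-G",
              "A-G-U-G-C-G-x-C-U-x_4_-U",
              "G-x_8_-U-x-U-x_4:5_-C-A-G/A-x_3_-A",
              "A/C-G/U-U-x_1:3_-C")) {
    expect_equal(render_consensus(parse_consensus(s)), s)
  }
  expect_error(parse_consensus("A-?-G"), "unparseable")
})

test_that("a planted consensus motif is recovered from noisy flanks", {
  # sequences share the conserved threonine intron prefix with random tails
  set.seed(14)
  motif <- "AUUGCGUCGUUGUGC"
  seqs <- vapply(1:6, function(i) {
    paste0(motif, paste(sample(c("A", "C", "G", "U"), 6, replace = TRUE),
                        collapse = ""))
  }, character(1))
  cc <- consensus(seqs, identity_threshold = 0.8)
  expect_equal(substr(render_consensus(cc), 1, nchar("A-U-U-G-C-G-U-C-G-U-U-G-U-G-C")),
               "A-U-U-G-C-G-U-C-G-U-U-G-U-G-C")
})

test_that("the packaged consensus table has 12 intron-bearing standard isotypes", {
  t2 <- table2_fixture()
  expect_equal(count_intron_isotypes(t2), 12)
  absent <- names(t2)[vapply(t2, length, integer(1)) == 0]
  expect_setequal(absent, c("Arg", "Asn", "Asp", "Gln", "His", "Pro", "Trp", "Val"))
  expect_equal(count_intron_isotypes(list()), 0)
  expect_equal(count_intron_isotypes(list(Ala = t2$Ala, Lys = t2$Lys,
                                          Met = t2$Met)), 3)
  # multi-line isotypes are stored as lists of alternatives
  expect_length(t2$Ser, 4)
  expect_length(t2$Cys, 2)
})

test_that("clustering separates identical consensuses from a distant one", {
  cs <- list(a = "A-A-A-A-A-A", b = "A-A-A-A-A-A", c = "G-C-G-C-G-C")
  cl <- cluster_consensuses(cs, k = 2)
  g <- setNames(cl$groups$group, cl$groups$isotype)
  expect_equal(g[["a"]], g[["b"]])
  expect_false(g[["a"]] == g[["c"]])
  expect_equal(g[["c"]], "ungrouped")
})

test_that("Glu and Thr share their 15-token prefix and co-cluster at k = 4", {
  t2 <- table2_fixture()
  glu <- t2$Glu[[1]]
  thr <- t2$Thr[[1]]
  expect_equal(glu$bases[1:15], thr$bases[1:15])
  expect_true(all(glu$type[1:15] == "literal"))
  withc <- t2[vapply(t2, length, integer(1)) > 0]
  cl <- cluster_consensuses(withc, k = 4)
  g <- setNames(cl$groups$group, cl$groups$isotype)
  expect_equal(g[["Glu"]], g[["Thr"]])
  expect_false(g[["Glu"]] == "ungrouped")
  # deterministic given identical input
  cl2 <- cluster_consensuses(withc, k = 4)
  expect_equal(cl$groups, cl2$groups)
})

test_that("the consensus dendrogram serializes to newick", {
  t2 <- table2_fixture()
  withc <- t2[vapply(t2, length, integer(1)) > 0]
  cl <- cluster_consensuses(withc, k = 4)
  nwk <- ape::write.tree(ape::as.phylo(cl$hclust))
  expect_match(nwk, "Glu")
  expect_match(nwk, ";$")
})
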