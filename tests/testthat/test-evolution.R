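test_that("pairwise counts separate transitions from transversions", {
  expect_equal(pairwise_counts("AAA", "GGG"),
               c(sites = 3, transitions = 3, transversions = 0))
  expect_equal(pairwise_counts("AAA", "CCC"),
               c(sites = 3, transitions = 0, transversions = 3))
  # positionwise by hand: A/G ts, C/C same, G/A ts, U/U same
  expect_equal(pairwise_counts("ACGU", "GCAU"),
               c(sites = 4, transitions = 2, transversions = 0))
  # gap columns are skipped
  expect_equal(pairwise_counts("A-GU", "AC-U"),
               c(sites = 2, transitions = 0, transversions = 0))
  expect_error(pairwise_counts("AAA", "AAAA"), "equal length")
})

test_that("Ts/Tv ratio is undefined without transversions", {
  expect_true(ts_tv_ratio(c("AAAA", "AAAA"))$undefined)
  expect_true(ts_tv_ratio(c("AAA", "GGG"))$undefined)
  r <- ts_tv_ratio(c("AAAA", "GGGC"))
  expect_false(r$undefined)
  expect_equal(r$R, 3)
  expect_error(ts_tv_ratio("AAA"), ">= 2")
})

test_that("Ts/Tv ratio is invariant under sequence order permutation", {
  set.seed(3)
  aln <- vapply(1:5, function(i) {
    paste(sample(c("A", "C", "G", "U"), 60, replace = TRUE), collapse = "")
  }, character(1))
  base <- ts_tv_ratio(aln)$R
  expect_equal(ts_tv_ratio(rev(aln))$R, base)
  expect_equal(ts_tv_ratio(aln[c(3, 1, 5, 2, 4)])$R, base)
})

test_that("K2P distance matches the closed form and its boundary behaviour", {
  expect_equal(k2p_distance("ACGUACGUAC", "ACGUACGUAC"), 0)
  # P = Q = 0.1 over 10 sites: one transition, one transversion
  a <- "AAAAAAAAAA"
  b <- "GCAAAAAAAA"
  expect_equal(k2p_distance(a, b),
               -0.5 * log((1 - 2 * 0.1 - 0.1) * sqrt(1 - 2 * 0.1)))
  # saturation: P = 0.5, Q = 0 makes the first factor vanish
  expect_error(k2p_distance("AAAAAAAAAA", "GGGGGAAAAA"), "saturation")
})

test_that("K2P agrees with the reference implementation and is monotone in P", {
  aln <- c(s1 = "ACGUACGUACGUACGUACGGAUCCGUAAGCUA",
           s2 = "ACGUACGCACGUAAGUACGGAUCCGUGGGCUA")
  ours <- k2p_distance(aln[1], aln[2])
  bin <- ape::as.DNAbin(t(sapply(gsub("U", "T", aln), function(s)
    strsplit(tolower(s), "")[[1]])))
  ref <- as.numeric(ape::dist.dna(bin, model = "K80"))
  expect_equal(ours, ref, tolerance = 1e-12)

  # monotone in P at fixed Q inside the valid region
  q_block <- "CCCCC"  # 5 transversions
  base <- strsplit(paste(rep("A", 45), collapse = ""), "")[[1]]
  dists <- vapply(0:8, function(k) {
    derived <- base
    if (k > 0) derived[seq_len(k)] <- "G"
    k2p_distance(paste(c(base, strsplit(q_block, "")[[1]]), collapse = ""),
                 paste(c(derived, rep("A", 5)), collapse = ""))
  }, numeric(1))
  expect_true(all(diff(dists) > 0))
})

test_that("the 3-taxon NJ closed form gives branch lengths (0, 2, 4)", {
  d <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- nj_tree(d)
  bl <- setNames(tree$edge.length,
                 tree$tip.label[tree$edge[, 2]])
  expect_equal(bl[["A"]], 0)
  expect_equal(bl[["B"]], 2)
  expect_equal(bl[["C"]], 4)
})

test_that("NJ recovers random additive trees exactly", {
  set.seed(17)
  for (rep in 1:10) {
    sim <- simulate_additive_matrix(sample(5:8, 1))
    tree <- nj_tree(sim$d)
    expect_equal(phangorn::RF.dist(tree, sim$tree), 0)
    path <- ape::cophenetic.phylo(tree)[rownames(sim$d), colnames(sim$d)]
    expect_lt(max(abs(path - sim$d)), 1e-9)
  }
})

test_that("NJ topology agrees with the reference implementation on noisy matrices", {
  set.seed(23)
  for (rep in 1:5) {
    sim <- simulate_additive_matrix(7)
    d <- sim$d + matrix(runif(49, 0, 0.01), 7, 7)
    d <- (d + t(d)) / 2
    diag(d) <- 0
    ours <- nj_tree(d)
    ref <- ape::nj(as.dist(d))
    expect_equal(phangorn::RF.dist(ours, ref), 0)
  }
})

test_that("NJ rejects malformed distance matrices", {
  d <- matrix(c(0, 1, 2, 9, 0, 3, 2, 3, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d), "symmetric")
  d2 <- matrix(c(0, -1, 2, -1, 0, 3, 2, 3, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d2), "negative")
  expect_error(nj_tree(matrix(0, 2, 2)), ">= 3")
})

test_that("bootstrap recovers well-separated clades with high support", {
  set.seed(31)
  # two 4-leaf clades: clade B diverges from A at ~25% of 200 columns
  # (moderate divergence keeps K2P well inside its valid region)
  blockA <- paste(sample(c("A", "C", "G", "U"), 200, replace = TRUE), collapse = "")
  jitter <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(length(ch), k)
    ch[i] <- sample(c("A", "C", "G", "U"), k, replace = TRUE)
    paste(ch, collapse = "")
  }
  blockB <- jitter(blockA, 50)
  aln <- c(a1 = jitter(blockA, 4), a2 = jitter(blockA, 4),
           a3 = jitter(blockA, 4), a4 = jitter(blockA, 4),
           b1 = jitter(blockB, 4), b2 = jitter(blockB, 4),
           b3 = jitter(blockB, 4), b4 = jitter(blockB, 4))
  tree <- suppressWarnings(bootstrap_support(aln, replicates = 50, seed = 5))
  # the root bipartition (a* vs b*) must be near-unanimous
  expect_gte(max(tree$node.label, na.rm = TRUE), 0.95)

  # determinism under a fixed seed
  tree2 <- suppressWarnings(bootstrap_support(aln, replicates = 50, seed = 5))
  expect_equal(tree$node.label, tree2$node.label)
  expect_equal(ape::write.tree(tree), ape::write.tree(tree2))

  # replicates = 0 returns the unadorned tree
  plain <- suppressWarnings(bootstrap_support(aln, replicates = 0))
  expect_null(plain$node.label)
})
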