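test_that("length windows classify tRF (14-29) and tiRNA (30-50)", {
  expect_equal(classify_length_window(20), "tRF")
  expect_equal(classify_length_window(31), "tiRNA")  # overlap resolves to tiRNA
  expect_equal(classify_length_window(30), "tiRNA")
  expect_equal(classify_length_window(c(13, 14, 29, 50, 51, 55)),
               c("none", "tRF", "tRF", "tiRNA", "none", "none"))
})

make_refs <- function() {
  set.seed(99)
  seqs <- vapply(1:3, function(i) {
    paste(sample(c("A", "C", "G", "U"), 72, replace = TRUE), collapse = "")
  }, character(1))
  dplyr::bind_rows(
    trna_record("g", start = 0, end = 72, isotype = "Glu", anticodon = "UUC",
                mature_seq = sub("^(.{34}).{3}", paste0("\\1", "UUC"), seqs[1]),
                anticodon_offset = 34),
    trna_record("g", start = 100, end = 172, isotype = "Gly", anticodon = "GCC",
                mature_seq = sub("^(.{34}).{3}", paste0("\\1", "GCC"), seqs[2]),
                anticodon_offset = 34),
    trna_record("g", start = 200, end = 272, isotype = "His", anticodon = "GUG",
                mature_seq = sub("^(.{34}).{3}", paste0("\\1", "GUG"), seqs[3]),
                anticodon_offset = 34)
  )
}

test_that("terminal matches classify as five_prime/three_prime with the right parent", {
  refs <- make_refs()
  frag5 <- substr(refs$mature_seq[1], 1, 20)
  fc5 <- classify_ends(frag5, refs)
  expect_equal(fc5$end_class, "five_prime")
  expect_equal(fc5$parent$isotype, "Glu")
  expect_equal(fc5$mismatches_used, 0)

  frag3 <- substr(refs$mature_seq[2], 55, 72)
  fc3 <- classify_ends(frag3, refs)
  expect_equal(fc3$end_class, "three_prime")
  expect_equal(fc3$parent$isotype, "Gly")
})

test_that("internal matches and non-matches classify as tRF-1", {
  refs <- make_refs()
  motif <- "GGCCUUAUCGUCUAGUGAU"
  ref <- refs$mature_seq[1]
  with_motif <- paste0(substr(ref, 1, 40), motif, substr(ref, 60, 72))
  refs$mature_seq[1] <- with_motif
  refs$anticodon_offset[1] <- NA_integer_  # anticodon site was overwritten
  fc <- classify_ends(motif, refs)
  expect_equal(fc$end_class, "tRF1")
  expect_equal(fc$parent$isotype, "Glu")

  nohit <- classify_ends(paste(rep("ACGU", 5), collapse = ""), refs)
  expect_equal(nohit$end_class, "tRF1")
  expect_null(nohit$parent)

  expect_error(classify_ends("ACGUACGUACGUACG", refs[0, ]), "empty reference")
})

test_that("prefix beats suffix on mismatch ties and mismatch allowance works", {
  ref <- trna_record("g", start = 0, end = 20, isotype = "Ala", anticodon = "UGC",
                     mature_seq = "AAAACCCCGGGGUUUUAAAA")
  # fragment equals both the 4-nt prefix and suffix
  fc <- classify_ends("AAAA", ref)
  expect_equal(fc$end_class, "five_prime")
  # one substitution only matches under max_mismatch = 1
  fc0 <- classify_ends("AAAACCCCGGGGUUUUAAAG"                  , ref)
  expect_equal(fc0$end_class, "tRF1")
  fc1 <- classify_ends("AAAACCCCGGGGUUUUAAAG", ref, max_mismatch = 1)
  expect_equal(fc1$end_class, "five_prime")
  expect_equal(fc1$mismatches_used, 1)
})

test_that("end classes are mutually exclusive and exhaustive on planted sets", {
  sim <- generate(sim_config(seed = 21, n_genomes = 4))
  frags <- sim$fragments
  cls <- classify_fragments(setNames(frags$seq, frags$fragment_id), sim$records)
  expect_true(all(cls$end_class %in% c("five_prime", "three_prime", "tRF1")))
  # planted-truth recovery at 0 mismatches is exact
  expect_equal(cls$end_class, frags$end_class)
  expect_equal(cls$length_class, frags$length_class)
})

test_that("conserved_motif finds the longest common substring", {
  expect_equal(conserved_motif(c("GAUUACCAGGAU", "GAUUACCAGGAU"), min_len = 4),
               "GAUUACCAGGAU")
  expect_null(conserved_motif(c("AAAA", "CCCC"), min_len = 2))
  expect_error(conserved_motif("AAAA"), "at least 2")
  # DNA input is normalized: the printed DNA motif matches RNA fragments
  expect_equal(conserved_motif(c("TTGGCCTTATCGTCTAGTGATAA",
                                 "CCGGCCUUAUCGUCUAGUGAUGG")),
               "GGCCUUAUCGUCUAGUGAU")
})

test_that("conserved_motif agrees with the brute-force all-substrings oracle", {
  set.seed(42)
  for (rep in 1:8) {
    planted <- paste(sample(c("A", "C", "G", "U"), 12, replace = TRUE), collapse = "")
    frags <- vapply(1:3, function(i) {
      pre <- paste(sample(c("A", "C", "G", "U"), sample(5:15, 1), replace = TRUE),
                   collapse = "")
      post <- paste(sample(c("A", "C", "G", "U"), sample(5:15, 1), replace = TRUE),
                    collapse = "")
      paste0(pre, planted, post)
    }, character(1))
    got <- conserved_motif(frags, min_len = 4)
    want <- lcs_oracle(frags, min_len = 4)
    expect_equal(got, want)
    # the motif is a substring of every input
    expect_true(all(vapply(frags, function(f) grepl(got, f, fixed = TRUE),
                           logical(1))))
    expect_gte(nchar(got), 12)
  }
})
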