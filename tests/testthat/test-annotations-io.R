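test_that("tRNAscan rows become normalized records with 0-based half-open coordinates", {
  txt <- trnascan_text(c(
    scan_row("NC_1", 1, 100, 172, "Asn", "GTT"),
    scan_row("NC_1", 2, 500, 430, "Ala", "TGC"),
    scan_row("NC_1", 3, 700, 780, "Ile2", "CAT"),
    scan_row("NC_1", 4, 900, 1010, "Lys", "TTT", ib = 938, ie = 967)
  ))
  rec <- parse_trnascan_table(txt)
  expect_equal(nrow(rec), 4)
  expect_length(parse_errors(rec), 0)

  expect_equal(rec$start[1], 99)
  expect_equal(rec$end[1], 172)
  expect_equal(rec$strand[1], "+")
  expect_equal(rec$anticodon[1], "GUU")

  # begin > end rows are minus-strand, coordinates ascending
  expect_equal(rec$strand[2], "-")
  expect_equal(rec$start[2], 429)
  expect_equal(rec$end[2], 500)

  # special isotype passes through, DNA anticodon normalized
  expect_equal(rec$isotype[3], "Ile2")
  expect_equal(rec$anticodon[3], "CAU")

  # genomic intron bounds become gene-relative half-open intervals
  expect_equal(parse_introns(rec$introns[4]), list(c(38L, 68L)))
})

test_that("tRNAscan parser collects per-row errors and keeps going", {
  txt <- trnascan_text(c(
    scan_row("NC_1", 1, 100, 172, "Asn", "GTT"),
    "NC_1\tnot\tenough",
    scan_row("NC_1", 3, "abc", 300, "Ala", "TGC"),
    scan_row("NC_1", 4, 400, 470, "Gly", "GCC")
  ))
  rec <- parse_trnascan_table(txt)
  expect_equal(nrow(rec), 2)
  expect_length(parse_errors(rec), 2)
  expect_match(parse_errors(rec)[1], "fields")
})

test_that("empty tRNAscan input yields an empty record set, not an error", {
  rec <- parse_trnascan_table(trnascan_text(character(0)))
  expect_equal(nrow(rec), 0)
})

test_that("minus-strand intron conversion mirrors the plus-strand one", {
  # same gene and intron, written on both strands: gene-relative intervals
  # must agree
  plus <- parse_trnascan_table(trnascan_text(
    scan_row("g", 1, 101, 200, "Lys", "TTT", ib = 140, ie = 169)))
  minus <- parse_trnascan_table(trnascan_text(
    scan_row("g", 1, 200, 101, "Lys", "TTT", ib = 161, ie = 132)))
  expect_equal(parse_introns(plus$introns[1]), parse_introns(minus$introns[1]))
})

test_that("GFF3 features are classified and converted to internal coordinates", {
  txt <- c(
    gff3_line("chr1", "rRNA", 1001, 2500, "+", "product=16S ribosomal RNA"),
    gff3_line("chr1", "rRNA", 3000, 5800, "+", "product=23S ribosomal RNA"),
    gff3_line("chr1", "tRNA", 2600, 2680, "+", "product=trnA-UGC"),
    gff3_line("chr1", "tRNA", 100, 50, "+", "product=trnX"),
    gff3_line("chr1", "gene", 1, 10, "+", "ID=skipme")
  )
  f <- parse_gff3(txt)
  expect_equal(nrow(f), 3)
  expect_equal(f$kind, c("rRNA_16S", "rRNA_23S", "tRNA"))
  expect_equal(f$start[1], 1000)
  expect_equal(f$end[1], 2500)
  expect_equal(f$anticodon[3], "UGC")
  expect_length(parse_errors(f), 1)
  expect_match(parse_errors(f), "end < start")
})

test_that("GFF3 coordinate conversion composes to identity", {
  for (s1 in c(1L, 37L, 1000L)) {
    e1 <- s1 + 71L
    f <- parse_gff3(gff3_line("c", "tRNA", s1, e1, "+", "product=trnA-UGC"))
    expect_equal(f$start + 1L, s1)
    expect_equal(f$end, e1)
  }
})

test_that("GenBank features parse spans, strands and join() intron evidence", {
  gb <- c(
    "LOCUS       TESTGEN    5000 bp    DNA    circular PLN",
    "FEATURES             Location/Qualifiers",
    "     tRNA            100..172",
    "                     /product=\"tRNA-Asn\"",
    "     tRNA            join(100..130,180..230)",
    "                     /product=\"tRNA-Lys\"",
    "     tRNA            complement(300..372)",
    "                     /product=\"tRNA-Ala\"",
    "     rRNA            1000..2500",
    "                     /product=\"16S ribosomal RNA\"",
    "     tRNA            oops..bad",
    "                     /product=\"tRNA-Gly\"",
    "//"
  )
  f <- parse_genbank_features(gb)
  expect_equal(nrow(f), 4)
  expect_equal(f$genome_id[1], "TESTGEN")
  expect_equal(f$kind, c("tRNA", "tRNA", "tRNA", "rRNA_16S"))
  expect_equal(f$start[1], 99)
  expect_equal(f$end[1], 172)
  # intron = set difference of the span and the joined pieces
  # (oracle: span [99,230) minus pieces [99,130) u [179,230) = [130,179)... in
  # 1-based terms 131..179, i.e. genomic 0-based half-open [130, 179))
  expect_equal(f$introns[2], "130-179")
  expect_equal(f$strand[3], "-")
  expect_length(parse_errors(f), 1)
  expect_match(parse_errors(f), "unparseable location")
})

test_that("the spec's join example infers the expected genomic intron gap", {
  gb <- c(
    "LOCUS       J1    500 bp DNA",
    "FEATURES             Location/Qualifiers",
    "     tRNA            join(101..130,181..230)",
    "                     /product=\"tRNA-Lys\"",
    "//"
  )
  f <- parse_genbank_features(gb)
  # pieces cover [100,130) and [180,230): the gap is [130,180)
  expect_equal(f$introns[1], "130-180")
})

test_that("merging identical records from two sources is idempotent", {
  a <- parse_trnascan_table(trnascan_text(scan_row("g", 1, 101, 172, "Met", "CAT")))
  b <- a
  b$source <- "geseq"
  b$supports <- "geseq"
  m <- merge_annotations(list(a, b))
  expect_equal(nrow(m), 1)
  expect_equal(m$supports, "geseq+trnascan")
  expect_false(m$discordant)
  # merging the merge changes nothing
  m2 <- merge_annotations(list(m))
  expect_equal(m2$supports, m$supports)
  expect_equal(nrow(m2), 1)
})

test_that("isotype conflicts resolve by source precedence and are flagged", {
  a <- parse_trnascan_table(trnascan_text(scan_row("g", 1, 101, 172, "Met", "CAT")))
  b <- a
  b$source <- "aragorn"
  b$supports <- "aragorn"
  b$isotype <- "Ile2"
  m <- merge_annotations(list(b, a))
  expect_equal(nrow(m), 1)
  expect_equal(m$isotype, "Met")   # trnascan > aragorn
  expect_true(m$discordant)
})

test_that("non-overlapping records are both retained and merge is order-independent", {
  a <- trna_record("g", start = 0, end = 72, isotype = "Met", anticodon = "CAU",
                   source = "trnascan")
  b <- trna_record("g", start = 500, end = 572, isotype = "Ala", anticodon = "UGC",
                   source = "aragorn")
  m1 <- merge_annotations(list(a, b))
  m2 <- merge_annotations(list(b, a))
  expect_equal(nrow(m1), 2)
  expect_equal(m1, m2)
})

test_that("records survive a TSV round trip unchanged", {
  rec <- dplyr::bind_rows(
    mini_records(),
    trna_record("g3", start = 10, end = 120, strand = "-", isotype = "Lys",
                anticodon = "UUU", gene_seq = paste(rep("ACGU", 25), collapse = ""),
                introns = list(c(38L, 68L)), score = 77.5)
  )
  path <- tempfile(fileext = ".tsv")
  write_records_tsv(rec, path)
  back <- read_records_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(rec))
})

test_that("record invariants reject malformed inputs", {
  expect_error(trna_record("g", start = 10, end = 10, isotype = "Met",
                           anticodon = "CAU"), "start")
  expect_error(trna_record("g", start = 0, end = 72, isotype = "Met",
                           anticodon = "CAUXX"), "anticodon")
  expect_error(trna_record("g", start = 0, end = 72, isotype = "Lys",
                           anticodon = "UUU", introns = list(c(10L, 100L))),
               "intron")
})
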