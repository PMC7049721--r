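test_that("read collapsing merges duplicates and sums abundances", {
  p <- write_fasta_file(c("a", "b", "c"), c("AAA", "CCC", "AAA"))
  rs <- read_sequences(p, format = "fasta")
  expect_equal(nrow(rs$reads), 2L)
  expect_equal(rs$reads$abundance[rs$reads$sequence == "AAA"], 2L)
  expect_equal(rs$reads$abundance[rs$reads$sequence == "CCC"], 1L)
  expect_equal(total_abundance(rs), 3L)
})

test_that("collapsed headers contribute their count; others default to 1", {
  p <- write_fasta_file(c("r1_17", "plain", "x_2_5", "bad_n7"),
                        c("UGACAGAAGAGAGUGAGCAC", "ACGUACG", "AAACCC", "GGGUUU"))
  rs <- read_sequences(p, format = "collapsed")
  ab <- setNames(rs$reads$abundance, rs$reads$sequence)
  expect_equal(unname(ab["UGACAGAAGAGAGUGAGCAC"]), 17L)
  expect_equal(unname(ab["ACGUACG"]), 1L)
  expect_equal(unname(ab["AAACCC"]), 5L)   # final underscore-delimited token
  expect_equal(unname(ab["GGGUUU"]), 1L)   # non-numeric suffix
})

test_that("FASTQ records are counted per occurrence, qualities ignored", {
  seqs <- rep("ACGTACGTACGTACGTACGT", 4L)   # DNA input, U-normalized
  p <- write_fastq_file(seqs)
  n_records <- sum(startsWith(readLines(p), "@"))   # independent count
  rs <- read_sequences(p, format = "fastq")
  expect_equal(nrow(rs$reads), 1L)
  expect_equal(rs$reads$abundance, n_records)
  expect_equal(rs$reads$sequence, "ACGUACGUACGUACGUACGU")
})

test_that("collapsed FASTA round-trips exactly and re-reading is idempotent", {
  set.seed(5)
  rs <- read_set(replicate(20, random_rna(sample(19:24, 1))),
                 sample(1:50, 20, replace = TRUE))
  p <- tempfile(fileext = ".fa")
  write_collapsed_fasta(rs, p)
  back <- read_sequences(p, format = "collapsed")
  expect_equal(back$reads, rs$reads)
  p2 <- tempfile(fileext = ".fa")
  write_collapsed_fasta(back, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("transcriptome reader tokenizes ids and rejects bad input", {
  p <- write_fasta_file(c("AT1G01010.1 | symbol", "AT2G02020.1"),
                        c("ATGCATGC", "GGGCCC"))
  tx <- read_transcriptome(p)
  expect_equal(names(tx), c("AT1G01010.1", "AT2G02020.1"))
  expect_equal(unname(tx[1]), "AUGCAUGC")   # canonical RNA alphabet

  dup <- write_fasta_file(c("t1", "t1"), c("AAA", "CCC"))
  expect_error(read_transcriptome(dup), "duplicate transcript id")
  empty <- write_fasta_file(c("t1", "t2"), c("AAA", ""))
  expect_error(read_transcriptome(empty), "empty sequence")
  expect_error(read_transcriptome(tempfile()), "no such file")
})

test_that("validated-interaction tables are parsed with a tolerant schema", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c(
    "mirna_id\tmirna_sequence\ttranscript_id\tcleavage_position\textra",
    "miR1\tUGACAGAAGAGAGUGAGCAC\tAT1G01010.1\t1001\tfoo",
    "miR2\tUUGACAGAAGAUAGAGAGCAC\tAT2G02020.1\t52\tbar",
    "miR3\tACGUACGUACGUACGUACGUA\tAT3G03030.1\t7\tbaz"
  ), p)
  v <- read_validated(p)
  expect_equal(nrow(v), 3L)
  expect_equal(v$cleavage_position, c(1001L, 52L, 7L))
  expect_false("extra" %in% names(v))

  bad <- tempfile()
  writeLines(c("mirna_id\tmirna_sequence\ttranscript_id\tcleavage_position",
               "miR1\tACGU\tt1\t0"), bad)
  expect_error(read_validated(bad), "cleavage_position")
  miss <- tempfile()
  writeLines(c("mirna_id\ttranscript_id", "miR1\tt1"), miss)
  expect_error(read_validated(miss), "missing column")
})

test_that("miRNA annotations get species and clade metadata", {
  p <- write_fasta_file(c("ath-miR156a MIMAT0000166", "osa-miR156b X"),
                        c("UGACAGAAGAGAGUGAGCAC", "UGACAGAAGAGAGUGAGCAC"))
  mi <- read_mirnas(p)
  expect_equal(mi$species, c("ath", "osa"))
  expect_equal(mi$clade, c("Brassicaceae", "Poaceae"))
  short <- write_fasta_file("xxx-miR1", "ACGUACGU")
  expect_warning(read_mirnas(short), "19-25")
})

test_that("read_set enforces its invariants", {
  expect_error(read_set("ACGU", 0L), "abundance")
  expect_error(read_set(c("ACGU", ""), 1L), "length")
  expect_error(read_set("ACGB", 1L), "characters")
  rs <- read_set(character(0))
  expect_equal(total_abundance(rs), 0L)
})
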