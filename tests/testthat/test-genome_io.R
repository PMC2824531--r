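test_that("FASTA reader parses, folds case, and preserves order", {
  f <- tempfile(fileext = ".fna")
  writeLines(c(">seq1 some description", "acgt", ">seq2", "GGCC", "aatt"), f)
  s <- read_fasta(f, "dna")
  expect_identical(names(s), c("seq1", "seq2"))
  expect_identical(unname(s), c("ACGT", "GGCCAATT"))

  empty <- tempfile()
  writeLines(character(0), empty)
  expect_length(read_fasta(empty, "dna"), 0)
})

test_that("FASTA reader rejects malformed input with line numbers", {
  f <- tempfile()
  writeLines(c("ACGT", ">late"), f)
  expect_error(read_fasta(f, "dna"), "line 1")

  f2 <- tempfile()
  writeLines(c(">a", "ACGJ"), f2)
  expect_error(read_fasta(f2, "dna"), "J")

  f3 <- tempfile()
  writeLines(c(">a", "ACGT", ">a", "GGGG"), f3)
  expect_error(read_fasta(f3, "dna"), "duplicate")
})

test_that("FASTA writer round-trips and agrees with Biostrings", {
  set.seed(41)
  seqs <- setNames(vapply(1:8, function(i) rand_aa_seq(sample(20:90, 1)), ""),
                   paste0("p", 1:8))
  f <- tempfile(fileext = ".faa")
  write_fasta(seqs, f, width = 37)
  expect_identical(read_fasta(f, "protein"), seqs)
  ref <- Biostrings::readAAStringSet(f)
  expect_identical(setNames(as.character(ref), names(ref)), seqs)
})

test_that("translation follows the plain standard code", {
  expect_identical(translate_cds("ATG"), "M")
  expect_identical(translate_cds("ATGTAA"), "M")
  expect_identical(translate_cds("ATGNNTTAA"), "MX")
  expect_error(translate_cds("ATGA"), "divisible by 3")
  expect_error(translate_cds("ATGTAAGGG"), "codon index 2")
  # cross-check against Biostrings on unambiguous stop-free codons
  set.seed(42)
  for (i in 1:10) {
    aa <- rand_aa_seq(40)
    nt <- reverse_translate(aa, 0.5)
    core <- substr(nt, 1, nchar(nt) - 3)
    expect_identical(
      translate_cds(core),
      as.character(Biostrings::translate(Biostrings::DNAString(core))))
  }
})

test_that("hit tables round-trip and reject bad lines precisely", {
  h <- rand_hits(paste0("a", 1:5), paste0("b", 1:5), density = 0.8)
  f <- tempfile()
  write_hit_table(h, f)
  h2 <- read_hit_table(f)
  expect_identical(h2$qseqid, h$qseqid)
  expect_equal(h2$evalue, h$evalue, tolerance = 1e-2)
  expect_identical(h2[c("length", "qstart", "qend")],
                   h[c("length", "qstart", "qend")])

  f2 <- tempfile()
  writeLines(c("# a comment", "# another"), f2)
  expect_identical(nrow(read_hit_table(f2)), 0L)

  f3 <- tempfile()
  writeLines(paste(rep("x", 11), collapse = "\t"), f3)
  expect_error(read_hit_table(f3), "line 1")

  f4 <- tempfile()
  writeLines(paste(c("a", "b", "oops", rep("1", 9)), collapse = "\t"), f4)
  expect_error(read_hit_table(f4), "unparseable")
})

test_that("report tables print percentages at one decimal and round-trip", {
  tab <- data.frame(set = c("core", "clade"), count = c(10L, 4L),
                    pct_of_total = c(83.94, 12.25))
  f <- tempfile()
  write_report_table(tab, f)
  txt <- readLines(f)
  expect_match(txt[2], "83.9")
  rt <- read_report_table(f)
  expect_identical(rt$count, tab$count)
  expect_equal(rt$pct_of_total, c(83.9, 12.2))

  f2 <- tempfile()
  write_report_table(tab[0, ], f2)
  expect_length(readLines(f2), 1L)  # header only
  expect_error(write_report_table(unname(tab), f2), "named")
})

test_that("genome collections validate ids, nesting and focal membership", {
  meta <- genome_meta(c("gA", "gB", "gC"), paste0("sp_", 1:3),
                      c("cold", "warm", "warm"))
  cds <- data.frame(cds_id = c("x1", "x2", "y1"),
                    genome_id = c("gA", "gA", "gB"),
                    nt_seq = NA_character_, aa_seq = c("MA", "MC", "MD"))
  coll <- genome_collection(meta, cds, list(c("gA", "gB", "gC"),
                                            c("gA", "gB")), "gA")
  expect_s3_class(coll, "genome_collection")
  expect_named(proteome(coll, "gA"), c("x1", "x2"))

  expect_error(genome_collection(meta, cds,
                                 list(c("gA", "gB"), c("gA", "gC")), "gA"),
               "not nested")
  expect_error(genome_collection(meta, cds, list(c("gB", "gC")), "gA"),
               "focal")
  cds_bad <- cds; cds_bad$cds_id[2] <- "x1"
  expect_error(genome_collection(meta, cds_bad, list(meta$genome_id), "gA"),
               "duplicate")
})

test_that("collections round-trip through FASTA + metadata on disk", {
  s <- small_sim_run(seed = 9, n_genomes = 3, n_core = 4, n_private = 1,
                     mean_len = 40)
  d <- tempfile()
  write_collection(s$collection, d)
  back <- read_collection(d)
  expect_identical(back$meta, s$collection$meta)
  expect_identical(back$hierarchy, s$collection$hierarchy)
  o <- order(s$collection$cds$cds_id)
  ob <- order(back$cds$cds_id)
  expect_equal(back$cds[ob, ], s$collection$cds[o, ], ignore_attr = TRUE)
})
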