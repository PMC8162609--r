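test_that("FASTA reading concatenates wrapped lines and uppercases", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a first record", "acgt", "ACGT", ">b", "TTTT"), f)
  rec <- read_fasta(f)
  expect_equal(rec$id, c("a", "b"))
  expect_equal(rec$seq, c("ACGTACGT", "TTTT"))
  expect_equal(rec$desc, c("first record", ""))
})

test_that("FASTA writing preserves order, wraps at width, round-trips", {
  f <- withr::local_tempfile(fileext = ".fa")
  rec <- seq_set(c("z9", "a1"), c(strrep("ACGTA", 30L), "ACGT"),
                 c("late", ""))
  write_fasta(rec, f)
  lines <- readLines(f)
  expect_equal(lines[1L], ">z9 late")            # input order kept
  expect_equal(sum(startsWith(lines, ">")), 2L)
  expect_equal(sum(!startsWith(lines, ">")) - 1L, 3L)  # 150 bp at 70 -> 3 lines
  expect_equal(read_fasta(f), rec)
  expect_error(write_fasta(rec, f, width = 0), "width")
  expect_error(write_fasta(rec[0, ], f), "no records")
})

test_that("FASTA contract errors name the problem", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "TTTT"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(c(">a", "ACGT", ">b", "AC#T"), f)
  expect_error(read_fasta(f), "line 4")
  file.create(f2 <- withr::local_tempfile(fileext = ".fa"))
  expect_error(read_fasta(f2), "empty")
  writeLines(c("ACGT"), f)
  expect_error(read_fasta(f), ">")
})

test_that("FASTQ round-trips byte-exactly and validates records", {
  f <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "IIII"), f)
  r <- read_fastq(f)
  expect_equal(r$id, "r1")
  expect_equal(r$seq, "ACGT")
  expect_equal(r$qual, "IIII")
  set.seed(1)
  sim <- simulate_reads(seq_set("c1", random_dna(600)),
                        read_sim_spec(coverage = 5, paired = FALSE, seed = 2))
  write_fastq(sim$reads1, f)
  expect_identical(read_fastq(f), sim$reads1)

  writeLines(c("@r1", "ACGT", "+", "III"), f)
  expect_error(read_fastq(f), "mismatch")
  writeLines(c("@r1", "ACGT", "+"), f)
  expect_error(read_fastq(f), "truncated")
  file.create(f3 <- withr::local_tempfile(fileext = ".fq"))
  expect_equal(nrow(read_fastq(f3)), 0L)
})

test_that("GFF3 round-trips CDS features with products and checks bounds", {
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  contig <- paste0("TTTTTT", "ATGAAATAA", "CCCCC")   # CDS at 7..15
  write_fasta(seq_set("c1", contig), fa)
  ann <- annotation_set("g", seq_set("c1", contig),
                        data.frame(feature_id = "g_00001", contig_id = "c1",
                                   start = 7L, end = 15L, strand = "+",
                                   type = "CDS", product = "widget synthase"))
  write_gff3(ann, gff)
  back <- read_gff3(gff, fa, genome_id = "g")
  expect_equal(back$features[, c("feature_id", "contig_id", "start", "end",
                                 "strand", "product")],
               ann$features[, c("feature_id", "contig_id", "start", "end",
                                "strand", "product")])
  expect_error(
    annotation_set("g", seq_set("c1", contig),
                   data.frame(feature_id = "x", contig_id = "c1",
                              start = 10L, end = 25L, strand = "+",
                              type = "CDS", product = "p")),
    "bounds")
  expect_error(
    annotation_set("g", seq_set("c1", contig),
                   data.frame(feature_id = "x", contig_id = "nope",
                              start = 1L, end = 9L, strand = "+",
                              type = "CDS", product = "p")),
    "unknown contig")
})

test_that("PGAP inputs share entry order and translate consistently", {
  contig <- paste0("TTAATTAACTAA", "ATGAAATAA", "TTAATTAACTAA",
                   "ATGTGGTGGTAA", "TTAATTAACTAA", "ATGCCCTAA",
                   "TTAATTAACTAA")
  feats <- data.frame(feature_id = c("g1", "g2", "g3"),
                      contig_id = "c1",
                      start = c(13L, 34L, 58L),
                      end = c(21L, 45L, 66L),
                      strand = "+", type = "CDS",
                      product = c("hypothetical protein", "tryptophan thing",
                                  "proline thing"))
  ann <- annotation_set("g", seq_set("c1", contig), feats)
  prefix <- file.path(withr::local_tempdir(), "g")
  paths <- write_pgap_inputs(ann, prefix)
  pep <- read_fasta(paths[["pep"]], alphabet = "any")
  nuc <- read_fasta(paths[["nuc"]])
  fun <- read.delim(paths[["fun"]], header = FALSE)
  expect_equal(pep$id, c("g1", "g2", "g3"))
  expect_equal(nuc$id, pep$id)
  expect_equal(fun$V1, pep$id)
  expect_equal(fun$V2, rep("-", 3L))
  expect_equal(fun$V3, feats$product)
  expect_equal(pep$seq[1L], "MK")
  expect_equal(nuc$seq[1L], "ATGAAATAA")
  # translation consistency across the three files
  expect_equal(translate_cds(nuc$seq, init_met = TRUE), pep$seq)
  expect_error(write_pgap_inputs(annotation_set("g", seq_set("c1", contig)),
                                 prefix), "no CDS")
})

test_that("CDS with internal stops are skipped in all three PGAP files", {
  contig <- paste0("TTAATTAACTAA", "ATGAAATAA", "TTAATTAACTAA")
  # fake a feature whose span includes an in-frame stop before the end
  feats <- data.frame(feature_id = c("ok", "bad"), contig_id = "c1",
                      start = c(13L, 10L), end = c(21L, 24L),
                      strand = "+", type = "CDS", product = "p")
  ann <- annotation_set("g", seq_set("c1", contig), feats)
  prefix <- file.path(withr::local_tempdir(), "g")
  expect_warning(paths <- write_pgap_inputs(ann, prefix), "internal stop")
  expect_equal(read_fasta(paths[["pep"]], alphabet = "any")$id, "ok")
  expect_equal(read_fasta(paths[["nuc"]])$id, "ok")
  expect_equal(nrow(read.delim(paths[["fun"]], header = FALSE)), 1L)
})
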