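test_that("random genes have start/stop structure and no internal stops", {
  set.seed(3)
  expect_error(random_gene(8), "multiple of 3")
  g9 <- random_gene(9)
  expect_equal(nchar(g9), 9L)
  expect_equal(substr(g9, 1, 3), "ATG")
  expect_true(substr(g9, 7, 9) %in% c("TAA", "TAG", "TGA"))
  genes <- vapply(rep(99L, 1000L), random_gene, "")
  internal <- vapply(genes, function(g) {
    p <- seq(1L, nchar(g) - 3L, by = 3L)  # all codons but the last
    any(substring(g, p, p + 2L) %in% c("TAA", "TAG", "TGA"))
  }, NA)
  expect_false(any(internal))
})

test_that("accessory spectrum reproduces the target discovery curve", {
  G <- 12L
  pfirst <- function(s, N) {
    if (N - 1L > G - s) return(0)
    exp(lchoose(G - s, N - 1L) - lchoose(G, N - 1L)) * s / (G - N + 1L)
  }
  for (alpha in c(0.3, 0.7)) {
    cs <- accessory_spectrum(G, 60, alpha)
    expected <- vapply(2:G, function(N) {
      sum(vapply(seq_along(cs), function(s) cs[s] * pfirst(s, N), 0))
    }, 0)
    target <- 60 * (2:G)^(-alpha)
    expect_lt(max(abs(expected - target) / target), 0.06)
  }
  expect_equal(accessory_spectrum(12L, 0, 0.5), integer(11L))
})

test_that("pangenome generation is deterministic and truth is a partition", {
  sp <- pangenome_spec(n_genomes = 4, core_families = 6, kappa = 8,
                       alpha_true = 0.5, gene_len_range = c(300L, 600L),
                       seed = 7)
  a <- generate_pangenome(sp)
  b <- generate_pangenome(sp)
  expect_identical(a, b)
  sim <- small_sim()
  # every gene in exactly one family
  expect_false(anyDuplicated(sim$truth$feature_id) > 0)
  all_feats <- unlist(lapply(sim$genomes, function(g) g$features$feature_id))
  expect_setequal(sim$truth$feature_id, all_feats)
  # family membership lists agree with the emitted genomes
  nm <- sort(names(sim$families))
  emitted <- lapply(nm, function(f) {
    sort(unique(sim$truth$genome_id[sim$truth$family_id == f]))
  })
  expect_identical(emitted, unname(lapply(sim$families[nm], sort)))
})

test_that("kappa = 0 yields a pure core pangenome", {
  sim <- generate_pangenome(pangenome_spec(n_genomes = 3, core_families = 10,
                                           kappa = 0, alpha_true = 0.5,
                                           seed = 2))
  expect_equal(length(sim$families), 10L)
  for (g in sim$genomes) expect_equal(nrow(g$features), 10L)
  expect_true(all(vapply(sim$families, length, 0L) == 3L))
})

test_that("emitted gene coordinates re-extract the planted genes", {
  sim <- small_sim()
  for (g in sim$genomes[1:2]) {
    nuc <- cds_sequences(g)$nuc
    expect_true(all(substr(nuc, 1, 3) == "ATG"))
    expect_true(all(substring(nuc, nchar(nuc) - 2L) %in%
                      c("TAA", "TAG", "TGA")))
  }
  # family members are exact copies across genomes
  nucs <- do.call(rbind, lapply(sim$genomes, function(g) {
    cbind(cds_sequences(g)[, "nuc", drop = FALSE],
          fam = g$features$family_id)
  }))
  per_fam <- tapply(nucs$nuc, nucs$fam, function(x) length(unique(x)))
  expect_true(all(per_fam == 1L))
})

test_that("read simulation matches the coverage contract", {
  ctg <- seq_set("c1", random_dna(1000))
  set.seed(1)
  rd <- simulate_reads(ctg, read_sim_spec(read_len = 100, coverage = 10,
                                          paired = FALSE, error_rate = 0,
                                          seed = 5))
  expect_equal(nrow(rd$reads1), 100L)   # ceil(10 * 1000 / 100)
  expect_null(rd$reads2)
  # error-free reads are exact substrings of a strand of the contig
  onref <- vapply(rd$reads1$seq[1:50], function(s) {
    grepl(s, ctg$seq, fixed = TRUE) || grepl(revcomp(s), ctg$seq, fixed = TRUE)
  }, NA)
  expect_true(all(onref))
})

test_that("paired simulation emits matched /1 and /2 mates", {
  ctg <- seq_set("c1", random_dna(2000))
  rd <- simulate_reads(ctg, read_sim_spec(coverage = 4, paired = TRUE,
                                          seed = 8))
  expect_equal(sub("/1$", "", rd$reads1$id), sub("/2$", "", rd$reads2$id))
  expect_true(all(grepl("/1$", rd$reads1$id)))
  expect_true(all(grepl("/2$", rd$reads2$id)))
  expect_identical(simulate_reads(ctg, read_sim_spec(coverage = 4, seed = 8)),
                   rd)
  expect_warning(simulate_reads(seq_set("tiny", "ACGTACGT"),
                                read_sim_spec(coverage = 2, paired = FALSE,
                                              seed = 1)),
                 "skipped")
})

test_that("planting excises genes from the reference but not the reads source", {
  sim <- small_sim()
  g <- sim$genomes[[1L]]
  expect_identical(plant_missing_genes(g, 0)$reference, g$contigs)
  pl <- plant_missing_genes(g, 2, seed = 9)
  expect_equal(nchar(pl$reference$seq),
               nchar(g$contigs$seq) - sum(nchar(pl$planted$nuc)))
  # every planted gene absent (as substring, either strand) from the
  # excised reference
  for (nuc in pl$planted$nuc) {
    expect_false(grepl(nuc, pl$reference$seq, fixed = TRUE))
    expect_false(grepl(revcomp(nuc), pl$reference$seq, fixed = TRUE))
  }
  expect_identical(pl$original, g$contigs)
  expect_error(plant_missing_genes(g, nrow(g$features)), "less than")
})
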