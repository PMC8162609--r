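# Shared fixtures, generated in code and cached per test session.

.fixture_cache <- new.env()

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small pangenome for fast module tests
small_sim <- function() {
  cached("small_sim", generate_pangenome(
    pangenome_spec(n_genomes = 4, core_families = 6, kappa = 8,
                   alpha_true = 0.5, gene_len_range = c(300L, 600L),
                   seed = 7)))
}

# study-condition fixture: 12-genome pangenome, 5 genes excised from one
# genome, error-free 30x paired 100 bp reads from the original genome
stage1_fixture <- function() {
  cached("stage1", {
    sim <- generate_pangenome(pangenome_spec(seed = 11))
    g <- sim$genomes[[3L]]
    pl <- plant_missing_genes(g, 5, seed = 42)
    rd <- simulate_reads(seq_set(g$contigs$id, pl$original$seq),
                         read_sim_spec(seed = 5))
    list(sim = sim, genome = g, planted = pl, reads = rd)
  })
}

stage1_result <- function() {
  cached("stage1_result", {
    fx <- stage1_fixture()
    run_discovery(fx$planted$reference, fx$reads$reads1, fx$reads$reads2,
                  genome_id = "G03")
  })
}

# tiny three-organism run directory for pipeline tests; returns a config
pipeline_fixture <- function(outdir) {
  sim <- generate_pangenome(
    pangenome_spec(n_genomes = 3, core_families = 5, kappa = 4,
                   alpha_true = 0.5, gene_len_range = c(300L, 450L),
                   spacer_len_range = c(60L, 120L), seed = 4))
  orgs <- list()
  for (g in names(sim$genomes)) {
    ann <- sim$genomes[[g]]
    pl <- plant_missing_genes(ann, 1, seed = match(g, names(sim$genomes)))
    rd <- simulate_reads(seq_set(ann$contigs$id, pl$original$seq),
                         read_sim_spec(coverage = 20,
                                       seed = 10 + match(g, names(sim$genomes))))
    d <- file.path(outdir, "inputs", g)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_fasta(pl$reference, file.path(d, "ref.fasta"))
    write_fastq(rd$reads1, file.path(d, "r1.fastq"))
    write_fastq(rd$reads2, file.path(d, "r2.fastq"))
    orgs[[g]] <- data.frame(genome_id = g,
                            reference = file.path(d, "ref.fasta"),
                            reads1 = file.path(d, "r1.fastq"),
                            reads2 = file.path(d, "r2.fastq"))
  }
  run_config(do.call(rbind, orgs), outdir = file.path(outdir, "out"),
             n_perms = 50, seed = 9)
}

# md5 digests of the machine-readable outputs of a run directory
run_table_digests <- function(outdir) {
  fs <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  fs <- fs[grepl("\\.(tsv|json|nwk|fasta|fastq|gff3|pep|nuc|function)$", fs)]
  fs <- fs[!grepl("state\\.json$", fs)]
  fs <- fs[order(sub(outdir, "", fs, fixed = TRUE))]
  stats::setNames(unname(tools::md5sum(fs)),
                  sub(outdir, "", fs, fixed = TRUE))
}
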