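# Synthetic multi-strain pangenomes with known family structure, simulated
# sequencing reads, and planted missing-gene scenarios. These generators are
# the package's test bed: every pipeline stage can be exercised against a
# known truth table without downloading any data.

#' Specification of a synthetic pangenome
#'
#' @param n_genomes number of genomes (>= 2).
#' @param core_families number of gene families present in every genome.
#' @param kappa Heap's-law scale: the expected number of not-yet-seen gene
#'   families contributed by the N-th genome of a random genome ordering is
#'   `kappa * N^-alpha_true`.
#' @param alpha_true Heap's-law decay exponent of the new-gene curve.
#' @param gene_len_range min/max gene length in nucleotides (multiples of 3,
#'   >= 150, stop codon included).
#' @param spacer_len_range min/max intergenic spacer length.
#' @param gc GC fraction of generated genes.
#' @param seed integer seed; generation is deterministic under it.
#' @return an object of class `pangenome_spec`.
#' @export
pangenome_spec <- function(n_genomes = 12L, core_families = 20L, kappa = 60,
                           alpha_true = 0.45, gene_len_range = c(300L, 900L),
                           spacer_len_range = c(60L, 200L), gc = 0.5,
                           seed = 1L) {
  stopifnot(n_genomes >= 2L, core_families >= 0L, kappa >= 0, alpha_true > 0,
            length(gene_len_range) == 2L, gene_len_range[1L] >= 150L,
            all(gene_len_range %% 3L == 0L),
            gene_len_range[1L] <= gene_len_range[2L],
            length(spacer_len_range) == 2L, spacer_len_range[1L] >= 0L,
            gc > 0, gc < 1)
  structure(list(n_genomes = as.integer(n_genomes),
                 core_families = as.integer(core_families),
                 kappa = kappa, alpha_true = alpha_true,
                 gene_len_range = as.integer(gene_len_range),
                 spacer_len_range = as.integer(spacer_len_range),
                 gc = gc, seed = as.integer(seed)),
            class = "pangenome_spec")
}

#' Specification of simulated sequencing reads
#'
#' @param read_len read length (>= 50).
#' @param coverage mean per-base coverage.
#' @param paired generate read pairs (FR orientation) instead of single-end.
#' @param insert_mean,insert_sd fragment-size distribution (paired only).
#' @param error_rate i.i.d. substitution error rate in `[0, 0.1)`.
#' @param seed integer seed.
#' @return an object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(read_len = 100L, coverage = 30, paired = TRUE,
                          insert_mean = 300, insert_sd = 30,
                          error_rate = 0, seed = 1L) {
  stopifnot(read_len >= 50L, coverage > 0, error_rate >= 0, error_rate < 0.1,
            insert_mean > 0, insert_sd > 0)
  if (paired && insert_mean < read_len) {
    stop("insert_mean must be >= read_len for paired reads")
  }
  structure(list(read_len = as.integer(read_len), coverage = coverage,
                 paired = isTRUE(paired), insert_mean = insert_mean,
                 insert_sd = insert_sd, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "read_sim_spec")
}

.stop_codons <- c("TAA", "TAG", "TGA")

#' Generate a random protein-coding gene
#'
#' The gene starts with `ATG`, ends with a stop codon, and contains no
#' in-frame internal stop. Uses the current RNG state.
#'
#' @param length gene length in nucleotides (multiple of 3, >= 9).
#' @param gc GC fraction used when drawing codon bases.
#' @return a nucleotide string.
#' @export
random_gene <- function(length, gc = 0.5) {
  if (length %% 3L != 0L || length < 9L) {
    stop("gene length must be a multiple of 3 and >= 9")
  }
  n_mid <- length %/% 3L - 2L
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  draw <- function(n) {
    m <- matrix(sample(names(p), 3L * n, replace = TRUE, prob = p), nrow = n)
    paste0(m[, 1L], m[, 2L], m[, 3L])
  }
  mid <- character(0)
  if (n_mid > 0L) {
    mid <- draw(n_mid)
    while (any(bad <- mid %in% .stop_codons)) mid[bad] <- draw(sum(bad))
  }
  paste0("ATG", paste(mid, collapse = ""), sample(.stop_codons, 1L))
}

# Intergenic spacers are start-codon-free on both strands and carry stop
# codons in all six frames, so ORF calls on adjacent genes start exactly at
# the genes' own start codons (guaranteed for spacers >= 24 nt).
# The insulator has an in-frame stop in every frame of both strands and is
# placed at both spacer ends; the filler uses {A,C,T} with no "CA"
# dinucleotide, which excludes ATG/GTG/TTG on the forward strand (no G)
# and CAT/CAC/CAA (reverse-strand starts) alike.
.insulator <- "TTAATTAACTAA"

.spacer <- function(len) {
  if (len <= 0L) return("")
  ni <- nchar(.insulator)
  if (len < 2L * ni) {
    return(substr(strrep(.insulator, ceiling(len / ni)), 1L, len))
  }
  nf <- len - 2L * ni
  filler <- ""
  if (nf > 0L) {
    ch <- sample(c("A", "C", "T"), nf, replace = TRUE)
    ca <- which(ch[-nf] == "C" & ch[-1L] == "A")
    while (length(ca)) {
      ch[ca + 1L] <- "T"
      ca <- which(ch[-nf] == "C" & ch[-1L] == "A")
    }
    filler <- paste(ch, collapse = "")
  }
  paste0(.insulator, filler, .insulator)
}

# P(a family present in s of G genomes is first seen at position N of a
# uniformly random genome ordering)
.p_first <- function(s, N, G) {
  if (N - 1L > G - s) return(0)
  exp(lchoose(G - s, N - 1L) - lchoose(G, N - 1L)) * s / (G - N + 1L)
}

#' Accessory family frequency spectrum for a target new-gene curve
#'
#' Solves (by back-substitution, then rounding) for the number of accessory
#' families present in exactly `s` of `G` genomes such that the expected
#' number of families first seen at position `N` of a random genome ordering
#' equals `kappa * N^-alpha` for `N = 2..G`.
#'
#' @param G number of genomes.
#' @param kappa,alpha target Heap's-law parameters.
#' @return integer vector of length `G - 1`: counts for sizes `1..G-1`.
#' @export
accessory_spectrum <- function(G, kappa, alpha) {
  if (kappa <= 0) return(integer(G - 1L))
  c_s <- numeric(G - 1L)
  for (N in G:2L) {
    s <- G - N + 1L
    resid <- kappa * N^(-alpha)
    if (s > 1L) {
      resid <- resid - sum(vapply(seq_len(s - 1L),
                                  function(j) c_s[j] * .p_first(j, N, G), 0))
    }
    c_s[s] <- max(0, resid / .p_first(s, N, G))
  }
  as.integer(pmax(0, round(c_s)))
}

# balanced membership assignment: each size-s family takes the s least-loaded
# genomes (random tie-break), keeping per-genome accessory load even
.assign_members <- function(counts, G) {
  members <- list()
  load <- numeric(G)
  for (s in seq_along(counts)) {
    if (counts[s] < 1L) next
    for (i in seq_len(counts[s])) {
      ord <- order(load, sample.int(G))
      mem <- sort(ord[seq_len(s)])
      load[mem] <- load[mem] + 1
      members[[length(members) + 1L]] <- mem
    }
  }
  members
}

#' Generate a synthetic multi-strain pangenome
#'
#' Core families are present in all genomes; accessory families are planted
#' with the frequency spectrum of [accessory_spectrum()], so the expected
#' permutation new-gene curve follows `kappa * N^-alpha_true`. Family members
#' are exact gene copies; genes are separated by stop-rich spacers and laid
#' on one contig per genome in randomised order and strand.
#'
#' @param spec a [pangenome_spec()].
#' @return a list of class `pangenome_sim` with elements `genomes` (named
#'   list of [annotation_set()]s; feature `product` carries the family label),
#'   `truth` (data frame `genome_id`, `feature_id`, `family_id`) and
#'   `families` (named list: family id -> genome ids).
#' @export
generate_pangenome <- function(spec) {
  stopifnot(inherits(spec, "pangenome_spec"))
  set.seed(spec$seed)
  G <- spec$n_genomes
  genome_ids <- sprintf("G%02d", seq_len(G))
  counts <- accessory_spectrum(G, spec$kappa, spec$alpha_true)
  acc_members <- .assign_members(counts, G)
  n_fam <- spec$core_families + length(acc_members)
  if (n_fam == 0L) stop("specification yields zero gene families")
  fam_ids <- sprintf("F%04d", seq_len(n_fam))
  members <- c(rep(list(seq_len(G)), spec$core_families), acc_members)
  names(members) <- fam_ids
  lens <- 3L * resample(seq(spec$gene_len_range[1L] %/% 3L,
                            spec$gene_len_range[2L] %/% 3L),
                        n_fam, replace = TRUE)
  genes <- vapply(lens, random_gene, "", gc = spec$gc)
  names(genes) <- fam_ids

  genomes <- vector("list", G)
  truth <- vector("list", G)
  for (g in seq_len(G)) {
    fams <- fam_ids[vapply(members, function(m) g %in% m, NA)]
    fams <- sample(fams)
    n <- length(fams)
    spac <- vapply(resample(seq(spec$spacer_len_range[1L],
                                spec$spacer_len_range[2L]),
                            n + 1L, replace = TRUE), .spacer, "")
    strands <- sample(c("+", "-"), n, replace = TRUE)
    placed <- ifelse(strands == "+", genes[fams], revcomp(genes[fams]))
    pieces <- character(2L * n + 1L)
    pieces[seq(1L, 2L * n + 1L, 2L)] <- spac
    pieces[seq(2L, 2L * n, 2L)] <- placed
    contig <- paste(pieces, collapse = "")
    off <- cumsum(nchar(pieces))
    starts <- off[seq(1L, 2L * n - 1L, 2L)] + 1L
    ends <- off[seq(2L, 2L * n, 2L)]
    feats <- data.frame(feature_id = sprintf("%s_%05d", genome_ids[g], seq_len(n)),
                        contig_id = paste0(genome_ids[g], "_c1"),
                        start = starts, end = ends, strand = strands,
                        type = "CDS",
                        product = paste(fams, "protein"),
                        family_id = fams, stringsAsFactors = FALSE)
    genomes[[g]] <- annotation_set(genome_ids[g],
                                   seq_set(paste0(genome_ids[g], "_c1"), contig),
                                   feats)
    truth[[g]] <- data.frame(genome_id = genome_ids[g],
                             feature_id = feats$feature_id,
                             family_id = fams, stringsAsFactors = FALSE)
  }
  names(genomes) <- genome_ids
  structure(list(genomes = genomes,
                 truth = do.call(rbind, truth),
                 families = lapply(members, function(m) genome_ids[m]),
                 spec = spec),
            class = "pangenome_sim")
}

#' @export
print.pangenome_sim <- function(x, ...) {
  cat(sprintf("<pangenome_sim> %d genomes, %d families (%d core), %d genes\n",
              length(x$genomes), length(x$families),
              sum(vapply(x$families, length, 0L) == length(x$genomes)),
              nrow(x$truth)))
  invisible(x)
}

#' Simulate sequencing reads from a genome
#'
#' Per contig, `ceiling(coverage * length / read_len)` reads are drawn
#' (halved per mate when paired) at uniform positions and strands, with
#' i.i.d. substitution errors at `error_rate` and constant quality `"I"`.
#' Paired mates carry `/1` and `/2` id suffixes. Contigs shorter than the
#' read length are skipped with a warning.
#'
#' @param records a [seq_set()] of contigs (or an [annotation_set()]).
#' @param spec a [read_sim_spec()].
#' @return `list(reads1 = , reads2 = )`; `reads2` is `NULL` for single-end.
#' @export
simulate_reads <- function(records, spec) {
  stopifnot(inherits(spec, "read_sim_spec"))
  if (inherits(records, "annotation_set")) records <- records$contigs
  set.seed(spec$seed)
  rl <- spec$read_len
  mutate_reads <- function(seqs) {
    if (spec$error_rate <= 0) return(seqs)
    n_err <- stats::rbinom(length(seqs), rl, spec$error_rate)
    for (i in which(n_err > 0L)) {
      pos <- sample.int(rl, n_err[i])
      ch <- strsplit(seqs[i], "")[[1L]]
      ch[pos] <- vapply(ch[pos],
                        function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                        "")
      seqs[i] <- paste(ch, collapse = "")
    }
    seqs
  }
  r1 <- list(); r2 <- list()
  for (ci in seq_len(nrow(records))) {
    cs <- records$seq[ci]; L <- nchar(cs); cid <- records$id[ci]
    if (L < rl) {
      warning("contig ", cid, " shorter than read length; skipped")
      next
    }
    n <- ceiling(spec$coverage * L / rl)
    if (!spec$paired) {
      starts <- sample.int(L - rl + 1L, n, replace = TRUE)
      seqs <- substring(cs, starts, starts + rl - 1L)
      minus <- sample(c(TRUE, FALSE), n, replace = TRUE)
      seqs[minus] <- revcomp(seqs[minus])
      r1[[length(r1) + 1L]] <-
        read_set(sprintf("%s_r%06d", cid, seq_len(n)), mutate_reads(seqs),
                 rep(strrep("I", rl), length(seqs)))
    } else {
      np <- ceiling(n / 2)
      ins <- pmin(pmax(round(stats::rnorm(np, spec$insert_mean, spec$insert_sd)),
                       rl), L)
      starts <- vapply(ins, function(i) sample.int(L - i + 1L, 1L), 0L)
      left <- substring(cs, starts, starts + rl - 1L)
      right <- revcomp(substring(cs, starts + ins - rl, starts + ins - 1L))
      flip <- sample(c(TRUE, FALSE), np, replace = TRUE)
      m1 <- ifelse(flip, right, left)
      m2 <- ifelse(flip, left, right)
      ids <- sprintf("%s_p%06d", cid, seq_len(np))
      r1[[length(r1) + 1L]] <- read_set(paste0(ids, "/1"), mutate_reads(m1),
                                        rep(strrep("I", rl), np))
      r2[[length(r2) + 1L]] <- read_set(paste0(ids, "/2"), mutate_reads(m2),
                                        rep(strrep("I", rl), np))
    }
  }
  list(reads1 = if (length(r1)) do.call(rbind, r1) else empty_reads(),
       reads2 = if (spec$paired) {
         if (length(r2)) do.call(rbind, r2) else empty_reads()
       } else NULL)
}

#' Excise genes from a genome to build a planted missing-gene scenario
#'
#' Randomly chosen genes are deleted from the genome sequence (spacers
#' joined); reads simulated from the *original* genome then carry the
#' planted genes only in the read set, emulating products missing from the
#' reference assembly.
#'
#' @param genome an [annotation_set()] (e.g. one genome of
#'   [generate_pangenome()]).
#' @param n_plant number of genes to excise (less than the gene count).
#' @param seed optional seed for the choice of genes.
#' @return a list with `reference` (excised [seq_set()]), `original`
#'   (untouched contigs), `planted` (feature rows, with `nuc` sequences)
#'   and `planted_ids`.
#' @export
plant_missing_genes <- function(genome, n_plant, seed = NULL) {
  stopifnot(inherits(genome, "annotation_set"))
  n_genes <- nrow(genome$features)
  if (n_plant >= n_genes) stop("n_plant must be less than the gene count")
  if (!is.null(seed)) set.seed(seed)
  if (n_plant == 0L) {
    return(list(reference = genome$contigs, original = genome$contigs,
                planted = genome$features[0, ], planted_ids = character()))
  }
  pick <- sort(sample.int(n_genes, n_plant))
  planted <- cds_sequences(genome)[pick, , drop = FALSE]
  contigs <- genome$contigs
  for (cid in unique(planted$contig_id)) {
    spans <- planted[planted$contig_id == cid, , drop = FALSE]
    spans <- spans[order(-spans$start), , drop = FALSE]
    s <- contigs$seq[contigs$id == cid]
    for (i in seq_len(nrow(spans))) {
      s <- paste0(substr(s, 1L, spans$start[i] - 1L),
                  substring(s, spans$end[i] + 1L))
    }
    contigs$seq[contigs$id == cid] <- s
  }
  list(reference = contigs, original = genome$contigs,
       planted = planted, planted_ids = planted$feature_id)
}
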