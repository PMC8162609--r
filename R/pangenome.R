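# Stage-2 comparative analysis: gene-family (GF) clustering by all-vs-all
# protein similarity, permutation pan/core/new-gene curves, Heap's-law
# fitting, unique/shared gene summaries, and pan-based distance trees.

#' Cluster genes into families by all-vs-all protein similarity
#'
#' Builds the undirected hit graph from an all-vs-all [search_hits()] run
#' (self-hits excluded) under the given thresholds; gene families are the
#' connected components (single linkage). Genes with no qualifying hit form
#' singleton families.
#'
#' @param genomes a named list: genome id -> [annotation_set()] (or a data
#'   frame with `feature_id` and `protein` columns).
#' @param scheme a [scoring_scheme()] (protein mode).
#' @param thresholds a [similarity_thresholds()].
#' @return an object of class `gene_family_clusters`: list with `clusters`
#'   (data frame `cluster_id`, `genome_id`, `feature_id`), `genome_ids`,
#'   `method = "GF"`.
#' @export
cluster_gene_families <- function(genomes,
                                  scheme = scoring_scheme("protein"),
                                  thresholds = similarity_thresholds()) {
  stopifnot(length(genomes) >= 2L, !is.null(names(genomes)))
  tabs <- lapply(names(genomes), function(g) {
    x <- genomes[[g]]
    f <- if (inherits(x, "annotation_set")) annotation_proteins(x) else x
    if (nrow(f) == 0L) {
      warning("genome ", g, " has zero genes")
      return(data.frame(genome_id = character(), feature_id = character(),
                        protein = character(), stringsAsFactors = FALSE))
    }
    data.frame(genome_id = g, feature_id = f$feature_id,
               protein = f$protein, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, tabs)
  if (nrow(all) == 0L) stop("no genes in any genome")
  uid <- paste(all$genome_id, all$feature_id, sep = "::")
  if (anyDuplicated(uid)) stop("duplicate (genome, feature) pair")
  prots <- seq_set(uid, all$protein)
  hits <- search_hits(prots, prots, scheme, thresholds)
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  g <- igraph::graph_from_data_frame(hits[, c("query_id", "subject_id")],
                                     directed = FALSE, vertices = prots$id)
  memb <- igraph::components(g)$membership
  # deterministic cluster ids: order components by their smallest member
  comp <- split(names(memb), memb)
  comp <- comp[order(vapply(comp, min, ""))]
  cl <- data.frame(
    cluster_id = rep(sprintf("GF%05d", seq_along(comp)), lengths(comp)),
    uid = unlist(comp, use.names = FALSE), stringsAsFactors = FALSE)
  idx <- match(cl$uid, uid)
  structure(list(clusters = data.frame(cluster_id = cl$cluster_id,
                                       genome_id = all$genome_id[idx],
                                       feature_id = all$feature_id[idx],
                                       stringsAsFactors = FALSE),
                 genome_ids = names(genomes), method = "GF"),
            class = "gene_family_clusters")
}

#' Gene-family clusters from a synthetic truth table
#'
#' Converts the known family structure of [generate_pangenome()] into the
#' same container [cluster_gene_families()] produces, for truth-based
#' pan-genome analysis and as a test oracle.
#'
#' @param sim a `pangenome_sim`.
#' @return a `gene_family_clusters`.
#' @export
truth_clusters <- function(sim) {
  stopifnot(inherits(sim, "pangenome_sim"))
  t <- sim$truth
  structure(list(clusters = data.frame(cluster_id = t$family_id,
                                       genome_id = t$genome_id,
                                       feature_id = t$feature_id,
                                       stringsAsFactors = FALSE),
                 genome_ids = names(sim$genomes), method = "truth"),
            class = "gene_family_clusters")
}

#' Family-by-genome gene count matrix
#'
#' @param clusters a `gene_family_clusters`.
#' @param genome_ids genome column order (defaults to the clustering's).
#' @return integer matrix, rows = clusters, columns = genomes; entry =
#'   gene copies of that genome in that cluster.
#' @export
pan_matrix <- function(clusters, genome_ids = clusters$genome_ids) {
  cl <- clusters$clusters
  m <- table(factor(cl$cluster_id, levels = sort(unique(cl$cluster_id))),
             factor(cl$genome_id, levels = genome_ids))
  mat <- matrix(as.integer(m), nrow = nrow(m),
                dimnames = list(rownames(m), colnames(m)))
  mat
}

#' Pan/core/new-gene accumulation curves over genome orderings
#'
#' For each genome ordering, reports for `N = 1..G` the number of gene
#' families seen in the first N genomes (`pan`), present in all first N
#' (`core`), and first seen at position N (`new`). All `G!` orders are
#' enumerated exactly when `G! <= 5040` (G <= 7); otherwise `n_perms`
#' random orders are sampled (deterministic under `seed`).
#'
#' @param mat a [pan_matrix()].
#' @param n_perms number of sampled orderings.
#' @param seed RNG seed for sampling.
#' @return a data frame `perm_id`, `N`, `pan`, `core`, `new`.
#' @export
sample_curves <- function(mat, n_perms = 1000L, seed = 1L) {
  stopifnot(n_perms >= 1L)
  G <- ncol(mat)
  P <- (mat > 0L) * 1L
  if (factorial(G) <= 5040) {
    orders <- all_permutations(G)
  } else {
    set.seed(seed)
    orders <- t(vapply(seq_len(n_perms), function(i) sample.int(G),
                       integer(G)))
  }
  ntot <- nrow(P)
  full <- rowSums(P) == G
  res <- vector("list", nrow(orders))
  for (p in seq_len(nrow(orders))) {
    Pp <- P[, orders[p, ], drop = FALSE]
    fo <- max.col(Pp, ties.method = "first")
    newv <- tabulate(fo, G)
    panv <- cumsum(newv)
    fz <- max.col(1L - Pp, ties.method = "first")  # first absence
    corev <- ntot - cumsum(tabulate(fz[!full], G))
    res[[p]] <- data.frame(perm_id = p, N = seq_len(G), pan = panv,
                           core = corev, new = newv)
  }
  do.call(rbind, res)
}

#' Fit Heap's law to the new-gene curve
#'
#' Summarises `new(N)` over orderings by the chosen statistic for
#' `N = 2..G` (N = 1 is the whole first genome, not a discovery event) and
#' fits `s(N) = kappa * N^-alpha` by least squares on `(ln N, ln s(N))`
#' using only points with `s(N) > 0`. Verdict: `"open"` iff
#' `alpha <= 1`, `"closed"` for finite `alpha > 1`, `"degenerate"` when
#' fewer than two positive points exist (`alpha = Inf` sentinel).
#'
#' @param samples a [sample_curves()] data frame.
#' @param statistic `"median"` or `"mean"`.
#' @return an object of class `heap_fit`: `kappa`, `alpha`, `statistic`,
#'   `rss` (log-scale residual sum of squares), `verdict`, `points`.
#' @export
fit_heaps_law <- function(samples, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  G <- max(samples$N)
  if (G < 3L) stop("need at least 3 genomes to fit Heap's law")
  stat_fun <- if (statistic == "median") stats::median else mean
  s <- vapply(2:G, function(N) stat_fun(samples$new[samples$N == N]), 0)
  pts <- data.frame(N = 2:G, s = s)
  pos <- pts$s > 0
  if (sum(pos) < 2L) {
    return(structure(list(kappa = NA_real_, alpha = Inf,
                          statistic = statistic, rss = NA_real_,
                          verdict = "degenerate", points = pts),
                     class = "heap_fit"))
  }
  fit <- stats::lm(log(s) ~ log(N), data = pts[pos, ])
  alpha <- -unname(stats::coef(fit)[2L])
  structure(list(kappa = exp(unname(stats::coef(fit)[1L])), alpha = alpha,
                 statistic = statistic,
                 rss = sum(stats::residuals(fit)^2),
                 verdict = if (alpha <= 1) "open" else "closed",
                 points = pts),
            class = "heap_fit")
}

#' @export
print.heap_fit <- function(x, ...) {
  cat(sprintf("<heap_fit> %s: kappa=%.4g alpha=%.4f (%s), rss=%.4g\n",
              x$statistic, x$kappa, x$alpha, x$verdict, x$rss))
  invisible(x)
}

#' Unique genes per genome
#'
#' Counts, for each genome, its genes lying in clusters confined to that
#' genome.
#'
#' @param mat a [pan_matrix()].
#' @return named integer vector, genome id -> unique gene count.
#' @export
unique_genes <- function(mat) {
  pres <- mat > 0L
  uniq <- rowSums(pres) == 1L
  stats::setNames(as.integer(colSums(mat[uniq, , drop = FALSE])),
                  colnames(mat))
}

#' Distribution of gene families by number of genomes sharing them
#'
#' @param mat a [pan_matrix()].
#' @return named integer vector: `n` genomes -> cluster count; the entry at
#'   `G` is the core.
#' @export
shared_distribution <- function(mat) {
  G <- ncol(mat)
  stats::setNames(tabulate(rowSums(mat > 0L), G), seq_len(G))
}

#' Jaccard distance matrix between genomes on family presence
#'
#' `d(a, b) = 1 - |families with both| / |families with either|`.
#'
#' @param mat a [pan_matrix()].
#' @return symmetric matrix with zero diagonal.
#' @export
pan_distance_matrix <- function(mat) {
  pres <- (mat > 0L) * 1L
  if (any(colSums(pres) == 0L)) {
    warning("genome with zero families: distance 1 to all others")
  }
  inter <- crossprod(pres)
  sz <- diag(inter)
  un <- outer(sz, sz, "+") - inter
  d <- 1 - inter / un
  d[un == 0] <- 1
  diag(d) <- 0
  d
}

#' Build a NJ or UPGMA tree from a distance matrix
#'
#' Neighbor-joining negative branch lengths are clamped to zero (with a
#' message). Leaf labels are processed in lexicographic order so ties are
#' broken deterministically.
#'
#' @param d symmetric distance matrix with zero diagonal, >= 3 genomes.
#' @param method `"nj"` or `"upgma"`.
#' @return a newick string (with trailing semicolon).
#' @export
build_tree <- function(d, method = c("nj", "upgma")) {
  method <- match.arg(method)
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  if (ncol(d) < 3L) stop("need at least 3 genomes")
  ord <- order(colnames(d))
  d <- d[ord, ord]
  if (method == "nj") {
    tr <- ape::nj(stats::as.dist(d))
    if (any(tr$edge.length < 0)) {
      message("negative NJ branch lengths clamped to 0")
      tr$edge.length[tr$edge.length < 0] <- 0
    }
  } else {
    tr <- ape::as.phylo(stats::hclust(stats::as.dist(d), method = "average"))
  }
  ape::write.tree(tr)
}
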