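prot_genomes <- function(lists) {
  # named list of feature_id -> protein tables
  out <- lapply(names(lists), function(g) {
    data.frame(feature_id = names(lists[[g]]),
               protein = unname(unlist(lists[[g]])),
               stringsAsFactors = FALSE)
  })
  names(out) <- names(lists)
  out
}

test_that("identical proteins across genomes form one family", {
  set.seed(51)
  p <- random_protein(150L)
  gs <- prot_genomes(list(a = c(g1 = p), b = c(g1 = p), c = c(g1 = p)))
  cl <- cluster_gene_families(gs)
  expect_equal(length(unique(cl$clusters$cluster_id)), 1L)
  expect_equal(nrow(cl$clusters), 3L)
})

test_that("single linkage chains A-B and B-C into one family", {
  set.seed(52)
  b <- random_protein(300L)
  a <- substr(b, 1L, 200L)     # fully covered by b
  c_ <- substr(b, 101L, 300L)  # fully covered by b; shares only half of a
  thr <- similarity_thresholds()
  gs <- prot_genomes(list(ga = c(x = a), gb = c(x = b), gc = c(x = c_)))
  hits <- search_hits(seq_set(c("a", "b", "c"), c(a, b, c_)),
                      seq_set(c("a", "b", "c"), c(a, b, c_)),
                      thresholds = thr)
  cross <- hits[hits$query_id != hits$subject_id, ]
  expect_setequal(paste(cross$query_id, cross$subject_id),
                  c("a b", "b a", "b c", "c b"))   # no direct a-c edge
  cl <- cluster_gene_families(gs, thresholds = thr)
  expect_equal(length(unique(cl$clusters$cluster_id)), 1L)
})

test_that("families equal brute-force components on random instances", {
  set.seed(53)
  sch <- scoring_scheme("protein")
  thr <- similarity_thresholds(max_evalue = 1e-3, min_identity = 0.6,
                               min_coverage = 0.6)
  for (i in 1:100) {
    n_fam <- sample(2:4, 1L)
    fams <- vapply(rep(80L, n_fam), random_protein, "")
    genomes <- lapply(1:2, function(g) {
      pick <- sample(n_fam, sample(1:n_fam, 1L))
      prots <- vapply(fams[pick], function(p) {
        if (stats::runif(1) < 0.5) p else mutate_protein(p, 0.1)
      }, "")
      data.frame(feature_id = sprintf("f%d_%d", g, seq_along(pick)),
                 protein = unname(prots), stringsAsFactors = FALSE)
    })
    names(genomes) <- c("gA", "gB")
    cl <- cluster_gene_families(genomes, sch, thr)
    # oracle: union-find over the all-pairs qualifying hit list
    all <- rbind(cbind(genomes$gA, genome = "gA"),
                 cbind(genomes$gB, genome = "gB"))
    uid <- paste(all$genome, all$feature_id, sep = "::")
    db_len <- sum(nchar(all$protein))
    edges <- list()
    for (x in seq_along(uid)) {
      for (y in seq_along(uid)) {
        if (x == y) next
        al <- local_align(all$protein[x], all$protein[y], sch)
        if (is.null(al)) next
        if (evalue(al$score, nchar(all$protein[x]), db_len, sch) <=
              thr$max_evalue && al$identity >= thr$min_identity &&
            max(al$q_coverage, al$s_coverage) >= thr$min_coverage) {
          edges[[length(edges) + 1L]] <- c(uid[x], uid[y])
        }
      }
    }
    want <- oracle_components(uid, do.call(rbind, c(edges, list(NULL))))
    got_uid <- paste(cl$clusters$genome_id, cl$clusters$feature_id,
                     sep = "::")
    got <- split(got_uid, cl$clusters$cluster_id)
    canon <- function(part) sort(vapply(part, function(x)
      paste(sort(x), collapse = "|"), ""))
    expect_identical(unname(canon(got)), unname(canon(want)),
                     info = paste("instance", i))
  }
})

test_that("the pan matrix conserves gene counts and matches the truth", {
  sim <- small_sim()
  cl <- truth_clusters(sim)
  mat <- pan_matrix(cl)
  expect_equal(sum(mat), nrow(sim$truth))
  expect_equal(unname(colSums(mat)),
               unname(vapply(sim$genomes, function(g) nrow(g$features), 0L)))
  # sequence-level clustering reproduces the truth partition
  scl <- cluster_gene_families(sim$genomes)
  smat <- pan_matrix(scl)
  sig <- function(m) sort(unname(apply(m[, sort(colnames(m)), drop = FALSE],
                                       1L, paste, collapse = ",")))
  expect_identical(sig(smat), sig(mat))
})

test_that("curves satisfy the pan/core/new identities on every order", {
  set.seed(54)
  mat <- matrix(rbinom(40L * 8L, 2L, 0.4), 40L, 8L,
                dimnames = list(sprintf("cl%02d", 1:40), sprintf("g%d", 1:8)))
  mat <- mat[rowSums(mat) > 0, ]
  curves <- sample_curves(mat, n_perms = 50L, seed = 3)
  for (p in unique(curves$perm_id)) {
    cc <- curves[curves$perm_id == p, ]
    expect_equal(cc$pan, cumsum(cc$new))
    expect_true(all(diff(cc$pan) >= 0))
    expect_true(all(diff(cc$core) <= 0))
    expect_equal(cc$pan[1L], cc$core[1L])
  }
  # the full pangenome is order-free
  expect_equal(length(unique(curves$pan[curves$N == 8L])), 1L)
  expect_equal(unique(curves$pan[curves$N == 8L]), nrow(mat))
})

test_that("exhaustive enumeration matches the hand-coded curve oracle", {
  set.seed(55)
  mat <- matrix(rbinom(25L * 5L, 1L, 0.5), 25L, 5L,
                dimnames = list(sprintf("c%02d", 1:25), sprintf("g%d", 1:5)))
  mat <- mat[rowSums(mat) > 0, ]
  curves <- sample_curves(mat)          # G = 5 -> all 120 orders
  expect_equal(length(unique(curves$perm_id)), 120L)
  # recompute every order with the oracle; orders are lexicographic
  orders <- pancraft:::all_permutations(5L)
  pres <- mat > 0
  for (p in seq_len(nrow(orders))) {
    cc <- curves[curves$perm_id == p, c("N", "pan", "core", "new")]
    rownames(cc) <- NULL
    expect_equal(cc, oracle_curve(pres, orders[p, ]), ignore_attr = TRUE)
  }
})

test_that("toy three-genome curves match hand enumeration", {
  # clusters: 2 core, 1 only-g1, 1 shared g1&g2
  mat <- matrix(c(1, 1, 1,
                  1, 1, 1,
                  1, 0, 0,
                  1, 1, 0), 4L, 3L, byrow = TRUE,
                dimnames = list(paste0("c", 1:4), c("g1", "g2", "g3")))
  curves <- sample_curves(mat)          # exhaustive: 6 orders
  pan2 <- curves$pan[curves$N == 2L]
  # by hand over the 6 orders of (g1,g2,g3): pan after two genomes
  expect_equal(sort(pan2), c(3, 3, 4, 4, 4, 4))
  expect_equal(stats::median(pan2), 4)
  expect_equal(unname(shared_distribution(mat)), c(1L, 1L, 2L))
})

test_that("Heap's-law fitting recovers exact power laws and degenerates", {
  G <- 10L
  newv <- round(100 * (2:G)^(-0.5), 8)
  samples <- data.frame(perm_id = 1L, N = c(1L, 2:G),
                        pan = 0, core = 0, new = c(500, newv))
  fit <- fit_heaps_law(samples, "median")
  expect_equal(fit$alpha, 0.5, tolerance = 1e-3)
  expect_equal(fit$kappa, 100, tolerance = 1e-2)
  expect_lt(fit$rss, 1e-6)
  expect_equal(fit$verdict, "open")
  zero <- data.frame(perm_id = 1L, N = 1:5, pan = 10, core = 10, new = 0)
  expect_equal(fit_heaps_law(zero)$verdict, "degenerate")
  expect_equal(fit_heaps_law(zero)$alpha, Inf)
  steep <- data.frame(perm_id = 1L, N = c(1L, 2:G), pan = 0, core = 0,
                      new = c(500, round(100 * (2:G)^(-1.6), 8)))
  expect_equal(fit_heaps_law(steep)$verdict, "closed")
})

test_that("unique genes and sharing histogram follow the matrix", {
  ident <- matrix(1L, 5L, 3L, dimnames = list(paste0("c", 1:5),
                                              paste0("g", 1:3)))
  expect_true(all(unique_genes(ident) == 0L))
  expect_equal(unname(shared_distribution(ident)), c(0L, 0L, 5L))
  m <- matrix(c(2, 0, 0,
                1, 0, 0,
                1, 1, 0,
                1, 1, 1), 4L, 3L, byrow = TRUE,
              dimnames = list(paste0("c", 1:4), paste0("g", 1:3)))
  expect_equal(unname(unique_genes(m)), c(3L, 0L, 0L))
  sim <- small_sim()
  mat <- pan_matrix(truth_clusters(sim))
  # truth comparison: private-family gene counts
  fam_sizes <- vapply(sim$families, length, 0L)
  private <- names(fam_sizes)[fam_sizes == 1L]
  want <- table(factor(sim$truth$genome_id[sim$truth$family_id %in% private],
                       levels = colnames(mat)))
  expect_equal(unname(unique_genes(mat)), unname(as.integer(want)))
})

test_that("pan distances are Jaccard and satisfy the triangle inequality", {
  ident <- matrix(1L, 5L, 3L, dimnames = list(paste0("c", 1:5),
                                              paste0("g", 1:3)))
  expect_true(all(pan_distance_matrix(ident)[upper.tri(diag(3))] == 0))
  disj <- diag(3L); dimnames(disj) <- list(paste0("c", 1:3), paste0("g", 1:3))
  expect_true(all(pan_distance_matrix(disj)[upper.tri(diag(3))] == 1))
  set.seed(56)
  for (i in 1:100) {
    m <- matrix(rbinom(30L, 1L, 0.6), 10L, 3L,
                dimnames = list(paste0("c", 1:10), paste0("g", 1:3)))
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (nrow(m) == 0L || any(colSums(m) == 0L)) next
    d <- pan_distance_matrix(m)
    expect_lte(d["g1", "g3"], d["g1", "g2"] + d["g2", "g3"] + 1e-12)
    expect_equal(d, t(d))
  }
})

test_that("UPGMA matches the textbook agglomeration, NJ recovers topology", {
  d <- matrix(c(0, 2, 4,
                2, 0, 4,
                4, 4, 0), 3L, 3L, dimnames = list(c("a", "b", "c"),
                                                  c("a", "b", "c")))
  expect_equal(build_tree(d, "upgma"), "(c:2,(a:1,b:1):1);")
  # additive distances from tree ((A:1,B:2):1,(C:3,D:4):1)
  dd <- matrix(0, 4L, 4L, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  dd["A", "B"] <- dd["B", "A"] <- 3
  dd["A", "C"] <- dd["C", "A"] <- 6
  dd["A", "D"] <- dd["D", "A"] <- 7
  dd["B", "C"] <- dd["C", "B"] <- 7
  dd["B", "D"] <- dd["D", "B"] <- 8
  dd["C", "D"] <- dd["D", "C"] <- 9
  nwk <- build_tree(dd, "nj")
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, LETTERS[1:4])
  # A,B on one side of the internal edge
  split_ab <- ape::prop.part(tr)
  expect_true(any(vapply(split_ab, function(s)
    setequal(tr$tip.label[s], c("A", "B")) ||
      setequal(tr$tip.label[s], c("C", "D")), NA)))
  coph <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(max(abs(coph - dd)), 0, tolerance = 1e-8)
  expect_error(build_tree(dd[, c(2, 1, 3, 4)], "nj"), "symmetric")
})
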