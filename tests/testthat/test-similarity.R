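test_that("self-alignment scores the BLOSUM62 diagonal with full coverage", {
  set.seed(31)
  p <- random_protein(40L)
  sch <- scoring_scheme("protein")
  hit <- local_align(p, p, sch)
  diag_sum <- sum(apply(cbind(strsplit(p, "")[[1L]]), 1L,
                        function(a) sch$matrix[a, a]))
  expect_equal(hit$score, diag_sum)
  expect_equal(hit$identity, 1)
  expect_equal(hit$q_coverage, 1)
  expect_equal(hit$s_coverage, 1)
  expect_equal(hit$q_start, 1L)
  expect_equal(hit$s_end, 40L)
})

test_that("all-negative pairs align to nothing", {
  sch <- scoring_scheme("protein")
  # G vs W scores -2, G vs F -3: every pair negative
  expect_null(local_align("GGGGG", "WFWFW", sch))
  expect_error(local_align("ACGU", "ACGT", scoring_scheme("nucleotide")),
               "alphabet")
})

test_that("alignment scores equal the Gotoh enumeration oracle", {
  set.seed(32)
  sch <- scoring_scheme("protein")
  for (i in 1:50) {
    a <- random_protein(sample(5:30, 1L))
    b <- if (i %% 3 == 0) mutate_protein(a, 0.3) else
      random_protein(sample(5:30, 1L))
    want <- oracle_local_score(a, b, sch$matrix, sch$gap_open, sch$gap_extend)
    got <- local_align(a, b, sch)
    got_score <- if (is.null(got)) 0 else got$score
    expect_equal(got_score, max(want, 0), info = paste(a, b))
    # score symmetry
    rev <- local_align(b, a, sch)
    rev_score <- if (is.null(rev)) 0 else rev$score
    expect_equal(got_score, rev_score)
  }
})

test_that("e-values follow the Karlin-Altschul form", {
  sch <- scoring_scheme("protein")
  s1 <- log(sch$k_const * 100 * 1000) / sch$lambda
  expect_equal(evalue(s1, 100, 1000, sch), 1.0)
  expect_equal(evalue(50, 100, 2000, sch), 2 * evalue(50, 100, 1000, sch))
  expect_error(evalue(-3, 100, 1000, sch), "positive")
  expect_error(evalue(50, 0, 1000, sch), "positive")
  # a 200-aa self-hit against a 1e5-residue database is far below 1e-10
  set.seed(33)
  p <- random_protein(200L)
  self <- local_align(p, p, sch)
  expect_lt(evalue(self$score, 200, 1e5, sch), 1e-10)
})

test_that("search finds self-hits and rejects unrelated proteins", {
  set.seed(34)
  prots <- seq_set(sprintf("p%02d", 1:12),
                   vapply(rep(300L, 12L), random_protein, ""))
  hits <- search_hits(prots, prots)
  self <- hits[hits$query_id == hits$subject_id, ]
  expect_setequal(self$query_id, prots$id)
  expect_true(all(self$identity == 1))
  # unrelated random proteins never pass the default thresholds
  cross <- hits[hits$query_id != hits$subject_id, ]
  expect_equal(nrow(cross), 0L)
})

test_that("seeded search equals the exhaustive all-pairs search", {
  set.seed(35)
  base <- vapply(rep(120L, 5L), random_protein, "")
  seqs <- c(base,
            vapply(base[1:3], mutate_protein, "", frac = 0.15),
            vapply(rep(120L, 4L), random_protein, ""))
  ss <- seq_set(sprintf("q%02d", seq_along(seqs)), seqs)
  sch <- scoring_scheme("protein")
  thr <- similarity_thresholds()
  got <- search_hits(ss, ss, sch, thr)
  db_len <- sum(nchar(ss$seq))
  want <- list()
  for (i in seq_len(nrow(ss))) {
    for (j in seq_len(nrow(ss))) {
      al <- local_align(ss$seq[i], ss$seq[j], sch)
      if (is.null(al)) next
      ev <- evalue(al$score, nchar(ss$seq[i]), db_len, sch)
      if (ev <= thr$max_evalue && al$identity >= thr$min_identity &&
          max(al$q_coverage, al$s_coverage) >= thr$min_coverage) {
        want[[length(want) + 1L]] <- data.frame(query_id = ss$id[i],
                                                subject_id = ss$id[j],
                                                score = al$score)
      }
    }
  }
  want <- do.call(rbind, want)
  key <- function(d) sort(paste(d$query_id, d$subject_id, d$score))
  expect_identical(key(got), key(want))
  expect_gt(nrow(want), nrow(ss))  # the mutated copies must be found
})

test_that("raising any threshold never adds hits", {
  set.seed(36)
  base <- vapply(rep(150L, 4L), random_protein, "")
  seqs <- c(base, vapply(base, mutate_protein, "", frac = 0.2))
  ss <- seq_set(sprintf("m%02d", seq_along(seqs)), seqs)
  loose <- search_hits(ss, ss, thresholds = similarity_thresholds(
    max_evalue = 1e-5, min_identity = 0.5, min_coverage = 0.5))
  for (thr in list(similarity_thresholds(1e-10, 0.5, 0.5),
                   similarity_thresholds(1e-5, 0.8, 0.5),
                   similarity_thresholds(1e-5, 0.5, 0.9))) {
    tight <- search_hits(ss, ss, thresholds = thr)
    key <- function(d) paste(d$query_id, d$subject_id)
    expect_true(all(key(tight) %in% key(loose)))
    expect_lte(nrow(tight), nrow(loose))
  }
})
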