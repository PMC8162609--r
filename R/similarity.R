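# Local pairwise similarity search with e-value, identity and coverage
# filtering. Alignment is exact affine-gap Smith-Waterman (via
# Biostrings::pairwiseAlignment); word seeding is only a candidate filter,
# so kept hits equal those of an exhaustive all-pairs search whenever the
# alignment contains an exact word match.

#' Alignment scoring scheme
#'
#' Protein mode scores with BLOSUM62; nucleotide mode with match +1 /
#' mismatch -2. Affine gaps cost `gap_open + gap_extend * length`. The
#' Karlin-Altschul constants `lambda` and `k_const` parameterise the
#' e-value `E = K * m * n * exp(-lambda * S)`; they are fixed defaults (no
#' edge-effect correction), as the e-value serves as a filter threshold,
#' not a calibrated statistic.
#'
#' @param mode `"protein"` or `"nucleotide"`.
#' @param gap_open,gap_extend affine gap penalties (`gap_open >=
#'   gap_extend >= 1`).
#' @param lambda,k_const Karlin-Altschul constants; defaults 0.267/0.041
#'   (protein) and 1.28/0.46 (nucleotide).
#' @param word_size seed word length for [search_hits()]; defaults 4
#'   (protein) and 11 (nucleotide).
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(mode = c("protein", "nucleotide"),
                           gap_open = 11, gap_extend = 1,
                           lambda = NULL, k_const = NULL, word_size = NULL) {
  mode <- match.arg(mode)
  stopifnot(gap_open >= gap_extend, gap_extend >= 1)
  if (mode == "protein") {
    mat <- .blosum62()
    lambda <- lambda %||% 0.267
    k_const <- k_const %||% 0.041
    word_size <- word_size %||% 4L
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                    baseOnly = TRUE)
    lambda <- lambda %||% 1.28
    k_const <- k_const %||% 0.46
    word_size <- word_size %||% 11L
  }
  structure(list(mode = mode, matrix = mat, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, k_const = k_const,
                 word_size = as.integer(word_size)),
            class = "scoring_scheme")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.blosum62_cache <- new.env()
.blosum62 <- function() {
  if (is.null(.blosum62_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum62_cache$m <- e$BLOSUM62
  }
  .blosum62_cache$m
}

#' Similarity filtering thresholds
#'
#' Defaults mirror the comparison settings used throughout the pipeline:
#' e-value 1e-10, identity 0.7, coverage 0.7.
#'
#' @param max_evalue maximum e-value.
#' @param min_identity minimum identity (matches / alignment columns,
#'   gaps included in the denominator), in (0, 1].
#' @param min_coverage minimum of `max(query, subject)` span coverage,
#'   in (0, 1].
#' @return an object of class `similarity_thresholds`.
#' @export
similarity_thresholds <- function(max_evalue = 1e-10, min_identity = 0.70,
                                  min_coverage = 0.70) {
  stopifnot(max_evalue > 0, min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1)
  structure(list(max_evalue = max_evalue, min_identity = min_identity,
                 min_coverage = min_coverage),
            class = "similarity_thresholds")
}

.check_alphabet <- function(x, scheme, what) {
  ok <- rownames(scheme$matrix)
  bad <- !vapply(strsplit(toupper(x), "", fixed = TRUE),
                 function(ch) all(ch %in% ok), NA)
  if (any(bad)) {
    stop(what, " contains characters outside the ", scheme$mode,
         " scoring alphabet")
  }
}

#' Karlin-Altschul e-value
#'
#' `E = K * m * n * exp(-lambda * S)`: monotone decreasing in the score,
#' linear in the search-space size `m * n`.
#'
#' @param score positive alignment score.
#' @param m query length.
#' @param n database length (total subject residues).
#' @param scheme a [scoring_scheme()].
#' @return the expected number of chance hits at this score or better.
#' @export
evalue <- function(score, m, n, scheme) {
  if (any(m <= 0) || any(n <= 0)) stop("sequence lengths must be positive")
  if (any(score <= 0)) stop("score must be positive")
  scheme$k_const * m * n * exp(-scheme$lambda * score)
}

# shared: turn a PairwiseAlignments object (possibly vectorised over
# patterns) into a hit data frame; evalue filled by callers
.aln_stats <- function(pa, qlen, slen) {
  sc <- Biostrings::score(pa)
  nm <- Biostrings::nmatch(pa)
  cols <- Biostrings::nchar(pa)
  qs <- IRanges::start(Biostrings::pattern(pa))
  qe <- IRanges::end(Biostrings::pattern(pa))
  ss <- IRanges::start(Biostrings::subject(pa))
  se <- IRanges::end(Biostrings::subject(pa))
  data.frame(score = sc, identity = nm / cols,
             q_coverage = (qe - qs + 1L) / qlen,
             s_coverage = (se - ss + 1L) / slen,
             q_start = qs, q_end = qe, s_start = ss, s_end = se,
             aln_len = cols, n_match = nm, stringsAsFactors = FALSE)
}

#' Optimal affine-gap local alignment of two sequences
#'
#' Exact Smith-Waterman with affine gaps under the given scheme. Returns
#' `NULL` when the best local score is not positive.
#'
#' @param a,b sequences (query, subject).
#' @param scheme a [scoring_scheme()].
#' @return a one-row data frame (`score`, `evalue` computed with
#'   `n = nchar(b)`, `identity`, coverages, spans), or `NULL`.
#' @export
local_align <- function(a, b, scheme = scoring_scheme("protein")) {
  stopifnot(nzchar(a), nzchar(b))
  .check_alphabet(c(a, b), scheme, "sequence")
  pa <- Biostrings::pairwiseAlignment(
    pattern = toupper(a), subject = toupper(b), type = "local",
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  if (Biostrings::score(pa) <= 0) return(NULL)
  st <- .aln_stats(pa, nchar(a), nchar(b))
  st$evalue <- evalue(st$score, nchar(a), nchar(b), scheme)
  st[, c("score", "evalue", "identity", "q_coverage", "s_coverage",
         "q_start", "q_end", "s_start", "s_end", "aln_len", "n_match")]
}

# word -> subject-index postings for seeding
.word_index <- function(seqs, w) {
  env <- new.env(hash = TRUE, size = max(2L * sum(nchar(seqs)), 16L))
  for (i in seq_along(seqs)) {
    for (word in unique(kmer_set(seqs[i], w))) {
      env[[word]] <- c(env[[word]], i)
    }
  }
  env
}

#' Similarity search of queries against subjects
#'
#' Candidate pairs are found by shared-word seeding (word size from the
#' scheme), then aligned exactly with [local_align()]'s machinery. Hits
#' are kept iff `evalue <= max_evalue`, `identity >= min_identity` and
#' `max(q_coverage, s_coverage) >= min_coverage`, with the database length
#' `n` equal to the total subject residues. Sorted by `(query_id, evalue)`.
#'
#' @param queries,subjects [seq_set()] data frames.
#' @param scheme a [scoring_scheme()].
#' @param thresholds a [similarity_thresholds()].
#' @return a hit data frame (possibly empty) with columns `query_id`,
#'   `subject_id`, `score`, `evalue`, `identity`, `q_coverage`,
#'   `s_coverage`, spans, `aln_len`, `n_match`.
#' @export
search_hits <- function(queries, subjects, scheme = scoring_scheme("protein"),
                        thresholds = similarity_thresholds()) {
  empty <- data.frame(query_id = character(), subject_id = character(),
                      score = numeric(), evalue = numeric(),
                      identity = numeric(), q_coverage = numeric(),
                      s_coverage = numeric(), q_start = integer(),
                      q_end = integer(), s_start = integer(),
                      s_end = integer(), aln_len = integer(),
                      n_match = integer(), stringsAsFactors = FALSE)
  if (is.null(queries) || nrow(queries) == 0L ||
      is.null(subjects) || nrow(subjects) == 0L) {
    return(empty)
  }
  w <- scheme$word_size
  db_len <- sum(nchar(subjects$seq))
  # collapse duplicate sequences: alignments depend only on the sequence
  uq <- !duplicated(queries$seq)
  us <- !duplicated(subjects$seq)
  qseq <- queries$seq[uq]
  sseq <- subjects$seq[us]
  qgrp <- split(queries$id, match(queries$seq, qseq))
  sgrp <- split(subjects$id, match(subjects$seq, sseq))
  widx <- .word_index(sseq, w)
  cand_q <- integer(); cand_s <- integer()
  for (qi in seq_along(qseq)) {
    words <- unique(kmer_set(qseq[qi], w))
    if (!length(words)) next
    sj <- unique(unlist(mget(words, envir = widx, ifnotfound = list(NULL)),
                        use.names = FALSE))
    if (length(sj)) {
      cand_q <- c(cand_q, rep.int(qi, length(sj)))
      cand_s <- c(cand_s, sj)
    }
  }
  if (!length(cand_q)) return(empty)
  res <- list()
  xset <- if (scheme$mode == "protein") Biostrings::AAStringSet else
    Biostrings::DNAStringSet
  for (sj in unique(cand_s)) {
    qis <- cand_q[cand_s == sj]
    # score-only prepass: the e-value filter depends only on the score, so
    # full traceback is computed just for candidates that can still qualify
    sc <- Biostrings::pairwiseAlignment(
      pattern = xset(qseq[qis]), subject = sseq[sj], type = "local",
      substitutionMatrix = scheme$matrix,
      gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
      scoreOnly = TRUE)
    ok <- sc > 0
    ok[ok] <- evalue(sc[ok], nchar(qseq[qis[ok]]), db_len, scheme) <=
      thresholds$max_evalue
    if (!any(ok)) next
    qis <- qis[ok]
    pa <- Biostrings::pairwiseAlignment(
      pattern = xset(qseq[qis]), subject = sseq[sj], type = "local",
      substitutionMatrix = scheme$matrix,
      gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
    st <- .aln_stats(pa, nchar(qseq[qis]), nchar(sseq[sj]))
    st$qi <- qis; st$sj <- sj
    st <- st[st$score > 0, , drop = FALSE]
    if (nrow(st)) res[[length(res) + 1L]] <- st
  }
  if (!length(res)) return(empty)
  h <- do.call(rbind, res)
  h$evalue <- evalue(h$score, nchar(qseq[h$qi]), db_len, scheme)
  keep <- h$evalue <= thresholds$max_evalue &
    h$identity >= thresholds$min_identity &
    pmax(h$q_coverage, h$s_coverage) >= thresholds$min_coverage
  h <- h[keep, , drop = FALSE]
  if (!nrow(h)) return(empty)
  # expand duplicate-sequence groups back to concrete ids
  out <- list()
  for (i in seq_len(nrow(h))) {
    qids <- qgrp[[as.character(h$qi[i])]]
    sids <- sgrp[[as.character(h$sj[i])]]
    g <- expand.grid(query_id = qids, subject_id = sids,
                     stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- cbind(g, h[rep(i, nrow(g)),
                                          !(names(h) %in% c("qi", "sj")),
                                          drop = FALSE])
  }
  h <- do.call(rbind, out)
  h <- h[order(h$query_id, h$evalue, h$subject_id), , drop = FALSE]
  rownames(h) <- NULL
  h[, c("query_id", "subject_id", "score", "evalue", "identity",
        "q_coverage", "s_coverage", "q_start", "q_end", "s_start", "s_end",
        "aln_len", "n_match")]
}

#' Write hits as a BLAST outfmt-6 style table
#'
#' Columns: qid, sid, percent identity, alignment length, mismatches
#' (non-match columns, gaps included), gap opens (not tracked; 0), qstart,
#' qend, sstart, send, evalue, score (raw score as bit-score proxy).
#'
#' @param hits a [search_hits()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  df <- data.frame(qid = hits$query_id, sid = hits$subject_id,
                   pident = round(100 * hits$identity, 2),
                   length = hits$aln_len,
                   mismatches = hits$aln_len - hits$n_match,
                   gapopens = 0L,
                   qstart = hits$q_start, qend = hits$q_end,
                   sstart = hits$s_start, send = hits$s_end,
                   evalue = hits$evalue, score = hits$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
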