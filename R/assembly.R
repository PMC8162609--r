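# De novo assembly of unmapped reads: k-mer counting into a bidirected de
# Bruijn graph, error pruning, and unitig (maximal non-branching path)
# extraction. Unitig-only assembly is sufficient downstream, where only
# ORF-bearing contigs are needed.

# fast scalar-ish reverse complement for short fixed-k strings (avoids
# XStringSet construction overhead in graph-walk hot paths)
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Build a de Bruijn graph from reads
#'
#' Every k-mer of every read is counted under its canonical form; k-mers
#' containing non-ACGT bases are dropped. An empty read set yields an empty
#' graph.
#'
#' @param reads a [read_set()] data frame, or a list of them.
#' @param k odd k-mer size (default 31).
#' @return an object of class `debruijn_graph` with fields `k` and `counts`
#'   (named integer vector over canonical k-mers, lexicographically sorted).
#' @export
build_debruijn <- function(reads, k = 31L) {
  stopifnot(k %% 2L == 1L, k >= 3L)
  if (is.data.frame(reads)) reads <- list(reads)
  seqs <- unlist(lapply(reads, function(r) r$seq), use.names = FALSE)
  seqs <- seqs[nchar(seqs) >= k]
  if (!length(seqs)) {
    return(structure(list(k = as.integer(k),
                          counts = stats::setNames(integer(), character())),
                     class = "debruijn_graph"))
  }
  km <- unlist(lapply(seqs, kmer_set, k = k), use.names = FALSE)
  km <- km[!grepl("[^ACGT]", km)]
  if (!length(km)) {
    return(structure(list(k = as.integer(k),
                          counts = stats::setNames(integer(), character())),
                     class = "debruijn_graph"))
  }
  canon <- canonical_kmers(km)
  tab <- table(canon)
  counts <- stats::setNames(as.integer(tab), names(tab))
  counts <- counts[sort(names(counts), method = "radix")]
  structure(list(k = as.integer(k), counts = counts),
            class = "debruijn_graph")
}

#' @export
print.debruijn_graph <- function(x, ...) {
  cat(sprintf("<debruijn_graph> k=%d, %d distinct k-mers\n",
              x$k, length(x$counts)))
  invisible(x)
}

# --- unitig machinery -------------------------------------------------------

# decompose a canonical k-mer set into unitigs; returns a list of records
# (seq, members = canonical member k-mers, dead_left, dead_right)
.unitigs <- function(kmers, k) {
  if (!length(kmers)) return(list())
  pres <- new.env(hash = TRUE, size = max(2L * length(kmers), 16L))
  for (km in kmers) assign(km, TRUE, envir = pres)
  has <- function(x) !is.na(mget(x, envir = pres,
                                 ifnotfound = NA)[[1L]])[1L]
  outn <- function(s) {
    cands <- paste0(substr(s, 2L, k), c("A", "C", "G", "T"))
    rc <- revcomp_chr(cands)
    canon <- ifelse(cands <= rc, cands, rc)
    found <- vapply(canon, function(x) !is.na(mget(x, envir = pres,
                                                   ifnotfound = NA)[[1L]]),
                    NA, USE.NAMES = FALSE)
    cands[found]
  }
  visited <- new.env(hash = TRUE, size = max(2L * length(kmers), 16L))
  seen <- function(x) !is.na(mget(x, envir = visited, ifnotfound = NA)[[1L]])
  out <- list()
  for (start in kmers) {
    if (seen(start)) next
    assign(start, TRUE, envir = visited)
    members <- start
    walk <- function(s0) {
      # returns list(seq, dead): extend rightwards from oriented seed s0
      s <- s0; cur <- s0
      repeat {
        nx <- outn(cur)
        if (length(nx) != 1L) return(list(seq = s, dead = length(nx) == 0L))
        nxt <- nx
        if (length(outn(revcomp_chr(nxt))) != 1L) {
          return(list(seq = s, dead = FALSE))
        }
        rc <- revcomp_chr(nxt)
        cn <- if (nxt <= rc) nxt else rc
        if (seen(cn)) return(list(seq = s, dead = FALSE))
        assign(cn, TRUE, envir = visited)
        members <<- c(members, cn)
        s <- paste0(s, substr(nxt, k, k))
        cur <- nxt
      }
    }
    right <- walk(start)
    left <- walk(revcomp_chr(start))
    lseq <- revcomp_chr(left$seq)           # ends with `start`
    seq <- paste0(substr(lseq, 1L, nchar(lseq) - k), right$seq)
    out[[length(out) + 1L]] <- list(seq = seq, members = members,
                                    dead_left = left$dead,
                                    dead_right = right$dead)
  }
  out
}

#' Prune a de Bruijn graph
#'
#' Removes k-mers below a count threshold, then iteratively removes
#' dead-end paths (tips) shorter than `tip_len`. Idempotent on its own
#' output.
#'
#' @param graph a [build_debruijn()] result.
#' @param min_count minimum k-mer multiplicity retained.
#' @param tip_len tips strictly shorter than this many nucleotides are
#'   removed (default `2 * k`).
#' @return a pruned `debruijn_graph`.
#' @export
prune_graph <- function(graph, min_count = 2L, tip_len = 2L * graph$k) {
  stopifnot(inherits(graph, "debruijn_graph"))
  counts <- graph$counts[graph$counts >= min_count]
  repeat {
    uni <- .unitigs(names(counts), graph$k)
    drop <- character()
    for (u in uni) {
      is_tip <- xor(u$dead_left, u$dead_right) && nchar(u$seq) < tip_len
      if (is_tip) drop <- c(drop, u$members)
    }
    if (!length(drop)) break
    counts <- counts[!(names(counts) %in% drop)]
  }
  structure(list(k = graph$k, counts = counts), class = "debruijn_graph")
}

#' Extract unitig contigs from a (pruned) de Bruijn graph
#'
#' Contigs are maximal non-branching paths of the bidirected graph, each
#' emitted once as the lexicographically smaller of the sequence and its
#' reverse complement, sorted by decreasing length (ties by sequence) and
#' named `contig_1`, `contig_2`, ... Deterministic and independent of the
#' read input order.
#'
#' @param graph a [build_debruijn()] (ideally pruned) graph.
#' @param min_len minimum contig length retained.
#' @return a data frame with columns `contig_id`, `sequence`,
#'   `mean_kmer_coverage`.
#' @export
extract_contigs <- function(graph, min_len = 200L) {
  stopifnot(inherits(graph, "debruijn_graph"))
  uni <- .unitigs(names(graph$counts), graph$k)
  if (!length(uni)) {
    return(data.frame(contig_id = character(), sequence = character(),
                      mean_kmer_coverage = numeric(),
                      stringsAsFactors = FALSE))
  }
  seqs <- vapply(uni, function(u) {
    rc <- revcomp_chr(u$seq)
    if (u$seq <= rc) u$seq else rc
  }, "")
  cov <- vapply(uni, function(u) mean(graph$counts[u$members]), 0)
  keep <- nchar(seqs) >= min_len
  seqs <- seqs[keep]; cov <- cov[keep]
  if (!length(seqs)) {
    return(data.frame(contig_id = character(), sequence = character(),
                      mean_kmer_coverage = numeric(),
                      stringsAsFactors = FALSE))
  }
  ord <- order(-nchar(seqs), seqs)
  data.frame(contig_id = sprintf("contig_%d", seq_along(ord)),
             sequence = seqs[ord], mean_kmer_coverage = cov[ord],
             stringsAsFactors = FALSE)
}

#' Write assembled contigs as FASTA
#'
#' The mean k-mer coverage is carried in the description field.
#'
#' @param contigs an [extract_contigs()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path) {
  if (nrow(contigs) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  write_fasta(seq_set(contigs$contig_id, contigs$sequence,
                      sprintf("cov=%.2f", contigs$mean_kmer_coverage)),
              path)
  invisible(path)
}
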