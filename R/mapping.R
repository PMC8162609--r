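# Read partitioning against a reference: a k-mer seed-and-ungapped-extend
# classifier standing in for a full read aligner. The pipeline only needs
# the mapped/unmapped split, not alignments, so seeds on a shared diagonal
# followed by an ungapped identity check are sufficient.

#' Mapping parameters
#'
#' @param k seed k-mer size (odd, in 15..31).
#' @param min_seed_hits minimum seed k-mers on one (contig, strand, diagonal)
#'   bin before extension is attempted.
#' @param min_identity minimum identity of the ungapped extension over the
#'   read's aligned span.
#' @return an object of class `map_params`.
#' @export
map_params <- function(k = 21L, min_seed_hits = 2L, min_identity = 0.9) {
  stopifnot(k %% 2L == 1L, k >= 15L, k <= 31L, min_seed_hits >= 1L,
            min_identity > 0, min_identity <= 1)
  structure(list(k = as.integer(k), min_seed_hits = as.integer(min_seed_hits),
                 min_identity = min_identity), class = "map_params")
}

#' Build a k-mer index of a reference
#'
#' Every position of every contig is indexed under the canonical form
#' (lexicographic minimum of k-mer and reverse complement), so a k-mer and
#' its reverse complement retrieve the same postings.
#'
#' @param reference a [seq_set()] of contigs.
#' @param k odd k-mer size in 15..31.
#' @return an object of class `kmer_index`.
#' @export
build_kmer_index <- function(reference, k = 21L) {
  stopifnot(k %% 2L == 1L, k >= 15L, k <= 31L)
  usable <- nchar(reference$seq) >= k
  if (!any(usable)) stop("all contigs shorter than k = ", k)
  key <- character(); contig <- integer(); pos <- integer(); fwd <- logical()
  for (ci in which(usable)) {
    km <- kmer_set(reference$seq[ci], k)
    keep <- !grepl("[^ACGT]", km)
    if (!any(keep)) next
    km <- km[keep]
    canon <- canonical_kmers(km)
    key <- c(key, canon)
    contig <- c(contig, rep.int(ci, length(km)))
    pos <- c(pos, (which(keep) - 1L))
    fwd <- c(fwd, km == canon)
  }
  env <- new.env(hash = TRUE, size = max(2L * length(key), 16L))
  idx <- split(seq_along(key), key)
  list2env(idx, env)
  structure(list(k = as.integer(k), env = env, contig = contig, pos = pos,
                 fwd = fwd, contig_ids = reference$id,
                 contig_seqs = reference$seq,
                 contig_lens = nchar(reference$seq)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d, %d contigs, %d indexed positions\n",
              x$k, length(x$contig_ids), length(x$contig)))
  invisible(x)
}

# ungapped identity of `rseq` placed at 0-based contig offset `d`,
# clipped to contig bounds; returns identity over the aligned span
.extend_identity <- function(rseq, cseq, d) {
  L <- nchar(rseq); cl <- nchar(cseq)
  i1 <- max(0L, -d); i2 <- min(L, cl - d)
  if (i2 - i1 <= 0L) return(0)
  a <- utf8ToInt(substr(rseq, i1 + 1L, i2))
  b <- utf8ToInt(substr(cseq, d + i1 + 1L, d + i2))
  mean(a == b)
}

# batched classifier: one pass over all reads with vectorised k-mer
# canonicalisation, then a light per-read loop over seed postings only
.classify_many <- function(seqs, index, params) {
  n <- length(seqs)
  if (!n) return(logical())
  k <- index$k
  L <- nchar(seqs)
  mapped <- logical(n)
  short <- L < k
  if (any(short)) warning(sum(short), " read(s) shorter than k classified unmapped")
  use <- which(!short)
  if (!length(use)) return(mapped)
  kml <- lapply(seqs[use], kmer_set, k = k)
  lens <- lengths(kml)
  km <- unlist(kml, use.names = FALSE)
  ridx <- rep.int(seq_along(use), lens)
  jpos <- unlist(lapply(lens, function(m) 0:(m - 1L)), use.names = FALSE)
  keep <- !grepl("[^ACGT]", km)
  km <- km[keep]; ridx <- ridx[keep]; jpos <- jpos[keep]
  if (!length(km)) return(mapped)
  rc <- revcomp(km)
  canon <- ifelse(km <= rc, km, rc)
  read_fwd <- km == canon
  post <- mget(canon, envir = index$env, ifnotfound = list(NULL))
  nhit <- lengths(post)
  hit <- nhit > 0L
  if (!any(hit)) return(mapped)
  rows <- unlist(post[hit], use.names = FALSE)
  rep_i <- rep.int(which(hit), nhit[hit])
  h_read <- ridx[rep_i]
  same <- read_fwd[rep_i] == index$fwd[rows]
  ctg <- index$contig[rows]
  Lr <- L[use][h_read]
  diag <- ifelse(same, index$pos[rows] - jpos[rep_i],
                 index$pos[rows] - (Lr - k - jpos[rep_i]))
  rcseqs <- revcomp(seqs[use])
  ord <- order(h_read)
  h_read <- h_read[ord]; same <- same[ord]; ctg <- ctg[ord]; diag <- diag[ord]
  bounds <- c(0L, cumsum(tabulate(h_read, length(use))))
  for (ri in unique(h_read)) {
    span <- (bounds[ri] + 1L):bounds[ri + 1L]
    key <- paste0(ctg[span], ifelse(same[span], "+", "-"), diag[span])
    uk <- unique(key)
    cnt <- tabulate(match(key, uk), length(uk))
    cand <- which(cnt >= params$min_seed_hits)
    if (!length(cand)) next
    for (ci in cand[order(-cnt[cand])]) {
      first <- span[match(uk[ci], key)]
      rseq <- if (same[first]) seqs[use][ri] else rcseqs[ri]
      if (.extend_identity(rseq, index$contig_seqs[ctg[first]],
                           diag[first]) >= params$min_identity) {
        mapped[use[ri]] <- TRUE
        break
      }
    }
  }
  mapped
}

#' Classify one read as mapped or unmapped
#'
#' A read is mapped iff some (contig, strand, diagonal) bin collects at
#' least `min_seed_hits` seed k-mers and the ungapped extension along that
#' diagonal (clipped to contig bounds) reaches `min_identity` over the
#' read's aligned span.
#'
#' @param read a single sequence string, or a one-row [read_set()].
#' @param index a [build_kmer_index()] result.
#' @param params a [map_params()].
#' @return `"mapped"` or `"unmapped"`.
#' @export
classify_read <- function(read, index, params = map_params()) {
  seq <- if (is.data.frame(read)) read$seq[1L] else read
  if (.classify_many(seq, index, params)) "mapped" else "unmapped"
}

#' Partition reads into mapped and unmapped sets
#'
#' Single-end: unmapped reads become singletons. Paired: pairs with both
#' mates unmapped are retained as pairs; pairs with exactly one unmapped
#' mate contribute that mate to the singletons. Read counts are conserved.
#'
#' @param reads1 a [read_set()] data frame.
#' @param reads2 mate reads (or `NULL` for single-end).
#' @param index a [build_kmer_index()].
#' @param params a [map_params()].
#' @return `list(pairs1, pairs2, singletons, counts)` where `counts` has
#'   `total`, `mapped`, `unmapped_pair_reads`, `singletons`.
#' @export
partition_reads <- function(reads1, reads2 = NULL, index,
                            params = map_params()) {
  classify_all <- function(r) {
    if (nrow(r) == 0L) return(logical())
    .classify_many(r$seq, index, params)
  }
  if (is.null(reads2) || nrow(reads2) == 0L) {
    mapped <- classify_all(reads1)
    singles <- reads1[!mapped, , drop = FALSE]
    counts <- c(total = nrow(reads1), mapped = sum(mapped),
                unmapped_pair_reads = 0L, singletons = nrow(singles))
    return(list(pairs1 = empty_reads(), pairs2 = empty_reads(),
                singletons = singles, counts = counts))
  }
  b1 <- strip_mate_suffix(reads1$id); b2 <- strip_mate_suffix(reads2$id)
  orphan <- c(setdiff(b1, b2), setdiff(b2, b1))
  if (length(orphan)) {
    stop("paired files are not id-matched; first orphan: ", orphan[1L])
  }
  reads2 <- reads2[match(b1, b2), , drop = FALSE]
  m1 <- classify_all(reads1); m2 <- classify_all(reads2)
  both_un <- !m1 & !m2
  one_un1 <- !m1 & m2
  one_un2 <- m1 & !m2
  singles <- rbind(reads1[one_un1, , drop = FALSE],
                   reads2[one_un2, , drop = FALSE])
  counts <- c(total = nrow(reads1) + nrow(reads2),
              mapped = sum(m1) + sum(m2),
              unmapped_pair_reads = 2L * sum(both_un),
              singletons = nrow(singles))
  list(pairs1 = reads1[both_un, , drop = FALSE],
       pairs2 = reads2[both_un, , drop = FALSE],
       singletons = singles, counts = counts)
}

#' Repair read pairs into synchronized pairs plus singletons
#'
#' Ids present in both files (after stripping `/1`/`/2` suffixes) are
#' returned as id-synchronized pairs in `r1` order; ids present in only one
#' file become singletons. Assemblies downstream rely on the paired outputs
#' being id-synchronized.
#'
#' @param r1,r2 [read_set()] data frames.
#' @return `list(paired1, paired2, singletons)`.
#' @export
repair_pairs <- function(r1, r2) {
  b1 <- strip_mate_suffix(r1$id); b2 <- strip_mate_suffix(r2$id)
  if (anyDuplicated(b1)) stop("duplicate read id in first file: ",
                              b1[duplicated(b1)][1L])
  if (anyDuplicated(b2)) stop("duplicate read id in second file: ",
                              b2[duplicated(b2)][1L])
  common <- b1[b1 %in% b2]
  list(paired1 = r1[match(common, b1), , drop = FALSE],
       paired2 = r2[match(common, b2), , drop = FALSE],
       singletons = rbind(r1[!(b1 %in% b2), , drop = FALSE],
                          r2[!(b2 %in% b1), , drop = FALSE]))
}

#' Write a mapping summary TSV
#'
#' @param counts the `counts` element of [partition_reads()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mapping_summary <- function(counts, path) {
  df <- data.frame(metric = names(counts), value = as.integer(counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
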