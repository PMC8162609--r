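# Independent oracles used to cross-check the package's implementations.
# Each is written from the definition, not from the implementation's code
# path.

# --- affine-gap local alignment score, Gotoh three-state DP ---------------
oracle_local_score <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1L, m + 1L)       # match/mismatch state
  X <- matrix(NEG, n + 1L, m + 1L)     # gap in b (deletion from a)
  Y <- matrix(NEG, n + 1L, m + 1L)     # gap in a
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      s <- mat[av[i - 1L], bv[j - 1L]]
      X[i, j] <- max(M[i - 1L, j] - gap_open - gap_extend,
                     X[i - 1L, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1L] - gap_open - gap_extend,
                     Y[i, j - 1L] - gap_extend)
      M[i, j] <- max(0, M[i - 1L, j - 1L] + s,
                     X[i - 1L, j - 1L] + s, Y[i - 1L, j - 1L] + s)
      # an optimal local alignment never ends in a gap, so track M only
      best <- max(best, M[i, j])
    }
  }
  best
}

# --- brute-force six-frame ORF scan ---------------------------------------
# every start codon is extended to the first in-frame stop; per (frame,
# stop) the earliest start after the preceding in-frame stop is kept
oracle_orfs <- function(seq, min_orf_nt = 150L,
                        starts = c("ATG", "GTG", "TTG")) {
  stops <- c("TAA", "TAG", "TGA")
  one <- function(s, strand) {
    L <- nchar(s)
    out <- list()
    for (f in 0:2) {
      i <- f + 1L
      prev_stop_end <- f  # position before the first codon
      while (i + 2L <= L) {
        codon <- substr(s, i, i + 2L)
        if (codon %in% stops) {
          # find earliest start strictly after prev_stop_end, before i
          j <- prev_stop_end + 1L
          found <- NA
          while (j < i) {
            if (substr(s, j, j + 2L) %in% starts) { found <- j; break }
            j <- j + 3L
          }
          if (!is.na(found) && (i + 2L - found + 1L) >= min_orf_nt) {
            out[[length(out) + 1L]] <- c(found, i + 2L)
          }
          prev_stop_end <- i + 2L
        }
        i <- i + 3L
      }
    }
    out
  }
  L <- nchar(seq)
  res <- list()
  for (o in one(seq, "+")) {
    res[[length(res) + 1L]] <- data.frame(start = o[1L], end = o[2L],
                                          strand = "+")
  }
  for (o in one(paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1L]]),
                      collapse = ""), "-")) {
    res[[length(res) + 1L]] <- data.frame(start = L - o[2L] + 1L,
                                          end = L - o[1L] + 1L, strand = "-")
  }
  if (!length(res)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character()))
  }
  df <- do.call(rbind, res)
  df <- df[order(df$start, df$end, df$strand), ]
  rownames(df) <- NULL
  df
}

# --- union-find connected components --------------------------------------
oracle_components <- function(vertices, edges) {
  if (is.null(edges)) edges <- matrix(character(), 0L, 2L)
  parent <- stats::setNames(vertices, vertices)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      ra <- find(edges[i, 1L]); rb <- find(edges[i, 2L])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(vertices, find, "")
  split(vertices, roots)
}

# --- pan/core/new curves for one explicit genome order --------------------
oracle_curve <- function(presence, ord) {
  G <- length(ord)
  seen <- rep(FALSE, nrow(presence))
  allin <- rep(TRUE, nrow(presence))
  out <- data.frame(N = seq_len(G), pan = 0L, core = 0L, new = 0L)
  for (N in seq_len(G)) {
    p <- presence[, ord[N]]
    out$new[N] <- sum(p & !seen)
    seen <- seen | p
    allin <- allin & p
    out$pan[N] <- sum(seen)
    out$core[N] <- sum(allin)
  }
  out
}

# random protein/dna helpers
random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n, replace = TRUE),
        collapse = "")
}
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate a fraction of residues (never to the original letter)
mutate_protein <- function(p, frac) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  ch <- strsplit(p, "")[[1L]]
  idx <- sample(length(ch), round(frac * length(ch)))
  ch[idx] <- vapply(ch[idx], function(x) sample(setdiff(aa, x), 1L), "")
  paste(ch, collapse = "")
}
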