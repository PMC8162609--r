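#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

# shared low-level sequence helpers

#' Reverse complement of nucleotide strings
#'
#' Vectorised reverse complement over character vectors; IUPAC ambiguity
#' letters are handled by [Biostrings::reverseComplement()].
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAAC"))
revcomp <- function(x) {
  if (!length(x)) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# all k-mers of a single sequence, 5'->3'; character(0) when too short
kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  substring(seq, 1:(n - k + 1L), k:n)
}

# canonical form: lexicographic min of a k-mer and its reverse complement
canonical_kmers <- function(kmers) {
  if (!length(kmers)) return(character())
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

# sequence records ------------------------------------------------------------

#' Construct a set of sequence records
#'
#' The in-memory representation of FASTA content: a data frame with columns
#' `id` (unique, whitespace-free), `desc` (free text) and `seq`.
#'
#' @param id character vector of identifiers.
#' @param seq character vector of sequences.
#' @param desc character vector of descriptions (defaults to empty).
#' @return a `data.frame` with columns `id`, `desc`, `seq`.
#' @export
seq_set <- function(id, seq, desc = "") {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) stop("id and seq lengths differ")
  if (any(grepl("\\s", id))) stop("sequence ids must not contain whitespace")
  if (anyDuplicated(id)) {
    stop("duplicate sequence id: ", id[duplicated(id)][1L])
  }
  if (length(id) && any(!nzchar(seq))) stop("zero-length sequence not allowed")
  data.frame(id = id, desc = rep_len(as.character(desc), length(id)),
             seq = seq, stringsAsFactors = FALSE)
}

#' Construct a set of read records
#'
#' FASTQ content in memory: columns `id`, `seq` and `qual` (Phred+33,
#' same length as `seq`).
#'
#' @param id,seq,qual character vectors of equal length.
#' @return a `data.frame` with columns `id`, `seq`, `qual`.
#' @export
read_set <- function(id, seq, qual) {
  id <- as.character(id); seq <- toupper(as.character(seq))
  qual <- as.character(qual)
  if (length(qual) == 1L && length(id) != 1L) qual <- rep(qual, length(id))
  if (length(id) != length(seq) || length(seq) != length(qual)) {
    stop("id, seq and qual lengths differ")
  }
  bad <- nchar(seq) != nchar(qual)
  if (any(bad)) {
    stop("quality length differs from sequence length for read: ",
         id[bad][1L])
  }
  data.frame(id = id, seq = seq, qual = qual, stringsAsFactors = FALSE)
}

empty_reads <- function() read_set(character(), character(), character())

# strip paired-end mate suffixes ("/1", "/2") from read ids
strip_mate_suffix <- function(ids) sub("/[12]$", "", ids)

#' Construct an annotation set
#'
#' A genome's contigs plus its CDS features. Validates that every feature
#' lies on a known contig within bounds, that feature ids are unique, and
#' that CDS lengths are multiples of three.
#'
#' @param genome_id single token naming the genome.
#' @param contigs a [seq_set()] data frame of contig sequences.
#' @param features a data frame with columns `feature_id`, `contig_id`,
#'   `start`, `end` (1-based inclusive), `strand` (`+`/`-`) and `product`;
#'   extra columns (e.g. cached `nuc`/`protein`) are preserved.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(genome_id, contigs, features = NULL) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  if (anyDuplicated(contigs$id)) stop("duplicate contig id")
  if (is.null(features) || nrow(features) == 0L) {
    features <- data.frame(feature_id = character(), contig_id = character(),
                           start = integer(), end = integer(),
                           strand = character(), type = character(),
                           product = character(), stringsAsFactors = FALSE)
  } else {
    features <- as.data.frame(features, stringsAsFactors = FALSE)
    if (!"type" %in% names(features)) features$type <- "CDS"
    if (!"product" %in% names(features)) features$product <- "hypothetical protein"
    if (anyDuplicated(features$feature_id)) {
      stop("duplicate feature id: ",
           features$feature_id[duplicated(features$feature_id)][1L])
    }
    unknown <- setdiff(features$contig_id, contigs$id)
    if (length(unknown)) stop("feature references unknown contig: ", unknown[1L])
    clen <- stats::setNames(nchar(contigs$seq), contigs$id)
    bad <- features$start < 1L | features$end > clen[features$contig_id] |
      features$start > features$end
    if (any(bad)) {
      stop("feature out of contig bounds: ", features$feature_id[bad][1L])
    }
    if (any((features$end - features$start + 1L) %% 3L != 0L)) {
      stop("CDS length not a multiple of 3: ",
           features$feature_id[(features$end - features$start + 1L) %% 3L != 0L][1L])
    }
    if (!all(features$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  }
  structure(list(genome_id = genome_id, contigs = contigs, features = features),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %s: %d contig(s) (%d bp), %d CDS\n",
              x$genome_id, nrow(x$contigs), sum(nchar(x$contigs$seq)),
              nrow(x$features)))
  invisible(x)
}

# all permutations of 1..n (n small), rows in lexicographic order
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    out[r + seq_len(nrow(sub)), ] <- cbind(first, matrix(rest[sub], nrow(sub)))
    r <- r + nrow(sub)
  }
  out
}

# sample() that never falls into the scalar 1:n trap
resample <- function(x, ...) x[sample.int(length(x), ...)]

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000000L) * 2039L + h %% 100000L
}
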