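# Standardized CDS annotation: six-frame ORF calling with bacterial
# (table 11) translation and product naming by similarity transfer.

#' Annotation parameters
#'
#' @param min_orf_nt minimum ORF length in nucleotides, stop codon
#'   included (multiple of 3, >= 30).
#' @param start_codons accepted start codons.
#' @param genetic_code NCBI translation table id (default "11", bacterial).
#' @return an object of class `annot_params`.
#' @export
annot_params <- function(min_orf_nt = 150L,
                         start_codons = c("ATG", "GTG", "TTG"),
                         genetic_code = "11") {
  stopifnot(min_orf_nt %% 3L == 0L, min_orf_nt >= 30L,
            all(nchar(start_codons) == 3L))
  structure(list(min_orf_nt = as.integer(min_orf_nt),
                 start_codons = toupper(start_codons),
                 genetic_code = genetic_code),
            class = "annot_params")
}

#' Translate CDS nucleotide sequences (bacterial code)
#'
#' Standard table-11 translation. The trailing stop codon (if any) is
#' dropped; internal stops render as `*` (callers reject those CDS).
#' Codons containing `N` translate to `X` unless unambiguous.
#'
#' @param nuc character vector of CDS sequences (lengths multiples of 3).
#' @param init_met when `TRUE`, alternative start codons (GTG/TTG) are
#'   rendered as `M`, the bacterial initiator methionine convention.
#' @param genetic_code NCBI translation table id.
#' @return character vector of protein sequences (no trailing stop).
#' @export
translate_cds <- function(nuc, init_met = FALSE, genetic_code = "11") {
  if (!length(nuc)) return(character())
  if (any(nchar(nuc) %% 3L != 0L)) {
    stop("CDS length not a multiple of 3")
  }
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAStringSet(toupper(nuc)),
    genetic.code = Biostrings::getGeneticCode(genetic_code),
    no.init.codon = TRUE, if.fuzzy.codon = "solve")))
  aa <- sub("\\*$", "", aa)
  if (init_met) {
    first <- toupper(substr(nuc, 1L, 3L))
    aa <- ifelse(first %in% c("ATG", "GTG", "TTG") & nchar(aa) > 0L,
                 paste0("M", substring(aa, 2L)), aa)
  }
  aa
}

# ORFs on one strand of `s`: for each in-frame stop codon, the longest ORF
# ending at that stop (earliest start codon after the previous stop)
.scan_strand <- function(s, params) {
  L <- nchar(s)
  res <- list()
  if (L < params$min_orf_nt) return(res)
  for (f in 0:2) {
    cpos <- seq(f + 1L, L - 2L, by = 3L)
    if (!length(cpos)) next
    codons <- substring(s, cpos, cpos + 2L)
    stop_i <- which(codons %in% .stop_codons)
    start_i <- which(codons %in% params$start_codons)
    prev <- 0L
    for (si in stop_i) {
      cand <- start_i[start_i > prev & start_i < si]
      if (length(cand)) {
        st <- cand[1L]
        if ((si - st + 1L) * 3L >= params$min_orf_nt) {
          res[[length(res) + 1L]] <- c(start = cpos[st], end = cpos[si] + 2L,
                                       frame = f)
        }
      }
      prev <- si
    }
  }
  res
}

#' Find open reading frames on a contig
#'
#' Scans all six frames; for each stop codon the longest ORF ending at that
#' stop (earliest in-frame start codon after the previous stop) is called
#' when its length (stop included) reaches `min_orf_nt`. Minus-strand calls
#' are reported in plus-strand coordinates with `strand = "-"`. Calls are
#' sorted by `(start, end)`.
#'
#' @param contig a single sequence string, or a one-row [seq_set()].
#' @param params an [annot_params()].
#' @return data frame with columns `start`, `end`, `strand`, `frame`,
#'   `nuc` (stop included) and `protein` (stop excluded, initiator as `M`).
#' @export
find_orfs <- function(contig, params = annot_params()) {
  seq <- toupper(if (is.data.frame(contig)) contig$seq[1L] else contig)
  empty <- data.frame(start = integer(), end = integer(), strand = character(),
                      frame = integer(), nuc = character(),
                      protein = character(), stringsAsFactors = FALSE)
  if (!nzchar(seq)) return(empty)
  L <- nchar(seq)
  plus <- .scan_strand(seq, params)
  rs <- revcomp(seq)
  minus <- .scan_strand(rs, params)
  rows <- list()
  for (o in plus) {
    rows[[length(rows) + 1L]] <-
      data.frame(start = o[["start"]], end = o[["end"]], strand = "+",
                 frame = o[["frame"]], stringsAsFactors = FALSE)
  }
  for (o in minus) {
    rows[[length(rows) + 1L]] <-
      data.frame(start = L - o[["end"]] + 1L, end = L - o[["start"]] + 1L,
                 strand = "-", frame = o[["frame"]], stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  df <- do.call(rbind, rows)
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  nuc <- substr(rep(seq, nrow(df)), df$start, df$end)
  m <- df$strand == "-"
  if (any(m)) nuc[m] <- revcomp(nuc[m])
  df$nuc <- nuc
  df$protein <- translate_cds(nuc, init_met = TRUE, params$genetic_code)
  df
}

#' Annotate a genome (contig set) by ORF calling
#'
#' Features are numbered sequentially in coordinate order per contig order,
#' as `<genome_id>_NNNNN`. All products start as `"hypothetical protein"`;
#' use [assign_products()] to transfer names from a reference protein set.
#'
#' @param genome_id genome identifier token.
#' @param contigs a [seq_set()] data frame.
#' @param params an [annot_params()].
#' @return an [annotation_set()] whose features carry cached `nuc` and
#'   `protein` columns.
#' @export
annotate_genome <- function(genome_id, contigs, params = annot_params()) {
  if (is.null(contigs) || nrow(contigs) == 0L) {
    return(annotation_set(genome_id, seq_set(character(), character())))
  }
  feats <- list()
  for (ci in seq_len(nrow(contigs))) {
    orfs <- find_orfs(contigs$seq[ci], params)
    if (nrow(orfs) == 0L) next
    orfs$contig_id <- contigs$id[ci]
    feats[[length(feats) + 1L]] <- orfs
  }
  if (!length(feats)) return(annotation_set(genome_id, contigs))
  f <- do.call(rbind, feats)
  f$feature_id <- sprintf("%s_%05d", genome_id, seq_len(nrow(f)))
  f$type <- "CDS"
  f$product <- "hypothetical protein"
  f <- f[, c("feature_id", "contig_id", "start", "end", "strand", "frame",
             "type", "product", "nuc", "protein")]
  annotation_set(genome_id, contigs, f)
}

#' Transfer product names from a reference protein set
#'
#' Each CDS whose best qualifying hit (under the similarity thresholds)
#' against the reference proteins exists takes that hit's product name
#' (the reference record's description, falling back to its id); all other
#' CDS keep `"hypothetical protein"`. Idempotent.
#'
#' @param ann an [annotation_set()] with cached proteins (or any
#'   annotation set; proteins are derived if absent).
#' @param ref_proteins a [seq_set()] of named reference proteins.
#' @param scheme a [scoring_scheme()] (protein mode).
#' @param thresholds a [similarity_thresholds()].
#' @return the annotation set with updated `product` fields.
#' @export
assign_products <- function(ann, ref_proteins,
                            scheme = scoring_scheme("protein"),
                            thresholds = similarity_thresholds()) {
  stopifnot(inherits(ann, "annotation_set"))
  if (nrow(ann$features) == 0L || is.null(ref_proteins) ||
      nrow(ref_proteins) == 0L) {
    return(ann)
  }
  prot <- annotation_proteins(ann)
  hits <- search_hits(seq_set(prot$feature_id, prot$protein),
                      ref_proteins, scheme, thresholds)
  if (nrow(hits) == 0L) return(ann)
  best <- hits[order(hits$query_id, hits$evalue, -hits$score,
                     hits$subject_id), ]
  best <- best[!duplicated(best$query_id), , drop = FALSE]
  name_of <- stats::setNames(
    ifelse(nzchar(ref_proteins$desc), ref_proteins$desc, ref_proteins$id),
    ref_proteins$id)
  idx <- match(best$query_id, ann$features$feature_id)
  ann$features$product[idx] <- unname(name_of[best$subject_id])
  ann
}

# features with a guaranteed `protein` column
annotation_proteins <- function(ann) {
  f <- ann$features
  if (!"protein" %in% names(f)) {
    f <- cds_sequences(ann)
    f$protein <- translate_cds(f$nuc, init_met = TRUE)
  }
  f
}
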