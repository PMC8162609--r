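# Readers/writers for the on-disk formats the pipeline touches:
# FASTA, FASTQ (Phred+33), GFF3, and PGAP-style pep/nuc/function inputs.

.iupac_chars <- "ACGTNRYSWKMBDHVacgtnryswkmbdhv"

# locate the first offending FASTA line to report a useful error
.fasta_diagnose <- function(path, msg) {
  lines <- readLines(path, warn = FALSE)
  ok <- sprintf("[%s]*", .iupac_chars)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">") || !nzchar(ln)) next
    if (!grepl(sprintf("^[%s]*$", .iupac_chars), ln)) {
      stop(sprintf("invalid character in FASTA sequence at %s line %d", path, i))
    }
  }
  stop("malformed FASTA file ", path, ": ", msg)
}

#' Read a FASTA file
#'
#' Wrapped sequence lines are concatenated and sequences are uppercased.
#' Header lines are split into an `id` (first whitespace-delimited token)
#' and a free-text `desc`.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"dna"` (default; rejects non-IUPAC characters) or
#'   `"any"` (e.g. protein FASTA).
#' @return a [seq_set()] data frame with columns `id`, `desc`, `seq`.
#' @export
read_fasta <- function(path, alphabet = c("dna", "any")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!startsWith(first, ">")) {
    stop("not FASTA (line 1 does not start with '>'): ", path)
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) .fasta_diagnose(path, conditionMessage(e)))
  seqs <- toupper(as.character(set))
  if (alphabet == "dna") {
    bad <- !grepl(sprintf("^[%s]+$", .iupac_chars), seqs)
    if (any(bad)) .fasta_diagnose(path, "non-IUPAC character")
  }
  hdr <- names(set)
  ids <- sub("\\s.*$", "", hdr)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sequence id '%s' in %s",
                 ids[duplicated(ids)][1L], path))
  }
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seq_set(ids, seqs, desc)
}

#' Write a FASTA file
#'
#' Records are written in the given order (order preservation is relied on
#' by [update_genome()]'s append-at-end contract).
#'
#' @param records a [seq_set()] data frame (`id`, optional `desc`, `seq`).
#' @param path output path.
#' @param width line width for sequence wrapping (positive integer).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.null(records) || nrow(records) == 0L) stop("no records to write")
  if (!is.numeric(width) || length(width) != 1L || width < 1L) {
    stop("width must be a positive integer")
  }
  desc <- if ("desc" %in% names(records)) records$desc else ""
  nm <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  x <- Biostrings::BStringSet(stats::setNames(records$seq, nm))
  Biostrings::writeXStringSet(x, filepath = path, width = as.integer(width))
  invisible(path)
}

#' Read a FASTQ file
#'
#' Expects 4-line records with Phred+33 qualities. An empty file yields an
#' empty read set.
#'
#' @param path path to a FASTQ file.
#' @return a [read_set()] data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  if (file.size(path) == 0L) return(empty_reads())
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("truncated FASTQ record at end of %s (%d lines)",
                 path, length(lines)))
  }
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  qual <- lines[seq(4L, length(lines), by = 4L)]
  if (!all(startsWith(hdr, "@"))) {
    stop("malformed FASTQ header (missing '@') in ", path)
  }
  if (!all(startsWith(plus, "+"))) {
    stop("malformed FASTQ separator (missing '+') in ", path)
  }
  bad <- nchar(seqs) != nchar(qual)
  if (any(bad)) {
    stop(sprintf("quality/sequence length mismatch for read '%s' in %s",
                 sub("^@", "", sub("\\s.*$", "", hdr[bad][1L])), path))
  }
  read_set(sub("^@", "", sub("\\s.*$", "", hdr)), seqs, qual)
}

#' Write a FASTQ file
#'
#' @param records a [read_set()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  if (is.null(records) || nrow(records) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  bad <- nchar(records$seq) != nchar(records$qual)
  if (any(bad)) {
    stop("quality length differs from sequence length for read: ",
         records$id[bad][1L])
  }
  out <- character(4L * nrow(records))
  out[seq(1L, length(out), 4L)] <- paste0("@", records$id)
  out[seq(2L, length(out), 4L)] <- records$seq
  out[seq(3L, length(out), 4L)] <- "+"
  out[seq(4L, length(out), 4L)] <- records$qual
  writeLines(out, path)
  invisible(path)
}

#' Read a GFF3 + FASTA annotation
#'
#' Only CDS features are retained. The product is taken from the `product`
#' attribute (default `"hypothetical protein"`); feature ids come from the
#' `ID` attribute.
#'
#' @param path GFF3 file.
#' @param fasta_path FASTA file with the contig sequences.
#' @param genome_id genome identifier; defaults to the GFF3 file stem.
#' @return an [annotation_set()].
#' @export
read_gff3 <- function(path, fasta_path,
                      genome_id = tools::file_path_sans_ext(basename(path))) {
  contigs <- read_fasta(fasta_path)
  g <- as.data.frame(rtracklayer::readGFF(path))
  g <- g[g$type == "CDS", , drop = FALSE]
  if (nrow(g) == 0L) return(annotation_set(genome_id, contigs))
  fid <- if ("ID" %in% names(g)) as.character(g$ID) else
    sprintf("%s_%05d", genome_id, seq_len(nrow(g)))
  prod <- if ("product" %in% names(g)) as.character(g$product) else
    rep(NA_character_, nrow(g))
  prod[is.na(prod) | !nzchar(prod)] <- "hypothetical protein"
  feats <- data.frame(feature_id = fid,
                      contig_id = as.character(g$seqid),
                      start = as.integer(g$start), end = as.integer(g$end),
                      strand = as.character(g$strand), type = "CDS",
                      product = prod, stringsAsFactors = FALSE)
  annotation_set(genome_id, contigs, feats)
}

#' Write an annotation set as GFF3
#'
#' @param ann an [annotation_set()].
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  f <- ann$features
  if (nrow(f) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(seqnames = f$contig_id,
                               ranges = IRanges::IRanges(f$start, f$end),
                               strand = f$strand)
  S4Vectors::mcols(gr)$source <- "pancraft"
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- f$feature_id
  S4Vectors::mcols(gr)$product <- f$product
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Extract CDS nucleotide sequences from an annotation set
#'
#' @param ann an [annotation_set()].
#' @return the feature data frame with a `nuc` column (strand-resolved CDS
#'   sequence, stop codon included).
#' @export
cds_sequences <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  f <- ann$features
  if (nrow(f) == 0L) { f$nuc <- character(); return(f) }
  cs <- stats::setNames(ann$contigs$seq, ann$contigs$id)
  nuc <- substr(cs[f$contig_id], f$start, f$end)
  minus <- f$strand == "-"
  if (any(minus)) nuc[minus] <- revcomp(nuc[minus])
  f$nuc <- unname(nuc)
  f
}

#' Write PGAP-style comparison inputs (pep, nuc, function)
#'
#' Writes `<prefix>.pep` (translated proteins, no stop symbol),
#' `<prefix>.nuc` (CDS nucleotide sequences) and `<prefix>.function`
#' (tab-delimited `feature_id<TAB>-<TAB>product`; the COG column is fixed
#' to `-`). Entry order is identical across the three files. CDS containing
#' an internal stop are skipped in all three files with a warning.
#'
#' @param ann an [annotation_set()] with at least one CDS.
#' @param out_prefix path prefix for the three files.
#' @return named character vector of the three paths (`pep`, `nuc`,
#'   `fun`), invisibly.
#' @export
write_pgap_inputs <- function(ann, out_prefix) {
  stopifnot(inherits(ann, "annotation_set"))
  f <- cds_sequences(ann)
  if (nrow(f) == 0L) stop("annotation set has no CDS")
  pep <- if ("protein" %in% names(f)) f$protein else translate_cds(f$nuc, init_met = TRUE)
  internal <- grepl("\\*", pep)
  if (any(internal)) {
    warning(sum(internal), " CDS with internal stop codon skipped: ",
            paste(utils::head(f$feature_id[internal], 3L), collapse = ", "))
    f <- f[!internal, , drop = FALSE]
    pep <- pep[!internal]
  }
  if (nrow(f) == 0L) stop("no translatable CDS left to write")
  paths <- c(pep = paste0(out_prefix, ".pep"),
             nuc = paste0(out_prefix, ".nuc"),
             fun = paste0(out_prefix, ".function"))
  write_fasta(seq_set(f$feature_id, pep, f$product), paths["pep"])
  write_fasta(seq_set(f$feature_id, f$nuc, f$product), paths["nuc"])
  writeLines(paste(f$feature_id, "-", f$product, sep = "\t"), paths["fun"])
  invisible(paths)
}

#' Read a PGAP-style protein (pep) file
#'
#' Convenience reader used by the comparison stage; the description field
#' carries the product name.
#'
#' @param path a `.pep` FASTA file.
#' @return a [seq_set()] data frame.
#' @export
read_pep <- function(path) read_fasta(path, alphabet = "any")
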