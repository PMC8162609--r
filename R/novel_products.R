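# Stage-1 orchestration: identify assembled CDS with no similarity to the
# reference's CDS set, append them to the genome file, and re-annotate.

#' Identify assembled CDS absent from the reference annotation
#'
#' Returns exactly those assembly CDS having no hit against the reference
#' CDS set that passes the thresholds (protein-level comparison by
#' default). Redundant assembled CDS that hit each other under the same
#' thresholds are collapsed to the longest representative, so one missing
#' gene yields one product. Results are ordered by assembly coordinates.
#'
#' @param ref_ann reference [annotation_set()].
#' @param asm_ann assembly [annotation_set()].
#' @param scheme a [scoring_scheme()].
#' @param thresholds a [similarity_thresholds()].
#' @param level `"protein"` (default) or `"nucleotide"` comparison.
#' @return feature rows of `asm_ann` (with `nuc`/`protein` columns).
#' @export
identify_new_products <- function(ref_ann, asm_ann,
                                  scheme = scoring_scheme("protein"),
                                  thresholds = similarity_thresholds(),
                                  level = c("protein", "nucleotide")) {
  level <- match.arg(level)
  asm <- annotation_proteins(asm_ann)
  if (nrow(asm) == 0L) return(asm)
  ref <- annotation_proteins(ref_ann)
  qcol <- if (level == "protein") "protein" else "nuc"
  if (level == "nucleotide" && scheme$mode != "nucleotide") {
    scheme <- scoring_scheme("nucleotide")
  }
  queries <- seq_set(asm$feature_id, asm[[qcol]])
  hit_ids <- character()
  if (nrow(ref) > 0L) {
    hits <- search_hits(queries, seq_set(ref$feature_id, ref[[qcol]]),
                        scheme, thresholds)
    hit_ids <- unique(hits$query_id)
  }
  new <- asm[!(asm$feature_id %in% hit_ids), , drop = FALSE]
  if (nrow(new) > 1L) {
    # collapse mutually similar assembled CDS to the longest representative
    self <- search_hits(seq_set(new$feature_id, new[[qcol]]),
                        seq_set(new$feature_id, new[[qcol]]),
                        scheme, thresholds)
    self <- self[self$query_id != self$subject_id, , drop = FALSE]
    if (nrow(self)) {
      g <- igraph::graph_from_data_frame(
        self[, c("query_id", "subject_id")], directed = FALSE,
        vertices = new$feature_id)
      comp <- igraph::components(g)$membership
      len <- stats::setNames(nchar(new$nuc), new$feature_id)
      keep <- vapply(split(names(comp), comp), function(ids) {
        ids[order(-len[ids], ids)][1L]
      }, "")
      new <- new[new$feature_id %in% keep, , drop = FALSE]
    }
  }
  ord <- order(match(new$contig_id, asm_ann$contigs$id), new$start, new$end)
  new <- new[ord, , drop = FALSE]
  rownames(new) <- NULL
  new
}

#' Append newly identified products to a genome file
#'
#' The output contains the original records, byte-identical and in their
#' original order, followed by one record per new feature (id
#' `new_<feature_id>`, sequence = the CDS nucleotide sequence).
#'
#' @param reference a [seq_set()] of the original genome records.
#' @param new_features feature rows from [identify_new_products()].
#' @param asm_contigs the assembly [seq_set()] (used to resolve features
#'   lacking a cached `nuc` sequence).
#' @return the updated [seq_set()].
#' @export
update_genome <- function(reference, new_features, asm_contigs = NULL) {
  if (is.null(new_features) || nrow(new_features) == 0L) return(reference)
  if (!"nuc" %in% names(new_features)) {
    if (is.null(asm_contigs)) stop("cannot resolve new features: no sequences")
    tmp <- annotation_set("asm", asm_contigs, new_features)
    new_features <- cds_sequences(tmp)
  }
  if (any(is.na(new_features$nuc)) || any(!nzchar(new_features$nuc))) {
    stop("unresolvable new feature sequence")
  }
  rbind(reference,
        seq_set(paste0("new_", new_features$feature_id), new_features$nuc,
                new_features$product))
}

#' Stage-1 discovery report
#'
#' Mirrors the per-strain report columns: named new products, hypothetical
#' proteins, their total, and the mean CDS length in nucleotides.
#'
#' @param new_features identified feature rows (after product assignment).
#' @return a one-row data frame (`new_products`, `hypothetical`, `total`,
#'   `mean_len_nt`).
#' @export
discovery_report <- function(new_features) {
  n <- nrow(new_features)
  hyp <- if (n) sum(new_features$product == "hypothetical protein") else 0L
  data.frame(new_products = n - hyp, hypothetical = hyp, total = n,
             mean_len_nt = if (n) as.integer(round(mean(nchar(new_features$nuc))))
                           else 0L)
}

#' Run stage 1: recover gene products missing from a reference
#'
#' Executes partition, pair repair, assembly, annotation of reference and
#' assembly, identification of new products, genome update, and a second
#' annotation round.
#'
#' @param reference a [seq_set()] (or FASTA path) of the reference genome.
#' @param reads1 a [read_set()] (or FASTQ path).
#' @param reads2 mate reads (or `NULL` for single-end).
#' @param genome_id identifier used for feature ids.
#' @param map a [map_params()].
#' @param k_asm assembly k-mer size.
#' @param min_contig_len minimum assembled contig length.
#' @param annot an [annot_params()].
#' @param scheme a [scoring_scheme()].
#' @param thresholds a [similarity_thresholds()].
#' @param known_proteins optional [seq_set()] of named proteins used to
#'   name the identified products.
#' @return a list with `updated` (updated genome records), `new_features`,
#'   `report` ([discovery_report()]), `second_annotation`
#'   (re-annotation of the updated genome), `asm_contigs`, `counts`
#'   (mapping counts).
#' @export
run_discovery <- function(reference, reads1, reads2 = NULL,
                          genome_id = "genome",
                          map = map_params(), k_asm = 31L,
                          min_contig_len = 200L,
                          annot = annot_params(),
                          scheme = scoring_scheme("protein"),
                          thresholds = similarity_thresholds(),
                          known_proteins = NULL) {
  if (is.character(reference)) reference <- read_fasta(reference)
  if (is.character(reads1)) reads1 <- read_fastq(reads1)
  if (is.character(reads2)) reads2 <- read_fastq(reads2)
  index <- build_kmer_index(reference, map$k)
  part <- partition_reads(reads1, reads2, index, map)
  rep_ <- if (nrow(part$pairs1)) repair_pairs(part$pairs1, part$pairs2) else
    list(paired1 = empty_reads(), paired2 = empty_reads(),
         singletons = empty_reads())
  asm_reads <- list(rep_$paired1, rep_$paired2, rep_$singletons,
                    part$singletons)
  graph <- prune_graph(build_debruijn(asm_reads, k_asm))
  contigs <- extract_contigs(graph, min_contig_len)
  asm_records <- if (nrow(contigs)) {
    seq_set(contigs$contig_id, contigs$sequence)
  } else {
    seq_set(character(), character())
  }
  ref_ann <- annotate_genome(genome_id, reference, annot)
  asm_ann <- annotate_genome(paste0(genome_id, "_asm"), asm_records, annot)
  new <- identify_new_products(ref_ann, asm_ann, scheme, thresholds)
  updated <- update_genome(reference, new, asm_records)
  if (!is.null(known_proteins) && nrow(new) > 0L) {
    tmp <- annotation_set(paste0(genome_id, "_new"), asm_records, new)
    tmp <- assign_products(tmp, known_proteins, scheme, thresholds)
    new$product <- tmp$features$product
  }
  second <- annotate_genome(genome_id, updated, annot)
  list(updated = updated, new_features = new, report = discovery_report(new),
       second_annotation = second, asm_contigs = contigs,
       counts = part$counts)
}
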