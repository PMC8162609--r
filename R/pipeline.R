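# Run configuration, resumable step-state store, and the end-to-end runner
# tying stage 1 (per-organism gene recovery) and stage 2 (pan-genome
# comparison) together. The step status store is a single JSON file per run
# directory; a step is skipped on resume only while the whole upstream
# chain is unchanged, so stale intermediates are never reused.

.pipeline_steps <- c("partition", "repair", "assemble", "annotate_ref",
                     "annotate_asm", "identify", "update", "reannotate",
                     "genfiles", "cluster", "curves", "fit", "reports")

#' Pipeline run configuration
#'
#' @param organisms a data frame (or list coercible to one) with columns
#'   `genome_id`, `reference` (FASTA path), `reads1` (FASTQ path) and
#'   optionally `reads2` (`NA` for single-end).
#' @param outdir run directory (created if needed).
#' @param thresholds a [similarity_thresholds()].
#' @param map a [map_params()].
#' @param k_asm assembly k-mer size.
#' @param min_contig_len minimum assembled contig length.
#' @param annot an [annot_params()].
#' @param n_perms genome-order permutations for the pan-genome curves.
#' @param seed master seed; every stochastic step derives a named sub-seed
#'   from it.
#' @param known_proteins optional FASTA of named proteins used to name
#'   recovered products.
#' @return an object of class `run_config`.
#' @export
run_config <- function(organisms, outdir,
                       thresholds = similarity_thresholds(),
                       map = map_params(), k_asm = 31L,
                       min_contig_len = 200L, annot = annot_params(),
                       n_perms = 1000L, seed = 1L, known_proteins = NULL) {
  organisms <- as.data.frame(organisms, stringsAsFactors = FALSE)
  stopifnot(all(c("genome_id", "reference", "reads1") %in% names(organisms)),
            nrow(organisms) >= 1L)
  if (!"reads2" %in% names(organisms)) organisms$reads2 <- NA_character_
  structure(list(organisms = organisms, outdir = outdir,
                 thresholds = thresholds, map = map,
                 k_asm = as.integer(k_asm),
                 min_contig_len = as.integer(min_contig_len), annot = annot,
                 n_perms = as.integer(n_perms), seed = as.integer(seed),
                 known_proteins = known_proteins),
            class = "run_config")
}

# --- step state store -------------------------------------------------------

fresh_state <- function() {
  steps <- lapply(.pipeline_steps, function(s) {
    list(status = "pending", params_hash = "", outputs = character(),
         started_at = "", ended_at = "")
  })
  names(steps) <- .pipeline_steps
  list(steps = steps)
}

#' Save pipeline state (atomic)
#'
#' Writes the step-state store as human-readable JSON via a temp-file +
#' rename, so a crash never leaves a truncated store.
#'
#' @param state a state list (see [load_state()]).
#' @param path target path.
#' @return `path`, invisibly.
#' @export
save_state <- function(state, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(state, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Load pipeline state
#'
#' A missing file yields a fresh all-pending state; a corrupt file raises
#' an error naming the file (never a silent reset).
#'
#' @param path state file path.
#' @return the state list.
#' @export
load_state <- function(path) {
  if (!file.exists(path)) return(fresh_state())
  st <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e) {
                   stop("corrupt state file ", path, ": ",
                        conditionMessage(e), call. = FALSE)
                 })
  if (!is.list(st) || is.null(st$steps) ||
      !all(.pipeline_steps %in% names(st$steps))) {
    stop("corrupt state file ", path, ": missing step records")
  }
  st$steps <- lapply(st$steps, function(s) {
    s$outputs <- as.character(unlist(s$outputs))
    s
  })
  st
}

# digest of a step's effective parameters plus the content digests of the
# run's input files, so edited inputs invalidate downstream results
.step_hash <- function(step, config) {
  files <- c(config$organisms$reference, config$organisms$reads1,
             stats::na.omit(config$organisms$reads2), config$known_proteins)
  digests <- unname(tools::md5sum(files[!is.na(files)]))
  pars <- switch(step,
    partition = list(config$map),
    repair = list(),
    assemble = list(config$k_asm, config$min_contig_len),
    annotate_ref = list(config$annot),
    annotate_asm = list(config$annot),
    identify = list(config$thresholds),
    update = list(),
    reannotate = list(config$annot, config$thresholds),
    genfiles = list(),
    cluster = list(config$thresholds),
    curves = list(config$n_perms, config$seed),
    fit = list(),
    reports = list())
  rlang::hash(list(step, config$organisms$genome_id, digests, pars,
                   config$seed))
}

# --- step implementations (file-mediated, so resume is trivially correct) ---

.org_dir <- function(config, g) file.path(config$outdir, "stage1", g)

.load_ann <- function(dir, stem, genome_id) {
  read_gff3(file.path(dir, paste0(stem, ".gff3")),
            file.path(dir, paste0(stem, ".fasta")), genome_id = genome_id)
}

.save_ann <- function(ann, dir, stem) {
  if (nrow(ann$contigs)) {
    write_fasta(ann$contigs, file.path(dir, paste0(stem, ".fasta")))
  } else {
    file.create(file.path(dir, paste0(stem, ".fasta")))
  }
  write_gff3(ann, file.path(dir, paste0(stem, ".gff3")))
  c(file.path(dir, paste0(stem, ".fasta")),
    file.path(dir, paste0(stem, ".gff3")))
}

# read an annotation whose FASTA may be legitimately empty
.load_ann_maybe_empty <- function(dir, stem, genome_id) {
  fa <- file.path(dir, paste0(stem, ".fasta"))
  if (file.size(fa) == 0L) {
    return(annotation_set(genome_id, seq_set(character(), character())))
  }
  .load_ann(dir, stem, genome_id)
}

.step_partition <- function(config) {
  out <- character()
  for (i in seq_len(nrow(config$organisms))) {
    o <- config$organisms[i, ]
    d <- .org_dir(config, o$genome_id)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    reference <- read_fasta(o$reference)
    idx <- build_kmer_index(reference, config$map$k)
    r1 <- read_fastq(o$reads1)
    r2 <- if (!is.na(o$reads2)) read_fastq(o$reads2) else NULL
    part <- partition_reads(r1, r2, idx, config$map)
    write_fastq(part$pairs1, file.path(d, "unmapped_1.fastq"))
    write_fastq(part$pairs2, file.path(d, "unmapped_2.fastq"))
    write_fastq(part$singletons, file.path(d, "unmapped_singletons.fastq"))
    write_mapping_summary(part$counts, file.path(d, "mapping_summary.tsv"))
    out <- c(out, file.path(d, c("unmapped_1.fastq", "unmapped_2.fastq",
                                 "unmapped_singletons.fastq",
                                 "mapping_summary.tsv")))
  }
  out
}

.step_repair <- function(config) {
  out <- character()
  for (g in config$organisms$genome_id) {
    d <- .org_dir(config, g)
    p1 <- read_fastq(file.path(d, "unmapped_1.fastq"))
    p2 <- read_fastq(file.path(d, "unmapped_2.fastq"))
    rep_ <- repair_pairs(p1, p2)
    singles <- rbind(read_fastq(file.path(d, "unmapped_singletons.fastq")),
                     rep_$singletons)
    write_fastq(rep_$paired1, file.path(d, "repaired_1.fastq"))
    write_fastq(rep_$paired2, file.path(d, "repaired_2.fastq"))
    write_fastq(singles, file.path(d, "repaired_singletons.fastq"))
    out <- c(out, file.path(d, c("repaired_1.fastq", "repaired_2.fastq",
                                 "repaired_singletons.fastq")))
  }
  out
}

.step_assemble <- function(config) {
  out <- character()
  for (g in config$organisms$genome_id) {
    d <- .org_dir(config, g)
    reads <- list(read_fastq(file.path(d, "repaired_1.fastq")),
                  read_fastq(file.path(d, "repaired_2.fastq")),
                  read_fastq(file.path(d, "repaired_singletons.fastq")))
    graph <- prune_graph(build_debruijn(reads, config$k_asm))
    contigs <- extract_contigs(graph, config$min_contig_len)
    write_contigs(contigs, file.path(d, "contigs.fasta"))
    out <- c(out, file.path(d, "contigs.fasta"))
  }
  out
}

.step_annotate_ref <- function(config) {
  out <- character()
  for (i in seq_len(nrow(config$organisms))) {
    o <- config$organisms[i, ]
    d <- .org_dir(config, o$genome_id)
    ann <- annotate_genome(o$genome_id, read_fasta(o$reference), config$annot)
    out <- c(out, .save_ann(ann, d, "ref"))
  }
  out
}

.step_annotate_asm <- function(config) {
  out <- character()
  for (g in config$organisms$genome_id) {
    d <- .org_dir(config, g)
    fa <- file.path(d, "contigs.fasta")
    contigs <- if (file.size(fa) > 0L) read_fasta(fa) else
      seq_set(character(), character())
    ann <- annotate_genome(paste0(g, "_asm"), contigs, config$annot)
    out <- c(out, .save_ann(ann, d, "asm"))
  }
  out
}

.step_identify <- function(config) {
  out <- character()
  for (g in config$organisms$genome_id) {
    d <- .org_dir(config, g)
    ref_ann <- .load_ann(d, "ref", g)
    asm_ann <- .load_ann_maybe_empty(d, "asm", paste0(g, "_asm"))
    new <- identify_new_products(ref_ann, asm_ann,
                                 thresholds = config$thresholds)
    utils::write.table(
      new[, c("feature_id", "contig_id", "start", "end", "strand", "product")],
      file.path(d, "new_products.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(new)) {
      write_fasta(seq_set(new$feature_id, new$nuc), file.path(d, "new_products.fna"))
      write_fasta(seq_set(new$feature_id, new$protein),
                  file.path(d, "new_products.faa"))
    } else {
      file.create(file.path(d, "new_products.fna"),
                  file.path(d, "new_products.faa"))
    }
    out <- c(out, file.path(d, c("new_products.tsv", "new_products.fna",
                                 "new_products.faa")))
  }
  out
}

.step_update <- function(config) {
  out <- character()
  for (i in seq_len(nrow(config$organisms))) {
    o <- config$organisms[i, ]
    d <- .org_dir(config, o$genome_id)
    reference <- read_fasta(o$reference)
    fna <- file.path(d, "new_products.fna")
    updated <- if (file.size(fna) > 0L) {
      new <- read_fasta(fna)
      rbind(reference, seq_set(paste0("new_", new$id), new$seq))
    } else reference
    write_fasta(updated, file.path(d, "updated.fasta"))
    out <- c(out, file.path(d, "updated.fasta"))
  }
  out
}

.step_reannotate <- function(config) {
  out <- character()
  known <- if (!is.null(config$known_proteins)) {
    read_fasta(config$known_proteins)
  } else NULL
  for (g in config$organisms$genome_id) {
    d <- .org_dir(config, g)
    ann <- annotate_genome(g, read_fasta(file.path(d, "updated.fasta")),
                           config$annot)
    if (!is.null(known)) {
      ann <- assign_products(ann, known, thresholds = config$thresholds)
    }
    out <- c(out, .save_ann(ann, d, "updated"))
    # per-organism discovery report from the identified set
    new <- utils::read.delim(file.path(d, "new_products.tsv"),
                             stringsAsFactors = FALSE)
    fna <- file.path(d, "new_products.fna")
    rep_df <- if (nrow(new) && file.size(fna) > 0L) {
      nf <- read_fasta(fna)
      prod <- new$product
      if (!is.null(known) && nrow(nf)) {
        tmp <- annotation_set(g, nf,
                              data.frame(feature_id = nf$id, contig_id = nf$id,
                                         start = 1L, end = nchar(nf$seq),
                                         strand = "+", type = "CDS",
                                         product = "hypothetical protein"))
        tmp <- assign_products(tmp, known, thresholds = config$thresholds)
        prod <- tmp$features$product
      }
      discovery_report(data.frame(product = prod, nuc = nf$seq))
    } else discovery_report(new[0, c("feature_id", "product"), drop = FALSE])
    rep_df <- cbind(genome_id = g, rep_df)
    utils::write.table(rep_df, file.path(d, "report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out <- c(out, file.path(d, "report.tsv"))
  }
  out
}

.step_genfiles <- function(config) {
  out <- character()
  for (g in config$organisms$genome_id) {
    d <- .org_dir(config, g)
    ann <- .load_ann(d, "updated", g)
    paths <- write_pgap_inputs(ann, file.path(d, g))
    out <- c(out, unname(paths))
  }
  out
}

.stage2_dir <- function(config) file.path(config$outdir, "stage2")

.step_cluster <- function(config) {
  d2 <- .stage2_dir(config)
  dir.create(d2, recursive = TRUE, showWarnings = FALSE)
  orgs <- config$organisms$genome_id
  if (length(orgs) < 2L) {
    writeLines("single-organism run: pan-genome comparison skipped",
               file.path(d2, "SKIPPED"))
    return(file.path(d2, "SKIPPED"))
  }
  genomes <- lapply(orgs, function(g) {
    pep <- read_pep(file.path(.org_dir(config, g), paste0(g, ".pep")))
    data.frame(feature_id = pep$id, protein = pep$seq,
               stringsAsFactors = FALSE)
  })
  names(genomes) <- orgs
  cl <- cluster_gene_families(genomes, thresholds = config$thresholds)
  utils::write.table(cl$clusters, file.path(d2, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mat <- pan_matrix(cl)
  utils::write.table(data.frame(cluster_id = rownames(mat), mat,
                                check.names = FALSE),
                     file.path(d2, "pan_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  file.path(d2, c("clusters.tsv", "pan_matrix.tsv"))
}

.read_pan_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  storage.mode(mat) <- "integer"
  mat
}

.step_curves <- function(config) {
  d2 <- .stage2_dir(config)
  if (nrow(config$organisms) < 2L) return(character())
  mat <- .read_pan_matrix(file.path(d2, "pan_matrix.tsv"))
  curves <- sample_curves(mat, config$n_perms,
                          seed = derive_seed(config$seed, "curves"))
  utils::write.table(curves, file.path(d2, "curves.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  file.path(d2, "curves.tsv")
}

.step_fit <- function(config) {
  d2 <- .stage2_dir(config)
  if (nrow(config$organisms) < 3L) return(character())
  curves <- utils::read.delim(file.path(d2, "curves.tsv"),
                              stringsAsFactors = FALSE)
  fits <- list(median = fit_heaps_law(curves, "median"),
               mean = fit_heaps_law(curves, "mean"))
  jsonlite::write_json(
    lapply(fits, function(f) f[c("kappa", "alpha", "statistic", "rss",
                                 "verdict")]),
    file.path(d2, "heapfit.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  file.path(d2, "heapfit.json")
}

.step_reports <- function(config) {
  d2 <- .stage2_dir(config)
  if (nrow(config$organisms) < 3L) return(character())
  results <- list(
    curves = utils::read.delim(file.path(d2, "curves.tsv"),
                               stringsAsFactors = FALSE),
    pan_matrix = .read_pan_matrix(file.path(d2, "pan_matrix.tsv")),
    heapfit = jsonlite::fromJSON(file.path(d2, "heapfit.json")),
    reports = do.call(rbind, lapply(config$organisms$genome_id, function(g) {
      utils::read.delim(file.path(.org_dir(config, g), "report.tsv"),
                        stringsAsFactors = FALSE)
    })))
  render_reports(results, d2)
}

#' Run the pipeline
#'
#' Executes the fixed step order. With `resume = TRUE`, a step is skipped
#' when it is recorded `done` with a matching parameter hash, all its
#' outputs exist, and no earlier step was re-executed; any change upstream
#' re-runs all downstream steps. Progress is logged one line per step.
#'
#' @param config a [run_config()].
#' @param resume reuse recorded step results when valid.
#' @param quiet suppress per-step logging.
#' @return the final state list, invisibly.
#' @export
run_pipeline <- function(config, resume = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  state_path <- file.path(config$outdir, "state.json")
  state <- if (resume) load_state(state_path) else fresh_state()
  log <- function(...) if (!quiet) message(sprintf(...))
  fail_before <- getOption("pancraft.fail_before", NULL)
  chain_ok <- TRUE
  for (step in .pipeline_steps) {
    h <- .step_hash(step, config)
    rec <- state$steps[[step]]
    if (resume && chain_ok && identical(rec$status, "done") &&
        identical(rec$params_hash, h) &&
        (length(rec$outputs) == 0L || all(file.exists(rec$outputs)))) {
      log("[%s] skipped (up to date)", step)
      next
    }
    chain_ok <- FALSE
    if (!is.null(fail_before) && identical(step, fail_before)) {
      stop("injected failure before step ", step)
    }
    rec$status <- "running"
    rec$started_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    state$steps[[step]] <- rec
    save_state(state, state_path)
    t0 <- proc.time()[["elapsed"]]
    outputs <- tryCatch(
      switch(step,
             partition = .step_partition(config),
             repair = .step_repair(config),
             assemble = .step_assemble(config),
             annotate_ref = .step_annotate_ref(config),
             annotate_asm = .step_annotate_asm(config),
             identify = .step_identify(config),
             update = .step_update(config),
             reannotate = .step_reannotate(config),
             genfiles = .step_genfiles(config),
             cluster = .step_cluster(config),
             curves = .step_curves(config),
             fit = .step_fit(config),
             reports = .step_reports(config)),
      error = function(e) {
        rec$status <- "failed"
        rec$ended_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
        state$steps[[step]] <- rec
        save_state(state, state_path)
        stop("step '", step, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
    rec$status <- "done"
    rec$params_hash <- h
    rec$outputs <- as.character(outputs)
    rec$ended_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    state$steps[[step]] <- rec
    save_state(state, state_path)
    log("[%s] done in %.1fs", step, proc.time()[["elapsed"]] - t0)
  }
  invisible(state)
}
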