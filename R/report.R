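# Rendering of stage-2 result figures and their machine-readable sibling
# tables. Plots are presentation only; every number shown is also written
# as TSV/JSON, and tests assert on the tables, never the images.

#' Render pan-genome report figures and tables
#'
#' Writes `boxplot.png` (pan and core size per N, with both fitted alpha
#' values annotated), `barplot_uniques.png`, `barplot.png` (ortholog
#' sharing), `pie_shared.png`, the pan-based NJ and UPGMA trees as `.nwk`
#' and `.png`, and sibling TSV tables (`unique_genes.tsv`,
#' `shared_distribution.tsv`, `distances.tsv`). Tables are written
#' deterministically.
#'
#' @param results list with `curves` (a [sample_curves()] frame),
#'   `pan_matrix`, `heapfit` (list with `median`/`mean` entries), and
#'   optionally `reports` (per-organism stage-1 reports).
#' @param outdir output directory.
#' @return character vector of written paths.
#' @export
render_reports <- function(results, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- character()
  emit <- function(p) { out <<- c(out, p); p }
  curves <- results$curves
  mat <- results$pan_matrix
  hf <- results$heapfit

  uniq <- unique_genes(mat)
  utils::write.table(data.frame(genome_id = names(uniq),
                                unique_genes = as.integer(uniq)),
                     emit(file.path(outdir, "unique_genes.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  shared <- shared_distribution(mat)
  utils::write.table(data.frame(n_genomes = as.integer(names(shared)),
                                clusters = as.integer(shared)),
                     emit(file.path(outdir, "shared_distribution.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  d <- pan_distance_matrix(mat)
  utils::write.table(data.frame(genome_id = rownames(d), d,
                                check.names = FALSE),
                     emit(file.path(outdir, "distances.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(build_tree(d, "nj"),
             emit(file.path(outdir, "PanBased.Neighbor-joining.nwk")))
  writeLines(build_tree(d, "upgma"),
             emit(file.path(outdir, "PanBased.UPGMA.nwk")))

  long <- rbind(data.frame(N = curves$N, size = curves$pan, what = "pangenome"),
                data.frame(N = curves$N, size = curves$core, what = "core genome"))
  ann_txt <- sprintf("alpha (median) = %.4f\nalpha (mean) = %.4f",
                     as.numeric(hf$median$alpha), as.numeric(hf$mean$alpha))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$N), y = .data$size,
                                          fill = .data$what)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::annotate("text", x = Inf, y = Inf, hjust = 1.05, vjust = 1.3,
                      label = ann_txt, size = 3) +
    ggplot2::labs(x = "genomes considered (N)", y = "gene families",
                  fill = NULL, title = "Pan and core genome accumulation")
  suppressMessages(ggplot2::ggsave(emit(file.path(outdir, "boxplot.png")), p,
                                   width = 7, height = 5, dpi = 120))

  ud <- data.frame(genome_id = names(uniq), n = as.integer(uniq))
  p2 <- ggplot2::ggplot(ud, ggplot2::aes(x = .data$genome_id, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "unique genes", title = "Unique genes per genome") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  suppressMessages(ggplot2::ggsave(emit(file.path(outdir, "barplot_uniques.png")),
                                   p2, width = 7, height = 5, dpi = 120))

  sd_df <- data.frame(n_genomes = factor(as.integer(names(shared))),
                      clusters = as.integer(shared))
  p3 <- ggplot2::ggplot(sd_df, ggplot2::aes(x = .data$n_genomes,
                                            y = .data$clusters)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "genomes sharing the family", y = "gene families",
                  title = "Ortholog sharing")
  suppressMessages(ggplot2::ggsave(emit(file.path(outdir, "barplot.png")), p3,
                                   width = 7, height = 5, dpi = 120))

  p4 <- ggplot2::ggplot(sd_df[sd_df$clusters > 0, ],
                        ggplot2::aes(x = "", y = .data$clusters,
                                     fill = .data$n_genomes)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "genomes",
                  title = "Gene families shared between strains") +
    ggplot2::theme_void()
  suppressMessages(ggplot2::ggsave(emit(file.path(outdir, "pie_shared.png")),
                                   p4, width = 6, height = 5, dpi = 120))

  for (m in c("Neighbor-joining", "UPGMA")) {
    tr <- ape::read.tree(file.path(outdir, sprintf("PanBased.%s.nwk", m)))
    grDevices::png(emit(file.path(outdir, sprintf("PanBased.%s.png", m))),
                   width = 700, height = 500)
    ape::plot.phylo(tr, main = sprintf("Pan-based %s tree", m))
    grDevices::dev.off()
  }
  out
}
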