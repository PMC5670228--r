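#' Run the full reactivation analysis on an input bundle
#'
#' Chains every stage of the pipeline on an in-memory bundle (the list
#' produced by [simulate_bundle()] or assembled from the file readers):
#' cross orientation, SNP-to-gene allelic aggregation, RPRT expression,
#' normalisation, lineage assignment, the gene-by-group ratio matrix,
#' timing classification, per-cell reactivation percentages, the
#' correlation screen and the Xist anti-correlation test, plus — when
#' ChIP windows / TF scores are present — allele-resolved TSS enrichment
#' with Wilcoxon class comparisons and the Myc-score Kruskal-Wallis /
#' Dunn analysis. The pipeline itself draws no random numbers, so
#' identical inputs give identical outputs.
#'
#' @param bundle Named list with `cells`, `annotation`, `snps`,
#'   `expr_counts`, `allele_counts` and optionally `chip_windows`,
#'   `tf_scores`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every result table is
#'   written there as TSV together with the config and a small run log
#'   (config checksum, seed, row counts).
#' @return List of class `xreact_results`: `gene_allelic`, `expression`,
#'   `lineages`, `stage_ratios`, `timing`, `cell_react`, `screen`,
#'   `xist_cor`, and when available `chip_scores`, `chip_tests`,
#'   `tf_myc`, `tf_kw`, `tf_dunn`.
#' @export
run_pipeline <- function(bundle, config = pipeline_config(),
                         out_dir = NULL) {
  needed <- c("cells", "annotation", "snps", "expr_counts",
              "allele_counts")
  producer <- c(cells = "cell metadata (cells.tsv)",
                annotation = "gene annotation (annotation.tsv)",
                snps = "SNP table (snp_table.tsv)",
                expr_counts = "expression counts (expr_counts.tsv)",
                allele_counts = "allelic counts (allele_counts.tsv)")
  for (f in needed) {
    if (is.null(bundle[[f]])) {
      stop("missing upstream artifact `", f, "`: provide ",
           producer[[f]], " or regenerate the bundle", call. = FALSE)
    }
  }

  counts <- orient_cross(bundle$allele_counts, bundle$cells)
  gene_allelic <- aggregate_gene_counts(
    counts, bundle$snps, blacklist = snp_blacklist(),
    snp_min_reads = config$snp_min_reads,
    gene_min_reads = config$gene_min_reads)
  expression <- rprt_table(
    bundle$expr_counts, bundle$annotation, bundle$cells,
    cap = config$rt_cap, expressed_min = config$rprt_expressed,
    well_min = config$rprt_well)
  norm <- normalize_for_clustering(bundle$expr_counts)
  lineages <- assign_lineages(bundle$cells, norm)

  x_ids <- bundle$annotation$gene_id[bundle$annotation$is_x_linked]
  stage_ratios <- stage_ratio_matrix(
    gene_allelic, expression, lineages, genes = x_ids,
    min_frac = config$group_min_frac,
    min_cells = config$group_min_cells)
  timing <- classify_timing(
    stage_ratios, bundle$annotation, mono = config$ratio_mono,
    react = config$reactivated, escapee_min = config$escapee_min)

  cell_react <- percent_reactivated(
    gene_allelic, bundle$annotation, expression,
    threshold = config$reactivated)
  screen <- correlation_screen(expression, cell_react)
  icm_cells <- lineages$cell_id[!is.na(lineages$lineage_group) &
                                  lineages$lineage_group != "E3.5_TE"]
  xist_cor <- xist_anticorrelation(
    dplyr::filter(cell_react, .data$cell_id %in% icm_cells))

  res <- list(gene_allelic = gene_allelic, expression = expression,
              lineages = lineages, stage_ratios = stage_ratios,
              timing = timing, cell_react = cell_react,
              screen = screen, xist_cor = xist_cor, config = config)

  if (!is.null(bundle$chip_windows)) {
    ann_x <- dplyr::filter(bundle$annotation, .data$is_x_linked)
    chip_scores <- purrr::map_dfr(
      c("H3K27me3", "H3K4me3"), function(mk) {
        purrr::map_dfr(c("paternal", "maternal"), function(al) {
          tss_window_score(ann_x, bundle$chip_windows, mark = mk,
                           allele = al, extent = config$chip_extent)
        })
      }) |>
      dplyr::inner_join(dplyr::select(timing, "gene_id", "timing"),
                        by = "gene_id")
    res$chip_scores <- chip_scores
    pairs <- list(c("early", "late"), c("early", "very_late"),
                  c("escapee", "late"), c("escapee", "very_late"))
    res$chip_tests <- purrr::map_dfr(
      c("H3K27me3", "H3K4me3"), function(mk) {
        sub <- dplyr::filter(chip_scores, .data$mark == mk,
                             .data$allele == "paternal")
        purrr::map_dfr(pairs, function(pr) {
          if (!all(pr %in% sub$timing)) return(NULL)
          dplyr::mutate(
            compare_groups_wilcoxon(sub, pr[1], pr[2]),
            mark = mk, .before = 1)
        })
      })
  }
  if (!is.null(bundle$tf_scores)) {
    tf_myc <- sum_tf_scores(bundle$tf_scores, "myc2") |>
      dplyr::inner_join(dplyr::select(timing, "gene_id", "timing"),
                        by = "gene_id")
    res$tf_myc <- tf_myc
    if (length(unique(tf_myc$timing)) >= 2) {
      res$tf_kw <- compare_groups_kw(tf_myc)
      res$tf_dunn <- dunn_posthoc(tf_myc)
    }
  }

  if (!is.null(out_dir)) write_results(res, out_dir)
  structure(res, class = "xreact_results")
}

#' @export
print.xreact_results <- function(x, ...) {
  cat("xreact pipeline results\n")
  cat("  cells:", nrow(x$lineages), "|", "genes classified:",
      nrow(x$timing), "\n")
  cat("  timing classes:\n")
  print(table(x$timing$timing))
  cat("  Xist anti-correlation: ")
  print(x$xist_cor)
  invisible(x)
}

write_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_table(res$gene_allelic, p("gene_allelic.tsv"))
  write_table(res$expression, p("expression_rprt.tsv"))
  write_table(res$lineages, p("lineage.tsv"))
  write_table(res$stage_ratios, p("stage_ratios.tsv"))
  write_table(res$timing, p("timing.tsv"))
  write_table(res$cell_react, p("cell_reactivation.tsv"))
  write_table(res$screen, p("correlation_screen.tsv"))
  if (!is.null(res$chip_tests)) {
    write_table(res$chip_tests, p("chip_tests.tsv"))
  }
  if (!is.null(res$tf_dunn)) write_table(res$tf_dunn, p("tf_dunn.tsv"))
  write_config(res$config, p("config.yaml"))
  log <- list(
    seed = res$config$seed,
    config_md5 = unname(tools::md5sum(p("config.yaml"))),
    r_version = as.character(getRversion()),
    rows = list(gene_allelic = nrow(res$gene_allelic),
                expression = nrow(res$expression),
                cells = nrow(res$lineages),
                genes_classified = nrow(res$timing)),
    xist = list(rho = res$xist_cor$estimate, p = res$xist_cor$p.value)
  )
  yaml::write_yaml(log, p("run_log.yaml"))
  invisible(out_dir)
}
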