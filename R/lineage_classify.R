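#' Default lineage marker panel
#'
#' Named lineage-specific factors used to separate epiblast (Epi),
#' primitive endoderm (PrE) and trophectoderm (TE) cells: pluripotency /
#' Epi markers (Nanog, Prdm14, Esrrb, Sox2, Pou5f1, Klf4, Tcfcp2l1), PrE
#' markers (Gata4, Gata6, Sox17, Pdgfra) and TE markers (Cdx2, Eomes,
#' Krt8). Extend by row-binding further `gene_id, role` pairs; every
#' marker must carry exactly one role.
#'
#' @return Tibble with columns `gene_id` and `role`
#'   (`"Epi"`, `"PrE"`, `"TE"`).
#' @export
marker_panel <- function() {
  tibble::tibble(
    gene_id = c("Nanog", "Prdm14", "Esrrb", "Sox2", "Pou5f1", "Klf4",
                "Tcfcp2l1", "Gata4", "Gata6", "Sox17", "Pdgfra",
                "Cdx2", "Eomes", "Krt8"),
    role = c(rep("Epi", 7), rep("PrE", 4), rep("TE", 3))
  )
}

check_panel <- function(panel) {
  require_columns(panel, c("gene_id", "role"), "panel")
  if (anyDuplicated(panel$gene_id) > 0L) {
    stop("marker panel assigns more than one role to a gene",
         call. = FALSE)
  }
  stopifnot(all(panel$role %in% c("Epi", "PrE", "TE")))
  panel
}

#' Normalise counts for clustering
#'
#' Median-of-ratios size factors (the reference for each gene is its
#' geometric mean across cells, computed over genes detected in every
#' cell; each cell's factor is the median ratio to that reference)
#' followed by a `log2(count / size_factor + 1)` variance-stabilising
#' transform. Doubling a cell's library exactly doubles its size factor,
#' leaving the normalised values unchanged.
#'
#' @param expr_counts Tibble `gene_id, cell_id, read_count` with
#'   non-negative counts.
#' @return Tibble `gene_id, cell_id, norm_expr`, all values finite.
#' @export
normalize_for_clustering <- function(expr_counts) {
  require_columns(expr_counts, c("gene_id", "cell_id", "read_count"),
                  "expr_counts")
  stopifnot(all(expr_counts$read_count >= 0))
  mat <- counts_matrix(expr_counts)
  zero_cells <- colnames(mat)[colSums(mat) == 0]
  if (length(zero_cells) > 0L) {
    stop("cell(s) with all-zero counts: ",
         paste(zero_cells, collapse = ", "), call. = FALSE)
  }
  all_pos <- rowSums(mat == 0) == 0L
  if (any(all_pos)) {
    ref_rows <- which(all_pos)
  } else {
    # dropout leaves no all-positive gene: fall back to genes detected in
    # at least half the cells, with the geometric mean and the per-cell
    # median taken over positive counts only (positive-counts estimator)
    ref_rows <- which(rowMeans(mat > 0) >= 0.5)
    if (length(ref_rows) == 0L) {
      stop("too few detected genes to form the median-of-ratios ",
           "reference", call. = FALSE)
    }
  }
  sub <- mat[ref_rows, , drop = FALSE]
  logsub <- log(sub)
  logsub[sub == 0] <- NA
  log_ref <- rowMeans(logsub, na.rm = TRUE)
  sf <- apply(logsub, 2, function(col) {
    exp(stats::median(col - log_ref, na.rm = TRUE))
  })
  if (any(!is.finite(sf))) {
    stop("cell(s) with no detected reference gene: ",
         paste(colnames(mat)[!is.finite(sf)], collapse = ", "),
         call. = FALSE)
  }
  norm <- log2(sweep(mat, 2, sf, "/") + 1)
  tidyr::pivot_longer(
    tibble::as_tibble(norm, rownames = "gene_id"),
    -"gene_id", names_to = "cell_id", values_to = "norm_expr"
  )
}

counts_matrix <- function(long, value = "read_count") {
  wide <- tidyr::pivot_wider(
    dplyr::select(long, "gene_id", "cell_id",
                  dplyr::all_of(value)),
    names_from = "cell_id", values_from = dplyr::all_of(value),
    values_fill = 0
  )
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$gene_id
  mat[, order(colnames(mat)), drop = FALSE]
}

#' Principal component analysis of cells
#'
#' Centered PCA of cells on either the most variable genes or a marker
#' panel. Components are ordered by decreasing variance and each
#' component's sign is fixed by making its largest-magnitude gene loading
#' positive, so results are deterministic.
#'
#' @param norm_expr Output of [normalize_for_clustering()].
#' @param genes `"top_variable"` (default) or `"panel"`.
#' @param n_top Number of most-variable genes when `genes =
#'   "top_variable"`; clamped (with a warning) to the genes available.
#' @param panel Marker panel tibble when `genes = "panel"`.
#' @return Object of class `xreact_pca`: list with `scores` (tibble
#'   `cell_id, PC1, ...`), `sdev`, `var_explained` and `genes_used`.
#' @export
pca_cells <- function(norm_expr, genes = c("top_variable", "panel"),
                      n_top = 1000, panel = marker_panel()) {
  genes <- match.arg(genes)
  mat <- counts_matrix(norm_expr, "norm_expr")
  if (ncol(mat) < 2L) stop("PCA needs at least 2 cells", call. = FALSE)
  if (genes == "panel") {
    keep <- rownames(mat) %in% check_panel(panel)$gene_id
    if (!any(keep)) stop("no panel gene found in the matrix", call. = FALSE)
    mat <- mat[keep, , drop = FALSE]
  } else {
    if (n_top > nrow(mat)) {
      warning("n_top exceeds the number of genes; using all ",
              nrow(mat), call. = FALSE)
      n_top <- nrow(mat)
    }
    vars <- apply(mat, 1, stats::var)
    mat <- mat[order(-vars)[seq_len(n_top)], , drop = FALSE]
  }
  fit <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  # deterministic sign: largest-magnitude loading positive per component
  for (j in seq_len(ncol(fit$rotation))) {
    i <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[i, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  scores <- tibble::as_tibble(fit$x, rownames = "cell_id")
  structure(
    list(scores = scores, sdev = fit$sdev,
         var_explained = fit$sdev^2 / sum(fit$sdev^2),
         genes_used = rownames(mat)),
    class = "xreact_pca"
  )
}

#' @export
print.xreact_pca <- function(x, ...) {
  cat("PCA of", nrow(x$scores), "cells on", length(x$genes_used),
      "genes\n")
  cat("variance explained (PC1..PC3):",
      paste0(round(100 * utils::head(x$var_explained, 3), 1), "%",
             collapse = ", "), "\n")
  invisible(x)
}

#' Hierarchical clustering of cells (Pearson correlation, Ward linkage)
#'
#' Cells are clustered on the distance `1 - r` where `r` is the Pearson
#' correlation between their normalised expression profiles, with Ward
#' linkage (`hclust` method `"ward.D2"`). Cells are ordered
#' lexicographically by id before clustering, so the partition does not
#' depend on input order.
#'
#' @param norm_expr Output of [normalize_for_clustering()] (optionally
#'   pre-filtered to a gene subset).
#' @param n_clusters Number of clusters to cut the tree into.
#' @return Object of class `xreact_clust`: list with `labels` (tibble
#'   `cell_id, cluster_id`) and the `hclust` tree.
#' @export
hier_cluster <- function(norm_expr, n_clusters = 2) {
  mat <- counts_matrix(norm_expr, "norm_expr")
  if (ncol(mat) < n_clusters) {
    stop("fewer cells than requested clusters", call. = FALSE)
  }
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant-expression cell(s) (undefined correlation): ",
         paste(colnames(mat)[sds == 0], collapse = ", "), call. = FALSE)
  }
  d <- stats::as.dist(1 - stats::cor(mat))
  tree <- stats::hclust(d, method = "ward.D2")
  labels <- stats::cutree(tree, k = n_clusters)
  structure(
    list(labels = tibble::tibble(cell_id = names(labels),
                                 cluster_id = unname(labels)),
         tree = tree),
    class = "xreact_clust"
  )
}

#' @export
print.xreact_clust <- function(x, ...) {
  cat("hierarchical clustering of", nrow(x$labels), "cells into",
      length(unique(x$labels$cluster_id)), "clusters\n")
  invisible(x)
}

#' Assign cells to lineage groups
#'
#' Trophectoderm cells (by `tissue_hint`) form `E3.5_TE`. ICM cells at
#' E3.5 are kept as one pre-lineage group, `E3.5_ICM` — lineages are not
#' yet transcriptionally established at that stage, so only the soft
#' `epi_score` / `pre_score` are reported for them. ICM cells at E4.0 are
#' split into two clusters on the marker panel (Pearson-Ward); the
#' cluster with the higher mean `epi_score` becomes `E4.0_Epi`
#' (pluripotency markers such as Nanog, Prdm14), the other `E4.0_PrE`
#' (Gata4/Gata6-class markers). A tie in mean scores is an error, never a
#' silent coin flip.
#'
#' @param cells Cell metadata (`cell_id, stage, tissue_hint`).
#' @param norm_expr Output of [normalize_for_clustering()].
#' @param panel Marker panel; see [marker_panel()].
#' @return Tibble `cell_id, cluster_id, lineage_group, epi_score,
#'   pre_score`.
#' @export
assign_lineages <- function(cells, norm_expr, panel = marker_panel()) {
  require_columns(cells, c("cell_id", "stage", "tissue_hint"), "cells")
  panel <- check_panel(panel)
  stopifnot(all(cells$stage %in% c("E3.5", "E4.0")))

  scores <- norm_expr |>
    dplyr::inner_join(panel, by = "gene_id") |>
    dplyr::filter(.data$role %in% c("Epi", "PrE")) |>
    dplyr::group_by(.data$cell_id, .data$role) |>
    dplyr::summarise(score = mean(.data$norm_expr), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "role", values_from = "score") |>
    dplyr::rename(epi_score = "Epi", pre_score = "PrE")

  out <- cells |>
    dplyr::select("cell_id", "stage", "tissue_hint") |>
    dplyr::left_join(scores, by = "cell_id") |>
    dplyr::mutate(cluster_id = NA_integer_,
                  lineage_group = NA_character_)
  if (any(!is.finite(out$epi_score)) || any(!is.finite(out$pre_score))) {
    stop("marker scores missing for some cells; check that panel genes ",
         "are present in the expression table", call. = FALSE)
  }

  te <- out$tissue_hint == "TE"
  if (any(te & out$stage != "E3.5")) {
    stop("TE cells outside stage E3.5 are not part of the four analysis ",
         "groups", call. = FALSE)
  }
  out$lineage_group[te] <- "E3.5_TE"
  out$lineage_group[!te & out$stage == "E3.5"] <- "E3.5_ICM"

  icm4 <- out$cell_id[!te & out$stage == "E4.0"]
  if (length(icm4) > 0L) {
    sub <- dplyr::filter(norm_expr, .data$cell_id %in% icm4,
                         .data$gene_id %in% panel$gene_id)
    cl <- hier_cluster(sub, n_clusters = 2)
    lab <- dplyr::left_join(cl$labels,
                            dplyr::select(out, "cell_id", "epi_score"),
                            by = "cell_id")
    means <- tapply(lab$epi_score, lab$cluster_id, mean)
    if (length(unique(means)) < 2L) {
      stop("E4.0 clusters have equal mean epiblast scores; lineage ",
           "assignment unresolved", call. = FALSE)
    }
    epi_cluster <- as.integer(names(which.max(means)))
    idx <- match(cl$labels$cell_id, out$cell_id)
    out$cluster_id[idx] <- cl$labels$cluster_id
    out$lineage_group[idx] <- ifelse(
      cl$labels$cluster_id == epi_cluster, "E4.0_Epi", "E4.0_PrE")
  }
  dplyr::select(out, "cell_id", "cluster_id", "lineage_group",
                "epi_score", "pre_score")
}

#' @describeIn pca_cells ggplot of cells on the first two components.
#' @param object,x An `xreact_pca` object.
#' @param colour_by Optional tibble `cell_id, group` used to colour cells.
#' @param ... Unused.
#' @export
autoplot.xreact_pca <- function(object, colour_by = NULL, ...) {
  df <- object$scores
  if (!is.null(colour_by)) {
    df <- dplyr::left_join(df, colour_by, by = "cell_id")
    p <- ggplot2::ggplot(df, ggplot2::aes(
      .data$PC1, .data$PC2, colour = .data$group))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])
    ) +
    ggplot2::theme_minimal()
}
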