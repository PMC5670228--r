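#' Per-cell percentage of reactivated X-linked genes
#'
#' For each cell, counts the informative X-linked genes whose allelic
#' ratio strictly exceeds `threshold` (paternal-X reactivation) and
#' reports the percentage among all informative X-linked genes.
#' Imprinted-flagged genes (Xist, Xlr3a) are excluded from the count —
#' their paternal expression is not reactivation. When an expression
#' table is supplied, the gene set is further restricted to
#' well-expressed genes, matching the allele-specific analysis filter;
#' Xist's RPRT is attached as `xist_rprt` for the anti-correlation test.
#' Male cells can be included as controls: their X profiles pass through
#' the same counting.
#'
#' @param gene_allelic Output of [aggregate_gene_counts()].
#' @param annotation Annotation with `gene_id`, `is_x_linked`,
#'   `is_imprinted_flagged`.
#' @param expression Optional [rprt_table()] output.
#' @param threshold Strict reactivation threshold on the allelic ratio.
#' @param xist_gene Gene id of Xist in the annotation.
#' @return Tibble `cell_id, n_informative_x, n_reactivated_x,
#'   pct_reactivated, xist_rprt`. Cells with zero informative X-linked
#'   genes get `NA` with a warning.
#' @export
percent_reactivated <- function(gene_allelic, annotation,
                                expression = NULL, threshold = 0.20,
                                xist_gene = "Xist") {
  require_columns(annotation, c("gene_id", "is_x_linked",
                                "is_imprinted_flagged"), "annotation")
  x_genes <- annotation$gene_id[annotation$is_x_linked &
                                  !annotation$is_imprinted_flagged]
  df <- dplyr::filter(gene_allelic, .data$gene_id %in% x_genes,
                      .data$informative)
  if (!is.null(expression)) {
    df <- dplyr::semi_join(
      df, dplyr::filter(expression, .data$well_expressed),
      by = c("gene_id", "cell_id"))
  }
  out <- df |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      n_informative_x = dplyr::n(),
      n_reactivated_x = sum(.data$allelic_ratio > threshold),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct_reactivated =
                    100 * .data$n_reactivated_x / .data$n_informative_x)

  all_cells <- unique(gene_allelic$cell_id)
  missing <- setdiff(all_cells, out$cell_id)
  if (length(missing) > 0L) {
    warning(length(missing),
            " cell(s) had no informative X-linked gene; reported as NA",
            call. = FALSE)
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(cell_id = missing, n_informative_x = 0L,
                     n_reactivated_x = NA_integer_,
                     pct_reactivated = NA_real_))
  }
  if (!is.null(expression)) {
    xist <- expression |>
      dplyr::filter(.data$gene_id == xist_gene) |>
      dplyr::select("cell_id", xist_rprt = "rprt")
    out <- dplyr::left_join(out, xist, by = "cell_id")
  }
  dplyr::arrange(out, .data$cell_id)
}

#' Genome-wide expression / reactivation correlation screen
#'
#' Pearson correlation, per gene, between its expression (RPRT) across
#' cells and the per-cell percentage of reactivated X-linked genes, with
#' two-sided t-distribution p-values and Benjamini-Hochberg adjustment
#' across all tested genes. Genes must be expressed in at least
#' `min_cells` cells; zero-variance genes are reported with `NA` and
#' excluded from the BH family.
#'
#' @param expression [rprt_table()] output.
#' @param cell_react [percent_reactivated()] output.
#' @param min_cells Minimum cells with both values (>= 3).
#' @return Tibble `gene_id, n, r, p, q`, sorted by `q` (NAs last).
#' @export
correlation_screen <- function(expression, cell_react, min_cells = 3) {
  stopifnot(min_cells >= 3)
  df <- expression |>
    dplyr::inner_join(
      dplyr::select(cell_react, "cell_id", "pct_reactivated"),
      by = "cell_id") |>
    dplyr::filter(!is.na(.data$pct_reactivated))

  per_gene <- df |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_expressed = sum(.data$expressed),
      r = if (dplyr::n() >= min_cells &&
              stats::sd(.data$rprt) > 0 &&
              stats::sd(.data$pct_reactivated) > 0) {
        stats::cor(.data$rprt, .data$pct_reactivated)
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_expressed >= min_cells)

  # two-sided p from the t distribution with n - 2 df
  tstat <- per_gene$r * sqrt((per_gene$n - 2) / pmax(1 - per_gene$r^2,
                                                     .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = per_gene$n - 2)
  q <- rep(NA_real_, length(p))
  tested <- !is.na(p)
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  out <- dplyr::mutate(
    dplyr::select(per_gene, "gene_id", "n", "r"),
    p = p, q = q)
  dplyr::arrange(out, is.na(.data$q), .data$q)
}

#' Spearman correlation with a permutation p-value
#'
#' Spearman's rho with average ranks for ties. For `n <= exact_n` the
#' two-sided p-value is exact: every permutation of one variable is
#' enumerated and the fraction with `|rho|` at least the observed value
#' is returned. Above that, the usual t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` is used.
#'
#' @param x,y Numeric vectors of equal length (n >= 4), neither constant.
#' @param exact_n Largest n for which the permutation null is enumerated.
#' @return List `estimate` (rho), `p.value`, `method`, `n`.
#' @export
spearman_perm <- function(x, y, exact_n = 9) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: Spearman correlation undefined", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_n) {
    perms <- all_permutations(n)
    rxs <- as.vector(scale(rx))
    rys <- as.vector(scale(ry))
    rho_all <- as.vector(matrix(rys[perms], nrow(perms)) %*% rxs) / (n - 1)
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "spearman_exact_permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- min(p, 1)
    method <- "spearman_t_approximation"
  }
  list(estimate = rho, p.value = p, method = method, n = n)
}

# all permutations of 1..n as an (n!) x n matrix
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    rest <- setdiff(seq_len(n), i)
    out[rows, 1L] <- i
    out[rows, -1L] <- matrix(rest[sub], nrow(sub))
  }
  out
}

#' Xist / reactivation anti-correlation test
#'
#' Tests whether cells expressing more Xist reactivate fewer X-linked
#' genes: Spearman correlation between per-cell Xist RPRT and the
#' percentage of reactivated X-linked genes ([spearman_perm()], exact
#' permutation p at small n). A negative rho supports Xist-dependent
#' maintenance of paternal-X silencing.
#'
#' @param cell_react [percent_reactivated()] output with `xist_rprt`.
#' @param exact_n Passed to [spearman_perm()].
#' @return Object of class `xreact_cor` with `estimate`, `p.value`,
#'   `method`, `n`; supports `tidy()` and `glance()`.
#' @export
xist_anticorrelation <- function(cell_react, exact_n = 9) {
  require_columns(cell_react, c("pct_reactivated", "xist_rprt"),
                  "cell_react")
  ok <- !is.na(cell_react$pct_reactivated) &
    !is.na(cell_react$xist_rprt)
  res <- spearman_perm(cell_react$xist_rprt[ok],
                       cell_react$pct_reactivated[ok],
                       exact_n = exact_n)
  structure(res, class = "xreact_cor")
}

#' @export
print.xreact_cor <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, p = %.4g (%s, n = %d)\n",
              x$estimate, x$p.value, x$method, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy methods for correlation results
#'
#' @param x An `xreact_cor` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.xreact_cor <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, p.value = x$p.value,
                 method = x$method)
}

#' @rdname tidy.xreact_cor
#' @export
glance.xreact_cor <- function(x, ...) {
  tibble::tibble(n = x$n, method = x$method)
}

#' Scatter plot of Xist expression versus reactivation percentage
#'
#' @param cell_react [percent_reactivated()] output with `xist_rprt`.
#' @return A ggplot.
#' @export
plot_xist_reactivation <- function(cell_react) {
  require_columns(cell_react, c("pct_reactivated", "xist_rprt"),
                  "cell_react")
  ggplot2::ggplot(cell_react, ggplot2::aes(
    .data$xist_rprt, .data$pct_reactivated)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = "Xist expression (RPRT)",
                  y = "% reactivated X-linked genes") +
    ggplot2::theme_minimal()
}
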