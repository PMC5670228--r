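#' Allele-resolved histone-mark score around a TSS
#'
#' Sums the scores of all 100-bp ChIP windows overlapping a scoring
#' interval anchored at each gene's TSS. The default (`mode =
#' "downstream"`) runs from the TSS into the gene body, strand-aware:
#' `[TSS, TSS + extent)` on the plus strand, `(TSS - extent, TSS]` on
#' the minus strand, where `extent` is capped at the gene length (short
#' genes are scored over their full length only). `mode = "symmetric"`
#' instead centres the same total extent on the TSS. Any intersection
#' counts the whole window's score; no pro-rating.
#'
#' @param annotation Gene annotation (`gene_id, chrom, strand, tss,
#'   gene_length`; `tss` 1-based).
#' @param windows ChIP windows from [read_bed_windows()] (0-based
#'   half-open, `score`, optional `allele`/`mark`).
#' @param mark,allele Optional filters applied to `windows` first.
#' @param extent Maximum scoring extent, bp.
#' @param mode `"downstream"` (default) or `"symmetric"`.
#' @return Tibble `gene_id, mark, allele, summed_score, window_used_bp`.
#'   Genes on chromosomes absent from `windows` get `NA` with one
#'   warning.
#' @export
tss_window_score <- function(annotation, windows, mark = NULL,
                             allele = NULL, extent = 5000,
                             mode = c("downstream", "symmetric")) {
  mode <- match.arg(mode)
  require_columns(annotation, c("gene_id", "chrom", "strand", "tss",
                                "gene_length"), "annotation")
  require_columns(windows, c("chrom", "start", "end", "score"),
                  "windows")
  if (!is.null(mark)) {
    windows <- dplyr::filter(windows, .data$mark == !!mark)
  }
  if (!is.null(allele)) {
    windows <- dplyr::filter(windows, .data$allele == !!allele)
  }

  ext <- pmin(extent, annotation$gene_length)
  tss0 <- annotation$tss - 1L # 0-based TSS
  iv_start <- ifelse(annotation$strand == "+", tss0, tss0 + 1L - ext)
  iv_end <- ifelse(annotation$strand == "+", tss0 + ext, tss0 + 1L)
  if (mode == "symmetric") {
    mid <- tss0
    iv_start <- mid - floor(ext / 2)
    iv_end <- mid + ceiling(ext / 2)
  }

  by_chrom <- split(windows, windows$chrom)
  known <- annotation$chrom %in% names(by_chrom)
  if (any(!known)) {
    warning(sum(!known), " gene(s) on chromosome(s) absent from the ",
            "window set; scored as NA", call. = FALSE)
  }
  score <- purrr::map_dbl(seq_len(nrow(annotation)), function(i) {
    if (!known[i]) return(NA_real_)
    w <- by_chrom[[annotation$chrom[i]]]
    hit <- w$start < iv_end[i] & w$end > iv_start[i]
    sum(w$score[hit])
  })
  tibble::tibble(
    gene_id = annotation$gene_id,
    mark = if (is.null(mark)) NA_character_ else mark,
    allele = if (is.null(allele)) NA_character_ else allele,
    summed_score = score,
    window_used_bp = as.integer(ext)
  )
}

#' Two-group Wilcoxon rank-sum comparison of enrichment scores
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum test between two timing
#' classes. The exact null distribution is used when the smaller group
#' has at most `exact_max` observations and there are no ties; otherwise
#' the normal approximation with tie correction (no continuity
#' correction) is used.
#'
#' @param scores Tibble with a grouping column and a score column.
#' @param class_a,class_b The two class labels to compare.
#' @param class_col,score_col Column names (strings).
#' @param exact_max Largest min(n, m) for the exact distribution.
#' @return One-row tibble: `class_a, class_b, n_a, n_b, statistic, p,
#'   method`.
#' @export
compare_groups_wilcoxon <- function(scores, class_a, class_b,
                                    class_col = "timing",
                                    score_col = "summed_score",
                                    exact_max = 8) {
  require_columns(scores, c(class_col, score_col), "scores")
  x <- scores[[score_col]][scores[[class_col]] == class_a]
  y <- scores[[score_col]][scores[[class_col]] == class_b]
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) {
    stop("empty group in Wilcoxon comparison: ", class_a, " (n=",
         length(x), ") vs ", class_b, " (n=", length(y), ")",
         call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= exact_max && !ties
  fit <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = FALSE))
  tibble::tibble(
    class_a = class_a, class_b = class_b,
    n_a = length(x), n_b = length(y),
    statistic = unname(fit$statistic), p = fit$p.value,
    method = if (exact) "exact" else "normal_tie_corrected"
  )
}

#' Kruskal-Wallis test across timing classes
#'
#' @inheritParams compare_groups_wilcoxon
#' @return One-row tibble `statistic` (H, tie-corrected), `df`, `p`,
#'   `n_groups`.
#' @export
compare_groups_kw <- function(scores, class_col = "timing",
                              score_col = "summed_score") {
  require_columns(scores, c(class_col, score_col), "scores")
  scores <- scores[!is.na(scores[[score_col]]), ]
  groups <- split(scores[[score_col]], scores[[class_col]])
  if (length(groups) < 2L || any(lengths(groups) == 0L)) {
    stop("Kruskal-Wallis needs >= 2 non-empty groups", call. = FALSE)
  }
  fit <- stats::kruskal.test(scores[[score_col]],
                             factor(scores[[class_col]]))
  tibble::tibble(statistic = unname(fit$statistic),
                 df = unname(fit$parameter), p = fit$p.value,
                 n_groups = length(groups))
}

#' Dunn's post hoc test with Benjamini-Hochberg correction
#'
#' Pairwise two-sided Dunn z-tests on the pooled ranks after a
#' Kruskal-Wallis analysis, with the usual tie correction in the
#' variance and BH adjustment across all pairs:
#' `z = (Ri - Rj) / sqrt((N(N+1)/12 - T) (1/ni + 1/nj))` with
#' `T = sum(t^3 - t) / (12 (N - 1))` over tie groups.
#'
#' @inheritParams compare_groups_wilcoxon
#' @return Tibble with one row per class pair: `class_a, class_b, z, p,
#'   q`.
#' @export
dunn_posthoc <- function(scores, class_col = "timing",
                         score_col = "summed_score") {
  require_columns(scores, c(class_col, score_col), "scores")
  scores <- scores[!is.na(scores[[score_col]]), ]
  cls <- factor(scores[[class_col]])
  if (nlevels(cls) < 2L) stop("need >= 2 groups", call. = FALSE)
  val <- scores[[score_col]]
  n_total <- length(val)
  r <- rank(val)
  mean_r <- tapply(r, cls, mean)
  n_g <- tapply(r, cls, length)
  tie_tab <- table(val)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (n_total - 1))
  v0 <- n_total * (n_total + 1) / 12 - tie_corr

  pairs <- utils::combn(levels(cls), 2)
  z <- purrr::map_dbl(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    (mean_r[[a]] - mean_r[[b]]) /
      sqrt(v0 * (1 / n_g[[a]] + 1 / n_g[[b]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  tibble::tibble(
    class_a = pairs[1, ], class_b = pairs[2, ],
    z = z, p = p, q = stats::p.adjust(p, method = "BH")
  )
}

#' Canonical transcription-factor sets
#'
#' `pluripotency6`: Nanog, Oct4, Sox2, Klf4, Esrrb, Tcfcp2l1 —
#' pluripotency / epiblast factors. `myc2`: Myc and Mycn (Mycl
#' association scores were never measured and are not part of the set).
#'
#' @param name Set name.
#' @return Character vector of TF names.
#' @export
tf_set <- function(name = c("pluripotency6", "myc2")) {
  name <- match.arg(name)
  switch(name,
         pluripotency6 = c("Nanog", "Oct4", "Sox2", "Klf4", "Esrrb",
                           "Tcfcp2l1"),
         myc2 = c("Myc", "Mycn"))
}

#' Sum TF-gene association scores over a factor set
#'
#' Each TF-gene association score lies in \[0, 1\] (probability-like:
#' higher means the gene is more likely a direct target). Scores of the
#' requested TFs are summed per gene; a missing TF-gene pair contributes
#' 0, and genes absent from the table score 0 when listed in `genes`.
#'
#' @param tf_table Tibble `gene_id, tf, score` (scores in \[0, 1\]).
#' @param tfs A [tf_set()] name or a character vector of TF names; every
#'   requested TF must occur in the table, otherwise a configuration
#'   error is raised.
#' @param genes Optional gene universe to report (absent genes score 0);
#'   default: genes present in the table.
#' @return Tibble `gene_id, tf_set, summed_score`.
#' @export
sum_tf_scores <- function(tf_table, tfs = "pluripotency6",
                          genes = NULL) {
  require_columns(tf_table, c("gene_id", "tf", "score"), "tf_table")
  set_name <- if (length(tfs) == 1L &&
                  tfs %in% c("pluripotency6", "myc2")) tfs else "custom"
  if (set_name != "custom") tfs <- tf_set(tfs)
  unknown <- setdiff(tfs, unique(tf_table$tf))
  if (length(unknown) > 0L) {
    stop("unknown TF name(s) not present in the score table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(genes)) genes <- unique(tf_table$gene_id)
  sums <- tf_table |>
    dplyr::filter(.data$tf %in% tfs) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(summed_score = sum(.data$score), .groups = "drop")
  tibble::tibble(gene_id = genes, tf_set = set_name) |>
    dplyr::left_join(sums, by = "gene_id") |>
    dplyr::mutate(summed_score = dplyr::coalesce(.data$summed_score, 0))
}
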