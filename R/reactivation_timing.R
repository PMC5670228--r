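#' Group-level inclusion rule for a gene
#'
#' A gene enters group-level analysis when it is well expressed in at
#' least `min_frac` of the group's cells and in at least `min_cells`
#' cells; the absolute minimum is waived for trophectoderm, whose samples
#' are few.
#'
#' @param n_well Number of group cells in which the gene is well
#'   expressed (vectorised).
#' @param n_cells Group size.
#' @param is_te Whether the group is TE (waives `min_cells`).
#' @param min_frac,min_cells Rule thresholds.
#' @return Logical vector.
#' @export
#' @examples
#' group_inclusion(2, 10) # 20% < 25% -> FALSE
#' group_inclusion(1, 4, is_te = TRUE) # 25%, TE exempt -> TRUE
group_inclusion <- function(n_well, n_cells, is_te = FALSE,
                            min_frac = 0.25, min_cells = 2) {
  n_well / n_cells >= min_frac & (is_te | n_well >= min_cells)
}

#' Mean allelic ratio of usable cells
#'
#' Arithmetic mean over the cells where the gene is both informative and
#' well expressed; `NA` when no cell qualifies.
#'
#' @param ratios Per-cell allelic ratios of the usable cells.
#' @return Scalar mean or `NA`.
#' @export
mean_stage_ratio <- function(ratios) {
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) == 0L) return(NA_real_)
  mean(ratios)
}

#' Is a gene reactivated at a given mean ratio?
#'
#' Reactivation from the paternal X requires strictly more than
#' `threshold` (default 20%) of the gene's expression to come from the
#' paternal allele.
#'
#' @param mean_ratio Group mean allelic ratio (vectorised, NAs propagate).
#' @param threshold Strict lower bound.
#' @return Logical vector.
#' @export
is_reactivated <- function(mean_ratio, threshold = 0.20) {
  mean_ratio > threshold
}

#' Gene-by-group mean allelic-ratio matrix
#'
#' For every gene and lineage group, applies the inclusion rule
#' ([group_inclusion()]) and computes the mean allelic ratio over cells
#' in which the gene is informative and well expressed. Genes retained
#' for the reactivation heatmap must additionally be included in both
#' E4.0 lineages (PrE and Epi), where reactivation is read out; the
#' `keep` column records this.
#'
#' @param gene_allelic Output of [aggregate_gene_counts()].
#' @param expression Output of [rprt_table()] (for the well-expressed
#'   flag).
#' @param lineages Output of [assign_lineages()] (`cell_id,
#'   lineage_group`).
#' @param genes Optional vector restricting to a gene set (e.g. X-linked
#'   genes from the annotation).
#' @param min_frac,min_cells Inclusion thresholds.
#' @return Object of class `xreact_stage_ratios`: a tibble with one row
#'   per (gene, group): `gene_id, group, n_cells, n_well, included,
#'   n_cells_used, mean_ratio, keep`.
#' @export
stage_ratio_matrix <- function(gene_allelic, expression, lineages,
                               genes = NULL, min_frac = 0.25,
                               min_cells = 2) {
  require_columns(lineages, c("cell_id", "lineage_group"), "lineages")
  if (any(is.na(lineages$lineage_group))) {
    warning("cells without a lineage group are ignored", call. = FALSE)
    lineages <- dplyr::filter(lineages, !is.na(.data$lineage_group))
  }
  group_sizes <- dplyr::count(lineages, .data$lineage_group,
                              name = "n_cells")

  df <- expression |>
    dplyr::inner_join(
      dplyr::select(lineages, "cell_id", "lineage_group"),
      by = "cell_id") |>
    dplyr::left_join(
      dplyr::select(gene_allelic, "gene_id", "cell_id", "informative",
                    "allelic_ratio"),
      by = c("gene_id", "cell_id"))
  if (!is.null(genes)) df <- dplyr::filter(df, .data$gene_id %in% genes)

  out <- df |>
    dplyr::group_by(.data$gene_id, group = .data$lineage_group) |>
    dplyr::summarise(
      n_well = sum(.data$well_expressed),
      n_cells_used = sum(.data$well_expressed & !is.na(.data$informative) &
                           .data$informative),
      mean_ratio = mean_stage_ratio(
        .data$allelic_ratio[.data$well_expressed]),
      .groups = "drop"
    ) |>
    tidyr::complete(gene_id, group = lineage_groups(),
                    fill = list(n_well = 0L, n_cells_used = 0L,
                                mean_ratio = NA_real_)) |>
    dplyr::inner_join(group_sizes, by = c(group = "lineage_group")) |>
    dplyr::mutate(
      included = group_inclusion(.data$n_well, .data$n_cells,
                                 is_te = .data$group == "E3.5_TE",
                                 min_frac = min_frac,
                                 min_cells = min_cells),
      mean_ratio = dplyr::if_else(.data$included, .data$mean_ratio,
                                  NA_real_)
    )

  e4_ok <- out |>
    dplyr::filter(.data$group %in% c("E4.0_PrE", "E4.0_Epi")) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(keep = all(.data$included), .groups = "drop")
  out <- dplyr::left_join(out, e4_ok, by = "gene_id") |>
    dplyr::select("gene_id", "group", "n_cells", "n_well", "included",
                  "n_cells_used", "mean_ratio", "keep") |>
    dplyr::arrange(.data$gene_id,
                   match(.data$group, lineage_groups()))
  class(out) <- c("xreact_stage_ratios", class(out))
  out
}

#' Classify the reactivation timing of X-linked genes
#'
#' Rule ladder over the four group means (TE, pre-lineage ICM, PrE, Epi);
#' the first matching rule wins and is recorded in `rule_fired`:
#'
#' 1. manual override (e.g. from RNA-FISH), when supplied — never
#'    inferred;
#' 2. `other`: imprinted-flagged genes (such as Xist and Xlr3a),
#'    regardless of their ratios;
#' 3. `escapee`: ratio > `escapee_min` in every observed group (TE
#'    included) with E4.0 Epi observed — the gene was never subject to
#'    imprinted silencing;
#' 4. `early`: silenced in TE (ratio <= `mono` or a prior-knowledge
#'    silencing flag) but already reactivated (> `react`) in the E3.5
#'    ICM;
#' 5. `late`: TE silenced or unobserved, E3.5 ICM not reactivated (or
#'    unobserved), reactivated in the E4.0 epiblast;
#' 6. `very_late`: TE silenced and no later group above `react` — still
#'    repressed on the Xp at E4.0;
#' 7. `unclassified`: the decisive groups are missing.
#'
#' Genes whose TE mean falls between `escapee_min` and `react` sit
#' between the escapee and reactivation boundaries and are flagged in
#' `te_boundary_flag`.
#'
#' @param stage_ratios Output of [stage_ratio_matrix()] (only genes with
#'   `keep = TRUE` are classified unless `keep_only = FALSE`).
#' @param annotation Optional annotation supplying
#'   `is_imprinted_flagged` and `prior_silenced` per gene.
#' @param overrides Optional tibble `gene_id, timing` of manual classes.
#' @param mono Monoallelic boundary (TE silencing), default 0.15.
#' @param react Reactivation threshold, default 0.20.
#' @param escapee_min Escapee boundary, default 0.15.
#' @param keep_only Restrict to heatmap-kept genes (default TRUE).
#' @return Tibble `gene_id, timing, rule_fired, te_boundary_flag` plus
#'   the four group means as columns.
#' @export
classify_timing <- function(stage_ratios, annotation = NULL,
                            overrides = NULL, mono = 0.15, react = 0.20,
                            escapee_min = 0.15, keep_only = TRUE) {
  wide <- tidyr::pivot_wider(
    dplyr::select(stage_ratios, "gene_id", "group", "mean_ratio",
                  "keep"),
    names_from = "group", values_from = "mean_ratio")
  for (g in lineage_groups()) if (!g %in% names(wide)) wide[[g]] <- NA_real_
  if (keep_only) wide <- dplyr::filter(wide, .data$keep)

  flags <- tibble::tibble(gene_id = wide$gene_id,
                          imprinted = FALSE, prior_silenced = FALSE)
  if (!is.null(annotation)) {
    ann <- dplyr::select(
      annotation, "gene_id",
      imprinted = "is_imprinted_flagged",
      prior_silenced2 = dplyr::any_of("prior_silenced"))
    flags <- dplyr::select(flags, "gene_id") |>
      dplyr::left_join(ann, by = "gene_id") |>
      dplyr::mutate(
        imprinted = dplyr::coalesce(.data$imprinted, FALSE),
        prior_silenced = if ("prior_silenced2" %in% names(ann)) {
          dplyr::coalesce(.data$prior_silenced2, FALSE)
        } else FALSE)
  }

  classify_one <- function(te, icm, pre, epi, imprinted, prior) {
    gt <- function(x, thr) !is.na(x) & x > thr
    le_or_na <- function(x, thr) is.na(x) | x <= thr
    te_silenced <- (!is.na(te) & te <= mono) | prior
    if (imprinted) {
      return(c("other", "imprinted_flag"))
    }
    esc <- gt(epi, escapee_min) &&
      (is.na(te) | te > escapee_min) &&
      (is.na(icm) | icm > escapee_min) &&
      (is.na(pre) | pre > escapee_min)
    if (esc) {
      return(c("escapee", "ratio_above_escapee_min_in_all_observed"))
    }
    if (te_silenced && gt(icm, react)) {
      return(c("early", "te_silenced_icm_reactivated"))
    }
    if (le_or_na(te, mono) && le_or_na(icm, react) && gt(epi, react)) {
      return(c("late", "epi_reactivated_only"))
    }
    if (te_silenced && !is.na(epi) &&
        le_or_na(icm, react) && le_or_na(pre, react) &&
        le_or_na(epi, react)) {
      return(c("very_late", "no_group_reactivated"))
    }
    c("unclassified", "decisive_groups_missing")
  }

  res <- purrr::pmap(
    list(wide$E3.5_TE, wide$E3.5_ICM, wide$E4.0_PrE, wide$E4.0_Epi,
         flags$imprinted, flags$prior_silenced),
    classify_one)
  out <- tibble::tibble(
    gene_id = wide$gene_id,
    timing = purrr::map_chr(res, 1),
    rule_fired = purrr::map_chr(res, 2),
    te_boundary_flag = !is.na(wide$E3.5_TE) &
      wide$E3.5_TE > escapee_min & wide$E3.5_TE <= react,
    E3.5_TE = wide$E3.5_TE, E3.5_ICM = wide$E3.5_ICM,
    E4.0_PrE = wide$E4.0_PrE, E4.0_Epi = wide$E4.0_Epi
  )
  if (!is.null(overrides)) {
    require_columns(overrides, c("gene_id", "timing"), "overrides")
    idx <- match(out$gene_id, overrides$gene_id)
    hit <- !is.na(idx)
    out$timing[hit] <- overrides$timing[idx[hit]]
    out$rule_fired[hit] <- "manual_override"
  }
  out
}

#' Ordered heatmap matrix of group mean ratios
#'
#' Orders genes by genomic position (TSS) or by timing class (then
#' position) and attaches a colour bin per cell: `maternal` for ratios
#' at/below the monoallelic-maternal boundary, `paternal` at/above the
#' paternal boundary, `gradient` in between, `missing` for NA.
#'
#' @param stage_ratios Output of [stage_ratio_matrix()].
#' @param annotation Annotation with `gene_id` and `tss` (for ordering).
#' @param timing Optional [classify_timing()] output (needed for
#'   `order = "timing"`).
#' @param order `"genomic_position"` or `"timing"`.
#' @param mono,pat Colour-bin boundaries.
#' @return Object of class `xreact_heatmap`: long tibble `gene_id, group,
#'   mean_ratio, bin` with genes ordered as factor levels.
#' @export
heatmap_matrix <- function(stage_ratios, annotation,
                           timing = NULL,
                           order = c("genomic_position", "timing"),
                           mono = 0.15, pat = 0.85) {
  order <- match.arg(order)
  require_columns(annotation, c("gene_id", "tss"), "annotation")
  df <- stage_ratios |>
    dplyr::filter(.data$keep) |>
    dplyr::select("gene_id", "group", "mean_ratio") |>
    dplyr::left_join(dplyr::select(annotation, "gene_id", "tss"),
                     by = "gene_id")
  if (order == "timing") {
    if (is.null(timing)) {
      stop("timing classification required for order = \"timing\"",
           call. = FALSE)
    }
    lev <- c("escapee", "early", "late", "very_late", "other",
             "unclassified")
    df <- df |>
      dplyr::left_join(dplyr::select(timing, "gene_id", "timing"),
                       by = "gene_id") |>
      dplyr::arrange(match(.data$timing, lev), .data$tss)
  } else {
    df <- dplyr::arrange(df, .data$tss)
  }
  df <- df |>
    dplyr::mutate(
      gene_id = factor(.data$gene_id, levels = unique(.data$gene_id)),
      group = factor(.data$group, levels = lineage_groups()),
      bin = dplyr::case_when(
        is.na(.data$mean_ratio) ~ "missing",
        .data$mean_ratio <= mono ~ "maternal",
        .data$mean_ratio >= pat ~ "paternal",
        TRUE ~ "gradient"
      )
    )
  class(df) <- c("xreact_heatmap", class(df))
  df
}

#' @describeIn heatmap_matrix ggplot tile heatmap (maternal red, paternal
#'   blue, gradient in between, missing grey).
#' @param object An `xreact_heatmap`.
#' @param ... Unused.
#' @export
autoplot.xreact_heatmap <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    .data$group, .data$gene_id, fill = .data$mean_ratio)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "red", mid = "yellow", high = "blue", midpoint = 0.5,
      limits = c(0, 1), na.value = "grey85",
      name = "paternal ratio") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}
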