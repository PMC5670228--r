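#' Allelic ratio
#'
#' Fraction of reads assigned to the paternal allele:
#' `pat / (pat + mat)`. The ratio is the pipeline's central quantity —
#' 0 means strictly maternal expression, 1 strictly paternal.
#'
#' @param mat_reads,pat_reads Non-negative read counts (vectorised).
#' @return Numeric vector in \[0, 1\].
#' @export
#' @examples
#' allelic_ratio(17, 3) # 0.15
allelic_ratio <- function(mat_reads, pat_reads) {
  stopifnot(all(mat_reads >= 0), all(pat_reads >= 0))
  tot <- mat_reads + pat_reads
  if (any(tot == 0)) {
    stop("allelic ratio undefined when maternal + paternal reads = 0",
         call. = FALSE)
  }
  pat_reads / tot
}

#' Allelic-state call from a ratio
#'
#' Ratios at or below `ratio_mono` are monoallelic maternal, at or above
#' `ratio_pat` monoallelic paternal; strictly between the two boundaries
#' the gene is biallelic.
#'
#' @param ratio Numeric vector in \[0, 1\] (NAs propagate).
#' @param ratio_mono,ratio_pat Monoallelic boundaries (inclusive).
#' @return Character vector: `"mono_maternal"`, `"biallelic"`,
#'   `"mono_paternal"` or `NA`.
#' @export
classify_allelic_state <- function(ratio, ratio_mono = 0.15,
                                   ratio_pat = 0.85) {
  if (any(ratio < 0 | ratio > 1, na.rm = TRUE)) {
    stop("allelic ratio must lie in [0, 1]", call. = FALSE)
  }
  dplyr::case_when(
    is.na(ratio) ~ NA_character_,
    ratio <= ratio_mono ~ "mono_maternal",
    ratio >= ratio_pat ~ "mono_paternal",
    TRUE ~ "biallelic"
  )
}

#' Aggregate SNP-level allele counts to per-gene allelic profiles
#'
#' For every (gene, cell) pair, sums maternal and paternal reads over the
#' gene's SNPs, keeping only SNPs that individually carry at least
#' `snp_min_reads` allele-assigned (maternal + paternal) reads — low-count
#' SNPs contribute nothing. A gene is informative in a cell when the
#' surviving total reaches `gene_min_reads` and at least one SNP
#' contributed; only then are the allelic ratio and state call computed.
#' Reads on non-parental alleles (`other_count`) are carried through but
#' never enter the ratio.
#'
#' @param counts Allele-count tibble (`cell_id, chrom, pos, mat_count,
#'   pat_count, other_count`), already oriented with [orient_cross()].
#' @param snps SNP table mapping positions to genes (`chrom, pos, gene_id`).
#' @param blacklist Positions to drop first; see [snp_blacklist()]. `NULL`
#'   to skip.
#' @param snp_min_reads Per-SNP inclusion gate (maternal + paternal reads,
#'   counted jointly).
#' @param gene_min_reads Per-gene informativity threshold on the surviving
#'   total.
#' @return Tibble with one row per observed (gene, cell): `gene_id,
#'   cell_id, mat_reads, pat_reads, other_reads, n_snps_used, informative,
#'   allelic_ratio, allelic_call`. SNP rows without a gene are skipped; the
#'   number skipped is reported once as a warning.
#' @export
aggregate_gene_counts <- function(counts, snps,
                                  blacklist = snp_blacklist(),
                                  snp_min_reads = 5,
                                  gene_min_reads = 8) {
  require_columns(counts, c("cell_id", "chrom", "pos", "mat_count",
                            "pat_count"), "counts")
  require_columns(snps, c("chrom", "pos", "gene_id"), "snps")
  counts <- apply_blacklist(counts, blacklist)
  if (!"other_count" %in% names(counts)) counts$other_count <- 0L

  joined <- dplyr::inner_join(
    counts,
    dplyr::select(snps, "chrom", "pos", "gene_id"),
    by = c("chrom", "pos")
  )
  n_orphan <- sum(is.na(joined$gene_id))
  if (n_orphan > 0L) {
    warning(n_orphan, " SNP count row(s) without a gene_id were skipped",
            call. = FALSE)
    joined <- dplyr::filter(joined, !is.na(.data$gene_id))
  }

  out <- joined |>
    dplyr::mutate(
      snp_total = .data$mat_count + .data$pat_count,
      used = .data$snp_total >= snp_min_reads
    ) |>
    dplyr::group_by(.data$gene_id, .data$cell_id) |>
    dplyr::summarise(
      mat_reads = sum(.data$mat_count[.data$used]),
      pat_reads = sum(.data$pat_count[.data$used]),
      other_reads = sum(.data$other_count),
      n_snps_used = sum(.data$used),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      informative = .data$mat_reads + .data$pat_reads >= gene_min_reads &
        .data$n_snps_used >= 1L,
      allelic_ratio = dplyr::if_else(
        .data$informative,
        .data$pat_reads / (.data$mat_reads + .data$pat_reads),
        NA_real_
      ),
      allelic_call = classify_allelic_state(.data$allelic_ratio)
    )
  dplyr::arrange(out, .data$gene_id, .data$cell_id)
}

#' Informativity of an aggregated profile
#'
#' A gene is informative in a cell when its surviving maternal + paternal
#' total reaches the per-gene read threshold (with at least one
#' contributing SNP); non-informative profiles get a missing ratio and
#' call. The threshold exists to damp allelic-ratio noise in genes with
#' few polymorphic positions.
#'
#' @param mat_reads,pat_reads Post-SNP-filter read sums (vectorised).
#' @param n_snps_used Number of SNPs that contributed.
#' @param gene_min_reads Minimum total.
#' @return Logical vector.
#' @export
informativity <- function(mat_reads, pat_reads, n_snps_used = 1L,
                          gene_min_reads = 8) {
  mat_reads + pat_reads >= gene_min_reads & n_snps_used >= 1L
}
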