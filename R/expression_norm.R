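#' Retrotranscribed length of a transcript
#'
#' The single-cell amplification protocol reverse-transcribes only up to
#' about 3 kb from the 3' end, so reads cannot accumulate along the full
#' transcript. The effective ("retrotranscribed") length used for
#' normalisation is the transcript length capped at `cap`.
#'
#' @param transcript_length Positive length(s) in bp.
#' @param cap 3' coverage cap in bp.
#' @return `pmin(transcript_length, cap)`.
#' @export
#' @examples
#' retrotranscribed_length(5000) # 3000
retrotranscribed_length <- function(transcript_length, cap = 3000) {
  if (any(transcript_length <= 0, na.rm = TRUE)) {
    stop("transcript_length must be positive", call. = FALSE)
  }
  pmin(transcript_length, cap)
}

#' RPRT: retrotranscribed length per million mapped reads
#'
#' RPKM with the retrotranscribed length in place of the gene length:
#' `read_count / (rt_length/1000) / (total_mapped_reads/1e6)`. Linear in
#' the read count, inversely proportional to library size.
#'
#' @param read_count Reads assigned to the gene in the cell.
#' @param rt_length_bp Retrotranscribed length, bp (> 0).
#' @param total_mapped_reads Cell library size (> 0).
#' @return Non-negative numeric.
#' @export
#' @examples
#' rprt(100, 2000, 1e6) # 50
rprt <- function(read_count, rt_length_bp, total_mapped_reads) {
  if (any(rt_length_bp <= 0) || any(total_mapped_reads <= 0)) {
    stop("rt_length_bp and total_mapped_reads must be positive",
         call. = FALSE)
  }
  read_count / (rt_length_bp / 1000) / (total_mapped_reads / 1e6)
}

#' Expression flags from an RPRT value
#'
#' Strict thresholds: RPRT > `expressed_min` marks a gene expressed,
#' RPRT > `well_min` well expressed (genes below `expressed_min` are
#' treated as non-expressed). Allele-specific analyses are restricted to
#' well-expressed genes to avoid single-cell amplification noise, so
#' `well_expressed` always implies `expressed`.
#'
#' @param rprt_value Non-negative numeric vector.
#' @param expressed_min,well_min Strict lower bounds.
#' @return Tibble with logical columns `expressed` and `well_expressed`.
#' @export
expression_flags <- function(rprt_value, expressed_min = 1, well_min = 4) {
  stopifnot(all(rprt_value >= 0, na.rm = TRUE), expressed_min <= well_min)
  tibble::tibble(
    expressed = rprt_value > expressed_min,
    well_expressed = rprt_value > well_min
  )
}

#' Per-gene, per-cell RPRT table
#'
#' Joins raw counts with annotation and cell metadata and computes RPRT
#' plus the expression flags for every (gene, cell) pair present in
#' `expr_counts`.
#'
#' @param expr_counts Tibble `gene_id, cell_id, read_count` of reads per
#'   gene and cell.
#' @param annotation Gene annotation with `gene_id` and `transcript_length`.
#' @param cells Cell table with `cell_id` and `total_mapped_reads`.
#' @param cap Retrotranscribed-length cap, bp.
#' @param expressed_min,well_min Flag thresholds (strict).
#' @return Tibble `gene_id, cell_id, rprt, expressed, well_expressed`.
#' @export
rprt_table <- function(expr_counts, annotation, cells, cap = 3000,
                       expressed_min = 1, well_min = 4) {
  require_columns(expr_counts, c("gene_id", "cell_id", "read_count"),
                  "expr_counts")
  require_columns(annotation, c("gene_id", "transcript_length"),
                  "annotation")
  require_columns(cells, c("cell_id", "total_mapped_reads"), "cells")
  out <- expr_counts |>
    dplyr::inner_join(
      dplyr::select(annotation, "gene_id", "transcript_length"),
      by = "gene_id") |>
    dplyr::inner_join(
      dplyr::select(cells, "cell_id", "total_mapped_reads"),
      by = "cell_id") |>
    dplyr::mutate(
      rprt = rprt(.data$read_count,
                  retrotranscribed_length(.data$transcript_length, cap),
                  .data$total_mapped_reads)
    )
  dplyr::bind_cols(
    dplyr::select(out, "gene_id", "cell_id", "rprt"),
    expression_flags(out$rprt, expressed_min, well_min)
  )
}
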