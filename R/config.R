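#' Pipeline configuration
#'
#' Collects every numeric threshold used across the pipeline in one named
#' list, so that each cutoff is set in exactly one place and can be
#' round-tripped to a YAML file alongside results.
#'
#' @param ratio_mono Allelic-ratio boundary at/below which a gene is called
#'   monoallelic maternal (and at/above `ratio_pat`, monoallelic paternal).
#'   Ratios strictly between the two boundaries are biallelic.
#' @param ratio_pat Upper monoallelic boundary (paternal).
#' @param reactivated Strict lower bound on the allelic ratio for calling a
#'   gene reactivated from the paternal X (ratio > threshold).
#' @param rprt_expressed Strict RPRT lower bound for "expressed".
#' @param rprt_well Strict RPRT lower bound for "well expressed"; only
#'   well-expressed genes enter allele-specific analyses.
#' @param snp_min_reads Minimum maternal+paternal reads a single SNP must
#'   carry to contribute to its gene's allelic counts.
#' @param gene_min_reads Minimum summed maternal+paternal reads (over
#'   surviving SNPs) for a gene to be informative in a cell.
#' @param group_min_frac Minimum fraction of a lineage group's cells in which
#'   a gene must be well expressed for group-level analysis.
#' @param group_min_cells Minimum number of such cells (waived for TE).
#' @param rt_cap Retrotranscribed-length cap in bp (3' coverage limit of the
#'   amplification protocol).
#' @param chip_extent TSS window extent in bp for histone-mark scoring.
#' @param window_size Nominal ChIP window width in bp.
#' @param escapee_min Strict lower bound on the ratio, in every observed
#'   group, for the escapee call.
#' @param seed Integer seed recorded with the config.
#'
#' @return A named list of class `xreact_config`.
#' @seealso [write_config()], [read_config()]
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$reactivated
pipeline_config <- function(ratio_mono = 0.15,
                            ratio_pat = 0.85,
                            reactivated = 0.20,
                            rprt_expressed = 1,
                            rprt_well = 4,
                            snp_min_reads = 5,
                            gene_min_reads = 8,
                            group_min_frac = 0.25,
                            group_min_cells = 2,
                            rt_cap = 3000,
                            chip_extent = 5000,
                            window_size = 100,
                            escapee_min = 0.15,
                            seed = 1L) {
  cfg <- list(
    ratio_mono = ratio_mono, ratio_pat = ratio_pat,
    reactivated = reactivated,
    rprt_expressed = rprt_expressed, rprt_well = rprt_well,
    snp_min_reads = snp_min_reads, gene_min_reads = gene_min_reads,
    group_min_frac = group_min_frac, group_min_cells = group_min_cells,
    rt_cap = rt_cap, chip_extent = chip_extent, window_size = window_size,
    escapee_min = escapee_min, seed = as.integer(seed)
  )
  stopifnot(
    cfg$ratio_mono < cfg$ratio_pat,
    cfg$reactivated > 0, cfg$reactivated < 1,
    cfg$rprt_expressed <= cfg$rprt_well,
    cfg$snp_min_reads >= 1, cfg$gene_min_reads >= 1,
    cfg$group_min_frac > 0, cfg$group_min_frac <= 1,
    cfg$rt_cap > 0, cfg$chip_extent > 0, cfg$window_size > 0
  )
  structure(cfg, class = c("xreact_config", "list"))
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()] list.
#' @param path File path.
#' @return `read_config()` returns a validated `xreact_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

# canonical lineage group labels, in developmental order
lineage_groups <- function() {
  c("E3.5_TE", "E3.5_ICM", "E4.0_PrE", "E4.0_Epi")
}
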