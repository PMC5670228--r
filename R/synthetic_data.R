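#' Configuration of the synthetic blastocyst generator
#'
#' Parameters of the ground-truthed simulator. Defaults emulate the
#' study conditions: two stages (E3.5, E4.0) with 15 trophectoderm and
#' 15 pre-lineage ICM cells at E3.5 and 20 PrE + 20 Epi precursor cells
#' at E4.0; X-linked genes split across the four reactivation-timing
#' classes; negative-binomial sequencing depth with dropout (3'-biased
#' single-cell protocol noise); binomial allele sampling at SNPs; marker
#' genes elevated in their lineage; Xist expression anti-correlated with
#' each cell's paternal-X activity.
#'
#' True per-group paternal fractions are drawn inside bands that keep at
#' least a 0.1 margin from every classifier threshold (0.15 / 0.20), so
#' class recovery is well posed; `hard_mode = TRUE` removes the margins
#' for robustness testing.
#'
#' @param n_genes_x,n_genes_autosomal Gene counts (X includes Xist; the
#'   autosomal set includes the marker panel).
#' @param class_proportions Named proportions over early / late /
#'   very_late / escapee; must sum to 1.
#' @param cells_per_group Named cell counts for the four groups.
#' @param n_male_e35 Optional male E3.5 ICM control cells (single X:
#'   fully maternal, no Xist).
#' @param snps_per_gene Range (min, max) of SNPs per gene.
#' @param depth_mean,depth_size Negative-binomial reads per gene per
#'   cell (mean and dispersion size).
#' @param dropout Probability a (gene, cell) measurement is zeroed.
#' @param marker_effect Fold elevation of a marker in its own lineage.
#' @param xist_suppression Slope in \[0, 1\] linking a cell's
#'   reactivation propensity to loss of Xist expression (0 = off).
#' @param chip_effect Fold elevation of paternal H3K27me3 window score
#'   means for late / very-late genes (H3K4me3 mirrored; 0 = no effect).
#' @param tf_effect Beta-parameter shift enriching Myc-family scores in
#'   early / escapee genes (0 = no effect).
#' @param hard_mode Remove truth margins around thresholds.
#' @param seed Mandatory integer seed; all draws derive from it.
#' @return Named list of class `xreact_sim_config`.
#' @export
sim_config <- function(n_genes_x = 100, n_genes_autosomal = 50,
                       class_proportions = c(early = 0.2, late = 0.4,
                                             very_late = 0.2,
                                             escapee = 0.2),
                       cells_per_group = c(E3.5_TE = 15, E3.5_ICM = 15,
                                           E4.0_PrE = 20,
                                           E4.0_Epi = 20),
                       n_male_e35 = 0,
                       snps_per_gene = c(1, 4),
                       depth_mean = 60, depth_size = 2,
                       dropout = 0.15,
                       marker_effect = 6,
                       xist_suppression = 0.9,
                       chip_effect = 3,
                       tf_effect = 2,
                       hard_mode = FALSE,
                       seed = 1L) {
  stopifnot(
    abs(sum(class_proportions) - 1) < 1e-8,
    all(names(class_proportions) %in%
          c("early", "late", "very_late", "escapee")),
    all(cells_per_group >= 1),
    setequal(names(cells_per_group), lineage_groups()),
    n_genes_x >= 4, n_genes_autosomal >= 1,
    snps_per_gene[1] >= 1, snps_per_gene[2] >= snps_per_gene[1],
    depth_mean > 0, depth_size > 0,
    dropout >= 0, dropout <= 1,
    xist_suppression >= 0, xist_suppression <= 1,
    !is.null(seed)
  )
  structure(
    list(n_genes_x = n_genes_x, n_genes_autosomal = n_genes_autosomal,
         class_proportions = class_proportions,
         cells_per_group = cells_per_group, n_male_e35 = n_male_e35,
         snps_per_gene = snps_per_gene, depth_mean = depth_mean,
         depth_size = depth_size, dropout = dropout,
         marker_effect = marker_effect,
         xist_suppression = xist_suppression,
         chip_effect = chip_effect, tf_effect = tf_effect,
         hard_mode = hard_mode, seed = as.integer(seed)),
    class = c("xreact_sim_config", "list")
  )
}

# truth bands for per-group paternal fractions, by timing class
truth_bands <- function(hard_mode) {
  if (hard_mode) {
    list(silent = c(0, 0.14), active = c(0.21, 0.90),
         escapee = c(0.16, 0.90))
  } else {
    list(silent = c(0, 0.04), active = c(0.35, 0.65),
         escapee = c(0.35, 0.65))
  }
}

#' Generate the ground truth of a synthetic experiment
#'
#' Draws, for every X-linked gene, a timing class (by the configured
#' proportions, with every class represented) and a true paternal
#' fraction per lineage group consistent with the class: early genes are
#' silent on the Xp in TE, already reactivated in the E3.5 ICM,
#' re-silenced in PrE and active in Epi; late genes silent until the
#' Epi; very-late genes silent everywhere; escapees active everywhere
#' including TE. Xist is emitted as an imprinted-flagged X-linked gene
#' expressed from the paternal X. Each cell gets a latent lineage and a
#' reactivation propensity in \[0, 1\] that later modulates both its
#' paternal fractions and its Xist level.
#'
#' @param config A [sim_config()].
#' @return List of class `xreact_truth`: `genes` (gene_id, chrom, class,
#'   `frac_<group>` columns), `cells` (cell_id, embryo_id, stage, sex,
#'   true_lineage, propensity) and the config.
#' @export
generate_truth <- function(config = sim_config()) {
  set.seed(config$seed)
  bands <- truth_bands(config$hard_mode)
  classes <- c("early", "late", "very_late", "escapee")
  prop <- config$class_proportions[classes]
  prop[is.na(prop)] <- 0
  n_x <- config$n_genes_x - 1L # one slot reserved for Xist
  n_per <- floor(prop * n_x)
  while (sum(n_per) < n_x) {
    i <- which.max(prop * n_x - n_per)
    n_per[i] <- n_per[i] + 1L
  }
  if (any(prop > 0 & n_per == 0)) {
    stop("class proportions infeasible at ", n_x, " genes", call. = FALSE)
  }
  # classes are assigned to random gene positions, so class membership is
  # independent of genomic position and gene size
  cls <- sample(rep(classes, times = n_per))

  band_draw <- function(n, band) stats::runif(n, band[1], band[2])
  frac_for <- function(cl, group) {
    kind <- switch(
      group,
      "E3.5_TE" = ifelse(cl == "escapee", "escapee", "silent"),
      "E3.5_ICM" = ifelse(cl == "early", "active",
                          ifelse(cl == "escapee", "escapee", "silent")),
      "E4.0_PrE" = ifelse(cl == "escapee", "escapee", "silent"),
      "E4.0_Epi" = ifelse(cl %in% c("early", "late"), "active",
                          ifelse(cl == "escapee", "escapee", "silent"))
    )
    vapply(kind, function(k) band_draw(1, bands[[k]]), numeric(1))
  }

  genes <- tibble::tibble(
    gene_id = sprintf("Xg%03d", seq_len(n_x)),
    chrom = "chrX",
    class = cls,
    frac_E3.5_TE = frac_for(cls, "E3.5_TE"),
    frac_E3.5_ICM = frac_for(cls, "E3.5_ICM"),
    frac_E4.0_PrE = frac_for(cls, "E4.0_PrE"),
    frac_E4.0_Epi = frac_for(cls, "E4.0_Epi")
  )
  # Xist: imprinted, expressed from the paternal X in all groups
  genes <- dplyr::bind_rows(genes, tibble::tibble(
    gene_id = "Xist", chrom = "chrX", class = "other",
    frac_E3.5_TE = 0.95, frac_E3.5_ICM = 0.95,
    frac_E4.0_PrE = 0.95, frac_E4.0_Epi = 0.95))

  groups <- lineage_groups()
  n_cells <- config$cells_per_group[groups]
  lin <- rep(groups, times = n_cells)
  cells <- tibble::tibble(
    true_lineage = lin,
    stage = substr(lin, 1, 4),
    sex = "F"
  )
  # reactivation propensity: Epi precursors furthest along, TE fixed low
  cells$propensity <- dplyr::case_when(
    cells$true_lineage == "E3.5_TE" ~ 0,
    cells$true_lineage == "E3.5_ICM" ~ stats::runif(nrow(cells), 0, 0.8),
    cells$true_lineage == "E4.0_PrE" ~ stats::runif(nrow(cells), 0, 0.6),
    cells$true_lineage == "E4.0_Epi" ~ stats::runif(nrow(cells), 0.4, 1)
  )
  if (config$n_male_e35 > 0) {
    cells <- dplyr::bind_rows(cells, tibble::tibble(
      true_lineage = rep("E3.5_ICM", config$n_male_e35),
      stage = "E3.5", sex = "M", propensity = 1))
  }
  cells <- dplyr::mutate(
    cells,
    cell_id = sprintf("cell%03d", dplyr::row_number()),
    embryo_id = paste0("emb_", .data$stage, "_",
                       1 + (dplyr::row_number() %% 5))
  ) |>
    dplyr::select("cell_id", "embryo_id", "stage", "sex",
                  "true_lineage", "propensity")

  structure(list(genes = genes, cells = cells, config = config),
            class = "xreact_truth")
}

#' @export
print.xreact_truth <- function(x, ...) {
  cat("synthetic truth:", nrow(x$genes), "X-linked genes,",
      nrow(x$cells), "cells\n")
  print(table(x$genes$class))
  invisible(x)
}

#' Simulate the sequencing layer of a synthetic experiment
#'
#' Turns a [generate_truth()] object into the full tabular input bundle:
#' cell metadata, gene annotation, SNP table, per-gene expression read
#' counts and per-SNP allelic counts. Per (gene, cell), total reads are
#' negative binomial around the configured depth and zeroed with the
#' dropout probability; the total is partitioned across the gene's SNPs
#' and each SNP's paternal count is binomial at the cell's true paternal
#' fraction (the group fraction modulated by the cell's reactivation
#' propensity). Marker genes are elevated in their lineage; Xist is high
#' in TE and in low-propensity ICM cells and lost in Epi precursors;
#' male control cells are fully maternal with no Xist.
#'
#' @param truth A `xreact_truth` from [generate_truth()].
#' @return List: tibbles `cells`, `annotation`, `snps`, `expr_counts`,
#'   `allele_counts`, plus `truth`.
#' @export
simulate_counts <- function(truth) {
  config <- truth$config
  set.seed(config$seed + 1L)
  panel <- marker_panel()
  groups <- lineage_groups()

  # ---- annotation ----------------------------------------------------------
  x_genes <- truth$genes
  auto_ids <- c(panel$gene_id,
                sprintf("Ag%03d",
                        seq_len(max(0, config$n_genes_autosomal -
                                      nrow(panel)))))
  ann_x <- tibble::tibble(
    gene_id = x_genes$gene_id, chrom = "chrX",
    strand = rep(c("+", "-"), length.out = nrow(x_genes)),
    tss = 100000L + 20000L * (seq_len(nrow(x_genes)) - 1L),
    gene_length = sample(2000:12000, nrow(x_genes), replace = TRUE),
    transcript_length = sample(800:6000, nrow(x_genes), replace = TRUE),
    flags = ifelse(x_genes$gene_id == "Xist", "x_linked,imprinted",
                   "x_linked")
  )
  ann_a <- tibble::tibble(
    gene_id = auto_ids, chrom = "chr1",
    strand = rep(c("+", "-"), length.out = length(auto_ids)),
    tss = 100000L + 20000L * (seq_along(auto_ids) - 1L),
    gene_length = sample(2000:12000, length(auto_ids), replace = TRUE),
    transcript_length = sample(800:6000, length(auto_ids),
                               replace = TRUE),
    flags = ""
  )
  annotation <- dplyr::bind_rows(ann_x, ann_a) |>
    dplyr::mutate(
      is_x_linked = grepl("x_linked", .data$flags),
      is_imprinted_flagged = grepl("imprinted", .data$flags),
      prior_silenced = FALSE
    )

  # ---- SNP table -----------------------------------------------------------
  n_snps <- sample(config$snps_per_gene[1]:config$snps_per_gene[2],
                   nrow(annotation), replace = TRUE)
  alleles <- c("A", "C", "G", "T")
  snps <- purrr::map_dfr(seq_len(nrow(annotation)), function(i) {
    a <- annotation[i, ]
    lo <- if (a$strand == "+") a$tss else a$tss - a$gene_length + 1L
    pos <- sort(sample(lo:(lo + a$gene_length - 1L), n_snps[i]))
    mat <- sample(alleles, n_snps[i], replace = TRUE)
    pat <- vapply(mat, function(m) sample(setdiff(alleles, m), 1),
                  character(1))
    tibble::tibble(chrom = a$chrom, pos = pos, mat_allele = mat,
                   pat_allele = unname(pat), gene_id = a$gene_id)
  })

  # ---- cells ---------------------------------------------------------------
  cells <- truth$cells |>
    dplyr::mutate(
      tissue_hint = ifelse(.data$true_lineage == "E3.5_TE", "TE", "ICM"),
      cross = "BC",
      total_mapped_reads = round(stats::rlnorm(dplyr::n(), log(1e6),
                                               0.2))
    )

  # ---- expression means ----------------------------------------------------
  # marker fold change by (role, lineage); lineage factors are near-silent
  # outside their lineage, while the pre-lineage ICM co-expresses both
  # Epi and PrE programmes at intermediate level
  marker_mult <- function(role, lineage) {
    own <- c(Epi = "E4.0_Epi", PrE = "E4.0_PrE", TE = "E3.5_TE")[role]
    dplyr::case_when(
      lineage == own ~ config$marker_effect,
      role %in% c("Epi", "PrE") & lineage == "E3.5_ICM" ~
        config$marker_effect / 3,
      TRUE ~ 0.05
    )
  }

  grid <- tidyr::expand_grid(gene_id = annotation$gene_id,
                             cell_id = cells$cell_id) |>
    dplyr::left_join(
      dplyr::select(cells, "cell_id", "true_lineage", "propensity",
                    "sex"),
      by = "cell_id")
  role <- panel$role[match(grid$gene_id, panel$gene_id)]
  mu <- rep(config$depth_mean, nrow(grid))
  is_marker <- !is.na(role)
  mu[is_marker] <- config$depth_mean *
    marker_mult(role[is_marker], grid$true_lineage[is_marker])
  # Xist: high in TE/early ICM, fading with reactivation propensity,
  # lost in Epi precursors
  is_xist <- grid$gene_id == "Xist"
  xist_base <- c(E3.5_TE = 1, E3.5_ICM = 0.9, E4.0_PrE = 0.9,
                 E4.0_Epi = 0.25)[grid$true_lineage[is_xist]]
  mu[is_xist] <- config$depth_mean * 4 * xist_base *
    (1 - config$xist_suppression * grid$propensity[is_xist])
  mu[is_xist & grid$sex == "M"] <- 0.01

  tot <- stats::rnbinom(nrow(grid), mu = mu, size = config$depth_size)
  # dropout is expression-dependent (logistic in log mean, slope 1.5),
  # anchored so that a gene at the reference depth drops out with the
  # configured probability; abundant transcripts are rarely lost
  if (config$dropout > 0) {
    x0 <- log(config$depth_mean) -
      log((1 - config$dropout) / config$dropout) / 1.5
    p_drop <- stats::plogis(-1.5 * (log(pmax(mu, 1e-6)) - x0))
    tot[stats::runif(nrow(grid)) < p_drop] <- 0L
  }
  expr_counts <- tibble::tibble(gene_id = grid$gene_id,
                                cell_id = grid$cell_id,
                                read_count = tot)

  # ---- allelic counts ------------------------------------------------------
  frac_cols <- paste0("frac_", groups)
  xfrac <- as.matrix(truth$genes[, frac_cols])
  rownames(xfrac) <- truth$genes$gene_id

  allele <- grid |>
    dplyr::mutate(read_count = tot) |>
    dplyr::filter(.data$read_count > 0)
  gi <- match(allele$gene_id, rownames(xfrac))
  col <- match(paste0("frac_", allele$true_lineage), frac_cols)
  base_frac <- ifelse(is.na(gi), 0.5, xfrac[cbind(gi, col)])
  modul <- ifelse(allele$true_lineage == "E3.5_TE" |
                    is.na(gi), 1, 0.5 + allele$propensity)
  frac <- pmin(pmax(base_frac * modul, 0), 0.97)
  frac[!is.na(gi) & allele$sex == "M"] <- 0 # single maternal X

  # expand to (gene, cell, SNP) rows and partition each gene total across
  # its SNPs by sequential conditional binomials (exact multinomial split)
  snp_idx <- snps |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(snp_j = dplyr::row_number(), snp_k = dplyr::n()) |>
    dplyr::ungroup()
  allele$pair_id <- seq_len(nrow(allele))
  exp_df <- dplyr::inner_join(
    dplyr::mutate(allele, frac = frac),
    dplyr::select(snp_idx, "gene_id", "chrom", "pos", "snp_j", "snp_k"),
    by = "gene_id", relationship = "many-to-many")
  remaining <- allele$read_count
  exp_df$snp_total <- 0L
  for (j in seq_len(if (nrow(exp_df) > 0) max(exp_df$snp_k) else 0L)) {
    rows <- which(exp_df$snp_j == j)
    ids <- exp_df$pair_id[rows]
    cnt <- stats::rbinom(length(rows), remaining[ids],
                         1 / (exp_df$snp_k[rows] - j + 1))
    exp_df$snp_total[rows] <- cnt
    remaining[ids] <- remaining[ids] - cnt
  }
  pat <- stats::rbinom(nrow(exp_df), exp_df$snp_total, exp_df$frac)
  allele_counts <- tibble::tibble(
    cell_id = exp_df$cell_id, chrom = exp_df$chrom, pos = exp_df$pos,
    mat_count = exp_df$snp_total - pat, pat_count = pat,
    other_count = 0L
  ) |>
    dplyr::arrange(.data$cell_id, .data$chrom, .data$pos)

  list(
    cells = dplyr::select(cells, "cell_id", "embryo_id", "stage",
                          "tissue_hint", "cross", "sex",
                          "total_mapped_reads"),
    annotation = annotation,
    snps = snps,
    expr_counts = expr_counts,
    allele_counts = allele_counts,
    truth = truth
  )
}

#' Simulate allele-resolved histone-mark windows
#'
#' Emits 100-bp ChIP windows around every X-linked gene's TSS for both
#' marks and both alleles. Paternal H3K27me3 window scores for late /
#' very-late genes are drawn from a `(1 + chip_effect)`-fold higher-mean
#' gamma distribution than for early / escapee genes; H3K4me3 is
#' mirrored (active genes enriched); maternal windows show no class
#' effect. With `chip_effect = 0` all classes are exchangeable.
#'
#' @param truth A `xreact_truth`.
#' @param annotation Annotation from [simulate_counts()] (TSS positions).
#' @return Tibble of windows: `chrom, start, end, score, strand, allele,
#'   mark`.
#' @export
simulate_chip_windows <- function(truth, annotation) {
  config <- truth$config
  set.seed(config$seed + 2L)
  ann <- dplyr::inner_join(
    dplyr::select(annotation, "gene_id", "chrom", "strand", "tss",
                  "gene_length"),
    dplyr::select(truth$genes, "gene_id", "class"),
    by = "gene_id")
  base <- 2
  high <- base * (1 + config$chip_effect)
  repressed <- ann$class %in% c("late", "very_late", "other")

  # windows tile the scored extent downstream of each TSS; only a random
  # 60% of them carry an enriched signal and are emitted
  ext <- pmin(5000L, ann$gene_length)
  tss0 <- ann$tss - 1L
  n_win <- as.integer(ceiling(ext / 100))
  first <- ifelse(ann$strand == "+", tss0, tss0 + 1L - ext)
  gene_row <- rep(seq_len(nrow(ann)), times = n_win)
  starts <- rep(first, times = n_win) +
    100L * (sequence(n_win) - 1L)

  one_track <- function(mark, allele) {
    mean_score <- rep(base, nrow(ann))
    if (allele == "paternal") {
      if (mark == "H3K27me3") {
        mean_score[repressed] <- high
      } else {
        mean_score[!repressed] <- high
      }
    }
    keep <- stats::runif(length(starts)) < 0.6
    rows <- gene_row[keep]
    tibble::tibble(
      chrom = ann$chrom[rows], start = as.integer(starts[keep]),
      end = as.integer(starts[keep] + 100L),
      score = round(stats::rgamma(sum(keep), shape = 3,
                                  scale = mean_score[rows] / 3), 3),
      strand = ".", allele = allele, mark = mark
    )
  }
  dplyr::bind_rows(
    one_track("H3K27me3", "paternal"),
    one_track("H3K27me3", "maternal"),
    one_track("H3K4me3", "paternal"),
    one_track("H3K4me3", "maternal")
  )
}

#' Simulate TF-gene association scores
#'
#' Beta-distributed scores in \[0, 1\] per (gene, TF). Myc-family scores
#' are enriched for early / escapee genes and depleted for late /
#' very-late genes (strength `tf_effect`); pluripotency-factor scores
#' are class-independent.
#'
#' @param truth A `xreact_truth`.
#' @return Tibble `gene_id, tf, score`.
#' @export
simulate_tf_scores <- function(truth) {
  config <- truth$config
  set.seed(config$seed + 3L)
  genes <- truth$genes
  tfs <- c(tf_set("pluripotency6"), tf_set("myc2"))
  grid <- tidyr::expand_grid(gene_id = genes$gene_id, tf = tfs) |>
    dplyr::left_join(dplyr::select(genes, "gene_id", "class"),
                     by = "gene_id")
  myc <- grid$tf %in% tf_set("myc2")
  enriched <- grid$class %in% c("early", "escapee")
  a <- ifelse(myc & enriched, 2 + config$tf_effect, 1.5)
  b <- ifelse(myc & !enriched, 2 + config$tf_effect, 3)
  tibble::tibble(gene_id = grid$gene_id, tf = grid$tf,
                 score = round(stats::rbeta(nrow(grid), a, b), 4))
}

#' Generate a complete synthetic input bundle
#'
#' Chains [generate_truth()], [simulate_counts()],
#' [simulate_chip_windows()] and [simulate_tf_scores()]. All randomness
#' derives from `config$seed` (each layer uses a fixed offset of it), so
#' identical configs give identical bundles.
#'
#' @param config A [sim_config()].
#' @return List: `cells, annotation, snps, expr_counts, allele_counts,
#'   chip_windows, tf_scores, truth`.
#' @seealso [write_bundle()] to materialise the bundle as files,
#'   [run_pipeline()] to analyse it.
#' @export
simulate_bundle <- function(config = sim_config()) {
  truth <- generate_truth(config)
  out <- simulate_counts(truth)
  out$chip_windows <- simulate_chip_windows(truth, out$annotation)
  out$tf_scores <- simulate_tf_scores(truth)
  out
}

#' Write a synthetic bundle to a directory
#'
#' Materialises every table of a [simulate_bundle()] result in the
#' pipeline's external formats (TSV; BED for windows), plus the truth
#' tables, so the files round-trip through the package readers.
#'
#' @param bundle A [simulate_bundle()] list.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_table(bundle$cells, p("cells.tsv"))
  write_table(dplyr::select(bundle$annotation, "gene_id", "chrom",
                            "strand", "tss", "gene_length",
                            "transcript_length", "flags"),
              p("annotation.tsv"))
  write_table(bundle$snps, p("snp_table.tsv"))
  write_table(bundle$expr_counts, p("expr_counts.tsv"))
  write_table(bundle$allele_counts, p("allele_counts.tsv"))
  write_bed_windows(bundle$chip_windows, p("windows.bed"))
  write_table(bundle$tf_scores, p("tf_scores.tsv"))
  write_table(bundle$truth$genes, p("truth_genes.tsv"))
  write_table(bundle$truth$cells, p("truth_cells.tsv"))
  write_config(pipeline_config(seed = bundle$truth$config$seed),
               p("config.yaml"))
  invisible(dir)
}
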