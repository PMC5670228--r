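test_that("the generator is deterministic given a seed", {
  cfg <- sim_config(n_genes_x = 20, n_genes_autosomal = 20, seed = 42)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_equal(b1$allele_counts, b2$allele_counts)
  expect_equal(b1$expr_counts, b2$expr_counts)
  expect_equal(b1$chip_windows, b2$chip_windows)
  expect_equal(b1$tf_scores, b2$tf_scores)
  b3 <- simulate_bundle(sim_config(n_genes_x = 20, n_genes_autosomal = 20,
                                   seed = 43))
  expect_false(identical(b1$allele_counts, b3$allele_counts))
})

test_that("class proportions drive the truth table", {
  cfg <- sim_config(n_genes_x = 30,
                    class_proportions = c(early = 1, late = 0,
                                          very_late = 0, escapee = 0),
                    seed = 5)
  tr <- generate_truth(cfg)
  expect_equal(sum(tr$genes$class == "early"), 29L) # all but Xist
  expect_equal(tr$genes$class[tr$genes$gene_id == "Xist"], "other")
})

test_that("true fractions respect their class definitions with margin", {
  tr <- generate_truth(sim_config(seed = 19))
  g <- tr$genes[tr$genes$class != "other", ]
  margin <- 0.1
  silent_max <- 0.15 - margin
  react_min <- 0.20 + margin
  esc_min <- 0.15 + margin
  by_class <- split(g, g$class)
  with(by_class$early, {
    expect_true(all(frac_E3.5_TE <= silent_max))
    expect_true(all(frac_E3.5_ICM >= react_min))
    expect_true(all(frac_E4.0_PrE < 0.1)) # re-silenced in PrE
    expect_true(all(frac_E4.0_Epi >= react_min))
  })
  with(by_class$late, {
    expect_true(all(frac_E3.5_TE <= silent_max))
    expect_true(all(frac_E3.5_ICM <= silent_max))
    expect_true(all(frac_E4.0_Epi >= react_min))
  })
  with(by_class$very_late, {
    expect_true(all(frac_E3.5_TE <= silent_max))
    expect_true(all(frac_E4.0_Epi <= 0.20 - margin))
  })
  with(by_class$escapee, {
    expect_true(all(frac_E3.5_TE >= esc_min))
    expect_true(all(frac_E3.5_ICM >= esc_min))
    expect_true(all(frac_E4.0_PrE >= 0.25))
    expect_true(all(frac_E4.0_Epi >= esc_min))
  })
})

test_that("full dropout zeroes every measurement", {
  cfg <- sim_config(n_genes_x = 10, n_genes_autosomal = 15, dropout = 1,
                    seed = 3)
  b <- simulate_counts(generate_truth(cfg))
  expect_true(all(b$expr_counts$read_count == 0))
  expect_equal(nrow(b$allele_counts), 0L)
})

test_that("a zero true fraction never yields paternal reads", {
  cfg <- sim_config(n_genes_x = 10, n_genes_autosomal = 15,
                    dropout = 0, seed = 23)
  tr <- generate_truth(cfg)
  tr$genes[tr$genes$class == "very_late",
           paste0("frac_", xreact:::lineage_groups())] <- 0
  b <- simulate_counts(tr)
  vlate <- tr$genes$gene_id[tr$genes$class == "very_late"]
  vl_snps <- b$snps$pos[b$snps$gene_id %in% vlate]
  expect_true(all(b$allele_counts$pat_count[
    b$allele_counts$pos %in% vl_snps & b$allele_counts$chrom == "chrX"] == 0))
})

test_that("empirical allele fractions converge to the truth", {
  # TE cells are unmodulated, so escapee genes in TE read out their true
  # fraction directly; high depth gives a tight law-of-large-numbers check
  cfg <- sim_config(n_genes_x = 12, n_genes_autosomal = 15, dropout = 0,
                    depth_mean = 800, seed = 29,
                    cells_per_group = c(E3.5_TE = 15, E3.5_ICM = 2,
                                        E4.0_PrE = 2, E4.0_Epi = 2))
  tr <- generate_truth(cfg)
  b <- simulate_counts(tr)
  te_cells <- b$cells$cell_id[b$cells$tissue_hint == "TE"]
  esc <- tr$genes[tr$genes$class == "escapee", ]
  for (i in seq_len(min(3, nrow(esc)))) {
    pos <- b$snps$pos[b$snps$gene_id == esc$gene_id[i]]
    sub <- b$allele_counts[b$allele_counts$pos %in% pos &
                             b$allele_counts$chrom == "chrX" &
                             b$allele_counts$cell_id %in% te_cells, ]
    tot_reads <- sum(sub$mat_count + sub$pat_count)
    expect_gt(tot_reads, 5000)
    expect_lt(abs(sum(sub$pat_count) / tot_reads - esc$frac_E3.5_TE[i]),
              0.02)
  }
})

test_that("ChIP windows tile valid coordinates with the class effect", {
  cfg <- sim_config(n_genes_x = 40, seed = 7)
  tr <- generate_truth(cfg)
  b <- simulate_counts(tr)
  w <- simulate_chip_windows(tr, b$annotation)
  expect_true(all(w$start >= 0))
  expect_true(all(w$end - w$start == 100))
  expect_true(all(w$score >= 0))
  expect_setequal(unique(w$mark), c("H3K27me3", "H3K4me3"))
  expect_setequal(unique(w$allele), c("paternal", "maternal"))
  # paternal H3K27me3 higher for late/very-late, H3K4me3 mirrored
  sc <- tss_window_score(dplyr::filter(b$annotation, is_x_linked),
                         w, mark = "H3K27me3", allele = "paternal") |>
    dplyr::inner_join(dplyr::select(tr$genes, gene_id, class),
                      by = "gene_id")
  m_late <- mean(sc$summed_score[sc$class %in% c("late", "very_late")])
  m_early <- mean(sc$summed_score[sc$class %in% c("early", "escapee")])
  expect_gt(m_late, 2 * m_early)
})

test_that("TF scores stay in [0, 1] with Myc depletion in late classes", {
  cfg <- sim_config(n_genes_x = 60, seed = 15)
  tr <- generate_truth(cfg)
  tf <- simulate_tf_scores(tr)
  expect_true(all(tf$score >= 0 & tf$score <= 1))
  myc <- sum_tf_scores(tf, "myc2") |>
    dplyr::inner_join(dplyr::select(tr$genes, gene_id, class),
                      by = "gene_id")
  expect_gt(mean(myc$summed_score[myc$class %in% c("early", "escapee")]),
            mean(myc$summed_score[myc$class %in% c("late", "very_late")]))
})

test_that("a written bundle parses back through the readers unchanged", {
  dir <- withr::local_tempdir()
  b <- simulate_bundle(sim_config(n_genes_x = 15, n_genes_autosomal = 16,
                                  seed = 9))
  expect_no_warning(write_bundle(b, dir))
  expect_no_warning({
    cells <- read_cells(file.path(dir, "cells.tsv"))
    snps <- read_snp_table(file.path(dir, "snp_table.tsv"))
    ann <- read_annotation(file.path(dir, "annotation.tsv"))
    counts <- read_allele_counts(file.path(dir, "allele_counts.tsv"))
    wins <- read_bed_windows(file.path(dir, "windows.bed"))
    tf <- read_tf_scores(file.path(dir, "tf_scores.tsv"))
  })
  expect_equal(cells$cell_id, b$cells$cell_id)
  expect_equal(snps$pos, b$snps$pos)
  expect_equal(ann$is_x_linked, b$annotation$is_x_linked)
  expect_equal(counts$pat_count, b$allele_counts$pat_count)
  expect_equal(wins$score, b$chip_windows$score)
  expect_equal(wins$start, b$chip_windows$start)
  expect_equal(tf$score, b$tf_scores$score)
})

test_that("male control cells are fully maternal with silent Xist", {
  cfg <- sim_config(n_genes_x = 10, n_genes_autosomal = 15,
                    n_male_e35 = 4, dropout = 0, seed = 33)
  b <- simulate_counts(generate_truth(cfg))
  males <- b$cells$cell_id[b$cells$sex == "M"]
  expect_length(males, 4L)
  x_pos <- b$snps$pos[b$snps$chrom == "chrX"]
  male_x <- b$allele_counts[b$allele_counts$cell_id %in% males &
                              b$allele_counts$pos %in% x_pos &
                              b$allele_counts$chrom == "chrX", ]
  expect_true(all(male_x$pat_count == 0))
  xist <- b$expr_counts[b$expr_counts$gene_id == "Xist" &
                          b$expr_counts$cell_id %in% males, ]
  expect_true(all(xist$read_count <= 1))
})
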