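# small long-format count table: genes x cells from a matrix
long_counts <- function(mat) {
  tibble::as_tibble(mat, rownames = "gene_id") |>
    tidyr::pivot_longer(-gene_id, names_to = "cell_id",
                        values_to = "read_count")
}

test_that("median-of-ratios normalisation has unit factors for identical cells", {
  mat <- matrix(c(3, 10, 0, 7), 4, 3,
                dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
  out <- normalize_for_clustering(long_counts(mat))
  # all cells identical: size factors 1, transform is log2(count + 1)
  expect_equal(out$norm_expr, log2(rep(c(3, 10, 0, 7), each = 3) + 1))
  # zero counts stay zero after the transform
  expect_true(all(out$norm_expr[out$gene_id == "g3"] == 0))
})

test_that("doubling a cell's library doubles its size factor exactly", {
  set.seed(5)
  base <- matrix(rpois(40, 20) + 1, 10, 4,
                 dimnames = list(paste0("g", 1:10), paste0("c", 1:4)))
  doubled <- cbind(base, c5 = 2 * base[, 1])
  out <- normalize_for_clustering(long_counts(doubled))
  wide <- tidyr::pivot_wider(out, names_from = "cell_id",
                             values_from = "norm_expr")
  expect_equal(wide$c5, wide$c1)
})

test_that("all-zero cells are rejected by name", {
  mat <- matrix(c(1, 2, 0, 0), 2, 2,
                dimnames = list(c("g1", "g2"), c("good", "empty")))
  expect_error(normalize_for_clustering(long_counts(mat)), "empty")
})

test_that("PCA separates disjoint marker groups and is deterministic", {
  # two cell groups with disjoint expressed gene sets, no noise
  mat <- cbind(
    matrix(rep(c(10, 10, 10, 0, 0, 0), 3), 6, 3,
           dimnames = list(paste0("g", 1:6), paste0("a", 1:3))),
    matrix(rep(c(0, 0, 0, 10, 10, 10), 3), 6, 3,
           dimnames = list(NULL, paste0("b", 1:3)))
  )
  norm <- long_counts(mat)
  names(norm)[3] <- "norm_expr"
  fit <- pca_cells(norm, n_top = 6)
  pc1 <- fit$scores$PC1
  names(pc1) <- fit$scores$cell_id
  a <- pc1[paste0("a", 1:3)]; b <- pc1[paste0("b", 1:3)]
  expect_gt(min(abs(outer(a, b, "-"))), max(dist(a), dist(b)))
  # components ordered by decreasing variance
  expect_true(all(diff(fit$sdev) <= 1e-12))
  # duplicated cell lands on identical coordinates
  mat2 <- cbind(mat, a1bis = mat[, "a1"])
  norm2 <- long_counts(mat2)
  names(norm2)[3] <- "norm_expr"
  fit2 <- pca_cells(norm2, n_top = 6)
  s <- fit2$scores
  expect_equal(unlist(s[s$cell_id == "a1bis", -1]),
               unlist(s[s$cell_id == "a1", -1]))
  # n_top clamps with a warning
  expect_warning(pca_cells(norm, n_top = 100), "exceeds")
})

test_that("Pearson-Ward clustering matches a naive Lance-Williams oracle", {
  naive_ward <- function(mat, k) {
    # O(n^3) agglomeration with the ward.D2 update on 1 - cor distances
    d <- as.matrix(stats::as.dist(1 - stats::cor(mat)))
    n <- ncol(mat)
    members <- as.list(seq_len(n))
    sizes <- rep(1, n)
    active <- rep(TRUE, n)
    while (sum(active) > k) {
      idx <- which(active)
      best <- c(NA, NA); bestd <- Inf
      for (i in idx) for (j in idx) if (i < j && d[i, j] < bestd) {
        bestd <- d[i, j]; best <- c(i, j)
      }
      i <- best[1]; j <- best[2]
      for (h in idx) {
        if (h == i || h == j) next
        d2 <- ((sizes[i] + sizes[h]) * d[i, h]^2 +
                 (sizes[j] + sizes[h]) * d[j, h]^2 -
                 sizes[h] * d[i, j]^2) /
          (sizes[i] + sizes[j] + sizes[h])
        d[i, h] <- d[h, i] <- sqrt(d2)
      }
      members[[i]] <- c(members[[i]], members[[j]])
      sizes[i] <- sizes[i] + sizes[j]
      active[j] <- FALSE
    }
    lab <- integer(n)
    for (ci in seq_along(which(active))) {
      lab[members[[which(active)[ci]]]] <- ci
    }
    lab
  }
  same_partition <- function(a, b) {
    length(unique(paste(a, b))) == length(unique(a)) &&
      length(unique(a)) == length(unique(b))
  }
  set.seed(21)
  for (rep in 1:10) {
    n_cells <- sample(5:8, 1)
    mat <- matrix(rpois(12 * n_cells, 10), 12, n_cells,
                  dimnames = list(paste0("g", 1:12),
                                  paste0("c", seq_len(n_cells))))
    grp <- rep(c(0, 1), length.out = n_cells)
    mat[1:6, grp == 1] <- mat[1:6, grp == 1] + 30
    norm <- long_counts(mat)
    names(norm)[3] <- "norm_expr"
    k <- sample(2:3, 1)
    got <- hier_cluster(norm, n_clusters = k)
    want <- naive_ward(mat[, sort(colnames(mat))], k)
    expect_true(same_partition(got$labels$cluster_id, want))
  }
})

test_that("clustering is invariant to cell order and flags constant cells", {
  set.seed(9)
  mat <- matrix(rpois(60, 15), 10, 6,
                dimnames = list(paste0("g", 1:10), paste0("c", 1:6)))
  mat[1:5, 4:6] <- mat[1:5, 4:6] + 40
  norm <- long_counts(mat)
  names(norm)[3] <- "norm_expr"
  a <- hier_cluster(norm, 2)
  b <- hier_cluster(norm[sample(nrow(norm)), ], 2)
  expect_equal(a$labels, b$labels)

  flat <- mat
  flat[, 2] <- 7 # constant profile: correlation undefined
  normf <- long_counts(flat)
  names(normf)[3] <- "norm_expr"
  expect_error(hier_cluster(normf, 2), "c2")
})

test_that("lineage assignment follows stage, hint and marker scores", {
  panel <- marker_panel()
  epi_m <- panel$gene_id[panel$role == "Epi"]
  pre_m <- panel$gene_id[panel$role == "PrE"]
  te_m <- panel$gene_id[panel$role == "TE"]
  cells <- tibble::tibble(
    cell_id = c("te1", "icm1", "epi1", "epi2", "pre1", "pre2"),
    stage = c("E3.5", "E3.5", "E4.0", "E4.0", "E4.0", "E4.0"),
    tissue_hint = c("TE", "ICM", "ICM", "ICM", "ICM", "ICM")
  )
  expr <- tidyr::expand_grid(gene_id = panel$gene_id,
                             cell_id = cells$cell_id) |>
    dplyr::mutate(read_count = dplyr::case_when(
      gene_id %in% epi_m & cell_id %in% c("epi1", "epi2") ~ 100,
      gene_id %in% pre_m & cell_id %in% c("pre1", "pre2") ~ 100,
      gene_id %in% te_m & cell_id == "te1" ~ 100,
      TRUE ~ 2
    ))
  norm <- normalize_for_clustering(expr)
  out <- assign_lineages(cells, norm)
  got <- out$lineage_group
  names(got) <- out$cell_id
  expect_equal(unname(got[c("te1", "icm1")]), c("E3.5_TE", "E3.5_ICM"))
  expect_equal(unname(got[c("epi1", "epi2")]),
               rep("E4.0_Epi", 2)) # high Nanog/Prdm14-class markers
  expect_equal(unname(got[c("pre1", "pre2")]),
               rep("E4.0_PrE", 2)) # high Gata4/Gata6-class markers
  # Epi cells score higher on the epiblast panel than PrE cells
  expect_gt(min(out$epi_score[out$lineage_group == "E4.0_Epi"]),
            max(out$epi_score[out$lineage_group == "E4.0_PrE"]))
})

test_that("tied cluster scores abort instead of guessing", {
  panel <- marker_panel()
  cells <- tibble::tibble(cell_id = c("x1", "x2"), stage = "E4.0",
                          tissue_hint = "ICM")
  # two cells with identical epiblast-marker means but distinct profiles
  expr <- tidyr::expand_grid(gene_id = panel$gene_id,
                             cell_id = cells$cell_id) |>
    dplyr::mutate(read_count = dplyr::case_when(
      gene_id == "Gata4" & cell_id == "x1" ~ 50,
      gene_id == "Gata6" & cell_id == "x2" ~ 50,
      TRUE ~ 10
    ))
  norm <- normalize_for_clustering(expr)
  expect_error(assign_lineages(cells, norm), "unresolved")
})
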