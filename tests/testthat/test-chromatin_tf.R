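test_windows <- function(starts, scores, chrom = "chrX",
                         allele = "paternal", mark = "H3K27me3") {
  tibble::tibble(chrom = chrom, start = as.integer(starts),
                 end = as.integer(starts + 100L), score = scores,
                 strand = ".", allele = allele, mark = mark)
}

plus_gene <- function(tss = 10001L, len = 8000L, id = "g1") {
  tibble::tibble(gene_id = id, chrom = "chrX", strand = "+",
                 tss = tss, gene_length = len)
}

test_that("TSS window scores sum overlapping whole windows", {
  # gene TSS at 1-based 10001 -> 0-based 10000; extent 5000 -> [10000, 15000)
  ann <- plus_gene()
  expect_equal(
    tss_window_score(ann, test_windows(c(20000, 30000), c(1, 2)))$summed_score,
    0)
  got <- tss_window_score(ann, test_windows(c(10000, 14000), c(3, 4.5)))
  expect_equal(got$summed_score, 7.5)
  expect_equal(got$window_used_bp, 5000L)
  # partial overlap counts the full window, both at the start and the end
  got <- tss_window_score(ann, test_windows(c(9950, 14950), c(1, 10)))
  expect_equal(got$summed_score, 11)
  # window ending exactly at the interval start does not overlap
  expect_equal(
    tss_window_score(ann, test_windows(9900, 5))$summed_score, 0)
  expect_equal(
    tss_window_score(ann, test_windows(15000, 5))$summed_score, 0)
})

test_that("short genes are scored over their own length only", {
  ann <- plus_gene(len = 3000L)
  got <- tss_window_score(ann, test_windows(c(10000, 12900, 13000),
                                            c(1, 2, 4)))
  expect_equal(got$window_used_bp, 3000L)
  expect_equal(got$summed_score, 3) # [10000, 13000): third window out
})

test_that("minus-strand genes are scored upstream of their TSS coordinate", {
  # TSS (gene end) at 1-based 20000 -> extent runs (15000, 20000] 1-based
  ann <- tibble::tibble(gene_id = "gm", chrom = "chrX", strand = "-",
                        tss = 20000L, gene_length = 8000L)
  got <- tss_window_score(ann, test_windows(c(15000, 19900, 20000),
                                            c(1, 2, 4)))
  expect_equal(got$summed_score, 3) # interval [15000, 20000): last out
})

test_that("windows are filtered by mark and allele and NA off-chromosome", {
  ann <- plus_gene()
  w <- dplyr::bind_rows(
    test_windows(10000, 3, mark = "H3K27me3", allele = "paternal"),
    test_windows(10000, 5, mark = "H3K4me3", allele = "paternal"),
    test_windows(10000, 7, mark = "H3K27me3", allele = "maternal"))
  expect_equal(tss_window_score(ann, w, mark = "H3K27me3",
                                allele = "paternal")$summed_score, 3)
  expect_equal(tss_window_score(ann, w, mark = "H3K4me3",
                                allele = "paternal")$summed_score, 5)
  ann2 <- dplyr::mutate(plus_gene(id = "g2"), chrom = "chr9")
  expect_warning(got <- tss_window_score(ann2, w), "absent")
  expect_true(is.na(got$summed_score))
})

test_that("TSS scoring is additive over disjoint sets and order-invariant", {
  set.seed(6)
  ann <- plus_gene()
  w1 <- test_windows(seq(10000, 12000, 100), runif(21))
  w2 <- test_windows(seq(13000, 14000, 100), runif(11))
  s1 <- tss_window_score(ann, w1)$summed_score
  s2 <- tss_window_score(ann, w2)$summed_score
  both <- dplyr::bind_rows(w1, w2)
  expect_equal(tss_window_score(ann, both)$summed_score, s1 + s2)
  shuffled <- both[sample(nrow(both)), ]
  expect_equal(tss_window_score(ann, shuffled)$summed_score, s1 + s2)
})

test_that("Wilcoxon comparisons match exact enumeration and known cases", {
  # identical groups: p = 1
  sc <- tibble::tibble(timing = rep(c("early", "late"), each = 3),
                       summed_score = c(1, 2, 3, 1, 2, 3))
  expect_equal(compare_groups_wilcoxon(sc, "early", "late")$p, 1)

  # (3, 3) exact p equals enumeration over all 20 assignments
  set.seed(31)
  for (rep in 1:10) {
    x <- sample(1:100, 3)
    y <- sample(101:200, 3) - sample(0:150, 3)
    if (anyDuplicated(c(x, y))) next
    sc <- tibble::tibble(timing = rep(c("a", "b"), each = 3),
                         summed_score = c(x, y))
    got <- compare_groups_wilcoxon(sc, "a", "b")
    expect_equal(got$method, "exact")
    expect_equal(got$p, wilcox_enum_p(x, y))
  }

  # completely separated groups of 5: minimal two-sided exact p = 2/252
  sc <- tibble::tibble(timing = rep(c("lo", "hi"), each = 5),
                       summed_score = c(1:5, 101:105))
  expect_equal(compare_groups_wilcoxon(sc, "lo", "hi")$p, 2 / 252)

  expect_error(compare_groups_wilcoxon(sc, "lo", "absent"), "empty")
})

test_that("Kruskal-Wallis and Dunn behave on identical and shifted groups", {
  sc <- tibble::tibble(timing = rep(c("a", "b", "c"), each = 4),
                       summed_score = rep(c(1, 2, 3, 4), 3))
  kw <- compare_groups_kw(sc)
  expect_equal(kw$statistic, 0, tolerance = 1e-12)
  expect_equal(kw$p, 1)

  dn <- dunn_posthoc(sc)
  expect_equal(nrow(dn), 3L)
  expect_true(all(abs(dn$z) < 1e-12))
  expect_true(all(dn$q >= dn$p)) # BH never decreases a p-value

  # KW p matches a rank permutation Monte-Carlo null
  set.seed(17)
  sc2 <- tibble::tibble(
    timing = rep(c("a", "b", "c"), times = c(5, 6, 5)),
    summed_score = c(rnorm(5, 0), rnorm(6, 1.5), rnorm(5, 0.5)))
  kw2 <- compare_groups_kw(sc2)
  h_obs <- kw2$statistic
  n_perm <- 10000
  h_null <- replicate(n_perm, {
    stats::kruskal.test(sample(sc2$summed_score),
                        factor(sc2$timing))$statistic
  })
  p_mc <- mean(h_null >= h_obs - 1e-12)
  se <- sqrt(p_mc * (1 - p_mc) / n_perm) + 1e-4
  expect_lt(abs(kw2$p - p_mc), 4 * se + 0.01)

  sc_bad <- sc[sc$timing != "c", ]
  expect_error(compare_groups_kw(sc_bad[sc_bad$timing == "a", ]),
               "2 non-empty")
})

test_that("Dunn z-statistics match a hand computation without ties", {
  # groups a = {1, 2}, b = {3, 4}: pooled ranks 1..4, mean 1.5 vs 3.5
  sc <- tibble::tibble(timing = c("a", "a", "b", "b"),
                       summed_score = c(1, 2, 3, 4))
  dn <- dunn_posthoc(sc)
  # var0 = N(N+1)/12 = 4*5/12; z = (1.5 - 3.5)/sqrt(var0 * (1/2 + 1/2))
  expect_equal(dn$z, -2 / sqrt(4 * 5 / 12))
  expect_equal(dn$p, 2 * pnorm(-abs(dn$z)))
})

test_that("TF score sums use the canonical sets and a zero default", {
  tf <- tibble::tibble(
    gene_id = c("g1", "g1", "g1", "g2"),
    tf = c("Nanog", "Oct4", "Myc", "Mycn"),
    score = c(0.9, 0.8, 0.5, 0.3))
  # remaining pluripotency TFs must exist in the table for the set
  tf_full <- dplyr::bind_rows(tf, tibble::tibble(
    gene_id = "g3", tf = c("Sox2", "Klf4", "Esrrb", "Tcfcp2l1"),
    score = 0))
  out <- sum_tf_scores(tf_full, "pluripotency6")
  expect_equal(out$summed_score[out$gene_id == "g1"], 1.7)
  expect_equal(out$summed_score[out$gene_id == "g2"], 0)
  out <- sum_tf_scores(tf_full, "myc2",
                       genes = c("g1", "g2", "absent"))
  expect_equal(out$summed_score, c(0.5, 0.3, 0))
  # a single-TF custom set is that TF's score
  out <- sum_tf_scores(tf_full, "Nanog")
  expect_equal(out$summed_score[out$gene_id == "g1"], 0.9)
  expect_error(sum_tf_scores(tf, "pluripotency6"), "Sox2")
})
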