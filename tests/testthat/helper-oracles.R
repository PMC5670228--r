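# Independent oracles shared across test files. Each is a deliberately
# naive implementation (loops, enumeration) kept separate from the
# package's own code paths.

# all permutations of 1..n, built by insertion (independent of the
# package's recursive generator)
perms_by_insertion <- function(n) {
  out <- matrix(1L, 1, 1)
  for (k in 2:n) {
    grown <- vector("list", nrow(out) * k)
    idx <- 1L
    for (r in seq_len(nrow(out))) {
      row <- out[r, ]
      for (pos in 0:(k - 1)) {
        grown[[idx]] <- append(row, k, after = pos)
        idx <- idx + 1L
      }
    }
    out <- do.call(rbind, grown)
  }
  out
}

# naive per-SNP aggregation loop: per (gene, cell), walk SNPs one by one
naive_aggregate <- function(counts, snps, snp_min = 5, gene_min = 8) {
  res <- list()
  for (g in sort(unique(snps$gene_id))) {
    gpos <- snps[snps$gene_id == g, c("chrom", "pos")]
    for (cl in sort(unique(counts$cell_id))) {
      mat <- 0L; pat <- 0L; used <- 0L; seen <- FALSE
      for (i in seq_len(nrow(gpos))) {
        hit <- counts$cell_id == cl & counts$chrom == gpos$chrom[i] &
          counts$pos == gpos$pos[i]
        if (!any(hit)) next
        seen <- TRUE
        m <- sum(counts$mat_count[hit]); p <- sum(counts$pat_count[hit])
        if (m + p >= snp_min) {
          mat <- mat + m; pat <- pat + p; used <- used + 1L
        }
      }
      if (seen) {
        res[[length(res) + 1L]] <- data.frame(
          gene_id = g, cell_id = cl, mat_reads = mat, pat_reads = pat,
          n_snps_used = used,
          informative = (mat + pat >= gene_min) && used >= 1L)
      }
    }
  }
  do.call(rbind, res)
}

# textbook BH step-up: sort, cummin from the largest rank down
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- cummin(rev(p[o] * m / seq_len(m))[seq_len(m)])
  q <- numeric(m)
  q[o] <- rev(q_sorted)
  pmin(q, 1)
}

# exact two-sided rank-sum p by enumerating all group assignments
wilcox_enum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  w_null <- apply(combos, 2, function(id) {
    sum(r[id]) - nx * (nx + 1) / 2
  })
  lo <- mean(w_null <= w_obs)
  hi <- mean(w_null >= w_obs)
  min(1, 2 * min(lo, hi))
}

# small stage-ratio table in the shape classify_timing() expects
make_stage_ratios <- function(gene_id, te, icm, pre, epi) {
  n <- length(gene_id)
  tibble::tibble(
    gene_id = rep(gene_id, each = 4),
    group = rep(xreact:::lineage_groups(), n),
    mean_ratio = as.vector(rbind(te, icm, pre, epi)),
    n_cells = 10L, n_well = 5L, included = TRUE,
    n_cells_used = 5L, keep = TRUE
  )
}
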