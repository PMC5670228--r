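#' Read-level quality-control rule
#'
#' Thresholds for discarding raw sequencing reads before any counting.
#' A read is discarded if any of the following fires, checked in order:
#' more than `max_lowqual_frac` of its bases are below `phred_min`;
#' more than `max_n_frac` of its bases are N; at least `max_at_frac` of
#' its bases are A or T; or it contains a contiguous run of A and/or T
#' (mixed runs count) longer than `max_at_run` bases.
#'
#' @param max_lowqual_frac Maximum tolerated fraction of low-quality bases.
#' @param phred_min Phred score below which a base counts as low quality.
#' @param max_n_frac Maximum tolerated fraction of N bases.
#' @param max_at_frac A/T content at or above this fraction discards.
#' @param max_at_run Longest tolerated contiguous A/T run, in bases.
#' @return A named list of class `qc_rule`.
#' @export
qc_rule <- function(max_lowqual_frac = 0.50, phred_min = 5,
                    max_n_frac = 0.05, max_at_frac = 0.80,
                    max_at_run = 15L) {
  stopifnot(
    max_lowqual_frac > 0, max_lowqual_frac <= 1,
    max_n_frac > 0, max_n_frac <= 1,
    max_at_frac > 0, max_at_frac <= 1,
    max_at_run >= 1
  )
  structure(
    list(max_lowqual_frac = max_lowqual_frac, phred_min = phred_min,
         max_n_frac = max_n_frac, max_at_frac = max_at_frac,
         max_at_run = as.integer(max_at_run)),
    class = c("qc_rule", "list")
  )
}

#' Quality-control filter for a single read
#'
#' @param sequence Read sequence, a single string over A/C/G/T/N.
#' @param qualities Per-base Phred scores: either an integer vector the same
#'   length as the sequence, or a Phred+33 encoded string.
#' @param rule A [qc_rule()].
#' @return A list with `keep` (logical) and `reason` (`NA` if kept, otherwise
#'   the first criterion that fired: `"lowqual"`, `"ncontent"`, `"at_content"`
#'   or `"polyAT"`).
#' @export
#' @examples
#' read_qc_filter("ACGTACGT", rep(40L, 8))
read_qc_filter <- function(sequence, qualities, rule = qc_rule()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (is.character(qualities) && length(qualities) == 1L) {
    qualities <- utf8ToInt(qualities) - 33L
  }
  if (length(qualities) != length(bases)) {
    stop("sequence and qualities differ in length (",
         length(bases), " vs ", length(qualities), ")", call. = FALSE)
  }
  if (length(bases) == 0L) stop("empty read", call. = FALSE)

  n <- length(bases)
  is_at <- bases %in% c("A", "T")
  reason <- NA_character_
  if (mean(qualities < rule$phred_min) > rule$max_lowqual_frac) {
    reason <- "lowqual"
  } else if (mean(bases == "N") > rule$max_n_frac) {
    reason <- "ncontent"
  } else if (mean(is_at) >= rule$max_at_frac) {
    reason <- "at_content"
  } else {
    runs <- rle(is_at)
    if (any(runs$lengths[runs$values] > rule$max_at_run)) {
      reason <- "polyAT"
    }
  }
  list(keep = is.na(reason), reason = reason)
}

#' Quality-control filter over a table of reads
#'
#' Applies [read_qc_filter()] to every row; rows are independent, so the
#' result does not depend on their order.
#'
#' @param reads A data frame with columns `sequence` and `quality` (Phred+33
#'   string or list-column of integer vectors).
#' @param rule A [qc_rule()].
#' @return The input as a tibble with `keep` and `reason` columns appended.
#' @export
qc_reads <- function(reads, rule = qc_rule()) {
  require_columns(reads, c("sequence", "quality"), "reads")
  res <- purrr::map2(reads$sequence, reads$quality,
                     function(s, q) read_qc_filter(s, q, rule))
  dplyr::mutate(tibble::as_tibble(reads),
                keep = purrr::map_lgl(res, "keep"),
                reason = purrr::map_chr(res, "reason"))
}

# ---- table readers ---------------------------------------------------------

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop("`", what, "` is missing mandatory column(s): ",
         paste0(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

check_coordinates <- function(raw, col, path) {
  vals <- suppressWarnings(as.numeric(raw[[col]]))
  bad <- which(is.na(vals) & !is.na(raw[[col]]))
  if (length(bad) > 0L) {
    stop("malformed coordinate in `", col, "` of ", path,
         " at line ", bad[1] + 1L, " (value: ", raw[[col]][bad[1]], ")",
         call. = FALSE)
  }
  vals
}

read_table_checked <- function(path, mandatory, coord_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  require_columns(raw, mandatory, basename(path))
  for (col in coord_cols) raw[[col]] <- check_coordinates(raw, col, path)
  raw
}

#' Read the external tables of the pipeline
#'
#' All tables are headered TSV. Coordinates in `snp_table.tsv` and
#' `annotation.tsv` are 1-based inclusive; BED files are standard 0-based
#' half-open. Unknown extra columns are preserved. A missing mandatory
#' column raises a schema error naming the column; a malformed coordinate
#' raises a parse error with its line number.
#'
#' * `read_snp_table()`: `chrom, pos, mat_allele, pat_allele, gene_id`
#' * `read_allele_counts()`: `cell_id, chrom, pos, mat_count, pat_count,
#'   other_count`
#' * `read_cells()`: `cell_id, embryo_id, stage, tissue_hint, cross, sex,
#'   total_mapped_reads`
#' * `read_annotation()`: `gene_id, chrom, strand, tss, gene_length,
#'   transcript_length, flags` (flags: comma-separated subset of
#'   `x_linked`, `imprinted`, `prior_silenced`; expanded to logical columns)
#' * `read_tf_scores()`: `gene_id, tf, score`
#'
#' @param path Path to the TSV file.
#' @return A tibble with typed columns.
#' @name readers
NULL

#' @rdname readers
#' @export
read_snp_table <- function(path) {
  raw <- read_table_checked(
    path, c("chrom", "pos", "mat_allele", "pat_allele", "gene_id"), "pos")
  out <- dplyr::mutate(
    raw,
    pos = as.integer(.data$pos),
    mat_allele = toupper(.data$mat_allele),
    pat_allele = toupper(.data$pat_allele),
    gene_id = dplyr::na_if(.data$gene_id, "")
  )
  bad <- out$mat_allele == out$pat_allele |
    !(out$mat_allele %in% c("A", "C", "G", "T")) |
    !(out$pat_allele %in% c("A", "C", "G", "T")) |
    out$pos < 1L
  if (any(bad, na.rm = TRUE)) {
    stop("invalid SNP record(s) at row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  out
}

#' @rdname readers
#' @export
read_allele_counts <- function(path) {
  raw <- read_table_checked(
    path,
    c("cell_id", "chrom", "pos", "mat_count", "pat_count", "other_count"),
    "pos")
  dplyr::mutate(raw,
                pos = as.integer(.data$pos),
                mat_count = as.integer(.data$mat_count),
                pat_count = as.integer(.data$pat_count),
                other_count = as.integer(.data$other_count))
}

#' @rdname readers
#' @export
read_cells <- function(path) {
  raw <- read_table_checked(
    path,
    c("cell_id", "embryo_id", "stage", "tissue_hint", "cross", "sex",
      "total_mapped_reads"))
  out <- dplyr::mutate(raw,
                       total_mapped_reads =
                         as.numeric(.data$total_mapped_reads))
  stopifnot(all(out$total_mapped_reads > 0))
  out
}

#' @rdname readers
#' @export
read_annotation <- function(path) {
  raw <- read_table_checked(
    path,
    c("gene_id", "chrom", "strand", "tss", "gene_length",
      "transcript_length", "flags"),
    c("tss", "gene_length", "transcript_length"))
  out <- dplyr::mutate(
    raw,
    tss = as.integer(.data$tss),
    gene_length = as.integer(.data$gene_length),
    transcript_length = as.integer(.data$transcript_length),
    flags = dplyr::coalesce(.data$flags, ""),
    is_x_linked = grepl("x_linked", .data$flags),
    is_imprinted_flagged = grepl("imprinted", .data$flags),
    prior_silenced = grepl("prior_silenced", .data$flags)
  )
  stopifnot(all(out$strand %in% c("+", "-")),
            all(out$gene_length > 0), all(out$transcript_length > 0))
  out
}

#' @rdname readers
#' @export
read_tf_scores <- function(path) {
  raw <- read_table_checked(path, c("gene_id", "tf", "score"))
  out <- dplyr::mutate(raw, score = as.numeric(.data$score))
  if (any(out$score < 0 | out$score > 1, na.rm = TRUE)) {
    stop("TF association scores must lie in [0, 1]", call. = FALSE)
  }
  out
}

#' Read allele-resolved ChIP windows from BED
#'
#' Standard BED (0-based half-open) with the window score in column 5.
#' Columns 7 and 8, when present, carry the allele (`maternal`/`paternal`)
#' and the histone mark; otherwise both may be supplied as arguments (the
#' usual case when they are encoded in the file name).
#'
#' @param path BED file path.
#' @param allele,mark Defaults used when the file lacks columns 7-8.
#' @return Tibble: `chrom, start, end, score, strand, allele, mark`.
#' @export
read_bed_windows <- function(path, allele = NA_character_,
                             mark = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), score = numeric(),
                          strand = character(), allele = character(),
                          mark = character()))
  }
  if (ncol(raw) < 5L) {
    stop("`", basename(path),
         "` needs at least 5 BED columns (score in column 5)",
         call. = FALSE)
  }
  start <- check_coordinates(raw, "X2", path)
  end <- check_coordinates(raw, "X3", path)
  bad <- which(end <= start | start < 0)
  if (length(bad) > 0L) {
    stop("invalid BED interval at line ", bad[1], " of ", path,
         call. = FALSE)
  }
  tibble::tibble(
    chrom = raw$X1,
    start = as.integer(start),
    end = as.integer(end),
    score = as.numeric(raw$X5),
    strand = if (ncol(raw) >= 6L) raw$X6 else NA_character_,
    allele = if (ncol(raw) >= 7L) raw$X7 else allele,
    mark = if (ncol(raw) >= 8L) raw$X8 else mark
  )
}

#' Write a table (or BED windows) back to disk
#'
#' `write_table()` writes any tibble as headered TSV; `write_bed_windows()`
#' writes the 8-column BED dialect read by [read_bed_windows()]. Round-trip
#' write-then-read is the identity on the mandatory columns.
#'
#' @param x Tibble to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
write_bed_windows <- function(x, path) {
  require_columns(x, c("chrom", "start", "end", "score"), "windows")
  bed <- tibble::tibble(
    chrom = x$chrom, start = x$start, end = x$end, name = ".",
    score = x$score,
    strand = if ("strand" %in% names(x)) {
      dplyr::coalesce(x$strand, ".")
    } else ".",
    allele = if ("allele" %in% names(x)) x$allele else ".",
    mark = if ("mark" %in% names(x)) x$mark else "."
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# ---- SNP blacklist and cross orientation -----------------------------------

#' Default SNP blacklist
#'
#' Positions excluded from allelic counting. Ships with the known
#' problematic SNP chrX:37,805,131 (mm10, in Rhox5), annotated A for
#' C57BL/6J but absent from hybrid samples.
#'
#' @return Tibble with `chrom` and `pos` (1-based).
#' @export
snp_blacklist <- function() {
  tibble::tibble(chrom = "chrX", pos = 37805131L)
}

#' Remove blacklisted SNP positions
#'
#' Drops exactly the (chrom, pos) pairs listed in `blacklist` from a SNP
#' table or an allele-count table; all other rows are untouched.
#'
#' @param x Table with `chrom` and `pos` columns.
#' @param blacklist Tibble of positions to drop; see [snp_blacklist()].
#' @return `x` without the blacklisted rows.
#' @export
apply_blacklist <- function(x, blacklist = snp_blacklist()) {
  require_columns(x, c("chrom", "pos"), "x")
  if (is.null(blacklist) || nrow(blacklist) == 0L) {
    return(tibble::as_tibble(x))
  }
  dplyr::anti_join(tibble::as_tibble(x), blacklist,
                   by = c("chrom", "pos"))
}

#' Orient allele counts so that "paternal" always means the Xp under study
#'
#' In the forward BC cross (maternal C57BL/6J x paternal CAST/EiJ) the
#' paternal allele is the CAST one; in the reverse CB cross the parental
#' origins are swapped, so maternal and paternal counts are exchanged at
#' load time for CB cells.
#'
#' @param counts Allele-count tibble (`cell_id, mat_count, pat_count`, ...).
#' @param cells Cell metadata with `cell_id` and `cross` (`"BC"` or `"CB"`).
#' @return `counts` with columns swapped for CB cells.
#' @export
orient_cross <- function(counts, cells) {
  require_columns(counts, c("cell_id", "mat_count", "pat_count"), "counts")
  require_columns(cells, c("cell_id", "cross"), "cells")
  stopifnot(all(cells$cross %in% c("BC", "CB")))
  cb <- cells$cell_id[cells$cross == "CB"]
  if (length(cb) == 0L) return(tibble::as_tibble(counts))
  flip <- counts$cell_id %in% cb
  out <- tibble::as_tibble(counts)
  tmp <- out$mat_count[flip]
  out$mat_count[flip] <- out$pat_count[flip]
  out$pat_count[flip] <- tmp
  out
}
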