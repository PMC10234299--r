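#' Read and filter a PAF alignment file
#'
#' Reads minimap2-style PAF (12 mandatory columns, 0-based half-open
#' coordinates; SAM-style tags beyond column 12 are ignored) and applies the
#' pipeline's alignment filters: mapping quality at least `min_mapq`,
#' reference-axis alignment width at least `min_aln_width`, and contig length
#' at least `min_ctg_size`. Records tagged as secondary (`tp:A:S`) are dropped
#' with a warning. Input order is preserved.
#'
#' Sample and haplotype identity come from file provenance (one PAF per
#' haplotype assembly), not from contig names.
#'
#' @param path Path to a PAF file.
#' @param sample Sample label attached to every record.
#' @param hap Haplotype label (e.g. `"H1"`).
#' @param t An [asm_thresholds()] object.
#' @return A tibble with columns `qname, qlen, qstart, qend, strand, tname,
#'   tlen, tstart, tend, nmatch, alen, mapq, sample, hap`.
#' @examples
#' paf <- tempfile(fileext = ".paf")
#' writeLines("ctg1\t150000\t0\t2000\t+\tchr1\t1000000\t5000\t7000\t2000\t2000\t60",
#'            paf)
#' read_paf(paf, sample = "S1", hap = "H1")
#' @export
read_paf <- function(path, sample = "sample", hap = "H1",
                     t = asm_thresholds()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(empty_alignments())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  bad <- which(n_col < 12)
  if (length(bad) > 0) {
    stop("PAF parse error at line ", bad[1], ": expected >= 12 columns, got ",
         n_col[bad[1]], call. = FALSE)
  }
  secondary <- vapply(fields, function(f) any(f[-(1:12)] == "tp:A:S"),
                      logical(1))
  if (any(secondary)) {
    warning(sum(secondary), " secondary alignment(s) (tp:A:S) dropped")
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:12))
  num_cols <- c(2, 3, 4, 7, 8, 9, 10, 11, 12)
  nums <- suppressWarnings(apply(m[, num_cols, drop = FALSE], 2, as.numeric))
  nums <- matrix(nums, ncol = length(num_cols))
  bad <- which(apply(nums, 1, function(r) any(is.na(r))))
  if (length(bad) > 0) {
    stop("PAF parse error at line ", bad[1], ": non-integer coordinate",
         call. = FALSE)
  }
  aln <- tibble(
    qname = m[, 1], qlen = nums[, 1], qstart = nums[, 2], qend = nums[, 3],
    strand = m[, 5], tname = m[, 6], tlen = nums[, 4], tstart = nums[, 5],
    tend = nums[, 6], nmatch = nums[, 7], alen = nums[, 8], mapq = nums[, 9],
    sample = sample, hap = hap
  )
  bad <- which(aln$qstart >= aln$qend | aln$tstart >= aln$tend |
                 aln$qstart < 0 | aln$tstart < 0 |
                 aln$qend > aln$qlen | aln$tend > aln$tlen)
  if (length(bad) > 0) {
    stop("PAF parse error at line ", bad[1],
         ": invalid interval (need 0 <= start < end <= length)",
         call. = FALSE)
  }
  if (!all(aln$strand %in% c("+", "-"))) {
    bad <- which(!aln$strand %in% c("+", "-"))[1]
    stop("PAF parse error at line ", bad, ": strand must be '+' or '-'",
         call. = FALSE)
  }
  aln <- aln[!secondary, , drop = FALSE]
  filter_alignments(aln, t)
}

empty_alignments <- function() {
  tibble(
    qname = character(), qlen = numeric(), qstart = numeric(),
    qend = numeric(), strand = character(), tname = character(),
    tlen = numeric(), tstart = numeric(), tend = numeric(),
    nmatch = numeric(), alen = numeric(), mapq = numeric(),
    sample = character(), hap = character()
  )
}

#' Apply the alignment filters to an alignment tibble
#'
#' Keeps records with `mapq >= min_mapq`, reference width
#' `tend - tstart >= min_aln_width`, and `qlen >= min_ctg_size`. Idempotent.
#'
#' @param aln Alignment tibble as returned by [read_paf()].
#' @param t An [asm_thresholds()] object.
#' @return The filtered tibble, input order preserved.
#' @export
filter_alignments <- function(aln, t = asm_thresholds()) {
  check_alignments(aln)
  aln %>%
    filter(.data$mapq >= t$min_mapq,
           (.data$tend - .data$tstart) >= t$min_aln_width,
           .data$qlen >= t$min_ctg_size)
}

#' Group and order alignments per contig
#'
#' Sorts records within each (sample, haplotype, contig) by contig coordinate
#' (`qstart`), breaking ties by `tstart` then `tname`. This is the canonical
#' ordering every downstream stage assumes.
#'
#' @param aln Filtered alignment tibble.
#' @return The same tibble, grouped-ordered; errors if `qlen` is inconsistent
#'   within a contig.
#' @export
group_alignments <- function(aln) {
  check_alignments(aln)
  bad <- aln %>%
    group_by(.data$sample, .data$hap, .data$qname) %>%
    summarise(n_len = dplyr::n_distinct(.data$qlen), .groups = "drop") %>%
    filter(.data$n_len > 1)
  if (nrow(bad) > 0) {
    stop("data error: inconsistent contig length for ",
         paste(bad$qname, collapse = ", "), call. = FALSE)
  }
  arrange(aln, .data$sample, .data$hap, .data$qname, .data$qstart,
          .data$tstart, .data$tname)
}

#' Read a BED file into a tibble
#'
#' BED is 0-based half-open. Columns beyond the first three are kept as
#' `name`, `score`, `strand` when present; `#`/`track`/`browser` lines and
#' `## thresholds:` headers are skipped.
#'
#' @param path Path to a BED file.
#' @return Tibble with columns `chrom, start, end` (+ optional BED6 columns).
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  k <- min(lengths(fields))
  m <- do.call(rbind, lapply(fields, `[`, seq_len(min(k, 6))))
  out <- tibble(chrom = m[, 1], start = as.numeric(m[, 2]),
                end = as.numeric(m[, 3]))
  if (k >= 4) out$name <- m[, 4]
  if (k >= 5) out$score <- suppressWarnings(as.numeric(m[, 5]))
  if (k >= 6) out$strand <- m[, 6]
  out
}

#' Write intervals as BED with a thresholds header
#'
#' @param x Tibble with at least `chrom, start, end`; `name`, `score`,
#'   `strand` are written when present.
#' @param path Output path.
#' @param t Optional [asm_thresholds()] echoed as a `## thresholds:` line.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, t = NULL) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(t)) writeLines(thresholds_header(t), con)
  if (nrow(x) > 0) {
    body <- do.call(paste, c(lapply(cols, function(cn) {
      v <- x[[cn]]
      if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE) else v
    }), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' Write a result tibble as TSV with a thresholds header
#'
#' @param x A tibble.
#' @param path Output path.
#' @param t Optional [asm_thresholds()] echoed as a `## thresholds:` line.
#' @return `path`, invisibly.
#' @export
write_qc_tsv <- function(x, path, t = NULL) {
  con <- file(path, "w")
  if (!is.null(t)) writeLines(thresholds_header(t), con)
  close(con)
  x <- dplyr::select(x, !dplyr::where(is.list))
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write alignments as normalized BED-like TSV
#'
#' Columns: `chrom start end contig contig_start contig_end strand mapq
#' sample hap`, all coordinates 0-based half-open.
#'
#' @inheritParams write_qc_tsv
#' @param aln Alignment tibble.
#' @export
write_alignments <- function(aln, path, t = NULL) {
  check_alignments(aln)
  out <- aln %>%
    transmute(chrom = .data$tname, start = .data$tstart, end = .data$tend,
              contig = .data$qname, contig_start = .data$qstart,
              contig_end = .data$qend, strand = .data$strand,
              mapq = .data$mapq, sample = .data$sample, hap = .data$hap)
  write_qc_tsv(out, path, t)
}

#' Write an alignment tibble as PAF
#'
#' @param aln Alignment tibble with the canonical columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(aln, path) {
  check_alignments(aln)
  rows <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                  aln$qname, as.integer(aln$qlen), as.integer(aln$qstart),
                  as.integer(aln$qend), aln$strand, aln$tname,
                  as.integer(aln$tlen), as.integer(aln$tstart),
                  as.integer(aln$tend), as.integer(aln$nmatch),
                  as.integer(aln$alen), as.integer(aln$mapq))
  writeLines(rows, path)
  invisible(path)
}
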