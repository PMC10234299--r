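#' Multi-coverage regions of a haploid assembly
#'
#' A haploid assembly should tile the reference at coverage 1; this sweeps
#' the contig alignments of each (sample, haplotype, chromosome) and reports
#' the maximal reference intervals covered by two or more alignments, with
#' the contributing contigs and the maximum simultaneous depth. A region is
#' flagged `embedded` when one contributing contig's entire aligned span on
#' that chromosome lies inside another contributor's span — the signature of
#' a contig fully contained in a larger one.
#'
#' @param aln Alignment tibble.
#' @return Tibble `sample, hap, chrom, start, end, depth, contigs
#'   (comma-separated), embedded`.
#' @export
multicoverage_regions <- function(aln) {
  check_alignments(aln)
  aln %>%
    group_by(.data$sample, .data$hap, .data$tname) %>%
    group_map(function(g, key) {
      ir <- IRanges::IRanges(start = g$tstart + 1, end = g$tend)
      cov <- IRanges::coverage(ir)
      high <- IRanges::slice(cov, lower = 2, rangesOnly = TRUE)
      if (length(high) == 0) return(NULL)
      spans <- g %>%
        group_by(.data$qname) %>%
        summarise(s = min(.data$tstart), e = max(.data$tend),
                  .groups = "drop")
      reg <- tibble(
        sample = key$sample, hap = key$hap, chrom = key$tname,
        start = IRanges::start(high) - 1,
        end = as.numeric(IRanges::end(high))
      )
      hits <- IRanges::findOverlaps(high, ir)
      reg$depth <- vapply(seq_along(high), function(i) {
        v <- IRanges::Views(cov, IRanges::IRanges(IRanges::start(high)[i],
                                                  IRanges::end(high)[i]))
        max(IRanges::viewMaxs(v))
      }, 0)
      contributors <- split(g$qname[S4Vectors::subjectHits(hits)],
                            S4Vectors::queryHits(hits))
      reg$contigs <- vapply(seq_along(high), function(i) {
        paste(sort(unique(contributors[[as.character(i)]])), collapse = ",")
      }, "")
      reg$embedded <- vapply(seq_along(high), function(i) {
        ct <- unique(contributors[[as.character(i)]])
        if (length(ct) < 2) return(FALSE)
        sp <- spans %>% filter(.data$qname %in% ct)
        for (a in seq_len(nrow(sp))) {
          inside <- sp$s >= sp$s[a] & sp$e <= sp$e[a]
          inside[a] <- FALSE
          if (any(inside)) return(TRUE)
        }
        FALSE
      }, logical(1))
      reg
    }) %>%
    bind_rows()
}

#' Convert windowed read depth to diploid copy number
#'
#' Scales each window's depth by the mean depth over control (copy-number
#' stable) windows so that the control mean maps to diploid copy number 2.
#' When a `gc` column is present, scaling is done per GC decile (a linear
#' per-decile correction for GC bias); otherwise a single global factor is
#' used.
#'
#' @param depth Tibble `chrom, start, end, depth` and optionally `gc`.
#' @param control Control-region tibble `chrom, start, end`; windows
#'   overlapping these regions calibrate the scaling.
#' @param gc_correct Use per-GC-decile scaling when a `gc` column exists.
#' @return `depth` with a `cn` column (diploid copy number).
#' @export
depth_to_copy_number <- function(depth, control, gc_correct = TRUE) {
  hits <- GenomicRanges::findOverlaps(as_granges0(depth),
                                      as_granges0(control))
  ctrl_idx <- unique(S4Vectors::queryHits(hits))
  if (length(ctrl_idx) == 0) {
    stop("no depth windows overlap the control regions", call. = FALSE)
  }
  if (gc_correct && "gc" %in% names(depth)) {
    brk <- unique(stats::quantile(depth$gc, probs = seq(0, 1, 0.1),
                                  na.rm = TRUE))
    decile <- cut(depth$gc, breaks = brk, include.lowest = TRUE)
    ctrl_mean <- tapply(depth$depth[ctrl_idx], decile[ctrl_idx], mean)
    fallback <- mean(depth$depth[ctrl_idx])
    denom <- as.numeric(ctrl_mean[as.character(decile)])
    denom[is.na(denom) | denom == 0] <- fallback
  } else {
    denom <- mean(depth$depth[ctrl_idx])
  }
  if (any(denom == 0) || all(is.na(denom))) {
    stop("control windows have zero mean depth", call. = FALSE)
  }
  depth %>% mutate(cn = 2 * .data$depth / denom)
}

#' Four-way copy-number category
#'
#' The classification rule applied to a region's rounded sample diploid copy
#' number `s` and reference (k-merized) copy number `r`, with
#' `delta = s - r`:
#' `noCN` when `s` equals the diploid copy number or `delta = 0`; otherwise
#' `CNV` when `s < cn_high` and `delta >= 1`; otherwise `more10CN` when
#' `s > cn_high` and `delta >= 1`; otherwise `none`. A sample copy number
#' exactly at `cn_high` with an increase satisfies neither bound and falls
#' to `none`. Categories are mutually exclusive and exhaustive.
#'
#' @param sample_cn,ref_cn Integer (or rounded) copy numbers, vectorized.
#' @param t An [asm_thresholds()] object.
#' @return Character vector of categories.
#' @export
cnv_category <- function(sample_cn, ref_cn, t = asm_thresholds()) {
  delta <- sample_cn - ref_cn
  dplyr::case_when(
    sample_cn == t$cn_diploid | delta == 0 ~ "noCN",
    sample_cn < t$cn_high & delta >= 1 ~ "CNV",
    sample_cn > t$cn_high & delta >= 1 ~ "more10CN",
    TRUE ~ "none"
  )
}

#' Classify regions against sample and reference copy-number tracks
#'
#' For each region, averages the overlapping windows of the sample and
#' reference copy-number tracks, rounds half-up to integers, and applies
#' [cnv_category()]. Regions covered by no window in either track are
#' `uncallable`.
#'
#' @param regions Tibble `chrom, start, end` (e.g. from
#'   [multicoverage_regions()]).
#' @param sample_cn Tibble `chrom, start, end, cn` (sample diploid CN).
#' @param ref_cn Tibble `chrom, start, end, cn` (reference k-mer CN).
#' @param t An [asm_thresholds()] object.
#' @return `regions` plus `mean_sample_cn, mean_ref_cn, delta, category`.
#' @export
classify_cnv <- function(regions, sample_cn, ref_cn, t = asm_thresholds()) {
  region_mean <- function(track) {
    if (nrow(regions) == 0) return(numeric(0))
    hits <- GenomicRanges::findOverlaps(as_granges0(regions),
                                        as_granges0(track))
    means <- tapply(track$cn[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits), mean)
    out <- rep(NA_real_, nrow(regions))
    out[as.integer(names(means))] <- as.numeric(means)
    out
  }
  ms <- region_mean(sample_cn)
  mr <- region_mean(ref_cn)
  rs <- floor(ms + 0.5)  # round half-up; region-level rule uses integers
  rr <- floor(mr + 0.5)
  regions %>%
    mutate(
      mean_sample_cn = ms, mean_ref_cn = mr,
      delta = rs - rr,
      category = ifelse(is.na(ms) | is.na(mr), "uncallable",
                        cnv_category(rs, rr, t)))
}

#' Screen a contig-overlap region for loss of heterozygosity
#'
#' Over a region where two contigs of the same haplotype overlap, computes
#' the per-window heterozygous-variant density of each overlapping contig
#' and flags an LOH-like pattern when one contig's density falls below
#' `loh_frac` of the assembly-wide median density while that contig is
#' nearly identical to the opposite parental haplotype (its differences from
#' the opposite-haplotype sequence are below `loh_frac` of the expected
#' heterozygous rate).
#'
#' @param region One-row tibble `chrom, start, end` (the contig overlap).
#' @param het Tibble `contig, pos` of heterozygous-variant positions within
#'   the region, for each overlapping contig.
#' @param cross_hap_diffs Tibble `contig, pos` of positions at which each
#'   overlapping contig differs from the opposite-haplotype sequence over
#'   the same interval.
#' @param median_density Assembly-wide median het density (variants per bp).
#' @param window Window size in bp for the density profile.
#' @param loh_frac Fraction of the expected rate below which a contig counts
#'   as variant-depleted / near-identical (default 0.1).
#' @return Tibble with one row per contig: `contig, n_het, density,
#'   n_diffs, expected_het, loh_flag`; per-window densities in the `windows`
#'   attribute. With no variants supplied the flag is `NA` (uncallable).
#' @export
loh_screen <- function(region, het, cross_hap_diffs, median_density,
                       window = 50000, loh_frac = 0.1) {
  width <- region$end - region$start
  contigs <- unique(c(het$contig, cross_hap_diffs$contig))
  if (length(contigs) == 0) {
    return(tibble(contig = character(), n_het = integer(),
                  density = numeric(), n_diffs = integer(),
                  expected_het = numeric(), loh_flag = logical()))
  }
  starts <- seq(region$start, region$end - 1, by = window)
  win <- tidyr::expand_grid(contig = contigs, win_start = starts) %>%
    mutate(win_end = pmin(.data$win_start + window, region$end))
  win$n_het <- purrr::map2_int(win$contig, win$win_start, function(ct, ws) {
    sum(het$contig == ct & het$pos >= ws & het$pos < min(ws + window,
                                                         region$end))
  })
  win$density <- win$n_het / (win$win_end - win$win_start)
  expected <- median_density * width
  summary <- tibble(contig = contigs) %>%
    mutate(
      n_het = vapply(.data$contig, function(ct)
        sum(het$contig == ct), integer(1)),
      density = .data$n_het / width,
      n_diffs = vapply(.data$contig, function(ct)
        sum(cross_hap_diffs$contig == ct), integer(1)),
      expected_het = expected,
      loh_flag = if (nrow(het) == 0 && nrow(cross_hap_diffs) == 0) NA else
        .data$density < loh_frac * median_density &
        .data$n_diffs < loh_frac * expected)
  attr(summary, "windows") <- win
  summary
}
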