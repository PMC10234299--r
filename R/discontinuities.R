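#' Intra-contig alignment discontinuities
#'
#' Walks query-adjacent alignment pairs of each contig (on one chromosome)
#' and measures the gap between them on both axes: the target gap in
#' reference coordinates and the query gap (unaligned bases) in contig
#' coordinates, strand-aware on the contig's forward coordinate system. A
#' pair is reported when its target gap is non-negative and below
#' `max_discontinuity` (default 1 Mbp) and at least one of the two gaps is
#' positive. Classification: `contraction` when the target gap exceeds the
#' query gap, `expansion` when it is smaller (a pure insertion has target gap
#' 0), `neutral` when equal; the event size is the absolute difference.
#' Pairs with overlapping query intervals (split/supplementary artifacts) are
#' skipped with a warning; pairs spanning a strand switch are evaluated and
#' flagged `strand_switch`.
#'
#' @param aln Grouped alignment tibble ([group_alignments()]).
#' @param t An [asm_thresholds()] object.
#' @return Tibble `sample, hap, contig, chrom, start, end, target_gap,
#'   query_gap, class, event_size, unaligned, strand_switch` (the interval is
#'   the target gap, 0-based half-open; zero-width for point insertions).
#' @export
find_discontinuities <- function(aln, t = asm_thresholds()) {
  check_alignments(aln)
  aln <- group_alignments(aln)
  skipped <- 0L
  out <- aln %>%
    group_by(.data$sample, .data$hap, .data$qname) %>%
    group_map(function(g, key) {
      if (nrow(g) < 2) return(NULL)
      i <- seq_len(nrow(g) - 1)
      same_chrom <- g$tname[i] == g$tname[i + 1]
      qgap <- g$qstart[i + 1] - g$qend[i]
      neg <- same_chrom & qgap < 0
      skipped <<- skipped + sum(neg)
      s1 <- g$strand[i]
      s2 <- g$strand[i + 1]
      # target gap on the contig's forward coordinate system
      tgap <- dplyr::case_when(
        s1 == "+" & s2 == "+" ~ g$tstart[i + 1] - g$tend[i],
        s1 == "-" & s2 == "-" ~ g$tstart[i] - g$tend[i + 1],
        TRUE ~ pmax(g$tstart[i], g$tstart[i + 1]) -
          pmin(g$tend[i], g$tend[i + 1])
      )
      keep <- same_chrom & !neg & tgap >= 0 &
        tgap < t$max_discontinuity & (tgap > 0 | qgap > 0)
      if (!any(keep)) return(NULL)
      k <- which(keep)
      gstart <- pmin(g$tend[k], g$tend[k + 1])
      tibble(
        sample = key$sample, hap = key$hap, contig = key$qname,
        chrom = g$tname[k],
        start = gstart,
        end = gstart + tgap[k],
        target_gap = tgap[k], query_gap = qgap[k],
        class = dplyr::case_when(
          tgap[k] > qgap[k] ~ "contraction",
          tgap[k] < qgap[k] ~ "expansion",
          TRUE ~ "neutral"),
        event_size = abs(tgap[k] - qgap[k]),
        unaligned = qgap[k],
        strand_switch = s1[k] != s2[k]
      )
    }) %>%
    bind_rows()
  if (skipped > 0) {
    warning(skipped, " alignment pair(s) with overlapping query intervals ",
            "skipped")
  }
  if (nrow(out) == 0) {
    out <- tibble(sample = character(), hap = character(),
                  contig = character(), chrom = character(),
                  start = numeric(), end = numeric(), target_gap = numeric(),
                  query_gap = numeric(), class = character(),
                  event_size = numeric(), unaligned = numeric(),
                  strand_switch = logical())
  }
  out
}

#' Flag discontinuities near centromeric satellite DNA
#'
#' Sets `censat_flag` on every discontinuity whose target interval lies
#' within `censat_pad` (default 1 Mbp) of a centromeric satellite interval.
#'
#' @param discs Output of [find_discontinuities()].
#' @param censat Centromeric satellite track (`chrom, start, end`).
#' @param t An [asm_thresholds()] object.
#' @return `discs` with a logical `censat_flag` column.
#' @export
censat_flagging <- function(discs, censat, t = asm_thresholds()) {
  if (nrow(discs) == 0) return(discs %>% mutate(censat_flag = logical(0)))
  d_left <- point_track_distance(discs$chrom, discs$start, censat)
  d_right <- point_track_distance(discs$chrom, pmax(discs$start,
                                                    discs$end - 1), censat)
  discs %>% mutate(censat_flag = pmin(d_left, d_right) <= t$censat_pad)
}

#' Per-assembly unaligned-base summary
#'
#' Sums the unaligned (query-gap) bases of each haploid assembly, split by
#' the CENSAT flag, and reports them as percentages of the assembly length.
#'
#' @param discs Output of [censat_flagging()].
#' @param assembly_lengths Tibble `sample, hap, length` (total assembly bp).
#' @return Tibble `sample, hap, unaligned_censat, unaligned_outside,
#'   pct_censat, pct_outside, total_unaligned`.
#' @export
summarize_unaligned <- function(discs, assembly_lengths) {
  base <- assembly_lengths %>%
    dplyr::select("sample", "hap", "length")
  sums <- discs %>%
    group_by(.data$sample, .data$hap) %>%
    summarise(
      unaligned_censat = sum(.data$query_gap[.data$censat_flag]),
      unaligned_outside = sum(.data$query_gap[!.data$censat_flag]),
      .groups = "drop")
  base %>%
    left_join(sums, by = c("sample", "hap")) %>%
    mutate(
      unaligned_censat = dplyr::coalesce(.data$unaligned_censat, 0),
      unaligned_outside = dplyr::coalesce(.data$unaligned_outside, 0),
      pct_censat = 100 * .data$unaligned_censat / .data$length,
      pct_outside = 100 * .data$unaligned_outside / .data$length,
      total_unaligned = .data$unaligned_censat + .data$unaligned_outside)
}

#' Recurrent structural-variant regions
#'
#' Filters pooled discontinuities to contractions/expansions with event size
#' at least `recur_min_event` (default 100 bp), merges overlapping target
#' intervals per class, and keeps merged regions supported by at least
#' `recur_min_assemblies` (default 5) distinct haploid assemblies. Point
#' insertions are widened to 1 bp for the overlap computation.
#'
#' @param discs Pooled discontinuity tibble.
#' @param t An [asm_thresholds()] object.
#' @return Tibble `chrom, start, end, class, n_assemblies, event_sizes`
#'   (list-column of the supporting per-assembly event sizes).
#' @export
recurrent_sv_regions <- function(discs, t = asm_thresholds()) {
  cand <- discs %>%
    filter(.data$class %in% c("contraction", "expansion"),
           .data$event_size >= t$recur_min_event)
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  class = character(), n_assemblies = integer(),
                  event_sizes = list())
  if (nrow(cand) == 0) return(empty)
  asm <- assembly_id(cand$sample, cand$hap)
  out <- list()
  for (cl in unique(cand$class)) {
    sub <- which(cand$class == cl)
    merged <- merge_intervals(cand[sub, , drop = FALSE])
    merged$class <- cl
    merged$n_assemblies <- vapply(merged$.members, function(m)
      dplyr::n_distinct(asm[sub][m]), integer(1))
    merged$event_sizes <- lapply(merged$.members, function(m)
      cand$event_size[sub][m])
    out[[cl]] <- merged %>% dplyr::select(-".members")
  }
  bind_rows(out) %>%
    filter(.data$n_assemblies >= t$recur_min_assemblies) %>%
    arrange(.data$chrom, .data$start)
}
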