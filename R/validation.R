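#' Long-read spanning of assembly gaps
#'
#' A read spans a gap when its alignment interval strictly contains the gap
#' (`read start < gap start` and `read end > gap end`) and its mapping
#' quality is at least `min_mapq`. A gap is `spanned` when at least
#' `span_min_reads` (default 10) such reads exist — evidence the gap could
#' be closed with the longer read type.
#'
#' @param gaps Gap tibble ([report_gaps()]), columns `chrom, start, end`.
#' @param reads Read-alignment tibble `chrom, start, end, mapq` (BED-like,
#'   0-based half-open).
#' @param t An [asm_thresholds()] object.
#' @return `gaps` plus `n_spanning` and logical `spanned`.
#' @export
gap_spanning <- function(gaps, reads, t = asm_thresholds()) {
  reads <- reads %>% filter(.data$mapq >= t$min_mapq)
  if (nrow(gaps) == 0) {
    return(gaps %>% mutate(n_spanning = integer(0), spanned = logical(0)))
  }
  n <- integer(nrow(gaps))
  if (nrow(reads) > 0) {
    hits <- GenomicRanges::findOverlaps(as_granges0(gaps),
                                        as_granges0(reads), type = "within")
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    strict <- reads$start[si] < gaps$start[qi] & reads$end[si] > gaps$end[qi]
    tb <- table(qi[strict])
    n[as.integer(names(tb))] <- as.integer(tb)
  }
  gaps %>% mutate(n_spanning = n, spanned = n >= t$span_min_reads)
}

#' Phasing concordance in megabase blocks
#'
#' Splits each chromosome into `phase_block`-sized blocks (default 1 Mbp)
#' and assigns every block of each test haplotype to truth haplotype H1 or
#' H2 by majority vote over the informative (truth-heterozygous) sites it
#' contains; ties and empty blocks are unassigned. Because the truth
#' labelling of haplotypes is arbitrary, each test haplotype is first
#' anchored to the truth haplotype it matches at the majority of informative
#' sites genome-wide; a block is concordant when its assignment agrees with
#' that anchor, so relabelling the truth haplotypes leaves the concordance
#' unchanged. Large-scale switch errors appear as maximal runs of
#' consecutive discordant blocks, which are reported per haplotype.
#'
#' @param truth Tibble `chrom, pos, h1, h2` of phased truth variants
#'   (alleles per truth haplotype).
#' @param test Tibble `chrom, pos, h1, h2` of the assembly's per-haplotype
#'   alleles at (a subset of) the same positions.
#' @param t An [asm_thresholds()] object.
#' @return An object of class `asm_phasing`: the per-block tibble (`chrom,
#'   block, start, end, hap, n_sites, n_match_h1, n_match_h2, assigned,
#'   concordant`), with per-chromosome summaries, switch runs and the
#'   overall concordance available via [tidy()]/[glance()] or the
#'   `by_chrom`/`switch_runs`/`overall` attributes.
#' @export
phase_concordance <- function(truth, test, t = asm_thresholds()) {
  joined <- dplyr::inner_join(truth, test, by = c("chrom", "pos"),
                              suffix = c("_truth", "_test"))
  joined <- joined %>% filter(.data$h1_truth != .data$h2_truth)
  if (nrow(joined) == 0) {
    stop("no overlapping informative positions between truth and test",
         call. = FALSE)
  }
  blocks <- purrr::map_dfr(c("h1", "h2"), function(hp) {
    joined %>%
      mutate(block = floor(.data$pos / t$phase_block),
             test_allele = .data[[paste0(hp, "_test")]]) %>%
      group_by(.data$chrom, .data$block) %>%
      summarise(
        n_sites = dplyr::n(),
        n_match_h1 = sum(.data$test_allele == .data$h1_truth),
        n_match_h2 = sum(.data$test_allele == .data$h2_truth),
        .groups = "drop") %>%
      mutate(
        hap = toupper(hp),
        start = .data$block * t$phase_block,
        end = (.data$block + 1) * t$phase_block,
        assigned = dplyr::case_when(
          .data$n_match_h1 > .data$n_match_h2 ~ "H1",
          .data$n_match_h2 > .data$n_match_h1 ~ "H2",
          TRUE ~ "unassigned")) %>%
      mutate(
        # genome-wide majority anchors this test haplotype to a truth label
        anchor = {
          tot1 <- sum(.data$n_match_h1)
          tot2 <- sum(.data$n_match_h2)
          if (tot1 == tot2) toupper(hp) else if (tot1 > tot2) "H1" else "H2"
        },
        concordant = ifelse(.data$assigned == "unassigned", NA,
                            .data$assigned == .data$anchor))
  }) %>%
    dplyr::select("chrom", "block", "start", "end", "hap", "n_sites",
                  "n_match_h1", "n_match_h2", "assigned", "anchor",
                  "concordant") %>%
    arrange(.data$hap, .data$chrom, .data$block)

  by_chrom <- blocks %>%
    filter(!is.na(.data$concordant)) %>%
    group_by(.data$chrom, .data$hap) %>%
    summarise(n_assigned = dplyr::n(),
              n_concordant = sum(.data$concordant),
              concordance = 100 * mean(.data$concordant),
              .groups = "drop")

  switch_runs <- blocks %>%
    filter(!is.na(.data$concordant)) %>%
    group_by(.data$hap, .data$chrom) %>%
    arrange(.data$block, .by_group = TRUE) %>%
    group_map(function(g, key) {
      if (!any(!g$concordant)) return(NULL)
      brk <- cumsum(c(TRUE, diff(g$block) != 1 |
                        g$concordant[-nrow(g)] != g$concordant[-1]))
      runs <- tibble(disc = !g$concordant, run = brk, block = g$block,
                     start = g$start, end = g$end) %>%
        group_by(.data$run) %>%
        summarise(disc = .data$disc[1], n_blocks = dplyr::n(),
                  start = min(.data$start), end = max(.data$end),
                  first_block = min(.data$block), .groups = "drop") %>%
        filter(.data$disc)
      runs %>% mutate(hap = key$hap, chrom = key$chrom) %>%
        dplyr::select("hap", "chrom", "first_block", "start", "end",
                      "n_blocks")
    }) %>%
    bind_rows()

  overall <- blocks %>%
    filter(!is.na(.data$concordant)) %>%
    summarise(n_blocks = dplyr::n(),
              n_assigned = dplyr::n(),
              concordance = 100 * mean(.data$concordant))

  structure(blocks,
            by_chrom = by_chrom,
            switch_runs = switch_runs,
            overall = overall,
            class = c("asm_phasing", class(blocks)))
}
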