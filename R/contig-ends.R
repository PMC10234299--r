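#' Simple contig ends
#'
#' For each contig, walking inward from each contig extremity (query
#' coordinate order), the first alignment whose reference span is at least
#' `min_simple_end_aln` (default 25 kbp) defines that side's end. The end
#' position is the target coordinate of the alignment's outer boundary on
#' that side, strand-aware: on the left side a `+` alignment anchors at
#' `tstart` and a `-` alignment at `tend`, and conversely on the right side.
#' One alignment may serve both sides. Contigs with no qualifying alignment
#' are listed in the `skipped` attribute rather than raising an error.
#'
#' @param aln Grouped alignment tibble (see [group_alignments()]).
#' @param t An [asm_thresholds()] object.
#' @return Tibble with columns `sample, hap, contig, side, chrom, pos,
#'   aln_len, kind`; attribute `skipped` lists contigs without a qualifying
#'   alignment.
#' @export
simple_ends <- function(aln, t = asm_thresholds()) {
  contig_end_scan(aln, min_span = t$min_simple_end_aln, kind = "simple")
}

contig_end_scan <- function(aln, min_span, kind) {
  check_alignments(aln)
  aln <- group_alignments(aln)
  res <- aln %>%
    mutate(tspan = .data$tend - .data$tstart) %>%
    group_by(.data$sample, .data$hap, .data$qname) %>%
    group_map(function(g, key) {
      ok <- which(g$tspan >= min_span)
      if (length(ok) == 0) {
        return(tibble(sample = key$sample, hap = key$hap,
                      contig = key$qname, side = NA_character_,
                      chrom = NA_character_, pos = NA_real_,
                      aln_len = NA_real_, kind = kind))
      }
      li <- ok[1]
      ri <- ok[length(ok)]
      tibble(
        sample = key$sample, hap = key$hap, contig = key$qname,
        side = c("left", "right"),
        chrom = c(g$tname[li], g$tname[ri]),
        pos = c(if (g$strand[li] == "+") g$tstart[li] else g$tend[li],
                if (g$strand[ri] == "+") g$tend[ri] else g$tstart[ri]),
        aln_len = c(g$tspan[li], g$tspan[ri]),
        kind = kind
      )
    }) %>%
    bind_rows()
  skipped <- res %>% filter(is.na(.data$side)) %>%
    dplyr::distinct(.data$sample, .data$hap, .data$contig)
  out <- res %>% filter(!is.na(.data$side))
  attr(out, "skipped") <- skipped
  out
}

# exact minimal partition of one contig's (query-ordered) alignments into
# pieces whose reference span is at most `limit`; ties broken by the largest
# total target jump at the cut points, then by earliest cuts. Single-alignment
# pieces are always feasible.
split_contig_pieces <- function(tstart, tend, limit) {
  n <- length(tstart)
  if (n == 1) return(list(1L))
  jump <- pmax(0, pmax(tstart[-n] - tend[-1], tstart[-1] - tend[-n]))
  # feasible[i, j]: alignments i..j form an allowed piece
  best_k <- rep(Inf, n + 1)   # min pieces for prefix of length j
  best_j <- rep(-Inf, n + 1)  # max jump sum at cuts among minimal partitions
  best_cut <- vector("list", n + 1)
  best_k[1] <- 0
  best_j[1] <- 0
  best_cut[[1]] <- integer()
  for (j in seq_len(n)) {
    for (i in seq_len(j)) {
      span <- max(tend[i:j]) - min(tstart[i:j])
      if (i != j && span > limit) next
      if (!is.finite(best_k[i])) next
      k <- best_k[i] + 1
      js <- best_j[i] + if (i > 1) jump[i - 1] else 0
      better <- k < best_k[j + 1] ||
        (k == best_k[j + 1] && js > best_j[j + 1])
      if (better) {
        best_k[j + 1] <- k
        best_j[j + 1] <- js
        best_cut[[j + 1]] <- if (i > 1) c(best_cut[[i]], i - 1L)
                             else best_cut[[i]]
      }
    }
  }
  cuts <- best_cut[[n + 1]]
  bounds <- c(0L, sort(cuts), n)
  lapply(seq_len(length(bounds) - 1),
         function(p) (bounds[p] + 1L):bounds[p + 1L])
}

#' Contig-end alignments and contig pieces
#'
#' Extracts terminal contig alignments of at least `min_ctg_end_aln` (default
#' 50 kbp) on the reference. When the reference span from the leftmost to the
#' rightmost alignment of a contig exceeds the contig length by more than
#' `overextension_frac` (default 5%), the contig is partitioned into the
#' minimal number of pieces — cut at the largest target-coordinate jumps
#' between query-adjacent alignments — such that each piece satisfies the
#' span constraint. Contigs aligning to several chromosomes are always split
#' at chromosome boundaries first. Each piece reports its own left/right end
#' from its outermost qualifying terminal alignments; pieces with no
#' qualifying alignment keep `NA` end positions.
#'
#' @inheritParams simple_ends
#' @return Tibble with one row per contig piece: `sample, hap, contig, piece,
#'   chrom, span_start, span_end, span, contig_len, n_aln, left_pos,
#'   right_pos, left_aln_len, right_aln_len`.
#' @export
end_alignments <- function(aln, t = asm_thresholds()) {
  check_alignments(aln)
  aln <- group_alignments(aln)
  aln %>%
    group_by(.data$sample, .data$hap, .data$qname, .data$tname) %>%
    group_map(function(g, key) {
      limit <- g$qlen[1] * (1 + t$overextension_frac)
      pieces <- split_contig_pieces(g$tstart, g$tend, limit)
      purrr::map_dfr(seq_along(pieces), function(p) {
        gp <- g[pieces[[p]], , drop = FALSE]
        span_start <- min(gp$tstart)
        span_end <- max(gp$tend)
        ok <- which((gp$tend - gp$tstart) >= t$min_ctg_end_aln)
        li <- if (length(ok) > 0) ok[1] else NA_integer_
        ri <- if (length(ok) > 0) ok[length(ok)] else NA_integer_
        tibble(
          sample = key$sample, hap = key$hap, contig = key$qname,
          piece = p, chrom = key$tname,
          span_start = span_start, span_end = span_end,
          span = span_end - span_start, contig_len = g$qlen[1],
          n_aln = nrow(gp),
          left_pos = if (is.na(li)) NA_real_ else
            if (gp$strand[li] == "+") gp$tstart[li] else gp$tend[li],
          right_pos = if (is.na(ri)) NA_real_ else
            if (gp$strand[ri] == "+") gp$tend[ri] else gp$tstart[ri],
          left_aln_len = if (is.na(li)) NA_real_ else
            gp$tend[li] - gp$tstart[li],
          right_aln_len = if (is.na(ri)) NA_real_ else
            gp$tend[ri] - gp$tstart[ri]
        )
      })
    }) %>%
    bind_rows()
}

#' Contig-end alignments as end points
#'
#' Flattens [end_alignments()] pieces into one row per reported end, in the
#' same shape as [simple_ends()] (with `kind = "end_alignment"`).
#'
#' @param pieces Output of [end_alignments()].
#' @return Tibble `sample, hap, contig, piece, side, chrom, pos, aln_len,
#'   kind`.
#' @export
piece_ends <- function(pieces) {
  bind_rows(
    pieces %>%
      filter(!is.na(.data$left_pos)) %>%
      transmute(.data$sample, .data$hap, .data$contig, .data$piece,
                side = "left", .data$chrom, pos = .data$left_pos,
                aln_len = .data$left_aln_len, kind = "end_alignment"),
    pieces %>%
      filter(!is.na(.data$right_pos)) %>%
      transmute(.data$sample, .data$hap, .data$contig, .data$piece,
                side = "right", .data$chrom, pos = .data$right_pos,
                aln_len = .data$right_aln_len, kind = "end_alignment")
  )
}

#' Assembly gaps between subsequent contig-end alignments
#'
#' Within one (sample, haplotype), contig pieces are sorted per chromosome by
#' their left-end position; every adjacent pair whose end alignments leave
#' reference space between them (`right end of piece i < left end of piece
#' i+1`) yields an assembly-gap region. Overlapping or abutting pieces emit
#' nothing. Pieces without qualifying end alignments are ignored.
#'
#' @param pieces Output of [end_alignments()] for a single (sample,
#'   haplotype); mixing haplotypes is a usage error because gaps are defined
#'   per haploid assembly.
#' @return Tibble `chrom, start, end, left_contig, left_piece, right_contig,
#'   right_piece, sample, hap` (0-based half-open intervals).
#' @export
report_gaps <- function(pieces) {
  if (nrow(pieces) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  left_contig = character(), left_piece = integer(),
                  right_contig = character(), right_piece = integer(),
                  sample = character(), hap = character()))
  }
  if (nrow(dplyr::distinct(pieces, .data$sample, .data$hap)) > 1) {
    stop("usage error: report_gaps() expects pieces from a single ",
         "(sample, haplotype); split first, e.g. with group_split()",
         call. = FALSE)
  }
  pieces %>%
    filter(!is.na(.data$left_pos), !is.na(.data$right_pos)) %>%
    mutate(lo = pmin(.data$left_pos, .data$right_pos),
           hi = pmax(.data$left_pos, .data$right_pos)) %>%
    group_by(.data$chrom) %>%
    arrange(.data$lo, .by_group = TRUE) %>%
    group_map(function(g, key) {
      if (nrow(g) < 2) return(NULL)
      # running maximum of right ends: a piece wholly inside another piece's
      # span (e.g. an embedded contig) must not delimit a gap
      runmax <- cummax(g$hi)
      flank <- vapply(seq_len(nrow(g)),
                      function(i) which(g$hi == runmax[i])[1], 0L)
      i <- seq_len(nrow(g) - 1)
      gap <- tibble(
        chrom = key$chrom,
        start = runmax[i],
        end = g$lo[i + 1],
        left_contig = g$contig[flank[i]], left_piece = g$piece[flank[i]],
        right_contig = g$contig[i + 1], right_piece = g$piece[i + 1],
        sample = g$sample[i], hap = g$hap[i]
      )
      gap %>% filter(.data$start < .data$end)
    }) %>%
    bind_rows()
}

#' Gaps for every (sample, haplotype) in one call
#'
#' Convenience wrapper applying [report_gaps()] per haploid assembly.
#'
#' @param pieces Output of [end_alignments()], any number of assemblies.
#' @return Row-bound gap tibble (see [report_gaps()]).
#' @export
report_gaps_all <- function(pieces) {
  pieces %>%
    group_by(.data$sample, .data$hap) %>%
    group_split() %>%
    purrr::map_dfr(report_gaps)
}

#' Contigs whose reference span exceeds their length by more than 5%
#'
#' One row per offending contig/chromosome with the end-to-end reference
#' span, contig length and their ratio. The comparison is strictly greater
#' than `1 + overextension_frac`.
#'
#' @inheritParams simple_ends
#' @return Tibble `sample, hap, contig, chrom, span, contig_len, ratio`.
#' @export
overextended_contigs <- function(aln, t = asm_thresholds()) {
  check_alignments(aln)
  aln %>%
    group_by(.data$sample, .data$hap, contig = .data$qname,
             chrom = .data$tname) %>%
    summarise(span = max(.data$tend) - min(.data$tstart),
              contig_len = .data$qlen[1], .groups = "drop") %>%
    mutate(ratio = .data$span / .data$contig_len) %>%
    filter(.data$ratio > 1 + t$overextension_frac) %>%
    arrange(.data$sample, .data$hap, .data$contig)
}
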