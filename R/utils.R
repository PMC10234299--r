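# internal helpers shared across modules

#' @importFrom rlang .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# tibble of intervals (chrom/start/end, 0-based half-open) -> GRanges (1-based)
as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1,
                              end = pmax(x$end, x$start + 1))
  )
}

# minimum distance from each point (chrom, pos; 0-based) to intervals of a
# track tibble (chrom/start/end, 0-based half-open); Inf when the chromosome
# carries no track interval. Zero-width intervals are treated as points.
point_track_distance <- function(chrom, pos, track) {
  out <- rep(Inf, length(pos))
  if (is.null(track) || nrow(track) == 0) return(out)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    tk <- track[track$chrom == ch, , drop = FALSE]
    if (nrow(tk) == 0) next
    q <- IRanges::IRanges(start = pos[idx] + 1, width = 1)
    s <- IRanges::IRanges(start = tk$start + 1,
                          end = pmax(tk$end, tk$start + 1))
    hit <- IRanges::distanceToNearest(q, s)
    d <- rep(Inf, length(idx))
    d[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
    out[idx] <- d
  }
  out
}

# merge overlapping/abutting 0-based half-open intervals; returns tibble with
# chrom/start/end plus the row indices of `x` contributing to each merged
# region (list-column .members)
merge_intervals <- function(x, min_width_one = TRUE) {
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  .members = list()))
  }
  w <- if (min_width_one) pmax(x$end, x$start + 1) else x$end
  gr <- GenomicRanges::GRanges(x$chrom,
                               IRanges::IRanges(x$start + 1, w))
  red <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(gr, red)
  members <- split(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov))
  tibble(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1,
    end = as.numeric(GenomicRanges::end(red)),
    .members = unname(members[as.character(seq_along(red))])
  )
}

# validate an alignment tibble has the canonical columns
check_alignments <- function(aln) {
  need <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
            "tstart", "tend", "nmatch", "alen", "mapq", "sample", "hap")
  missing <- setdiff(need, names(aln))
  if (length(missing) > 0) {
    stop("alignment table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(aln)
}

assembly_id <- function(sample, hap) paste(sample, hap, sep = ".")
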