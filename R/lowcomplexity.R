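# dinucleotide machinery: binned counts, Z-score tracts, content windows

# logical vector over positions 1..(n-1): pair (i, i+1) equals one of `dinucs`
dinuc_pair_match <- function(chars, dinucs) {
  n <- length(chars)
  if (n < 2) return(logical(0))
  a <- chars[-n]
  b <- chars[-1]
  hit <- rep(FALSE, n - 1)
  for (d in dinucs) {
    hit <- hit | (a == substr(d, 1, 1) & b == substr(d, 2, 2))
  }
  hit
}

#' Binned dinucleotide counts along a sequence
#'
#' Counts overlapping occurrences of each tracked dinucleotide (default TA,
#' TC and GA) in non-overlapping bins (default 100 bp). An occurrence is
#' counted in a bin only when both of its bases lie inside the bin;
#' occurrences straddling a bin boundary are counted in neither bin and their
#' number is recorded in the `straddle` attribute. The final partial bin is
#' kept with its true width.
#'
#' @param seq A DNA string (characters in A, C, G, T, N).
#' @param t An [asm_thresholds()] object (bin size = `dinuc_bin`).
#' @param dinucs Tracked dinucleotides.
#' @return A tibble of class `dinuc_profile` with columns `bin, start, end,
#'   width` and one count column per dinucleotide; attributes `bin_size`,
#'   `seq_length` and `straddle` (named straddle counts).
#' @export
dinucleotide_profile <- function(seq, t = asm_thresholds(),
                                 dinucs = c("TA", "TC", "GA")) {
  if (length(seq) != 1 || !nzchar(seq)) {
    stop("empty sequence", call. = FALSE)
  }
  n <- nchar(seq)
  if (n < 2) stop("sequence must be at least 2 bp", call. = FALSE)
  bin <- t$dinuc_bin
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n_bins <- ceiling(n / bin)
  starts <- (seq_len(n_bins) - 1) * bin
  ends <- pmin(starts + bin, n)
  out <- tibble(bin = seq_len(n_bins), start = starts, end = ends,
                width = ends - starts)
  # pair at position i (1-based, covering i..i+1) belongs to bin of i iff
  # i+1 is in the same bin
  pos <- seq_len(n - 1)
  bin_of_first <- (pos - 1) %/% bin + 1
  bin_of_second <- pos %/% bin + 1
  inside <- bin_of_first == bin_of_second
  straddle <- stats::setNames(numeric(length(dinucs)), dinucs)
  for (d in dinucs) {
    hit <- dinuc_pair_match(chars, d)
    counts <- tabulate(bin_of_first[hit & inside], nbins = n_bins)
    straddle[d] <- sum(hit & !inside)
    out[[d]] <- counts
  }
  attr(out, "bin_size") <- bin
  attr(out, "seq_length") <- n
  attr(out, "straddle") <- straddle
  attr(out, "dinucs") <- dinucs
  class(out) <- c("dinuc_profile", class(out))
  out
}

#' Dinucleotide-enriched tracts from a binned profile
#'
#' Per dinucleotide, bin counts are transformed to Z-scores over all bins of
#' the sequence; bins with `Z >= z_cutoff` (default 1.96) are enriched, and
#' maximal runs of enriched bins form tracts whose size is the run length
#' times the bin size. A dinucleotide whose bin counts have zero standard
#' deviation yields no tracts (recorded in the `degenerate` attribute).
#'
#' @param profile A [dinucleotide_profile()].
#' @param t An [asm_thresholds()] object.
#' @return Tibble `dinuc, start, end, size, n_bins, max_z`; attribute
#'   `degenerate` names dinucleotides with zero variance.
#' @export
enriched_tracts <- function(profile, t = asm_thresholds()) {
  stopifnot(inherits(profile, "dinuc_profile"))
  if (nrow(profile) < 2) {
    stop("need at least 2 bins to compute Z-scores", call. = FALSE)
  }
  bin <- attr(profile, "bin_size")
  dinucs <- attr(profile, "dinucs")
  degenerate <- character()
  res <- list()
  for (d in dinucs) {
    x <- profile[[d]]
    s <- stats::sd(x)
    if (is.na(s) || s == 0) {
      degenerate <- c(degenerate, d)
      next
    }
    z <- (x - mean(x)) / s
    flagged <- z >= t$z_cutoff
    r <- rle(flagged)
    stops <- cumsum(r$lengths)
    starts_i <- stops - r$lengths + 1
    runs <- which(r$values)
    if (length(runs) == 0) next
    res[[d]] <- tibble(
      dinuc = d,
      start = profile$start[starts_i[runs]],
      end = profile$start[starts_i[runs]] + r$lengths[runs] * bin,
      size = r$lengths[runs] * bin,
      n_bins = r$lengths[runs],
      max_z = vapply(runs, function(k)
        max(z[starts_i[k]:stops[k]]), 0)
    )
  }
  out <- bind_rows(res)
  if (length(res) == 0) {
    out <- tibble(dinuc = character(), start = numeric(), end = numeric(),
                  size = numeric(), n_bins = integer(), max_z = numeric())
  }
  attr(out, "degenerate") <- degenerate
  out
}

# sliding-window dinucleotide-content screen shared by gatc/at windows;
# content = fraction of bases covered by occurrences of the dinucleotides
content_windows <- function(seqs, dinucs, window, step, frac) {
  if (is.character(seqs) && is.null(names(seqs))) {
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  res <- list()
  for (ch in names(seqs)) {
    s <- toupper(seqs[[ch]])
    n <- nchar(s)
    if (n < window) next
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    pair <- dinuc_pair_match(chars, dinucs)
    covered <- logical(n)
    covered[which(pair)] <- TRUE
    covered[which(pair) + 1] <- TRUE
    cum <- cumsum(c(0, covered))
    starts <- seq(0, n - window, by = step)
    content <- (cum[starts + window + 1] - cum[starts + 1]) / window
    flagged <- content >= frac
    if (!any(flagged)) next
    win <- tibble(chrom = ch, start = starts[flagged],
                  end = starts[flagged] + window)
    res[[ch]] <- merge_intervals(win) %>%
      dplyr::select("chrom", "start", "end")
  }
  if (length(res) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  bind_rows(res)
}

#' High-GA/TC windows
#'
#' Flags sliding windows (default 1 kbp, 100-bp step) in which at least
#' `gatc_frac` (default 80%) of bases participate in GA or TC dinucleotide
#' occurrences, and merges overlapping flagged windows into one interval per
#' region. Pure GA or TC tracts score 1.0 on this measure; uniform-random
#' sequence scores about 0.25, so the 80% threshold separates them cleanly.
#'
#' @param seqs Named character vector of sequences (e.g. the reference
#'   chromosomes) or a single string.
#' @param t An [asm_thresholds()] object.
#' @param step Window step in bp.
#' @return Tibble `chrom, start, end` of merged flagged windows.
#' @export
gatc_windows <- function(seqs, t = asm_thresholds(), step = 100) {
  content_windows(seqs, c("GA", "TC"), t$gatc_window, step, t$gatc_frac)
}

#' High-AT windows
#'
#' Same machinery as [gatc_windows()] applied to the AT/TA dinucleotide pair,
#' with the same content threshold by default.
#'
#' @inheritParams gatc_windows
#' @export
at_windows <- function(seqs, t = asm_thresholds(), step = 100) {
  content_windows(seqs, c("AT", "TA"), t$gatc_window, step, t$gatc_frac)
}
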