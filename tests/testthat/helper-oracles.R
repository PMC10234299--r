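# independent brute-force oracles used to cross-check the implementations

# all optimal partitions of alignments 1..n into contiguous pieces with
# reference span <= limit (single-alignment pieces always allowed):
# minimal piece count first, then maximal total target jump at the cuts.
# Returns a list of integer cut-point sets (cut after alignment i).
oracle_partitions <- function(tstart, tend, limit) {
  n <- length(tstart)
  if (n == 1) return(list(integer()))
  jump <- pmax(0, pmax(tstart[-n] - tend[-1], tstart[-1] - tend[-n]))
  feasible <- function(i, j) {
    i == j || (max(tend[i:j]) - min(tstart[i:j])) <= limit
  }
  best <- NULL
  best_k <- Inf
  best_j <- -Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    ok <- all(vapply(seq_len(length(bounds) - 1), function(p)
      feasible(bounds[p] + 1, bounds[p + 1]), logical(1)))
    if (!ok) next
    k <- length(cuts) + 1
    js <- sum(jump[cuts])
    if (k < best_k || (k == best_k && js > best_j)) {
      best <- list(cuts)
      best_k <- k
      best_j <- js
    } else if (k == best_k && js == best_j) {
      best <- c(best, list(cuts))
    }
  }
  best
}

# per-base depth over [lo, hi) for 0-based half-open intervals
oracle_depth_regions <- function(starts, ends, min_depth = 2) {
  lo <- min(starts)
  hi <- max(ends)
  depth <- integer(hi - lo)
  for (k in seq_along(starts)) {
    idx <- seq.int(starts[k] - lo + 1, ends[k] - lo)
    depth[idx] <- depth[idx] + 1
  }
  high <- depth >= min_depth
  r <- rle(high)
  stop_i <- cumsum(r$lengths)
  start_i <- stop_i - r$lengths + 1
  keep <- which(r$values)
  tibble::tibble(start = lo + start_i[keep] - 1, end = lo + stop_i[keep])
}

# nearest-qualifying-by-priority label assignment for one end
oracle_label <- function(chrom, pos, tracks, seqlengths, t, priority) {
  dist_to <- function(track) {
    tk <- track[track$chrom == chrom, , drop = FALSE]
    if (nrow(tk) == 0) return(Inf)
    # intervening-base count, as IRanges::distance (adjacent = 0)
    min(vapply(seq_len(nrow(tk)), function(i) {
      e <- max(tk$end[i], tk$start[i] + 1)
      if (pos >= tk$start[i] && pos < e) 0
      else if (pos >= e) pos - e
      else tk$start[i] - pos - 1
    }, 0))
  }
  d <- vapply(names(tracks), function(nm) dist_to(tracks[[nm]]), 0)
  for (lab in priority) {
    if (lab == "chromosome_end") {
      if (min(pos, seqlengths[[chrom]] - pos) <= t$chrom_end_window)
        return(lab)
    } else if (lab == "SD+GA/TC") {
      if (all(c("SD", "GA/TC") %in% names(d)) &&
          d[["SD"]] <= t$proximity && d[["GA/TC"]] <= t$proximity)
        return(lab)
    } else if (lab %in% names(d)) {
      if (d[[lab]] <= t$proximity) return(lab)
    }
  }
  NA_character_
}

# direct overlapping-occurrence count of dinucleotide `d` in a string
oracle_dinuc_count <- function(seq, d) {
  n <- nchar(seq)
  if (n < 2) return(0L)
  sum(vapply(seq_len(n - 1), function(i)
    substr(seq, i, i + 1) == d, logical(1)))
}

# naive merge of same-class 0-based intervals + distinct-assembly counts
oracle_merge_support <- function(df) {
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  out <- list()
  for (ch in unique(df$chrom)) {
    g <- df[df$chrom == ch, , drop = FALSE]
    e <- pmax(g$end, g$start + 1)
    cur_s <- g$start[1]; cur_e <- e[1]; members <- 1
    flush_row <- function(s, en, m) {
      tibble::tibble(chrom = ch, start = s, end = en,
                     n_assemblies = length(unique(g$asm[m])))
    }
    rows <- list()
    for (i in seq_len(nrow(g))[-1]) {
      if (g$start[i] <= cur_e) {  # overlapping or abutting, as reduce()
        cur_e <- max(cur_e, e[i]); members <- c(members, i)
      } else {
        rows[[length(rows) + 1]] <- flush_row(cur_s, cur_e, members)
        cur_s <- g$start[i]; cur_e <- e[i]; members <- i
      }
    }
    rows[[length(rows) + 1]] <- flush_row(cur_s, cur_e, members)
    out[[ch]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(out)
}
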