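#' Priority-ordered annotation of contig ends
#'
#' Assigns exactly one label to every contig end: the highest-priority
#' feature track lying within `proximity` (default 10 kbp) of the end.
#' Chromosome ends (within `chrom_end_window`, default 100 kbp, of a
#' reference chromosome terminus) take implicit top priority. When the
#' composite label `"SD+GA/TC"` is part of the priority order, ends within
#' proximity of both an SD and a GA/TC window get that combined label rather
#' than plain SD. Ends matching no track are `poisson_end` if they occur in
#' only one haplotype (see [poisson_ends()]) and `other` otherwise, so
#' category counts always sum to the total number of ends.
#'
#' @param ends End tibble from [simple_ends()] or [piece_ends()], pooled
#'   across the assemblies being compared.
#' @param tracks Named list of interval tibbles (`chrom, start, end`);
#'   typical names: `SD`, `satellite`, `GA/TC`, `AT`.
#' @param seqlengths Named vector of reference chromosome lengths.
#' @param t An [asm_thresholds()] object.
#' @param priority Character vector, highest first. Must contain
#'   `chromosome_end` and every track name used; may contain `SD+GA/TC`.
#' @return The input tibble plus `label` and `distance` (0 when inside the
#'   assigned feature; `NA` distance for `poisson_end`/`other`).
#' @export
annotate_ends <- function(ends, tracks, seqlengths, t = asm_thresholds(),
                          priority = c("chromosome_end", "SD+GA/TC", "SD",
                                       "satellite", "GA/TC", "AT",
                                       "poisson_end", "other")) {
  if (anyDuplicated(priority)) {
    stop("configuration error: duplicated entries in priority order",
         call. = FALSE)
  }
  track_names <- intersect(priority, names(tracks))
  dist <- purrr::map(tracks[track_names],
                     ~ point_track_distance(ends$chrom, ends$pos, .x))
  chrom_len <- seqlengths[ends$chrom]
  d_chrom_end <- pmin(ends$pos, chrom_len - ends$pos)
  label <- rep(NA_character_, nrow(ends))
  distance <- rep(NA_real_, nrow(ends))
  composite <- "SD+GA/TC" %in% priority && all(c("SD", "GA/TC") %in%
                                                 names(dist))
  for (lab in priority) {
    open <- is.na(label)
    if (lab == "chromosome_end") {
      hit <- open & d_chrom_end <= t$chrom_end_window
      label[hit] <- lab
      distance[hit] <- d_chrom_end[hit]
    } else if (lab == "SD+GA/TC") {
      if (!composite) next
      hit <- open & dist[["SD"]] <= t$proximity &
        dist[["GA/TC"]] <= t$proximity
      label[hit] <- lab
      distance[hit] <- pmax(dist[["SD"]], dist[["GA/TC"]])[hit]
    } else if (lab %in% names(dist)) {
      hit <- open & dist[[lab]] <= t$proximity
      label[hit] <- lab
      distance[hit] <- dist[[lab]][hit]
    }
  }
  if (any(is.na(label))) {
    pois <- poisson_ends(ends, cluster_distance = t$proximity)
    label[is.na(label) & pois] <- "poisson_end"
    label[is.na(label)] <- "other"
  }
  ends %>% mutate(label = label, distance = distance)
}

#' Nonrecurrent (Poisson) contig ends
#'
#' An end is a Poisson end when no end from any other haploid assembly lies
#' within `cluster_distance` on the same chromosome — a break private to one
#' haplotype and therefore likely random rather than sequence-driven.
#'
#' @param ends Pooled end tibble (all samples/haplotypes).
#' @param cluster_distance Clustering distance in bp (default: the 10-kbp
#'   proximity).
#' @return Logical vector along the rows of `ends`.
#' @export
poisson_ends <- function(ends, cluster_distance = 10000) {
  out <- logical(nrow(ends))
  grp <- assembly_id(ends$sample, ends$hap)
  for (ch in unique(ends$chrom)) {
    idx <- which(ends$chrom == ch)
    pos <- ends$pos[idx]
    g <- grp[idx]
    ord <- order(pos)
    pos_s <- pos[ord]
    g_s <- g[ord]
    n <- length(pos_s)
    recurrent <- logical(n)
    for (i in seq_len(n)) {
      j <- i - 1
      while (j >= 1 && pos_s[i] - pos_s[j] <= cluster_distance) {
        if (g_s[j] != g_s[i]) { recurrent[i] <- TRUE; break }
        j <- j - 1
      }
      if (recurrent[i]) next
      j <- i + 1
      while (j <= n && pos_s[j] - pos_s[i] <= cluster_distance) {
        if (g_s[j] != g_s[i]) { recurrent[i] <- TRUE; break }
        j <- j + 1
      }
    }
    out[idx[ord]] <- !recurrent
  }
  out
}

#' Permutation enrichment of contig ends near feature tracks
#'
#' Compares the observed number of ends within `proximity` of a track with
#' the distribution obtained by placing the same number of ends uniformly at
#' random over the reference (`n_permutations` draws, default 10,000). Fold
#' enrichment is observed over the median of the random counts; the empirical
#' p-value is `(1 + #random >= observed) / (1 + n_permutations)`. Unlike
#' [annotate_ends()], an end here may count toward several tracks.
#'
#' @param ends Pooled end tibble; must be non-empty.
#' @param tracks A single interval tibble or a named list of them.
#' @param seqlengths Named vector of reference chromosome lengths.
#' @param t An [asm_thresholds()] object.
#' @param seed Integer seed for the random placements.
#' @param n_permutations Number of permutations (defaults to
#'   `t$n_permutations`).
#' @return A tibble of class `asm_enrichment`, one row per track: `track,
#'   observed, random_median, fold, p, n_permutations, seed, flag`. The
#'   random counts are kept in the `random_counts` attribute (a named list)
#'   for plotting. When the random median is 0 the fold is reported as the
#'   observed count and flagged `median_zero`; an empty track is flagged
#'   `empty_track` with `NA` fold.
#' @export
permutation_enrichment <- function(ends, tracks, seqlengths,
                                   t = asm_thresholds(), seed = 1,
                                   n_permutations = t$n_permutations) {
  if (nrow(ends) == 0) stop("no contig ends supplied", call. = FALSE)
  if (is.data.frame(tracks)) tracks <- list(track = tracks)
  n_ends <- nrow(ends)
  chroms <- names(seqlengths)
  offsets <- stats::setNames(cumsum(c(0, unname(seqlengths)))[
    seq_along(chroms)], chroms)
  total <- sum(seqlengths)

  flatten_track <- function(track) {
    if (nrow(track) == 0) return(NULL)
    track <- track %>% filter(.data$chrom %in% chroms)
    if (nrow(track) == 0) return(NULL)
    padded <- track %>%
      mutate(start = pmax(0, .data$start - t$proximity),
             end = pmin(seqlengths[.data$chrom], .data$end + t$proximity))
    m <- merge_intervals(padded)
    g <- m %>% mutate(gs = .data$start + offsets[.data$chrom],
                      ge = .data$end + offsets[.data$chrom]) %>%
      arrange(.data$gs)
    g
  }
  count_hits <- function(gpos, flat) {
    if (is.null(flat)) return(rep(0L, 0))
    iv <- findInterval(gpos, flat$gs)
    hit <- iv >= 1 & gpos < flat$ge[pmax(iv, 1)]
    hit
  }

  obs_gpos <- ends$pos + offsets[ends$chrom]
  res <- list()
  rand_counts <- list()
  with_seed(seed, {
    rand_gpos <- stats::runif(n_permutations * n_ends, min = 0, max = total)
    perm_id <- rep(seq_len(n_permutations), each = n_ends)
    for (nm in names(tracks)) {
      flat <- flatten_track(tracks[[nm]])
      if (is.null(flat)) {
        res[[nm]] <- tibble(track = nm, observed = 0, random_median = 0,
                            fold = NA_real_, p = NA_real_,
                            n_permutations = n_permutations, seed = seed,
                            flag = "empty_track")
        rand_counts[[nm]] <- rep(0, n_permutations)
        next
      }
      observed <- sum(count_hits(obs_gpos, flat))
      hits <- count_hits(rand_gpos, flat)
      counts <- as.numeric(rowsum(as.integer(hits), perm_id))
      med <- stats::median(counts)
      fold <- if (med == 0) observed else observed / med
      res[[nm]] <- tibble(
        track = nm, observed = observed, random_median = med,
        fold = fold,
        p = (1 + sum(counts >= observed)) / (1 + n_permutations),
        n_permutations = n_permutations, seed = seed,
        flag = if (med == 0) "median_zero" else NA_character_)
      rand_counts[[nm]] <- counts
    }
  })
  out <- bind_rows(res)
  attr(out, "random_counts") <- rand_counts
  class(out) <- c("asm_enrichment", class(out))
  out
}

#' Nonredundant recurrent gap regions
#'
#' Pools per-haplotype assembly gaps across assemblies, merges overlapping
#' gaps into maximal regions, counts the distinct haploid assemblies
#' contributing to each region, and keeps regions supported by at least
#' `min_count` assemblies. Regions overlapping an optional exclusion track
#' (typically satellite DNA) are removed.
#'
#' @param gaps Gap tibble from [report_gaps_all()], pooled.
#' @param min_count Minimum number of distinct assemblies (default 5).
#' @param exclude Optional interval tibble; merged regions overlapping it are
#'   dropped.
#' @return Tibble `chrom, start, end, n_assemblies`.
#' @export
recurrent_gap_regions <- function(gaps, min_count = 5, exclude = NULL) {
  if (nrow(gaps) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_assemblies = integer()))
  }
  merged <- merge_intervals(gaps)
  asm <- assembly_id(gaps$sample, gaps$hap)
  merged$n_assemblies <- vapply(merged$.members, function(m)
    dplyr::n_distinct(asm[m]), integer(1))
  out <- merged %>%
    dplyr::select(-".members") %>%
    filter(.data$n_assemblies >= min_count)
  if (!is.null(exclude) && nrow(exclude) > 0 && nrow(out) > 0) {
    hits <- GenomicRanges::findOverlaps(as_granges0(out),
                                        as_granges0(exclude))
    drop <- unique(S4Vectors::queryHits(hits))
    if (length(drop) > 0) out <- out[-drop, , drop = FALSE]
  }
  out
}

#' Per-gene gap recurrence
#'
#' Collapses the gene track to one range per gene (subsequent ranges of the
#' same gene are merged into their bounding interval) and counts, for every
#' gene, the number of distinct haploid assemblies whose gaps overlap it by
#' at least 1 bp.
#'
#' @param gaps Pooled gap tibble ([report_gaps_all()]).
#' @param genes Gene track tibble `chrom, start, end, name`.
#' @return Tibble `gene, chrom, start, end, n_assemblies`, sorted by
#'   decreasing recurrence.
#' @export
gene_overlap <- function(gaps, genes) {
  collapsed <- genes %>%
    group_by(gene = .data$name, .data$chrom) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  if (nrow(gaps) == 0 || nrow(collapsed) == 0) {
    return(collapsed %>% mutate(n_assemblies = 0L))
  }
  hits <- GenomicRanges::findOverlaps(as_granges0(collapsed),
                                      as_granges0(gaps))
  asm <- assembly_id(gaps$sample, gaps$hap)
  counts <- tibble(gene_i = S4Vectors::queryHits(hits),
                   asm = asm[S4Vectors::subjectHits(hits)]) %>%
    group_by(.data$gene_i) %>%
    summarise(n_assemblies = dplyr::n_distinct(.data$asm), .groups = "drop")
  collapsed$n_assemblies <- 0L
  collapsed$n_assemblies[counts$gene_i] <- counts$n_assemblies
  arrange(collapsed, dplyr::desc(.data$n_assemblies), .data$chrom,
          .data$start)
}
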