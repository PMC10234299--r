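#' Specify a synthetic annotated reference genome
#'
#' Describes a small reference with planted feature classes mirroring the
#' annotation tracks used for contig-break analysis: segmental-duplication
#' (SD) blocks with a given sequence identity and copy count, satellite
#' arrays built from a repeated monomer, and low-complexity dinucleotide
#' tracts (GA/TC or AT/TA). Background sequence is seed-driven uniform-random
#' ACGT; features are placed non-overlapping, evenly spaced along each
#' chromosome in the order given.
#'
#' @param chrom_length Length of each chromosome in bp.
#' @param n_chromosomes Number of chromosomes (named `chr1`, `chr2`, ...).
#' @param sd_blocks Tibble with columns `length`, `identity` (fraction),
#'   `copies`; each block contributes `copies` placed intervals whose
#'   sequences differ at about `1 - identity` of positions.
#' @param satellite_arrays Tibble with columns `length`, `monomer` (a short
#'   DNA string repeated to fill the array).
#' @param gatc_tracts Tibble with columns `length`, `dinuc` (one of
#'   `"GA", "TC", "AT", "TA"`); GA/TC tracts are annotated on the `GA/TC`
#'   track, AT/TA tracts on the `AT` track.
#' @param gene_intervals Optional tibble `chrom, start, end, name` used as the
#'   gene annotation track (annotation only; does not alter sequence).
#' @param seed Integer seed; the same spec and seed give byte-identical
#'   output.
#' @return An object of class `reference_spec`.
#' @seealso [build_reference()]
#' @export
reference_spec <- function(chrom_length, n_chromosomes = 1,
                           sd_blocks = NULL, satellite_arrays = NULL,
                           gatc_tracts = NULL, gene_intervals = NULL,
                           seed = 1) {
  stopifnot(chrom_length > 0, n_chromosomes >= 1)
  if (!is.null(gatc_tracts) && nrow(gatc_tracts) > 0 &&
      !all(gatc_tracts$dinuc %in% c("GA", "TC", "AT", "TA"))) {
    stop("specification error: gatc_tracts$dinuc must be GA, TC, AT or TA",
         call. = FALSE)
  }
  structure(
    list(chrom_length = chrom_length, n_chromosomes = n_chromosomes,
         sd_blocks = sd_blocks, satellite_arrays = satellite_arrays,
         gatc_tracts = gatc_tracts, gene_intervals = gene_intervals,
         seed = as.integer(seed)),
    class = "reference_spec"
  )
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

mutate_seq <- function(x, rate) {
  if (rate <= 0) return(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  idx <- which(stats::runif(length(chars)) < rate)
  for (i in idx) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Build a synthetic reference and its annotation tracks
#'
#' @param spec A [reference_spec()].
#' @return A list of class `asm_reference` with elements `sequences` (named
#'   character vector), `seqlengths` (named numeric), `tracks` (named list of
#'   interval tibbles: `SD`, `satellite`, `GA/TC`, `AT`, `gene`), and `spec`.
#' @examples
#' ref <- build_reference(reference_spec(chrom_length = 50000, seed = 7))
#' nchar(ref$sequences[["chr1"]])
#' @export
build_reference <- function(spec) {
  stopifnot(inherits(spec, "reference_spec"))
  with_seed(spec$seed, {
    chroms <- paste0("chr", seq_len(spec$n_chromosomes))
    L <- spec$chrom_length

    # expand feature instances in declaration order
    inst <- list()
    if (!is.null(spec$sd_blocks) && nrow(spec$sd_blocks) > 0) {
      for (b in seq_len(nrow(spec$sd_blocks))) {
        blk <- spec$sd_blocks[b, ]
        src <- rand_seq(blk$length)
        for (cp in seq_len(blk$copies)) {
          sq <- if (cp == 1) src else mutate_seq(src, 1 - blk$identity)
          inst[[length(inst) + 1]] <- list(
            track = "SD", name = sprintf("SD%d.%d", b, cp),
            score = blk$identity, seq = sq)
        }
      }
    }
    if (!is.null(spec$satellite_arrays) && nrow(spec$satellite_arrays) > 0) {
      for (b in seq_len(nrow(spec$satellite_arrays))) {
        ar <- spec$satellite_arrays[b, ]
        sq <- strrep(ar$monomer, ceiling(ar$length / nchar(ar$monomer)))
        inst[[length(inst) + 1]] <- list(
          track = "satellite", name = sprintf("SAT%d", b), score = 0,
          seq = substr(sq, 1, ar$length))
      }
    }
    if (!is.null(spec$gatc_tracts) && nrow(spec$gatc_tracts) > 0) {
      for (b in seq_len(nrow(spec$gatc_tracts))) {
        tr <- spec$gatc_tracts[b, ]
        track <- if (tr$dinuc %in% c("GA", "TC")) "GA/TC" else "AT"
        sq <- strrep(tr$dinuc, ceiling(tr$length / 2))
        inst[[length(inst) + 1]] <- list(
          track = track, name = sprintf("%s%d", tr$dinuc, b), score = 0,
          seq = substr(sq, 1, tr$length))
      }
    }

    # round-robin chromosome assignment, then even spacing per chromosome
    feat <- tibble(
      chrom = if (length(inst) > 0)
        chroms[(seq_along(inst) - 1) %% spec$n_chromosomes + 1]
      else character(),
      track = vapply(inst, `[[`, "", "track"),
      name = vapply(inst, `[[`, "", "name"),
      score = vapply(inst, `[[`, 0, "score"),
      len = vapply(inst, function(i) nchar(i$seq), 0)
    )
    seqs <- stats::setNames(vector("list", length(chroms)), chroms)
    feat$start <- NA_real_
    for (ch in chroms) {
      idx <- which(feat$chrom == ch)
      total <- sum(feat$len[idx])
      gapw <- floor((L - total) / (length(idx) + 1))
      if (length(idx) > 0 && gapw < 1) {
        stop("specification error: planted features do not fit in ",
             "chromosome ", ch, call. = FALSE)
      }
      pos <- gapw
      for (i in idx) {
        feat$start[i] <- pos
        pos <- pos + feat$len[i] + gapw
      }
      bg <- rand_seq(L)
      for (i in idx) {
        substr(bg, feat$start[i] + 1, feat$start[i] + feat$len[i]) <-
          inst[[i]]$seq
      }
      seqs[[ch]] <- bg
    }
    feat$end <- feat$start + feat$len

    tracks <- list()
    for (tk in c("SD", "satellite", "GA/TC", "AT")) {
      tracks[[tk]] <- feat %>%
        filter(.data$track == tk) %>%
        transmute(chrom = .data$chrom, start = .data$start, end = .data$end,
                  name = .data$name, score = .data$score)
    }
    tracks$gene <- if (!is.null(spec$gene_intervals)) {
      as_tibble(spec$gene_intervals)
    } else {
      tibble(chrom = character(), start = numeric(), end = numeric(),
             name = character())
    }

    structure(
      list(sequences = unlist(seqs),
           seqlengths = stats::setNames(rep(L, length(chroms)), chroms),
           tracks = tracks, spec = spec),
      class = "asm_reference"
    )
  })
}

#' Plan of planted assembly events
#'
#' Events are given in reference coordinates (0-based half-open) and applied
#' per haplotype. Kinds:
#' \describe{
#'   \item{gap}{`[start, end)` is absent and the contig is split around it.}
#'   \item{contraction}{`[start, end)` is absent from the contig (contig
#'     continues); downstream this is a target gap with no query gap.}
#'   \item{expansion}{`size` bp of novel sequence is inserted at `start`
#'     (`end == start`); a query gap with no target gap.}
#'   \item{inversion}{`[start, end)` appears reverse-complemented inside the
#'     contig.}
#'   \item{embedded_contig}{an additional contig duplicating `[start, end)`
#'     of the same haplotype's span.}
#'   \item{cn_gain}{an extra tandem copy of `[start, end)` inside the contig,
#'     producing a multi-coverage region.}
#' }
#'
#' @param events Tibble with columns `hap, kind, chrom, start, end` and
#'   optionally `size` (required for `expansion`).
#' @return An object of class `assembly_plan`.
#' @export
assembly_plan <- function(events) {
  events <- as_tibble(events)
  kinds <- c("gap", "contraction", "expansion", "inversion",
             "embedded_contig", "cn_gain")
  if (!all(events$kind %in% kinds)) {
    stop("specification error: unknown event kind(s): ",
         paste(setdiff(events$kind, kinds), collapse = ", "), call. = FALSE)
  }
  if (!"size" %in% names(events)) events$size <- NA_real_
  events <- events %>%
    mutate(size = ifelse(.data$kind == "expansion", .data$size,
                         .data$end - .data$start))
  if (any(events$kind == "expansion" &
          (is.na(events$size) | events$size <= 0 |
             events$end != events$start))) {
    stop("specification error: expansion events need end == start and a ",
         "positive size", call. = FALSE)
  }
  if (any(events$start < 0 | events$end < events$start)) {
    stop("specification error: invalid event interval", call. = FALSE)
  }
  # non-overlap within haplotype (points get width 1 for the check)
  ov <- events %>%
    mutate(.e = pmax(.data$end, .data$start + 1)) %>%
    group_by(.data$hap, .data$chrom) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(prev_end = dplyr::lag(.data$.e)) %>%
    filter(!is.na(.data$prev_end) & .data$start < .data$prev_end)
  if (nrow(ov) > 0) {
    stop("specification error: overlapping events within one haplotype",
         call. = FALSE)
  }
  structure(list(events = arrange(events, .data$hap, .data$chrom,
                                  .data$start)),
            class = "assembly_plan")
}

#' Simulate a fragmented diploid assembly with ground truth
#'
#' Derives per-haplotype contigs deterministically from the reference and an
#' [assembly_plan()], and constructs the truth alignment set analytically
#' (one record per maximal co-linear segment) rather than with an aligner, so
#' the test surface carries no aligner nondeterminism. Synthetic mapping
#' quality is 60 unless low-quality records are injected via `low_mapq_frac`.
#'
#' @param reference An `asm_reference` from [build_reference()].
#' @param plan An [assembly_plan()].
#' @param sample Sample label recorded on all outputs.
#' @param mapq Synthetic mapping quality for truth alignments.
#' @param low_mapq_frac Fraction of truth alignment records whose mapq is set
#'   to 2 (seed-driven; for testing the mapq filter).
#' @return A list of class `asm_assembly` with elements `contigs` (named list
#'   per haplotype of named character vectors), `alignments` (truth alignment
#'   tibble in canonical [read_paf()] form), and `truth` (one row per planted
#'   event with its expected downstream call).
#' @export
simulate_assembly <- function(reference, plan, sample = "synthetic",
                              mapq = 60, low_mapq_frac = 0, haps = NULL) {
  stopifnot(inherits(reference, "asm_reference"),
            inherits(plan, "assembly_plan"))
  events <- plan$events
  if (is.null(haps)) haps <- unique(events$hap)
  bad <- events %>%
    filter(!.data$chrom %in% names(reference$seqlengths) |
             .data$end > reference$seqlengths[.data$chrom])
  if (nrow(bad) > 0) {
    stop("specification error: event outside reference bounds", call. = FALSE)
  }
  with_seed(reference$spec$seed * 7L + 13L, {
    contigs <- list()
    aln_rows <- list()
    truth_rows <- list()
    for (hp in haps) {
      hp_ct <- list()
      ct_i <- 0
      for (ch in names(reference$sequences)) {
        ev <- events %>% filter(.data$hap == hp, .data$chrom == ch)
        L <- reference$seqlengths[[ch]]
        segs <- list()          # segments of the contig under construction
        cursor <- 0
        new_contig <- function() list()
        add_seg <- function(segs, tstart, tend, strand = "+", novel = 0) {
          if (novel == 0 && tend <= tstart) return(segs)
          segs[[length(segs) + 1]] <- list(tstart = tstart, tend = tend,
                                           strand = strand, novel = novel)
          segs
        }
        flush <- function(segs) {
          if (length(segs) == 0) return(invisible(NULL))
          ct_i <<- ct_i + 1
          qname <- sprintf("%s_%s_ctg%03d", hp, ch, ct_i)
          built <- build_contig(segs, reference$sequences[[ch]], ch, L,
                                qname, mapq)
          hp_ct[[qname]] <<- built$seq
          aln_rows[[length(aln_rows) + 1]] <<-
            built$aln %>% mutate(sample = sample, hap = hp)
          invisible(NULL)
        }
        embeds <- ev %>% filter(.data$kind == "embedded_contig")
        for (i in seq_len(nrow(ev))) {
          e <- ev[i, ]
          if (e$kind == "gap") {
            segs <- add_seg(segs, cursor, e$start)
            flush(segs); segs <- new_contig()
            cursor <- e$end
          } else if (e$kind == "contraction") {
            segs <- add_seg(segs, cursor, e$start)
            cursor <- e$end
          } else if (e$kind == "expansion") {
            segs <- add_seg(segs, cursor, e$start)
            segs <- add_seg(segs, e$start, e$start, novel = e$size)
            cursor <- e$start
          } else if (e$kind == "inversion") {
            segs <- add_seg(segs, cursor, e$start)
            segs <- add_seg(segs, e$start, e$end, strand = "-")
            cursor <- e$end
          } else if (e$kind == "cn_gain") {
            segs <- add_seg(segs, cursor, e$end)
            segs <- add_seg(segs, e$start, e$end)
            cursor <- e$end
          }
        }
        segs <- add_seg(segs, cursor, L)
        flush(segs)
        # embedded contigs are additional contigs duplicating a sub-interval
        for (i in seq_len(nrow(embeds))) {
          e <- embeds[i, ]
          ct_i <- ct_i + 1
          qname <- sprintf("%s_%s_embed%02d", hp, ch, i)
          sq <- substr(reference$sequences[[ch]], e$start + 1, e$end)
          hp_ct[[qname]] <- sq
          aln_rows[[length(aln_rows) + 1]] <-
            tibble(qname = qname, qlen = nchar(sq), qstart = 0,
                   qend = nchar(sq), strand = "+", tname = ch, tlen = L,
                   tstart = e$start, tend = e$end, nmatch = nchar(sq),
                   alen = nchar(sq), mapq = mapq, sample = sample, hap = hp)
        }
      }
      contigs[[hp]] <- unlist(hp_ct)
    }
    aln <- bind_rows(aln_rows)
    if (low_mapq_frac > 0) {
      k <- ceiling(low_mapq_frac * nrow(aln))
      aln$mapq[sample.int(nrow(aln), k)] <- 2
    }
    expected <- c(gap = "gap_region",
                  contraction = "discontinuity_contraction",
                  expansion = "discontinuity_expansion",
                  inversion = "strand_switch",
                  embedded_contig = "multicoverage_embedded",
                  cn_gain = "multicoverage")
    truth <- events %>%
      mutate(sample = sample, expected_call = unname(expected[.data$kind]))
    structure(list(contigs = contigs, alignments = aln, truth = truth),
              class = "asm_assembly")
  })
}

# turn a segment list into contig sequence + merged co-linear truth records
build_contig <- function(segs, ref_seq, chrom, chrom_len, qname, mapq) {
  # merge query-adjacent co-linear aligned segments
  merged <- list(segs[[1]])
  for (s in segs[-1]) {
    p <- merged[[length(merged)]]
    colinear <- p$novel == 0 && s$novel == 0 && p$strand == s$strand &&
      ((p$strand == "+" && p$tend == s$tstart) ||
         (p$strand == "-" && p$tstart == s$tend))
    if (colinear) {
      merged[[length(merged)]]$tstart <- min(p$tstart, s$tstart)
      merged[[length(merged)]]$tend <- max(p$tend, s$tend)
    } else {
      merged[[length(merged) + 1]] <- s
    }
  }
  widths <- vapply(merged, function(s)
    if (s$novel > 0) s$novel else s$tend - s$tstart, 0)
  qstarts <- cumsum(c(0, widths[-length(widths)]))
  qlen <- sum(widths)
  pieces <- character(length(merged))
  rows <- list()
  for (i in seq_along(merged)) {
    s <- merged[[i]]
    if (s$novel > 0) {
      pieces[i] <- rand_seq(s$novel)
    } else {
      sq <- substr(ref_seq, s$tstart + 1, s$tend)
      pieces[i] <- if (s$strand == "-") revcomp(sq) else sq
      rows[[length(rows) + 1]] <- tibble(
        qname = qname, qlen = qlen, qstart = qstarts[i],
        qend = qstarts[i] + widths[i], strand = s$strand, tname = chrom,
        tlen = chrom_len, tstart = s$tstart, tend = s$tend,
        nmatch = widths[i], alen = widths[i], mapq = mapq)
    }
  }
  list(seq = paste(pieces, collapse = ""), aln = bind_rows(rows))
}

#' Write a synthetic reference to FASTA and BED tracks
#'
#' @param reference An `asm_reference`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes `reference.fasta` plus one BED per track
#'   (`sd.bed`, `satellite.bed`, `gatc.bed`, `at.bed`, `gene.bed`).
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dss <- Biostrings::DNAStringSet(reference$sequences)
  Biostrings::writeXStringSet(dss, file.path(dir, "reference.fasta"))
  files <- c(SD = "sd.bed", satellite = "satellite.bed", `GA/TC` = "gatc.bed",
             AT = "at.bed", gene = "gene.bed")
  for (tk in names(files)) {
    if (!is.null(reference$tracks[[tk]])) {
      write_bed(reference$tracks[[tk]], file.path(dir, files[[tk]]))
    }
  }
  invisible(dir)
}

#' Write a simulated assembly: per-haplotype FASTA, truth PAF and truth BED
#'
#' @param assembly An `asm_assembly` from [simulate_assembly()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_assembly <- function(assembly, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (hp in names(assembly$contigs)) {
    dss <- Biostrings::DNAStringSet(assembly$contigs[[hp]])
    Biostrings::writeXStringSet(dss, file.path(dir, paste0(hp, ".fasta")))
    write_paf(assembly$alignments %>% filter(.data$hap == hp),
              file.path(dir, paste0(hp, ".paf")))
  }
  truth <- assembly$truth %>%
    transmute(chrom = .data$chrom, start = .data$start, end = .data$end,
              name = paste(.data$hap, .data$kind, .data$expected_call,
                           sep = "|"),
              score = .data$size, strand = "+")
  write_bed(truth, file.path(dir, "truth_events.bed"))
  invisible(dir)
}

#' Demonstration study conditions: reference spec
#'
#' A 10-Mbp single-chromosome reference carrying the feature classes the
#' pipeline annotates: four SD intervals (two blocks at 99% and 98% identity,
#' two copies each), one 250-kbp satellite array, GA/TC tracts of 3000, 2000
#' and 600 bp, and one 1500-bp AT tract. These sizes fall in the tract range
#' the analysis is designed to size (hundreds of bp to a few kbp) and the SD
#' identities mirror the high-identity duplications where assembly breaks
#' concentrate.
#'
#' @param seed Integer seed.
#' @return A [reference_spec()].
#' @export
demo_reference_spec <- function(seed = 42) {
  reference_spec(
    chrom_length = 10e6,
    n_chromosomes = 1,
    sd_blocks = tibble(length = c(60000, 50000), identity = c(0.99, 0.98),
                       copies = c(2, 2)),
    satellite_arrays = tibble(length = 250000, monomer = "AATGGAATGGAATGC"),
    gatc_tracts = tibble(length = c(3000, 2000, 600, 1500),
                         dinuc = c("GA", "TC", "GA", "AT")),
    seed = seed
  )
}

#' Demonstration study conditions: diploid assembly plan
#'
#' Builds the planted-event plan for a two-haplotype assembly of the demo
#' reference: 12 gaps (six per haplotype, five of which sit on annotated
#' features — SDs, the satellite array, GA/TC tracts — and one private per
#' haplotype), 6 contractions, 6 expansions, 2 inversions and 3 embedded
#' contigs, all placed in feature-free zones so every event is independently
#' recoverable at exact coordinates.
#'
#' @param reference The built demo reference ([build_reference()] of
#'   [demo_reference_spec()]).
#' @return An [assembly_plan()].
#' @export
demo_assembly_plan <- function(reference) {
  tk <- reference$tracks
  ctr <- function(x) floor((x$start + x$end) / 2)
  sd_c <- ctr(tk$SD)
  sat_c <- ctr(tk$satellite)
  ga_c <- ctr(tk$`GA/TC`)
  # midpoints of feature-free zones, for events that must not touch features
  occ <- bind_rows(tk$SD, tk$satellite, tk$`GA/TC`, tk$AT) %>%
    arrange(.data$start)
  L <- reference$seqlengths[[1]]
  mids <- floor(c((occ$end[-nrow(occ)] + occ$start[-1]) / 2,
                  (occ$end[nrow(occ)] + L) / 2))
  gap_w <- 20000
  gap_at <- function(hap, centers) {
    tibble(hap = hap, kind = "gap", chrom = "chr1",
           start = centers - gap_w / 2, end = centers + gap_w / 2)
  }
  ev <- bind_rows(
    gap_at("H1", c(sd_c[1], sd_c[3], sat_c[1], ga_c[1], ga_c[2])),
    tibble(hap = "H1", kind = "gap", chrom = "chr1",
           start = 9.2e6, end = 9.2e6 + gap_w),
    gap_at("H2", c(sd_c[1], sd_c[3], sat_c[1], ga_c[1], ga_c[2])),
    tibble(hap = "H2", kind = "gap", chrom = "chr1",
           start = 9.4e6, end = 9.4e6 + gap_w),
    tibble(hap = "H1", kind = "contraction", chrom = "chr1",
           start = mids[1:3], end = mids[1:3] + c(5000, 30000, 800)),
    tibble(hap = "H2", kind = "contraction", chrom = "chr1",
           start = mids[1:3] + 60000, end = mids[1:3] + 60000 +
             c(4000, 25000, 1200)),
    tibble(hap = "H1", kind = "expansion", chrom = "chr1",
           start = mids[4:6] - 40000, end = mids[4:6] - 40000,
           size = c(2000, 10000, 50000)),
    tibble(hap = "H2", kind = "expansion", chrom = "chr1",
           start = mids[4:6] + 40000, end = mids[4:6] + 40000,
           size = c(3000, 8000, 40000)),
    tibble(hap = "H1", kind = "inversion", chrom = "chr1",
           start = mids[7], end = mids[7] + 200000),
    tibble(hap = "H2", kind = "inversion", chrom = "chr1",
           start = mids[7] + 250000, end = mids[7] + 250000 + 150000),
    tibble(hap = "H1", kind = "embedded_contig", chrom = "chr1",
           start = c(mids[8], mids[9]), end = c(mids[8] + 150000,
                                                mids[9] + 200000)),
    tibble(hap = "H2", kind = "embedded_contig", chrom = "chr1",
           start = mids[8] + 10000, end = mids[8] + 10000 + 180000)
  )
  assembly_plan(ev)
}

#' Build the full demonstration truth set
#'
#' Convenience wrapper: builds the demo reference, plants the demo events in
#' both haplotypes, attaches a small gene track (eight genes, several
#' overlapping planted break sites), and returns everything needed to
#' exercise the pipeline end to end.
#'
#' @param seed Integer seed for the generator.
#' @return List with elements `reference`, `plan`, `assembly`.
#' @export
demo_truth <- function(seed = 42) {
  ref <- build_reference(demo_reference_spec(seed))
  plan <- demo_assembly_plan(ref)
  tk <- ref$tracks
  gene_anchor <- c(tk$SD$start[1], tk$SD$start[3], tk$satellite$start[1],
                   tk$`GA/TC`$start[1], 1.1e6, 3.3e6, 6.7e6, 8.9e6)
  ref$tracks$gene <- tibble(
    chrom = "chr1",
    start = pmax(0, gene_anchor - 5000),
    end = pmin(ref$seqlengths[["chr1"]], gene_anchor + 45000),
    name = sprintf("GENE%02d", seq_along(gene_anchor))
  )
  asm <- simulate_assembly(ref, plan)
  list(reference = ref, plan = plan, assembly = asm)
}
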