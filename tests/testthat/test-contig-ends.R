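t0 <- asm_thresholds()

test_that("a single qualifying alignment provides both simple ends", {
  a <- mk_aln("c1", 150000, 0, 30000, 100000, 130000)
  se <- simple_ends(a, t0)
  expect_equal(nrow(se), 2)
  expect_equal(se$pos[se$side == "left"], 100000)
  expect_equal(se$pos[se$side == "right"], 130000)
})

test_that("simple ends skip sub-25kbp terminal alignments", {
  a <- mk_aln("c1", 1e6,
              qstart = c(0, 20000, 900000),
              qend = c(10000, 60000, 910000),
              tstart = c(0, 20000, 900000),
              tend = c(10000, 60000, 910000))
  se <- simple_ends(a, t0)
  expect_equal(se$pos[se$side == "left"], 20000)   # 10-kbp outer fails floor
  expect_equal(se$aln_len[se$side == "left"], 40000)
  expect_equal(se$pos[se$side == "right"], 60000)  # right inward scan too
})

test_that("contigs without qualifying alignments land in the skipped report", {
  a <- mk_aln("c1", 150000, 0, 10000, 0, 10000)
  se <- simple_ends(a, t0)
  expect_equal(nrow(se), 0)
  expect_equal(attr(se, "skipped")$contig, "c1")
})

test_that("simple ends equal an exhaustive per-side scan on random contigs", {
  set.seed(7)
  aln <- purrr::map_dfr(1:20, function(i) {
    n <- sample(2:6, 1)
    qs <- sort(sample.int(8e5, n))
    w <- sample(c(5000, 20000, 30000, 60000), n, replace = TRUE)
    mk_aln(paste0("ctg", i), 1e6, qs, qs + w, qs + 17, qs + 17 + w)
  })
  se <- simple_ends(aln, t0)
  for (ct in unique(aln$qname)) {
    g <- dplyr::arrange(dplyr::filter(aln, qname == ct), qstart)
    ok <- which((g$tend - g$tstart) >= t0$min_simple_end_aln)
    mine <- dplyr::filter(se, contig == ct)
    if (length(ok) == 0) {
      expect_equal(nrow(mine), 0)
    } else {
      expect_equal(mine$pos[mine$side == "left"], g$tstart[ok[1]])
      expect_equal(mine$pos[mine$side == "right"],
                   g$tend[ok[length(ok)]])
    }
  }
})

test_that("contigs within the 5% overextension stay in one piece", {
  a <- mk_aln("c1", 1e6, c(0, 940000), c(60000, 1000000),
              c(10000000, 10940000), c(10060000, 11000000))
  p <- end_alignments(a, t0)
  expect_equal(nrow(p), 1)
  expect_equal(p$span, 1000000)
  expect_equal(p$left_pos, 10000000)
  expect_equal(p$right_pos, 11000000)
})

test_that("overextended contigs split at the largest target jump", {
  a <- mk_aln("c1", 1e6, c(0, 940000), c(60000, 1000000),
              c(10000000, 11060000), c(10060000, 11120000))
  p <- end_alignments(a, t0)
  expect_equal(nrow(p), 2)
  expect_true(all(p$span <= 1e6 * 1.05))
  ox <- overextended_contigs(a, t0)
  expect_equal(nrow(ox), 1)
  expect_equal(ox$ratio, 1.12)
})

test_that("a span of exactly 1.05x the contig is not overextended", {
  a <- mk_aln("c1", 1e6, c(0, 990000), c(60000, 1000000),
              c(0, 990000), c(60000, 1050000))
  expect_equal(nrow(overextended_contigs(a, t0)), 0)
  expect_equal(nrow(end_alignments(a, t0)), 1)
})

test_that("piece decomposition is optimal against exhaustive search", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(2:8, 1)
    qlen <- 500000
    tstart <- sort(sample.int(3e6, n)) - 1
    tend <- tstart + sample.int(150000, n) + 50000
    t_loc <- asm_thresholds()
    limit <- qlen * (1 + t_loc$overextension_frac)
    aln <- mk_aln("c", qlen,
                  qstart = seq(0, by = 60000, length.out = n),
                  qend = seq(50000, by = 60000, length.out = n),
                  tstart = tstart, tend = tend)
    p <- end_alignments(aln, t_loc)
    # recover implied cut set from piece memberships
    spans <- p %>% dplyr::arrange(piece)
    opt <- oracle_partitions(tstart, tend, limit)
    sizes <- vapply(opt, length, 0L) + 1L
    expect_equal(nrow(spans), sizes[1])
    # every piece satisfies the constraint (single-alignment pieces exempt)
    expect_true(all(spans$span <= limit | spans$n_aln == 1))
    # the chosen cut set is among the optima
    cuts <- cumsum(spans$n_aln)
    cuts <- cuts[-length(cuts)]
    jump <- pmax(0, pmax(tstart[-n] - tend[-1], tstart[-1] - tend[-n]))
    best_js <- if (length(opt[[1]]) > 0) sum(jump[opt[[1]]]) else 0
    got_js <- if (length(cuts) > 0) sum(jump[cuts]) else 0
    expect_equal(got_js, best_js)
  }
})

test_that("gaps appear exactly between subsequent pieces", {
  a <- dplyr::bind_rows(
    mk_aln("c1", 4e6, 0, 4e6, 1000000, 5000000),
    mk_aln("c2", 2e6, 0, 2e6, 5200000, 7200000))
  gaps <- report_gaps(end_alignments(a, t0))
  expect_equal(nrow(gaps), 1)
  expect_equal(gaps$start, 5000000)
  expect_equal(gaps$end, 5200000)
  # overlapping pieces emit nothing
  b <- dplyr::bind_rows(
    mk_aln("c1", 4e6, 0, 4e6, 1000000, 5000000),
    mk_aln("c2", 2e6, 0, 2e6, 4900000, 6900000))
  expect_equal(nrow(report_gaps(end_alignments(b, t0))), 0)
})

test_that("report_gaps refuses mixed haplotypes", {
  a <- dplyr::bind_rows(
    mk_aln("c1", 4e6, 0, 4e6, 0, 4e6, hap = "H1"),
    mk_aln("c2", 4e6, 0, 4e6, 5e6, 9e6, hap = "H2"))
  expect_error(report_gaps(end_alignments(a, t0)), "single")
})

test_that("planted gaps are recovered exactly on the synthetic diploid", {
  demo <- demo_cache()
  aln <- group_alignments(filter_alignments(demo$assembly$alignments, t0))
  gaps <- report_gaps_all(end_alignments(aln, t0)) %>%
    dplyr::arrange(hap, start)
  truth <- demo$assembly$truth %>%
    dplyr::filter(kind == "gap") %>%
    dplyr::arrange(hap, start)
  expect_equal(nrow(gaps), nrow(truth))
  expect_equal(gaps$start, truth$start)
  expect_equal(gaps$end, truth$end)
})

test_that("simple ends and assembly gaps agree as in real assemblies", {
  demo <- demo_cache()
  aln <- group_alignments(filter_alignments(demo$assembly$alignments, t0))
  gaps <- report_gaps_all(end_alignments(aln, t0))
  se <- simple_ends(aln, t0)
  # interior ends (excluding chromosome termini) should fall inside gaps
  interior <- se %>%
    dplyr::filter(pos > 100000, pos < 10e6 - 100000)
  in_gap <- purrr::map2_lgl(interior$pos, interior$hap, function(p, hp) {
    any(gaps$hap == hp & gaps$start <= p & p <= gaps$end)
  })
  # embedded-contig ends do not delimit gaps; everything else must
  non_embed <- !grepl("embed", interior$contig)
  expect_gte(mean(in_gap[non_embed]), 0.85)
  gap_has_end <- purrr::pmap_lgl(gaps, function(start, end, hap, ...) {
    any(se$hap == hap & se$pos >= start & se$pos <= end)
  })
  expect_gt(mean(gap_has_end), 0.99)
})
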