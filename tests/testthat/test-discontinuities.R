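t0 <- asm_thresholds()

two_block_contig <- function(tgap, qgap, strand = c("+", "+")) {
  # one contig, two alignments separated by tgap on target, qgap on query
  if (strand[1] == "+") {
    t1 <- c(1e6, 1e6 + 5e5 + tgap)
    t2 <- c(1.5e6, 1.5e6 + 4e5 + tgap)
    mk_aln("c1", 2e6, qstart = c(0, 5e5 + qgap),
           qend = c(5e5, 9e5 + qgap),
           tstart = t1, tend = t2, strand = strand)
  } else {
    # reverse-strand contig: query-later alignments sit left on the target
    mk_aln("c1", 2e6, qstart = c(0, 5e5 + qgap),
           qend = c(5e5, 9e5 + qgap),
           tstart = c(2e6 + tgap, 1.6e6), tend = c(2.5e6 + tgap, 2e6),
           strand = strand)
  }
}

test_that("contractions and expansions follow the target/query gap rule", {
  d1 <- find_discontinuities(two_block_contig(50000, 10000), t0)
  expect_equal(d1$class, "contraction")
  expect_equal(d1$event_size, 40000)
  expect_equal(d1$unaligned, 10000)
  d2 <- find_discontinuities(two_block_contig(1000, 30000), t0)
  expect_equal(d2$class, "expansion")
  expect_equal(d2$event_size, 29000)
  d3 <- find_discontinuities(two_block_contig(1200000, 0), t0)
  expect_equal(nrow(d3), 0)  # >= 1 Mbp is not a discontinuity
  d4 <- find_discontinuities(two_block_contig(0, 7000), t0)
  expect_equal(d4$class, "expansion")  # point insertion
  expect_equal(d4$start, d4$end)
  d5 <- find_discontinuities(two_block_contig(4000, 4000), t0)
  expect_equal(d5$class, "neutral")
  expect_equal(d5$event_size, 0)
})

test_that("classification is antisymmetric under gap swap", {
  for (gaps in list(c(3000, 500), c(120, 80000), c(999999, 0))) {
    a <- find_discontinuities(two_block_contig(gaps[1], gaps[2]), t0)
    b <- find_discontinuities(two_block_contig(gaps[2], gaps[1]), t0)
    swap <- c(contraction = "expansion", expansion = "contraction",
              neutral = "neutral")
    expect_equal(b$class, unname(swap[a$class]))
    expect_equal(a$event_size, b$event_size)
  }
})

test_that("reverse-strand pairs are measured on forward contig coordinates", {
  d <- find_discontinuities(two_block_contig(30000, 2000,
                                             strand = c("-", "-")), t0)
  expect_equal(d$class, "contraction")
  expect_equal(d$target_gap, 30000)
  expect_equal(d$query_gap, 2000)
  expect_equal(d$start, 2e6)        # gap sits between the target intervals
  expect_equal(d$end, 2e6 + 30000)
})

test_that("overlapping query intervals are skipped with a warning", {
  a <- mk_aln("c1", 2e6, qstart = c(0, 400000), qend = c(500000, 900000),
              tstart = c(0, 600000), tend = c(500000, 1100000))
  expect_warning(d <- find_discontinuities(a, t0), "overlapping query")
  expect_equal(nrow(d), 0)
})

test_that("planted contractions and expansions are recovered exactly", {
  demo <- demo_cache()
  aln <- group_alignments(filter_alignments(demo$assembly$alignments, t0))
  discs <- find_discontinuities(aln, t0) %>%
    dplyr::filter(class != "neutral") %>%
    dplyr::arrange(hap, start)
  truth <- demo$assembly$truth %>%
    dplyr::filter(kind %in% c("contraction", "expansion")) %>%
    dplyr::arrange(hap, start)
  expect_equal(nrow(discs), nrow(truth))
  expect_equal(discs$class, truth$kind)
  expect_equal(discs$start, truth$start)
  expect_equal(discs$event_size, truth$size)
  # an event-free haplotype yields no calls
  ref <- build_reference(reference_spec(chrom_length = 1e6, seed = 4))
  clean <- simulate_assembly(ref, assembly_plan(
    tibble::tibble(hap = "H1", kind = "inversion", chrom = "chr1",
                   start = 4e5, end = 5e5)))
  d0 <- find_discontinuities(clean$alignments, t0)
  expect_equal(nrow(d0), 0)  # inversion breakpoints carry no gap
})

test_that("CENSAT flagging applies the 1-Mbp pad on either side", {
  censat <- mk_track(5e6, 5.3e6)
  discs <- tibble::tibble(
    sample = "S", hap = "H1", contig = "c", chrom = "chr1",
    start = c(4.5e6, 6.8e6, 4.05e6, 5.1e6),
    end = c(4.5e6 + 100, 6.8e6 + 100, 4.1e6, 5.15e6),
    target_gap = 100, query_gap = 0, class = "contraction",
    event_size = 100, unaligned = 0, strand_switch = FALSE)
  f <- censat_flagging(discs, censat, t0)
  expect_equal(f$censat_flag, c(TRUE, FALSE, TRUE, TRUE))
  # graded distances match a direct check
  set.seed(43)
  d2 <- discs[rep(1, 10), ] %>%
    dplyr::mutate(start = round(seq(3e6, 8e6, length.out = 10)),
                  end = start + 1000)
  f2 <- censat_flagging(d2, censat, t0)
  want <- d2$start <= 5.3e6 + 1e6 & d2$end >= 5e6 - 1e6
  expect_equal(f2$censat_flag, want)
})

test_that("unaligned-base totals are conserved inside and outside censat", {
  discs <- tibble::tibble(
    sample = "S", hap = c("H1", "H1", "H1"), contig = "c", chrom = "chr1",
    start = c(1e6, 5e6, 7e6), end = c(1e6, 5e6, 7e6),
    target_gap = 0, query_gap = c(30000, 20000, 5000),
    class = "expansion", event_size = c(30000, 20000, 5000),
    unaligned = c(30000, 20000, 5000), strand_switch = FALSE,
    censat_flag = c(FALSE, TRUE, TRUE))
  lens <- tibble::tibble(sample = "S", hap = "H1", length = 3e6)
  s <- summarize_unaligned(discs, lens)
  expect_equal(s$unaligned_outside, 30000)
  expect_equal(s$unaligned_censat, 25000)
  expect_equal(s$pct_outside, 1.0)
  expect_equal(s$total_unaligned,
               s$unaligned_censat + s$unaligned_outside)
  # empty input gives zeros, not NA
  s0 <- summarize_unaligned(discs[0, ], lens)
  expect_equal(s0$total_unaligned, 0)
  expect_equal(s0$pct_censat, 0)
})

test_that("recurrent SV regions need 5 assemblies and 100-bp events", {
  base <- tibble::tibble(
    sample = "S", contig = "c", chrom = "chr1",
    start = 1e6, end = 1e6 + 5000, target_gap = 5000, query_gap = 0,
    class = "contraction", event_size = 5000, unaligned = 0,
    strand_switch = FALSE)
  six <- purrr::map_dfr(1:6, ~ base %>% dplyr::mutate(hap = paste0("H", .x)))
  r <- recurrent_sv_regions(six, t0)
  expect_equal(nrow(r), 1)
  expect_equal(r$n_assemblies, 6)
  expect_equal(sort(unlist(r$event_sizes)), rep(5000, 6))
  small <- purrr::map_dfr(1:10, ~ base %>%
                            dplyr::mutate(hap = paste0("H", .x),
                                          event_size = 80))
  expect_equal(nrow(recurrent_sv_regions(small, t0)), 0)
})

test_that("recurrence merging equals a naive same-class union", {
  set.seed(47)
  pool <- purrr::map_dfr(1:40, function(i) {
    s <- sample.int(3e6, 1)
    tibble::tibble(
      sample = "S", hap = paste0("H", sample.int(8, 1)), contig = "c",
      chrom = "chr1", start = s, end = s + sample.int(40000, 1),
      target_gap = 0, query_gap = 0,
      class = sample(c("contraction", "expansion"), 1),
      event_size = sample.int(5000, 1) + 100, unaligned = 0,
      strand_switch = FALSE)
  })
  mine <- recurrent_sv_regions(pool, asm_thresholds(recur_min_assemblies = 1))
  for (cl in c("contraction", "expansion")) {
    sub <- pool %>% dplyr::filter(class == cl) %>%
      dplyr::mutate(asm = paste(sample, hap))
    naive <- oracle_merge_support(sub)
    m <- mine %>% dplyr::filter(class == cl)
    expect_equal(m$start, naive$start)
    expect_equal(m$end, naive$end)
    expect_equal(m$n_assemblies, naive$n_assemblies)
  }
})
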