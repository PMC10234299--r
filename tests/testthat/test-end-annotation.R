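t0 <- asm_thresholds()

mk_ends <- function(pos, chrom = "chr1", sample = "S1", hap = "H1",
                    contig = "c") {
  tibble::tibble(sample = sample, hap = hap,
                 contig = paste0(contig, seq_along(pos)),
                 side = "left", chrom = chrom, pos = pos,
                 aln_len = 30000, kind = "simple")
}

test_that("chromosome ends outrank SDs in the priority order", {
  sl <- c(chr1 = 1000000)
  tracks <- list(SD = mk_track(40000, 60000))
  ann <- annotate_ends(mk_ends(50000), tracks, sl, t0)
  expect_equal(ann$label, "chromosome_end")
})

test_that("proximity is measured to the nearest feature edge", {
  sl <- c(chr1 = 1000000)
  tracks <- list(SD = mk_track(495000, 498000))
  ann <- annotate_ends(mk_ends(500000), tracks, sl, t0)
  expect_equal(ann$label, "SD")
  expect_equal(ann$distance, 2000)  # bases between interval end and the end
  far <- annotate_ends(mk_ends(515000), tracks, sl, t0)
  expect_true(far$label %in% c("poisson_end", "other"))
})

test_that("the composite SD+GA/TC label beats plain SD", {
  sl <- c(chr1 = 1000000)
  tracks <- list(SD = mk_track(495000, 520000),
                 `GA/TC` = mk_track(505000, 506000))
  ann <- annotate_ends(mk_ends(c(500000, 540000)), tracks, sl, t0)
  # the unmatched end is private to this haplotype, hence a Poisson end
  expect_equal(ann$label, c("SD+GA/TC", "poisson_end"))
})

test_that("duplicate priorities are rejected", {
  expect_error(annotate_ends(mk_ends(1), list(), c(chr1 = 100),
                             t0, priority = c("SD", "SD")),
               "duplicated")
})

test_that("labels agree with a brute-force per-end scan", {
  set.seed(21)
  sl <- c(chr1 = 2e6, chr2 = 2e6)
  tracks <- list(
    SD = mk_track(sort(sample.int(19e5, 6)), NA) %>%
      dplyr::mutate(end = start + 30000),
    satellite = mk_track(sort(sample.int(19e5, 3)), NA) %>%
      dplyr::mutate(end = start + 50000),
    `GA/TC` = mk_track(sort(sample.int(19e5, 8)), NA) %>%
      dplyr::mutate(end = start + 2000),
    AT = mk_track(sort(sample.int(19e5, 4)), NA, chrom = "chr2") %>%
      dplyr::mutate(end = start + 2000)
  )
  ends <- dplyr::bind_rows(
    mk_ends(sample.int(2e6, 100), chrom = "chr1"),
    mk_ends(sample.int(2e6, 100), chrom = "chr2"))
  priority <- c("chromosome_end", "SD+GA/TC", "SD", "satellite", "GA/TC",
                "AT", "poisson_end", "other")
  ann <- annotate_ends(ends, tracks, sl, t0, priority)
  want <- vapply(seq_len(nrow(ends)), function(i)
    oracle_label(ends$chrom[i], ends$pos[i], tracks, sl, t0, priority),
    "")
  got <- ann$label
  got[got %in% c("poisson_end", "other")] <- NA
  expect_equal(got, want)
  # nonredundant accounting: labels always sum to the number of ends
  expect_equal(sum(table(ann$label)), nrow(ends))
})

test_that("poisson ends are exactly the single-haplotype breaks", {
  # one assembly: everything is nonrecurrent
  e1 <- mk_ends(c(1e5, 5e5, 9e5))
  expect_true(all(poisson_ends(e1)))
  # coincident break in the other haplotype: neither is poisson
  e2 <- dplyr::bind_rows(mk_ends(5e5, hap = "H1"), mk_ends(5e5, hap = "H2"))
  expect_false(any(poisson_ends(e2)))
  # six haplotypes sharing five breaks, plus one private break each
  shared <- seq(1e6, 5e6, length.out = 5)
  ends6 <- purrr::map_dfr(1:6, function(h) {
    mk_ends(c(shared, 6e6 + h * 1e5), hap = paste0("H", h))
  })
  pois <- poisson_ends(ends6)
  expect_equal(sum(pois), 6)
  expect_true(all(ends6$pos[pois] > 6e6))
})

test_that("enrichment saturates at fold 1 when the track covers everything", {
  sl <- c(chr1 = 1e6)
  ends <- mk_ends(sample(1e6, 50))
  enr <- permutation_enrichment(ends, mk_track(0, 1e6), sl,
                                t0, seed = 1, n_permutations = 200)
  expect_equal(enr$fold, 1)
  expect_equal(enr$p, 1)
  expect_equal(enr$observed, 50)
})

test_that("a track away from all observed ends is depleted", {
  sl <- c(chr1 = 1e6)
  ends <- mk_ends(seq(10000, 200000, by = 5000))
  enr <- permutation_enrichment(ends, mk_track(800000, 900000), sl,
                                t0, seed = 3, n_permutations = 1000)
  expect_equal(enr$observed, 0)
  expect_lte(enr$fold, 1)
})

test_that("planted enrichment matches the closed-form binomial expectation", {
  sl <- c(chr1 = 1e6)
  set.seed(5)
  ends <- mk_ends(sample(500000:599999, 100, replace = TRUE))
  track <- mk_track(500000, 600000)
  enr <- permutation_enrichment(ends, track, sl, t0, seed = 11,
                                n_permutations = 2000)
  expect_equal(enr$observed, 100)
  # uniform placement hits within proximity with probability
  # (100000 + 2*10000) / 1e6 = 0.12; the random median is the binomial median
  expect_equal(enr$random_median, qbinom(0.5, 100, 0.12))
  expect_equal(enr$fold, 100 / qbinom(0.5, 100, 0.12), tolerance = 0.1)
})

test_that("enrichment is reproducible for a fixed seed", {
  sl <- c(chr1 = 1e6)
  ends <- mk_ends(sample(1e6, 30))
  e1 <- permutation_enrichment(ends, mk_track(2e5, 3e5), sl, t0,
                               seed = 7, n_permutations = 500)
  e2 <- permutation_enrichment(ends, mk_track(2e5, 3e5), sl, t0,
                               seed = 7, n_permutations = 500)
  expect_identical(tidy(e1), tidy(e2))
  expect_error(permutation_enrichment(mk_ends(numeric()), mk_track(1, 2),
                                      sl, t0), "no contig ends")
})

test_that("recurrent gap regions honour the assembly-count threshold", {
  gap1 <- tibble::tibble(chrom = "chr1", start = 1e5, end = 2e5)
  gaps5 <- purrr::map_dfr(1:5, function(h)
    gap1 %>% dplyr::mutate(sample = "S", hap = paste0("H", h)))
  r5 <- recurrent_gap_regions(gaps5, min_count = 5)
  expect_equal(nrow(r5), 1)
  expect_equal(r5$n_assemblies, 5)
  expect_equal(r5$start, 1e5)
  r4 <- recurrent_gap_regions(gaps5[1:4, ], min_count = 5)
  expect_equal(nrow(r4), 0)
  # satellite exclusion removes overlapping regions
  excl <- recurrent_gap_regions(gaps5, min_count = 5,
                                exclude = mk_track(1.5e5, 1.6e5))
  expect_equal(nrow(excl), 0)
})

test_that("recurrence merging equals a naive interval union", {
  set.seed(31)
  gaps <- purrr::map_dfr(1:20, function(h) {
    s <- sort(sample.int(2e6, 8))
    tibble::tibble(chrom = "chr1", start = s, end = s + sample(5e4, 8),
                   sample = "S", hap = paste0("H", h))
  })
  mine <- recurrent_gap_regions(gaps, min_count = 1)
  naive <- oracle_merge_support(gaps %>%
                                  dplyr::mutate(asm = paste0(sample, hap)))
  expect_equal(mine$start, naive$start)
  expect_equal(mine$end, naive$end)
  expect_equal(mine$n_assemblies, naive$n_assemblies)
})

test_that("gene recurrence counts assemblies on collapsed gene ranges", {
  gaps <- purrr::map_dfr(1:7, function(h)
    tibble::tibble(chrom = "chr1", start = 1e5, end = 3e5, sample = "S",
                   hap = paste0("H", h)))
  genes <- tibble::tibble(chrom = "chr1", start = 150000, end = 160000,
                          name = "GENE1")
  expect_equal(gene_overlap(gaps, genes)$n_assemblies, 7)
  # two exon blocks collapse; a gap touching only the intron still counts
  genes2 <- tibble::tibble(chrom = "chr1",
                           start = c(500000, 560000),
                           end = c(510000, 570000),
                           name = "GENE2")
  gap_intron <- tibble::tibble(chrom = "chr1", start = 520000, end = 540000,
                               sample = "S", hap = "H1")
  ov <- gene_overlap(gap_intron, genes2)
  expect_equal(ov$n_assemblies, 1)
  expect_equal(ov$start, 500000)
  expect_equal(ov$end, 570000)
})

test_that("gene recurrence equals brute-force all-pairs overlap", {
  set.seed(41)
  genes <- tibble::tibble(chrom = "chr1",
                          start = sort(sample.int(2e6, 30)),
                          name = sprintf("G%02d", 1:30)) %>%
    dplyr::mutate(end = start + 20000)
  gaps <- purrr::map_dfr(1:10, function(h) {
    s <- sort(sample.int(2e6, 5))
    tibble::tibble(chrom = "chr1", start = s, end = s + 30000,
                   sample = "S", hap = paste0("H", h))
  })
  mine <- gene_overlap(gaps, genes) %>% dplyr::arrange(gene)
  want <- vapply(seq_len(nrow(genes)), function(i) {
    hit <- gaps$start < genes$end[i] & gaps$end > genes$start[i]
    length(unique(paste(gaps$sample[hit], gaps$hap[hit])))
  }, 0L)
  expect_equal(mine$n_assemblies, want[order(genes$name)])
})
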