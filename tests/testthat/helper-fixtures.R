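# compact constructors for alignment rows and interval tables

mk_aln <- function(qname, qlen, qstart, qend, tstart, tend,
                   strand = "+", tname = "chr1", tlen = 1e7, mapq = 60,
                   sample = "S1", hap = "H1") {
  tibble::tibble(
    qname = qname, qlen = qlen, qstart = qstart, qend = qend,
    strand = strand, tname = tname, tlen = tlen, tstart = tstart,
    tend = tend, nmatch = tend - tstart, alen = tend - tstart, mapq = mapq,
    sample = sample, hap = hap
  )
}

mk_track <- function(starts, ends, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = starts, end = ends)
}

paf_line <- function(qname = "ctg1", qlen = 150000, qstart = 0, qend = 2000,
                     strand = "+", tname = "chr1", tlen = 1e6,
                     tstart = 5000, tend = 7000, mapq = 60, extra = NULL) {
  base <- paste(qname, qlen, qstart, qend, strand, tname, tlen, tstart,
                tend, tend - tstart, tend - tstart, mapq, sep = "\t")
  if (!is.null(extra)) base <- paste(base, extra, sep = "\t")
  base
}

write_paf_lines <- function(lines) {
  f <- tempfile(fileext = ".paf")
  writeLines(lines, f)
  f
}

# cached demo truth set (built once per test run)
demo_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- asmgaps::demo_truth(seed = 42)
    cache
  }
})
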