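#' Run the full assembly-evaluation chain on one alignment set
#'
#' Chains the analysis stages on filtered, grouped alignments: simple ends,
#' contig-end alignments and pieces, assembly gaps, end annotation against
#' the supplied tracks, intra-contig discontinuities with CENSAT flags, and
#' multi-coverage regions.
#'
#' @param aln Alignment tibble (already filtered; any number of haploid
#'   assemblies).
#' @param tracks Named list of annotation tracks (`SD`, `satellite`,
#'   `GA/TC`, `AT`, optionally `gene`).
#' @param seqlengths Named vector of reference chromosome lengths.
#' @param t An [asm_thresholds()] object.
#' @return Named list of tibbles: `simple_ends`, `pieces`, `gaps`,
#'   `annotated_ends`, `discontinuities`, `multicoverage`,
#'   `overextended`.
#' @export
evaluate_assembly <- function(aln, tracks, seqlengths,
                              t = asm_thresholds()) {
  aln <- group_alignments(aln)
  ends <- simple_ends(aln, t)
  pieces <- end_alignments(aln, t)
  gaps <- report_gaps_all(pieces)
  annotated <- annotate_ends(ends, tracks, seqlengths, t)
  discs <- find_discontinuities(aln, t)
  censat <- tracks$satellite
  if (!is.null(censat)) discs <- censat_flagging(discs, censat, t)
  list(
    simple_ends = ends,
    pieces = pieces,
    gaps = gaps,
    annotated_ends = annotated,
    discontinuities = discs,
    multicoverage = multicoverage_regions(aln),
    overextended = overextended_contigs(aln, t)
  )
}
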