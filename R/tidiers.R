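#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a permutation-enrichment result
#'
#' @param x An `asm_enrichment` object.
#' @param ... Unused.
#' @return A plain tibble, one row per track, with the enrichment columns.
#' @method tidy asm_enrichment
#' @export
tidy.asm_enrichment <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "asm_enrichment")
  out
}

#' @rdname tidy.asm_enrichment
#' @return For `glance()`: a one-row summary (number of tracks, permutation
#'   count, strongest enrichment).
#' @method glance asm_enrichment
#' @export
glance.asm_enrichment <- function(x, ...) {
  tibble(
    n_tracks = nrow(x),
    n_permutations = x$n_permutations[1],
    max_fold = suppressWarnings(max(x$fold, na.rm = TRUE)),
    min_p = suppressWarnings(min(x$p, na.rm = TRUE))
  )
}

#' Tidy a phasing-concordance result
#'
#' `tidy()` returns the per-block table; `glance()` the overall concordance
#' with block and switch-run counts.
#'
#' @param x An `asm_phasing` object.
#' @param ... Unused.
#' @method tidy asm_phasing
#' @export
tidy.asm_phasing <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "asm_phasing")
  attr(out, "by_chrom") <- NULL
  attr(out, "switch_runs") <- NULL
  attr(out, "overall") <- NULL
  out
}

#' @rdname tidy.asm_phasing
#' @method glance asm_phasing
#' @export
glance.asm_phasing <- function(x, ...) {
  ov <- attr(x, "overall")
  sw <- attr(x, "switch_runs")
  tibble(
    n_blocks = ov$n_blocks,
    concordance = ov$concordance,
    n_switch_runs = if (is.null(sw) || nrow(sw) == 0) 0L else nrow(sw)
  )
}

#' Per-chromosome phasing summary
#'
#' @param x An `asm_phasing` object.
#' @return Tibble `chrom, hap, n_assigned, n_concordant, concordance`.
#' @export
phase_by_chrom <- function(x) attr(x, "by_chrom")

#' Discordant block runs (candidate large-scale switch errors)
#'
#' @param x An `asm_phasing` object.
#' @return Tibble `hap, chrom, first_block, start, end, n_blocks`.
#' @export
phase_switch_runs <- function(x) attr(x, "switch_runs")
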