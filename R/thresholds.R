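#' Analysis thresholds
#'
#' Central, validated container for every numeric threshold used by the
#' pipeline. All stages read their cut-offs from this object so that a run is
#' fully described by one set of values, which every writer echoes into a
#' `## thresholds:` header line.
#'
#' @param ... Named overrides of individual thresholds (see Details).
#'
#' @details Defaults (all coordinates/sizes in bp):
#' \describe{
#'   \item{min_mapq}{minimum mapping quality for alignments and reads (10).}
#'   \item{min_aln_width}{minimum alignment width on the reference (1000).}
#'   \item{min_ctg_size}{minimum total contig size (100000).}
#'   \item{min_ctg_end_aln}{minimum terminal alignment for contig-end
#'     alignments (50000).}
#'   \item{min_simple_end_aln}{minimum alignment for simple contig ends
#'     (25000).}
#'   \item{overextension_frac}{allowed excess of reference span over contig
#'     length before a contig is split into pieces (0.05).}
#'   \item{proximity}{distance within which a contig end counts as near a
#'     feature (10000).}
#'   \item{chrom_end_window}{distance from a chromosome terminus that defines
#'     a chromosome-end break (100000).}
#'   \item{max_discontinuity}{upper bound on an intra-contig alignment gap
#'     (1e6).}
#'   \item{censat_pad}{distance to centromeric satellite DNA that sets the
#'     CENSAT flag (1e6).}
#'   \item{recur_min_assemblies}{assemblies required for a recurrent region
#'     (5).}
#'   \item{recur_min_event}{minimum event size entering recurrence (100).}
#'   \item{dinuc_bin}{bin size for dinucleotide profiles (100).}
#'   \item{z_cutoff}{Z-score marking a dinucleotide-enriched bin (1.96).}
#'   \item{gatc_window}{window for GA/TC content screening (1000).}
#'   \item{gatc_frac}{GA/TC content fraction flagging a window (0.80).}
#'   \item{span_min_reads}{long reads required to call a gap spanned (10).}
#'   \item{phase_block}{block size for phasing concordance (1e6).}
#'   \item{cn_diploid}{diploid copy number (2).}
#'   \item{cn_high}{copy number above which calls become `more10CN` (10).}
#'   \item{n_permutations}{permutations for enrichment tests (10000).}
#'   \item{depth_window_unmasked}{unmasked bases per read-depth window (500).}
#' }
#'
#' `min_mapq` may be 0 (disables the filter); all sizes must be positive and
#' fractions must lie in (0, 1].
#'
#' @return An object of class `asm_thresholds` (a validated named list).
#' @examples
#' t <- asm_thresholds()
#' t$min_mapq
#' asm_thresholds(min_mapq = 0, proximity = 5000)$proximity
#' @export
asm_thresholds <- function(...) {
  t <- .threshold_defaults()
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == ""))) {
    stop("all threshold overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(names(over), names(t))
  if (length(unknown) > 0) {
    stop("unknown threshold key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  t[names(over)] <- lapply(over, as.numeric)
  validate_thresholds(t)
}

.threshold_defaults <- function() {
  list(
    min_mapq = 10,
    min_aln_width = 1000,
    min_ctg_size = 100000,
    min_ctg_end_aln = 50000,
    min_simple_end_aln = 25000,
    overextension_frac = 0.05,
    proximity = 10000,
    chrom_end_window = 100000,
    max_discontinuity = 1000000,
    censat_pad = 1000000,
    recur_min_assemblies = 5,
    recur_min_event = 100,
    dinuc_bin = 100,
    z_cutoff = 1.96,
    gatc_window = 1000,
    gatc_frac = 0.80,
    span_min_reads = 10,
    phase_block = 1000000,
    cn_diploid = 2,
    cn_high = 10,
    n_permutations = 10000,
    depth_window_unmasked = 500
  )
}

validate_thresholds <- function(t) {
  sizes <- c("min_aln_width", "min_ctg_size", "min_ctg_end_aln",
             "min_simple_end_aln", "proximity", "chrom_end_window",
             "max_discontinuity", "censat_pad", "recur_min_event",
             "dinuc_bin", "gatc_window", "phase_block",
             "depth_window_unmasked")
  counts <- c("recur_min_assemblies", "span_min_reads", "n_permutations",
              "cn_diploid", "cn_high")
  fracs <- c("overextension_frac", "gatc_frac")
  for (k in names(t)) {
    v <- t[[k]]
    if (length(v) != 1 || !is.finite(v)) {
      stop("configuration error: threshold '", k,
           "' must be a single finite number", call. = FALSE)
    }
  }
  for (k in sizes) {
    if (t[[k]] <= 0) {
      stop("configuration error: size threshold '", k,
           "' must be positive (got ", t[[k]], ")", call. = FALSE)
    }
  }
  for (k in counts) {
    if (t[[k]] < 0 || t[[k]] != round(t[[k]])) {
      stop("configuration error: count threshold '", k,
           "' must be a non-negative integer (got ", t[[k]], ")",
           call. = FALSE)
    }
  }
  for (k in fracs) {
    if (t[[k]] <= 0 || t[[k]] > 1) {
      stop("configuration error: fraction '", k,
           "' must lie in (0, 1] (got ", t[[k]], ")", call. = FALSE)
    }
  }
  if (t$z_cutoff <= 0) {
    stop("configuration error: 'z_cutoff' must be positive", call. = FALSE)
  }
  if (t$min_mapq < 0) {
    stop("configuration error: 'min_mapq' must be >= 0", call. = FALSE)
  }
  structure(t, class = "asm_thresholds")
}

#' Read thresholds from a flat key=value file
#'
#' The configuration format is a flat text file with one `key = value` pair
#' per line; blank lines and `#`-comments are allowed. Precedence is
#' CLI/function overrides, then file values, then package defaults.
#'
#' @param path Path to a key=value file, or `NULL` for defaults only.
#' @param overrides Named list of values that beat the file.
#' @return An `asm_thresholds` object.
#' @export
read_thresholds <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) {
        stop("configuration error: cannot parse line '", ln, "'",
             call. = FALSE)
      }
      key <- trimws(kv[1])
      val <- suppressWarnings(as.numeric(trimws(kv[2])))
      if (is.na(val)) {
        stop("configuration error: non-numeric value for key '", key, "'",
             call. = FALSE)
      }
      vals[[key]] <- val
    }
  }
  vals[names(overrides)] <- overrides
  do.call(asm_thresholds, vals)
}

#' Serialize thresholds into the one-line run header
#'
#' Every output writer embeds this line so a run can be reproduced from its
#' outputs alone. [parse_thresholds_header()] inverts it.
#'
#' @param t An `asm_thresholds` object.
#' @return A single string of the form `## thresholds: key=value ...`.
#' @export
thresholds_header <- function(t) {
  stopifnot(inherits(t, "asm_thresholds"))
  paste0("## thresholds: ",
         paste(names(t), unlist(t), sep = "=", collapse = " "))
}

#' @rdname thresholds_header
#' @param line A header line produced by [thresholds_header()].
#' @export
parse_thresholds_header <- function(line) {
  body <- sub("^## thresholds:\\s*", "", line)
  kv <- strsplit(strsplit(trimws(body), "\\s+")[[1]], "=", fixed = TRUE)
  vals <- lapply(kv, function(x) as.numeric(x[2]))
  names(vals) <- vapply(kv, `[`, "", 1)
  do.call(asm_thresholds, vals)
}

#' @export
print.asm_thresholds <- function(x, ...) {
  cat("<asm_thresholds>\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}
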