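#' Parameters for terminal inverted repeat detection
#'
#' The detector looks for the highest-scoring local alignment between the
#' chromosome and its reverse complement that starts within the first
#' `end_window` bp of the query and ends within the last `end_window` bp
#' of the subject — i.e. an inverted repeat anchored at both chromosome
#' ends, with slack for end-polishing artifacts. Only the gap costs are
#' fixed by the underlying blastn-style convention (gap open 2, extend
#' 1, as penalties); match/mismatch default to the +1/-2 pair valid with
#' those costs. A gap of length g scores `gap_open + g * gap_extend`.
#'
#' @param end_window Anchor slack at each chromosome end, bp.
#' @param match,mismatch,gap_open,gap_extend Alignment scores
#'   (penalties negative).
#' @param seed_k Exact seed length gating the alignment; chromosomes
#'   without a shared `seed_k`-mer near both ends are reported TIR-free
#'   without running the dynamic program.
#' @param min_report Minimum query-side alignment span reported as a TIR,
#'   bp. If smaller than `seed_k`, the seed gate is skipped and the
#'   alignment is always run.
#' @param band Half-width of the alignment band around the end-anchored
#'   diagonal, bp.
#' @param xdrop Score drop-off terminating the outward extension.
#' @return A `tir_params` list.
#' @export
tir_params <- function(end_window = 99, match = 1, mismatch = -2,
                       gap_open = -2, gap_extend = -1, seed_k = 15,
                       min_report = 20, band = 200, xdrop = 500) {
  stopifnot(end_window >= 0, match > 0, mismatch < 0, gap_extend <= 0,
            gap_open <= 0, seed_k >= 1, band >= 1, xdrop > 0)
  structure(list(end_window = end_window, match = match,
                 mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, seed_k = seed_k,
                 min_report = min_report, band = band, xdrop = xdrop),
            class = "tir_params")
}

# any shared seed_k-mer near both ends on a diagonal within the band?
has_corner_seed <- function(a, b, params) {
  k <- params$seed_k
  window <- min(nchar(a), max(params$end_window + k, 2000L))
  if (window < k) return(FALSE)
  pos <- seq_len(window - k + 1L)
  ka <- substring(a, pos, pos + k - 1L)
  kb <- substring(b, pos, pos + k - 1L)
  common <- intersect(ka, kb)
  for (kmer in common) {
    pa <- pos[ka == kmer]
    pb <- pos[kb == kmer]
    if (min(abs(outer(pa, pb, "-"))) <= params$band) return(TRUE)
  }
  FALSE
}

#' Detect the terminal inverted repeat of a linear chromosome
#'
#' Aligns the first half of the chromosome S against the first half of
#' `revcomp(S)` (equivalently, the reverse complement of the second
#' half), requiring the alignment to start within `end_window` bp of
#' both sequence starts, by banded affine-gap dynamic programming seeded
#' on an exact shared k-mer near the ends. The alignment's query span is
#' the TIR length; restricting both sides to the first half caps
#' `tir_len` at L/2, so a perfectly palindromic chromosome yields
#' `fraction = 1`. The reported fraction `2 * tir_len / L` counts both
#' repeat copies.
#'
#' @param chromosome A [linear_chromosome()] with `topology = "linear"`.
#' @param params A [tir_params()].
#' @return One-row `data.frame`: `chrom_id`, `detected`, `tir_len`,
#'   `fraction`, `left_start`, `right_end` (0-based half-open coordinates
#'   of the left copy start and right copy end on S), `identity`,
#'   `score`.
#' @export
find_terminal_inverted_repeat <- function(chromosome,
                                          params = tir_params()) {
  stopifnot(inherits(chromosome, "linear_chromosome"))
  if (chromosome$topology != "linear")
    stop("TIR detection is defined for linear chromosomes only")
  L <- chromosome$length
  if (L <= 2 * params$seed_k)
    stop("chromosome too short for TIR detection (L <= 2*seed_k)")
  n <- L %/% 2L
  a <- substr(chromosome$seq, 1L, n)
  b <- substr(revcomp(chromosome$seq), 1L, n)

  empty <- data.frame(chrom_id = chromosome$id, detected = FALSE,
                      tir_len = 0, fraction = 0, left_start = NA_real_,
                      right_end = NA_real_, identity = NA_real_,
                      score = NA_real_, stringsAsFactors = FALSE)
  if (params$min_report >= params$seed_k &&
      !has_corner_seed(a, b, params))
    return(empty)

  res <- tir_banded_align_cpp(a, b, params$end_window, params$match,
                              params$mismatch, params$gap_open,
                              params$gap_extend, params$band, params$xdrop)
  if (!isTRUE(res$found)) return(empty)
  span <- res$qend - res$qstart
  if (span < params$min_report) return(empty)
  data.frame(chrom_id = chromosome$id, detected = TRUE, tir_len = span,
             fraction = 2 * span / L, left_start = res$qstart,
             right_end = L - res$sstart, identity = res$matches / res$cols,
             score = res$score, stringsAsFactors = FALSE)
}

#' Summarise TIR results over a cohort
#'
#' Reports the detected count and fraction, and — over detected TIRs —
#' the median, lower/upper quartile (linear interpolation) and standard
#' deviation (denominator n-1) of the TIR length and of the chromosome
#' fraction. With a single detected TIR the SD is reported missing.
#'
#' @param results `data.frame` of rows from
#'   [find_terminal_inverted_repeat()].
#' @return One-row summary `data.frame`.
#' @export
tir_summary <- function(results) {
  if (is.null(results) || nrow(results) == 0L)
    stop("no TIR results to summarise")
  det <- results[results$detected, , drop = FALSE]
  qs <- function(x, p) unname(quantile(x, p, type = 7))
  sdx <- function(x) if (length(x) >= 2L) sd(x) else NA_real_
  stat <- function(x) {
    if (nrow(det) == 0L)
      return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_,
               sd = NA_real_))
    c(median = median(x), q1 = qs(x, 0.25), q3 = qs(x, 0.75), sd = sdx(x))
  }
  len <- stat(det$tir_len)
  frac <- stat(det$fraction)
  data.frame(n = nrow(results), n_detected = nrow(det),
             detected_fraction = nrow(det) / nrow(results),
             tir_len_median = len[["median"]], tir_len_q1 = len[["q1"]],
             tir_len_q3 = len[["q3"]], tir_len_sd = len[["sd"]],
             fraction_median = frac[["median"]],
             fraction_q1 = frac[["q1"]], fraction_q3 = frac[["q3"]],
             fraction_sd = frac[["sd"]], stringsAsFactors = FALSE)
}
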