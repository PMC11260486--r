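#' Orient a chromosome so dnaA runs forward
#'
#' Linear chromosomes are deposited in arbitrary orientation; for
#' centre-relative analyses all genomes are put into a canonical frame
#' with the dnaA replication-initiation gene on the `+` strand. If dnaA
#' is on `-`, the sequence is reverse-complemented and every feature is
#' mapped by `(start', end') = (L - end, L - start)` with its strand
#' inverted. Applying the operation twice restores the input.
#'
#' @param chromosome A [linear_chromosome()] (or `NULL` to transform
#'   coordinates only; then `L` must be given).
#' @param features Feature `data.frame` containing at least one row with
#'   `model_id == "dnaA"`; multiple dnaA copies must share a strand.
#' @param L Chromosome length, required when `chromosome` is `NULL`.
#' @return List with `chromosome`, `features`, and logical `flipped`.
#' @export
orient_by_dnaA <- function(chromosome, features, L = NULL) {
  if (!is.null(chromosome)) L <- chromosome$length
  if (is.null(L)) stop("chromosome or L must be supplied")
  validate_features(features, setNames(L, unique(features$replicon_id)))
  dnaa <- features[features$model_id == "dnaA", , drop = FALSE]
  if (nrow(dnaa) == 0L) stop("no dnaA feature found; cannot orient")
  strands <- unique(dnaa$strand)
  if (length(strands) > 1L)
    stop("multiple dnaA copies on opposite strands; no orientation rule")
  flipped <- strands == "-"
  if (flipped) {
    if (!is.null(chromosome))
      chromosome <- linear_chromosome(chromosome$id, revcomp(chromosome$seq),
                                      chromosome$topology)
    new_start <- L - features$end
    features$end <- L - features$start
    features$start <- new_start
    features$strand <- ifelse(features$strand == "+", "-", "+")
  }
  list(chromosome = chromosome, features = features, flipped = flipped)
}

#' Centre-relative feature coordinates
#'
#' Each feature is reduced to its midpoint `(start + end)/2` (real
#' valued, no rounding, so long and short features enter positional
#' analyses with equal weight), the signed offset `midpoint - L/2` from
#' the mathematical chromosome centre, and the arm-length-normalised
#' position `arm_pos = offset / (L/2)` in `[-1, 1]`. In the dnaA-forward
#' frame a negative offset lies upstream of the centre.
#'
#' @param features Feature `data.frame`.
#' @param L Chromosome length (bp), or a named vector indexed by
#'   `replicon_id` (or by `genome_id` when present) for pooled tables.
#' @return `features` with `midpoint`, `offset`, `arm_pos` columns added.
#' @export
center_offset <- function(features, L) {
  if (length(L) > 1L || !is.null(names(L))) {
    key <- if ("genome_id" %in% names(features)) features$genome_id
           else features$replicon_id
    Lv <- unname(L[key])
    if (anyNA(Lv)) stop("missing length for some replicons")
  } else Lv <- rep(L, nrow(features))
  if (any(Lv <= 0)) stop("chromosome length must be positive")
  features$midpoint <- (features$start + features$end) / 2
  features$offset <- features$midpoint - Lv / 2
  features$arm_pos <- features$offset / (Lv / 2)
  features
}

#' Distinguish primary from duplicate gene copies
#'
#' For each gene model (grouped by `model_id`, and by `genome_id` when
#' present) the copy closest to the chromosome centre — minimal
#' `|offset|` — is ranked `primary`; all other copies are `secondary`.
#' By construction a secondary copy is never more central than its
#' primary. Exact `|offset|` ties are broken towards the smaller start
#' coordinate.
#'
#' @param centered Feature `data.frame` with an `offset` column (see
#'   [center_offset()]).
#' @return `centered` with a `copy_rank` column.
#' @export
assign_primary_copies <- function(centered) {
  if (!"offset" %in% names(centered))
    stop("run center_offset() first: no offset column")
  key <- if ("genome_id" %in% names(centered))
    paste(centered$genome_id, centered$model_id, sep = "\r")
  else centered$model_id
  centered$copy_rank <- "secondary"
  ord <- order(key, abs(centered$offset), centered$start)
  first <- !duplicated(key[ord])
  centered$copy_rank[ord[first]] <- "primary"
  centered
}

#' Signed distance of the most central dnaA copy
#'
#' Convenience accessor for the dnaA-to-centre statistic: the midpoint
#' offset of the dnaA copy nearest the centre (the primary copy when
#' several are annotated).
#'
#' @param centered Centred feature `data.frame`.
#' @return Offset in bp (negative = upstream of the centre).
#' @export
dnaa_center_offset <- function(centered) {
  d <- centered[centered$model_id == "dnaA", , drop = FALSE]
  if (nrow(d) == 0L) stop("no dnaA feature present")
  d$offset[which.min(abs(d$offset))]
}
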