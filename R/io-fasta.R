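#' Read chromosomes from a FASTA file
#'
#' Sequences are uppercased and any character outside `A/C/G/T/N` is
#' replaced by `N` with a warning. Record ids are the first whitespace-
#' delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @param topology Topology assigned to every record (`"linear"` default).
#' @return A list of [linear_chromosome()] objects.
#' @export
parse_fasta <- function(path, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    warning("non-ACGTN characters replaced by N in record(s): ",
            paste(ids[bad], collapse = ", "))
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  mapply(function(id, s) linear_chromosome(id, s, topology),
         ids, seqs, SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' Write chromosomes to a FASTA file
#'
#' Uppercase sequence, wrapped at 80 columns.
#'
#' @param chromosomes A [linear_chromosome()] or list thereof.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(chromosomes, path) {
  if (inherits(chromosomes, "linear_chromosome"))
    chromosomes <- list(chromosomes)
  seqs <- Biostrings::DNAStringSet(vapply(chromosomes, function(x) x$seq,
                                          character(1)))
  names(seqs) <- vapply(chromosomes, function(x) x$id, character(1))
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}
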