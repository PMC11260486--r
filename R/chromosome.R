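#' Construct a chromosome record
#'
#' A chromosome (or any replicon) is a named nucleotide sequence with a
#' declared topology. Sequences are stored uppercase; length is derived
#' from the sequence.
#'
#' @param id Non-empty sequence identifier.
#' @param seq Nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @param topology `"linear"` or `"circular"`.
#' @return An object of class `linear_chromosome`: a list with fields
#'   `id`, `seq`, `topology`, `length`.
#' @export
linear_chromosome <- function(id, seq, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("chromosome id must be a non-empty string")
  seq <- toupper(as.character(seq))
  structure(
    list(id = id, seq = seq, topology = topology, length = nchar(seq)),
    class = "linear_chromosome"
  )
}

#' @export
print.linear_chromosome <- function(x, ...) {
  cat(sprintf("<linear_chromosome> %s: %s bp (%s)\n",
              x$id, format(x$length, big.mark = ","), x$topology))
  invisible(x)
}

#' Construct an assembly record
#'
#' @param genome_id Genome identifier.
#' @param contigs List of [linear_chromosome()] objects with unique ids.
#' @param level Assembly level: `"complete"`, `"chromosome"`, `"contig"`
#'   or `"scaffold"`.
#' @return An object of class `assembly_record`.
#' @export
assembly_record <- function(genome_id, contigs,
                            level = c("complete", "chromosome", "contig",
                                      "scaffold")) {
  level <- match.arg(level)
  if (length(contigs) < 1L) stop("assembly must contain at least one contig")
  ids <- vapply(contigs, function(x) x$id, character(1))
  if (anyDuplicated(ids)) stop("contig ids must be unique within an assembly")
  structure(list(genome_id = genome_id, contigs = contigs, level = level),
            class = "assembly_record")
}

#' Classify assembly quality
#'
#' Assemblies are put into three classes by completeness: complete or
#' chromosome level assemblies are high-quality (HQ); contig or scaffold
#' level assemblies with at most 100 contigs are medium-quality (MQ);
#' everything else is low-quality (LQ).
#'
#' @param assembly An [assembly_record()], or an assembly level string if
#'   `n_contigs` is given.
#' @param n_contigs Contig count, used when `assembly` is a level string.
#' @return `"HQ"`, `"MQ"` or `"LQ"`.
#' @export
assembly_quality_class <- function(assembly, n_contigs = NULL) {
  if (inherits(assembly, "assembly_record")) {
    level <- assembly$level
    n_contigs <- length(assembly$contigs)
  } else {
    level <- match.arg(assembly, c("complete", "chromosome", "contig",
                                   "scaffold"))
    if (is.null(n_contigs)) stop("n_contigs required when passing a level")
  }
  if (level %in% c("complete", "chromosome")) return("HQ")
  if (n_contigs <= 100L) "MQ" else "LQ"
}

#' Reverse complement of a nucleotide string
#'
#' @param seq Character string over the DNA alphabet (IUPAC codes allowed).
#' @return The reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' GC content of a chromosome
#'
#' Fraction (G + C) / (A + C + G + T); `N` bases are excluded from the
#' denominator.
#'
#' @param chromosome A [linear_chromosome()] or a plain sequence string.
#' @return GC fraction in `[0, 1]`.
#' @export
gc_content <- function(chromosome) {
  seq <- if (inherits(chromosome, "linear_chromosome")) chromosome$seq
         else toupper(as.character(chromosome))
  if (!nzchar(seq)) stop("empty sequence")
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(seq),
                                        letters = c("A", "C", "G", "T"))
  denom <- sum(counts)
  if (denom == 0) stop("sequence contains no unambiguous A/C/G/T bases")
  unname((counts[["C"]] + counts[["G"]]) / denom)
}
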