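#' Read a plasmid marker-domain list
#'
#' One domain accession per line (PFAM-style); blank lines and `#`
#' comments are ignored. The method classifies an extrachromosomal
#' replicon as a plasmid if any of these domains is present; the list
#' itself is an input (curated lists of ~170 plasmid-specific PFAM
#' domains exist), the rule is the method.
#'
#' @param path Path to the list file.
#' @return Character vector of unique accessions with attribute
#'   `source` (path).
#' @export
read_domain_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  x <- unique(x)
  if (length(x) == 0L) stop("domain list is empty: ", path)
  attr(x, "source") <- normalizePath(path)
  x
}

#' Classify an extrachromosomal replicon
#'
#' A replicon is a plasmid iff it carries at least one hit against the
#' marker-domain list; otherwise it stays `extrachromosomal`. No
#' e-value threshold is applied (presence only). Chromosomes must not be
#' passed in.
#'
#' @param hits Character vector of domain accessions hit on the
#'   replicon, or a hit `data.frame` with a `domain_accession` column.
#' @param domain_list Marker accessions (see [read_domain_list()]).
#' @param is_chromosome Caller-provided flag; `TRUE` raises an error.
#' @return `"plasmid"` or `"extrachromosomal"`.
#' @export
classify_replicon <- function(hits, domain_list, is_chromosome = FALSE) {
  if (isTRUE(is_chromosome))
    stop("replicon is flagged as a chromosome; classification applies to ",
         "extrachromosomal elements only")
  if (is.data.frame(hits)) hits <- hits$domain_accession
  if (length(intersect(hits, domain_list)) > 0L) "plasmid"
  else "extrachromosomal"
}

#' Classify a panel of replicons from a hit table
#'
#' @param hit_table `data.frame` with columns `replicon_id`,
#'   `domain_accession` (one row per hit).
#' @param domain_list Marker accessions.
#' @param replicon_ids Replicons to classify; defaults to those present
#'   in the table. Replicons without any hit are `extrachromosomal`.
#' @return Named character vector of classes.
#' @export
classify_replicons <- function(hit_table, domain_list,
                               replicon_ids = NULL) {
  if (is.null(replicon_ids))
    replicon_ids <- unique(hit_table$replicon_id)
  vapply(replicon_ids, function(id)
    classify_replicon(hit_table$domain_accession[
      hit_table$replicon_id == id], domain_list),
    character(1))
}

#' Summarise replicon classifications
#'
#' @param classifications Character vector of `"plasmid"` /
#'   `"extrachromosomal"`.
#' @return List with `plasmid_fraction` and `counts`.
#' @export
classification_summary <- function(classifications) {
  if (length(classifications) == 0L) stop("no classifications supplied")
  counts <- table(factor(classifications,
                         levels = c("plasmid", "extrachromosomal")))
  list(plasmid_fraction = unname(counts[["plasmid"]]) /
         length(classifications),
       counts = counts)
}
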