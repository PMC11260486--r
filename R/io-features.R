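FEATURE_TYPES <- c("gene", "core_gene", "protocluster", "domain_hit")
PROTOCLUSTER_CATEGORIES <- c("NRPS", "PKS", "terpene", "RiPP",
                             "oligosaccharide", "other")

#' Build a feature table
#'
#' The internal feature representation is a plain `data.frame` with one
#' row per located annotation. Coordinates are 0-based half-open
#' (`start < end`); GFF3 and GenBank use 1-based inclusive coordinates
#' and are converted at the parsing boundary.
#'
#' @param replicon_id Replicon each feature lies on.
#' @param feature_type One of `gene`, `core_gene`, `protocluster`,
#'   `domain_hit`.
#' @param model_id Gene/model name (e.g. `dnaA`, a BUSCO model id, or a
#'   protocluster product type).
#' @param start,end 0-based half-open coordinates.
#' @param strand `"+"` or `"-"`.
#' @param category Protocluster category (`NA` for non-protoclusters).
#' @param status Optional status flag (e.g. BUSCO `Complete`,
#'   `Duplicated`, `Fragmented`).
#' @return A `data.frame` of feature records.
#' @export
feature_table <- function(replicon_id, feature_type, model_id, start, end,
                          strand, category = NA_character_,
                          status = NA_character_) {
  if (length(start) == 0L)
    return(data.frame(replicon_id = character(), feature_type = character(),
                      model_id = character(), category = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), status = character(),
                      stringsAsFactors = FALSE))
  df <- data.frame(replicon_id = replicon_id,
                   feature_type = feature_type,
                   model_id = model_id,
                   category = category,
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = strand,
                   status = status,
                   stringsAsFactors = FALSE)
  validate_features(df)
}

#' Validate a feature table
#'
#' Checks coordinate sanity (`0 <= start < end`, and `end <= L` when a
#' replicon length is supplied), strand values, and that protoclusters —
#' and only protoclusters — carry a category.
#'
#' @param features Feature `data.frame`.
#' @param replicon_lengths Optional named vector of replicon lengths.
#' @return `features`, invisibly-checked (returned unchanged).
#' @export
validate_features <- function(features, replicon_lengths = NULL) {
  need <- c("replicon_id", "feature_type", "model_id", "category",
            "start", "end", "strand")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("feature table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(features) == 0L) return(features)
  if (!all(features$feature_type %in% FEATURE_TYPES))
    stop("unknown feature_type value(s)")
  if (!all(features$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  bad <- which(!(features$start >= 0 & features$start < features$end))
  if (length(bad))
    stop("invalid coordinates (need 0 <= start < end) in row(s): ",
         paste(head(bad, 5), collapse = ", "))
  if (!is.null(replicon_lengths)) {
    L <- replicon_lengths[features$replicon_id]
    over <- which(!is.na(L) & features$end > L)
    if (length(over))
      stop("feature end exceeds replicon length in row(s): ",
           paste(head(over, 5), collapse = ", "))
  }
  is_pc <- features$feature_type == "protocluster"
  if (any(is_pc & (is.na(features$category) | !nzchar(features$category))))
    stop("protocluster features must carry a category")
  if (any(!is_pc & !is.na(features$category)))
    stop("category must be empty for non-protocluster features")
  features
}

#' Read a feature table from GFF3 or a BUSCO full table
#'
#' GFF3 is read through `rtracklayer`; coordinates are converted from
#' 1-based inclusive to the internal 0-based half-open convention.
#' BUSCO-style full tables (tab-separated, `#` comments; columns model id,
#' status, sequence, start, end, strand, ...) drop rows with status
#' `Missing`, retain all `Duplicated` rows, and retain `Fragmented` rows
#' flagged via the `status` column so callers can decide about them.
#'
#' @param path Input file.
#' @param format `"gff3"` or `"busco_tsv"`.
#' @return Feature `data.frame` (see [feature_table()]).
#' @export
parse_feature_table <- function(path, format = c("gff3", "busco_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "gff3") parse_gff3(path) else parse_busco_table(path)
}

parse_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L)
    return(feature_table(character(), character(), character(),
                         numeric(), numeric(), character()))
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  ftype <- ifelse(type %in% FEATURE_TYPES, type, "gene")
  model <- if ("Name" %in% names(meta)) as.character(meta$Name)
           else rep(NA_character_, length(gr))
  if ("ID" %in% names(meta))
    model <- ifelse(is.na(model), as.character(meta$ID), model)
  category <- if ("category" %in% names(meta)) as.character(meta$category)
              else rep(NA_character_, length(gr))
  category[ftype != "protocluster"] <- NA_character_
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  start1 <- BiocGenerics::start(gr)
  end1 <- BiocGenerics::end(gr)
  bad <- which(start1 - 1 >= end1)
  if (length(bad))
    stop("start > end after coordinate conversion in GFF3 row(s): ",
         paste(head(bad, 5), collapse = ", "))
  feature_table(as.character(GenomicRanges::seqnames(gr)), ftype, model,
                start1 - 1, end1, strand, category)
}

parse_busco_table <- function(path) {
  raw <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 6)
    stop("BUSCO full table needs at least 6 columns ",
         "(model, status, sequence, start, end, strand)")
  names(raw)[1:6] <- c("model_id", "status", "sequence", "start", "end",
                       "strand")
  keep <- raw$status != "Missing"
  raw <- raw[keep, , drop = FALSE]
  if (nrow(raw) == 0L)
    return(feature_table(character(), character(), character(),
                         numeric(), numeric(), character()))
  start0 <- as.numeric(raw$start) - 1
  end0 <- as.numeric(raw$end)
  bad <- which(!(start0 < end0))
  if (length(bad))
    stop("start > end after coordinate conversion for BUSCO model(s): ",
         paste(head(raw$model_id[bad], 5), collapse = ", "))
  feature_table(raw$sequence, "core_gene", raw$model_id, start0, end0,
                raw$strand, status = raw$status)
}

#' Write a feature table as GFF3
#'
#' Internal 0-based half-open coordinates are converted back to the
#' 1-based inclusive GFF3 convention, so `write` and `parse` are mutually
#' inverse on well-formed input.
#'
#' @param features Feature `data.frame`.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, source = "linchrom") {
  validate_features(features)
  gr <- GenomicRanges::GRanges(
    seqnames = features$replicon_id,
    ranges = IRanges::IRanges(start = features$start + 1,
                              end = features$end),
    strand = features$strand)
  S4Vectors::mcols(gr)$source <- source
  S4Vectors::mcols(gr)$type <- features$feature_type
  S4Vectors::mcols(gr)$ID <- sprintf("feat%06d", seq_len(nrow(features)))
  S4Vectors::mcols(gr)$Name <- features$model_id
  S4Vectors::mcols(gr)$category <- features$category
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
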