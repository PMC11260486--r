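# Product-type -> category fallback for antiSMASH records that lack an
# explicit /category qualifier (older outputs). Unlisted products map to
# "other".
AS_PRODUCT_CATEGORY <- c(
  T1PKS = "PKS", T2PKS = "PKS", T3PKS = "PKS", `transAT-PKS` = "PKS",
  `transAT-PKS-like` = "PKS", `PKS-like` = "PKS", `hglE-KS` = "PKS",
  arylpolyene = "PKS",
  NRPS = "NRPS", `NRPS-like` = "NRPS", CDPS = "NRPS",
  `NRP-metallophore` = "NRPS", `thioamide-NRP` = "NRPS", NAPAA = "NRPS",
  terpene = "terpene", `terpene-precursor` = "terpene",
  lassopeptide = "RiPP", thiopeptide = "RiPP", `RiPP-like` = "RiPP",
  `lanthipeptide-class-i` = "RiPP", `lanthipeptide-class-ii` = "RiPP",
  `lanthipeptide-class-iii` = "RiPP", `lanthipeptide-class-iv` = "RiPP",
  `lanthipeptide-class-v` = "RiPP", linaridin = "RiPP", LAP = "RiPP",
  cyanobactin = "RiPP", sactipeptide = "RiPP", bottromycin = "RiPP",
  microviridin = "RiPP", proteusin = "RiPP", ranthipeptide = "RiPP",
  epipeptide = "RiPP", `RRE-containing` = "RiPP", thioamitides = "RiPP",
  oligosaccharide = "oligosaccharide", saccharide = "oligosaccharide",
  amglyccycl = "oligosaccharide", cyclitol = "oligosaccharide")

normalize_as_category <- function(category, product) {
  if (!is.na(category) && nzchar(category)) {
    if (category %in% c("saccharide", "oligosaccharide"))
      return("oligosaccharide")
    if (category %in% PROTOCLUSTER_CATEGORIES) return(category)
    return("other")
  }
  cat <- AS_PRODUCT_CATEGORY[product]
  if (is.na(cat)) "other" else unname(cat)
}

#' Extract protocluster records from an antiSMASH GenBank file
#'
#' antiSMASH reports biosynthetic gene clusters at two annotation levels:
#' per-rule `protocluster` features and merged `region` features. This
#' parser emits one record per protocluster feature, never per region, so
#' hybrid regions contribute one record for each of their constituent
#' protoclusters. Each record carries the product type (`model_id`) and
#' one of the six antiSMASH categories: NRPS, PKS, terpene, RiPP,
#' oligosaccharide, other. The `/category` qualifier is used when present
#' and otherwise inferred from the product type.
#'
#' GenBank coordinates (1-based inclusive, possibly
#' `complement(a..b)` with `<`/`>` partial markers) are converted to the
#' internal 0-based half-open convention.
#'
#' @param path antiSMASH-annotated GenBank file (may contain several
#'   LOCUS records).
#' @return Feature `data.frame` with `feature_type = "protocluster"`.
#' @export
parse_antismash_protoclusters <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  locus <- NA_character_
  in_features <- FALSE
  feats <- list()          # each: list(key, location, quals = char lines)
  current <- NULL
  flush <- function() {
    if (!is.null(current) && current$key %in% c("protocluster", "region"))
      feats[[length(feats) + 1L]] <<- current
    current <<- NULL
  }
  for (ln in lines) {
    if (grepl("^LOCUS\\s", ln)) {
      flush(); in_features <- FALSE
      locus <- strsplit(trimws(sub("^LOCUS", "", ln)), "\\s+")[[1]][1]
      next
    }
    if (grepl("^FEATURES", ln)) { in_features <- TRUE; next }
    if (grepl("^ORIGIN", ln) || grepl("^//", ln)) {
      flush(); in_features <- FALSE; next
    }
    if (!in_features) next
    m <- regmatches(ln, regexec("^     (\\S+)\\s+(\\S.*)$", ln))[[1]]
    if (length(m) == 3L) {             # new feature line
      flush()
      current <- list(key = m[2], location = m[3], quals = character(),
                      locus = locus)
    } else if (!is.null(current)) {    # qualifier / continuation line
      current$quals <- c(current$quals, trimws(ln))
    }
  }
  flush()

  pcs <- Filter(function(f) f$key == "protocluster", feats)
  if (length(pcs) == 0L)
    return(feature_table(character(), character(), character(),
                         numeric(), numeric(), character()))

  rows <- lapply(seq_along(pcs), function(i) {
    f <- pcs[[i]]
    loc <- parse_genbank_location(f$location)
    qual <- parse_genbank_qualifiers(f$quals)
    product <- qual[["product"]]
    if (is.null(product) || !nzchar(product))
      stop("protocluster feature without a product qualifier at ",
           f$locus, ":", f$location)
    category <- normalize_as_category(
      if (is.null(qual[["category"]])) NA_character_ else qual[["category"]],
      product)
    data.frame(replicon_id = f$locus, feature_type = "protocluster",
               model_id = product, category = category,
               start = loc$start, end = loc$end, strand = loc$strand,
               status = NA_character_, stringsAsFactors = FALSE)
  })
  validate_features(do.call(rbind, rows))
}

# "complement(<123..456)" -> 0-based half-open span + strand
parse_genbank_location <- function(loc) {
  strand <- if (grepl("^complement", loc)) "-" else "+"
  nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
  if (length(nums) < 2L) stop("cannot parse GenBank location: ", loc)
  nums <- as.numeric(nums)
  list(start = min(nums) - 1, end = max(nums), strand = strand)
}

# Qualifier continuation lines are joined; values may span lines.
parse_genbank_qualifiers <- function(lines) {
  if (length(lines) == 0L) return(list())
  starts <- grepl("^/", lines)
  idx <- cumsum(starts)
  joined <- vapply(split(lines, idx), paste, character(1), collapse = " ")
  joined <- joined[grepl("^/", joined)]
  out <- list()
  for (q in joined) {
    m <- regmatches(q, regexec('^/([^=]+)=(.*)$', q))[[1]]
    if (length(m) == 3L) {
      val <- gsub('^"|"$', "", trimws(m[3]))
      out[[m[2]]] <- val
    } else {
      out[[sub("^/", "", q)]] <- TRUE
    }
  }
  out
}
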