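# Shared helpers: small sequence/annotation fixtures built in code.

rand_seq <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

write_fasta_text <- function(records, path = tempfile(fileext = ".fa")) {
  con <- file(path, "w")
  for (id in names(records)) {
    writeLines(paste0(">", id), con)
    writeLines(records[[id]], con)
  }
  close(con)
  path
}

# Minimal antiSMASH-dialect GenBank writer. `features` is a list of
# lists with key, location, and qualifiers (named character vector).
write_gbk <- function(loci, path = tempfile(fileext = ".gbk")) {
  con <- file(path, "w")
  for (locus in names(loci)) {
    writeLines(sprintf(
      "LOCUS       %s            100000 bp    DNA     linear   BCT",
      locus), con)
    writeLines("DEFINITION  synthetic antiSMASH-style record.", con)
    writeLines("FEATURES             Location/Qualifiers", con)
    for (f in loci[[locus]]) {
      writeLines(sprintf("     %-16s%s", f$key, f$location), con)
      for (qn in names(f$quals))
        writeLines(sprintf('                     /%s="%s"', qn,
                           f$quals[[qn]]), con)
    }
    writeLines("ORIGIN", con)
    writeLines("//", con)
  }
  close(con)
  path
}

proto <- function(location, product, category = NULL) {
  quals <- c(aStool = "rule-based-clusters", product = product)
  if (!is.null(category)) quals <- c(quals, category = category)
  list(key = "protocluster", location = location, quals = quals)
}

region <- function(location, product = "hybrid") {
  list(key = "region", location = location,
       quals = c(product = product))
}

busco_table_text <- function(rows, path = tempfile(fileext = ".tsv")) {
  con <- file(path, "w")
  writeLines("# BUSCO version is: 5.4.7", con)
  writeLines(paste("# Busco id", "Status", "Sequence", "Gene Start",
                   "Gene End", "Strand", "Score", "Length", sep = "\t"),
             con)
  for (r in rows) writeLines(paste(r, collapse = "\t"), con)
  close(con)
  path
}

# substitute a fraction of positions in a sequence string
mutate_string <- function(s, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- strsplit(s, "")[[1]]
  n <- rbinom(1, length(v), rate)
  if (n > 0) {
    pos <- sample(length(v), n)
    b <- c("A", "C", "G", "T")
    v[pos] <- vapply(v[pos], function(x) sample(b[b != x], 1),
                     character(1))
  }
  paste(v, collapse = "")
}

# exact canonical k-mer set of a sequence (brute-force oracle)
canonical_kmers <- function(s, k = 21) {
  n <- nchar(s)
  ss <- substring(s, 1:(n - k + 1), k:n)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(ss)))
  unique(ifelse(ss <= rc, ss, rc))
}

# Mash distance from an exact Jaccard index
mash_from_jaccard <- function(j, k = 21) {
  if (j == 0) return(1)
  min(1, -(1 / k) * log(2 * j / (1 + j)))
}

# all set partitions of 1..n as restricted-growth strings
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_max) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return()
    }
    for (lab in seq_len(next_max + 1L))
      recurse(c(labels, lab), max(next_max, lab))
  }
  recurse(integer(0), 0L)
  out
}

# hand-computed modularity for the exhaustive-search oracle
modularity_by_hand <- function(edges, membership) {
  m <- nrow(edges)
  deg <- table(factor(c(edges[, 1], edges[, 2]),
                      levels = seq_along(membership)))
  e_in <- sum(membership[edges[, 1]] == membership[edges[, 2]]) / m
  exp_in <- sum(tapply(as.numeric(deg), membership, sum)^2) / (2 * m)^2
  e_in - exp_in
}
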