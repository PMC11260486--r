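test_that("FASTA parsing normalises sequences and rejects bad files", {
  p <- write_fasta_text(list(chr1 = strrep("ACGT", 25),
                             chr2 = strrep("acgtacgtac", 20)))
  chroms <- parse_fasta(p)
  expect_length(chroms, 2)
  expect_equal(vapply(chroms, function(x) x$length, numeric(1)),
               c(chr1 = 100, chr2 = 200))
  expect_equal(substr(chroms$chr2$seq, 1, 4), "ACGT")  # uppercased

  p2 <- write_fasta_text(list(amb = "ACGRTT"))
  expect_warning(ch <- parse_fasta(p2), "non-ACGTN")
  expect_equal(ch$amb$seq, "ACGNTT")

  pdup <- write_fasta_text(list(a = "ACGT"))
  cat(">a\nGGCC\n", file = pdup, append = TRUE)
  expect_error(parse_fasta(pdup), "duplicate")
  pe <- tempfile(); file.create(pe)
  expect_error(parse_fasta(pe), "no records|empty")
})

test_that("FASTA write/parse round-trip is identity on records", {
  chroms <- list(linear_chromosome("c1", rand_seq(333, seed = 1)),
                 linear_chromosome("c2", rand_seq(85, seed = 2)))
  p <- tempfile(fileext = ".fa")
  write_fasta(chroms, p)
  back <- parse_fasta(p)
  expect_equal(unname(vapply(back, function(x) x$seq, character(1))),
               vapply(chroms, function(x) x$seq, character(1)))
})

test_that("GFF3 coordinates convert at the boundary and round-trip", {
  ft <- feature_table(replicon_id = "chr1",
                      feature_type = c("gene", "core_gene", "protocluster"),
                      model_id = c("dnaA", "core_001", "T1PKS"),
                      start = c(0, 150, 5000), end = c(100, 300, 25000),
                      strand = c("+", "-", "+"),
                      category = c(NA, NA, "PKS"))
  p <- tempfile(fileext = ".gff3")
  write_gff3(ft, p)
  # external convention is 1-based inclusive
  body <- read.delim(p, header = FALSE, comment.char = "#")
  expect_equal(body$V4[1], 1)    # internal 0 -> GFF3 1
  expect_equal(body$V5[1], 100)
  back <- parse_feature_table(p, "gff3")
  expect_equal(back$start, ft$start)
  expect_equal(back$end, ft$end)
  expect_equal(back$strand, ft$strand)
  expect_equal(back$model_id, ft$model_id)
  expect_equal(back$category, ft$category)
  # involution: writing the parse reproduces the file records
  p2 <- tempfile(fileext = ".gff3")
  write_gff3(back, p2)
  expect_equal(read.delim(p2, header = FALSE, comment.char = "#"), body)
})

test_that("BUSCO tables keep duplicates, drop missing, flag fragmented", {
  p <- busco_table_text(list(
    c("100at2", "Complete", "chr1", "1", "1500", "+", "500", "1500"),
    c("200at2", "Duplicated", "chr1", "5000", "6200", "-", "400", "1200"),
    c("200at2", "Duplicated", "chr1", "90000", "91200", "+", "398", "1200"),
    c("300at2", "Missing", "", "", "", "", "", ""),
    c("334658at1760", "Fragmented", "chr1", "7000", "7300", "+", "90",
      "300")))
  ft <- parse_feature_table(p, "busco_tsv")
  expect_equal(nrow(ft), 4)                      # Missing dropped
  expect_equal(sum(ft$model_id == "200at2"), 2)  # both Duplicated kept
  expect_true("334658at1760" %in% ft$model_id)   # Fragmented retained...
  expect_equal(ft$status[ft$model_id == "334658at1760"], "Fragmented")
  expect_equal(ft$start[ft$model_id == "100at2"], 0)  # 1-based -> 0-based
  expect_equal(ft$end[ft$model_id == "100at2"], 1500)

  pbad <- busco_table_text(list(
    c("bad1at2", "Complete", "chr1", "900", "100", "+", "1", "100")))
  expect_error(parse_feature_table(pbad, "busco_tsv"), "bad1at2")
})

test_that("antiSMASH protoclusters are extracted per protocluster, not per region", {
  gbk <- system.file("extdata", "antismash_synthetic.gbk",
                     package = "linchrom")
  pcs <- parse_antismash_protoclusters(gbk)
  # one record per protocluster feature; the hybrid region contributes
  # one record per constituent protocluster
  expect_equal(nrow(pcs), 5)
  expect_false("region" %in% pcs$feature_type)
  scan <- sum(grepl("^     protocluster", readLines(gbk)))  # text oracle
  expect_equal(nrow(pcs), scan)

  a <- pcs[pcs$replicon_id == "synthA", ]
  expect_equal(a$category, c("PKS", "NRPS", "terpene"))
  expect_equal(a$start, c(0, 19999, 60000))   # 1-based inclusive -> 0-based
  expect_equal(a$end, c(45000, 50000, 90000))
  b <- pcs[pcs$replicon_id == "synthB", ]
  expect_equal(b$category, c("RiPP", "other"))  # product-based fallback
  expect_equal(b$strand, c("-", "+"))

  # vacuous case and missing product
  empty <- write_gbk(list(locusX = list(region("1..100"))))
  expect_equal(nrow(parse_antismash_protoclusters(empty)), 0)
  bad <- write_gbk(list(locusY = list(
    list(key = "protocluster", location = "1..100",
         quals = c(aStool = "rule-based-clusters")))))
  expect_error(parse_antismash_protoclusters(bad), "product")
})

test_that("assembly quality classes split at the documented boundaries", {
  chr <- linear_chromosome("c", "ACGT")
  mk <- function(n) lapply(seq_len(n), function(i)
    linear_chromosome(paste0("c", i), "ACGT"))
  expect_equal(assembly_quality_class(
    assembly_record("g", mk(3), "chromosome")), "HQ")
  expect_equal(assembly_quality_class("contig", n_contigs = 100), "MQ")
  expect_equal(assembly_quality_class("contig", n_contigs = 101), "LQ")
  expect_equal(assembly_quality_class("complete", n_contigs = 1), "HQ")
  expect_error(assembly_record("g", list(chr, chr), "contig"), "unique")
})

test_that("GC content excludes N from the denominator", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("ANGC"), 2 / 3)
  expect_error(gc_content("NNNN"), "no unambiguous")
})
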