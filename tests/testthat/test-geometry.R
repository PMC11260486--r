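dnaa_feature <- function(start, end, strand, L = 1000) {
  feature_table("chr", "gene", "dnaA", start, end, strand)
}

test_that("dnaA orientation is identity on forward genomes and exact on reversed", {
  chrom <- linear_chromosome("chr", rand_seq(1000, seed = 1))
  fwd <- orient_by_dnaA(chrom, dnaa_feature(100, 200, "+"))
  expect_false(fwd$flipped)
  expect_identical(fwd$chromosome$seq, chrom$seq)
  expect_identical(fwd$features$start, 100)

  rev <- orient_by_dnaA(chrom, dnaa_feature(100, 200, "-"))
  expect_true(rev$flipped)
  expect_equal(rev$features$start, 800)
  expect_equal(rev$features$end, 900)
  expect_equal(rev$features$strand, "+")
  expect_identical(rev$chromosome$seq, revcomp(chrom$seq))
})

test_that("orientation errors match the preconditions", {
  chrom <- linear_chromosome("chr", rand_seq(1000, seed = 2))
  none <- feature_table("chr", "gene", "gyrB", 10, 50, "+")
  expect_error(orient_by_dnaA(chrom, none), "dnaA")
  two <- feature_table("chr", "gene", c("dnaA", "dnaA"),
                       c(10, 500), c(50, 600), c("+", "-"))
  expect_error(orient_by_dnaA(chrom, two), "opposite strands")
})

test_that("orientation is an involution preserving |offset| (50 random genomes)", {
  for (i in 1:50) {
    g <- generate_chromosome(synth_config(L = 20000, n_core = 8,
                                          gene_len = c(200, 400),
                                          seed = 1000 + i))
    once <- orient_by_dnaA(g$chromosome, g$features)
    # force two successive flips by putting dnaA back on the minus
    # strand each time: the flip transform must undo itself
    flip_once <- function(x) {
      f <- x$features
      f$strand <- ifelse(f$strand == "+", "-", "+")
      orient_by_dnaA(x$chromosome, f)
    }
    mid <- flip_once(once)
    expect_true(mid$flipped)
    twice <- flip_once(mid)
    expect_identical(twice$chromosome$seq, once$chromosome$seq)
    expect_equal(twice$features$start, once$features$start)
    expect_equal(twice$features$end, once$features$end)
    # orientation recovers the planted dnaA-forward frame
    expect_equal(sort(center_offset(once$features, g$L)$offset),
                 sort(g$truth$offset))
    # |offset| is invariant under orientation
    c0 <- center_offset(g$features, g$L)
    c1 <- center_offset(once$features, g$L)
    expect_equal(sort(abs(c1$offset)), sort(abs(c0$offset)))
  }
})

test_that("centre offsets follow the midpoint convention", {
  f <- feature_table("chr", "gene", c("a", "b", "c"),
                     start = c(450, 100, 0), end = c(550, 200, 1000),
                     strand = "+")
  cen <- center_offset(f, 1000)
  expect_equal(cen$midpoint, c(500, 150, 500))
  expect_equal(cen$offset, c(0, -350, 0))
  expect_equal(cen$arm_pos, c(0, -0.7, 0))
  expect_true(all(abs(cen$arm_pos) <= 1))
  expect_error(center_offset(f, 0), "positive")
})

test_that("the most central copy is primary, ties to the smaller start", {
  f <- feature_table("chr", "core_gene", c("m1", "m1", "m2"),
                     start = c(490000, 880000, 10000),
                     end = c(492000, 882000, 12000), strand = "+")
  cen <- assign_primary_copies(center_offset(f, 1e6))
  expect_equal(cen$copy_rank, c("primary", "secondary", "primary"))
  # offsets -10000 vs +400000: most central wins
  expect_equal(cen$offset[cen$copy_rank == "primary" &
                            cen$model_id == "m1"], -9000)
  # exact |offset| tie: equidistant copies, smaller start is primary
  tie <- feature_table("chr", "core_gene", "t", c(400, 550), c(450, 600),
                       strand = "+")
  ct <- assign_primary_copies(center_offset(tie, 1000))
  expect_equal(ct$copy_rank[ct$start == 400], "primary")
  single <- assign_primary_copies(center_offset(
    feature_table("chr", "core_gene", "s", 1, 5, "+"), 1000))
  expect_equal(single$copy_rank, "primary")
})

test_that("per model there is exactly one primary attaining min |offset|", {
  coh <- generate_cohort(5, L = 1e6, n_core = 20, n_dup = 5, n_bgc = 0,
                         seed = 17)
  cen <- assign_primary_copies(center_offset(
    coh$features[coh$features$feature_type == "core_gene", ],
    coh$lengths))
  for (g in unique(cen$genome_id)) {
    sub <- cen[cen$genome_id == g, ]
    for (m in unique(sub$model_id)) {
      copies <- sub[sub$model_id == m, ]
      expect_equal(sum(copies$copy_rank == "primary"), 1)
      expect_equal(min(abs(copies$offset)),
                   abs(copies$offset[copies$copy_rank == "primary"]))
      # a secondary copy is never more central than its primary
      if (nrow(copies) > 1)
        expect_true(all(abs(copies$offset[copies$copy_rank ==
          "secondary"]) >= abs(copies$offset[copies$copy_rank ==
          "primary"])))
    }
  }
})

test_that("dnaA distance statistic uses the most central copy", {
  f <- feature_table("chr", "gene", c("dnaA", "dnaA"),
                     start = c(480000, 900000), end = c(482000, 902000),
                     strand = "+")
  cen <- center_offset(f, 1e6)
  expect_equal(dnaa_center_offset(cen), -19000)
})
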