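test_that("sketching is deterministic, canonical, and boundary-safe", {
  s <- rand_seq(5000, seed = 61)
  a <- minhash_sketch(s, genome_id = "a")
  b <- minhash_sketch(s, genome_id = "a")
  expect_identical(a$hashes, b$hashes)
  expect_false(is.unsorted(a$hashes, strictly = TRUE))
  # a genome and its reverse complement share every canonical k-mer
  rc <- minhash_sketch(revcomp(s), genome_id = "rc")
  expect_identical(a$hashes, rc$hashes)
  # fewer distinct k-mers than s: the sketch holds all of them
  tiny <- minhash_sketch(rand_seq(120, seed = 62), genome_id = "t")
  expect_lt(length(tiny$hashes), tiny$s)
  expect_equal(length(tiny$hashes), 120 - 21 + 1)  # all distinct here
  # k-mers containing N are skipped
  with_n <- minhash_sketch(paste0(substr(s, 1, 100), "N",
                                  substr(s, 102, 5000)), genome_id = "n")
  expect_lte(length(setdiff(a$hashes, with_n$hashes)), 21)
  expect_error(minhash_sketch("ACGT"), "shorter than k")
  expect_error(minhash_sketch(s, k = 20), "odd")
})

test_that("Mash distance has its fixed points and caps", {
  s <- rand_seq(3000, seed = 63)
  a <- minhash_sketch(s, genome_id = "a")
  expect_equal(mash_distance(a, a), 0)
  b <- minhash_sketch(rand_seq(3000, seed = 64), genome_id = "b")
  expect_equal(mash_distance(a, b), 1)   # disjoint sketches cap at 1
  k15 <- minhash_sketch(s, k = 15, genome_id = "a15")
  expect_error(mash_distance(a, k15), "mismatched")
})

test_that("sketch distance agrees with the exact-Jaccard oracle", {
  base <- rand_seq(50000, seed = 65, gc = 0.72)
  mut <- mutate_string(base, 0.01, seed = 66)
  j <- length(intersect(canonical_kmers(base), canonical_kmers(mut))) /
    length(union(canonical_kmers(base), canonical_kmers(mut)))
  d_full <- mash_from_jaccard(j)
  d_sketch <- mash_distance(minhash_sketch(base, genome_id = "a"),
                            minhash_sketch(mut, genome_id = "b"))
  expect_lt(abs(d_full - d_sketch), 0.01)
})

test_that("estimated distance increases with the substitution rate", {
  means <- vapply(c(0.001, 0.01, 0.05), function(rate) {
    mean(vapply(1:10, function(rep) {
      base <- rand_seq(10000, seed = 700 + rep)
      mut <- mutate_string(base, rate, seed = 800 + rep)
      mash_distance(minhash_sketch(base, genome_id = "a"),
                    minhash_sketch(mut, genome_id = "b"))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("the similarity network applies the cutoff and keeps isolates", {
  D <- matrix(c(0, 0.01, 0.2,
                0.01, 0, 0.2,
                0.2, 0.2, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  net <- build_similarity_network(D, cutoff = 0.05)
  expect_equal(igraph::ecount(net$graph), 1)
  expect_equal(igraph::vcount(net$graph), 3)
  far <- build_similarity_network(D + 0.5 * (1 - diag(3)), cutoff = 0.05)
  expect_equal(igraph::ecount(far$graph), 0)
  comm <- louvain_communities(far, seed = 1)
  expect_equal(species_summary(comm)$n_singletons, 3)
  Dasym <- D; Dasym[1, 2] <- 0.02
  expect_error(build_similarity_network(Dasym), "symmetric")
  expect_equal(formals(build_similarity_network)$cutoff, 0.05)
})

test_that("Louvain attains the exhaustive-search optimum on two triangles", {
  edges <- rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))
  D <- matrix(1, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  diag(D) <- 0
  for (r in seq_len(nrow(edges))) D[edges[r, 1], edges[r, 2]] <-
      D[edges[r, 2], edges[r, 1]] <- 0.01
  net <- louvain_communities(build_similarity_network(D, 0.05), seed = 4)
  # oracle: enumerate all 203 partitions of 6 nodes, hand-computed Q
  qs <- vapply(all_partitions(6), function(p)
    modularity_by_hand(edges, p), numeric(1))
  expect_equal(max(qs), 0.5)
  expect_equal(net$Q, 0.5)
  expect_equal(species_summary(net)$n_species, 2)
  expect_equal(unname(net$communities[1:3]),
               rep(net$communities[["a"]], 3))
  # partition quality invariants
  g <- net$graph
  expect_gte(net$Q, modularity_direct(g, rep(1L, 6)))
  expect_gte(net$Q, modularity_direct(g, 1:6))
  expect_equal(net$Q, modularity_direct(g, net$communities))
})

test_that("single nodes and empty graphs behave at the boundary", {
  D1 <- matrix(0, 1, 1, dimnames = list("only", "only"))
  net <- louvain_communities(build_similarity_network(D1), seed = 1)
  expect_equal(species_summary(net)$n_species, 1)
  empty <- build_similarity_network(matrix(numeric(0), 0, 0))
  expect_error(louvain_communities(empty), "empty")
  expect_error(species_summary(setNames(integer(0), character(0))),
               "no community")
})

test_that("planted species clusters are recovered exactly", {
  ss <- generate_species_set(3, 4, within_rate = 0.005, L = 20000,
                             seed = 67)
  sk <- lapply(ss$genomes, minhash_sketch)
  D <- mash_distance_matrix(sk)
  # divergence structure separates cleanly at the 0.05 cutoff
  within <- outer(ss$truth$cluster, ss$truth$cluster, "==")
  expect_lt(max(D[within & upper.tri(D)]), 0.05)
  expect_gt(min(D[!within & upper.tri(D)]), 0.05)
  net <- build_similarity_network(D, cutoff = 0.05)
  for (seed in 1:5) {
    res <- louvain_communities(net, seed = seed)
    expect_equal(species_summary(res)$n_species, 3)
    agree <- igraph::compare(res$communities,
                             ss$truth$cluster, method = "adjusted.rand")
    expect_equal(agree, 1)
  }
})

test_that("species summaries count communities and singletons", {
  expect_equal(species_summary(c(a = 1, b = 1, c = 2, d = 3, e = 4)),
               list(n_species = 4, n_singletons = 3,
                    sizes = c(2L, 1L, 1L, 1L)))
  expect_equal(species_summary(rep(1L, 10))$n_singletons, 0)
})
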