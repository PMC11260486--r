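#' MinHash sketch of a genome
#'
#' Bottom-s MinHash sketch of the genome's canonical k-mers (the
#' lexicographic minimum of each k-mer and its reverse complement, so a
#' sequence and its reverse complement sketch identically). k-mers
#' containing `N` are skipped. Hash values are a 53-bit mix of the
#' 2-bit-encoded canonical k-mer with the sketch seed; 53 bits keeps
#' every value exactly representable as an R double, and at sketch sizes
#' of a few thousand the extra collision probability is negligible.
#'
#' @param genome A [linear_chromosome()], a list of them (multi-replicon
#'   genome), or a character vector of sequences.
#' @param k k-mer length (odd, <= 31).
#' @param s Sketch size: number of smallest distinct hashes retained
#'   (fewer only if the genome has fewer distinct k-mers).
#' @param hash_seed Seed of the hash function (not an RNG seed; sketches
#'   are deterministic).
#' @param genome_id Identifier stored in the sketch.
#' @return A `genome_sketch`: list with `genome_id`, `k`, `s`,
#'   `hash_seed`, `hashes` (sorted ascending, distinct).
#' @export
minhash_sketch <- function(genome, k = 21, s = 1000, hash_seed = 42,
                           genome_id = NULL) {
  if (inherits(genome, "linear_chromosome")) genome <- list(genome)
  if (is.list(genome)) {
    if (is.null(genome_id)) genome_id <- genome[[1]]$id
    seqs <- vapply(genome, function(x) x$seq, character(1))
  } else {
    seqs <- as.character(genome)
    if (is.null(genome_id)) genome_id <- "genome"
  }
  if (k %% 2 == 0) stop("k must be odd (canonical k-mers)")
  if (max(nchar(seqs)) < k) stop("sequence shorter than k")
  hashes <- minhash_sketch_cpp(seqs, as.integer(k), as.integer(s),
                               as.numeric(hash_seed))
  structure(list(genome_id = genome_id, k = k, s = s,
                 hash_seed = hash_seed, hashes = hashes),
            class = "genome_sketch")
}

#' @export
print.genome_sketch <- function(x, ...) {
  cat(sprintf("<genome_sketch> %s: k=%d, |hashes|=%d/%d\n", x$genome_id,
              x$k, length(x$hashes), x$s))
  invisible(x)
}

#' Mash distance between two sketches
#'
#' The Jaccard index is estimated from the s smallest hashes of the
#' merged hash sets: `j = shared / s'` where `s'` is the merged bottom
#' size (at most `s`). The distance is
#' `D = -(1/k) * log(2j / (1 + j))`, capped at 1 (`j = 0` gives 1,
#' `j = 1` gives 0).
#'
#' @param sketch_a,sketch_b `genome_sketch` objects with identical `k`
#'   and `hash_seed`.
#' @return Distance in `[0, 1]`.
#' @export
mash_distance <- function(sketch_a, sketch_b) {
  stopifnot(inherits(sketch_a, "genome_sketch"),
            inherits(sketch_b, "genome_sketch"))
  if (sketch_a$k != sketch_b$k || sketch_a$hash_seed != sketch_b$hash_seed)
    stop("sketches have mismatched k or hash seed")
  merged <- sort(unique(c(sketch_a$hashes, sketch_b$hashes)))
  s0 <- min(sketch_a$s, length(merged))
  bottom <- merged[seq_len(s0)]
  shared <- sum(bottom %in% sketch_a$hashes & bottom %in% sketch_b$hashes)
  j <- shared / s0
  if (j == 0) return(1)
  min(1, max(0, -(1 / sketch_a$k) * log(2 * j / (1 + j))))
}

#' Pairwise Mash distance matrix
#'
#' @param sketches List of `genome_sketch` objects.
#' @return Symmetric matrix of distances with genome ids as dimnames.
#' @export
mash_distance_matrix <- function(sketches) {
  n <- length(sketches)
  ids <- vapply(sketches, function(x) x$genome_id, character(1))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(D)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- mash_distance(sketches[[i]], sketches[[j]])
  }
  D
}

#' Build a genome similarity network from distances
#'
#' Genomes are nodes; an (unweighted) edge joins every pair at distance
#' at most `cutoff`. The default cutoff 0.05 corresponds to the 95%
#' whole-genome similarity convention for species delineation. Genomes
#' without any neighbour are kept as isolated nodes.
#'
#' @param distances Symmetric distance matrix (dimnames = genome ids).
#' @param cutoff Edge distance cutoff.
#' @return A `similarity_network`: list with `graph` (igraph),
#'   `cutoff`, `communities` (`NULL` until [louvain_communities()]),
#'   `Q`.
#' @export
build_similarity_network <- function(distances, cutoff = 0.05) {
  distances <- as.matrix(distances)
  if (nrow(distances) != ncol(distances) ||
      (length(distances) > 0 &&
       max(abs(distances - t(distances))) > 1e-12))
    stop("distance matrix must be symmetric")
  adj <- (distances <= cutoff)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  structure(list(graph = g, cutoff = cutoff, communities = NULL,
                 Q = NA_real_),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("<similarity_network> %d genomes, %d edges (cutoff %.3g)",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$cutoff))
  if (!is.null(x$communities))
    cat(sprintf("; %d communities, Q=%.4f",
                length(unique(x$communities)), x$Q))
  cat("\n")
  invisible(x)
}

#' Louvain community detection on a similarity network
#'
#' Runs the Louvain algorithm (greedy modularity optimisation with local
#' moves and graph aggregation) and stores the membership and the
#' modularity Q of the final partition. Node visit order is randomised,
#' so the seed is part of the result; isolated genomes become singleton
#' communities.
#'
#' @param network A [build_similarity_network()] result.
#' @param resolution Resolution parameter (1 = classic modularity).
#' @param seed RNG seed for the node visit order.
#' @return The network with `communities` (named membership vector) and
#'   `Q` filled in, plus a `seed` field.
#' @export
louvain_communities <- function(network, resolution = 1.0, seed = 1) {
  stopifnot(inherits(network, "similarity_network"))
  g <- network$graph
  if (igraph::vcount(g) == 0L) stop("empty graph")
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(cl)
  network$communities <- setNames(as.integer(memb),
                                  igraph::V(g)$name)
  network$Q <- igraph::modularity(g, memb)
  network$seed <- seed
  network
}

#' Summarise species communities
#'
#' @param network A network with communities assigned.
#' @return List with `n_species`, `n_singletons`, and `sizes` (community
#'   sizes, decreasing).
#' @export
species_summary <- function(network) {
  if (inherits(network, "similarity_network")) {
    if (is.null(network$communities))
      stop("no communities assigned; run louvain_communities() first")
    comm <- network$communities
  } else comm <- network
  if (length(comm) == 0L) stop("no community assignments")
  sizes <- sort(as.integer(table(comm)), decreasing = TRUE)
  list(n_species = length(sizes), n_singletons = sum(sizes == 1L),
       sizes = sizes)
}

#' Modularity of a partition (direct formula)
#'
#' Computes `Q = (1/2m) * sum_ij [A_ij - k_i k_j / (2m)] delta(c_i, c_j)`
#' directly from the adjacency structure. Exposed mainly for
#' verification against community-detection output.
#'
#' @param graph An igraph graph (undirected, unweighted).
#' @param membership Integer community labels per vertex.
#' @return Modularity Q.
#' @export
modularity_direct <- function(graph, membership) {
  m <- igraph::ecount(graph)
  if (m == 0L) return(0)
  deg <- igraph::degree(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  same <- membership[el[, 1]] == membership[el[, 2]]
  e_in <- sum(same) / m            # fraction of edges inside communities
  exp_in <- sum(vapply(split(deg, membership), sum, numeric(1))^2) /
    (2 * m)^2
  e_in - exp_in
}
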