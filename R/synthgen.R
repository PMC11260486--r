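BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

# Representative antiSMASH product type planted for each category.
CATEGORY_PRODUCT <- c(NRPS = "NRPS", PKS = "T1PKS", terpene = "terpene",
                      RiPP = "RiPP-like", oligosaccharide = "oligosaccharide",
                      other = "other")

#' Configuration for the synthetic chromosome generator
#'
#' Defines one synthetic linear chromosome: an i.i.d. base model at a
#' target GC, an optional planted terminal inverted repeat, a dnaA gene
#' planted near the chromosome centre, core genes placed by a
#' centre-anchored mixture model, optional duplicate core-gene copies and
#' BGC protoclusters placed by distal mixture models. Positional models
#' are mixtures of Gaussians on the arm-length scale (`arm_pos` in
#' `[-1, 1]`, 0 = chromosome centre, ±1 = chromosome ends), specified as
#' `list(mu=, sigma=, weight=)`.
#'
#' Defaults emulate the organisation observed on linear Streptomyces
#' chromosomes: a core-gene focal point at about 18% of the arm length on
#' either side of the centre with a mild downstream (positive-side)
#' excess, distal protoclusters and duplicate copies, and a dnaA gene
#' within a few percent of the arm length of the mathematical centre.
#'
#' @param L Chromosome length in bp.
#' @param gc Target GC fraction in (0, 1).
#' @param tir_len Planted terminal inverted repeat length (0 = none);
#'   must not exceed `L/2`.
#' @param n_core Number of core genes to plant.
#' @param n_dup Number of core-gene models additionally planted as a
#'   distal duplicate copy.
#' @param n_bgc Number of BGC protoclusters to plant.
#' @param core_model,dup_model,bgc_model,other_model Positional mixture
#'   models (arm_pos scale). `other_model` is used for protoclusters of
#'   category `other`, which are placed centrally.
#' @param bgc_category_probs Sampling weights of the six protocluster
#'   categories.
#' @param dnaa_model `c(mu=, sigma=)` for the dnaA arm_pos.
#' @param gene_len,bgc_len Length ranges (bp, uniform) for planted genes
#'   and protoclusters.
#' @param id Chromosome id.
#' @param seed RNG seed; a fixed seed yields byte-identical output.
#' @return A `synth_config` list.
#' @export
synth_config <- function(L = 200000, gc = 0.72, tir_len = 0,
                         n_core = 0, n_dup = 0, n_bgc = 0,
                         core_model = list(mu = c(-0.185, 0.185),
                                           sigma = c(0.10, 0.10),
                                           weight = c(0.45, 0.55)),
                         dup_model = list(mu = c(-0.85, 0.85),
                                          sigma = c(0.08, 0.08),
                                          weight = c(0.5, 0.5)),
                         bgc_model = list(mu = c(-0.85, 0.85),
                                          sigma = c(0.08, 0.08),
                                          weight = c(0.5, 0.5)),
                         other_model = list(mu = 0, sigma = 0.25,
                                            weight = 1),
                         bgc_category_probs = c(NRPS = 0.22, PKS = 0.30,
                                                terpene = 0.20,
                                                RiPP = 0.12,
                                                oligosaccharide = 0.04,
                                                other = 0.12),
                         dnaa_model = c(mu = -0.005, sigma = 0.05),
                         gene_len = c(1000, 3000),
                         bgc_len = c(20000, 100000),
                         id = "synth_chr", seed = 1) {
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  if (tir_len < 0 || tir_len > L / 2)
    stop("tir_len must satisfy 0 <= tir_len <= L/2")
  if (n_dup > n_core) stop("n_dup cannot exceed n_core")
  structure(list(L = L, gc = gc, tir_len = tir_len, n_core = n_core,
                 n_dup = n_dup, n_bgc = n_bgc, core_model = core_model,
                 dup_model = dup_model, bgc_model = bgc_model,
                 other_model = other_model,
                 bgc_category_probs = bgc_category_probs,
                 dnaa_model = dnaa_model, gene_len = gene_len,
                 bgc_len = bgc_len, id = id, seed = seed),
            class = "synth_config")
}

draw_arm_pos <- function(model) {
  i <- sample.int(length(model$mu), 1L, prob = model$weight)
  rnorm(1L, model$mu[i], model$sigma[i])
}

# Rejection-sample a non-overlapping interval for a feature of length
# `len` whose midpoint sits at arm_pos drawn from `model`.
place_interval <- function(model, len, L, occupied, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    ap <- draw_arm_pos(model)
    if (abs(ap) > 0.98) next
    mid <- L / 2 + ap * L / 2
    start <- round(mid - len / 2)
    end <- start + len
    if (start < 0 || end > L) next
    if (length(occupied) &&
        any(start < occupied[, 2] & end > occupied[, 1])) next
    return(c(start, end))
  }
  stop("could not place a feature of length ", len,
       " without overlap after ", max_tries, " rejections")
}

#' Generate one synthetic linear chromosome with annotations
#'
#' Draws an i.i.d. random sequence at the configured GC; if `tir_len > 0`
#' the last `tir_len` bases are overwritten with the reverse complement
#' of the first `tir_len` bases, and short purine-only spacers are placed
#' at the inner boundary of the two copies so the repeat cannot extend
#' past its planted boundary by chance complementarity of the flanks
#' (the planted length is the true maximal TIR length). Features are planted
#' in the dnaA-forward frame (dnaA on `+` near the centre, core genes /
#' duplicates / protoclusters from their positional models,
#' non-overlapping, gene lengths 1-3 kb and protocluster lengths
#' 20-100 kb); the whole chromosome is then stored reverse-complemented
#' with probability 1/2, emulating the arbitrary orientation of deposited
#' assemblies.
#'
#' @param config A [synth_config()].
#' @param sequence Generate the nucleotide sequence? With `FALSE` only
#'   coordinates and truth are produced (fast for large cohorts);
#'   requires `tir_len = 0`.
#' @return A list with `chromosome` ([linear_chromosome()] or `NULL`),
#'   `features` (feature `data.frame`, stored orientation), `truth`
#'   (planted values in the dnaA-forward frame, with attributes
#'   `tir_len` and `flipped`), and `L`.
#' @export
generate_chromosome <- function(config, sequence = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  if (!sequence && config$tir_len > 0)
    stop("sequence = FALSE is incompatible with a planted TIR")
  set.seed(config$seed)
  L <- config$L
  t <- config$tir_len

  s <- NULL
  if (sequence) {
    p <- c((1 - config$gc) / 2, config$gc / 2, config$gc / 2,
           (1 - config$gc) / 2)
    s <- sample(BASES, L, replace = TRUE, prob = p)
    if (t > 0) {
      s[(L - t + 1):L] <- unname(COMP[rev(s[1:t])])
      # Non-complementary spacer at the inner repeat boundary: the bases
      # just after the left copy and a band-wide window just before the
      # right copy are drawn purine-only, so no pairing between them is
      # complementary on any alignment diagonal within 200 bp. Without
      # this, chance complementarity of the flanks (including gapped
      # realignments) extends the repeat past its planted boundary and
      # the planted length would not be the true maximal TIR length.
      G <- 12L
      W <- 200L + G
      if (2 * t + G + W <= L) {
        s[(t + 1):(t + G)] <- sample(c("A", "G"), G, replace = TRUE)
        s[(L - t - W + 1):(L - t)] <- sample(c("A", "G"), W, replace = TRUE)
      }
    }
  }

  occupied <- matrix(numeric(0), ncol = 2)
  rows <- list()
  truth <- list()
  add <- function(fid, type, model_id, category, span, strand) {
    rows[[length(rows) + 1L]] <<- data.frame(
      replicon_id = config$id, feature_type = type, model_id = model_id,
      category = category, start = span[1], end = span[2], strand = strand,
      status = NA_character_, stringsAsFactors = FALSE)
    mid <- (span[1] + span[2]) / 2
    truth[[length(truth) + 1L]] <<- data.frame(
      feature_id = fid, model_id = model_id, feature_type = type,
      category = category, midpoint = mid, offset = mid - L / 2,
      arm_pos = (mid - L / 2) / (L / 2), length = span[2] - span[1],
      strand = strand, stringsAsFactors = FALSE)
    occupied <<- rbind(occupied, span)
  }

  # dnaA defines the planted frame: always '+' here
  dlen <- round(runif(1, config$gene_len[1], config$gene_len[2]))
  dnaa_mix <- list(mu = config$dnaa_model[["mu"]],
                   sigma = config$dnaa_model[["sigma"]], weight = 1)
  add("dnaA", "gene", "dnaA", NA_character_,
      place_interval(dnaa_mix, dlen, L, occupied), "+")

  if (config$n_core > 0) {
    for (i in seq_len(config$n_core)) {
      len <- round(runif(1, config$gene_len[1], config$gene_len[2]))
      add(sprintf("core_%03d", i), "core_gene", sprintf("core_%03d", i),
          NA_character_, place_interval(config$core_model, len, L, occupied),
          sample(c("+", "-"), 1L))
    }
    if (config$n_dup > 0) {
      for (m in sample(sprintf("core_%03d", seq_len(config$n_core)),
                       config$n_dup)) {
        len <- round(runif(1, config$gene_len[1], config$gene_len[2]))
        add(paste0(m, "_dup"), "core_gene", m, NA_character_,
            place_interval(config$dup_model, len, L, occupied),
            sample(c("+", "-"), 1L))
      }
    }
  }

  if (config$n_bgc > 0) {
    cats <- sample(names(config$bgc_category_probs), config$n_bgc,
                   replace = TRUE, prob = config$bgc_category_probs)
    for (i in seq_len(config$n_bgc)) {
      len <- round(runif(1, config$bgc_len[1], config$bgc_len[2]))
      model <- if (cats[i] == "other") config$other_model
               else config$bgc_model
      add(sprintf("bgc_%03d", i), "protocluster",
          unname(CATEGORY_PRODUCT[cats[i]]), cats[i],
          place_interval(model, len, L, occupied), "+")
    }
  }

  features <- do.call(rbind, rows)
  truth <- do.call(rbind, truth)

  # store in a random orientation, as deposited assemblies come
  flipped <- sample(c(TRUE, FALSE), 1L)
  if (flipped) {
    if (sequence) s <- unname(COMP[rev(s)])
    new_start <- L - features$end
    features$end <- L - features$start
    features$start <- new_start
    features$strand <- ifelse(features$strand == "+", "-", "+")
  }

  chromosome <- if (sequence)
    linear_chromosome(config$id, paste(s, collapse = ""), "linear")
  else NULL
  attr(truth, "tir_len") <- t
  attr(truth, "flipped") <- flipped
  list(chromosome = chromosome, features = validate_features(features),
       truth = truth, L = L)
}

#' Generate a cohort of synthetic genomes
#'
#' Convenience wrapper drawing `n_genomes` independent chromosomes from a
#' shared configuration (each with its own sub-seed) and pooling their
#' feature and truth tables. Defaults mirror a complete Streptomyces
#' chromosome: 9 Mb, 124 core-gene models, ~3 duplicated models and 12
#' non-overlapping protoclusters per genome.
#'
#' @param n_genomes Number of genomes.
#' @param L,n_core,n_dup,n_bgc,tir_len Passed to [synth_config()].
#' @param sequence Generate sequences (see [generate_chromosome()]).
#' @param seed Master seed; per-genome seeds are derived from it.
#' @param ... Further arguments to [synth_config()].
#' @return List with pooled `features`, pooled `truth` (both with a
#'   `genome_id` column), `lengths` (named vector), and `genomes` (list
#'   of per-genome results).
#' @export
generate_cohort <- function(n_genomes, L = 9e6, n_core = 124, n_dup = 3,
                            n_bgc = 12, tir_len = 0, sequence = FALSE,
                            seed = 1, ...) {
  set.seed(seed)
  seeds <- sample.int(2^30, n_genomes)
  genomes <- lapply(seq_len(n_genomes), function(i) {
    cfg <- synth_config(L = L, n_core = n_core, n_dup = n_dup,
                        n_bgc = n_bgc, tir_len = tir_len,
                        id = sprintf("g%03d", i), seed = seeds[i], ...)
    generate_chromosome(cfg, sequence = sequence)
  })
  features <- do.call(rbind, lapply(seq_along(genomes), function(i)
    cbind(genome_id = sprintf("g%03d", i), genomes[[i]]$features)))
  truth <- do.call(rbind, lapply(seq_along(genomes), function(i)
    cbind(genome_id = sprintf("g%03d", i), genomes[[i]]$truth)))
  lengths <- setNames(rep(L, n_genomes), sprintf("g%03d", seq_len(n_genomes)))
  list(features = features, truth = truth, lengths = lengths,
       genomes = genomes)
}

mutate_bases <- function(x, rate) {
  n <- rbinom(1L, length(x), rate)
  if (n == 0L) return(x)
  pos <- sample.int(length(x), n)
  x[pos] <- vapply(x[pos],
                   function(b) sample(BASES[BASES != b], 1L), character(1),
                   USE.NAMES = FALSE)
  x
}

#' Generate a set of genomes with planted species structure
#'
#' Each cluster gets one random base genome; members are derived from it
#' by independent per-site substitution at `within_rate` (no indels, so
#' the Mash-distance/rate relationship stays monotone). Cluster bases are
#' either mutually independent random sequences or derived from one
#' common ancestor at `between_rate`.
#'
#' @param n_clusters Number of species clusters.
#' @param genomes_per_cluster Genomes per cluster.
#' @param within_rate Within-cluster substitution rate, in `[0, 0.2)`.
#' @param between_mode `"independent"` or `"diverged"`.
#' @param between_rate Divergence rate of cluster bases from the common
#'   ancestor (only for `between_mode = "diverged"`); must exceed
#'   `within_rate`.
#' @param L Genome length in bp.
#' @param gc GC fraction.
#' @param seed RNG seed.
#' @return List with `genomes` (list of [linear_chromosome()]) and
#'   `truth` (`data.frame` of `genome_id`, `cluster`).
#' @export
generate_species_set <- function(n_clusters, genomes_per_cluster,
                                 within_rate = 0.005,
                                 between_mode = c("independent", "diverged"),
                                 between_rate = 0.1, L = 50000, gc = 0.72,
                                 seed = 1) {
  between_mode <- match.arg(between_mode)
  if (within_rate < 0 || within_rate >= 0.2)
    stop("within_rate must be in [0, 0.2)")
  if (between_mode == "diverged" && within_rate >= between_rate)
    stop("within_rate >= between_rate: clusters inseparable by construction")
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  ancestor <- sample(BASES, L, replace = TRUE, prob = p)
  genomes <- list()
  truth <- list()
  for (ci in seq_len(n_clusters)) {
    base <- if (between_mode == "independent")
      sample(BASES, L, replace = TRUE, prob = p)
    else mutate_bases(ancestor, between_rate)
    for (gi in seq_len(genomes_per_cluster)) {
      id <- sprintf("c%02d_g%02d", ci, gi)
      member <- mutate_bases(base, within_rate)
      genomes[[id]] <- linear_chromosome(id, paste(member, collapse = ""))
      truth[[id]] <- data.frame(genome_id = id, cluster = ci,
                                stringsAsFactors = FALSE)
    }
  }
  list(genomes = genomes, truth = do.call(rbind, unname(truth)))
}

#' Generate a panel of replicons with marker-domain hits
#'
#' Emulates the input of marker-domain plasmid classification: a table of
#' protein-domain hits per extrachromosomal replicon. Planted plasmids
#' carry at least one hit from `marker_domains`; the remaining replicons
#' carry only decoy domains absent from the marker list. All replicons
#' may carry decoy hits.
#'
#' @param n_plasmid Number of replicons planted as plasmids.
#' @param n_other Number of replicons without any marker domain.
#' @param marker_domains Non-empty character vector of marker accessions.
#' @param seed RNG seed.
#' @return List with `hits` (`data.frame`: `replicon_id`,
#'   `domain_accession`, `evalue`) and `truth` (`replicon_id`,
#'   `is_plasmid`).
#' @export
generate_replicon_panel <- function(n_plasmid, n_other, marker_domains,
                                    seed = 1) {
  if (length(marker_domains) == 0L) stop("marker_domains must be non-empty")
  set.seed(seed)
  decoys <- sprintf("DECOY%05d", 1:50)
  ids <- c(sprintf("plasmid_%02d", seq_len(n_plasmid)),
           sprintf("replicon_%02d", seq_len(n_other)))
  is_plasmid <- rep(c(TRUE, FALSE), c(n_plasmid, n_other))
  hits <- list()
  for (i in seq_along(ids)) {
    doms <- sample(decoys, rpois(1L, 2))
    if (is_plasmid[i])
      doms <- c(doms, sample(marker_domains, min(1L + rpois(1L, 1),
                                                 length(marker_domains))))
    if (length(doms))
      hits[[length(hits) + 1L]] <- data.frame(
        replicon_id = ids[i], domain_accession = doms,
        evalue = 10^-runif(length(doms), 3, 30), stringsAsFactors = FALSE)
  }
  hits <- if (length(hits)) do.call(rbind, hits)
          else data.frame(replicon_id = character(),
                          domain_accession = character(),
                          evalue = numeric(), stringsAsFactors = FALSE)
  list(hits = hits,
       truth = data.frame(replicon_id = ids, is_plasmid = is_plasmid,
                          stringsAsFactors = FALSE))
}

#' Write a data frame as a TSV file
#'
#' Tab-separated, header row, UTF-8, `.` for missing values.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".", fileEncoding = "UTF-8")
  invisible(path)
}
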