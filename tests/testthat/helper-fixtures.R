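# Shared fixtures and independent oracles. Everything is generated in code
# under fixed seeds; expensive fixtures are cached for the run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  val <- get0(key, envir = .fixture_cache)
  if (is.null(val)) {
    val <- force(expr)
    assign(key, val, envir = .fixture_cache)
  }
  val
}

# random symmetric distance matrix with zero diagonal, labelled a,b,c,...
random_dist_matrix <- function(n, seed) {
  stopifnot(n <= 26)
  set.seed(seed)
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2)
  d <- d + t(d)
  labels <- letters[seq_len(n)]
  dimnames(d) <- list(labels, labels)
  d
}

# exact Jaccard between two sequence sets from full k-mer inventories
exact_jaccard <- function(seq_a, seq_b, policy) {
  a <- kmer_inventory(seq_a, policy, drop_singletons = FALSE)$hashes
  b <- kmer_inventory(seq_b, policy, drop_singletons = FALSE)$hashes
  length(intersect(a, b)) / length(union(a, b))
}

# independent LCA oracle: walks parents on the raw node table, no package
# taxonomy helpers involved
oracle_lca <- function(nodes, ids) {
  path_of <- function(id) {
    out <- id
    while (TRUE) {
      p <- nodes$parent[nodes$id == id]
      if (p == id) break
      out <- c(out, p)
      id <- p
    }
    out
  }
  paths <- lapply(unique(ids), path_of)
  common <- Reduce(intersect, paths)
  common[1]
}

# hand-assembled classification report (for filter/redistribution tests)
manual_report <- function(tax, direct, unique_kmers = NULL, total = NULL,
                          unclassified = 0L) {
  ids <- tax$nodes$id
  dir <- integer(length(ids))
  dir[match(as.integer(names(direct)), ids)] <- as.integer(direct)
  uk <- integer(length(ids))
  if (!is.null(unique_kmers))
    uk[match(as.integer(names(unique_kmers)), ids)] <- as.integer(unique_kmers)
  tab <- data.frame(node_id = ids, rank = tax$nodes$rank,
                    name = tax$nodes$name, direct_reads = dir,
                    clade_reads = 0L, unique_kmers = uk,
                    stringsAsFactors = FALSE)
  rep <- structure(list(sample_id = "manual",
                        total_reads = if (is.null(total))
                          sum(dir) + unclassified else total,
                        unclassified_reads = unclassified,
                        filtered_reads = 0L, table = tab, taxonomy = tax),
                   class = "classification_report")
  prevderep:::recompute_clades(rep, tax)
}

# ten-species mixture used by the classifier recovery checks
mixture_fixture <- function() {
  cached("mixture", {
    mt <- make_taxonomy(10, genera = 3)
    genomes <- vapply(1:10, function(i) make_genome(25000, seed = 300 + i),
                      character(1))
    names(genomes) <- names(mt$genome_species)
    db <- build_lca_database(genomes, mt$genome_species, mt$tax, k = 31,
                             fragment_step = 5)
    profile <- (10:1) / sum(10:1)
    reads <- make_reads(genomes, profile, 150, 50000, error_rate = 0.005,
                        seed = 77)
    list(tax = mt$tax, genomes = genomes, genome_species = mt$genome_species,
         db = db, profile = profile, reads = reads)
  })
}

# small strain panel for dereplication tests
derep_fixture <- function() {
  cached("derep", {
    panel <- make_strain_panel(12, 5, 50000, within_divergence = 0.0025,
                               between_divergence = 0.05, seed = 11)
    list(genomes = panel$genomes, species = panel$species,
         ranked_ids = names(panel$genomes))
  })
}

# pipeline demo inputs: 4 species x 3 strains, 6 samples in 2 projects with
# varying species membership
pipeline_fixture <- function() {
  cached("pipeline", {
    panel <- make_strain_panel(4, 3, 20000, within_divergence = 0.0025,
                               between_divergence = 0.06, seed = 5)
    mt <- make_taxonomy(4, genera = 2)
    gs <- stats::setNames(mt$genome_species[panel$species],
                          names(panel$genomes))
    gmeta <- data.frame(genome_id = names(panel$genomes), source = "sim",
                        completeness = c(rep(99, 10), 55, 40),
                        contamination = c(rep(0.5, 10), 2, 9),
                        stringsAsFactors = FALSE)
    sp_g <- panel$genomes[paste0("s0", 1:4, "_t01")]
    mixes <- list(c(.4, .3, .2, .1), c(.4, .3, .2, .1), c(0, .5, .5, 0),
                  c(.5, .5, 0, 0), c(0, 0, .5, .5), c(.25, .25, .25, .25))
    samples <- lapply(seq_along(mixes), function(i) {
      w <- mixes[[i]]
      keep <- w > 0
      make_reads(sp_g[keep], w[keep] / sum(w), 120, 3000,
                 error_rate = 0.002, seed = 50 + i)$reads
    })
    names(samples) <- sprintf("sample%02d", seq_along(samples))
    smeta <- data.frame(sample_id = names(samples),
                        project_id = rep(c("projA", "projB"), each = 3),
                        cohort = "healthy", reads_count = 3000,
                        stringsAsFactors = FALSE)
    list(genomes = panel$genomes, gmeta = gmeta, samples = samples,
         smeta = smeta, tax = mt$tax, genome_species = gs)
  })
}
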