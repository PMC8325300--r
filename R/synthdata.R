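# Seeded simulators: random genomes, strain variants at controlled
# divergence, rank-complete taxonomies and read sets from genome mixtures.
# They define the study conditions for every other module's tests.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a random genome
#'
#' Uniform i.i.d. sequence over A/C/G/T; deterministic per seed.
#'
#' @param length genome length in bases (>= 1000).
#' @param seed RNG seed.
#' @return A nucleotide string.
#' @export
make_genome <- function(length, seed = 1L) {
  if (length < 1000L) stop("genome length must be >= 1000")
  with_seed(seed, cpp_random_genome(as.integer(length)))
}

#' Mutate a genome by independent substitutions
#'
#' Each base is substituted by one of the three other bases with
#' probability `rate` (no indels), so the expected nucleotide identity to
#' the original is exactly 1 - rate — the closed form that calibrates the
#' ANI estimator and the clustering thresholds.
#'
#' @param genome nucleotide string.
#' @param rate per-base substitution probability in \[0, 0.3\].
#' @param seed RNG seed.
#' @return The variant genome.
#' @export
mutate_genome <- function(genome, rate, seed = 1L) {
  if (rate < 0 || rate > 0.3) stop("rate must be in [0, 0.3]")
  with_seed(seed, as.character(cpp_mutate_seqs(genome, rate)))
}

#' Simulate a strain panel with planted cluster structure
#'
#' Generates `n_species` ancestral genomes by mutating one common ancestor
#' at `between_divergence` each (so inter-species pairwise divergence is
#' about twice that rate), then `strains_per_species` strains per species
#' by mutating the ancestor at `within_divergence` each. The planted
#' partition (strains of one species together) is returned alongside.
#'
#' @param n_species number of species groups.
#' @param strains_per_species strains per group.
#' @param genome_length length of every genome.
#' @param within_divergence per-base rate applied per strain (pairwise
#'   within-group divergence is about twice this).
#' @param between_divergence per-base rate applied per species ancestor.
#' @param seed RNG seed.
#' @return List `genomes` (named character vector, ids `s<species>_t<strain>`),
#'   `species` (named integer vector, the planted group of each genome).
#' @export
make_strain_panel <- function(n_species, strains_per_species, genome_length,
                              within_divergence = 0.0025,
                              between_divergence = 0.05, seed = 1L) {
  with_seed(seed, {
    ancestor <- cpp_random_genome(as.integer(genome_length))
    genomes <- character(0)
    species <- integer(0)
    for (s in seq_len(n_species)) {
      base <- as.character(cpp_mutate_seqs(ancestor, between_divergence))
      for (t in seq_len(strains_per_species)) {
        id <- sprintf("s%02d_t%02d", s, t)
        genomes[id] <- as.character(cpp_mutate_seqs(base, within_divergence))
        species[id] <- s
      }
    }
    list(genomes = genomes, species = species)
  })
}

#' Simulate shotgun reads from a genome mixture
#'
#' Reads are drawn from the genomes with probability proportional to
#' `abundance_profile * genome length` (fragment abundance semantics),
#' uniform start positions, either strand, and independent per-base
#' substitution errors at `error_rate`. The source genome of every read is
#' retained as a truth label.
#'
#' @param genomes named character vector of genome sequences.
#' @param abundance_profile fractions summing to 1, one per genome.
#' @param read_length read length in bases.
#' @param n_reads number of reads.
#' @param error_rate per-base error probability.
#' @param seed RNG seed.
#' @return List `reads` (character vector), `truth` (data.frame `read_id`,
#'   `genome_id`, `start`, `strand`).
#' @export
make_reads <- function(genomes, abundance_profile, read_length, n_reads,
                       error_rate = 0, seed = 1L) {
  stopifnot(length(genomes) == length(abundance_profile))
  if (abs(sum(abundance_profile) - 1) > 1e-9)
    stop("abundance_profile must sum to 1")
  glen <- nchar(genomes)
  if (any(read_length > glen)) stop("read_length exceeds a genome length")
  with_seed(seed, {
    w <- abundance_profile * glen
    gi <- sample.int(length(genomes), n_reads, replace = TRUE, prob = w / sum(w))
    start <- floor(runif(n_reads) * (glen[gi] - read_length + 1)) + 1L
    strand <- ifelse(runif(n_reads) < 0.5, "+", "-")
    reads <- substring(genomes[gi], start, start + read_length - 1L)
    minus <- strand == "-"
    if (any(minus)) reads[minus] <- as.character(cpp_revcomp(reads[minus]))
    if (error_rate > 0) reads <- as.character(cpp_mutate_seqs(reads, error_rate))
    list(reads = unname(reads),
         truth = data.frame(read_id = seq_len(n_reads),
                            genome_id = names(genomes)[gi],
                            start = start, strand = strand,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a rank-complete taxonomy
#'
#' Builds a root -> domain -> genus -> species tree with `n_species`
#' species distributed as evenly as possible among `genera` genera, plus a
#' genome-to-species map with one genome id per species.
#'
#' @param n_species number of species (>= genera).
#' @param genera number of genus nodes (>= 1).
#' @param seed RNG seed (species-to-genus assignment is round-robin and
#'   deterministic; the seed is kept for interface uniformity).
#' @return List `tax` (a [taxonomy()]), `genome_species` (named integer
#'   vector mapping genome ids `g<species>` to species node ids).
#' @export
make_taxonomy <- function(n_species, genera = 1L, seed = 1L) {
  stopifnot(n_species >= genera, genera >= 1L)
  root <- 1L; domain <- 2L
  genus_ids <- 2L + seq_len(genera)
  species_ids <- 2L + genera + seq_len(n_species)
  nodes <- data.frame(
    id = c(root, domain, genus_ids, species_ids),
    parent = c(root, root, rep(domain, genera),
               genus_ids[(seq_len(n_species) - 1L) %% genera + 1L]),
    rank = c("root", "domain", rep("genus", genera),
             rep("species", n_species)),
    name = c("root", "Bacteria", sprintf("genus_%02d", seq_len(genera)),
             sprintf("species_%03d", seq_len(n_species))),
    stringsAsFactors = FALSE)
  gs <- stats::setNames(species_ids, sprintf("g%03d", seq_len(n_species)))
  list(tax = taxonomy(nodes), genome_species = gs)
}
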