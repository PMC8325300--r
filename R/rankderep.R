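#' Genome qualification by panel containment
#'
#' A genome qualifies when its screen identity reaches the soft species
#' threshold (default 0.95) in at least one panel metagenome.
#'
#' @param identities numeric vector of screen identities, one per panel
#'   metagenome, in \[0, 1\].
#' @param threshold qualification identity (boundary inclusive).
#' @return TRUE/FALSE.
#' @export
qualify_genome <- function(identities, threshold = 0.95) {
  if (length(identities) == 0L) stop("empty identity vector: no panel")
  if (any(identities < 0 | identities > 1)) stop("identities must be in [0, 1]")
  any(identities >= threshold)
}

#' Prevalence score of a genome
#'
#' The arithmetic mean of the genome's screen identities across all panel
#' metagenomes. Metagenomes where the genome is not detected contribute
#' I = 0, so the score rewards both depth and breadth of containment.
#'
#' @inheritParams qualify_genome
#' @return Mean identity in \[0, 1\].
#' @export
prevalence_score <- function(identities) {
  if (length(identities) == 0L) stop("empty identity vector: no panel")
  if (any(identities < 0 | identities > 1)) stop("identities must be in [0, 1]")
  mean(identities)
}

#' Prevalence table from a screen-identity matrix
#'
#' @param identity_matrix genomes x metagenomes matrix of screen identities
#'   (see [screen_panel()]).
#' @param threshold qualification identity.
#' @return data.frame `genome_id`, `prevalence_score`, `qualified`, `rank`
#'   (rank only over qualified genomes, NA otherwise), sorted by rank then
#'   genome_id.
#' @export
prevalence_table <- function(identity_matrix, threshold = 0.95) {
  stopifnot(is.matrix(identity_matrix), !is.null(rownames(identity_matrix)))
  rec <- data.frame(genome_id = rownames(identity_matrix),
                    prevalence_score = rowMeans(identity_matrix),
                    qualified = apply(identity_matrix, 1, qualify_genome,
                                      threshold = threshold),
                    stringsAsFactors = FALSE)
  rank_genomes(rec)
}

#' Rank genomes by prevalence score
#'
#' Stable sort by prevalence score descending; ties broken by genome_id
#' ascending. Only qualified genomes receive ranks 1..N; unqualified rows
#' keep rank NA and sort last.
#'
#' @param records data.frame with `genome_id`, `prevalence_score` and
#'   optionally `qualified` (default all TRUE).
#' @return The records with a `rank` column, ordered by rank.
#' @export
rank_genomes <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("genome_id", "prevalence_score") %in% names(records)))
  if (is.null(records$qualified)) records$qualified <- TRUE
  ord <- order(-records$prevalence_score, records$genome_id)
  records <- records[ord, , drop = FALSE]
  records$rank <- NA_integer_
  q <- records$qualified
  records$rank[q] <- seq_len(sum(q))
  records <- records[order(!records$qualified, records$rank), , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Assembly quality filter
#'
#' Passes genomes with completeness >= 50, contamination <= 5 and quality
#' score `completeness - 5 * contamination` >= 50 (all boundaries
#' inclusive). Missing values fail with reason "unscored".
#'
#' @param meta data.frame with `genome_id`, `completeness`, `contamination`
#'   (percent scales, 0..100).
#' @return The input with `quality_score`, `pass` and `reason` columns.
#' @export
quality_filter <- function(meta) {
  stopifnot(is.data.frame(meta),
            all(c("genome_id", "completeness", "contamination") %in% names(meta)))
  score <- meta$completeness - 5 * meta$contamination
  unscored <- is.na(meta$completeness) | is.na(meta$contamination)
  pass <- !unscored & meta$completeness >= 50 & meta$contamination <= 5 &
    score >= 50
  meta$quality_score <- ifelse(unscored, NA_real_, score)
  meta$pass <- pass
  meta$reason <- ifelse(unscored, "unscored", ifelse(pass, "", "low_quality"))
  meta
}

# Consecutive full-length fragments of a genome; the trailing remainder
# shorter than fragment_length is dropped.
genome_fragments <- function(genome, fragment_length) {
  n <- nchar(genome)
  nfrag <- n %/% fragment_length
  if (nfrag == 0L) stop("genome shorter than fragment_length")
  starts <- (seq_len(nfrag) - 1L) * fragment_length + 1L
  substring(genome, starts, starts + fragment_length - 1L)
}

# Identity of one fragment given the containment c of its k-mers in the
# reference inventory: mean per-base identity from k-mer survival,
# I = c^(1/k) (a k-mer survives substitution at rate d with probability
# (1-d)^k, so c^(1/k) estimates 1-d).
fragment_identity <- function(c, k) c^(1 / k)

ani_from_inventory <- function(fragment_hashes, ref_inventory_hashes, k,
                               min_identity = 0.8) {
  ids <- vapply(fragment_hashes, function(h) {
    if (length(h) == 0L) return(0)
    fragment_identity(mean(sorted_member(sort(unique(h)), ref_inventory_hashes)), k)
  }, numeric(1))
  mapped <- ids >= min_identity
  ani <- if (any(mapped)) mean(ids[mapped]) else NA_real_
  list(ani = ani, fraction_mapped = mean(mapped),
       distance = if (is.na(ani)) NA_real_ else 1 - ani)
}

#' Fragment-based average nucleotide identity
#'
#' The query genome is cut into consecutive fragments (default 3,000 bp);
#' each fragment's identity to the reference is estimated from the fraction
#' c of its distinct canonical k-mers found in the reference's full k-mer
#' inventory, inverted through the k-mer survival model I = c^(1/k).
#' Fragments with identity below `min_identity` are considered unmapped;
#' ANI is the mean identity over mapped fragments. The estimate is
#' query-directional (approximately symmetric for genomes of similar size).
#'
#' @param query,reference nucleotide strings (character vectors are treated
#'   as contigs of one genome).
#' @param fragment_length fragment size in bases (default 3000).
#' @param k k-mer length for fragment matching (default 15).
#' @param min_identity mapping floor; fragments below it are unmapped.
#' @param hash_seed hash seed shared by query and reference hashing.
#' @return List `ani`, `fraction_mapped`, `distance` (= 1 - ani). When no
#'   fragment maps, `ani` and `distance` are NA; callers must treat the
#'   distance as larger than any clustering threshold.
#' @export
#' @examples
#' set.seed(1)
#' g <- make_genome(20000, seed = 1)
#' ani(g, g)$ani  # exactly 1
ani <- function(query, reference, fragment_length = 3000L, k = 15L,
                min_identity = 0.8, hash_seed = 1234L) {
  query <- paste(query, collapse = "")
  if (nchar(query) < fragment_length || sum(nchar(reference)) < fragment_length)
    stop("both genomes must be at least one fragment long")
  frags <- genome_fragments(query, fragment_length)
  fh <- cpp_kmer_hash_batch(frags, as.integer(k), hash_seed)
  fragment_hashes <- split(fh$hashes, rep(seq_along(frags), fh$n_kmers))
  ref <- cpp_kmer_counts(as.character(reference), as.integer(k), hash_seed)$hash
  ani_from_inventory(fragment_hashes, ref, k, min_identity)
}

# Precompute, per genome, the per-fragment hash lists (query side) and the
# full inventory (reference side) used by the greedy clustering.
ani_precompute <- function(genomes, fragment_length, k, hash_seed) {
  lapply(genomes, function(g) {
    g <- paste(g, collapse = "")
    frags <- genome_fragments(g, fragment_length)
    fh <- cpp_kmer_hash_batch(frags, as.integer(k), hash_seed)
    list(fragments = split(fh$hashes, rep(seq_along(frags), fh$n_kmers)),
         inventory = cpp_kmer_counts(g, as.integer(k), hash_seed)$hash)
  })
}

#' Greedy rank-ordered genome clustering
#'
#' Implements the two-tier greedy dereplication: the top-ranked unassigned
#' genome becomes a centroid; all unassigned genomes whose sketch (MASH)
#' distance to the centroid is <= `D_mash` are candidates; candidates whose
#' confirmed ANI distance (1 - ANI, query = candidate, reference =
#' centroid) is <= `D` join the cluster. The cluster is removed and the
#' procedure repeats until no genome remains. Candidates with undefined ANI
#' (no mapped fragments) are never assigned. Setting `D_mash = 1` disables
#' the pre-filter (exhaustive greedy clustering).
#'
#' @param ranked_ids genome ids in rank order (best first).
#' @param genomes named character vector/list of genome sequences.
#' @param sketches named list of `kmer_sketch` per genome (for the
#'   pre-filter); built internally when NULL.
#' @param D ANI distance threshold in (0, 0.5).
#' @param D_mash sketch-distance pre-filter, > D.
#' @param sketch_policy policy used when sketches are built internally.
#' @param fragment_length,ani_k,min_identity,hash_seed ANI parameters, see
#'   [ani()].
#' @return data.frame `cluster_id`, `centroid_id`, `member_id`,
#'   `distance_to_centroid` (NA for the centroid's own 0 row it is 0).
#' @export
greedy_cluster <- function(ranked_ids, genomes, sketches = NULL,
                           D = 0.025, D_mash = 0.08,
                           sketch_policy = genome_policy(),
                           fragment_length = 3000L, ani_k = 15L,
                           min_identity = 0.8, hash_seed = 1234L) {
  stopifnot(D > 0, D < 0.5, D_mash > D)
  stopifnot(all(ranked_ids %in% names(genomes)))
  if (is.null(sketches))
    sketches <- lapply(genomes[ranked_ids], make_sketch, policy = sketch_policy)
  k_sketch <- sketches[[1]]$policy$k
  pre <- ani_precompute(genomes[ranked_ids], fragment_length, ani_k, hash_seed)
  remaining <- ranked_ids
  rows <- list()
  cid <- 0L
  while (length(remaining) > 0L) {
    cid <- cid + 1L
    centroid <- remaining[1L]
    others <- remaining[-1L]
    cand <- others
    if (length(others) > 0L && D_mash < 1) {
      dm <- vapply(others, function(g)
        mash_distance(jaccard_estimate(sketches[[g]], sketches[[centroid]]),
                      k_sketch), numeric(1))
      cand <- others[dm <= D_mash]
    }
    members <- centroid
    dist <- 0
    if (length(cand) > 0L) {
      ad <- vapply(cand, function(g)
        ani_from_inventory(pre[[g]]$fragments, pre[[centroid]]$inventory,
                           ani_k, min_identity)$distance, numeric(1))
      keep <- !is.na(ad) & ad <= D
      members <- c(members, cand[keep])
      dist <- c(dist, ad[keep])
    }
    rows[[cid]] <- data.frame(cluster_id = cid, centroid_id = centroid,
                              member_id = members, distance_to_centroid = dist,
                              stringsAsFactors = FALSE)
    remaining <- setdiff(remaining, members)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Two-level genome dereplication
#'
#' Runs [greedy_cluster()] at the high-resolution threshold D = 0.025
#' (pre-filter 0.08), then clusters the resulting centroids again at the
#' species-level threshold D = 0.05 (pre-filter 0.1), preserving the
#' original ranks. The pre-filter pairs follow the empirical calibration
#' that sketch distances below 0.08 capture nearly all ANI distances below
#' 0.025, and 0.1 those below 0.05.
#'
#' @inheritParams greedy_cluster
#' @param D_high,D_mash_high thresholds of the high-resolution level.
#' @param D_species,D_mash_species thresholds of the species level.
#' @param ... further arguments passed to [greedy_cluster()].
#' @return List with `level_high` and `level_species` cluster tables and
#'   `species_membership`, mapping each species-level cluster to its
#'   constituent high-resolution centroids.
#' @export
two_level_dereplicate <- function(ranked_ids, genomes, sketches = NULL,
                                  D_high = 0.025, D_mash_high = 0.08,
                                  D_species = 0.05, D_mash_species = 0.1,
                                  sketch_policy = genome_policy(), ...) {
  if (is.null(sketches))
    sketches <- lapply(genomes[ranked_ids], make_sketch, policy = sketch_policy)
  high <- greedy_cluster(ranked_ids, genomes, sketches,
                         D = D_high, D_mash = D_mash_high,
                         sketch_policy = sketch_policy, ...)
  centroids <- unique(high$centroid_id)
  centroids <- centroids[order(match(centroids, ranked_ids))]
  species <- greedy_cluster(centroids, genomes, sketches[centroids],
                            D = D_species, D_mash = D_mash_species,
                            sketch_policy = sketch_policy, ...)
  membership <- species[, c("cluster_id", "member_id")]
  names(membership) <- c("species_cluster_id", "high_centroid_id")
  list(level_high = high, level_species = species,
       species_membership = membership)
}
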