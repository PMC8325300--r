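#' k-mer hashing policy
#'
#' A policy fixes everything that makes k-mer hashes comparable: the k-mer
#' length, the sketch size s (number of smallest hash values retained), the
#' singleton-handling rule and the hash seed. Sketches and inventories built
#' under different k or seed are incomparable and the estimators refuse to
#' mix them.
#'
#' The defaults follow common practice for gut metagenome work: k = 21
#' throughout; s = 10,000 with singleton k-mers discarded for metagenome
#' sample sketches (sequencing-error k-mers are mostly singletons), and
#' s = 1,000 with singletons kept for genome sketches (assemblies are far
#' less error dense and small genomes would otherwise lose signal).
#'
#' @param k odd integer k-mer length >= 3 (and <= 31).
#' @param sketch_size integer s >= 1, the number of minimal hashes retained.
#' @param drop_singletons logical; drop hashes seen exactly once across the
#'   input before truncation.
#' @param hash_seed integer seed mixed into the hash function; recorded in
#'   the sketch so results are reproducible.
#' @return A `kmer_policy` object.
#' @export
#' @examples
#' genome_policy()
#' kmer_policy(k = 21, sketch_size = 10000, drop_singletons = TRUE)
kmer_policy <- function(k = 21L, sketch_size = 1000L, drop_singletons = FALSE,
                        hash_seed = 1234L) {
  k <- as.integer(k)
  sketch_size <- as.integer(sketch_size)
  stopifnot(length(k) == 1L, length(sketch_size) == 1L)
  if (k < 3L || k > 31L || k %% 2L == 0L)
    stop("k must be odd and in 3..31")
  if (sketch_size < 1L) stop("sketch_size must be >= 1")
  structure(list(k = k, sketch_size = sketch_size,
                 drop_singletons = isTRUE(drop_singletons),
                 hash_seed = as.integer(hash_seed)),
            class = "kmer_policy")
}

#' @rdname kmer_policy
#' @export
genome_policy <- function(k = 21L, sketch_size = 1000L, hash_seed = 1234L) {
  kmer_policy(k, sketch_size, drop_singletons = FALSE, hash_seed = hash_seed)
}

#' @rdname kmer_policy
#' @export
metagenome_policy <- function(k = 21L, sketch_size = 10000L, hash_seed = 1234L) {
  kmer_policy(k, sketch_size, drop_singletons = TRUE, hash_seed = hash_seed)
}

#' @export
print.kmer_policy <- function(x, ...) {
  cat(sprintf("kmer_policy: k=%d s=%d drop_singletons=%s seed=%d\n",
              x$k, x$sketch_size, x$drop_singletons, x$hash_seed))
  invisible(x)
}

policy_compatible <- function(a, b) {
  a$k == b$k && a$hash_seed == b$hash_seed
}

stop_policy_mismatch <- function(a, b) {
  if (!policy_compatible(a, b))
    stop("policy mismatch: sketches/inventories must share k and hash_seed")
  invisible(TRUE)
}

#' Canonical k-mer hashes of a sequence
#'
#' Slides a window of length `policy$k` over the sequence and emits, per
#' window, the hash of the canonical k-mer (the lexicographic minimum of the
#' window and its reverse complement). Windows containing any character
#' outside A/C/G/T are skipped. A sequence shorter than k yields an empty
#' stream.
#'
#' @param sequence a single nucleotide string.
#' @param policy a [kmer_policy()].
#' @return Numeric vector of hash values, one per valid window, in order.
#' @export
#' @examples
#' p <- kmer_policy(k = 3, sketch_size = 10)
#' canonical_kmer_hashes("ACGT", p)
canonical_kmer_hashes <- function(sequence, policy) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            inherits(policy, "kmer_policy"))
  cpp_kmer_hashes(sequence, policy$k, policy$hash_seed)
}

#' Bottom-s MinHash sketch of a sequence set
#'
#' Computes all distinct canonical k-mer hashes of the input, optionally
#' drops hashes seen exactly once across the whole input (singletons), and
#' retains the s smallest surviving values. The count of distinct hashes
#' before truncation (after any singleton filtering) is recorded.
#'
#' @param sequences character vector of nucleotide sequences. Multi-contig
#'   genomes are passed as one element per contig; no artificial k-mers are
#'   formed across contig boundaries.
#' @param policy a [kmer_policy()].
#' @param source_id label stored in the sketch.
#' @return A `kmer_sketch` with elements `policy`, `hashes` (sorted
#'   ascending, length <= s, all distinct), `source_id`,
#'   `total_distinct_kmers`.
#' @export
make_sketch <- function(sequences, policy, source_id = "") {
  stopifnot(is.character(sequences), length(sequences) >= 1L,
            inherits(policy, "kmer_policy"))
  tab <- cpp_kmer_counts(sequences, policy$k, policy$hash_seed)
  hashes <- tab$hash
  if (policy$drop_singletons) hashes <- hashes[tab$count >= 2L]
  total <- length(hashes)
  if (total > policy$sketch_size) hashes <- hashes[seq_len(policy$sketch_size)]
  structure(list(policy = policy, hashes = hashes,
                 source_id = as.character(source_id),
                 total_distinct_kmers = total),
            class = "kmer_sketch")
}

#' @export
print.kmer_sketch <- function(x, ...) {
  cat(sprintf("kmer_sketch '%s': %d/%d hashes (k=%d, seed=%d)\n",
              x$source_id, length(x$hashes), x$total_distinct_kmers,
              x$policy$k, x$policy$hash_seed))
  invisible(x)
}

#' Full distinct-hash inventory of a sequence set
#'
#' The untruncated counterpart of [make_sketch()]: all distinct canonical
#' k-mer hashes. Used on the metagenome side of containment screening
#' (sketched genome hashes are looked up among all hashes of the
#' metagenome) and as the reference side of [ani()].
#'
#' @inheritParams make_sketch
#' @param drop_singletons drop hashes seen exactly once; defaults to the
#'   policy's setting.
#' @return A `kmer_inventory` with sorted distinct `hashes`.
#' @export
kmer_inventory <- function(sequences, policy, source_id = "",
                           drop_singletons = policy$drop_singletons) {
  stopifnot(is.character(sequences), length(sequences) >= 1L,
            inherits(policy, "kmer_policy"))
  tab <- cpp_kmer_counts(sequences, policy$k, policy$hash_seed)
  hashes <- tab$hash
  if (isTRUE(drop_singletons)) hashes <- hashes[tab$count >= 2L]
  structure(list(policy = policy, hashes = hashes,
                 source_id = as.character(source_id)),
            class = "kmer_inventory")
}

#' @export
print.kmer_inventory <- function(x, ...) {
  cat(sprintf("kmer_inventory '%s': %d distinct hashes (k=%d)\n",
              x$source_id, length(x$hashes), x$policy$k))
  invisible(x)
}

# Membership of sorted query values in a sorted reference vector.
sorted_member <- function(x, table) {
  if (length(table) == 0L) return(rep(FALSE, length(x)))
  idx <- findInterval(x, table)
  idx > 0L & table[pmax(idx, 1L)] == x
}

#' Jaccard similarity estimate from two sketches
#'
#' Merged bottom-s estimator: among the s smallest values of the union of
#' the two hash lists (s = the policy sketch size, or fewer if the union is
#' smaller), the estimate is the fraction present in both sketches. This is
#' the estimator of the MinHash sketching literature, not the simpler
#' `|intersection|/s`.
#'
#' @param a,b `kmer_sketch` objects built under the same k and hash seed.
#' @return Estimated Jaccard similarity in \[0, 1\].
#' @export
jaccard_estimate <- function(a, b) {
  stopifnot(inherits(a, "kmer_sketch"), inherits(b, "kmer_sketch"))
  stop_policy_mismatch(a$policy, b$policy)
  if (length(a$hashes) == 0L && length(b$hashes) == 0L)
    stop("jaccard undefined for two empty sketches")
  s <- min(a$policy$sketch_size, b$policy$sketch_size)
  u <- sort(unique(c(a$hashes, b$hashes)))
  if (length(u) > s) u <- u[seq_len(s)]
  shared <- sorted_member(u, a$hashes) & sorted_member(u, b$hashes)
  sum(shared) / length(u)
}

#' MASH distance from a Jaccard similarity
#'
#' D = -(1/k) * log(2j / (1 + j)), the mutation-rate-scaled dissimilarity
#' under a Poisson model of random k-mer survival. Disjoint sketches
#' (j = 0) are assigned the declared cap D = 1; identical sketches give 0.
#'
#' @param j Jaccard similarity in \[0, 1\] (vectorized).
#' @param k k-mer length used for the sketches.
#' @return Distance in \[0, 1\].
#' @export
#' @examples
#' mash_distance(0.5, 21)
mash_distance <- function(j, k) {
  if (any(j < 0 | j > 1)) stop("j must be in [0, 1]")
  d <- ifelse(j == 0, 1, pmin(1, -log(2 * j / (1 + j)) / k))
  pmax(d, 0)
}

#' Screen identity transform and its inverse
#'
#' Maps a containment fraction c (shared genome-sketch hashes / genome
#' sketch size) to an estimated genome-to-metagenome sequence identity
#' I = 1 + (1/k) * log(2c / (1 + c)), clamped to \[0, 1\], with I = 0 at
#' c = 0. `containment_at_identity()` is the analytic inverse
#' c = y / (2 - y), y = exp(k (I - 1)).
#'
#' @param c containment fraction(s) in \[0, 1\].
#' @param k k-mer length.
#' @return Identity value(s) in \[0, 1\].
#' @export
identity_from_containment <- function(c, k) {
  if (any(c < 0 | c > 1)) stop("containment must be in [0, 1]")
  i <- ifelse(c == 0, 0, 1 + log(2 * c / (1 + c)) / k)
  pmin(1, pmax(0, i))
}

#' @rdname identity_from_containment
#' @param identity identity value(s) in (0, 1\].
#' @export
containment_at_identity <- function(identity, k) {
  y <- exp(k * (identity - 1))
  y / (2 - y)
}

#' Containment screening of a genome sketch against a metagenome
#'
#' Looks up every hash of the genome sketch among all distinct hashes of
#' the metagenome and reports the containment fraction and the derived
#' screen identity. Containment is computed independently per genome; no
#' winner-take-all reassignment of shared hashes between genomes is
#' performed.
#'
#' @param genome_sketch non-empty `kmer_sketch` of a genome.
#' @param metagenome_inventory `kmer_inventory` of a metagenome built under
#'   the same k and hash seed.
#' @return A one-row data.frame: `genome_id`, `metagenome_id`,
#'   `containment`, `identity`.
#' @export
screen_identity <- function(genome_sketch, metagenome_inventory) {
  stopifnot(inherits(genome_sketch, "kmer_sketch"),
            inherits(metagenome_inventory, "kmer_inventory"))
  stop_policy_mismatch(genome_sketch$policy, metagenome_inventory$policy)
  if (length(genome_sketch$hashes) == 0L)
    stop("cannot screen an empty genome sketch")
  c <- mean(sorted_member(genome_sketch$hashes, metagenome_inventory$hashes))
  data.frame(genome_id = genome_sketch$source_id,
             metagenome_id = metagenome_inventory$source_id,
             containment = c,
             identity = identity_from_containment(c, genome_sketch$policy$k),
             stringsAsFactors = FALSE)
}

#' Screen a panel of genome sketches against a panel of metagenomes
#'
#' @param genome_sketches named list of `kmer_sketch`.
#' @param metagenome_inventories named list of `kmer_inventory`.
#' @return Matrix of screen identities, genomes x metagenomes.
#' @export
screen_panel <- function(genome_sketches, metagenome_inventories) {
  stopifnot(length(genome_sketches) >= 1L, length(metagenome_inventories) >= 1L)
  gid <- vapply(genome_sketches, function(s) s$source_id, character(1))
  mid <- vapply(metagenome_inventories, function(s) s$source_id, character(1))
  m <- matrix(0, length(gid), length(mid), dimnames = list(gid, mid))
  for (j in seq_along(metagenome_inventories)) {
    inv <- metagenome_inventories[[j]]
    for (i in seq_along(genome_sketches)) {
      m[i, j] <- screen_identity(genome_sketches[[i]], inv)$identity
    }
  }
  m
}
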