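test_that("canonical k-mer extraction follows the min(forward, revcomp) rule", {
  p <- kmer_policy(k = 3, sketch_size = 10)
  h_acg <- canonical_kmer_hashes("ACG", p)
  # ACGT has windows ACG and CGT; canon of both is ACG
  expect_equal(canonical_kmer_hashes("ACGT", p), rep(h_acg, 2))
  # windows containing N are skipped entirely
  expect_length(canonical_kmer_hashes("ACNGT", p), 0)
  # sequence shorter than k gives an empty stream, not an error
  expect_length(canonical_kmer_hashes("AC", p), 0)
})

test_that("a sequence and its reverse complement hash identically", {
  p <- kmer_policy(k = 5, sketch_size = 100)
  set.seed(4)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
    rc <- as.character(prevderep:::cpp_revcomp(s))
    expect_equal(sort(canonical_kmer_hashes(s, p)),
                 sort(canonical_kmer_hashes(rc, p)))
  }
})

test_that("sketches keep the s smallest distinct hashes of the inventory", {
  g <- make_genome(10000, seed = 21)
  pol <- genome_policy(sketch_size = 1000)
  sk <- make_sketch(g, pol, "g")
  expect_s3_class(sk, "kmer_sketch")
  expect_length(sk$hashes, 1000)
  expect_false(is.unsorted(sk$hashes, strictly = TRUE))
  # brute-force oracle: hash every window independently, canonicalize via
  # the single-window path, dedupe and sort
  windows <- substring(g, 1:(nchar(g) - 20), 21:nchar(g))
  oracle <- sort(unique(vapply(windows, function(w)
    canonical_kmer_hashes(w, pol), numeric(1), USE.NAMES = FALSE)))
  expect_equal(sk$total_distinct_kmers, length(oracle))
  expect_equal(sk$hashes, oracle[1:1000])
  # small input: no truncation
  small <- make_sketch("ACGTACGTTGCA", kmer_policy(k = 5, sketch_size = 100))
  expect_lte(length(small$hashes), 8)
  expect_equal(small$total_distinct_kmers, length(small$hashes))
})

test_that("singleton dropping removes once-seen k-mers before truncation", {
  pol_drop <- kmer_policy(k = 7, sketch_size = 50, drop_singletons = TRUE)
  pol_keep <- kmer_policy(k = 7, sketch_size = 50, drop_singletons = FALSE)
  set.seed(9)
  s <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
  # duplicated input: every k-mer occurs >= 2 times, the filter is a no-op
  expect_equal(make_sketch(c(s, s), pol_drop)$hashes,
               make_sketch(c(s, s), pol_keep)$hashes)
  # unique random k-mers all dropped -> flagged empty sketch, not an error
  sk <- make_sketch(s, pol_drop)
  expect_length(sk$hashes, 0)
  expect_equal(sk$total_distinct_kmers, 0)
})

test_that("sketching is deterministic and seed-sensitive", {
  g <- make_genome(5000, seed = 3)
  a <- make_sketch(g, genome_policy(hash_seed = 7))
  b <- make_sketch(g, genome_policy(hash_seed = 7))
  c <- make_sketch(g, genome_policy(hash_seed = 8))
  expect_identical(a$hashes, b$hashes)
  expect_false(identical(a$hashes, c$hashes))
})

test_that("jaccard estimator handles identity, disjointness and mismatch", {
  g <- make_genome(5000, seed = 31)
  pol <- genome_policy(sketch_size = 500)
  a <- make_sketch(g, pol)
  expect_equal(jaccard_estimate(a, a), 1.0)
  b <- make_sketch(make_genome(5000, seed = 32), pol)
  expect_equal(jaccard_estimate(a, b), 0.0)
  expect_error(jaccard_estimate(a, make_sketch(g, genome_policy(hash_seed = 9))),
               "policy mismatch")
  empty <- make_sketch("AAAA", kmer_policy(k = 21, sketch_size = 10,
                                           drop_singletons = TRUE))
  expect_error(jaccard_estimate(empty, empty), "empty")
})

test_that("jaccard estimates track the exact Jaccard of the inventories", {
  pol <- genome_policy(sketch_size = 1000)
  set.seed(100)
  n_ok <- 0L
  for (i in 1:10) {
    g1 <- make_genome(20000, seed = 400 + i)
    g2 <- mutate_genome(g1, runif(1, 0.002, 0.03), seed = 500 + i)
    J <- exact_jaccard(g1, g2, pol)
    est <- jaccard_estimate(make_sketch(g1, pol), make_sketch(g2, pol))
    tol <- 3 * sqrt(J * (1 - J) / 1000)
    n_ok <- n_ok + (abs(est - J) <= tol)
  }
  expect_gte(n_ok, 9L)
})

test_that("mash distance matches its formula, caps and monotonicity", {
  expect_equal(mash_distance(1, 21), 0)
  expect_equal(mash_distance(0, 21), 1)
  expect_equal(mash_distance(0.5, 21), -log(2 * 0.5 / 1.5) / 21)
  expect_error(mash_distance(1.2, 21), "\\[0, 1\\]")
  j <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(mash_distance(j, 21)) < 0))
  # round trip: inverting the formula recovers j to 1e-9
  d <- mash_distance(j, 21)
  y <- exp(-21 * d)
  expect_equal(y / (2 - y), j, tolerance = 1e-9)
})

test_that("screen identity maps containment correctly at the extremes", {
  g <- make_genome(5000, seed = 41)
  pol <- genome_policy(sketch_size = 500)
  sk <- make_sketch(g, pol, "g")
  hit <- screen_identity(sk, kmer_inventory(g, pol, "m"))
  expect_equal(hit$containment, 1)
  expect_equal(hit$identity, 1)
  miss <- screen_identity(sk, kmer_inventory(make_genome(5000, seed = 42),
                                             pol, "m2"))
  expect_equal(miss$containment, 0)
  expect_equal(miss$identity, 0)
  # identity strictly increasing in containment
  cs <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(identity_from_containment(cs, 21)) > 0))
})

test_that("multi-contig input forms no k-mers across contig boundaries", {
  pol <- kmer_policy(k = 7, sketch_size = 1000)
  g <- make_genome(2000, seed = 55)
  halves <- c(substr(g, 1, 1000), substr(g, 1001, 2000))
  joint <- kmer_inventory(g, pol)$hashes
  split <- kmer_inventory(halves, pol)$hashes
  # the split inventory misses exactly the junction-spanning k-mers
  expect_true(all(split %in% joint))
  junction <- substring(g, 995, 1006)
  expect_true(all(canonical_kmer_hashes(junction, pol) %in% joint))
})
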