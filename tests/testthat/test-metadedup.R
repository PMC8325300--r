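test_that("pairwise distances are zero for duplicates and capped for disjoint sets", {
  pol <- genome_policy(sketch_size = 200)
  g1 <- make_genome(5000, seed = 61)
  g2 <- make_genome(5000, seed = 62)
  sk <- list(a = make_sketch(g1, pol, "a"), b = make_sketch(g1, pol, "b"),
             c = make_sketch(g2, pol, "c"))
  d <- pairwise_distances(sk)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)
  expect_equal(d, t(d))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
})

test_that("pairwise distances equal per-pair scalar recomputation", {
  pol <- genome_policy(sketch_size = 300)
  base <- make_genome(8000, seed = 63)
  sketches <- lapply(1:5, function(i)
    make_sketch(mutate_genome(base, 0.005 * i, seed = 70 + i), pol,
                sprintf("s%d", i)))
  names(sketches) <- sprintf("s%d", 1:5)
  d <- pairwise_distances(sketches)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(d[i, j],
                 mash_distance(jaccard_estimate(sketches[[i]], sketches[[j]]),
                               pol$k))
  }
})

test_that("complete-linkage partition respects the diameter rule", {
  # two tight blocks far apart -> exactly two clusters
  labels <- letters[1:6]
  d <- matrix(0.5, 6, 6, dimnames = list(labels, labels))
  d[1:3, 1:3] <- 0.01
  d[4:6, 4:6] <- 0.01
  diag(d) <- 0
  part <- complete_linkage_partition(d, threshold = 0.05)
  expect_length(part$clusters, 2)
  expect_equal(part$clusters[[1]], c("a", "b", "c"))
  expect_equal(part$clusters[[2]], c("d", "e", "f"))
  # all-zero distances -> one cluster
  d0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_length(complete_linkage_partition(d0, 0.05)$clusters, 1)
})

test_that("a tied chain is split by the diameter constraint deterministically", {
  labels <- c("s1", "s2", "s3")
  d <- matrix(c(0, 0.04, 0.06,
                0.04, 0, 0.04,
                0.06, 0.04, 0), 3, 3, dimnames = list(labels, labels))
  part <- complete_linkage_partition(d, threshold = 0.05)
  # s2 joins exactly one neighbor; s1 and s3 (at 0.06) never share a cluster
  in_same <- function(x, y) any(vapply(part$clusters, function(cl)
    all(c(x, y) %in% cl), logical(1)))
  expect_false(in_same("s1", "s3"))
  expect_length(part$clusters, 2)
  # declared tie-break: the pair containing the smallest label merges first
  expect_true(in_same("s1", "s2"))
})

test_that("medoid minimizes the distance sum with lexicographic ties", {
  labels <- c("a", "b", "c")
  d <- matrix(c(0, 0.02, 0.08,
                0.02, 0, 0.05,
                0.08, 0.05, 0), 3, 3, dimnames = list(labels, labels))
  # sums: a = 0.10, b = 0.07, c = 0.13 -> b
  expect_equal(medoid(labels, d), "b")
  expect_equal(medoid("c", d), "c")
  # exact tie: equilateral -> smallest label
  dt <- matrix(0.1, 3, 3, dimnames = list(labels, labels)); diag(dt) <- 0
  expect_equal(medoid(labels, dt), "a")
  expect_error(medoid(c("a", "zzz"), d), "missing")
})

test_that("partitions and medoids satisfy their invariants on random matrices", {
  for (rep in 1:8) {
    n <- sample(4:12, 1)
    d <- random_dist_matrix(n, seed = 900 + rep)
    t <- 0.5
    part <- complete_linkage_partition(d, threshold = t)
    members <- sort(unlist(part$clusters))
    expect_equal(members, sort(rownames(d)))        # true partition
    for (ci in seq_along(part$clusters)) {
      cl <- part$clusters[[ci]]
      expect_lte(max(d[cl, cl]), t)                 # diameter property
      # medoid equals exhaustive argmin
      sums <- rowSums(d[cl, cl, drop = FALSE])
      expect_equal(min(sums[part$medoids[ci]]), min(sums))
    }
    # maximality: no two clusters could merge within the threshold
    if (length(part$clusters) > 1) {
      for (i in 1:(length(part$clusters) - 1)) {
        for (j in (i + 1):length(part$clusters)) {
          u <- c(part$clusters[[i]], part$clusters[[j]])
          expect_gt(max(d[u, u]), t)
        }
      }
    }
  }
})

test_that("within-project dedup retains one medoid per duplicate group", {
  pol <- genome_policy(sketch_size = 200)
  g <- lapply(1:3, function(i) make_genome(5000, seed = 80 + i))
  sketches <- list(
    p1a = make_sketch(g[[1]], pol, "p1a"), p1b = make_sketch(g[[1]], pol, "p1b"),
    p1c = make_sketch(g[[2]], pol, "p1c"),
    p2a = make_sketch(g[[3]], pol, "p2a"), p2b = make_sketch(g[[3]], pol, "p2b"),
    p2c = make_sketch(g[[3]], pol, "p2c"), p2d = make_sketch(g[[3]], pol, "p2d"),
    p3a = make_sketch(g[[2]], pol, "p3a"))
  meta <- data.frame(
    sample_id = names(sketches),
    project_id = c(rep("P1", 3), rep("P2", 4), "P3"),
    reads_count = 2e6, stringsAsFactors = FALSE)
  res <- dedup_samples(sketches, meta, threshold = 0.05)
  retained <- res$sample_id[res$is_medoid]
  # P1 has 2 planted groups, P2 one group of 4 identical, P3 a singleton
  expect_length(intersect(retained, c("p1a", "p1b", "p1c")), 2)
  expect_length(intersect(retained, c("p2a", "p2b", "p2c", "p2d")), 1)
  expect_true("p3a" %in% retained)
  expect_equal(sum(res$cluster_size[res$is_medoid]), nrow(meta))
})

test_that("dedup is idempotent on separated retained samples and applies read cut", {
  pol <- genome_policy(sketch_size = 200)
  sketches <- list(a = make_sketch(make_genome(5000, seed = 91), pol, "a"),
                   b = make_sketch(make_genome(5000, seed = 92), pol, "b"),
                   c = make_sketch(make_genome(5000, seed = 93), pol, "c"))
  meta <- data.frame(sample_id = c("a", "b", "c"), project_id = "P",
                     reads_count = c(2e6, 2e6, 5e5), stringsAsFactors = FALSE)
  res <- dedup_samples(sketches, meta, threshold = 0.05, min_reads = 1e6)
  expect_setequal(res$sample_id, c("a", "b"))       # shallow sample dropped
  expect_true(all(res$is_medoid))
  res2 <- dedup_samples(sketches[res$sample_id],
                        meta[meta$sample_id %in% res$sample_id, ],
                        threshold = 0.05)
  expect_equal(sort(res2$sample_id[res2$is_medoid]), sort(res$sample_id))
})

test_that("empty sketches are excluded from clustering and reported", {
  pol <- kmer_policy(k = 21, sketch_size = 50, drop_singletons = TRUE)
  good <- make_sketch(c(strrep("ACGTT", 100), strrep("ACGTT", 100)), pol, "g")
  empty <- make_sketch(paste(sample(c("A","C","G","T"), 50, replace = TRUE),
                             collapse = ""), pol, "e")
  res <- dedup_samples(list(g = good, e = empty),
                       data.frame(sample_id = c("g", "e"), project_id = "P"),
                       threshold = 0.05)
  expect_true(res$excluded_empty[res$sample_id == "e"])
  expect_false(res$is_medoid[res$sample_id == "e"])
  expect_true(res$is_medoid[res$sample_id == "g"])
})
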