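#' Pairwise MASH distance matrix between sample sketches
#'
#' Entry (i, j) is `mash_distance(jaccard_estimate(i, j), k)`. The matrix
#' is symmetric with a zero diagonal; disjoint sketches get the distance
#' cap 1.
#'
#' @param sketches named list of `kmer_sketch` objects under one policy.
#'   Unnamed lists are labelled by the sketches' `source_id`.
#' @return Symmetric numeric matrix with sample labels on both dimensions.
#' @export
pairwise_distances <- function(sketches) {
  stopifnot(length(sketches) >= 2L)
  labels <- names(sketches)
  if (is.null(labels))
    labels <- vapply(sketches, function(s) s$source_id, character(1))
  if (anyDuplicated(labels)) stop("duplicate sample labels")
  k <- sketches[[1]]$policy$k
  for (s in sketches) stop_policy_mismatch(sketches[[1]]$policy, s$policy)
  n <- length(sketches)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      dij <- mash_distance(jaccard_estimate(sketches[[i]], sketches[[j]]), k)
      d[i, j] <- dij
      d[j, i] <- dij
    }
  }
  d
}

validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    stop("distance matrix must carry identical row and column labels")
  if (any(!is.finite(d))) stop("distance matrix entries must be finite")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  invisible(TRUE)
}

#' Complete-linkage partition at a distance threshold
#'
#' Agglomerates clusters by complete linkage (inter-cluster distance = the
#' maximum pairwise member distance) and stops when no merge of height <=
#' `threshold` remains. Every cluster therefore has diameter <= threshold,
#' and no two output clusters could be merged without exceeding it. Ties in
#' merge height are broken deterministically: the pair whose smallest
#' member label sorts first (then the other cluster's smallest label) is
#' merged first.
#'
#' @param d labelled symmetric distance matrix (see [pairwise_distances()]).
#' @param threshold maximum allowed within-cluster pairwise distance.
#' @return A `sample_partition`: list with `threshold`, `clusters` (list of
#'   label vectors, each sorted), `medoids` (one label per cluster).
#' @export
complete_linkage_partition <- function(d, threshold = 0.05) {
  validate_distance_matrix(d)
  labels <- rownames(d)
  clusters <- as.list(labels)
  # inter-cluster complete-linkage distances, updated by Lance-Williams max
  cd <- d
  repeat {
    n <- length(clusters)
    if (n == 1L) break
    off <- cd
    diag(off) <- Inf
    h <- min(off)
    if (h > threshold) break
    idx <- which(off == h, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    key1 <- vapply(seq_len(nrow(idx)), function(r)
      min(clusters[[idx[r, 1]]], clusters[[idx[r, 2]]]), character(1))
    key2 <- vapply(seq_len(nrow(idx)), function(r)
      max(min(clusters[[idx[r, 1]]]), min(clusters[[idx[r, 2]]])), character(1))
    pick <- order(key1, key2)[1L]
    i <- idx[pick, 1]; j <- idx[pick, 2]
    clusters[[i]] <- sort(c(clusters[[i]], clusters[[j]]))
    clusters[[j]] <- NULL
    newd <- pmax(cd[i, ], cd[j, ])[-j]
    cd <- cd[-j, -j, drop = FALSE]
    cd[i - (i > j), ] <- newd
    cd[, i - (i > j)] <- newd
    diag(cd) <- 0
  }
  clusters <- clusters[order(vapply(clusters, min, character(1)))]
  medoids <- vapply(clusters, medoid, character(1), d = d)
  structure(list(threshold = threshold, clusters = clusters, medoids = medoids),
            class = "sample_partition")
}

#' @export
print.sample_partition <- function(x, ...) {
  cat(sprintf("sample_partition: %d clusters at threshold %g\n",
              length(x$clusters), x$threshold))
  invisible(x)
}

#' Medoid of a cluster
#'
#' The member with the minimum sum of distances to all cluster members;
#' exact ties go to the lexicographically smallest label. A singleton is
#' its own medoid.
#'
#' @param members character vector of member labels, all present in `d`.
#' @param d labelled distance matrix.
#' @return The medoid label.
#' @export
medoid <- function(members, d) {
  stopifnot(length(members) >= 1L)
  if (!all(members %in% rownames(d))) stop("cluster member missing from distance matrix")
  if (length(members) == 1L) return(members)
  sums <- rowSums(d[members, members, drop = FALSE])
  members <- sort(members)
  sums <- sums[members]
  members[which.min(sums)]
}

#' Deduplicate metagenome samples within projects
#'
#' Within each project, clusters the samples by complete linkage on the
#' pairwise sketch distance matrix at `threshold` and retains the medoid of
#' every cluster, so no two retained samples of a project are within
#' `threshold` of each other's cluster. Samples with empty sketches are
#' excluded before clustering and flagged in the output. An optional
#' minimum read count drops shallow samples first.
#'
#' @param sketches named list of `kmer_sketch`, one per sample.
#' @param sample_meta data.frame with columns `sample_id`, `project_id` and
#'   optionally `reads_count`.
#' @param threshold complete-linkage diameter cutoff (default 0.05).
#' @param min_reads optional minimum `reads_count`; samples below it are
#'   dropped before clustering (the conventional curation cut is 1e6).
#' @return data.frame with one row per clustered sample: `sample_id`,
#'   `project_id`, `cluster`, `cluster_size`, `is_medoid`, `excluded_empty`.
#'   Retained samples are the rows with `is_medoid == TRUE`.
#' @export
dedup_samples <- function(sketches, sample_meta, threshold = 0.05,
                          min_reads = NULL) {
  stopifnot(is.data.frame(sample_meta),
            all(c("sample_id", "project_id") %in% names(sample_meta)))
  ids <- sample_meta$sample_id
  if (!all(ids %in% names(sketches))) stop("missing sketches for some samples")
  if (!is.null(min_reads)) {
    stopifnot("reads_count" %in% names(sample_meta))
    sample_meta <- sample_meta[sample_meta$reads_count >= min_reads, , drop = FALSE]
  }
  out <- list()
  for (proj in unique(sample_meta$project_id)) {
    pid <- sample_meta$sample_id[sample_meta$project_id == proj]
    empty <- vapply(sketches[pid], function(s) length(s$hashes) == 0L, logical(1))
    if (any(empty)) {
      out[[length(out) + 1L]] <- data.frame(
        sample_id = pid[empty], project_id = proj, cluster = NA_integer_,
        cluster_size = NA_integer_, is_medoid = FALSE, excluded_empty = TRUE,
        stringsAsFactors = FALSE)
      pid <- pid[!empty]
    }
    if (length(pid) == 0L) next
    if (length(pid) == 1L) {
      out[[length(out) + 1L]] <- data.frame(
        sample_id = pid, project_id = proj, cluster = 1L, cluster_size = 1L,
        is_medoid = TRUE, excluded_empty = FALSE, stringsAsFactors = FALSE)
      next
    }
    part <- complete_linkage_partition(pairwise_distances(sketches[pid]),
                                       threshold = threshold)
    for (ci in seq_along(part$clusters)) {
      mem <- part$clusters[[ci]]
      out[[length(out) + 1L]] <- data.frame(
        sample_id = mem, project_id = proj, cluster = ci,
        cluster_size = length(mem), is_medoid = mem == part$medoids[[ci]],
        excluded_empty = FALSE, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
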