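#' Core species of a cohort
#'
#' Species present (readcount > 0, typically after false-positive filtering
#' and redistribution) in strictly more than `prevalence_cut` of the
#' cohort's samples.
#'
#' @param m abundance matrix, samples x species (non-negative readcounts;
#'   row and column names required).
#' @param annotations data.frame with `sample_id` and `cohort` covering all
#'   rows of `m`.
#' @param cohort cohort label to evaluate.
#' @param prevalence_cut prevalence fraction; inclusion requires prevalence
#'   strictly greater than this (default 0.70).
#' @return data.frame `species`, `prevalence`, `mean_abundance`, sorted by
#'   prevalence descending then species.
#' @export
core_species <- function(m, annotations, cohort, prevalence_cut = 0.70) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)),
            all(c("sample_id", "cohort") %in% names(annotations)))
  if (any(m < 0)) stop("readcounts must be non-negative")
  ids <- annotations$sample_id[annotations$cohort == cohort]
  ids <- intersect(rownames(m), ids)
  if (length(ids) == 0L) stop("no samples in cohort: ", cohort)
  sub <- m[ids, , drop = FALSE]
  prev <- colMeans(sub > 0)
  keep <- prev > prevalence_cut
  out <- data.frame(species = colnames(sub)[keep], prevalence = prev[keep],
                    mean_abundance = colMeans(sub[, keep, drop = FALSE]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$prevalence, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Centered log-ratio transform of a readcount matrix
#'
#' Adds a pseudo-count to every entry, then per sample (row) computes
#' ln(x) minus the row mean of ln(x). Rows sum to zero, removing the
#' compositional unit-sum constraint before ordination.
#'
#' @param m samples x species readcount matrix (>= 0).
#' @param pseudocount added to every count before the log (default 10);
#'   must be > 0 whenever zero counts are present.
#' @return Real-valued matrix of the same shape.
#' @export
clr_transform <- function(m, pseudocount = 10) {
  stopifnot(is.matrix(m))
  if (any(m < 0)) stop("readcounts must be non-negative")
  if (pseudocount <= 0 && any(m == 0))
    stop("pseudocount must be > 0 when zero counts are present")
  x <- log(m + pseudocount)
  sweep(x, 1, rowMeans(x))
}

#' PCA of a CLR-transformed abundance matrix
#'
#' Column-centered principal component analysis (no additional scaling).
#' Components are ordered by decreasing explained variance and signed so
#' the largest-magnitude loading of each component is positive.
#'
#' @param clr matrix from [clr_transform()] (>= 2 samples, >= 2 species).
#' @return List `scores` (samples x components), `loadings` (species x
#'   components), `explained_variance` (component variances, non-
#'   increasing, summing to the total column variance of `clr`).
#' @export
clr_pca <- function(clr) {
  stopifnot(is.matrix(clr))
  if (nrow(clr) < 2L || ncol(clr) < 2L)
    stop("PCA needs at least 2 samples and 2 species")
  p <- stats::prcomp(clr, center = TRUE, scale. = FALSE)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2, flip, `*`)
  loadings <- sweep(p$rotation, 2, flip, `*`)
  list(scores = scores, loadings = loadings,
       explained_variance = p$sdev^2)
}

#' Average-linkage clustering of projects
#'
#' The distance between two projects is the mean pairwise sample distance
#' across all their cross-project sample pairs; projects are clustered by
#' average linkage on these distances.
#'
#' @param d labelled sample distance matrix.
#' @param projects named character vector (or factor) mapping each sample
#'   label of `d` to its project.
#' @return List `project_distances` (matrix), `tree` (an [stats::hclust]
#'   dendrogram with merge heights), `newick` (the tree as a Newick
#'   string).
#' @export
project_linkage <- function(d, projects) {
  validate_distance_matrix(d)
  samples <- rownames(d)
  projects <- projects[samples]
  if (any(is.na(projects))) stop("every sample needs a project")
  plev <- sort(unique(as.character(projects)))
  if (length(plev) < 2L) stop("need at least two projects")
  pd <- matrix(0, length(plev), length(plev), dimnames = list(plev, plev))
  for (i in seq_along(plev)[-length(plev)]) {
    for (j in seq.int(i + 1L, length(plev))) {
      a <- samples[projects == plev[i]]
      b <- samples[projects == plev[j]]
      pd[i, j] <- pd[j, i] <- mean(d[a, b])
    }
  }
  tree <- stats::hclust(stats::as.dist(pd), method = "average")
  newick <- ape::write.tree(ape::as.phylo(tree))
  list(project_distances = pd, tree = tree, newick = newick)
}

#' Genome accumulation (rarefaction) curve
#'
#' For each random permutation of the metagenome panel, counts the
#' cumulative number of distinct genomes first qualified as metagenomes
#' are screened one by one; reports the per-step mean and spread across
#' permutations. The curve is monotone non-decreasing and its final value
#' always equals the total number of qualified genomes.
#'
#' @param q logical qualification matrix, genomes x metagenomes (TRUE =
#'   genome qualified in that metagenome, i.e. screen identity >= 0.95).
#' @param permutations number of random orderings (>= 1).
#' @param seed RNG seed.
#' @return List `curve` (data.frame `step`, `mean_genomes`, `min_genomes`,
#'   `max_genomes`) and `per_permutation` (matrix permutations x steps).
#' @export
rarefaction_curve <- function(q, permutations = 100L, seed = 1L) {
  stopifnot(is.matrix(q), permutations >= 1L)
  if (nrow(q) == 0L || ncol(q) == 0L) stop("empty qualification matrix")
  storage.mode(q) <- "logical"
  n <- ncol(q)
  per <- matrix(0L, permutations, n)
  with_seed(seed, {
    for (p in seq_len(permutations)) {
      perm <- sample.int(n)
      qp <- q[, perm, drop = FALSE]
      qp <- qp[rowSums(qp) > 0L, , drop = FALSE]
      first <- max.col(qp * 1, ties.method = "first")
      per[p, ] <- cumsum(tabulate(first, nbins = n))
    }
  })
  curve <- data.frame(step = seq_len(n),
                      mean_genomes = colMeans(per),
                      min_genomes = apply(per, 2, min),
                      max_genomes = apply(per, 2, max))
  list(curve = curve, per_permutation = per)
}
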