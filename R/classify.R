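#' Build an LCA k-mer classification database
#'
#' Every distinct canonical k-mer of the input genomes is assigned to the
#' lowest common ancestor of all species whose genomes contain it. Per-node
#' distinct-k-mer inventories are recorded, and species-to-node
#' redistribution probabilities are estimated by sliding fixed-length
#' fragments over each genome, classifying every fragment against the
#' finished k-mer map and normalizing the resulting call frequencies per
#' species. These conditional probabilities later drive the Bayesian
#' read redistribution of [redistribute_to_species()].
#'
#' @param genomes named character vector/list of genome sequences (name =
#'   genome id).
#' @param genome_species named integer vector mapping genome id to a
#'   species node id of `tax`.
#' @param tax a [taxonomy()].
#' @param k classifier k-mer length (default 31).
#' @param fragment_length read-sized fragment length for redistribution
#'   estimation (default 100; must be >= k).
#' @param fragment_step stride between fragment starts (default 1, i.e.
#'   every position; larger strides trade accuracy for speed).
#' @param hash_seed hash seed.
#' @return An `lca_database`: `k`, `hash_seed`, `tax`, sorted `kmer_hash`
#'   with aligned `kmer_node`, `node_kmer_counts` (named by node id), and
#'   `redistribution` (data.frame `node_id`, `species_id`, `prob`; probs
#'   sum to 1 per species).
#' @export
build_lca_database <- function(genomes, genome_species, tax, k = 31L,
                               fragment_length = 100L, fragment_step = 1L,
                               hash_seed = 1234L) {
  stopifnot(inherits(tax, "taxonomy"), length(genomes) >= 1L)
  k <- as.integer(k)
  if (k > fragment_length) stop("k must not exceed fragment_length")
  gids <- names(genomes)
  if (is.null(gids) || !all(gids %in% names(genome_species)))
    stop("every genome needs a species mapping")
  leaves <- tax_leaves(tax)
  sp <- genome_species[gids]
  if (!all(sp %in% tax$nodes$id)) stop("species ids missing from taxonomy")
  if (!all(tax$nodes$rank[match(sp, tax$nodes$id)] == "species"))
    stop("genomes must map to species-rank nodes")

  # distinct (hash, species) pairs across all genomes
  hs <- lapply(gids, function(g)
    cpp_kmer_counts(as.character(genomes[[g]]), k, hash_seed)$hash)
  all_h <- unlist(hs, use.names = FALSE)
  all_s <- rep(as.integer(sp), lengths(hs))
  ord <- order(all_h, all_s)
  all_h <- all_h[ord]; all_s <- all_s[ord]
  keep <- c(TRUE, all_h[-1] != all_h[-length(all_h)] |
              all_s[-1] != all_s[-length(all_s)])
  all_h <- all_h[keep]; all_s <- all_s[keep]
  new_h <- c(TRUE, all_h[-1] != all_h[-length(all_h)])
  grp <- cumsum(new_h)
  n_sp <- tabulate(grp)
  kmer_hash <- all_h[new_h]
  kmer_node <- all_s[new_h]          # correct for single-species k-mers
  multi <- which(n_sp > 1L)
  if (length(multi) > 0L) {
    # shared k-mers: LCA of their species sets (memoized per species set)
    starts <- which(new_h)
    cache <- new.env(parent = emptyenv())
    for (m in multi) {
      set <- sort(unique(all_s[seq.int(starts[m], starts[m] + n_sp[m] - 1L)]))
      key <- paste(set, collapse = ",")
      node <- get0(key, envir = cache)
      if (is.null(node)) {
        node <- tax_lca(tax, set)
        assign(key, node, envir = cache)
      }
      kmer_node[m] <- node
    }
  }
  counts <- table(factor(kmer_node, levels = tax$nodes$id))
  db <- structure(list(k = k, hash_seed = as.integer(hash_seed), tax = tax,
                       kmer_hash = kmer_hash, kmer_node = as.integer(kmer_node),
                       node_kmer_counts = stats::setNames(as.integer(counts),
                                                          tax$nodes$id),
                       redistribution = NULL),
                  class = "lca_database")
  db$redistribution <- estimate_redistribution(db, genomes, sp,
                                               fragment_length, fragment_step)
  db
}

#' @export
print.lca_database <- function(x, ...) {
  cat(sprintf("lca_database: %d k-mers (k=%d) over %d taxonomy nodes\n",
              length(x$kmer_hash), x$k, nrow(x$tax$nodes)))
  invisible(x)
}

# Sliding read-sized fragments of each genome, classified against the k-mer
# map; call frequencies normalized per source species.
estimate_redistribution <- function(db, genomes, species, fragment_length,
                                    fragment_step) {
  rows <- list()
  for (i in seq_along(genomes)) {
    g <- paste(as.character(genomes[[i]]), collapse = "")
    starts <- seq.int(1L, nchar(g) - fragment_length + 1L, by = fragment_step)
    frags <- substring(g, starts, starts + fragment_length - 1L)
    calls <- classify_batch(frags, db)$call
    calls <- calls[!is.na(calls)]
    rows[[i]] <- data.frame(species_id = as.integer(species[i]),
                            node_id = calls, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(list(n = rep(1L, nrow(tab))),
                          by = tab[c("species_id", "node_id")], FUN = sum)
  # several genomes may share a species; pool before normalizing
  tot <- stats::ave(agg$n, agg$species_id, FUN = sum)
  out <- data.frame(node_id = agg$node_id, species_id = agg$species_id,
                    prob = agg$n / tot)
  out <- out[order(out$species_id, out$node_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Vectorized LCA classification of many sequences. Returns the per-sequence
# call (node id, NA = unclassified), plus per-node counts of distinct
# database k-mers observed across all sequences.
classify_batch <- function(seqs, db) {
  tax <- db$tax
  node_ids <- tax$nodes$id
  n_nodes <- length(node_ids)
  leaves <- sort(tax_leaves(tax))
  # path indicator: nodes x leaves
  A <- matrix(0, n_nodes, length(leaves),
              dimnames = list(node_ids, leaves))
  for (j in seq_along(leaves)) {
    A[match(tax_ancestors(tax, leaves[j]), node_ids), j] <- 1
  }
  bh <- cpp_kmer_hash_batch(as.character(seqs), db$k, db$hash_seed)
  read_id <- rep(seq_along(seqs), bh$n_kmers)
  idx <- findInterval(bh$hashes, db$kmer_hash)
  hit <- idx > 0L & db$kmer_hash[pmax(idx, 1L)] == bh$hashes
  h_read <- read_id[hit]
  h_node <- match(db$kmer_node[idx[hit]], node_ids)
  n_reads <- length(seqs)
  M <- matrix(tabulate((h_node - 1L) * n_reads + h_read,
                       nbins = n_reads * n_nodes), n_reads, n_nodes)
  scores <- M %*% A
  best <- do.call(pmax, as.data.frame(scores))
  has_hit <- rowSums(M) > 0L
  call <- rep(NA_integer_, n_reads)
  if (any(has_hit)) {
    tied <- scores == best           # logical matrix reads x leaves
    pattern <- do.call(paste0, as.data.frame(tied + 0L))
    hp <- pattern[has_hit]
    u <- !duplicated(hp)
    pat_call <- stats::setNames(
      vapply(which(has_hit)[u], function(r) tax_lca(tax, leaves[tied[r, ]]),
             integer(1)),
      hp[u])
    call[has_hit] <- pat_call[hp]
  }
  # distinct observed database k-mers, tallied on the node each maps to
  obs_h <- unique(bh$hashes[hit])
  obs_node <- db$kmer_node[findInterval(obs_h, db$kmer_hash)]
  obs <- table(factor(obs_node, levels = node_ids))
  too_short <- bh$n_kmers == 0L & nchar(seqs) < db$k
  list(call = call,
       observed_unique = stats::setNames(as.integer(obs), node_ids),
       n_short = sum(too_short))
}

#' Classify a single read
#'
#' Collects the database hits of the read's canonical k-mers, scores every
#' root-to-leaf path of the taxonomy by the number of hits on its nodes,
#' and calls the deepest node of the maximal-score path. When several
#' paths tie, the call is the LCA of their deepest nodes. Reads with no
#' database hits (or shorter than k) are unclassified.
#'
#' @param read a nucleotide string.
#' @param db an [build_lca_database()] result.
#' @return Node id of the call, or NA when unclassified.
#' @export
classify_read <- function(read, db) {
  stopifnot(is.character(read), length(read) == 1L)
  classify_batch(read, db)$call
}

#' Classify a read set into a per-taxon report
#'
#' Aggregates per-read calls into direct and clade read counts for every
#' taxonomy node and counts, per clade, the distinct database k-mers
#' observed in the sample (exact accounting, no cardinality sketch).
#'
#' @param reads character vector of reads.
#' @param db an [build_lca_database()] result.
#' @param sample_id label carried into the report.
#' @return A `classification_report`: `sample_id`, `total_reads`,
#'   `unclassified_reads`, `filtered_reads` (0 before filtering) and
#'   `table` with one row per node: `node_id`, `rank`, `name`,
#'   `direct_reads`, `clade_reads`, `unique_kmers`.
#' @export
classify_sample <- function(reads, db, sample_id = "sample") {
  tax <- db$tax
  node_ids <- tax$nodes$id
  if (length(reads) == 0L) {
    cb <- list(call = integer(0),
               observed_unique = stats::setNames(integer(length(node_ids)),
                                                 node_ids))
  } else {
    cb <- classify_batch(reads, db)
  }
  direct <- tabulate(match(cb$call, node_ids), nbins = length(node_ids))
  tab <- data.frame(node_id = node_ids,
                    rank = tax$nodes$rank, name = tax$nodes$name,
                    direct_reads = direct,
                    clade_reads = 0L,
                    unique_kmers = as.integer(cb$observed_unique),
                    stringsAsFactors = FALSE)
  rep <- structure(list(sample_id = sample_id, total_reads = length(reads),
                        unclassified_reads = sum(is.na(cb$call)),
                        filtered_reads = 0L, table = tab,
                        taxonomy = db$tax),
                   class = "classification_report")
  recompute_clades(rep, db$tax)
}

# clade_reads and clade-level unique k-mers, bottom-up
recompute_clades <- function(report, tax) {
  tab <- report$table
  tab$clade_reads <- tab$direct_reads
  tab$clade_unique_kmers <- tab$unique_kmers
  idx <- match(tax_bottom_up(tax), tab$node_id)
  for (i in idx) {
    pid <- tax$nodes$parent[match(tab$node_id[i], tax$nodes$id)]
    if (pid == tab$node_id[i]) next
    pi <- match(pid, tab$node_id)
    tab$clade_reads[pi] <- tab$clade_reads[pi] + tab$clade_reads[i]
    tab$clade_unique_kmers[pi] <- tab$clade_unique_kmers[pi] +
      tab$clade_unique_kmers[i]
  }
  report$table <- tab
  report
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "classification_report '%s': %d reads, %d unclassified, %d filtered\n",
    x$sample_id, x$total_reads, x$unclassified_reads, x$filtered_reads))
  invisible(x)
}

#' Unique-k-mer false-positive filter
#'
#' Removes species calls supported by too few distinct database k-mers.
#' The depth-scaled threshold is T = kmer_rate * total_reads / 1e6
#' (real-valued); species whose observed distinct k-mer count is below T
#' have their reads zeroed, clade counts are recomputed, and the zeroed
#' reads are dropped from the classified total (recorded in
#' `filtered_reads`, not reassigned and not moved to unclassified).
#' Species at exactly T are kept.
#'
#' @param report a [classify_sample()] report.
#' @param kmer_rate distinct-k-mer threshold per million reads (default
#'   2000); 0 disables the filter.
#' @param all_ranks zero any sub-threshold node, not just species.
#' @return The filtered report; zeroed species are listed in
#'   `attr(, "zeroed_species")`.
#' @export
fp_filter <- function(report, kmer_rate = 2000, all_ranks = FALSE) {
  stopifnot(inherits(report, "classification_report"))
  tab <- report$table
  thr <- kmer_rate * report$total_reads / 1e6
  target <- if (all_ranks) rep(TRUE, nrow(tab)) else tab$rank == "species"
  zero <- target & tab$clade_unique_kmers < thr
  removed <- sum(tab$direct_reads[zero])
  report$filtered_reads <- report$filtered_reads + removed
  tab$direct_reads[zero] <- 0L
  report$table <- tab
  report <- recompute_clades(report, report$taxonomy)
  attr(report, "zeroed_species") <- report$table$node_id[zero]
  report
}

#' Species abundance by Bayesian read redistribution
#'
#' Moves reads classified at supra-species nodes down to species. For a
#' node n with direct reads R, each surviving species s below n receives
#' the share proportional to `redistribution(n, s) * m_s`, where m_s is the
#' species' current read mass (its direct count after filtering) — the
#' Bayes weighting of database-derived conditional probabilities by the
#' observed species signal. When all surviving species under n have zero
#' mass, the redistribution probabilities alone are used. Nodes with no
#' surviving descendant species keep their reads unassigned. Species reads
#' stay where they are. Counts are fractional; their total plus the
#' unassigned remainder equals the classified-after-filter total exactly.
#'
#' @param report a (typically [fp_filter()]ed) report.
#' @param db the database the report was classified against.
#' @return List with `abundance` (data.frame `species_id`, `name`, `reads`)
#'   and `unassigned_reads`.
#' @export
redistribute_to_species <- function(report, db) {
  stopifnot(inherits(report, "classification_report"),
            inherits(db, "lca_database"))
  if (is.null(db$redistribution) || nrow(db$redistribution) == 0L)
    stop("database has no redistribution table")
  tax <- db$tax
  tab <- report$table
  species <- tab$node_id[tab$rank == "species"]
  zeroed <- attr(report, "zeroed_species")
  surviving <- setdiff(species, zeroed)
  mass <- stats::setNames(as.numeric(tab$direct_reads[match(species, tab$node_id)]),
                          species)
  out_mass <- mass[as.character(surviving)]
  unassigned <- 0
  red <- db$redistribution
  for (i in seq_len(nrow(tab))) {
    if (tab$rank[i] == "species") next
    R <- tab$direct_reads[i]
    if (R == 0L) next
    clade_sp <- intersect(tax_clade(tax, tab$node_id[i]), surviving)
    if (length(clade_sp) == 0L) { unassigned <- unassigned + R; next }
    p <- red$prob[red$node_id == tab$node_id[i]]
    psp <- red$species_id[red$node_id == tab$node_id[i]]
    pr <- stats::setNames(rep(0, length(clade_sp)), clade_sp)
    common <- intersect(clade_sp, psp)
    pr[as.character(common)] <- p[match(common, psp)]
    w <- pr * mass[as.character(clade_sp)]
    if (sum(w) == 0) w <- pr
    if (sum(w) == 0) { unassigned <- unassigned + R; next }
    out_mass[as.character(clade_sp)] <- out_mass[as.character(clade_sp)] +
      R * w / sum(w)
  }
  ab <- data.frame(species_id = as.integer(names(out_mass)),
                   name = tab$name[match(as.integer(names(out_mass)),
                                         tab$node_id)],
                   reads = as.numeric(out_mass), stringsAsFactors = FALSE)
  rownames(ab) <- NULL
  list(abundance = ab, unassigned_reads = unassigned)
}
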