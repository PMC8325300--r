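# On-disk formats. Tabular outputs are TSV (tab separated, no quoting, '.'
# decimal) with a single '#'-prefixed provenance header line naming the
# producing stage, a parameter fingerprint and the seed; readers skip '#'
# lines. FASTA/FASTQ go through Biostrings. gzip input is read
# transparently.

stage_header <- function(stage, params = list(), seed = NA) {
  fp <- cpp_hash_string(paste(names(params), unlist(params), sep = "=",
                              collapse = ";"), 0)
  sprintf("# stage=%s params=%.0f seed=%s", stage, fp, seed)
}

#' Write / read a provenance-stamped TSV
#'
#' @param df data.frame to write.
#' @param path file path.
#' @param stage producing stage name for the header line.
#' @param params named list of stage parameters (fingerprinted into the
#'   header).
#' @param seed seed recorded in the header.
#' @return `read_stage_tsv` returns the data.frame.
#' @export
write_stage_tsv <- function(df, path, stage = "unknown", params = list(),
                            seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stage_header(stage, params, seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stage_tsv
#' @export
read_stage_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read and write FASTA
#'
#' @param path file path (.gz accepted on read).
#' @return `read_fasta` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param sequences named character vector.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read and write FASTQ
#'
#' Reading validates the four-line record structure first (record-indexed
#' errors on truncation or malformed separators), then parses with
#' Biostrings. Writing emits constant maximal base qualities; paired files
#' are handled by the caller as one pooled read stream.
#'
#' @param path file path (.gz accepted on read).
#' @return `read_fastq` returns a named character vector of reads.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4L != 0L)
    stop(sprintf("truncated FASTQ: record %d is incomplete in %s",
                 length(lines) %/% 4L + 1L, path))
  heads <- lines[seq(1L, length(lines), by = 4L)]
  seps <- lines[seq(3L, length(lines), by = 4L)]
  bad <- which(!startsWith(heads, "@") | !startsWith(seps, "+"))
  if (length(bad) > 0L)
    stop(sprintf("malformed FASTQ record %d in %s", bad[1L], path))
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fastq
#' @param reads named (or unnamed) character vector of reads.
#' @export
write_fastq <- function(reads, path) {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%d", seq_along(reads))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", reads, "\n+\n",
                    vapply(nchar(reads), function(n)
                      paste(rep("I", n), collapse = ""), character(1))), con)
  invisible(path)
}

#' Sketch serialization
#'
#' A JSON container holding the full policy (k, s, seed, singleton rule)
#' and the sorted hash list; byte-stable across runs.
#'
#' @param sketch a `kmer_sketch`.
#' @param path file path.
#' @return `read_sketch` returns the `kmer_sketch`.
#' @export
write_sketch <- function(sketch, path) {
  stopifnot(inherits(sketch, "kmer_sketch"))
  jsonlite::write_json(
    list(policy = unclass(sketch$policy), source_id = sketch$source_id,
         total_distinct_kmers = sketch$total_distinct_kmers,
         # 53-bit hash values exceed the default double rendering; write
         # them as exact integer strings
         hashes = sprintf("%.0f", sketch$hashes)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sketch
#' @export
read_sketch <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(policy = do.call(kmer_policy, x$policy),
                 hashes = as.numeric(x$hashes),
                 source_id = x$source_id,
                 total_distinct_kmers = as.integer(x$total_distinct_kmers)),
            class = "kmer_sketch")
}

#' Distance matrix TSV
#'
#' @param d labelled symmetric matrix.
#' @param path file path.
#' @inheritParams write_stage_tsv
#' @return `read_distance_matrix` returns the labelled matrix.
#' @export
write_distance_matrix <- function(d, path, stage = "distances",
                                  params = list(), seed = NA) {
  validate_distance_matrix(d)
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_stage_tsv(df, path, stage, params, seed)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  validate_distance_matrix(m)
  m
}

#' Taxonomy TSV (NCBI-dump-like node table)
#'
#' Columns: `id`, `parent`, `rank`, `name`.
#'
#' @param tax a [taxonomy()].
#' @param path file path.
#' @inheritParams write_stage_tsv
#' @return `read_taxonomy` returns the [taxonomy()].
#' @export
write_taxonomy <- function(tax, path, stage = "taxonomy", params = list(),
                           seed = NA) {
  stopifnot(inherits(tax, "taxonomy"))
  write_stage_tsv(tax$nodes, path, stage, params, seed)
}

#' @rdname write_taxonomy
#' @export
read_taxonomy <- function(path) {
  taxonomy(read_stage_tsv(path))
}

#' Kraken-style classification report TSV
#'
#' Fixed column order: `pct` (clade reads as a percentage of total reads),
#' `clade_reads`, `direct_reads`, `unique_kmers` (distinct database k-mers
#' observed in the clade), `rank`, `node_id`, `name` (indented two spaces
#' per taxonomy depth). An unclassified row (node_id 0, rank `U`) leads.
#' Reading re-validates the clade sums against the indentation structure.
#'
#' @param report a `classification_report`.
#' @param path file path.
#' @inheritParams write_stage_tsv
#' @return `read_kraken_report` returns the report table with an
#'   `unclassified_reads` / `total_reads` attribute.
#' @export
write_kraken_report <- function(report, path, stage = "classify",
                                params = list(), seed = NA) {
  stopifnot(inherits(report, "classification_report"))
  tax <- report$taxonomy
  tab <- report$table
  depth <- vapply(tab$node_id, function(i) length(tax_ancestors(tax, i)) - 1L,
                  integer(1))
  ord <- order(match(tab$node_id, dfs_order(tax)))
  tab <- tab[ord, , drop = FALSE]
  depth <- depth[ord]
  total <- max(report$total_reads, 1L)
  out <- data.frame(
    pct = round(100 * c(report$unclassified_reads, tab$clade_reads) / total, 2),
    clade_reads = c(report$unclassified_reads, tab$clade_reads),
    direct_reads = c(report$unclassified_reads, tab$direct_reads),
    unique_kmers = c(0L, tab$clade_unique_kmers),
    rank = c("U", tab$rank),
    node_id = c(0L, tab$node_id),
    name = c("unclassified",
             paste0(strrep("  ", depth), tab$name)),
    stringsAsFactors = FALSE)
  write_stage_tsv(out, path, stage,
                  c(params, list(sample_id = report$sample_id,
                                 total_reads = report$total_reads,
                                 filtered_reads = report$filtered_reads)),
                  seed)
}

# depth-first node order (children after their parent, by id)
dfs_order <- function(tax) {
  out <- integer(0)
  visit <- function(id) {
    out <<- c(out, id)
    kids <- sort(tax$nodes$id[tax$nodes$parent == id & tax$nodes$id != id])
    for (k in kids) visit(k)
  }
  visit(tax$root)
  out
}

#' @rdname write_kraken_report
#' @export
read_kraken_report <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  uncl <- tab$clade_reads[tab$rank == "U"]
  body <- tab[tab$rank != "U", , drop = FALSE]
  depth <- nchar(sub("[^ ].*$", "", body$name)) %/% 2L
  # clade = direct + sum of child clades, reconstructed from indentation
  for (i in seq_len(nrow(body))) {
    kids <- integer(0)
    j <- i + 1L
    while (j <= nrow(body) && depth[j] > depth[i]) {
      if (depth[j] == depth[i] + 1L) kids <- c(kids, j)
      j <- j + 1L
    }
    expected <- body$direct_reads[i] + sum(body$clade_reads[kids])
    if (body$clade_reads[i] != expected)
      stop(sprintf("inconsistent clade sums at report line %d", i))
  }
  attr(body, "unclassified_reads") <- uncl
  body
}

#' Abundance matrix TSV (samples x species)
#'
#' @param m numeric matrix with sample rows and species columns.
#' @param path file path.
#' @inheritParams write_stage_tsv
#' @return `read_abundance_matrix` returns the matrix.
#' @export
write_abundance_matrix <- function(m, path, stage = "abundance",
                                   params = list(), seed = NA) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_stage_tsv(df, path, stage, params, seed)
}

#' @rdname write_abundance_matrix
#' @export
read_abundance_matrix <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Newick export of a dendrogram
#'
#' @param tree an [stats::hclust] object.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' LCA database serialization
#'
#' JSON container with the classifier parameters, the taxonomy node table,
#' the sorted k-mer hash list with aligned node assignments, per-node
#' distinct-k-mer counts and the species redistribution table.
#'
#' @param db an `lca_database`.
#' @param path file path.
#' @return `read_lca_database` returns the `lca_database`.
#' @export
write_lca_database <- function(db, path) {
  stopifnot(inherits(db, "lca_database"))
  red <- db$redistribution
  jsonlite::write_json(
    list(k = db$k, hash_seed = db$hash_seed, nodes = db$tax$nodes,
         # hashes as exact integer strings, probabilities at full precision
         kmer_hash = sprintf("%.0f", db$kmer_hash),
         kmer_node = db$kmer_node,
         node_kmer_counts = as.list(db$node_kmer_counts),
         redistribution = list(node_id = red$node_id,
                               species_id = red$species_id,
                               prob = sprintf("%.17g", red$prob))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lca_database
#' @export
read_lca_database <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  red <- data.frame(node_id = as.integer(x$redistribution$node_id),
                    species_id = as.integer(x$redistribution$species_id),
                    prob = as.numeric(x$redistribution$prob))
  structure(list(k = as.integer(x$k), hash_seed = as.integer(x$hash_seed),
                 tax = taxonomy(x$nodes),
                 kmer_hash = as.numeric(x$kmer_hash),
                 kmer_node = as.integer(x$kmer_node),
                 node_kmer_counts = stats::setNames(
                   as.integer(unlist(x$node_kmer_counts)),
                   names(x$node_kmer_counts)),
                 redistribution = red),
            class = "lca_database")
}
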