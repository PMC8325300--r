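test_that("taxonomy validation and LCA behave on small trees", {
  mt <- make_taxonomy(4, genera = 2)
  tax <- mt$tax
  sp <- sort(tax$nodes$id[tax$nodes$rank == "species"])
  # species 1 and 3 share genus 3 (round-robin assignment)
  expect_equal(tax_lca(tax, sp[c(1, 3)]),
               tax$nodes$parent[tax$nodes$id == sp[1]])
  # across genera the LCA climbs to the domain
  expect_equal(tax_lca(tax, sp[1:2]), 2L)
  expect_equal(tax_lca(tax, sp[1]), sp[1])
  bad <- data.frame(id = 1:2, parent = c(1, 3), rank = "x", name = "x")
  expect_error(taxonomy(bad), "parent")
})

test_that("database k-mer LCA assignments match a brute-force oracle", {
  # three species with engineered sharing: g3 borrows half of g1
  mt <- make_taxonomy(3, genera = 1)
  g1 <- make_genome(3000, seed = 201)
  g2 <- make_genome(3000, seed = 202)
  g3 <- paste0(substr(g1, 1, 1500), make_genome(1500 + 1000, seed = 203))
  genomes <- c(g001 = g1, g002 = g2, g003 = g3)
  db <- build_lca_database(genomes, mt$genome_species, mt$tax, k = 21,
                           fragment_step = 7)
  pol_like <- function(g) unique(canonical_kmer_hashes(g, kmer_policy(
    k = 21, sketch_size = 1, hash_seed = 1234)))
  invs <- lapply(genomes, pol_like)
  sp <- mt$genome_species[names(genomes)]
  set.seed(7)
  for (h in sample(db$kmer_hash, 500)) {
    present <- names(invs)[vapply(invs, function(x) h %in% x, logical(1))]
    expect_equal(db$kmer_node[db$kmer_hash == h],
                 oracle_lca(mt$tax$nodes, unname(sp[present])))
  }
  # every k-mer of the union is in the database exactly once
  expect_equal(sort(db$kmer_hash), sort(unique(unlist(invs))))
  expect_false(is.unsorted(db$kmer_hash, strictly = TRUE))
})

test_that("disjoint genomes give species-level maps and identity redistribution", {
  mt <- make_taxonomy(2, genera = 1)
  genomes <- c(g001 = make_genome(2000, seed = 211),
               g002 = make_genome(2000, seed = 212))
  db <- build_lca_database(genomes, mt$genome_species, mt$tax, k = 31,
                           fragment_step = 3)
  sp <- sort(unname(mt$genome_species))
  expect_setequal(unique(db$kmer_node), sp)
  red <- db$redistribution
  expect_equal(red$node_id, red$species_id)
  expect_equal(red$prob, c(1, 1))
})

test_that("identical genomes under two species map everything to their LCA", {
  mt <- make_taxonomy(2, genera = 1)
  g <- make_genome(2000, seed = 213)
  genomes <- c(g001 = g, g002 = g)
  db <- build_lca_database(genomes, mt$genome_species, mt$tax, k = 31,
                           fragment_step = 3)
  genus <- mt$tax$nodes$id[mt$tax$nodes$rank == "genus"]
  expect_equal(unique(db$kmer_node), genus)
  # every species' fragment mass lands wholly on the shared genus node
  expect_true(all(db$redistribution$node_id == genus))
  expect_equal(db$redistribution$prob, c(1, 1))
})

test_that("read classification resolves unique, shared and tied signals", {
  mt <- make_taxonomy(2, genera = 1)
  shared <- make_genome(1500, seed = 221)
  u1 <- make_genome(1500, seed = 222)
  u2 <- make_genome(1500, seed = 223)
  genomes <- c(g001 = paste0(shared, u1), g002 = paste0(shared, u2))
  db <- build_lca_database(genomes, mt$genome_species, mt$tax, k = 31,
                           fragment_step = 5)
  sp <- mt$genome_species
  genus <- mt$tax$nodes$id[mt$tax$nodes$rank == "genus"]
  # read from a species-unique region -> that species
  expect_equal(classify_read(substr(u1, 100, 220), db), unname(sp["g001"]))
  # read from the shared region -> every k-mer maps to the genus LCA
  expect_equal(classify_read(substr(shared, 100, 220), db), genus)
  # balanced tie: equal-length unique material from both species -> LCA
  tie_read <- paste0(substr(u1, 1, 45), substr(u2, 1, 45))
  expect_equal(classify_read(tie_read, db), genus)
  # no database hits -> unclassified; short read -> unclassified
  expect_true(is.na(classify_read(make_genome(1000, seed = 224), db)))
  expect_true(is.na(classify_read("ACGT", db)))
})

test_that("sample reports satisfy conservation and clade-sum invariants", {
  fx <- mixture_fixture()
  rep0 <- classify_sample(fx$reads$reads[1:5000], fx$db, "s")
  tab <- rep0$table
  expect_equal(rep0$unclassified_reads + sum(tab$direct_reads),
               rep0$total_reads)
  for (i in seq_len(nrow(tab))) {
    kids <- tab$node_id[fx$tax$nodes$parent == tab$node_id[i] &
                          fx$tax$nodes$id != tab$node_id[i]]
    expect_equal(tab$clade_reads[i],
                 tab$direct_reads[i] +
                   sum(tab$clade_reads[tab$node_id %in% kids]))
  }
  # observed distinct k-mers never exceed the database inventory per node
  expect_true(all(tab$unique_kmers <=
                    fx$db$node_kmer_counts[as.character(tab$node_id)]))
  # empty read set -> all-zero report
  rep_empty <- classify_sample(character(0), fx$db, "empty")
  expect_equal(rep_empty$total_reads, 0)
  expect_true(all(rep_empty$table$clade_reads == 0))
})

test_that("reads from one species stay inside its lineage", {
  fx <- mixture_fixture()
  rs <- make_reads(fx$genomes[1], 1, 150, 2000, error_rate = 0.005,
                   seed = 231)
  rep1 <- classify_sample(rs$reads, fx$db, "pure")
  lineage <- prevderep:::tax_ancestors(fx$tax, fx$genome_species[[1]])
  off <- setdiff(rep1$table$node_id[rep1$table$direct_reads > 0], lineage)
  expect_length(off, 0)
})

test_that("the false-positive filter has an exact depth-scaled boundary", {
  fx <- mixture_fixture()
  rep0 <- classify_sample(fx$reads$reads[1:20000], fx$db, "s")
  tab <- rep0$table
  sp_rows <- which(tab$rank == "species")
  u <- min(tab$clade_unique_kmers[sp_rows])
  weakest <- tab$node_id[sp_rows][tab$clade_unique_kmers[sp_rows] == u]
  # threshold exactly at the weakest species' count -> everything kept
  rate_keep <- u * 1e6 / rep0$total_reads
  kept <- fp_filter(rep0, kmer_rate = rate_keep)
  expect_length(attr(kept, "zeroed_species"), 0)
  # nudging the threshold above that count zeroes exactly those species
  dropped <- fp_filter(rep0, kmer_rate = rate_keep * (1 + 1e-9))
  expect_setequal(attr(dropped, "zeroed_species"), weakest)
  d_tab <- dropped$table
  expect_true(all(d_tab$direct_reads[match(weakest, d_tab$node_id)] == 0))
  # zeroed reads leave the classified total, unclassified is untouched
  expect_equal(dropped$filtered_reads,
               sum(tab$direct_reads[match(weakest, tab$node_id)]))
  expect_equal(dropped$unclassified_reads, rep0$unclassified_reads)
  expect_equal(sum(d_tab$direct_reads) + dropped$filtered_reads +
                 dropped$unclassified_reads, rep0$total_reads)
  # rate 0 leaves the report unchanged
  expect_equal(fp_filter(rep0, kmer_rate = 0)$table, rep0$table)
})

test_that("raising the k-mer rate never revives a species", {
  fx <- mixture_fixture()
  rep0 <- classify_sample(fx$reads$reads[1:10000], fx$db, "s")
  surv <- function(rate) {
    f <- fp_filter(rep0, kmer_rate = rate)
    setdiff(f$table$node_id[f$table$rank == "species"],
            attr(f, "zeroed_species"))
  }
  prev <- surv(0)
  for (rate in c(500, 2000, 2e4, 2e5, 2e6)) {
    cur <- surv(rate)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("redistribution applies Bayes weighting over surviving species", {
  mt <- make_taxonomy(2, genera = 1)
  tax <- mt$tax
  genus <- tax$nodes$id[tax$nodes$rank == "genus"]
  sp <- sort(tax$nodes$id[tax$nodes$rank == "species"])
  fake_db <- structure(list(tax = tax, redistribution = data.frame(
    node_id = c(sp, genus, genus), species_id = c(sp, sp),
    prob = c(0.8, 0.8, 0.2, 0.2))), class = "lca_database")
  # equal priors -> 50/50 split of the genus reads
  rep_eq <- manual_report(tax, stats::setNames(c(100, 20, 20),
                                               c(genus, sp[1], sp[2])))
  out <- redistribute_to_species(rep_eq, fake_db)
  expect_equal(out$abundance$reads[order(out$abundance$species_id)],
               c(70, 70))
  # priors 30/10 with equal probabilities -> 75/25 split
  rep_sk <- manual_report(tax, stats::setNames(c(100, 30, 10),
                                               c(genus, sp[1], sp[2])))
  out2 <- redistribute_to_species(rep_sk, fake_db)
  expect_equal(out2$abundance$reads[order(out2$abundance$species_id)],
               c(30 + 75, 10 + 25))
  expect_equal(out2$unassigned_reads, 0)
  # all reads already at species rank -> identity
  rep_id <- manual_report(tax, stats::setNames(c(30, 10), sp))
  out3 <- redistribute_to_species(rep_id, fake_db)
  expect_equal(out3$abundance$reads[order(out3$abundance$species_id)],
               c(30, 10))
  # no surviving species under a node -> reads stay unassigned
  rep_none <- manual_report(tax, stats::setNames(100, genus))
  attr(rep_none, "zeroed_species") <- sp
  out4 <- redistribute_to_species(rep_none, fake_db)
  expect_equal(out4$unassigned_reads, 100)
  expect_length(out4$abundance$reads, 0)
})

test_that("reads from a genome absent from the database leave no species call", {
  fx <- mixture_fixture()
  alien <- make_genome(25000, seed = 241)
  rs <- make_reads(c(alien = alien), 1, 150, 5000, error_rate = 0.005,
                   seed = 242)
  rep0 <- classify_sample(rs$reads, fx$db, "alien")
  filt <- fp_filter(rep0, kmer_rate = 2000)
  sp_direct <- filt$table$direct_reads[filt$table$rank == "species"]
  expect_true(all(sp_direct == 0))
})
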