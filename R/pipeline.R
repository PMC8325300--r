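#' Pipeline configuration
#'
#' Collects every stage parameter with the method's standard defaults: the
#' 0.95 qualification identity, the 0.05 sample-dedup diameter, the
#' 0.025/0.08 and 0.05/0.1 ANI/sketch-distance clustering pairs, the
#' 2000-unique-k-mers-per-million false-positive rate, the CLR pseudocount
#' of 10 and the 0.70 core-prevalence cut. Overrides are echoed into the
#' run manifest.
#'
#' @param ... named overrides of the defaults listed above.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    sketch_k = 21L, genome_sketch_size = 1000L,
    metagenome_sketch_size = 10000L, hash_seed = 1234L,
    dedup_threshold = 0.05, min_reads = NULL,
    qualify_identity = 0.95,
    D_high = 0.025, D_mash_high = 0.08,
    D_species = 0.05, D_mash_species = 0.1,
    ani_fragment_length = 3000L, ani_k = 15L, ani_min_identity = 0.8,
    classifier_k = 31L, fragment_length = 100L, fragment_step = 1L,
    kmer_rate = 2000, pseudocount = 10, prevalence_cut = 0.70,
    stats_cohort = NULL, rarefaction_permutations = 50L,
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg$overrides <- names(dots)
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes sample deduplication, genome sketching and containment
#' screening, prevalence ranking, assembly quality filtering, two-level
#' greedy dereplication, classifier database construction from the
#' high-resolution representatives, per-sample classification, unique-
#' k-mer false-positive filtering, species read redistribution, and the
#' community statistics, writing every intermediate artifact plus a run
#' manifest into `out_dir`. The run is a pure function of (inputs, config,
#' seed): re-running with identical inputs yields byte-identical outputs.
#'
#' With `resume = TRUE`, stages whose artifacts are already present in
#' `out_dir` are loaded from disk (in order, up to the first stage with a
#' missing artifact) and only the remaining stages are recomputed; the
#' manifest marks each stage as computed or reused.
#'
#' @param genomes named character vector of genome sequences.
#' @param genome_meta data.frame with `genome_id`, `completeness`,
#'   `contamination` (and optionally `source`, taxonomy labels).
#' @param samples named list of read vectors, one element per metagenome
#'   sample.
#' @param sample_meta data.frame with `sample_id`, `project_id` and
#'   optionally `cohort`, `reads_count`.
#' @param tax a [taxonomy()].
#' @param genome_species named integer vector, genome id -> species node.
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param resume reuse existing artifacts (see above).
#' @return Invisibly, a list with the principal results: `retained`,
#'   `ranking`, `clusters`, `db` path, `abundance` matrix, `stats`, and
#'   the `manifest`.
#' @export
run_pipeline <- function(genomes, genome_meta, samples, sample_meta, tax,
                         genome_species, config = pipeline_config(),
                         out_dir, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"), inherits(tax, "taxonomy"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, sprintf(...))
  seed <- config$seed
  sid <- names(samples)
  stopifnot(!is.null(sid), !is.null(names(genomes)))

  # Stages are reusable only as an unbroken prefix: the first stage whose
  # artifacts are missing breaks the chain and everything downstream is
  # recomputed.
  chain <- isTRUE(resume)
  reuse <- function(files) {
    ok <- chain && all(file.exists(files))
    chain <<- ok
    ok
  }
  manifest_stages <- list()
  note <- function(stage, reused, n_in, n_out) {
    manifest_stages[[stage]] <<- list(stage = stage, reused = reused,
                                      n_in = n_in, n_out = n_out)
  }

  mpol <- kmer_policy(config$sketch_k, config$metagenome_sketch_size,
                      drop_singletons = TRUE, hash_seed = config$hash_seed)
  gpol <- kmer_policy(config$sketch_k, config$genome_sketch_size,
                      drop_singletons = FALSE, hash_seed = config$hash_seed)

  # -- stage 1: sample dedup ------------------------------------------------
  if (reuse(c(p("sample_distances.tsv"), p("retained_samples.tsv")))) {
    d_samples <- read_distance_matrix(p("sample_distances.tsv"))
    dedup <- read_stage_tsv(p("retained_samples.tsv"))
    note("dedup", TRUE, length(samples), sum(dedup$is_medoid))
  } else {
    sample_sketches <- lapply(sid, function(s)
      make_sketch(samples[[s]], mpol, source_id = s))
    names(sample_sketches) <- sid
    # rounded so values survive the TSV round-trip bit-exactly on resume
    d_samples <- round(pairwise_distances(sample_sketches), 12)
    write_distance_matrix(d_samples, p("sample_distances.tsv"), "dedup",
                          config[c("sketch_k", "metagenome_sketch_size")],
                          seed)
    dedup <- dedup_samples(sample_sketches, sample_meta,
                           threshold = config$dedup_threshold,
                           min_reads = config$min_reads)
    dedup$is_medoid <- as.logical(dedup$is_medoid)
    write_stage_tsv(dedup, p("retained_samples.tsv"), "dedup",
                    config["dedup_threshold"], seed)
    note("dedup", FALSE, length(samples), sum(dedup$is_medoid))
  }
  retained <- dedup$sample_id[dedup$is_medoid]

  # -- stage 2: genome sketching + containment screening --------------------
  if (reuse(p("screen_identities.tsv"))) {
    identity_matrix <- read_abundance_matrix(p("screen_identities.tsv"))
    note("screen", TRUE, length(genomes), length(identity_matrix))
  } else {
    genome_sketches <- lapply(names(genomes), function(g)
      make_sketch(genomes[[g]], gpol, source_id = g))
    names(genome_sketches) <- names(genomes)
    inventories <- lapply(retained, function(s)
      kmer_inventory(samples[[s]], mpol, source_id = s,
                     drop_singletons = FALSE))
    identity_matrix <- round(screen_panel(genome_sketches, inventories), 12)
    write_abundance_matrix(identity_matrix, p("screen_identities.tsv"),
                           "screen", config["genome_sketch_size"], seed)
    note("screen", FALSE, length(genomes), length(identity_matrix))
  }

  # -- stage 3: prevalence ranking ------------------------------------------
  if (reuse(p("ranking.tsv"))) {
    ranking <- read_stage_tsv(p("ranking.tsv"))
    note("rank", TRUE, nrow(identity_matrix), sum(ranking$qualified))
  } else {
    ranking <- prevalence_table(identity_matrix,
                                threshold = config$qualify_identity)
    write_stage_tsv(ranking, p("ranking.tsv"), "rank",
                    config["qualify_identity"], seed)
    note("rank", FALSE, nrow(identity_matrix), sum(ranking$qualified))
  }

  # -- stage 4: assembly quality filter -------------------------------------
  if (reuse(p("quality.tsv"))) {
    quality <- read_stage_tsv(p("quality.tsv"))
    note("quality", TRUE, nrow(quality), sum(quality$pass))
  } else {
    quality <- quality_filter(genome_meta)
    write_stage_tsv(quality, p("quality.tsv"), "quality", list(), seed)
    note("quality", FALSE, nrow(quality), sum(quality$pass))
  }

  # -- stage 5: two-level dereplication -------------------------------------
  keep_ids <- ranking$genome_id[ranking$qualified &
                                  ranking$genome_id %in%
                                    quality$genome_id[quality$pass]]
  if (reuse(c(p("clusters_high.tsv"), p("clusters_species.tsv")))) {
    clusters <- list(level_high = read_stage_tsv(p("clusters_high.tsv")),
                     level_species = read_stage_tsv(p("clusters_species.tsv")))
    note("cluster", TRUE, length(keep_ids),
         length(unique(clusters$level_high$cluster_id)))
  } else {
    clusters <- two_level_dereplicate(
      keep_ids, genomes,
      D_high = config$D_high, D_mash_high = config$D_mash_high,
      D_species = config$D_species, D_mash_species = config$D_mash_species,
      sketch_policy = gpol,
      fragment_length = config$ani_fragment_length, ani_k = config$ani_k,
      min_identity = config$ani_min_identity, hash_seed = config$hash_seed)
    write_stage_tsv(clusters$level_high, p("clusters_high.tsv"), "cluster",
                    config[c("D_high", "D_mash_high")], seed)
    write_stage_tsv(clusters$level_species, p("clusters_species.tsv"),
                    "cluster", config[c("D_species", "D_mash_species")], seed)
    note("cluster", FALSE, length(keep_ids),
         length(unique(clusters$level_high$cluster_id)))
  }
  representatives <- unique(clusters$level_high$centroid_id)

  # -- stage 6: classifier database -----------------------------------------
  if (reuse(p("database.json"))) {
    db <- read_lca_database(p("database.json"))
    note("build_db", TRUE, length(representatives), length(db$kmer_hash))
  } else {
    db <- build_lca_database(genomes[representatives],
                             genome_species, tax,
                             k = config$classifier_k,
                             fragment_length = config$fragment_length,
                             fragment_step = config$fragment_step,
                             hash_seed = config$hash_seed)
    write_lca_database(db, p("database.json"))
    note("build_db", FALSE, length(representatives), length(db$kmer_hash))
  }

  # -- stages 7-9: classify, filter, redistribute ---------------------------
  species_ids <- db$tax$nodes$id[db$tax$nodes$rank == "species"]
  species_names <- db$tax$nodes$name[match(species_ids, db$tax$nodes$id)]
  if (reuse(c(p(paste0("report_", retained, ".tsv")),
              p(paste0("filtered_", retained, ".tsv")),
              p("abundance.tsv")))) {
    abundance <- read_abundance_matrix(p("abundance.tsv"))
    note("classify", TRUE, length(retained), NA)
    note("fp_filter", TRUE, length(retained), NA)
    note("abundance", TRUE, length(retained), ncol(abundance))
  } else {
    abundance <- matrix(0, length(retained), length(species_ids),
                        dimnames = list(retained, species_names))
    for (s in retained) {
      rep0 <- classify_sample(samples[[s]], db, sample_id = s)
      write_kraken_report(rep0, p("report_%s.tsv", s), "classify",
                          config["classifier_k"], seed)
      repf <- fp_filter(rep0, kmer_rate = config$kmer_rate)
      write_kraken_report(repf, p("filtered_%s.tsv", s), "fp_filter",
                          config["kmer_rate"], seed)
      red <- redistribute_to_species(repf, db)
      abundance[s, match(red$abundance$species_id, species_ids)] <-
        red$abundance$reads
    }
    abundance <- round(abundance, 12)
    write_abundance_matrix(abundance, p("abundance.tsv"), "abundance",
                           config["kmer_rate"], seed)
    note("classify", FALSE, length(retained), NA)
    note("fp_filter", FALSE, length(retained), NA)
    note("abundance", FALSE, length(retained), ncol(abundance))
  }

  # -- stage 10: community statistics ---------------------------------------
  cohorts <- if ("cohort" %in% names(sample_meta))
    stats::setNames(sample_meta$cohort, sample_meta$sample_id)[retained]
  else stats::setNames(rep("all", length(retained)), retained)
  ann <- data.frame(sample_id = retained, cohort = unname(cohorts),
                    stringsAsFactors = FALSE)
  cohort <- if (is.null(config$stats_cohort)) sort(unique(ann$cohort))[1]
  else config$stats_cohort
  core <- core_species(abundance, ann, cohort,
                       prevalence_cut = config$prevalence_cut)
  write_stage_tsv(core, p("core_species.tsv"), "stats",
                  config["prevalence_cut"], seed)
  clr <- clr_transform(abundance, pseudocount = config$pseudocount)
  pca <- NULL
  if (nrow(clr) >= 2L && ncol(clr) >= 2L) {
    pca <- clr_pca(clr)
    write_stage_tsv(data.frame(sample_id = rownames(pca$scores), pca$scores,
                               check.names = FALSE, stringsAsFactors = FALSE),
                    p("pca_scores.tsv"), "stats", config["pseudocount"], seed)
  } else {
    # ordination is undefined below 2 samples/species; write an empty
    # scores table so the artifact set stays complete
    write_stage_tsv(data.frame(sample_id = character(0)),
                    p("pca_scores.tsv"), "stats", config["pseudocount"], seed)
  }
  projects <- stats::setNames(sample_meta$project_id, sample_meta$sample_id)
  tree <- NULL
  if (length(unique(projects[retained])) >= 2L && length(retained) >= 2L) {
    tree <- project_linkage(d_samples[retained, retained, drop = FALSE],
                            projects)
    write_newick(tree$tree, p("project_tree.nwk"))
  }
  qual_matrix <- identity_matrix >= config$qualify_identity
  rare <- rarefaction_curve(qual_matrix,
                            permutations = config$rarefaction_permutations,
                            seed = seed)
  write_stage_tsv(rare$curve, p("rarefaction.tsv"), "stats",
                  config["rarefaction_permutations"], seed)
  note("stats", FALSE, length(retained), nrow(core))

  manifest <- list(
    package = "prevderep",
    version = as.character(utils::packageVersion("prevderep")),
    seed = seed,
    parameters = unclass(config)[setdiff(names(unclass(config)), "overrides")],
    overridden = config$overrides,
    input_fingerprints = list(
      genomes = cpp_hash_string(paste(names(genomes), genomes,
                                      collapse = "|"), 0),
      samples = cpp_hash_string(paste(sid, vapply(samples, paste,
                                                  character(1),
                                                  collapse = ","),
                                      collapse = "|"), 0)),
    stages = unname(manifest_stages))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(list(retained = retained, ranking = ranking, clusters = clusters,
                 db = db, abundance = abundance,
                 stats = list(core = core, pca = pca, project_tree = tree,
                              rarefaction = rare),
                 manifest = manifest))
}
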