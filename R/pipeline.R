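#' Pipeline configuration
#'
#' Exactly one of `sim` (a [sim_config()], to generate inputs) or `paths`
#' (named list with any of `traits`, `taxonomy`, `pedigree`; files as
#' described in the reader documentation) must be supplied. Stages whose
#' inputs are unavailable are skipped and named in the run manifest.
#'
#' @param sim a `sim_config`, or `NULL` to load from files.
#' @param paths named list of input file paths, or `NULL` to simulate.
#' @param out_dir output directory (created if needed).
#' @param linkage,k_top,k_sub,features clustering options; see
#'   [hierarchical_cluster()] and [cut_two_level()].
#' @param uniformity_threshold,distinctness_threshold CV thresholds.
#' @param alpha significance level for letters and trends.
#' @param freq_thresholds hybridization-frequency class bounds.
#' @param seed integer; overrides `sim$seed` when simulating.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, paths = NULL,
                            out_dir = tempfile("pollenphen_run_"),
                            linkage = "ward", k_top = 4L, k_sub = 3L,
                            features = cluster_features(),
                            uniformity_threshold = 0.15,
                            distinctness_threshold = 0.15,
                            alpha = 0.05,
                            freq_thresholds = c(high = 0.20, medium = 0.05),
                            seed = 1L) {
  if (is.null(sim) == is.null(paths)) {
    stop("supply exactly one of `sim` or `paths`")
  }
  stopifnot(uniformity_threshold > 0, uniformity_threshold < 1,
            distinctness_threshold > 0, distinctness_threshold < 1,
            alpha > 0, alpha < 1)
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "sim_config"))
    sim$seed <- as.integer(seed)
  }
  structure(list(sim = sim, paths = paths, out_dir = out_dir,
                 linkage = linkage, k_top = as.integer(k_top),
                 k_sub = as.integer(k_sub), features = features,
                 uniformity_threshold = uniformity_threshold,
                 distinctness_threshold = distinctness_threshold,
                 alpha = alpha, freq_thresholds = freq_thresholds,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Generates or loads inputs, then runs every stage whose inputs are
#' available: uniformity/distinctness statistics, derived ratios and
#' size/shape classes, hierarchical clustering with the two-level cut and
#' group summaries, pedigree scores (family aggregation at both levels,
#' perforation-density progression in both modes, hybridization
#' frequency), and ordinal trend correlations. All stage outputs are
#' written as CSV (plus a Newick dendrogram) under `config$out_dir`
#' together with a JSON manifest recording package version, seed,
#' options, input hashes, and skipped stages. Stages are pure functions
#' of inputs and options, so a rerun with the same config is
#' bit-identical for every deterministic stage.
#'
#' @param config a `pipeline_config`.
#' @return List with the in-memory stage results and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  skipped <- list()
  input_hashes <- list()

  # ---- inputs ----
  if (!is.null(config$sim)) {
    ds <- generate_dataset(config$sim)
    table <- ds$table; taxonomy <- ds$taxonomy; ped <- ds$pedigree
    write_trait_table(table, file.path(config$out_dir, "trait_table.csv"))
    write_taxonomy(taxonomy, file.path(config$out_dir, "taxonomy.csv"))
    write_pedigree(ped, file.path(config$out_dir, "pedigree.csv"))
  } else {
    p <- config$paths
    table <- taxonomy <- ped <- NULL
    if (!is.null(p$traits)) {
      table <- read_trait_table(p$traits)
      input_hashes$traits <- unname(tools::md5sum(p$traits))
    }
    if (!is.null(p$taxonomy)) {
      taxonomy <- read_taxonomy(p$taxonomy)
      input_hashes$taxonomy <- unname(tools::md5sum(p$taxonomy))
    }
    if (!is.null(p$pedigree)) {
      ped <- read_pedigree(p$pedigree)
      input_hashes$pedigree <- unname(tools::md5sum(p$pedigree))
    }
  }

  results <- list()
  fail <- function(stage, e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  # ---- trait statistics ----
  if (!is.null(table)) {
    results$stats <- tryCatch(
      uniformity_distinctness_summary(table,
                                      threshold = config$uniformity_threshold),
      error = function(e) fail("stats", e))
    utils::write.csv(results$stats,
                     file.path(config$out_dir, "trait_stats.csv"),
                     row.names = FALSE)
    results$derived <- tryCatch(compute_derived_ratios(table),
                                error = function(e) fail("derived", e))
    means <- merge(taxon_means(table), results$derived,
                   by = "taxon_id", all = TRUE)
    means$size_class <- ifelse(is.na(means$P), NA, classify_size(means$P))
    means$shape_class <- ifelse(is.na(means$P_E), NA,
                                classify_shape(means$P_E))
    results$means <- means
    utils::write.csv(means, file.path(config$out_dir, "taxon_means.csv"),
                     row.names = FALSE)
  } else {
    skipped$stats <- "no trait table"
  }

  # ---- clustering ----
  if (!is.null(table)) {
    results$cluster <- tryCatch({
      fm <- build_feature_matrix(table, results$derived,
                                 features = config$features)
      hc <- hierarchical_cluster(fm, linkage = config$linkage)
      cut_two_level(hc, k_top = config$k_top, k_sub = config$k_sub)
    }, error = function(e) fail("cluster", e))
    utils::write.csv(results$cluster$assignments,
                     file.path(config$out_dir, "partition.csv"),
                     row.names = FALSE)
    export_newick(results$cluster,
                  file.path(config$out_dir, "dendrogram.nwk"))
    results$group_summaries <- tryCatch(
      group_summaries(table, results$derived, results$cluster,
                      alpha = config$alpha),
      error = function(e) fail("group_summaries", e))
    utils::write.csv(results$group_summaries,
                     file.path(config$out_dir, "group_summaries.csv"),
                     row.names = FALSE)
  } else {
    skipped$cluster <- "no trait table"
  }

  # ---- pedigree scores ----
  if (!is.null(ped) && nrow(ped) > 0) {
    if (!is.null(results$cluster)) {
      results$family_aggregation <- tryCatch(list(
        four_group = family_aggregation(results$cluster, ped, "four_group"),
        six_group = family_aggregation(results$cluster, ped, "six_group")
      ), error = function(e) fail("family_aggregation", e))
    } else {
      skipped$family_aggregation <- "no clustering"
    }
    if (!is.null(table)) {
      pd <- taxon_means(table)
      pd_means <- stats::setNames(pd$PD, pd$taxon_id)
      results$pd_progression <- tryCatch(list(
        exclude_unknown = pd_progression(pd_means, ped, "exclude_unknown",
                                         result = results$cluster),
        assume_lower = pd_progression(pd_means, ped, "assume_lower",
                                      result = results$cluster)
      ), error = function(e) fail("pd_progression", e))
    } else {
      skipped$pd_progression <- "no trait table"
    }
    results$hybridization <- tryCatch(
      hybridization_frequency(ped, thresholds = config$freq_thresholds),
      error = function(e) fail("hybridization", e))
    ped_rows <- data.frame(
      statistic = c("family_aggregation_four_group",
                    "family_aggregation_six_group",
                    "pd_progression_exclude_unknown",
                    "pd_progression_assume_lower"),
      percentage = c(
        if (!is.null(results$family_aggregation))
          c(results$family_aggregation$four_group$percentage,
            results$family_aggregation$six_group$percentage)
        else c(NA, NA),
        if (!is.null(results$pd_progression))
          c(results$pd_progression$exclude_unknown$percentage,
            results$pd_progression$assume_lower$percentage)
        else c(NA, NA)))
    utils::write.csv(ped_rows,
                     file.path(config$out_dir, "pedigree_scores.csv"),
                     row.names = FALSE)
    hy <- results$hybridization
    utils::write.csv(data.frame(species = names(hy$frequency),
                                frequency = hy$frequency,
                                class = hy$classification,
                                row.names = NULL),
                     file.path(config$out_dir, "hybridization.csv"),
                     row.names = FALSE)
  } else {
    skipped$pedigree_scores <- "no pedigree"
  }

  # ---- section aggregation & trends ----
  if (!is.null(taxonomy) && !is.null(results$cluster) &&
      any(taxonomy$rank == "species" & !is.na(taxonomy$section))) {
    results$section_aggregation <- tryCatch(
      section_aggregation(results$cluster, taxonomy),
      error = function(e) fail("section_aggregation", e))
  } else {
    skipped$section_aggregation <- "no sectioned species or no clustering"
  }
  if (!is.null(taxonomy) && !is.null(table)) {
    results$trends <- tryCatch(
      trend_summary(results$means, taxonomy, alpha = config$alpha),
      error = function(e) fail("trends", e))
    utils::write.csv(results$trends,
                     file.path(config$out_dir, "trends.csv"),
                     row.names = FALSE)
  } else {
    skipped$trends <- "no taxonomy or no trait table"
  }

  manifest <- list(
    package = "pollenphen",
    version = as.character(utils::packageVersion("pollenphen")),
    seed = config$seed,
    options = list(linkage = config$linkage, k_top = config$k_top,
                   k_sub = config$k_sub, features = config$features,
                   uniformity_threshold = config$uniformity_threshold,
                   distinctness_threshold = config$distinctness_threshold,
                   alpha = config$alpha),
    simulated = !is.null(config$sim),
    input_hashes = input_hashes,
    skipped_stages = skipped
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
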