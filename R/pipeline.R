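#' Pipeline configuration
#'
#' Bundles the inputs and tuning parameters of a full analysis run. Either
#' `simulation` (a [sim_config()]) or the three input paths must be given.
#' A single global `seed` derives the per-stage seeds by fixed offsets, so
#' one integer reproduces a run byte-for-byte.
#'
#' @param simulation Optional [sim_config()]; when set, inputs are simulated.
#' @param table,metadata,taxonomy Input TSV paths (ignored when simulating).
#' @param blocklist Genus blocklist (character vector or path to a text
#'   file, one genus per line).
#' @param groups Overlap group map or `NULL` for [default_overlap_groups()].
#' @param threshold Prevalence-test threshold.
#' @param rarefy_depth `"min"` (minimum library size) or an integer depth.
#' @param n_permutations Permutation count for PERMANOVA/envfit.
#' @param da_pairs List of 2-vectors of sample types to compare for
#'   differential abundance.
#' @param seed Global seed.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return A `tephra_pipeline_config` list.
#' @export
pipeline_config <- function(simulation = NULL,
                            table = NULL, metadata = NULL, taxonomy = NULL,
                            blocklist = default_blocklist(),
                            groups = NULL,
                            threshold = 0.5,
                            rarefy_depth = "min",
                            n_permutations = 999,
                            da_pairs = list(c("drill_core", "seawater"),
                                            c("drill_core", "borehole_fluid")),
                            seed = 1,
                            out_dir = NULL) {
  if (is.null(simulation) && (is.null(table) || is.null(metadata))) {
    abort("either a simulation config or table + metadata paths are required")
  }
  structure(
    list(simulation = simulation, table = table, metadata = metadata,
         taxonomy = taxonomy, blocklist = blocklist, groups = groups,
         threshold = threshold, rarefy_depth = rarefy_depth,
         n_permutations = n_permutations, da_pairs = da_pairs,
         seed = as.integer(seed), out_dir = out_dir),
    class = "tephra_pipeline_config"
  )
}

# fixed per-stage seed offsets: one global integer reproduces the whole run
.stage_seeds <- function(seed) {
  list(simulate = seed, rarefy = seed + 101L, nmds = seed + 211L,
       permanova = seed + 307L, envfit = seed + 401L)
}

#' Run the full analysis pipeline
#'
#' Stages, in fixed order: load or simulate the dataset; three-stage
#' decontamination and dataset cleaning; rarefaction; alpha diversity with
#' ANOVA and Tukey HSD across sample types; Bray-Curtis, NMDS and PERMANOVA
#' with pairwise comparisons; environmental vector fitting (depth and
#' temperature on the drill-core ordination); two-by-two differential
#' abundance. A manifest records per-stage seeds, content hashes, feature
#' and sample counts before and after each filter, and per-rule contaminant
#' tallies. Output tables are written under `out_dir` when configured.
#'
#' @param config A [pipeline_config()].
#' @return List: `results` (per-stage objects) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "tephra_pipeline_config"))
  seeds <- .stage_seeds(config$seed)
  t0 <- Sys.time()
  log_stage <- function(stage, ...) {
    inform(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                   paste(..., collapse = " ")))
  }

  # --- input stage -----------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- simulate_dataset(config$simulation, seed = seeds$simulate)
    dataset <- sim$dataset
    truth <- sim$truth
    log_stage("simulate", nrow(dataset$counts), "features,",
              ncol(dataset$counts), "samples")
  } else {
    for (p in c(config$table, config$metadata, config$taxonomy)) {
      if (!is.null(p) && !file.exists(p)) abort(paste0("input file not found: ", p))
    }
    dataset <- harmonize(
      read_feature_table(config$table),
      read_metadata(config$metadata),
      if (!is.null(config$taxonomy)) read_taxonomy(config$taxonomy) else NULL
    )
    log_stage("load", nrow(dataset$counts), "features,", ncol(dataset$counts), "samples")
  }
  blocklist <- config$blocklist
  if (is.character(blocklist) && length(blocklist) == 1 && file.exists(blocklist)) {
    blocklist <- read_blocklist(blocklist)
  }

  # --- decontamination -------------------------------------------------
  decon <- decontaminate(dataset, groups = config$groups,
                         blocklist = blocklist, threshold = config$threshold)
  cleaned <- decon$cleaned
  log_stage("decontaminate", nrow(cleaned$counts), "features retained of",
            nrow(dataset$counts))

  # --- rarefaction + alpha diversity -----------------------------------
  depth <- if (identical(config$rarefy_depth, "min")) {
    min(colSums(cleaned$counts))
  } else {
    as.integer(config$rarefy_depth)
  }
  rare <- rarefy_even_depth(cleaned$counts, depth = depth, seed = seeds$rarefy)
  alpha <- alpha_diversity(rare)
  alpha_md <- dplyr::left_join(alpha, cleaned$metadata, by = "sample_id")
  alpha_tests <- list(
    richness_anova = anova_oneway(alpha_md$richness, alpha_md$sample_type),
    richness_tukey = tukey_hsd(alpha_md$richness, alpha_md$sample_type),
    shannon_anova = anova_oneway(alpha_md$shannon, alpha_md$sample_type),
    shannon_tukey = tukey_hsd(alpha_md$shannon, alpha_md$sample_type)
  )
  log_stage("alpha", "depth", depth, ",", ncol(rare), "samples")

  # --- beta diversity --------------------------------------------------
  d <- bray_curtis(rare)
  ord <- nmds(d, seed = seeds$nmds)
  grp <- cleaned$metadata$sample_type[match(labels(d), cleaned$metadata$sample_id)]
  perma <- permanova(d, grp, n_permutations = config$n_permutations,
                     seed = seeds$permanova)
  pairwise <- pairwise_permanova(d, grp, n_permutations = config$n_permutations,
                                 seed = seeds$permanova)
  log_stage("beta", "stress", signif(ord$stress, 3), ", PERMANOVA p", perma$p)

  # --- envfit on drill cores -------------------------------------------
  core_ids <- cleaned$metadata$sample_id[cleaned$metadata$sample_type == "drill_core"]
  env <- NULL
  if (length(core_ids) >= 4) {
    core_rare <- rare[, intersect(colnames(rare), core_ids), drop = FALSE]
    core_rare <- core_rare[rowSums(core_rare) > 0, , drop = FALSE]
    core_ord <- nmds(bray_curtis(core_rare), seed = seeds$nmds)
    env <- envfit_vectors(
      core_ord,
      cleaned$metadata[, c("sample_id", "depth_m", "temperature_C")],
      n_permutations = config$n_permutations, seed = seeds$envfit
    )
    log_stage("envfit", paste(env$variable, "r2", signif(env$r_squared, 2),
                              collapse = "; "))
  }

  # --- differential abundance ------------------------------------------
  da <- purrr::map(config$da_pairs, function(pr) {
    types <- cleaned$metadata$sample_type
    if (sum(types == pr[1]) < 2 || sum(types == pr[2]) < 2) return(NULL)
    nb_wald_two_group(cleaned$counts, cleaned$metadata, pr[1], pr[2])
  })
  names(da) <- vapply(config$da_pairs, paste, character(1), collapse = "_vs_")
  da <- da[!vapply(da, is.null, logical(1))]
  log_stage("diffabund", length(da), "comparison(s)")

  results <- list(
    dataset = dataset, truth = truth, decontamination = decon,
    rarefied = rare, alpha = alpha, alpha_tests = alpha_tests,
    distance = d, ordination = ord, permanova = perma,
    pairwise_permanova = pairwise, envfit = env, differential_abundance = da
  )

  tallies <- decon$summary
  manifest <- list(
    seed = config$seed,
    stage_seeds = .stage_seeds(config$seed),
    n_features_input = nrow(dataset$counts),
    n_samples_input = ncol(dataset$counts),
    n_features_cleaned = nrow(cleaned$counts),
    n_samples_cleaned = ncol(cleaned$counts),
    n_samples_rarefied = ncol(rare),
    rarefaction_depth = depth,
    contaminant_tallies = as.list(setNames(tallies$n_features,
                                           paste(tallies$stage, tallies$rule, sep = ":"))),
    hashes = list(
      input_counts = rlang::hash(dataset$counts),
      cleaned_counts = rlang::hash(cleaned$counts),
      rarefied_counts = rlang::hash(rare),
      ordination = rlang::hash(ord$points)
    ),
    stress = ord$stress,
    permanova_p = perma$p,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  if (!is.null(config$out_dir)) {
    .write_pipeline_outputs(config$out_dir, results, manifest, decon)
  }
  list(results = results, manifest = manifest)
}

.write_pipeline_outputs <- function(dir, results, manifest, decon) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_feature_table(results$decontamination$cleaned$counts,
                      file.path(dir, "cleaned_table.tsv"))
  readr::write_tsv(decon$calls, file.path(dir, "calls.tsv"), progress = FALSE)
  readr::write_tsv(decon$census, file.path(dir, "census.tsv"), progress = FALSE)
  readr::write_tsv(results$alpha, file.path(dir, "alpha.tsv"), progress = FALSE)
  ord_out <- tidy(results$ordination)
  readr::write_tsv(ord_out, file.path(dir, "ordination.tsv"), progress = FALSE)
  tests <- list(
    permanova = as.list(results$permanova),
    pairwise_permanova = results$pairwise_permanova,
    alpha = purrr::map(results$alpha_tests, as.list),
    envfit = if (!is.null(results$envfit)) as.list(results$envfit) else NULL
  )
  jsonlite::write_json(tests, file.path(dir, "tests.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(results$differential_abundance)) {
    readr::write_tsv(results$differential_abundance[[nm]],
                     file.path(dir, paste0("da_", nm, ".tsv")), progress = FALSE)
  }
  # manifest last, so its presence marks a completed run
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
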