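#' Gaussian thermal niche weight
#'
#' Relative suitability of a habitat at temperature `temperature_C` for a
#' taxon with thermal optimum `optimum_C` and niche width `width_C`:
#' `exp(-(T - T_opt)^2 / (2 * width^2))`. Equals 1 at the optimum and decays
#' symmetrically; used by the simulator to structure endemic communities
#' along the borehole temperature gradient.
#'
#' @param temperature_C Habitat temperature (degrees C), finite.
#' @param optimum_C Per-taxon optimum temperature (degrees C).
#' @param width_C Niche width (degrees C), > 0.
#' @return Weight in (0, 1].
#' @export
niche_weight <- function(temperature_C, optimum_C, width_C) {
  if (any(!is.finite(temperature_C))) abort("temperature must be finite")
  if (any(!is.finite(optimum_C))) abort("optimum temperature must be finite")
  if (any(!is.finite(width_C)) || any(width_C <= 0)) abort("niche width must be > 0")
  exp(-((temperature_C - optimum_C)^2) / (2 * width_C^2))
}

#' Default drill-core sampling design
#'
#' Seventeen drill-core samples at successive depths through subaerial and
#' submarine tuff deposits, grouped in four depth categories, with the
#' in-situ temperature profile of a young hydrothermal system (maximum
#' near 124 degrees C around 100 m, cooling below the seawater-inflow
#' zone). Cores at or above 58 m (the zone of tidal flux) belong to the
#' subaerial deposit.
#'
#' @return Tibble with `sample_id`, `core_category`, `depth_m`,
#'   `temperature_C`, `deposit`.
#' @export
default_core_design <- function() {
  tibble(
    sample_id = c("C4", "C9", "C13", "C17", "C22", "C27", "C33", "C36",
                  "C39", "C42", "C45", "C49", "C52", "C55", "C59", "C62", "C65"),
    core_category = c(rep("DC_1", 2), rep("DC_2", 3), rep("DC_3", 7), rep("DC_4", 5)),
    depth_m = c(23, 35, 44, 55, 65, 78, 93, 102, 111, 120, 130, 139,
                148, 157, 166, 175, 181),
    temperature_C = c(20, 36, 59, 82.5, 101.5, 114, 123, 124, 121.5, 116,
                      107, 97, 84, 64, 55, 44.5, 37),
    deposit = ifelse(c(23, 35, 44, 55, 65, 78, 93, 102, 111, 120, 130, 139,
                       148, 157, 166, 175, 181) <= 58, "subaerial", "submarine")
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic amplicon community generator. Defaults mirror
#' the sampling design of a subsurface drilling campaign: 17 drill cores in
#' four depth categories, 18 borehole-fluid samples, 2 fumaroles, 4 seawater
#' profiles, 8 drilling-fluid aliquots and 2 extraction negative controls,
#' with 300 features split across five origin pools.
#'
#' @param n_endemic_subaerial,n_endemic_submarine,n_seawater,n_drillfluid_only,n_reagent
#'   Feature counts per origin pool.
#' @param cores Drill-core design tibble; see [default_core_design()].
#' @param n_borehole_fluid,n_fumarole,n_seawater_samples,n_drilling_fluid,n_negative_control
#'   Sample counts per non-core type.
#' @param meanlog,sdlog Log-normal base-abundance parameters (per-feature
#'   ranks, fixed across samples).
#' @param optimum_range Range (degrees C) of the uniform draw of per-feature
#'   thermal optima.
#' @param niche_width_C Thermal niche width (degrees C), > 0.
#' @param carryover_shape1,carryover_shape2 Beta law of the per-core
#'   drilling-fluid carryover fraction `c_j`.
#' @param carryover_fixed Optional fixed carryover fraction in [0, 1]
#'   overriding the Beta draw for every core (e.g. 0 for uncontaminated
#'   reference runs).
#' @param lib_meanlog,lib_sdlog Log-normal law of per-sample library sizes.
#' @param inflow_fraction Fraction of expected endemic mass replaced by the
#'   seawater pool in DC_4 cores (natural seawater inflow).
#' @param blocklist_genus_rate Fraction of reagent features assigned a
#'   blocklisted genus.
#' @param chloroplast_rate Fraction of all features assigned order
#'   "Chloroplast".
#' @return A `tephra_sim_config` list.
#' @export
sim_config <- function(n_endemic_subaerial = 60,
                       n_endemic_submarine = 120,
                       n_seawater = 70,
                       n_drillfluid_only = 35,
                       n_reagent = 15,
                       cores = default_core_design(),
                       n_borehole_fluid = 18,
                       n_fumarole = 2,
                       n_seawater_samples = 4,
                       n_drilling_fluid = 8,
                       n_negative_control = 2,
                       meanlog = 0, sdlog = 1,
                       optimum_range = c(10, 125),
                       niche_width_C = 25,
                       carryover_shape1 = 2, carryover_shape2 = 6,
                       carryover_fixed = NULL,
                       lib_meanlog = log(30000), lib_sdlog = 0.3,
                       inflow_fraction = 0.10,
                       blocklist_genus_rate = 0.05,
                       chloroplast_rate = 0.02) {
  cfg <- list(
    n_endemic_subaerial = n_endemic_subaerial,
    n_endemic_submarine = n_endemic_submarine,
    n_seawater = n_seawater,
    n_drillfluid_only = n_drillfluid_only,
    n_reagent = n_reagent,
    cores = as_tibble(cores),
    n_borehole_fluid = n_borehole_fluid,
    n_fumarole = n_fumarole,
    n_seawater_samples = n_seawater_samples,
    n_drilling_fluid = n_drilling_fluid,
    n_negative_control = n_negative_control,
    meanlog = meanlog, sdlog = sdlog,
    optimum_range = optimum_range,
    niche_width_C = niche_width_C,
    carryover_shape1 = carryover_shape1,
    carryover_shape2 = carryover_shape2,
    carryover_fixed = carryover_fixed,
    lib_meanlog = lib_meanlog, lib_sdlog = lib_sdlog,
    inflow_fraction = inflow_fraction,
    blocklist_genus_rate = blocklist_genus_rate,
    chloroplast_rate = chloroplast_rate
  )
  counts <- unlist(cfg[c("n_endemic_subaerial", "n_endemic_submarine",
                         "n_seawater", "n_drillfluid_only", "n_reagent")])
  if (any(counts < 0)) abort("pool feature counts must be >= 0")
  if (carryover_shape1 <= 0 || carryover_shape2 <= 0) abort("Beta parameters must be > 0")
  if (!is.null(carryover_fixed) &&
      (carryover_fixed < 0 || carryover_fixed > 1)) {
    abort("carryover_fixed must be in [0, 1]")
  }
  if (lib_sdlog <= 0) abort("library-size sdlog must be > 0")
  if (niche_width_C <= 0) abort("niche width must be > 0")
  if (inflow_fraction < 0 || inflow_fraction > 1) abort("inflow_fraction must be in [0,1]")
  structure(cfg, class = "tephra_sim_config")
}

# genus catalogues per origin; lineages are synthetic but use genera typical
# of each habitat so taxonomy output looks like a real SILVA assignment
.sim_genera <- function() {
  list(
    endemic_subaerial = c("Thermaerobacter", "Thioalkalimicrobium", "Salinarimonas",
                          "Marinobacter", "Nioella", "Ectothiorhodospira"),
    endemic_submarine = c("Geobacillus", "Thermus", "Sulfurospirillum",
                          "Methanobacterium", "Thermococcus", "Caldisericum",
                          "Desulfosporosinus", "Reyranella"),
    seawater = c("Synechococcus", "Planktomarina", "Sulfitobacter", "Polaribacter",
                 "Flavicella", "Pseudoalteromonas", "Aliivibrio"),
    drillfluid_only = c("Glaciecola", "Oceaniserpentilla", "Oleispira",
                        "Psychromonas", "Colwellia", "Marinomonas"),
    reagent = c("Aquabacterium", "Pelomonas", "Undibacterium", "Diaphorobacter")
  )
}

#' Default genus blocklist
#'
#' A small illustrative set of genera repeatedly reported as reagent and
#' kit contaminants in low-biomass sequencing surveys. Intended as a
#' starting point; studies should supply their own curated list (one genus
#' per line) via [read_blocklist()].
#'
#' @return Character vector of genus names.
#' @export
default_blocklist <- function() {
  c("Cutibacterium", "Ralstonia", "Burkholderia", "Bradyrhizobium",
    "Methylobacterium", "Staphylococcus", "Streptococcus", "Corynebacterium",
    "Escherichia", "Acinetobacter")
}

#' Read a genus blocklist file (one genus per line)
#' @param path Text file path; blank lines and `#` comments ignored.
#' @return Character vector of genus names.
#' @export
read_blocklist <- function(path) {
  x <- trimws(readr::read_lines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

# relative-abundance profile of a pool over the full feature space
.pool_profile <- function(base, idx, weights = NULL) {
  p <- numeric(length(base))
  w <- base[idx]
  if (!is.null(weights)) w <- w * weights
  if (length(idx) > 0 && sum(w) > 0) p[idx] <- w / sum(w)
  p
}

#' Simulate a contaminated amplicon dataset with ground truth
#'
#' Draws a features x samples count table emulating a low-biomass subsurface
#' drilling campaign. Endemic features (subaerial and submarine pools) have
#' log-normal base abundances modulated by a Gaussian thermal niche along the
#' borehole temperature profile. Each drill core receives drilling-fluid
#' carryover: a fraction `c_j ~ Beta` of its expected mass is replaced by the
#' profile of taxa specific to the recirculated drilling fluid. Deep (DC_4)
#' cores additionally receive seawater-pool mass at the configured inflow
#' fraction (natural seawater infiltration). Drilling-fluid samples contain
#' the seawater pool plus the fluid-specific pool; seawater samples the
#' seawater pool; negative controls the reagent pool. Counts are multinomial
#' at a log-normal library size. Output is bit-identical for a fixed seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list with elements `dataset` (a `tephra_dataset`) and `truth`
#'   (class `tephra_truth`): `features` (feature_id, origin), `mixing`
#'   (drill-core sample_id, carryover `c_j`), `library_sizes`,
#'   `expected` (features x drill-core matrix of the no-carryover expected
#'   relative abundances, the per-core target community), and `config`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "tephra_sim_config"))
  with_seed(seed, .simulate_impl(config))
}

.simulate_impl <- function(cfg) {
  origins <- rep(
    c("endemic_subaerial", "endemic_submarine", "seawater", "drillfluid_only", "reagent"),
    times = c(cfg$n_endemic_subaerial, cfg$n_endemic_submarine, cfg$n_seawater,
              cfg$n_drillfluid_only, cfg$n_reagent)
  )
  n_feat <- length(origins)
  if (n_feat == 0) abort("config requests zero features")
  feature_ids <- sprintf("ASV%04d", seq_len(n_feat))
  base <- rlnorm(n_feat, cfg$meanlog, cfg$sdlog)
  t_opt <- runif(n_feat, cfg$optimum_range[1], cfg$optimum_range[2])

  idx <- split(seq_len(n_feat), origins)
  for (pool in c("endemic_subaerial", "endemic_submarine", "seawater",
                 "drillfluid_only", "reagent")) {
    if (is.null(idx[[pool]])) idx[[pool]] <- integer(0)
  }

  cores <- cfg$cores
  md <- dplyr::bind_rows(
    tibble(sample_id = cores$sample_id, sample_type = "drill_core",
           core_category = cores$core_category, depth_m = cores$depth_m,
           temperature_C = cores$temperature_C),
    tibble(sample_id = sprintf("BF_%02d", seq_len(cfg$n_borehole_fluid)),
           sample_type = "borehole_fluid", core_category = "none",
           depth_m = round(runif(cfg$n_borehole_fluid, 58, 170)),
           temperature_C = round(runif(cfg$n_borehole_fluid, 54, 125), 1)),
    tibble(sample_id = sprintf("FUM_%d", seq_len(cfg$n_fumarole)),
           sample_type = "fumarole", core_category = "none",
           depth_m = 0, temperature_C = round(runif(cfg$n_fumarole, 80, 86), 1)),
    tibble(sample_id = sprintf("SW_%02d", 10 * seq_len(cfg$n_seawater_samples)),
           sample_type = "seawater", core_category = "none",
           depth_m = 10 * seq_len(cfg$n_seawater_samples),
           temperature_C = round(runif(cfg$n_seawater_samples, 9.5, 12), 1)),
    tibble(sample_id = sprintf("DF_%02d", seq_len(cfg$n_drilling_fluid)),
           sample_type = "drilling_fluid", core_category = "none",
           depth_m = NA_real_, temperature_C = 10),
    tibble(sample_id = sprintf("NC_%d", seq_len(cfg$n_negative_control)),
           sample_type = "negative_control", core_category = "none",
           depth_m = NA_real_, temperature_C = NA_real_)
  )
  md$is_control <- md$sample_type == "negative_control"
  md <- validate_metadata(md)

  sw_profile <- .pool_profile(base, idx$seawater)
  df_only_profile <- .pool_profile(base, idx$drillfluid_only)
  # drilling-fluid samples: marine seawater background plus taxa that bloomed
  # in the recirculated fluid
  df_sample_profile <- .pool_profile(base, c(idx$seawater, idx$drillfluid_only))
  reagent_profile <- .pool_profile(base, idx$reagent)

  endemic_profile <- function(deposit, temp) {
    pool <- if (deposit == "subaerial") idx$endemic_subaerial else idx$endemic_submarine
    if (length(pool) == 0) abort("empty endemic pool with nonzero requested mass")
    .pool_profile(base, pool, niche_weight(temp, t_opt[pool], cfg$niche_width_C))
  }

  n_cores <- nrow(cores)
  c_j <- if (!is.null(cfg$carryover_fixed)) {
    rep(cfg$carryover_fixed, n_cores)
  } else {
    rbeta(n_cores, cfg$carryover_shape1, cfg$carryover_shape2)
  }
  expected_true <- matrix(0, n_feat, n_cores,
                          dimnames = list(feature_ids, cores$sample_id))

  profiles <- matrix(0, n_feat, nrow(md), dimnames = list(feature_ids, md$sample_id))
  for (j in seq_len(nrow(md))) {
    row <- md[j, ]
    prof <- switch(
      row$sample_type,
      drill_core = {
        k <- match(row$sample_id, cores$sample_id)
        f_in <- if (cores$core_category[k] == "DC_4") cfg$inflow_fraction else 0
        true_vec <- (1 - f_in) * endemic_profile(cores$deposit[k], row$temperature_C) +
          f_in * sw_profile
        expected_true[, k] <- true_vec
        (1 - c_j[k]) * true_vec + c_j[k] * df_only_profile
      },
      borehole_fluid = endemic_profile("submarine", row$temperature_C),
      fumarole = endemic_profile("subaerial", row$temperature_C),
      seawater = sw_profile,
      drilling_fluid = df_sample_profile,
      negative_control = reagent_profile
    )
    if (sum(prof) <= 0) abort("empty pool with nonzero requested mass")
    profiles[, j] <- prof / sum(prof)
  }

  lib <- pmax(1L, as.integer(round(rlnorm(nrow(md), cfg$lib_meanlog, cfg$lib_sdlog))))
  counts <- matrix(0L, n_feat, nrow(md), dimnames = dimnames(profiles))
  for (j in seq_len(nrow(md))) {
    counts[, j] <- rmultinom(1, lib[j], profiles[, j])[, 1]
  }

  taxonomy <- .sim_taxonomy(feature_ids, origins, cfg)

  truth <- structure(
    list(
      features = tibble(feature_id = feature_ids, origin = origins),
      mixing = tibble(sample_id = cores$sample_id, c_j = c_j),
      library_sizes = tibble(sample_id = md$sample_id, library_size = lib),
      expected = expected_true,
      config = cfg
    ),
    class = "tephra_truth"
  )
  list(dataset = harmonize(counts, md, taxonomy), truth = truth)
}

# synthetic lineage catalogue; plants blocklisted genera on a fraction of
# reagent features and order Chloroplast on a fraction of all features so
# the taxonomy screen has known targets
.sim_taxonomy <- function(feature_ids, origins, cfg) {
  genera <- .sim_genera()
  phylum_of <- c(
    endemic_subaerial = "Firmicutes", endemic_submarine = "Firmicutes",
    seawater = "Proteobacteria", drillfluid_only = "Proteobacteria",
    reagent = "Proteobacteria"
  )
  n <- length(feature_ids)
  tax <- tibble(
    feature_id = feature_ids,
    kingdom = ifelse(origins == "endemic_submarine" &
                       seq_len(n) %% 11 == 0, "Archaea", "Bacteria"),
    phylum = unname(phylum_of[origins]),
    class = "Gammaproteobacteria",
    order = "Alteromonadales",
    family = "Alteromonadaceae",
    genus = vapply(seq_len(n), function(i) {
      g <- genera[[origins[i]]]
      g[(i %% length(g)) + 1L]
    }, character(1)),
    species = UNASSIGNED
  )
  reagent_idx <- which(origins == "reagent")
  n_block <- ceiling(cfg$blocklist_genus_rate * length(reagent_idx))
  if (n_block > 0 && length(reagent_idx) > 0) {
    pick <- reagent_idx[seq_len(min(n_block, length(reagent_idx)))]
    bl <- default_blocklist()
    tax$genus[pick] <- bl[((seq_along(pick) - 1L) %% length(bl)) + 1L]
  }
  n_chloro <- round(cfg$chloroplast_rate * n)
  if (n_chloro > 0) {
    pick <- sample(n, n_chloro)
    tax$phylum[pick] <- "Cyanobacteria"
    tax$class[pick] <- "Cyanobacteriia"
    tax$order[pick] <- "Chloroplast"
    tax$family[pick] <- UNASSIGNED
    tax$genus[pick] <- UNASSIGNED
  }
  tax
}

#' Score contaminant calls against simulation ground truth
#'
#' A feature is predicted positive when any call removes it; truth positives
#' are the features whose origin is in `positive_origins`. When no feature is
#' predicted positive, precision is undefined and reported as 0 with
#' `precision_defined = FALSE`.
#'
#' @param calls Tibble of contaminant calls (`feature_id`, `verdict`).
#' @param truth A `tephra_truth` from [simulate_dataset()].
#' @param positive_origins Origins counted as true contaminants.
#' @return One-row tibble: `tp`, `fp`, `fn`, `tn`, `precision`, `recall`,
#'   `f1`, `precision_defined`.
#' @export
evaluate_calls <- function(calls, truth,
                           positive_origins = c("drillfluid_only", "reagent")) {
  stopifnot(inherits(truth, "tephra_truth"))
  vocab <- union(c("endemic_subaerial", "endemic_submarine", "seawater",
                   "drillfluid_only", "reagent"), unique(truth$features$origin))
  bad_origin <- setdiff(positive_origins, vocab)
  if (length(bad_origin) > 0) {
    abort(paste0("unknown origin in positive_origins: ", bad_origin[1]))
  }
  unknown <- setdiff(unique(calls$feature_id), truth$features$feature_id)
  if (length(unknown) > 0) {
    abort(paste0("call references unknown feature '", unknown[1], "'"))
  }
  removed <- unique(calls$feature_id[calls$verdict == "remove"])
  pos <- truth$features$feature_id[truth$features$origin %in% positive_origins]
  neg <- setdiff(truth$features$feature_id, pos)
  tp <- length(intersect(removed, pos))
  fp <- length(intersect(removed, neg))
  fn <- length(setdiff(pos, removed))
  tn <- length(setdiff(neg, removed))
  precision_defined <- (tp + fp) > 0
  precision <- if (precision_defined) tp / (tp + fp) else 0
  recall <- if ((tp + fn) > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble(tp = tp, fp = fp, fn = fn, tn = tn,
         precision = precision, recall = recall, f1 = f1,
         precision_defined = precision_defined)
}

#' Mean compositional error of drill-core samples against ground truth
#'
#' For each drill-core sample present in `counts`, computes the Bray-Curtis
#' distance between the observed relative-abundance vector (over the
#' features retained in `counts`, zeros elsewhere) and the sample's true
#' expected community (endemic profile plus, for deep cores, the natural
#' seawater-inflow component). Removed contaminant features drop out of the
#' comparison; removed endemic features and retained contaminants both count
#' as error mass.
#'
#' @param counts Features x samples integer matrix (raw or cleaned).
#' @param truth A `tephra_truth`.
#' @return Mean Bray-Curtis distance across drill-core samples, in [0, 1].
#'   Per-sample distances are attached as attribute `"per_sample"`.
#' @export
composition_error <- function(counts, truth) {
  stopifnot(inherits(truth, "tephra_truth"))
  core_ids <- truth$mixing$sample_id
  present <- intersect(colnames(counts), core_ids)
  if (length(present) == 0) abort("no drill-core samples present in the table")
  all_feat <- rownames(truth$expected)
  unknown_feat <- setdiff(rownames(counts), all_feat)
  if (length(unknown_feat) > 0) {
    abort(paste0("feature '", unknown_feat[1], "' absent from truth"))
  }
  d <- vapply(present, function(s) {
    x <- numeric(length(all_feat))
    names(x) <- all_feat
    col <- counts[, s]
    if (sum(col) == 0) return(NA_real_)
    x[rownames(counts)] <- col / sum(col)
    y <- truth$expected[, s]
    sum(abs(x - y)) / sum(x + y)
  }, numeric(1))
  out <- mean(d, na.rm = TRUE)
  attr(out, "per_sample") <- d
  out
}

#' Write a simulated dataset (tables, truth, manifest) to a directory
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_feature_table(sim$dataset$counts, file.path(dir, "feature_table.tsv"))
  write_metadata(sim$dataset$metadata, file.path(dir, "metadata.tsv"))
  write_taxonomy(sim$dataset$taxonomy, file.path(dir, "taxonomy.tsv"))
  readr::write_tsv(sim$truth$features, file.path(dir, "truth.tsv"), progress = FALSE)
  manifest <- list(
    n_features = nrow(sim$dataset$counts),
    n_samples = ncol(sim$dataset$counts),
    carryover = as.list(setNames(sim$truth$mixing$c_j, sim$truth$mixing$sample_id)),
    library_sizes = as.list(setNames(sim$truth$library_sizes$library_size,
                                     sim$truth$library_sizes$sample_id))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
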