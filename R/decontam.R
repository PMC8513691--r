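#' Prevalence-based contaminant test against negative controls
#'
#' For each feature detected in at least one negative control, compares its
#' presence/absence prevalence in true samples versus negative controls with
#' a 2x2 chi-square test (no continuity correction), falling back to
#' Fisher's exact test whenever any expected cell is below 5. A feature is
#' called a contaminant when `p < threshold` and its prevalence fraction is
#' higher in controls than in true samples (one-sided direction: a feature
#' enriched in true samples is never flagged). Features absent from all
#' controls are retained without testing and receive no call.
#'
#' @param counts Features x samples integer matrix.
#' @param metadata Metadata tibble; `is_control` flags the negative controls.
#' @param threshold Decision threshold on the p-value (default 0.5, the
#'   aggressive midpoint commonly used for prevalence screening).
#' @param min_count Minimal count for a feature to be "present" in a sample.
#' @param n_true_min Minimal number of true (non-control) samples required.
#' @return Tibble of calls: `feature_id`, `stage` (`"prevalence"`),
#'   `verdict`, `rule` (`"prevalence_p"`), `evidence`, `p`.
#' @export
prevalence_contaminant_test <- function(counts, metadata, threshold = 0.5,
                                        min_count = 1, n_true_min = 2) {
  counts <- validate_feature_table(counts)
  metadata <- validate_metadata(metadata)
  md <- metadata[match(colnames(counts), metadata$sample_id), ]
  ctrl <- which(md$is_control)
  true_s <- which(!md$is_control)
  if (length(ctrl) == 0) abort("prevalence method requires negative controls")
  if (length(true_s) < n_true_min) {
    abort(paste0("prevalence method requires at least ", n_true_min, " true samples"))
  }
  present <- counts >= min_count
  a <- rowSums(present[, true_s, drop = FALSE])   # present in true samples
  b <- rowSums(present[, ctrl, drop = FALSE])     # present in controls
  n_t <- length(true_s)
  n_c <- length(ctrl)
  tested <- which(b > 0)
  if (length(tested) == 0) {
    return(tibble(feature_id = character(0), stage = character(0),
                  verdict = character(0), rule = character(0),
                  evidence = character(0), p = numeric(0)))
  }
  res <- purrr::map_dfr(tested, function(i) {
    p <- prevalence_p_value(a[i], n_t, b[i], n_c)
    remove <- p < threshold && (b[i] / n_c) > (a[i] / n_t)
    tibble(
      feature_id = rownames(counts)[i],
      stage = "prevalence",
      verdict = if (remove) "remove" else "retain",
      rule = "prevalence_p",
      evidence = sprintf("present %d/%d true, %d/%d control", a[i], n_t, b[i], n_c),
      p = p
    )
  })
  res
}

#' Prevalence 2x2 p-value (chi-square with Fisher fallback)
#'
#' Two-sided p-value for the table `[present, absent] x [true, control]`:
#' Pearson chi-square without continuity correction, or Fisher's exact test
#' when any expected cell is below 5.
#'
#' @param a Present count among true samples.
#' @param n_t Number of true samples.
#' @param b Present count among controls.
#' @param n_c Number of controls.
#' @return p-value in (0, 1].
#' @export
prevalence_p_value <- function(a, n_t, b, n_c) {
  tab <- matrix(c(a, n_t - a, b, n_c - b), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    fisher.test(tab)$p.value
  } else {
    suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  }
}

#' Taxonomy-based contaminant screen
#'
#' Flags features whose lineage marks them as non-target or as known
#' reagent contaminants: order Chloroplast, family Mitochondria, kingdom
#' Eukaryota, kingdom unassigned, or genus on a user-supplied blocklist
#' (case-insensitive exact match). A feature matching several rules gets
#' one call per matched rule.
#'
#' @param taxonomy Taxonomy tibble (`feature_id`, `kingdom` .. `species`).
#' @param blocklist Character vector of contaminant genera (may be empty);
#'   see [default_blocklist()] and [read_blocklist()].
#' @return Tibble of calls: `feature_id`, `stage` (`"taxonomy"`), `verdict`
#'   (`"remove"`), `rule`, `evidence`, `p` (`NA`).
#' @export
taxonomy_screen <- function(taxonomy, blocklist = character()) {
  stopifnot(all(c("feature_id", TAX_RANKS) %in% names(taxonomy)))
  rules <- list(
    chloroplast = tolower(taxonomy$order) == "chloroplast",
    mitochondria = tolower(taxonomy$family) == "mitochondria",
    eukaryote = tolower(taxonomy$kingdom) %in% c("eukaryota", "eukaryote"),
    unassigned_kingdom = taxonomy$kingdom == UNASSIGNED,
    genus_blocklist = tolower(taxonomy$genus) %in% tolower(blocklist)
  )
  evidence <- list(
    chloroplast = taxonomy$order, mitochondria = taxonomy$family,
    eukaryote = taxonomy$kingdom, unassigned_kingdom = taxonomy$kingdom,
    genus_blocklist = taxonomy$genus
  )
  purrr::map_dfr(names(rules), function(r) {
    hit <- which(rules[[r]])
    tibble(
      feature_id = taxonomy$feature_id[hit],
      stage = "taxonomy",
      verdict = "remove",
      rule = r,
      evidence = evidence[[r]][hit],
      p = NA_real_
    )
  })
}

#' Default habitat grouping for the overlap classifier
#'
#' Assigns samples to the four classifier groups: `SUB_A` (drill cores from
#' the subaerial deposit, at or above `subaerial_max_depth`), `SUB_M`
#' (deeper drill cores, submarine deposit), `DF` (drilling fluid), `SW`
#' (seawater). Drill cores with missing depth are excluded with a warning.
#'
#' @param metadata Metadata tibble.
#' @param subaerial_max_depth Depth (m below surface) of the subaerial /
#'   submarine boundary; defaults to 58 m, the zone of tidal flux.
#' @return Named list of sample-id vectors (`SUB_A`, `SUB_M`, `DF`, `SW`).
#' @export
default_overlap_groups <- function(metadata, subaerial_max_depth = 58) {
  metadata <- validate_metadata(metadata)
  cores <- metadata[metadata$sample_type == "drill_core", ]
  if (anyNA(cores$depth_m)) {
    warn("drill cores with missing depth excluded from overlap groups")
    cores <- cores[!is.na(cores$depth_m), ]
  }
  list(
    SUB_A = cores$sample_id[cores$depth_m <= subaerial_max_depth],
    SUB_M = cores$sample_id[cores$depth_m > subaerial_max_depth],
    DF = metadata$sample_id[metadata$sample_type == "drilling_fluid"],
    SW = metadata$sample_id[metadata$sample_type == "seawater"]
  )
}

#' Presence pattern of each feature across the four classifier groups
#'
#' A feature is present in a group when it has `count >= min_count` in at
#' least one sample of the group. The pattern is a pure function of the
#' table, the grouping and `min_count`.
#'
#' @param counts Features x samples integer matrix.
#' @param groups Named list mapping `SUB_A`, `SUB_M`, `DF`, `SW` to sample
#'   ids (see [default_overlap_groups()]). A sample may appear in only one
#'   group.
#' @param min_count Presence threshold (default 1: any read).
#' @return Tibble: `feature_id` plus logical columns `SUB_A`, `SUB_M`,
#'   `DF`, `SW`.
#' @export
presence_pattern <- function(counts, groups, min_count = 1) {
  counts <- validate_feature_table(counts)
  if (!all(OVERLAP_GROUPS %in% names(groups))) {
    abort(paste0("groups must name all of: ", paste(OVERLAP_GROUPS, collapse = ", ")))
  }
  all_ids <- unlist(groups[OVERLAP_GROUPS], use.names = FALSE)
  dup <- unique(all_ids[duplicated(all_ids)])
  if (length(dup) > 0) {
    abort(paste0("sample '", dup[1], "' assigned to two overlap groups"))
  }
  missing_s <- setdiff(all_ids, colnames(counts))
  if (length(missing_s) > 0) {
    abort(paste0("group sample '", missing_s[1], "' not in the feature table"))
  }
  out <- tibble(feature_id = rownames(counts))
  for (g in OVERLAP_GROUPS) {
    ids <- groups[[g]]
    out[[g]] <- if (length(ids) == 0) {
      rep(FALSE, nrow(counts))
    } else {
      rowSums(counts[, ids, drop = FALSE] >= min_count) > 0
    }
  }
  out
}

#' Classify features from their four-group presence pattern
#'
#' Rule priority (first match wins):
#' * `R1_subaerial_marine` (remove): present in subaerial cores and in the
#'   drilling fluid or seawater — no marine taxa are expected in the
#'   subaerial deposit, so these are marine contaminants.
#' * `R3_inflow_retained` (retain): present in submarine cores, drilling
#'   fluid and seawater but not subaerial cores — consistent with natural
#'   seawater inflow into the deep submarine deposit.
#' * `R2_drillfluid_only` (remove): shared only between submarine cores and
#'   the drilling fluid.
#' * `endemic_candidate` (retain): everything else.
#'
#' @param patterns Tibble from [presence_pattern()].
#' @return Tibble of calls: `feature_id`, `stage` (`"overlap"`), `verdict`,
#'   `rule`, `evidence` (the presence pattern string), `p` (`NA`).
#' @export
overlap_classify <- function(patterns) {
  stopifnot(all(c("feature_id", OVERLAP_GROUPS) %in% names(patterns)))
  rule <- dplyr::case_when(
    patterns$SUB_A & (patterns$DF | patterns$SW) ~ "R1_subaerial_marine",
    patterns$SUB_M & patterns$DF & patterns$SW ~ "R3_inflow_retained",
    patterns$SUB_M & patterns$DF ~ "R2_drillfluid_only",
    TRUE ~ "endemic_candidate"
  )
  tibble(
    feature_id = patterns$feature_id,
    stage = "overlap",
    verdict = ifelse(rule %in% c("R1_subaerial_marine", "R2_drillfluid_only"),
                     "remove", "retain"),
    rule = rule,
    evidence = pattern_string(patterns),
    p = NA_real_
  )
}

# "SUB_A+DF"-style label for a presence pattern; "none" when all-false
pattern_string <- function(patterns) {
  apply(as.matrix(patterns[, OVERLAP_GROUPS]), 1, function(f) {
    if (!any(f)) "none" else paste(OVERLAP_GROUPS[f], collapse = "+")
  })
}

#' Venn census of presence patterns
#'
#' Counts features in each of the 15 non-empty regions of the four-set Venn
#' diagram (subaerial cores, submarine cores, drilling fluid, seawater).
#' The region counts partition the features detected in at least one group;
#' the number of features with an all-false pattern is attached as attribute
#' `"n_no_presence"`.
#'
#' @param patterns Tibble from [presence_pattern()].
#' @return Tibble with logical columns `SUB_A`, `SUB_M`, `DF`, `SW`, the
#'   `region` label and the feature count `n`, one row per region.
#' @export
venn_census <- function(patterns) {
  stopifnot(all(OVERLAP_GROUPS %in% names(patterns)))
  regions <- tidyr::expand_grid(
    SUB_A = c(TRUE, FALSE), SUB_M = c(TRUE, FALSE),
    DF = c(TRUE, FALSE), SW = c(TRUE, FALSE)
  )
  regions <- regions[rowSums(regions) > 0, ]
  key <- pattern_string(patterns)
  regions$region <- pattern_string(regions)
  tab <- table(key)
  regions$n <- as.integer(ifelse(is.na(tab[regions$region]), 0L, tab[regions$region]))
  out <- dplyr::arrange(regions, dplyr::desc(.data$n))
  attr(out, "n_no_presence") <- sum(key == "none")
  out
}

#' Apply contaminant calls to a dataset
#'
#' Deletes every feature with at least one `remove` verdict (the whole row,
#' across all samples) and drops samples of the excluded types (by default
#' the drilling-fluid and negative-control samples, which have served their
#' purpose once the calls are made).
#'
#' @param dataset A `tephra_dataset`.
#' @param calls Tibble of calls (rows from any cascade stage, concatenated).
#' @param drop_sample_types Sample types removed from the cleaned dataset.
#' @return The cleaned `tephra_dataset`. A per-sample removal report
#'   (`sample_id`, `reads_before`, `reads_after`, `reads_removed`,
#'   `fraction_removed`, `dropped`) is attached as attribute
#'   `"removal_report"`.
#' @export
apply_calls <- function(dataset, calls,
                        drop_sample_types = c("drilling_fluid", "negative_control")) {
  stopifnot(inherits(dataset, "tephra_dataset"))
  unknown <- setdiff(unique(calls$feature_id), rownames(dataset$counts))
  if (length(unknown) > 0) {
    abort(paste0("call references unknown feature '", unknown[1], "'"))
  }
  removed_feat <- unique(calls$feature_id[calls$verdict == "remove"])
  keep_feat <- setdiff(rownames(dataset$counts), removed_feat)
  if (length(keep_feat) == 0) abort("all features removed")
  keep_samp <- dataset$metadata$sample_id[!dataset$metadata$sample_type %in% drop_sample_types]
  before <- colSums(dataset$counts)
  cleaned_counts <- dataset$counts[keep_feat, keep_samp, drop = FALSE]
  after_all <- colSums(dataset$counts[keep_feat, , drop = FALSE])
  report <- tibble(
    sample_id = colnames(dataset$counts),
    reads_before = as.integer(before),
    reads_after = as.integer(after_all),
    reads_removed = as.integer(before - after_all),
    fraction_removed = ifelse(before > 0, 1 - after_all / before, 0),
    dropped = !colnames(dataset$counts) %in% keep_samp
  )
  out <- harmonize(cleaned_counts, dataset$metadata, dataset$taxonomy)
  attr(out, "removal_report") <- report
  out
}

#' Run the full three-stage decontamination cascade
#'
#' Convenience wrapper: prevalence test against negative controls, taxonomy
#' screen, four-group overlap classification, then [apply_calls()].
#'
#' @param dataset A `tephra_dataset` (must contain negative controls for the
#'   prevalence stage).
#' @param groups Overlap group map; defaults to
#'   [default_overlap_groups()] on the dataset metadata.
#' @param blocklist Genus blocklist for the taxonomy screen.
#' @param threshold Prevalence-test threshold.
#' @param min_count Presence threshold shared by the prevalence test and
#'   the overlap patterns.
#' @return List: `calls` (all stages), `patterns`, `census`, `cleaned`
#'   (the cleaned dataset), `summary` (per-rule call counts).
#' @export
decontaminate <- function(dataset, groups = NULL,
                          blocklist = default_blocklist(),
                          threshold = 0.5, min_count = 1) {
  stopifnot(inherits(dataset, "tephra_dataset"))
  if (is.null(groups)) groups <- default_overlap_groups(dataset$metadata)
  prev <- prevalence_contaminant_test(dataset$counts, dataset$metadata,
                                      threshold = threshold, min_count = min_count)
  tax <- taxonomy_screen(dataset$taxonomy, blocklist)
  patterns <- presence_pattern(dataset$counts, groups, min_count = min_count)
  overlap <- overlap_classify(patterns)
  calls <- dplyr::bind_rows(prev, tax, overlap)
  cleaned <- apply_calls(dataset, calls)
  summary <- calls |>
    dplyr::filter(.data$verdict == "remove") |>
    dplyr::count(.data$stage, .data$rule, name = "n_features")
  list(calls = calls, patterns = patterns, census = venn_census(patterns),
       cleaned = cleaned, summary = summary)
}

#' Build a minimal incidence table realizing a given Venn census
#'
#' Constructs a presence/absence feature table with one sample per
#' classifier group and `n` features for each requested region, so that
#' [presence_pattern()] followed by [venn_census()] reproduces the census
#' exactly. Useful for desk-checking the overlap classifier against a
#' published region-by-region Venn count.
#'
#' @param census Data frame with logical columns `SUB_A`, `SUB_M`, `DF`,
#'   `SW` and an integer column `n` (features per region).
#' @return List: `counts` (incidence matrix), `groups` (one sample per
#'   group), `patterns` (the realized presence patterns).
#' @export
incidence_from_census <- function(census) {
  stopifnot(all(c(OVERLAP_GROUPS, "n") %in% names(census)))
  census <- census[census$n > 0, ]
  samples <- paste0("S_", OVERLAP_GROUPS)
  rows <- purrr::map(seq_len(nrow(census)), function(i) {
    matrix(rep(as.integer(unlist(census[i, OVERLAP_GROUPS])), census$n[i]),
           ncol = 4, byrow = TRUE)
  })
  counts <- do.call(rbind, rows)
  rownames(counts) <- sprintf("F%04d", seq_len(nrow(counts)))
  colnames(counts) <- samples
  counts <- validate_feature_table(counts)
  groups <- as.list(setNames(samples, OVERLAP_GROUPS))
  list(counts = counts, groups = groups,
       patterns = presence_pattern(counts, groups))
}
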