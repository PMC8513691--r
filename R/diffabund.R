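#' Median-of-ratios size factors
#'
#' Per-sample scaling factors making counts comparable across library
#' sizes. The reference for feature i is the geometric mean of its positive
#' counts; the factor for sample j is the median of `x_ij / g_i` over
#' features positive in sample j, rescaled so the factors have geometric
#' mean 1.
#'
#' @param counts Features x samples matrix; every sample needs at least one
#'   positive count on a feature with a positive reference.
#' @return Named positive numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  if (any(colSums(counts) == 0)) abort("every sample needs at least one positive count")
  logx <- log(counts)
  logx[!is.finite(logx)] <- NA
  g <- exp(rowMeans(logx, na.rm = TRUE))   # geometric mean of positive counts
  g[!is.finite(g)] <- 0                    # all-zero features drop out
  s <- vapply(seq_len(ncol(counts)), function(j) {
    use <- counts[, j] > 0 & g > 0
    if (!any(use)) {
      abort(paste0("sample '", colnames(counts)[j],
                   "' shares no positive feature with the reference"))
    }
    median(counts[use, j] / g[use])
  }, numeric(1))
  s <- s / exp(mean(log(s)))
  names(s) <- colnames(counts)
  s
}

#' Two-group negative-binomial Wald differential-abundance test
#'
#' A deliberately simple count-based test: counts are normalized by
#' median-of-ratios size factors; the per-feature dispersion is a
#' method-of-moments estimate `alpha = max(alpha_min, (V - mu) / mu^2)`
#' from the pooled within-group variance of the normalized counts; the
#' effect is `lfc = log2((mu_B + pseudo) / (mu_A + pseudo))` with a
#' delta-method standard error, and the Wald statistic is compared to a
#' standard normal. No dispersion shrinkage, no GLM iteration, no LFC
#' shrinkage: feature lists will differ from shrinkage-based tools, but the
#' statistical contract (type-I error control, unbiased fold-change
#' recovery) is testable.
#'
#' @param counts Features x samples integer matrix.
#' @param metadata Metadata tibble with `sample_id` and `group_col`.
#' @param group_a,group_b Labels of the two groups (lfc is B over A).
#' @param group_col Metadata column holding the labels.
#' @param alpha_min Dispersion floor.
#' @param pseudo Pseudo-count stabilizing the fold change.
#' @return Tibble, one row per tested feature (features with zero counts in
#'   all samples of both groups are excluded): `feature_id`, `base_mean`,
#'   `lfc`, `se`, `wald`, `p`, `p_adj`.
#' @export
nb_wald_two_group <- function(counts, metadata, group_a, group_b,
                              group_col = "sample_type",
                              alpha_min = 1e-8, pseudo = 0.5) {
  stopifnot(group_col %in% names(metadata))
  md <- metadata[match(colnames(counts), metadata$sample_id), ]
  ia <- which(md[[group_col]] == group_a)
  ib <- which(md[[group_col]] == group_b)
  if (length(ia) < 2 || length(ib) < 2) {
    abort("both groups need at least 2 samples")
  }
  x <- counts[, c(ia, ib), drop = FALSE]
  tested <- rowSums(x) > 0
  x <- x[tested, , drop = FALSE]
  if (nrow(x) == 0) abort("no feature with a positive count in either group")
  s <- size_factors(x)
  y <- sweep(x, 2, s, "/")
  na <- length(ia)
  nb <- length(ib)
  ya <- y[, seq_len(na), drop = FALSE]
  yb <- y[, na + seq_len(nb), drop = FALSE]
  mu_a <- rowMeans(ya)
  mu_b <- rowMeans(yb)
  mu_all <- rowMeans(y)
  v <- (rowSums((ya - mu_a)^2) + rowSums((yb - mu_b)^2)) / (na + nb - 2)
  alpha <- pmax(alpha_min, (v - mu_all) / mu_all^2)
  lfc <- log2((mu_b + pseudo) / (mu_a + pseudo))
  se2 <- (1 / log(2))^2 * (
    (mu_a + alpha * mu_a^2) / (na * (mu_a + pseudo)^2) +
      (mu_b + alpha * mu_b^2) / (nb * (mu_b + pseudo)^2)
  )
  se <- sqrt(se2)
  wald <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * pnorm(-abs(wald))
  tibble(
    feature_id = rownames(x),
    base_mean = mu_all,
    lfc = lfc,
    se = se,
    wald = wald,
    p = p,
    p_adj = benjamini_hochberg(p)
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in [0, 1].
#' @return Adjusted p-values (monotone in rank, capped at 1).
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Aggregate significant features into taxonomic bins (convenience)
#'
#' Labels each feature by its lowest assigned rank (species up to kingdom,
#' first non-`UNASSIGNED` name) and counts significant features per bin.
#' Bin construction is a reporting convenience, not part of the tested
#' statistical surface.
#'
#' @param results Tibble from [nb_wald_two_group()].
#' @param taxonomy Taxonomy tibble.
#' @param alpha Adjusted-p significance cutoff (default 0.01).
#' @return Tibble: `bin`, `n_features`, `mean_lfc`.
#' @export
bin_by_lowest_rank <- function(results, taxonomy, alpha = 0.01) {
  sig <- results[results$p_adj < alpha, ]
  tax <- taxonomy[match(sig$feature_id, taxonomy$feature_id), ]
  bin <- vapply(seq_len(nrow(tax)), function(i) {
    ranks <- rev(unlist(tax[i, TAX_RANKS]))
    hit <- ranks[ranks != UNASSIGNED]
    if (length(hit) == 0) UNASSIGNED else hit[[1]]
  }, character(1))
  tibble(bin = bin, lfc = sig$lfc) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_features = dplyr::n(), mean_lfc = mean(.data$lfc),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_features))
}
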