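#' Rarefy all samples to an even sequencing depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads. Samples whose library size is below `depth` are dropped with a
#' warning. Deterministic for a fixed seed.
#'
#' @param counts Features x samples integer matrix.
#' @param depth Target depth; defaults to the minimum library size.
#' @param seed Integer seed.
#' @return Rarefied features x samples integer matrix; every column sums to
#'   `depth`.
#' @export
rarefy_even_depth <- function(counts, depth = min(colSums(counts)), seed = 1) {
  counts <- validate_feature_table(counts)
  if (depth < 1) abort("rarefaction depth must be >= 1")
  lib <- colSums(counts)
  keep <- lib >= depth
  if (!any(keep)) abort("all samples are below the rarefaction depth")
  if (!all(keep)) {
    warn(paste0("dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
                paste(colnames(counts)[!keep], collapse = ", ")))
  }
  x <- counts[, keep, drop = FALSE]
  # vegan::rrarefy warns heuristically when the smallest count exceeds 1;
  # counts here are validated integers, so that advisory is noise
  out <- with_seed(seed, withCallingHandlers(
    t(vegan::rrarefy(t(x), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  ))
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(x)
  out
}

#' Observed richness of a count vector
#' @param x Non-negative count vector with a positive total.
#' @return Number of features with a positive count.
#' @export
observed_richness <- function(x) {
  if (sum(x) <= 0) abort("all-zero sample: richness undefined")
  sum(x > 0)
}

#' Shannon diversity (natural log) of a count vector
#'
#' `H = -sum p_i log p_i` over the positive relative abundances
#' `p_i = x_i / sum(x)`.
#'
#' @param x Non-negative count vector with a positive total.
#' @return Shannon index in nats.
#' @export
shannon <- function(x) {
  if (sum(x) <= 0) abort("all-zero sample: Shannon index undefined")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' Per-sample alpha diversity
#' @param counts Features x samples integer matrix.
#' @return Tibble: `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(counts) {
  counts <- validate_feature_table(counts)
  tibble(
    sample_id = colnames(counts),
    richness = apply(counts, 2, observed_richness),
    shannon = apply(counts, 2, shannon)
  )
}

#' One-way ANOVA on a diversity index
#'
#' Classical one-way fixed-effects analysis of variance,
#' `F = MS_between / MS_within` on (g - 1, N - g) degrees of freedom.
#'
#' @param values Numeric response (e.g., per-sample richness).
#' @param groups Group labels, same length as `values`; >= 2 groups.
#' @return One-row tibble: `name`, `statistic` (F), `df_between`,
#'   `df_within`, `p`. Group means are attached as attribute
#'   `"group_means"`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) abort("ANOVA requires at least 2 groups")
  fit <- aov(values ~ groups)
  s <- summary(fit)[[1]]
  out <- tibble(
    name = "anova_oneway",
    statistic = s[["F value"]][1],
    df_between = s[["Df"]][1],
    df_within = s[["Df"]][2],
    p = s[["Pr(>F)"]][1]
  )
  attr(out, "group_means") <- tapply(values, groups, mean)
  out
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range pairwise tests after a one-way ANOVA:
#' `q_ij = |mean_i - mean_j| / sqrt(MSE/2 * (1/n_i + 1/n_j))`, with p-values
#' from the studentized-range distribution on (g, N - g).
#'
#' @inheritParams anova_oneway
#' @return Tibble, one row per pair: `group_a`, `group_b`, `diff`
#'   (mean_b - mean_a), `statistic` (q), `df_within`, `p` (Tukey-adjusted).
#'   Group means attached as attribute `"group_means"`.
#' @export
tukey_hsd <- function(values, groups) {
  groups <- as.factor(droplevels(as.factor(groups)))
  n_g <- table(groups)
  small <- names(n_g)[n_g < 2]
  if (length(small) > 0) {
    abort(paste0("Tukey HSD requires >= 2 values per group; group '",
                 small[1], "' has ", n_g[small[1]]))
  }
  fit <- aov(values ~ groups)
  tk <- TukeyHSD(fit)$groups
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  mse <- sum(fit$residuals^2) / fit$df.residual
  means <- tapply(values, groups, mean)
  out <- purrr::map_dfr(seq_along(pairs), function(i) {
    b <- pairs[[i]][1]
    a <- pairs[[i]][2]
    q <- abs(means[b] - means[a]) / sqrt(mse / 2 * (1 / n_g[a] + 1 / n_g[b]))
    tibble(
      group_a = a, group_b = b,
      diff = unname(tk[i, "diff"]),
      statistic = unname(q),
      df_within = fit$df.residual,
      p = unname(tk[i, "p adj"])
    )
  })
  attr(out, "group_means") <- means
  out
}

#' Expected rarefied richness (hypergeometric closed form)
#'
#' Expected number of features observed when drawing `depth` reads without
#' replacement from a sample with counts `x`:
#' `S_exp = sum_i [1 - C(N - x_i, depth) / C(N, depth)]`.
#'
#' @param x Non-negative count vector.
#' @param depth Subsample size, `<= sum(x)`.
#' @return Expected richness.
#' @export
expected_rarefied_richness <- function(x, depth) {
  n <- sum(x)
  if (depth > n) abort("depth exceeds the sample library size")
  x <- x[x > 0]
  sum(1 - exp(lchoose(n - x, depth) - lchoose(n, depth)))
}
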