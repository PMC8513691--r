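# sums of squares decomposition of a squared-distance matrix by grouping:
# SS_total = (1/N) sum_{j<k} d^2, SS_within = sum_g (1/n_g) sum_{j<k in g} d^2
.permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  lev <- unique(groups)
  g <- length(lev)
  ss_total <- sum(d2) / (2 * n)
  ss_within <- sum(vapply(lev, function(l) {
    idx <- which(groups == l)
    sum(d2[idx, idx]) / (2 * length(idx))
  }, numeric(1)))
  ss_among <- ss_total - ss_within
  f <- if (ss_within == 0) {
    if (ss_among == 0) 0 else Inf
  } else {
    (ss_among / (g - 1)) / (ss_within / (n - g))
  }
  list(f = f, r2 = if (ss_total > 0) ss_among / ss_total else 0,
       df_between = g - 1, df_within = n - g)
}

# all permutations of 1..n as a matrix (n! rows); recursion is fine for the
# small n where exhaustive testing is meaningful
.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' PERMANOVA: permutation test of group separation on a distance matrix
#'
#' Partitions the sum of squared dissimilarities into among- and
#' within-group components and tests the pseudo-F ratio
#' `F = (SS_among / (g-1)) / (SS_within / (N-g))` by freely permuting the
#' group labels. `p = (1 + #[F_perm >= F_obs]) / (1 + n_permutations)`.
#' With `exhaustive = TRUE` every label permutation is enumerated and the
#' p-value is the exact fraction of permutations (identity included)
#' reaching `F_obs`.
#'
#' @param d A `dist` or symmetric dissimilarity matrix.
#' @param groups Group labels, one per sample; >= 2 non-empty groups.
#' @param n_permutations Number of random permutations (ignored when
#'   `exhaustive = TRUE`).
#' @param seed Integer seed.
#' @param exhaustive Enumerate all label permutations (feasible for small n).
#' @return One-row tibble: `name`, `statistic` (pseudo-F), `df_between`,
#'   `df_within`, `n_permutations`, `p`, `r_squared`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = 1,
                      exhaustive = FALSE) {
  m <- as.matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(m)) abort("one group label per sample required")
  sizes <- table(groups)
  if (length(sizes) < 2) abort("PERMANOVA requires at least 2 groups")
  if (any(sizes == 0)) abort("empty group")
  d2 <- m^2
  obs <- .permanova_f(d2, groups)
  if (obs$f == 0 && obs$r2 == 0) {
    # fully degenerate: all distances zero
    return(tibble(name = "permanova", statistic = 0,
                  df_between = obs$df_between, df_within = obs$df_within,
                  n_permutations = 0L, p = 1, r_squared = 0))
  }
  if (exhaustive) {
    perms <- .all_perms(length(groups))
    fs <- apply(perms, 1, function(idx) .permanova_f(d2, groups[idx])$f)
    p <- mean(fs >= obs$f - 1e-12)
    m_used <- nrow(perms) - 1L
  } else {
    count <- with_seed(seed, {
      sum(vapply(seq_len(n_permutations), function(b) {
        .permanova_f(d2, sample(groups))$f >= obs$f - 1e-12
      }, logical(1)))
    })
    p <- (1 + count) / (1 + n_permutations)
    m_used <- as.integer(n_permutations)
  }
  tibble(name = "permanova", statistic = obs$f,
         df_between = obs$df_between, df_within = obs$df_within,
         n_permutations = m_used, p = p, r_squared = obs$r2)
}

#' Pairwise PERMANOVA with multiple-testing adjustment
#'
#' Runs [permanova()] on every pair of groups (on the pair's sub-matrix)
#' and adjusts the p-values across pairs (Benjamini-Hochberg by default).
#'
#' @inheritParams permanova
#' @param adjust Adjustment method passed to [stats::p.adjust()].
#' @return Tibble, one row per pair: `group_a`, `group_b`, `statistic`,
#'   `df_between`, `df_within`, `n_permutations`, `p`, `p_adjusted`,
#'   `r_squared`.
#' @export
pairwise_permanova <- function(d, groups, n_permutations = 999, seed = 1,
                               adjust = "BH") {
  m <- as.matrix(d)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) < 2) abort("pairwise PERMANOVA requires at least 2 groups")
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  out <- purrr::map_dfr(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    idx <- which(groups %in% pr)
    res <- permanova(m[idx, idx], groups[idx],
                     n_permutations = n_permutations, seed = seed + i)
    dplyr::bind_cols(tibble(group_a = pr[1], group_b = pr[2]),
                     res[, setdiff(names(res), "name")])
  })
  out$p_adjusted <- p.adjust(out$p, method = adjust)
  out
}

#' Fit environmental vectors onto an ordination
#'
#' For each numeric variable, least-squares fit of the centered variable on
#' the ordination axes; `r2 = 1 - SS_res / SS_tot` and the direction is the
#' unit coefficient vector. Significance by permuting the variable values
#' across samples: `p = (1 + #[r2_perm >= r2_obs]) / (1 + m)`. Samples with
#' a missing value are dropped from that variable's fit with a warning.
#'
#' @param ordination A `tephra_nmds` or a samples x axes coordinate matrix
#'   with sample ids as row names.
#' @param env Data frame with `sample_id` and numeric variable columns.
#' @param n_permutations Number of random permutations.
#' @param seed Integer seed.
#' @param exhaustive Enumerate all permutations (small n only).
#' @return Tibble, one row per variable: `variable`, `r_squared`, `p`,
#'   `n_used`, plus one `direction_*` column per axis.
#' @export
envfit_vectors <- function(ordination, env, n_permutations = 999, seed = 1,
                           exhaustive = FALSE) {
  pts <- if (inherits(ordination, "tephra_nmds")) ordination$points else as.matrix(ordination)
  if (is.null(rownames(pts))) abort("ordination coordinates need sample ids as row names")
  stopifnot("sample_id" %in% names(env))
  vars <- setdiff(names(env), "sample_id")
  purrr::map_dfr(vars, function(v) {
    val <- env[[v]][match(rownames(pts), env$sample_id)]
    ok <- is.finite(val)
    if (sum(!ok) > 0) {
      warn(paste0("envfit: dropping ", sum(!ok), " sample(s) with missing '", v, "'"))
    }
    if (sum(ok) < 3) abort(paste0("envfit needs >= 3 finite values for '", v, "'"))
    y <- val[ok]
    if (sd(y) == 0) abort(paste0("zero variance in variable '", v, "'"))
    x <- scale(pts[ok, , drop = FALSE], scale = FALSE)
    r2_of <- function(yy) {
      yy <- yy - mean(yy)
      b <- qr.solve(crossprod(x), crossprod(x, yy))
      1 - sum((yy - x %*% b)^2) / sum(yy^2)
    }
    r2 <- r2_of(y)
    yy <- y - mean(y)
    b <- qr.solve(crossprod(x), crossprod(x, yy))
    dir <- as.vector(b) / sqrt(sum(b^2))
    if (exhaustive) {
      perms <- .all_perms(length(y))
      r2s <- apply(perms, 1, function(idx) r2_of(y[idx]))
      p <- mean(r2s >= r2 - 1e-12)
      m_used <- nrow(perms) - 1L
    } else {
      count <- with_seed(seed, {
        sum(vapply(seq_len(n_permutations), function(bb) {
          r2_of(sample(y)) >= r2 - 1e-12
        }, logical(1)))
      })
      p <- (1 + count) / (1 + n_permutations)
      m_used <- as.integer(n_permutations)
    }
    res <- tibble(variable = v, r_squared = r2, p = p, n_used = sum(ok))
    for (a in seq_len(ncol(pts))) res[[paste0("direction_", a)]] <- dir[a]
    res
  })
}
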