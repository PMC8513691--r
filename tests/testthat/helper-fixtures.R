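# Shared fixtures and independent oracles used across the suite. Oracles
# are deliberately written from first principles (enumeration, closed
# forms) and never call the package functions they check.

# small fully annotated dataset: 4 features x 6 samples
toy_dataset <- function() {
  counts <- matrix(
    c(10L, 0L, 5L, 2L, 0L, 0L,
      0L, 8L, 1L, 0L, 3L, 0L,
      4L, 4L, 4L, 4L, 4L, 4L,
      0L, 0L, 0L, 9L, 0L, 7L),
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("ASV", 1:4),
                    c("core1", "core2", "sw1", "df1", "nc1", "nc2"))
  )
  md <- tibble::tibble(
    sample_id = colnames(counts),
    sample_type = c("drill_core", "drill_core", "seawater", "drilling_fluid",
                    "negative_control", "negative_control"),
    core_category = c("DC_1", "DC_3", "none", "none", "none", "none"),
    depth_m = c(30, 100, 10, NA, NA, NA),
    temperature_C = c(25, 120, 11, 10, NA, NA),
    is_control = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  )
  tax <- tibble::tibble(
    feature_id = paste0("ASV", 1:4),
    kingdom = c("Bacteria", "Bacteria", "Bacteria", "Bacteria"),
    phylum = "Proteobacteria", class = "Gammaproteobacteria",
    order = c("Alteromonadales", "Chloroplast", "Alteromonadales", "Alteromonadales"),
    family = "Alteromonadaceae",
    genus = c("Marinobacter", "UNASSIGNED", "Glaciecola", "Colwellia"),
    species = "UNASSIGNED"
  )
  harmonize(counts, md, tax)
}

# published four-set Venn census: the six subaerial-region counts, the
# submarine-and-fluid-only region, and the retained triple overlap, plus
# arbitrary occupancies for the regions the source does not print
reference_census <- function() {
  tibble::tribble(
    ~SUB_A, ~SUB_M, ~DF,    ~SW,    ~n,
    TRUE,   FALSE,  TRUE,   FALSE,  93L,
    TRUE,   FALSE,  FALSE,  TRUE,   84L,
    TRUE,   FALSE,  TRUE,   TRUE,   14L,
    TRUE,   TRUE,   TRUE,   FALSE,  11L,
    TRUE,   TRUE,   FALSE,  TRUE,   16L,
    TRUE,   TRUE,   TRUE,   TRUE,   14L,
    FALSE,  TRUE,   TRUE,   FALSE,  128L,
    FALSE,  TRUE,   TRUE,   TRUE,   61L,
    TRUE,   FALSE,  FALSE,  FALSE,  200L,
    FALSE,  TRUE,   FALSE,  FALSE,  1500L,
    FALSE,  FALSE,  TRUE,   FALSE,  250L,
    FALSE,  FALSE,  FALSE,  TRUE,   300L,
    TRUE,   TRUE,   FALSE,  FALSE,  40L,
    FALSE,  TRUE,   FALSE,  TRUE,   90L,
    FALSE,  FALSE,  TRUE,   TRUE,   150L
  )
}

# two-sided Fisher exact p by direct hypergeometric enumeration for the
# 2x2 table [[a, n_t - a], [b, n_c - b]]
fisher_oracle_p <- function(a, n_t, b, n_c) {
  k <- a + b
  xs <- max(0, k - n_c):min(n_t, k)
  dens <- stats::dhyper(xs, n_t, n_c, k)
  obs <- stats::dhyper(a, n_t, n_c, k)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# all permutations of 1..n, one per row (for exhaustive-permutation oracles)
perms_oracle <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_oracle(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# PERMANOVA pseudo-F via Gower centering and hat-matrix traces — an
# algebraic route independent of the within/among sum decomposition
gower_f_oracle <- function(d, groups) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  j <- diag(n) - matrix(1 / n, n, n)
  g <- -0.5 * j %*% d2 %*% j
  x <- stats::model.matrix(~ factor(groups))
  h <- x %*% solve(crossprod(x)) %*% t(x)
  k <- length(unique(groups))
  ss_among <- sum(diag(h %*% g %*% h))
  ss_resid <- sum(diag((diag(n) - h) %*% g %*% (diag(n) - h)))
  (ss_among / (k - 1)) / (ss_resid / (n - k))
}

# Kruskal stress-1 recomputed from scratch for a given configuration
stress_oracle <- function(points, d) {
  delta <- as.vector(stats::as.dist(as.matrix(d)))
  dhat <- as.vector(stats::dist(points))
  ord <- order(delta, dhat)
  disp <- numeric(length(dhat))
  disp[ord] <- stats::isoreg(dhat[ord])$yf
  sqrt(sum((dhat - disp)^2) / sum(dhat^2))
}
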