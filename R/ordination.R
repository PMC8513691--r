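#' Bray-Curtis dissimilarity matrix
#'
#' `d(j, k) = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik)` between sample
#' columns; values in [0, 1], invariant to joint scaling of both samples.
#'
#' @param counts Features x samples matrix (counts or relative abundances),
#'   >= 2 samples, no all-zero sample.
#' @return A `dist` object over the samples.
#' @export
bray_curtis <- function(counts) {
  if (ncol(counts) < 2) abort("Bray-Curtis requires at least 2 samples")
  zero <- colSums(counts) == 0
  if (any(zero)) {
    abort(paste0("all-zero sample '", colnames(counts)[zero][1],
                 "': Bray-Curtis undefined"))
  }
  vegan::vegdist(t(counts), method = "bray")
}

# Kruskal stress-1 of a configuration against dissimilarities delta:
# sqrt(sum((dhat - disp)^2) / sum(dhat^2)) with disp the isotonic (PAV)
# regression of dhat on the rank order of delta (primary tie approach:
# ties in delta broken by dhat)
.stress1 <- function(conf, delta) {
  dhat <- as.vector(dist(conf))
  ord <- order(delta, dhat)
  disp <- numeric(length(dhat))
  disp[ord] <- isoreg(dhat[ord])$yf
  denom <- sum(dhat^2)
  if (denom == 0) return(1)
  list(stress = sqrt(sum((dhat - disp)^2) / denom), dhat = dhat, disp = disp)
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Embeds a dissimilarity matrix in `k` dimensions by minimizing Kruskal's
#' stress-1, the monotone misfit between embedding distances and the rank
#' order of the input dissimilarities. Disparities come from
#' pool-adjacent-violators isotonic regression (primary tie handling);
#' configurations are updated by iterative majorization (Guttman
#' transform), accepting an update only when stress decreases, so the
#' stress trace within a restart is non-increasing by construction. The
#' first restart starts from the classical metric-scaling solution, the
#' remaining restarts from random Gaussian configurations; the best
#' restart wins. Deterministic for a fixed seed.
#'
#' @param d A `dist` or symmetric matrix of dissimilarities (all finite).
#' @param k Embedding dimension (default 2); requires `n >= k + 1`.
#' @param n_restarts Number of starts (default 20).
#' @param max_iter Majorization iterations per restart.
#' @param tol Relative stress-improvement convergence tolerance.
#' @param seed Integer seed for the random restarts.
#' @return A `tephra_nmds` object: `points` (n x k, centered and rotated to
#'   principal axes), `stress`, `stress_trace` (best restart), `n_restarts`,
#'   `converged`, `sample_ids`.
#' @export
nmds <- function(d, k = 2, n_restarts = 20, max_iter = 300, tol = 1e-7, seed = 1) {
  m <- as.matrix(d)
  if (any(!is.finite(m))) abort("non-finite dissimilarities")
  n <- nrow(m)
  if (n < k + 1) abort("NMDS requires at least k + 1 samples")
  ids <- rownames(m) %||% paste0("s", seq_len(n))
  delta <- as.vector(as.dist(m))

  run_one <- function(conf) {
    st <- .stress1(conf, delta)
    trace <- st$stress
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      dhat <- st$dhat
      dhat[dhat == 0] <- 1e-12
      ratio <- st$disp / dhat
      bm <- matrix(0, n, n)
      bm[lower.tri(bm)] <- -ratio
      bm <- bm + t(bm)
      diag(bm) <- -rowSums(bm)
      new_conf <- bm %*% conf / n
      new_st <- .stress1(new_conf, delta)
      if (new_st$stress > st$stress) {
        # no improving majorization step left: local optimum reached
        converged <- TRUE
        break
      }
      improved <- st$stress - new_st$stress
      conf <- new_conf
      st <- new_st
      trace <- c(trace, st$stress)
      if (improved < tol) {  # stress is already on a [0, 1] scale
        converged <- TRUE
        break
      }
    }
    list(conf = conf, stress = st$stress, trace = trace, converged = converged)
  }

  best <- with_seed(seed, {
    init <- cmdscale(as.dist(m), k = k, list. = TRUE)$points
    if (ncol(init) < k) {
      init <- cbind(init, matrix(0, n, k - ncol(init)))
    }
    best <- run_one(scale(init, scale = FALSE))
    if (n_restarts > 1) {
      for (r in seq_len(n_restarts - 1)) {
        cand <- run_one(matrix(rnorm(n * k, sd = max(delta, 1e-9)), n, k))
        if (cand$stress < best$stress) best <- cand
      }
    }
    best
  })

  # center and rotate to principal axes (stress is invariant)
  pts <- scale(best$conf, scale = FALSE)
  pts <- pts %*% svd(pts)$v
  rownames(pts) <- ids
  colnames(pts) <- paste0("NMDS", seq_len(k))
  structure(
    list(points = pts, stress = .stress1(pts, delta)$stress,
         stress_trace = best$trace, n_restarts = n_restarts,
         converged = best$converged, sample_ids = ids),
    class = "tephra_nmds"
  )
}

#' @export
print.tephra_nmds <- function(x, ...) {
  cat("<tephra_nmds> ", length(x$sample_ids), " samples in ",
      ncol(x$points), " dimensions; stress = ", signif(x$stress, 4),
      if (x$converged) " (converged)" else " (not converged)", "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.tephra_nmds <- function(x, ...) {
  dplyr::bind_cols(tibble(sample_id = x$sample_ids), as_tibble(x$points))
}

#' @export
glance.tephra_nmds <- function(x, ...) {
  tibble(stress = x$stress, k = ncol(x$points), n_samples = length(x$sample_ids),
         n_restarts = x$n_restarts, converged = x$converged)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Ordination plot of an NMDS result
#'
#' @param object A `tephra_nmds`.
#' @param metadata Optional metadata tibble with `sample_id` used to colour
#'   points by `colour_by`.
#' @param colour_by Metadata column name (default `"sample_type"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tephra_nmds <- function(object, metadata = NULL,
                                 colour_by = "sample_type", ...) {
  df <- tidy(object)
  p <- if (!is.null(metadata) && colour_by %in% names(metadata)) {
    df <- dplyr::left_join(df, metadata, by = "sample_id")
    ggplot2::ggplot(df, ggplot2::aes(.data$NMDS1, .data$NMDS2,
                                     colour = .data[[colour_by]]))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$NMDS1, .data$NMDS2))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      subtitle = sprintf("stress = %.3f", object$stress),
      x = "NMDS1", y = "NMDS2"
    ) +
    ggplot2::theme_minimal()
}

#' Boxplot of alpha diversity by group
#'
#' @param alpha Tibble from [alpha_diversity()].
#' @param metadata Metadata tibble with `sample_id`.
#' @param group_by Metadata column for the x axis.
#' @return A ggplot (richness and Shannon panels).
#' @export
plot_alpha_diversity <- function(alpha, metadata, group_by = "sample_type") {
  df <- dplyr::left_join(alpha, metadata, by = "sample_id") |>
    tidyr::pivot_longer(c("richness", "shannon"),
                        names_to = "index", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data[[group_by]], .data$value,
                                   fill = .data[[group_by]])) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
                   legend.position = "none") +
    ggplot2::labs(x = NULL, y = NULL)
}
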