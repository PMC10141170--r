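#' Shannon alpha diversity of one community
#'
#' `H = -sum p_i log(p_i)` over taxa with positive abundance; natural log by
#' default. Delegates to [vegan::diversity()].
#'
#' @param x Non-negative abundance vector (counts or proportions) with a
#'   positive sum.
#' @param base Logarithm base (default `exp(1)`).
#' @return H >= 0.
#' @examples
#' shannon_diversity(c(1, 1, 2))  # 1.0397
#' @export
shannon_diversity <- function(x, base = exp(1)) {
  if (any(x < 0) || sum(x) <= 0) abort("`x` must be non-negative with a positive sum")
  unname(vegan::diversity(x, index = "shannon", base = base))
}

#' Per-sample Shannon diversity of an abundance table
#'
#' @param abundance Long tibble: feature column (first), `sample`, and an
#'   abundance column (`count` or `rel_abundance`; the last column is used).
#' @param base Logarithm base.
#' @return Tibble `sample`, `shannon`.
#' @export
sample_diversity <- function(abundance, base = exp(1)) {
  value <- names(abundance)[ncol(abundance)]
  abundance |>
    group_by(.data$sample) |>
    summarise(shannon = shannon_diversity(.data[[value]], base = base),
              .groups = "drop")
}

#' Bray-Curtis dissimilarity between two communities
#'
#' `d = sum |x_i - y_i| / sum (x_i + y_i)`, in \[0, 1\]. Delegates to
#' [vegan::vegdist()].
#'
#' @param x,y Non-negative abundance vectors over the same taxa, positive
#'   sums.
#' @return Dissimilarity in \[0, 1\].
#' @examples
#' bray_curtis(c(2, 0), c(1, 1))  # 0.5
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have the same length")
  if (sum(x) <= 0 || sum(y) <= 0) abort("both communities need a positive total")
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

#' Bray-Curtis distance matrix of an abundance table
#'
#' @inheritParams sample_diversity
#' @return A symmetric `matrix` of pairwise dissimilarities, samples in
#'   rows/columns.
#' @export
bray_curtis_matrix <- function(abundance) {
  value <- names(abundance)[ncol(abundance)]
  feature <- names(abundance)[1]
  wide <- tidyr::pivot_wider(abundance, names_from = dplyr::all_of(feature),
                             values_from = dplyr::all_of(value),
                             values_fill = 0)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$sample
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers `-D^2/2` and eigendecomposes it ([stats::cmdscale()]),
#' returning coordinate axes for the positive eigenvalues sorted in
#' decreasing order, with the percent variance each explains (relative to
#' the sum of positive eigenvalues).
#'
#' @param D Symmetric distance matrix with zero diagonal (or a `dist`).
#' @return Object of class `gm_pcoa`: `points` (tibble `sample`, `Axis1`,
#'   ...), `eigenvalues`, `variance_explained` (percent per retained axis).
#' @export
pcoa <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) abort("`D` must be symmetric")
  if (any(abs(diag(D)) > 1e-8)) abort("`D` must have a zero diagonal")
  n <- nrow(D)
  sc <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = n - 1,
                                         eig = TRUE))
  eig <- sc$eig
  keep <- which(eig > max(eig) * 1e-8)
  pts <- sc$points[, keep, drop = FALSE]
  colnames(pts) <- paste0("Axis", seq_along(keep))
  samples <- rownames(D) %||% paste0("s", seq_len(n))
  structure(
    list(points = bind_cols(tibble(sample = samples), as_tibble(pts)),
         eigenvalues = eig,
         variance_explained = 100 * eig[keep] / sum(eig[keep])),
    class = "gm_pcoa"
  )
}

#' @export
print.gm_pcoa <- function(x, ...) {
  cat("PCoA:", nrow(x$points), "samples,", ncol(x$points) - 1, "axes;",
      "Axis1 explains", round(x$variance_explained[1], 1), "% of variance\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gm_pcoa <- function(x, ...) x$points

#' @exportS3Method generics::glance
glance.gm_pcoa <- function(x, ...) {
  tibble(n_samples = nrow(x$points),
         n_axes = ncol(x$points) - 1,
         var_axis1 = x$variance_explained[1],
         var_axis2 = if (length(x$variance_explained) > 1)
           x$variance_explained[2] else NA_real_)
}

#' Ordination plot of a PCoA result
#'
#' @param object A `gm_pcoa`.
#' @param metadata Optional tibble `sample`, `condition` used to colour
#'   points.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.gm_pcoa <- function(object, metadata = NULL, ...) {
  pts <- object$points
  if (!"Axis2" %in% names(pts)) pts$Axis2 <- 0
  if (!is.null(metadata)) {
    pts <- left_join(pts, metadata[, c("sample", "condition")], by = "sample")
  }
  lab <- function(i) {
    v <- object$variance_explained
    if (i > length(v)) paste("Axis", i)
    else sprintf("Axis %d (%.1f%%)", i, v[i])
  }
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data$Axis1, .data$Axis2)) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
  if (!is.null(metadata)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$condition), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}
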