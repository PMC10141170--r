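#' Replace zero counts by a pseudo value
#'
#' Zero entries are replaced by `pseudo` (default half a read) before
#' conversion to relative abundances, so that cross-condition fold ratios
#' are always defined. Non-zero entries are untouched; the replaced cells
#' are recorded in the `pseudo_cells` attribute.
#'
#' @param counts Long tibble: feature column (first), `sample`, `count`.
#' @param pseudo Positive replacement value (default 0.5).
#' @return `counts` with zeros replaced; attribute `pseudo_cells` holds the
#'   affected (feature, sample) pairs.
#' @export
apply_pseudocount <- function(counts, pseudo = 0.5) {
  if (!is.numeric(pseudo) || pseudo <= 0) abort("`pseudo` must be > 0")
  feature <- names(counts)[1]
  zero <- counts$count == 0
  out <- mutate(counts, count = if_else(.data$count == 0, pseudo,
                                        as.numeric(.data$count)))
  attr(out, "pseudo_cells") <- counts[zero, c(feature, "sample")]
  attr(out, "pseudo") <- pseudo
  out
}

#' Classify modulation by a fold-change cutoff
#'
#' Scores the ratio of treatment to control mean abundance against a
#' five-fold cutoff: `increased` if `fold_ratio >= cutoff`, `reduced` if
#' `fold_ratio <= 1/cutoff`, else `unchanged`. Both bounds are inclusive.
#' Swapping treatment and control maps increased to reduced and back.
#'
#' @param mean_treatment,mean_control Positive means (after pseudocounts).
#' @param cutoff Fold cutoff > 1 (default 5).
#' @return Tibble `fold_ratio`, `call` (factor increased/unchanged/reduced).
#' @export
classify_modulation <- function(mean_treatment, mean_control, cutoff = 5) {
  if (cutoff <= 1) abort("`cutoff` must be > 1")
  if (any(mean_treatment <= 0) || any(mean_control <= 0)) {
    abort("means must be positive; apply a pseudocount first")
  }
  ratio <- unname(mean_treatment / mean_control)
  call <- dplyr::case_when(ratio >= cutoff ~ "increased",
                           ratio <= 1 / cutoff ~ "reduced",
                           TRUE ~ "unchanged")
  tibble(fold_ratio = ratio,
         call = factor(call, levels = c("increased", "unchanged", "reduced")))
}

#' Per-phylotype modulation and significance versus control
#'
#' For each non-control condition and phylotype: replicate-mean relative
#' abundances in treatment and control, the fold ratio and its five-fold
#' call ([classify_modulation()]), and an exact Mann-Whitney p-value across
#' replicates ([mann_whitney_exact()]); optionally a Welch t-test p-value.
#' No multiple-testing correction is applied.
#'
#' Zeros are handled by [apply_pseudocount()] on the count scale before
#' conversion to relative abundance, mirroring the use of pseudo values for
#' absent taxa; the `used_pseudo` flag marks phylotypes whose fold ratio
#' involved at least one replaced cell.
#'
#' @param counts Long tibble `phylotype`, `sample`, `count` (raw counts,
#'   e.g. from [collapse_phylotypes()]).
#' @param metadata Tibble `sample`, `condition`.
#' @param control Name of the control condition.
#' @param copy_numbers Optional tibble `phylotype`, `copy_number` for 16S
#'   copy-number renormalization before analysis.
#' @param cutoff Fold cutoff (default 5).
#' @param pseudo Pseudocount for zero cells (default 0.5).
#' @param alpha Significance level (default 0.05).
#' @param t_test Also compute a Welch t-test p-value (default FALSE).
#' @return Tibble of class `modulation_stats`: `condition`, `phylotype`,
#'   `mean_control`, `mean_treatment`, `fold_ratio`, `call`, `used_pseudo`,
#'   `p_mw`, (`p_t`,) `significant`, `direction`.
#' @export
modulation_stats <- function(counts, metadata, control = "control",
                             copy_numbers = NULL, cutoff = 5, pseudo = 0.5,
                             alpha = 0.05, t_test = FALSE) {
  stopifnot(all(c("phylotype", "sample", "count") %in% names(counts)))
  if (!control %in% metadata$condition) {
    abort(paste0("control condition '", control, "' not found in metadata"))
  }
  counts <- tidyr::complete(counts, .data$phylotype, .data$sample,
                            fill = list(count = 0))
  ps <- apply_pseudocount(counts, pseudo)
  pseudo_cells <- attr(ps, "pseudo_cells")
  rel <- if (is.null(copy_numbers)) {
    ps |>
      group_by(.data$sample) |>
      mutate(rel_abundance = .data$count / sum(.data$count)) |>
      ungroup() |>
      select(-"count")
  } else {
    renormalize_abundances(ps, copy_numbers)
  }
  rel <- inner_join(rel, metadata[, c("sample", "condition")], by = "sample")

  # matrix layout: phylotypes x samples, fast group-wise tests
  wide <- tidyr::pivot_wider(rel[, c("phylotype", "sample", "rel_abundance")],
                             names_from = "sample",
                             values_from = "rel_abundance", values_fill = 0)
  m <- as.matrix(wide[, -1]); rownames(m) <- wide$phylotype
  sample_cond <- setNames(metadata$condition, metadata$sample)[colnames(m)]
  ctrl_m <- m[, sample_cond == control, drop = FALSE]
  had_pseudo <- pseudo_cells |>
    left_join(metadata[, c("sample", "condition")], by = "sample") |>
    distinct(.data$phylotype, .data$condition)

  res <- purrr::map(setdiff(unique(sample_cond), control), function(cond) {
    trt_m <- m[, sample_cond == cond, drop = FALSE]
    mc <- unname(rowMeans(ctrl_m)); mt <- unname(rowMeans(trt_m))
    cls <- classify_modulation(mt, mc, cutoff)
    tests <- purrr::map(seq_len(nrow(m)), function(i) {
      mann_whitney_exact(trt_m[i, ], ctrl_m[i, ])
    })
    out <- tibble(
      condition = cond, phylotype = rownames(m),
      mean_control = mc, mean_treatment = mt,
      fold_ratio = cls$fold_ratio, call = cls$call,
      p_mw = purrr::map_dbl(tests, "p_value"),
      direction = purrr::map_dbl(tests, "direction")
    )
    if (t_test) {
      out$p_t <- purrr::map_dbl(seq_len(nrow(m)), function(i) {
        t_test_groups(trt_m[i, ], ctrl_m[i, ])$p_value
      })
    }
    out
  })
  out <- purrr::list_rbind(res) |>
    mutate(significant = .data$p_mw < alpha) |>
    left_join(mutate(had_pseudo, used_pseudo = TRUE),
              by = c("phylotype", "condition")) |>
    mutate(used_pseudo = !is.na(.data$used_pseudo))
  ctrl_pseudo <- unique(had_pseudo$phylotype[had_pseudo$condition == control])
  out$used_pseudo <- out$used_pseudo | out$phylotype %in% ctrl_pseudo
  attr(out, "alpha") <- alpha
  attr(out, "cutoff") <- cutoff
  attr(out, "pseudo") <- pseudo
  class(out) <- c("modulation_stats", class(out))
  out
}

#' Number of altered phylotypes per condition
#'
#' Counts modulation calls that are not `unchanged` (the "altered
#' phylotypes" summary of modulatory capacity).
#'
#' @param stats A `modulation_stats` tibble.
#' @param require_significant Additionally require the Mann-Whitney p-value
#'   below the stored `alpha` (default FALSE: the five-fold call alone).
#' @return Tibble `condition`, `n_altered`.
#' @export
count_altered <- function(stats, require_significant = FALSE) {
  x <- filter(stats, .data$call != "unchanged")
  if (require_significant) x <- filter(x, .data$significant)
  tidyr::complete(
    x |>
      group_by(.data$condition) |>
      summarise(n_altered = dplyr::n(), .groups = "drop"),
    condition = unique(stats$condition),
    fill = list(n_altered = 0L)
  )
}

#' Bar chart of altered-phylotype counts per condition
#'
#' @param stats A `modulation_stats` tibble.
#' @param ... Passed to [count_altered()].
#' @return A ggplot.
#' @export
plot_modulation_counts <- function(stats, ...) {
  counts <- count_altered(stats, ...)
  ggplot2::ggplot(counts,
                  ggplot2::aes(stats::reorder(.data$condition,
                                              -.data$n_altered),
                               .data$n_altered)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "altered phylotypes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
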