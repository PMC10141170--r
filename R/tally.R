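#' Instance accounting of responses across taxa and treatments
#'
#' The bookkeeping used when tabulating how often a family of related taxa
#' responded across treatments: with `k` taxon groups profiled against `m`
#' treatments there are `k * m` taxon-treatment combinations ("instances");
#' the tally reports how many were statistically significant (and the
#' percentage), and, per treatment class, how many instances moved in each
#' direction out of that class's `k * m_class` combinations.
#'
#' @param responses Tibble with one row per taxon-treatment combination:
#'   columns `taxon`, `treatment`, `significant` (logical), `direction`
#'   (+1 / -1 / 0; only significant rows are counted directionally).
#' @param classes Tibble `treatment`, `class` assigning each treatment to a
#'   class (e.g. prebiotic vs herb).
#' @return List of class `response_tally`: `summary` (one row: `n_taxa`,
#'   `n_treatments`, `n_combinations`, `n_significant`, `pct_significant`)
#'   and `by_class` (per class and direction: `n`, `n_combinations`,
#'   `pct`). Percentages are exact; print rounds to whole percent.
#' @export
tally_response_instances <- function(responses, classes) {
  need <- c("taxon", "treatment", "significant", "direction")
  miss <- setdiff(need, names(responses))
  if (length(miss)) abort(paste0("`responses` lacks: ",
                                 paste(miss, collapse = ", ")))
  taxa <- unique(responses$taxon)
  treatments <- unique(responses$treatment)
  n_comb <- length(taxa) * length(treatments)
  n_sig <- sum(responses$significant)
  by_class <- responses |>
    filter(.data$significant) |>
    inner_join(classes, by = "treatment") |>
    group_by(.data$class,
             direction = if_else(.data$direction > 0, "increased",
                                 "decreased")) |>
    summarise(n = dplyr::n(), .groups = "drop") |>
    left_join(classes |>
                filter(.data$treatment %in% treatments) |>
                group_by(.data$class) |>
                summarise(n_treatments = dplyr::n(), .groups = "drop"),
              by = "class") |>
    mutate(n_combinations = .data$n_treatments * length(taxa),
           pct = 100 * .data$n / .data$n_combinations)
  structure(
    list(summary = tibble(n_taxa = length(taxa),
                          n_treatments = length(treatments),
                          n_combinations = n_comb,
                          n_significant = n_sig,
                          pct_significant = 100 * n_sig / n_comb),
         by_class = by_class),
    class = "response_tally"
  )
}

#' @export
print.response_tally <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%d taxa x %d treatments = %d combinations; %d significant (%d%%)\n",
              s$n_taxa, s$n_treatments, s$n_combinations, s$n_significant,
              round(s$pct_significant)))
  b <- mutate(x$by_class, pct = round(.data$pct))
  print(b, n = Inf)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.response_tally <- function(x, ...) x$by_class

#' @exportS3Method generics::glance
glance.response_tally <- function(x, ...) x$summary
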