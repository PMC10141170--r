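#' Responder sets: taxa significantly increased by each treatment
#'
#' A treatment's responder set contains the phylotypes whose Mann-Whitney
#' p-value falls below `alpha` with a positive direction (treatment mean
#' above control mean). The decreased direction is available but off by
#' default.
#'
#' @param stats A `modulation_stats` tibble (all computed against the same
#'   control).
#' @param alpha Significance level (default 0.05).
#' @param direction `"increased"` (default) or `"decreased"`.
#' @return Tibble `treatment`, `phylotype`, one row per responder.
#' @export
responder_sets <- function(stats, alpha = 0.05, direction = "increased") {
  direction <- match.arg(direction, c("increased", "decreased"))
  sgn <- if (direction == "increased") 1 else -1
  stats |>
    filter(.data$p_mw < alpha,
           sign(.data$mean_treatment - .data$mean_control) == sgn) |>
    select(treatment = "condition", "phylotype")
}

#' Pairwise overlap f-score of two responder sets
#'
#' `o` is the number of taxa increased by both treatments, `s` the sum of
#' the two set sizes, and `f = 100 * o / s`, bounded above by 50 (reached
#' only for identical non-empty sets). When both sets are empty (`s = 0`),
#' `f` is undefined and reported as `NA`, distinguishing "no responders"
#' from "no overlap".
#'
#' @param a,b Character vectors of phylotype names (taxa are matched by
#'   exact display name, multi-names included).
#' @return Tibble `o`, `s`, `f`.
#' @examples
#' f_score(c("a", "b", "c"), c("b", "c", "d", "e"))  # o=2, s=7, f=28.57
#' @export
f_score <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  o <- length(intersect(a, b))
  s <- length(a) + length(b)
  tibble(o = o, s = s, f = if (s > 0) 100 * o / s else NA_real_)
}

#' All pairwise f-scores between treatments
#'
#' Computes [f_score()] for every unordered treatment pair (12 treatments
#' give 66 pairs).
#'
#' @param responders Tibble `treatment`, `phylotype` from
#'   [responder_sets()].
#' @param treatments Optional character vector fixing the treatment roster
#'   (so treatments with empty responder sets still appear); duplicate
#'   names are an error.
#' @return Tibble of class `fscore_pairs`: `treatment_a`, `treatment_b`,
#'   `o`, `s`, `f`.
#' @export
pairwise_f_scores <- function(responders, treatments = NULL) {
  treatments <- treatments %||% unique(responders$treatment)
  if (anyDuplicated(treatments)) {
    abort("duplicate treatment names in the roster")
  }
  if (length(treatments) < 2) abort("need at least two treatments")
  sets <- purrr::map(setNames(treatments, treatments), function(tr) {
    responders$phylotype[responders$treatment == tr]
  })
  pairs <- utils::combn(treatments, 2)
  out <- purrr::map(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    bind_cols(tibble(treatment_a = a, treatment_b = b),
              f_score(sets[[a]], sets[[b]]))
  }) |> purrr::list_rbind()
  class(out) <- c("fscore_pairs", class(out))
  out
}

#' Square (symmetric) f-score matrix
#'
#' @param fscores An `fscore_pairs` tibble.
#' @return A symmetric numeric matrix of f values with `NA` diagonal.
#' @export
fscore_matrix <- function(fscores) {
  treatments <- sort(unique(c(fscores$treatment_a, fscores$treatment_b)))
  m <- matrix(NA_real_, length(treatments), length(treatments),
              dimnames = list(treatments, treatments))
  m[cbind(fscores$treatment_a, fscores$treatment_b)] <- fscores$f
  m[cbind(fscores$treatment_b, fscores$treatment_a)] <- fscores$f
  m
}

#' Per-prebiotic profile of f-scores against medicinal herbs
#'
#' Restricts an f-score table to prebiotic-herb pairs, keeps pairs whose f
#' exceeds `threshold` strictly, and summarises per prebiotic: the herbs
#' hit, their number, and the mean and range of those f values.
#'
#' @param fscores An `fscore_pairs` tibble.
#' @param classes Tibble `treatment`, `class` with classes among
#'   `prebiotic`, `herb`, `mucin`, `control` (e.g.
#'   [read_treatment_metadata()]).
#' @param threshold Strict lower bound on f (default 10).
#' @return Tibble `prebiotic`, `n_herbs`, `herbs` (list-column), `mean_f`,
#'   `min_f`, `max_f`; prebiotics with no qualifying herb keep `n_herbs =
#'   0` and `NA` summaries.
#' @export
prebiotic_herb_profile <- function(fscores, classes, threshold = 10) {
  cls <- setNames(classes$class, classes$treatment)
  x <- fscores |>
    mutate(class_a = cls[.data$treatment_a], class_b = cls[.data$treatment_b]) |>
    filter((.data$class_a == "prebiotic" & .data$class_b == "herb") |
             (.data$class_a == "herb" & .data$class_b == "prebiotic")) |>
    mutate(prebiotic = if_else(.data$class_a == "prebiotic",
                               .data$treatment_a, .data$treatment_b),
           herb = if_else(.data$class_a == "prebiotic",
                          .data$treatment_b, .data$treatment_a))
  hits <- x |>
    filter(!is.na(.data$f), .data$f > threshold) |>
    group_by(.data$prebiotic) |>
    summarise(n_herbs = dplyr::n(), herbs = list(sort(.data$herb)),
              mean_f = mean(.data$f), min_f = min(.data$f),
              max_f = max(.data$f), .groups = "drop")
  all_pre <- sort(unique(x$prebiotic))
  left_join(tibble(prebiotic = all_pre), hits, by = "prebiotic") |>
    mutate(n_herbs = dplyr::coalesce(.data$n_herbs, 0L),
           herbs = purrr::map(.data$herbs, ~ .x %||% character()))
}

#' Heat map of pairwise f-scores
#'
#' @param fscores An `fscore_pairs` tibble.
#' @return A ggplot tile plot.
#' @export
plot_fscore_heatmap <- function(fscores) {
  m <- fscore_matrix(fscores)
  long <- as_tibble(as.table(m), .name_repair = ~ c("a", "b", "f"))
  ggplot2::ggplot(long, ggplot2::aes(.data$a, .data$b, fill = .data$f)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 50), na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "f%") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Read the treatment metadata table
#'
#' The packaged treatment roster (prebiotic group, sugar composition, and
#' linkage for each culture condition) ships at
#' `system.file("extdata", "treatments.tsv", package = "glycomod")`.
#'
#' @param path TSV with columns `treatment`, `class`, `group`, `sugar`,
#'   `linkage`.
#' @return Tibble with those columns; `class` validated against
#'   prebiotic/herb/mucin/control, `group` against \{1, 1a, 2, 3, 4, 5,
#'   NA\}.
#' @export
read_treatment_metadata <- function(path = system.file("extdata",
                                                       "treatments.tsv",
                                                       package = "glycomod")) {
  md <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("treatment", "class", "group", "sugar", "linkage")
  miss <- setdiff(need, names(md))
  if (length(miss)) abort(paste0("treatment metadata lacks: ",
                                 paste(miss, collapse = ", ")))
  if (!all(md$class %in% c("prebiotic", "herb", "mucin", "control"))) {
    abort("treatment class must be prebiotic/herb/mucin/control")
  }
  if (!all(is.na(md$group) | md$group %in% c("1", "1a", "2", "3", "4", "5"))) {
    abort("prebiotic group must be one of 1, 1a, 2, 3, 4, 5 or NA")
  }
  md
}
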