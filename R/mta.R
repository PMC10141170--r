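#' Multi-taxonomy assignment identity threshold
#'
#' For an ASV whose best alignment identity is `M`, the admission window for
#' additional reference taxa extends down to `M - (1 - M) / 4`: the closer
#' the best hit is to a perfect match, the narrower the window. At `M = 1`
#' the window closes entirely and only perfect matches qualify.
#'
#' @param M Numeric vector of best-hit identities, fractions in (0, 1].
#' @return Numeric vector of thresholds, same length as `M`.
#' @examples
#' mta_threshold(c(1, 0.96, 0.90))  # 1.000 0.950 0.875
#' @export
mta_threshold <- function(M) {
  if (!is.numeric(M) || any(is.na(M)) || any(M <= 0 | M > 1)) {
    abort("`M` must be numeric in (0, 1]")
  }
  M - (1 - M) / 4
}

#' Assign multi-taxonomy names to ASVs from alignment hits
#'
#' Implements the multi-taxonomy approach (MTA): per ASV, hits are sorted by
#' percent identity; with `M` the maximum identity, every reference whose
#' identity exceeds `mta_threshold(M)` strictly is admitted, and the
#' hit(s) achieving `M` itself are always admitted (so the assignment is
#' never empty and always contains the best hit). Members are de-duplicated
#' by full lineage and the display name is the sorted, `"/"`-joined set of
#' member species labels (falling back to the most specific available label
#' where the species field is missing).
#'
#' Identities are rounded to `digits` decimal places before comparison so
#' that tabular identity columns carrying 2-3 decimals do not produce
#' float-noise ties.
#'
#' @param hits Tibble from [read_hit_table()]: `asv_id`, `ref_id`,
#'   `identity`.
#' @param taxonomy Tibble from [read_taxonomy()]: `ref_id` plus rank columns.
#' @param digits Decimal places for identity comparison (default 6).
#' @return Tibble of class `mta_assignments`, one row per ASV: `asv_id`,
#'   `max_identity`, `threshold`, `n_members`, `display_name`, and a
#'   `members` list-column of lineage tibbles (with `ref_id` and
#'   `identity`).
#' @export
assign_taxonomy <- function(hits, taxonomy, digits = 6) {
  stopifnot(is.data.frame(hits), is.data.frame(taxonomy))
  if (nrow(hits) == 0) {
    out <- tibble(asv_id = character(), max_identity = double(),
                  threshold = double(), n_members = integer(),
                  display_name = character(), members = list())
    class(out) <- c("mta_assignments", class(out))
    return(out)
  }
  missing_refs <- setdiff(unique(hits$ref_id), taxonomy$ref_id)
  if (length(missing_refs)) {
    abort(paste0("hit table references unknown ref_id(s): ",
                 paste(sort(missing_refs), collapse = ", ")))
  }
  hits <- mutate(hits, identity = round(.data$identity, digits))
  lin <- taxonomy[, c("ref_id", taxonomic_ranks)]

  one_asv <- function(h) {
    M <- max(h$identity)
    t <- round(mta_threshold(M), digits)
    adm <- h$identity > t | h$identity == M
    members <- inner_join(h[adm, c("ref_id", "identity")], lin, by = "ref_id")
    members <- distinct(members, across(dplyr::all_of(taxonomic_ranks)),
                        .keep_all = TRUE)
    sp <- if_else(is.na(members$species), deepest_label(members),
                  members$species)
    sp[is.na(sp)] <- "unclassified"
    tibble(max_identity = M, threshold = t,
           n_members = nrow(members),
           display_name = paste(sort(unique(sp)), collapse = "/"),
           members = list(members))
  }

  out <- hits |>
    tidyr::nest(.by = "asv_id", .key = "h") |>
    mutate(res = purrr::map(.data$h, one_asv)) |>
    select(-"h") |>
    tidyr::unnest("res")
  class(out) <- c("mta_assignments", class(out))
  out
}

# Member labels of one assignment at a given rank, NA -> "unclassified"
member_labels_at_rank <- function(members, rank) {
  labs <- members[[rank]]
  labs[is.na(labs)] <- "unclassified"
  sort(unique(labs))
}

#' Collapse ASV counts into phylotypes at a taxonomic rank
#'
#' Each ASV's counts are added whole and undivided to exactly one phylotype:
#' the shared label if all assignment members agree at `rank`, otherwise the
#' sorted `"/"`-joined multi-name of the member labels at that rank. ASVs
#' absent from `assignments` (e.g. no alignment hits) are retained under the
#' phylotype `"unclassified"`. Column sums are conserved exactly.
#'
#' @param counts Long tibble `asv_id`, `sample`, `count`.
#' @param assignments An `mta_assignments` tibble from [assign_taxonomy()].
#' @param rank Rank at which to collapse (one of [taxonomic_ranks]).
#' @return Long tibble `phylotype`, `sample`, `count`, with attributes
#'   `rank` and `provenance` (tibble `asv_id` -> `phylotype`).
#' @export
collapse_phylotypes <- function(counts, assignments, rank = "species") {
  check_rank(rank)
  stopifnot(all(c("asv_id", "sample", "count") %in% names(counts)))
  name_of <- purrr::map_chr(assignments$members, function(m) {
    paste(member_labels_at_rank(m, rank), collapse = "/")
  })
  map <- tibble(asv_id = assignments$asv_id, phylotype = name_of)
  prov <- left_join(tibble(asv_id = unique(counts$asv_id)), map, by = "asv_id")
  prov$phylotype[is.na(prov$phylotype)] <- "unclassified"
  out <- counts |>
    left_join(prov, by = "asv_id") |>
    group_by(.data$phylotype, .data$sample) |>
    summarise(count = sum(.data$count), .groups = "drop")
  attr(out, "rank") <- rank
  attr(out, "provenance") <- prov
  out
}

#' Census of phylotypes across culture conditions
#'
#' A phylotype is present in a condition if any replicate has abundance at or
#' above `presence_floor` (default one count). Reports the de-duplicated
#' total across conditions, per-condition richness, and the mean richness
#' per condition.
#'
#' @param phylotypes Long tibble `phylotype`, `sample`, `count` (all
#'   collapsed at the same rank).
#' @param metadata Tibble `sample`, `condition`.
#' @param presence_floor Minimum abundance to count as present (default 1).
#' @return List of class `phylotype_census`: `total_unique`,
#'   `per_condition` (tibble `condition`, `n_phylotypes`),
#'   `mean_per_condition`.
#' @export
count_phylotypes <- function(phylotypes, metadata, presence_floor = 1) {
  stopifnot(presence_floor >= 0)
  present <- phylotypes |>
    inner_join(metadata[, c("sample", "condition")], by = "sample") |>
    group_by(.data$condition, .data$phylotype) |>
    summarise(present = any(.data$count >= presence_floor), .groups = "drop") |>
    filter(.data$present)
  per <- present |>
    group_by(.data$condition) |>
    summarise(n_phylotypes = dplyr::n(), .groups = "drop")
  structure(
    list(total_unique = dplyr::n_distinct(present$phylotype),
         per_condition = per,
         mean_per_condition = mean(per$n_phylotypes)),
    class = "phylotype_census"
  )
}

#' @export
print.phylotype_census <- function(x, ...) {
  cat("Phylotype census:", x$total_unique, "unique phylotypes;",
      "mean", round(x$mean_per_condition, 1), "per condition\n")
  print(x$per_condition, n = Inf)
  invisible(x)
}

#' Flat assignment report suitable for TSV export
#'
#' @param assignments An `mta_assignments` tibble.
#' @return Tibble `asv_id`, `max_identity`, `threshold`, `n_members`,
#'   `display_name`.
#' @export
assignment_report <- function(assignments) {
  as_tibble(assignments)[, c("asv_id", "max_identity", "threshold",
                             "n_members", "display_name")]
}
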