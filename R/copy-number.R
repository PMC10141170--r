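#' Build a hierarchical 16S copy-number index
#'
#' Averages reference 16S rRNA gene copy numbers at every taxonomic level,
#' in the style of rrnDB: for each rank and each taxon label observed at
#' that rank, the mean copy number over all reference records carrying the
#' label, plus a global mean as the final fallback.
#'
#' @param records Tibble with the seven rank columns and a `copy_number`
#'   column (values >= 1).
#' @return Object of class `cn_index`: per-rank lookup tables plus
#'   `global_mean`.
#' @examples
#' recs <- dplyr::bind_cols(
#'   parse_lineage(c("d__Bacteria;p__P;c__C;o__O;f__F;g__G;s__G a",
#'                   "d__Bacteria;p__P;c__C;o__O;f__F;g__G;s__G b")),
#'   tibble::tibble(copy_number = c(2, 4)))
#' build_copy_number_index(recs)
#' @export
build_copy_number_index <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("`records` must be a non-empty data frame")
  }
  stopifnot(all(taxonomic_ranks %in% names(records)),
            "copy_number" %in% names(records))
  cn <- records$copy_number
  if (any(is.na(cn)) || any(cn < 1)) abort("copy numbers must be >= 1")
  by_rank <- purrr::map(setNames(taxonomic_ranks, taxonomic_ranks), function(r) {
    records |>
      filter(!is.na(.data[[r]])) |>
      group_by(label = .data[[r]]) |>
      summarise(mean_cn = mean(.data$copy_number), .groups = "drop")
  })
  structure(list(by_rank = by_rank, global_mean = mean(cn)),
            class = "cn_index")
}

#' @export
print.cn_index <- function(x, ...) {
  n <- purrr::map_int(x$by_rank, nrow)
  cat("16S copy-number index: global mean", round(x$global_mean, 2), "\n")
  cat(paste0("  ", names(n), ": ", n, " taxa", collapse = "\n"), "\n")
  invisible(x)
}

# copy-number estimate for lineage rows: most specific rank with an index
# entry, walking species -> domain, else the global mean
cn_lookup_rows <- function(lineages, index) {
  est <- rep(NA_real_, nrow(lineages))
  for (r in rev(taxonomic_ranks)) {
    tab <- index$by_rank[[r]]
    hit <- match(lineages[[r]], tab$label)
    est <- if_else(is.na(est) & !is.na(hit), tab$mean_cn[hit], est)
  }
  est[is.na(est)] <- index$global_mean
  est
}

#' Estimate 16S copy numbers for lineages or multi-taxonomy assignments
#'
#' For a single lineage, the estimate is the index mean at the most specific
#' rank with an entry (species first, walking up to domain), falling back to
#' the global mean. For a multi-taxonomy assignment the estimate is the
#' unweighted arithmetic mean of its members' estimates.
#'
#' @param x Either an `mta_assignments` tibble (a `copy_number` column is
#'   appended) or a lineage tibble with the seven rank columns (a numeric
#'   vector is returned).
#' @param index A `cn_index` from [build_copy_number_index()].
#' @return `x` with a `copy_number` column, or a numeric vector for plain
#'   lineage input.
#' @export
estimate_copy_number <- function(x, index) {
  stopifnot(inherits(index, "cn_index"))
  if ("members" %in% names(x)) {
    cn <- purrr::map_dbl(x$members, function(m) mean(cn_lookup_rows(m, index)))
    return(mutate(x, copy_number = cn))
  }
  cn_lookup_rows(x, index)
}

#' Per-phylotype copy numbers from ASV-level estimates
#'
#' Averages the assignment-level copy-number estimates of the ASVs that were
#' collapsed into each phylotype. Phylotypes with no assigned ASV (the
#' `"unclassified"` bucket) receive the index global mean.
#'
#' @param phylotypes Collapsed table from [collapse_phylotypes()] (its
#'   `provenance` attribute links ASVs to phylotypes).
#' @param assignments `mta_assignments` tibble.
#' @param index A `cn_index`.
#' @return Tibble `phylotype`, `copy_number`.
#' @export
phylotype_copy_numbers <- function(phylotypes, assignments, index) {
  prov <- attr(phylotypes, "provenance")
  if (is.null(prov)) abort("`phylotypes` lacks a provenance attribute; use collapse_phylotypes()")
  est <- estimate_copy_number(assignments, index)
  out <- prov |>
    left_join(est[, c("asv_id", "copy_number")], by = "asv_id") |>
    group_by(.data$phylotype) |>
    summarise(copy_number = mean(.data$copy_number, na.rm = TRUE),
              .groups = "drop")
  out$copy_number[is.nan(out$copy_number)] <- index$global_mean
  out
}

#' Renormalize abundances by 16S copy number
#'
#' Divides each count by its phylotype's copy number and re-closes each
#' sample to relative abundances: `a_i = (c_i / cn_i) / sum_j (c_j / cn_j)`.
#' Zero counts stay zero; multiplying all copy numbers by a constant leaves
#' the result unchanged.
#'
#' @param counts Long tibble with a feature column (first column), `sample`,
#'   `count`.
#' @param copy_numbers Tibble mapping the feature column to `copy_number`
#'   (all > 0); every feature in `counts` must be covered.
#' @return Long tibble: feature, `sample`, `rel_abundance` (each sample sums
#'   to 1).
#' @export
renormalize_abundances <- function(counts, copy_numbers) {
  feature <- names(counts)[1]
  stopifnot(all(c("sample", "count") %in% names(counts)),
            all(c(feature, "copy_number") %in% names(copy_numbers)))
  if (any(copy_numbers$copy_number <= 0)) abort("copy numbers must be > 0")
  miss <- setdiff(unique(counts[[feature]]), copy_numbers[[feature]])
  if (length(miss)) {
    abort(paste0("no copy number for: ", paste(sort(miss), collapse = ", ")))
  }
  zero <- counts |>
    group_by(.data$sample) |>
    summarise(tot = sum(.data$count), .groups = "drop") |>
    filter(.data$tot <= 0)
  if (nrow(zero)) {
    abort(paste0("sample(s) with all-zero counts: ",
                 paste(zero$sample, collapse = ", ")))
  }
  counts |>
    left_join(copy_numbers[, c(feature, "copy_number")], by = feature) |>
    group_by(.data$sample) |>
    mutate(w = .data$count / .data$copy_number,
           rel_abundance = .data$w / sum(.data$w)) |>
    ungroup() |>
    select(-"w", -"copy_number", -"count")
}

#' Read a copy-number reference table
#'
#' TSV `lineage<TAB>copy_number`, lineage as a semicolon-delimited ranked
#' string.
#'
#' @param path File path.
#' @return Tibble with rank columns plus `copy_number`.
#' @export
read_copy_number_table <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("lineage", "copy_number"),
                         col_types = "cd", progress = FALSE)
  if (nrow(raw) && is.na(raw$copy_number[1])) raw <- raw[-1, ]  # header line
  bind_cols(parse_lineage(raw$lineage),
            tibble(copy_number = as.numeric(raw$copy_number)))
}
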