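#' Taxonomic ranks used throughout the package
#'
#' The fixed seven-rank hierarchy, from most to least inclusive. All lineage
#' tibbles carry one character column per rank; labels may be `NA` below some
#' rank, and no label may contain the reserved `"/"` separator (used to join
#' multi-taxonomy names) or the `";"` lineage delimiter.
#'
#' @format Character vector of length 7.
#' @export
taxonomic_ranks <- c("domain", "phylum", "class", "order", "family",
                     "genus", "species")

check_rank <- function(rank) {
  if (length(rank) != 1 || !rank %in% taxonomic_ranks) {
    abort(paste0("`rank` must be one of: ",
                 paste(taxonomic_ranks, collapse = ", ")))
  }
  rank
}

#' Parse semicolon-delimited lineage strings
#'
#' Converts ranked lineage strings such as
#' `"d__Bacteria;p__Bacteroidota;...;s__Bacteroides uniformis"` into a tibble
#' with one column per taxonomic rank. QIIME-style rank prefixes (`d__`,
#' `p__`, ..., `s__`) are accepted and stripped; bare semicolon-delimited
#' strings are read positionally (domain first). Empty fields become `NA`.
#'
#' @param x Character vector of lineage strings.
#' @return A tibble with columns `domain` ... `species`, one row per input.
#' @examples
#' parse_lineage("d__Bacteria;p__Firmicutes;c__Bacilli")
#' @export
parse_lineage <- function(x) {
  stopifnot(is.character(x))
  parts <- strsplit(x, ";", fixed = TRUE)
  rows <- purrr::map(parts, function(p) {
    p <- trimws(p)
    p <- sub("^[dpcofgs]__", "", p)
    p[p == ""] <- NA_character_
    length(p) <- length(taxonomic_ranks)   # pad with NA
    setNames(as.list(p), taxonomic_ranks)
  })
  out <- purrr::list_rbind(purrr::map(rows, as_tibble))
  bad <- purrr::map_lgl(seq_len(nrow(out)), function(i) {
    any(grepl("/", unlist(out[i, ]), fixed = TRUE))
  })
  if (any(bad)) {
    abort(paste0("Lineage labels may not contain '/': rows ",
                 paste(which(bad), collapse = ", ")))
  }
  out
}

#' Format lineage tibble rows back into semicolon-delimited strings
#'
#' @param lineages Tibble with the seven rank columns.
#' @param prefixes Prepend QIIME-style rank prefixes (default `FALSE`).
#' @return Character vector of lineage strings.
#' @export
format_lineage <- function(lineages, prefixes = FALSE) {
  stopifnot(all(taxonomic_ranks %in% names(lineages)))
  pre <- if (prefixes) paste0(substr(taxonomic_ranks, 1, 1), "__") else ""
  cols <- purrr::map2(taxonomic_ranks, pre, function(r, p) {
    v <- lineages[[r]]
    if_else(is.na(v), "", paste0(p, v))
  })
  out <- do.call(paste, c(cols, sep = ";"))
  sub(";+$", "", out)
}

# Most specific non-missing label of each lineage row; used as a display
# fallback when the species field is absent.
deepest_label <- function(lineages) {
  labs <- rep(NA_character_, nrow(lineages))
  for (r in taxonomic_ranks) {
    v <- lineages[[r]]
    labs <- if_else(!is.na(v), v, labs)
  }
  labs
}

#' Read a reference taxonomy table
#'
#' Expects a two-column TSV `ref_id<TAB>lineage` where the lineage is a
#' semicolon-delimited ranked string (QIIME prefixes optional). A header line
#' is detected and skipped if the second field does not look like a lineage.
#'
#' @param path File path (or literal text via [I()]).
#' @return Tibble: `ref_id` plus the seven rank columns.
#' @export
read_taxonomy <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("taxonomy table needs two tab-separated columns")
  raw <- raw[, 1:2]
  names(raw) <- c("ref_id", "lineage")
  if (nrow(raw) > 0 && !grepl(";|__", raw$lineage[[1]]) &&
      tolower(raw$ref_id[[1]]) %in% c("ref_id", "id", "feature_id")) {
    raw <- raw[-1, ]
  }
  bind_cols(raw["ref_id"], parse_lineage(raw$lineage))
}
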