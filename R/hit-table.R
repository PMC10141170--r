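#' Read a BLAST-style tabular alignment hit table
#'
#' Parses the standard 12-column tabular alignment format (`qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore`).
#' Only the first three columns are required: query (ASV) id, subject
#' (reference) id, and percent identity. Percent identities on the 0-100
#' scale are converted to fractions in (0, 1].
#'
#' @param path File path, connection, or literal text wrapped in [I()].
#' @param dialect Input dialect; only `"blast12"` (tab- or
#'   whitespace-separated 12-column tabular) is supported.
#' @return Tibble with columns `asv_id`, `ref_id`, `identity` (fraction) and
#'   `line` (1-based source line number). Row order is preserved. An empty
#'   input yields a zero-row tibble with a warning.
#' @examples
#' read_hit_table(I("asv1\trefA\t98.0\t250\t5\t0\t1\t250\t1\t250\t1e-50\t400"))
#' @export
read_hit_table <- function(path, dialect = c("blast12")) {
  dialect <- match.arg(dialect)
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    warn("hit table is empty: returning 0 hits")
    return(tibble(asv_id = character(), ref_id = character(),
                  identity = double(), line = integer()))
  }
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(paste0("malformed hit rows (need >= 3 columns) at line(s): ",
                 paste(lineno[nf < 3], collapse = ", ")))
  }
  pid <- suppressWarnings(as.numeric(purrr::map_chr(fields, 3)))
  if (anyNA(pid)) {
    abort(paste0("non-numeric percent identity at line(s): ",
                 paste(lineno[is.na(pid)], collapse = ", ")))
  }
  bad <- pid < 0 | pid > 100
  if (any(bad)) {
    abort(paste0("percent identity outside [0, 100] at line(s): ",
                 paste(lineno[bad], collapse = ", ")))
  }
  tibble(
    asv_id = purrr::map_chr(fields, 1),
    ref_id = purrr::map_chr(fields, 2),
    identity = pid / 100,
    line = lineno
  )
}

#' Read a sample-by-ASV count table
#'
#' Accepts the feature-table orientation (rows = ASVs/phylotypes, first
#' column the feature id, remaining columns one per sample) and returns the
#' long tidy form used by all downstream functions.
#'
#' @param path TSV path.
#' @param feature Name for the feature id column in the output
#'   (default `"asv_id"`).
#' @return Long tibble: `<feature>`, `sample`, `count`.
#' @export
read_count_table <- function(path, feature = "asv_id") {
  wide <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  names(wide)[1] <- feature
  tidyr::pivot_longer(wide, -1, names_to = "sample", values_to = "count")
}

#' Write a long feature table in wide TSV form
#'
#' @param x Long tibble with a feature column, `sample`, and a value column.
#' @param path Output path.
#' @param value Name of the value column (default the third column).
#' @export
write_feature_table <- function(x, path, value = names(x)[3]) {
  wide <- tidyr::pivot_wider(x[, c(names(x)[1], "sample", value)],
                             names_from = "sample",
                             values_from = dplyr::all_of(value),
                             values_fill = 0)
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' @param path TSV with columns `sample`, `condition`, `replicate` (extra
#'   columns are kept).
#' @return Tibble.
#' @export
read_metadata <- function(path) {
  md <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("sample", "condition")
  miss <- setdiff(need, names(md))
  if (length(miss)) abort(paste0("metadata lacks column(s): ",
                                 paste(miss, collapse = ", ")))
  md
}
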