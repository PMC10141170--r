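#' Phenotype vocabulary for community metabolic reconstruction
#'
#' The fixed label sets over which binary phenotype matrices and community
#' phenotype indices are computed: fermentation end products, vitamin and
#' cofactor biosynthesis pathways, and CAZyme glycosyl hydrolase (GH) /
#' polysaccharide lyase (PL) families. Defaults cover 170 GH and 33 PL
#' families; smaller vocabularies are useful for compact examples.
#'
#' @param n_gh,n_pl Number of GH and PL family labels (`GH1...`, `PL1...`).
#' @return Object of class `phenotype_vocabulary`: a list with elements
#'   `fermentation`, `vitamins`, `gh`, `pl`.
#' @export
phenotype_vocabulary <- function(n_gh = 170, n_pl = 33) {
  v <- list(
    fermentation = c("acetate", "propionate", "butyrate", "D-lactate",
                     "L-lactate", "ethanol", "formate"),
    vitamins = c("B1", "B2", "B3", "B5", "B6", "B7", "B9", "B12", "K",
                 "queuosine", "lipoate"),
    gh = if (n_gh > 0) paste0("GH", seq_len(n_gh)) else character(),
    pl = if (n_pl > 0) paste0("PL", seq_len(n_pl)) else character()
  )
  if (anyDuplicated(unlist(v))) abort("phenotype labels must be unique")
  structure(v, class = "phenotype_vocabulary")
}

#' @export
print.phenotype_vocabulary <- function(x, ...) {
  cat("Phenotype vocabulary:",
      length(x$fermentation), "fermentation products,",
      length(x$vitamins), "vitamins/cofactors,",
      length(x$gh), "GH families,", length(x$pl), "PL families\n")
  invisible(x)
}

#' All labels of a vocabulary, in canonical order
#' @param vocabulary A `phenotype_vocabulary`.
#' @export
phenotype_labels <- function(vocabulary) {
  unlist(vocabulary, use.names = FALSE)
}

#' Family (CAZyme) labels of a vocabulary
#' @param vocabulary A `phenotype_vocabulary`.
#' @export
family_labels <- function(vocabulary) {
  c(vocabulary$gh, vocabulary$pl)
}

#' @rdname phenotype_vocabulary
#' @param path JSON file path.
#' @export
write_vocabulary <- function(vocabulary, path) {
  jsonlite::write_json(unclass(vocabulary), path, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname phenotype_vocabulary
#' @export
read_vocabulary <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(purrr::map(v[c("fermentation", "vitamins", "gh", "pl")],
                       as.character),
            class = "phenotype_vocabulary")
}

#' Binarize CAZyme family counts
#'
#' A genome is scored 1 for a family if it encodes at least one enzyme of
#' that family, else 0. Idempotent: binarizing an already binary input
#' changes nothing.
#'
#' @param counts Numeric vector, matrix, or data frame of non-negative
#'   family counts.
#' @return Same shape, with entries in \{0, 1\}.
#' @examples
#' binarize_families(c(GH13 = 12, GH2 = 0))
#' @export
binarize_families <- function(counts) {
  if (is.data.frame(counts)) {
    return(mutate(counts, across(dplyr::where(is.numeric),
                                 ~ as.integer(.x >= 1))))
  }
  if (any(counts < 0, na.rm = TRUE)) abort("family counts must be >= 0")
  out <- as.integer(counts >= 1)
  attributes(out) <- attributes(counts)
  if (!is.null(dim(counts))) storage.mode(out) <- "integer"
  out
}

#' Read a genome annotation table
#'
#' TSV with columns `genome_id`, `lineage` (semicolon-delimited ranked
#' string), then one numeric column per CAZyme family (enzyme counts) and
#' per metabolic pathway (0/1 calls).
#'
#' @param path File path.
#' @return Wide tibble: `genome_id`, the seven rank columns, then the
#'   annotation columns.
#' @export
read_annotations <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  stopifnot(all(c("genome_id", "lineage") %in% names(raw)))
  bind_cols(raw["genome_id"], parse_lineage(raw$lineage),
            raw[, setdiff(names(raw), c("genome_id", "lineage"))])
}

#' Build the binary phenotype matrix (BPM)
#'
#' Family count columns are binarized (present if at least one enzyme);
#' pathway call columns are copied and validated as 0/1. Vocabulary labels
#' absent from the annotations default to 0; annotation columns that are
#' CAZyme-family-shaped (`GH<k>`/`PL<k>`) but not in the vocabulary are an
#' error.
#'
#' @param annotations Wide tibble from [read_annotations()] (or the
#'   synthetic generator): `genome_id`, rank columns, annotation columns.
#' @param vocabulary A `phenotype_vocabulary`.
#' @return Tibble of class `bpm`: `genome_id` plus one 0/1 column per
#'   vocabulary label, with the genome lineages in attribute `lineage`.
#' @export
build_bpm <- function(annotations, vocabulary) {
  stopifnot(inherits(vocabulary, "phenotype_vocabulary"),
            "genome_id" %in% names(annotations))
  if (nrow(annotations) == 0) abort("need at least one genome annotation")
  if (anyDuplicated(annotations$genome_id)) {
    abort(paste0("duplicate genome_id(s): ",
                 paste(unique(annotations$genome_id[duplicated(annotations$genome_id)]),
                       collapse = ", ")))
  }
  labels <- phenotype_labels(vocabulary)
  ann_cols <- setdiff(names(annotations), c("genome_id", taxonomic_ranks))
  rogue <- grep("^(GH|PL)[0-9]+$", setdiff(ann_cols, labels), value = TRUE)
  if (length(rogue)) {
    abort(paste0("family label(s) outside the vocabulary: ",
                 paste(rogue, collapse = ", ")))
  }
  fam <- intersect(family_labels(vocabulary), ann_cols)
  path <- intersect(c(vocabulary$fermentation, vocabulary$vitamins), ann_cols)
  mat <- matrix(0L, nrow(annotations), length(labels),
                dimnames = list(NULL, labels))
  if (length(fam)) {
    fm <- as.matrix(annotations[, fam])
    if (any(fm < 0)) abort("family counts must be >= 0")
    mat[, fam] <- binarize_families(fm)
  }
  if (length(path)) {
    pm <- as.matrix(annotations[, path])
    if (!all(pm %in% c(0, 1))) abort("pathway calls must be 0/1")
    mat[, path] <- as.integer(pm)
  }
  out <- bind_cols(annotations["genome_id"], as_tibble(mat))
  attr(out, "lineage") <- annotations[, c("genome_id",
                                          intersect(taxonomic_ranks,
                                                    names(annotations)))]
  attr(out, "vocabulary") <- vocabulary
  class(out) <- c("bpm", class(out))
  out
}

# default species -> genome mapping derived from the BPM's lineage attribute
default_genome_map <- function(bpm) {
  lin <- attr(bpm, "lineage")
  if (is.null(lin) || !"species" %in% names(lin)) {
    abort("`bpm` carries no genome lineages; supply `genome_map` explicitly")
  }
  tibble(species = lin$species, genome_id = lin$genome_id) |>
    filter(!is.na(.data$species))
}

#' Per-phylotype phenotype values from the BPM
#'
#' A phylotype's member species are taken from its display name (the
#' `"/"`-joined multi-name); each member is mapped to its reference
#' genome(s) and the phylotype's value for each phenotype is the unweighted
#' mean of the BPM entries over all genomes of all members. Phylotypes with
#' no mappable member (including `"unclassified"`) are excluded and listed
#' in the `unmapped` attribute.
#'
#' @param phylotype_names Character vector of phylotype display names.
#' @param bpm A `bpm` from [build_bpm()].
#' @param genome_map Optional tibble `species`, `genome_id`; defaults to the
#'   species labels of the BPM's genome lineages.
#' @return Long tibble `phylotype`, `phenotype`, `value` (in \[0, 1\]), with
#'   attribute `unmapped` (character vector).
#' @export
taxon_phenotype_values <- function(phylotype_names, bpm, genome_map = NULL) {
  stopifnot(inherits(bpm, "bpm"))
  genome_map <- genome_map %||% default_genome_map(bpm)
  phylotype_names <- unique(phylotype_names)
  labels <- setdiff(names(bpm), "genome_id")
  mat <- as.matrix(as_tibble(bpm)[, labels])
  rownames(mat) <- bpm$genome_id
  rows <- purrr::map(phylotype_names, function(p) {
    members <- strsplit(p, "/", fixed = TRUE)[[1]]
    genomes <- genome_map$genome_id[genome_map$species %in% members]
    if (length(genomes) == 0) return(NULL)
    vals <- colMeans(mat[genomes, , drop = FALSE])
    tibble(phylotype = p, phenotype = labels, value = unname(vals))
  })
  unmapped <- phylotype_names[purrr::map_lgl(rows, is.null)]
  if (length(unmapped)) {
    inform(paste0(length(unmapped),
                  " phylotype(s) had no genome mapping and were excluded"))
  }
  out <- purrr::list_rbind(rows)
  attr(out, "unmapped") <- unmapped
  out
}

#' Community phenotype index (CPI)
#'
#' The abundance-weighted mean of per-taxon phenotype values over the mapped
#' phylotypes of each sample: after restricting a sample's relative
#' abundances to phylotypes with a phenotype value and re-closing that
#' mapped mass to 1, `CPI = sum_t a_t * v_t`, which lies in \[0, 1\].
#' The mass fraction that was mappable is reported per sample.
#'
#' @param rel_abundance Long tibble `phylotype`, `sample`, `rel_abundance`.
#' @param taxon_values Long tibble from [taxon_phenotype_values()].
#' @return Long tibble `sample`, `phenotype`, `cpi`, with per-sample mapped
#'   mass in attribute `mapped_fraction` (tibble `sample`,
#'   `mapped_fraction`).
#' @export
community_phenotype_index <- function(rel_abundance, taxon_values) {
  stopifnot(all(c("phylotype", "sample", "rel_abundance") %in%
                  names(rel_abundance)))
  mapped <- rel_abundance |>
    filter(.data$phylotype %in% unique(taxon_values$phylotype))
  if (nrow(mapped) == 0) abort("no phylotype could be mapped to the BPM")
  frac <- rel_abundance |>
    group_by(.data$sample) |>
    summarise(total = sum(.data$rel_abundance), .groups = "drop") |>
    left_join(mapped |>
                group_by(.data$sample) |>
                summarise(m = sum(.data$rel_abundance), .groups = "drop"),
              by = "sample") |>
    mutate(mapped_fraction = dplyr::coalesce(.data$m, 0) / .data$total) |>
    select("sample", "mapped_fraction")
  bad <- frac$sample[frac$mapped_fraction <= 0]
  if (length(bad)) {
    abort(paste0("no mapped phylotypes in sample(s): ",
                 paste(bad, collapse = ", ")))
  }
  out <- mapped |>
    group_by(.data$sample) |>
    mutate(a = .data$rel_abundance / sum(.data$rel_abundance)) |>
    ungroup() |>
    inner_join(taxon_values, by = "phylotype",
               relationship = "many-to-many") |>
    group_by(.data$sample, .data$phenotype) |>
    summarise(cpi = sum(.data$a * .data$value), .groups = "drop")
  attr(out, "mapped_fraction") <- frac
  out
}

#' Percent change in community phenotype index versus control
#'
#' For each non-control condition and phenotype: the signed percent change
#' of the replicate-mean CPI relative to the control mean,
#' `100 * (mean_T - mean_C) / mean_C`, together with an exact Mann-Whitney
#' p-value across replicates. A zero control mean leaves the percent change
#' undefined (`NA`) and flags the row.
#'
#' @param cpi Long tibble from [community_phenotype_index()].
#' @param metadata Tibble `sample`, `condition`.
#' @param control Name of the control condition.
#' @param alpha Significance level used for the `significant` flag
#'   (default 0.05, no multiple-testing correction).
#' @return Tibble: `condition`, `phenotype`, `mean_control`,
#'   `mean_treatment`, `percent_change`, `undefined_change`, `p_mw`,
#'   `significant`, `direction`.
#' @export
phenotype_change_stats <- function(cpi, metadata, control = "control",
                                   alpha = 0.05) {
  dat <- inner_join(cpi, metadata[, c("sample", "condition")], by = "sample")
  if (!control %in% dat$condition) {
    abort(paste0("control condition '", control, "' not found"))
  }
  ctrl <- filter(dat, .data$condition == control)
  trt <- filter(dat, .data$condition != control)
  one <- function(vals, phen) {
    cc <- ctrl$cpi[ctrl$phenotype == phen]
    mt <- mean(vals); mc <- mean(cc)
    p <- mann_whitney_exact(vals, cc)$p_value
    tibble(mean_control = mc, mean_treatment = mt,
           percent_change = if (mc > 0) 100 * (mt - mc) / mc else NA_real_,
           undefined_change = mc <= 0,
           p_mw = p, significant = p < alpha,
           direction = sign(mt - mc))
  }
  trt |>
    group_by(.data$condition, .data$phenotype) |>
    summarise(res = list(one(.data$cpi, dplyr::cur_group()$phenotype)),
              .groups = "drop") |>
    tidyr::unnest("res")
}

#' Community-wide net shift in CAZyme family representation
#'
#' Sums the signed percent changes over GH/PL families for each condition,
#' optionally restricted to families whose Mann-Whitney p-value falls below
#' `alpha`.
#'
#' @param changes Tibble from [phenotype_change_stats()].
#' @param vocabulary A `phenotype_vocabulary`; only its GH/PL labels enter
#'   the sum.
#' @param only_significant Restrict to `significant` rows (default FALSE).
#' @return Tibble `condition`, `n_families`, `net_shift`.
#' @export
net_family_shift <- function(changes, vocabulary, only_significant = FALSE) {
  fams <- family_labels(vocabulary)
  x <- filter(changes, .data$phenotype %in% fams, !.data$undefined_change)
  if (only_significant) x <- filter(x, .data$significant)
  x |>
    group_by(.data$condition) |>
    summarise(n_families = dplyr::n(),
              net_shift = sum(.data$percent_change), .groups = "drop")
}
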