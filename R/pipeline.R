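#' Assemble and validate a pipeline run configuration
#'
#' @param hits,taxonomy,copy_numbers,annotations,counts,metadata Input file
#'   paths (see the readers: [read_hit_table()], [read_taxonomy()],
#'   [read_copy_number_table()], [read_annotations()],
#'   [read_count_table()], [read_metadata()]).
#' @param vocabulary Path to a vocabulary JSON, or a
#'   `phenotype_vocabulary`.
#' @param control Control condition name (must appear in the metadata).
#' @param alpha Significance level in (0, 1).
#' @param cutoff Fold cutoff (> 1).
#' @param pseudo Pseudocount for zero cells (> 0).
#' @param shannon_base Log base for Shannon diversity.
#' @param mta_digits Identity rounding for the multi-taxonomy rule.
#' @param rank Collapse rank.
#' @param seed Integer seed echoed into the manifest.
#' @param out_dir Output directory.
#' @return List of class `run_config`.
#' @export
run_config <- function(hits, taxonomy, copy_numbers, annotations, counts,
                       metadata, vocabulary = phenotype_vocabulary(),
                       control = "control",
                       alpha = 0.05, cutoff = 5, pseudo = 0.5,
                       shannon_base = exp(1), mta_digits = 6,
                       rank = "species", seed = 1, out_dir = "glycomod_run") {
  cfg <- list(hits = hits, taxonomy = taxonomy, copy_numbers = copy_numbers,
              annotations = annotations, counts = counts,
              metadata = metadata, vocabulary = vocabulary,
              control = control, alpha = alpha, cutoff = cutoff,
              pseudo = pseudo, shannon_base = shannon_base,
              mta_digits = mta_digits, rank = rank, seed = seed,
              out_dir = out_dir)
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must be in (0, 1)")
  if (cutoff <= 1) abort("`cutoff` must be > 1")
  if (pseudo <= 0) abort("`pseudo` must be > 0")
  check_rank(rank)
  for (f in c("hits", "taxonomy", "copy_numbers", "annotations", "counts",
              "metadata")) {
    if (!is.character(cfg[[f]]) || !file.exists(cfg[[f]])) {
      abort(paste0("config input `", f, "` is not a readable file: ",
                   cfg[[f]]))
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML or JSON file
#'
#' Relative input paths are resolved against the config file's directory.
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @param overrides Named list of fields to override (e.g. from a command
#'   line).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  raw[names(overrides)] <- overrides
  base <- dirname(normalizePath(path))
  for (f in c("hits", "taxonomy", "copy_numbers", "annotations", "counts",
              "metadata", "vocabulary")) {
    if (!is.null(raw[[f]]) && is.character(raw[[f]]) &&
        !file.exists(raw[[f]])) {
      cand <- file.path(base, raw[[f]])
      if (file.exists(cand)) raw[[f]] <- cand
    }
  }
  do.call(run_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full community-modulation analysis pipeline
#'
#' Executes the stages in order -- multi-taxonomy assignment, phylotype
#' collapse, 16S copy-number renormalization, alpha/beta diversity and
#' ordination, five-fold modulation scoring with exact Mann-Whitney tests,
#' community phenotype indices and phenotype change statistics, and
#' pairwise f-score overlap -- writing every module's table plus a
#' `manifest.json` (config echo, package version, input checksums, stage
#' outputs) into the output directory. Any stage failure aborts with the
#' stage name. Reruns with an identical config produce identical outputs.
#'
#' @param config A `run_config` (or a path to a YAML/JSON config).
#' @return Invisibly, a list of class `glycomod_run`: the output directory,
#'   manifest, and the in-memory result tables.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  log_msg <- function(...) inform(paste0("[glycomod] ", ...))

  metadata <- stage("metadata", {
    md <- read_metadata(config$metadata)
    if (!config$control %in% md$condition) {
      abort(paste0("control condition '", config$control,
                   "' absent from metadata"))
    }
    md
  })
  vocab <- stage("vocabulary", {
    if (inherits(config$vocabulary, "phenotype_vocabulary")) {
      config$vocabulary
    } else read_vocabulary(config$vocabulary)
  })

  log_msg("stage 1/7: multi-taxonomy assignment")
  assignments <- stage("assign", {
    hits <- read_hit_table(config$hits)
    taxonomy <- read_taxonomy(config$taxonomy)
    assign_taxonomy(hits, taxonomy, digits = config$mta_digits)
  })

  log_msg("stage 2/7: phylotype collapse")
  counts <- stage("counts", read_count_table(config$counts))
  shared <- intersect(unique(counts$sample), metadata$sample)
  if (length(shared) == 0) {
    abort("pipeline stage 'counts' failed: no shared sample ids between counts and metadata")
  }
  phylotypes <- stage("collapse",
                      collapse_phylotypes(counts, assignments,
                                          rank = config$rank))

  log_msg("stage 3/7: copy-number renormalization")
  cn <- stage("renormalize", {
    cn_index <- build_copy_number_index(
      read_copy_number_table(config$copy_numbers))
    phylotype_copy_numbers(phylotypes, assignments, cn_index)
  })
  rel <- stage("renormalize", renormalize_abundances(phylotypes, cn))

  log_msg("stage 4/7: diversity and ordination")
  diversity <- stage("diversity",
                     sample_diversity(rel, base = config$shannon_base))
  ord <- stage("ordination", pcoa(bray_curtis_matrix(rel)))

  log_msg("stage 5/7: modulation scoring and tests")
  stats <- stage("modulation", {
    modulation_stats(phylotypes, metadata, control = config$control,
                     copy_numbers = cn, cutoff = config$cutoff,
                     pseudo = config$pseudo, alpha = config$alpha)
  })

  log_msg("stage 6/7: community phenotype indices")
  cpi_res <- stage("cpi", {
    bpm <- build_bpm(read_annotations(config$annotations), vocab)
    tv <- taxon_phenotype_values(unique(rel$phylotype), bpm)
    cpi <- community_phenotype_index(rel, tv)
    changes <- phenotype_change_stats(cpi, metadata,
                                      control = config$control,
                                      alpha = config$alpha)
    list(cpi = cpi, changes = changes,
         net_shift = net_family_shift(changes, vocab))
  })

  log_msg("stage 7/7: f-score overlap analysis")
  fscores <- stage("fscore", {
    resp <- responder_sets(stats, alpha = config$alpha)
    trts <- setdiff(unique(metadata$condition), config$control)
    if (length(trts) >= 2) pairwise_f_scores(resp, treatments = trts)
    else NULL
  })

  out <- function(name) file.path(config$out_dir, name)
  readr::write_tsv(assignment_report(assignments), out("assignments.tsv"),
                   progress = FALSE)
  write_feature_table(phylotypes, out("phylotypes.tsv"), value = "count")
  write_feature_table(rel, out("relative_abundance.tsv"),
                      value = "rel_abundance")
  readr::write_tsv(diversity, out("diversity.tsv"), progress = FALSE)
  readr::write_tsv(tidy(ord), out("pcoa.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(stats), out("modulation_stats.tsv"),
                   progress = FALSE)
  readr::write_tsv(cpi_res$cpi, out("cpi.tsv"), progress = FALSE)
  readr::write_tsv(cpi_res$changes, out("phenotype_changes.tsv"),
                   progress = FALSE)
  if (!is.null(fscores)) {
    readr::write_tsv(as_tibble(fscores), out("fscores.tsv"),
                     progress = FALSE)
  }

  inputs <- unlist(config[c("hits", "taxonomy", "copy_numbers",
                            "annotations", "counts", "metadata")])
  manifest <- list(
    package = "glycomod",
    version = as.character(utils::packageVersion("glycomod")),
    config = config[setdiff(names(config), "vocabulary")],
    input_checksums = as.list(tools::md5sum(inputs)),
    outputs = list.files(config$out_dir, pattern = "\\.tsv$")
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  res <- structure(list(out_dir = config$out_dir, manifest = manifest,
                        assignments = assignments, phylotypes = phylotypes,
                        rel_abundance = rel, diversity = diversity,
                        pcoa = ord, modulation = stats, cpi = cpi_res$cpi,
                        phenotype_changes = cpi_res$changes,
                        fscores = fscores),
                   class = "glycomod_run")
  invisible(res)
}

#' @export
print.glycomod_run <- function(x, ...) {
  cat("glycomod run ->", x$out_dir, "\n ",
      length(x$manifest$outputs), "output tables;",
      nrow(x$modulation), "modulation rows;",
      dplyr::n_distinct(x$rel_abundance$phylotype), "phylotypes\n")
  invisible(x)
}
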