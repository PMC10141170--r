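# Synthetic world: reference taxonomy + copy numbers + genome annotations,
# an ASV registry with alignment hits exercising the identity-window rule,
# and replicated count tables with planted fold changes. Emits exactly the
# tabular formats the analysis functions read, so every stage can be tested
# against known ground truth without external databases.

#' Default phenotype prevalences for the synthetic reference database
#'
#' Marginal probabilities that a reference genome carries each phenotype.
#' Fermentation-product and vitamin prevalences are fixed at values typical
#' of human gut genome collections (acetate production near-universal,
#' butyrate a minority trait, most B-vitamin pathways in roughly half of
#' genomes); CAZyme family prevalence decays with family index so that a few
#' families are common and the long tail is rare, mimicking skewed GH/PL
#' family distributions.
#'
#' @param vocabulary A `phenotype_vocabulary`.
#' @return Named numeric vector over [phenotype_labels()].
#' @export
default_prevalence <- function(vocabulary) {
  ferm <- c(acetate = 0.85, propionate = 0.35, butyrate = 0.25,
            `D-lactate` = 0.30, `L-lactate` = 0.40, ethanol = 0.45,
            formate = 0.55)
  vit <- setNames(c(0.55, 0.60, 0.50, 0.45, 0.55, 0.35, 0.50, 0.20, 0.40,
                    0.45, 0.30), phenotype_vocabulary(0, 0)$vitamins)
  gh <- setNames(0.05 + 0.55 * exp(-(seq_along(vocabulary$gh) - 1) / 40),
                 vocabulary$gh)
  pl <- setNames(0.03 + 0.37 * exp(-(seq_along(vocabulary$pl) - 1) / 8),
                 vocabulary$pl)
  c(ferm[vocabulary$fermentation], vit[vocabulary$vitamins], gh, pl)
}

#' Generate a synthetic reference database
#'
#' Builds ranked lineages for `n_species` species spread over `n_genera`
#' genera (nested into families, orders, classes and phyla), integer 16S
#' copy numbers in \[1, 15\] correlated within genus, and one genome
#' annotation per species with genus-correlated phenotype content: each
#' genus draws a Bernoulli prior per phenotype from a Beta distribution
#' centred on the target prevalence, species draw from the genus prior, and
#' a small per-species flip noise is applied. Family counts for positive
#' genomes are `1 + Poisson(2)`.
#'
#' @param n_species,n_genera Sizes (`n_species >= n_genera >= 1`).
#' @param vocabulary A `phenotype_vocabulary`.
#' @param prevalence Named prevalence vector (default
#'   [default_prevalence()]); values in \[0, 1\].
#' @param genus_concentration Beta concentration of the genus prior
#'   (larger = stronger within-genus correlation; default 6).
#' @param flip_noise Per-species probability of flipping the genus draw
#'   (default 0.03).
#' @param seed Integer seed; same seed gives identical output.
#' @return List of class `reference_db`: `taxonomy` (`ref_id` + rank
#'   columns), `copy_numbers` (rank columns + `copy_number`), `annotations`
#'   (wide: `genome_id`, rank columns, one column per phenotype label),
#'   `vocabulary`.
#' @export
generate_reference_database <- function(n_species = 400, n_genera = 80,
                                        vocabulary = phenotype_vocabulary(),
                                        prevalence = NULL,
                                        genus_concentration = 6,
                                        flip_noise = 0.03,
                                        seed = 1) {
  stopifnot(n_species >= n_genera, n_genera >= 1)
  prevalence <- prevalence %||% default_prevalence(vocabulary)
  labels <- phenotype_labels(vocabulary)
  if (!all(labels %in% names(prevalence))) {
    abort("`prevalence` must cover every vocabulary label")
  }
  prevalence <- pmin(1, pmax(0, prevalence[labels]))

  withr::with_seed(seed, {
    n_phyla <- 4
    n_classes <- 6
    n_orders <- 10
    n_fam <- max(8, ceiling(n_genera / 4))
    fam_of_genus <- sample.int(n_fam, n_genera, replace = TRUE)
    ord_of_fam <- sample.int(n_orders, n_fam, replace = TRUE)
    cls_of_ord <- sample.int(n_classes, n_orders, replace = TRUE)
    phy_of_cls <- sample.int(n_phyla, n_classes, replace = TRUE)
    genus_of_sp <- sort(c(seq_len(n_genera),        # every genus non-empty
                          sample.int(n_genera, n_species - n_genera,
                                     replace = TRUE)))
    genus_names <- sprintf("Genus%03d", seq_len(n_genera))
    sp_index <- stats::ave(genus_of_sp, genus_of_sp, FUN = seq_along)
    species_names <- sprintf("%s sp%02d", genus_names[genus_of_sp], sp_index)

    g <- genus_of_sp
    taxonomy <- tibble(
      ref_id = sprintf("ref_%04d", seq_len(n_species)),
      domain = "Bacteria",
      phylum = sprintf("Phylum%d", phy_of_cls[cls_of_ord[ord_of_fam[fam_of_genus[g]]]]),
      class = sprintf("Class%d", cls_of_ord[ord_of_fam[fam_of_genus[g]]]),
      order = sprintf("Order%02d", ord_of_fam[fam_of_genus[g]]),
      family = sprintf("Family%02d", fam_of_genus[g]),
      genus = genus_names[g],
      species = species_names
    )

    genus_base_cn <- sample.int(12, n_genera, replace = TRUE)
    cn <- pmin(15L, pmax(1L, genus_base_cn[g] +
                           sample(-2:3, n_species, replace = TRUE)))
    copy_numbers <- bind_cols(taxonomy[, taxonomic_ranks],
                              tibble(copy_number = as.numeric(cn)))

    a <- genus_concentration * prevalence
    b <- genus_concentration * (1 - prevalence)
    genus_prior <- matrix(stats::rbeta(n_genera * length(labels),
                                       rep(a, each = n_genera),
                                       rep(b, each = n_genera)),
                          nrow = n_genera, dimnames = list(NULL, labels))
    # degenerate prevalences must stay degenerate
    genus_prior[, prevalence == 0] <- 0
    genus_prior[, prevalence == 1] <- 1
    p_sp <- genus_prior[g, , drop = FALSE]
    calls <- matrix(stats::rbinom(length(p_sp), 1, p_sp), nrow = n_species,
                    dimnames = list(NULL, labels))
    flip <- matrix(stats::rbinom(length(p_sp), 1, flip_noise) == 1,
                   nrow = n_species)
    flip[, prevalence %in% c(0, 1)] <- FALSE
    calls[flip] <- 1L - calls[flip]

    fam_cols <- family_labels(vocabulary)
    counts <- calls
    if (length(fam_cols)) {
      fc <- calls[, fam_cols, drop = FALSE]
      pos <- fc == 1
      fc[pos] <- 1L + stats::rpois(sum(pos), 2)
      counts[, fam_cols] <- fc
    }
    annotations <- bind_cols(
      tibble(genome_id = sprintf("gen_%04d", seq_len(n_species))),
      taxonomy[, taxonomic_ranks],
      as_tibble(counts)
    )
    structure(list(taxonomy = taxonomy, copy_numbers = copy_numbers,
                   annotations = annotations, vocabulary = vocabulary),
              class = "reference_db")
  })
}

#' Generate an alignment hit table with planted ambiguity
#'
#' One ASV is registered per reference species. Each ASV's top hit is its
#' true reference at identity `M ~ Uniform(identity_range)` (rounded to 3
#' decimals, as tabular identity columns carry). With probability
#' `ambiguity_rate` the ASV also receives 1-3 decoy hits with identities
#' strictly inside the admission window `(M - (1 - M)/4, M)` -- these are
#' planted multi-taxonomy members -- plus 1-3 decoys strictly below the
#' threshold, which must never become members. Decoys are drawn from the
#' same genus where possible.
#'
#' @param reference A `reference_db`.
#' @param ambiguity_rate Probability an ASV gets in-window decoys
#'   (default 0.3).
#' @param identity_range Range of top-hit identities (default
#'   `c(0.95, 1)`).
#' @param seed Integer seed.
#' @return List: `registry` (tibble `asv_id`, `ref_id`, `species`), `hits`
#'   (12-column tabular tibble), `truth` (tibble `asv_id`, `ref_id` of
#'   planted members).
#' @export
generate_hit_table <- function(reference, ambiguity_rate = 0.3,
                               identity_range = c(0.95, 1), seed = 1) {
  stopifnot(inherits(reference, "reference_db"),
            ambiguity_rate >= 0, ambiguity_rate <= 1)
  tax <- reference$taxonomy
  n <- nrow(tax)
  registry <- tibble(asv_id = sprintf("asv_%04d", seq_len(n)),
                     ref_id = tax$ref_id, species = tax$species)

  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(n), function(i) {
      M <- round(stats::runif(1, identity_range[1], identity_range[2]), 3)
      t <- M - (1 - M) / 4
      hit <- tibble(asv_id = registry$asv_id[i], ref_id = tax$ref_id[i],
                    identity = M, member = TRUE)
      others <- setdiff(which(tax$genus == tax$genus[i]), i)
      if (length(others) < 6) {
        others <- unique(c(others, sample(setdiff(seq_len(n), i),
                                          min(6, n - 1))))
      }
      # in-window decoys: 3-decimal identities strictly between t and M
      grid_in <- seq(ceiling(t * 1000 + 1e-6), floor(M * 1000 - 1e-6)) / 1000
      grid_in <- grid_in[grid_in > t & grid_in < M]
      if (stats::runif(1) < ambiguity_rate && length(grid_in) &&
          length(others)) {
        k <- min(sample.int(3, 1), length(others))
        ids <- sample(others, k); others <- setdiff(others, ids)
        hit <- bind_rows(hit, tibble(
          asv_id = registry$asv_id[i], ref_id = tax$ref_id[ids],
          identity = sample(grid_in, k, replace = TRUE), member = TRUE))
      }
      # below-threshold decoys, never members
      if (length(others)) {
        k <- min(sample.int(3, 1), length(others))
        ids <- sample(others, k)
        lo <- tibble(asv_id = registry$asv_id[i], ref_id = tax$ref_id[ids],
                     identity = round(stats::runif(k, 0.80,
                                                   max(0.801, t - 0.002)), 3),
                     member = FALSE)
        lo <- filter(lo, .data$identity < t - 1e-9)
        hit <- bind_rows(hit, lo)
      }
      hit
    })
    all_hits <- purrr::list_rbind(rows)
    blast <- mutate(
      all_hits,
      pident = .data$identity * 100, length = 420L, mismatch = 3L,
      gapopen = 0L, qstart = 1L, qend = 420L, sstart = 1L, send = 420L,
      evalue = 1e-150, bitscore = 700
    )[, c("asv_id", "ref_id", "pident", "length", "mismatch", "gapopen",
          "qstart", "qend", "sstart", "send", "evalue", "bitscore")]
    list(registry = registry, hits = blast,
         truth = all_hits[all_hits$member, c("asv_id", "ref_id")])
  })
}

#' Assemble a synthetic study world
#'
#' Bundles a reference database, an ASV registry with alignment hits, a
#' shared log-normal baseline community, and a study design of control plus
#' treatment conditions with planted fold changes. Defaults mirror the
#' emulated study: technical replicates (n = 4-6, default 6) sharing one
#' underlying composition, sequencing depth 1e5 reads, log-normal baseline
#' with sigma 1.5, and 10-fold planted responders. Responders are drawn
#' from a mid-abundance window (`responder_abundance_range`) so planted
#' effects are detectable at the stated depth while the planted mass keeps
#' compositional distortion of null taxa small.
#'
#' @param n_species,n_genera Reference database size.
#' @param treatments Character vector of treatment condition names.
#' @param control Control condition name (all fold changes 1).
#' @param replicates Technical replicates per condition (4-6 typical).
#' @param depth Reads per sample.
#' @param n_responders Planted responders per treatment.
#' @param effect_fold Planted fold change (> 0; default 10).
#' @param responder_overlap For exactly two treatments, the fraction `q` of
#'   each responder set shared between them (`NULL` = independent draws).
#' @param responder_abundance_range Baseline relative-abundance window from
#'   which responders are drawn.
#' @param baseline_sigma Log-normal sigma of the baseline community.
#' @param ambiguity_rate Passed to [generate_hit_table()].
#' @param dirichlet_theta Overdispersion of replicate compositions (0 =
#'   pure multinomial technical replicates, the default).
#' @param vocabulary Phenotype vocabulary for the reference database.
#' @param seed Integer seed; the whole world is a deterministic function of
#'   it.
#' @return List of class `synthetic_world`.
#' @export
synthetic_world <- function(n_species = 400, n_genera = 80,
                            treatments = c("fiber_A", "fiber_B"),
                            control = "control", replicates = 6,
                            depth = 1e5, n_responders = 12,
                            effect_fold = 10, responder_overlap = NULL,
                            responder_abundance_range = c(8e-4, 5e-3),
                            baseline_sigma = 1.5, ambiguity_rate = 0.3,
                            dirichlet_theta = 0,
                            vocabulary = phenotype_vocabulary(), seed = 1) {
  stopifnot(effect_fold > 0, replicates >= 2, depth >= 1)
  reference <- generate_reference_database(n_species, n_genera,
                                           vocabulary = vocabulary,
                                           seed = seed)
  asv <- generate_hit_table(reference, ambiguity_rate = ambiguity_rate,
                            seed = seed + 1L)
  withr::with_seed(seed + 2L, {
    base <- stats::rlnorm(n_species, 0, baseline_sigma)
    base <- base / sum(base)
    baseline <- tibble(asv_id = asv$registry$asv_id,
                       species = asv$registry$species,
                       rel_abundance = base)
    pool <- which(base >= responder_abundance_range[1] &
                    base <= responder_abundance_range[2])
    if (length(pool) < n_responders) {
      pool <- order(abs(base - mean(responder_abundance_range)))[
        seq_len(min(n_species, n_responders * 3))]
    }
    sets <- if (!is.null(responder_overlap) && length(treatments) == 2) {
      q <- responder_overlap
      stopifnot(q >= 0, q <= 1)
      n_shared <- round(q * n_responders)
      shared <- sample(pool, n_shared)
      rest <- setdiff(pool, shared)
      u1 <- sample(rest, n_responders - n_shared)
      u2 <- sample(setdiff(rest, u1), n_responders - n_shared)
      list(c(shared, u1), c(shared, u2))
    } else {
      purrr::map(treatments, function(tr) sample(pool, n_responders))
    }
    effects <- purrr::map2(treatments, sets, function(tr, idx) {
      tibble(condition = tr, species = baseline$species[idx],
             asv_id = baseline$asv_id[idx], fold = effect_fold)
    }) |> purrr::list_rbind()
  })
  structure(
    list(reference = reference, registry = asv$registry, hits = asv$hits,
         hit_truth = asv$truth, baseline = baseline, effects = effects,
         design = list(conditions = c(control, treatments),
                       control = control, replicates = replicates,
                       depth = depth, dirichlet_theta = dirichlet_theta),
         seed = seed),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  d <- x$design
  cat("Synthetic world:", nrow(x$baseline), "species,",
      length(d$conditions), "conditions x", d$replicates,
      "replicates, depth", format(d$depth, scientific = FALSE),
      "\n  planted effects:", nrow(x$effects), "(fold",
      paste(unique(x$effects$fold), collapse = "/"), ")\n")
  invisible(x)
}

#' Expected relative abundances per condition (the depth -> Inf limit)
#'
#' The exact compositions from which counts are drawn: baseline times the
#' planted fold changes, re-closed to 1. Useful for analytic round-trip
#' checks that bypass sampling noise.
#'
#' @param world A `synthetic_world`.
#' @return Long tibble `condition`, `asv_id`, `species`, `rel_abundance`.
#' @export
expected_abundances <- function(world) {
  purrr::map(world$design$conditions, function(cond) {
    p <- world$baseline$rel_abundance
    eff <- filter(world$effects, .data$condition == cond)
    fold <- rep(1, length(p))
    fold[match(eff$asv_id, world$baseline$asv_id)] <- eff$fold
    p <- p * fold
    tibble(condition = cond, asv_id = world$baseline$asv_id,
           species = world$baseline$species, rel_abundance = p / sum(p))
  }) |> purrr::list_rbind()
}

#' Draw the replicated count tables of a synthetic experiment
#'
#' For every condition, the expected composition ([expected_abundances()])
#' is sampled as multinomial counts at the design depth, one draw per
#' technical replicate (optionally Dirichlet-perturbed per replicate when
#' `dirichlet_theta > 0`). Deterministic given the seed.
#'
#' @param world A `synthetic_world`.
#' @param seed Integer seed (default: the world's seed + 3).
#' @return List of class `synthetic_experiment`: `counts` (long tibble
#'   `asv_id`, `sample`, `count`), `metadata` (`sample`, `condition`,
#'   `replicate`), `ground_truth` (planted responders per condition and the
#'   expected compositions).
#' @export
generate_experiment <- function(world, seed = world$seed + 3L) {
  stopifnot(inherits(world, "synthetic_world"))
  d <- world$design
  expected <- expected_abundances(world)
  withr::with_seed(seed, {
    res <- purrr::map(d$conditions, function(cond) {
      p <- expected$rel_abundance[expected$condition == cond]
      reps <- purrr::map(seq_len(d$replicates), function(r) {
        pr <- p
        if (d$dirichlet_theta > 0) {
          g <- stats::rgamma(length(p), shape = p / d$dirichlet_theta)
          pr <- g / sum(g)
        }
        tibble(asv_id = world$registry$asv_id,
               sample = sprintf("%s_r%d", cond, r),
               count = as.integer(stats::rmultinom(1, d$depth, pr)))
      })
      purrr::list_rbind(reps)
    })
    counts <- purrr::list_rbind(res)
  })
  metadata <- tidyr::expand_grid(condition = d$conditions,
                                 replicate = seq_len(d$replicates)) |>
    mutate(sample = sprintf("%s_r%d", .data$condition, .data$replicate)) |>
    select("sample", "condition", "replicate")
  structure(
    list(counts = counts, metadata = metadata,
         ground_truth = list(responders = world$effects,
                             expected = expected, seed = seed)),
    class = "synthetic_experiment"
  )
}

#' Write a synthetic world and experiment to disk in pipeline formats
#'
#' Emits exactly the files the analysis readers consume: `hits.tsv`
#' (12-column alignment tabular, no header), `taxonomy.tsv`,
#' `copy_numbers.tsv`, `annotations.tsv`, `counts.tsv` (features x
#' samples), `metadata.tsv`, `vocabulary.json`, and `ground_truth.json`.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @param experiment Optional pre-drawn `synthetic_experiment` (default: a
#'   fresh deterministic draw from the world's seed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir, experiment = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  experiment <- experiment %||% generate_experiment(world)
  readr::write_tsv(world$hits, file.path(dir, "hits.tsv"), col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(
    tibble(ref_id = world$reference$taxonomy$ref_id,
           lineage = format_lineage(world$reference$taxonomy,
                                    prefixes = TRUE)),
    file.path(dir, "taxonomy.tsv"), col_names = FALSE, progress = FALSE)
  readr::write_tsv(
    tibble(lineage = format_lineage(world$reference$copy_numbers,
                                    prefixes = TRUE),
           copy_number = world$reference$copy_numbers$copy_number),
    file.path(dir, "copy_numbers.tsv"), col_names = FALSE, progress = FALSE)
  ann <- world$reference$annotations
  readr::write_tsv(
    bind_cols(ann["genome_id"],
              tibble(lineage = format_lineage(ann, prefixes = TRUE)),
              ann[, setdiff(names(ann), c("genome_id", taxonomic_ranks))]),
    file.path(dir, "annotations.tsv"), progress = FALSE)
  write_feature_table(experiment$counts, file.path(dir, "counts.tsv"),
                      value = "count")
  readr::write_tsv(experiment$metadata, file.path(dir, "metadata.tsv"),
                   progress = FALSE)
  write_vocabulary(world$reference$vocabulary,
                   file.path(dir, "vocabulary.json"))
  jsonlite::write_json(
    list(seed = world$seed,
         design = world$design,
         responders = experiment$ground_truth$responders,
         baseline = world$baseline),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
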