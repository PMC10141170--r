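tiny_vocab <- phenotype_vocabulary(6, 2)

test_that("the generated world is a deterministic function of the seed", {
  w1 <- synthetic_world(n_species = 60, n_genera = 15, seed = 9,
                        vocabulary = tiny_vocab)
  w2 <- synthetic_world(n_species = 60, n_genera = 15, seed = 9,
                        vocabulary = tiny_vocab)
  expect_identical(w1$reference$taxonomy, w2$reference$taxonomy)
  expect_identical(w1$reference$annotations, w2$reference$annotations)
  expect_identical(w1$hits, w2$hits)
  expect_identical(w1$effects, w2$effects)
  e1 <- generate_experiment(w1); e2 <- generate_experiment(w2)
  expect_identical(e1$counts, e2$counts)
  w3 <- synthetic_world(n_species = 60, n_genera = 15, seed = 10,
                        vocabulary = tiny_vocab)
  expect_false(identical(w1$hits, w3$hits))
})

test_that("reference database honours prevalence targets and copy range", {
  prev <- default_prevalence(tiny_vocab)
  prev[["acetate"]] <- 1; prev[["GH2"]] <- 0
  db <- generate_reference_database(1000, 100, vocabulary = tiny_vocab,
                                    prevalence = prev, seed = 3)
  ann <- db$annotations
  expect_true(all(ann$acetate == 1))            # prevalence 1 -> all positive
  expect_true(all(ann$GH2 == 0))                # prevalence 0 -> all negative
  # empirical prevalence within the binomial 99% interval of the target
  for (lab in c("butyrate", "GH1", "B12")) {
    p <- prev[[lab]]
    k <- sum(ann[[lab]] >= 1)
    ci <- qbinom(c(0.005, 0.995), 1000, p)
    expect_gte(k, ci[1]); expect_lte(k, ci[2])
  }
  cn <- db$copy_numbers$copy_number
  expect_true(all(cn == round(cn) & cn >= 1 & cn <= 15))
  # genus correlation: within-genus variance of calls below global variance
  expect_true(all(table(db$taxonomy$genus) >= 1))
})

test_that("hit tables plant exactly the intended multi-taxonomy members", {
  db <- generate_reference_database(80, 20, vocabulary = tiny_vocab, seed = 6)
  # no ambiguity: every assignment has exactly one member
  h0 <- generate_hit_table(db, ambiguity_rate = 0, seed = 6)
  hits0 <- read_hit_table(I(paste(
    apply(h0$hits, 1, paste, collapse = "\t"), collapse = "\n")))
  asg0 <- assign_taxonomy(hits0, db$taxonomy)
  expect_true(all(asg0$n_members == 1))
  expect_equal(nrow(h0$truth), nrow(h0$registry))

  # with ambiguity: members recovered are exactly the planted ones,
  # below-threshold decoys never appear
  h1 <- generate_hit_table(db, ambiguity_rate = 1, seed = 7)
  hits1 <- read_hit_table(I(paste(
    apply(h1$hits, 1, paste, collapse = "\t"), collapse = "\n")))
  asg1 <- assign_taxonomy(hits1, db$taxonomy)
  truth_by_asv <- split(h1$truth$ref_id, h1$truth$asv_id)
  for (i in seq_len(nrow(asg1))) {
    got <- sort(asg1$members[[i]]$ref_id)
    want <- sort(unique(truth_by_asv[[asg1$asv_id[i]]]))
    # members are deduplicated by lineage, so compare at the species level
    want_sp <- sort(unique(db$taxonomy$species[match(want, db$taxonomy$ref_id)]))
    expect_equal(sort(unique(asg1$members[[i]]$species)), want_sp)
  }
  expect_gt(mean(asg1$n_members > 1), 0.5)
})

test_that("experiments hit the design depth and apply planted folds", {
  w <- synthetic_world(n_species = 60, n_genera = 15, seed = 14,
                       treatments = "fiber", n_responders = 5,
                       depth = 2e4, replicates = 4, vocabulary = tiny_vocab)
  ex <- generate_experiment(w)
  depths <- tapply(ex$counts$count, ex$counts$sample, sum)
  expect_true(all(depths == 2e4))
  expect_equal(nrow(ex$metadata), 8)
  exp_ab <- expected_abundances(w)
  sums <- tapply(exp_ab$rel_abundance, exp_ab$condition, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # the planted species' expected abundance ratio is fold / closure factor
  eff <- w$effects$asv_id
  ctrl <- exp_ab[exp_ab$condition == "control", ]
  trt <- exp_ab[exp_ab$condition == "fiber", ]
  ratio <- trt$rel_abundance[match(eff, trt$asv_id)] /
    ctrl$rel_abundance[match(eff, ctrl$asv_id)]
  m <- sum(ctrl$rel_abundance[match(eff, ctrl$asv_id)])
  expect_equal(ratio, rep(10 / (1 + 9 * m), length(eff)), tolerance = 1e-9)
})

test_that("CPI on exact abundances equals the analytic ground-truth product", {
  w <- synthetic_world(n_species = 50, n_genera = 12, seed = 20,
                       ambiguity_rate = 0, vocabulary = tiny_vocab)
  bpm <- build_bpm(w$reference$annotations, tiny_vocab)
  exp_ab <- expected_abundances(w)
  ctrl <- exp_ab[exp_ab$condition == "control", ]
  rel <- tibble::tibble(phylotype = ctrl$species, sample = "ctrl",
                        rel_abundance = ctrl$rel_abundance)
  tv <- taxon_phenotype_values(unique(rel$phylotype), bpm)
  cpi <- community_phenotype_index(rel, tv)
  # analytic: one genome per species, so CPI = sum a_s * bpm[s, ]
  ann <- w$reference$annotations
  for (ph in c("acetate", "GH1", "B2")) {
    v <- as.integer(ann[[ph]] >= 1)
    want <- sum(ctrl$rel_abundance * v[match(ctrl$species, ann$species)])
    expect_equal(cpi$cpi[cpi$phenotype == ph], want, tolerance = 1e-9)
  }
})

test_that("written worlds round-trip through the package readers", {
  w <- synthetic_world(n_species = 40, n_genera = 10, seed = 25,
                       vocabulary = tiny_vocab)
  d <- withr::local_tempdir()
  write_world(w, d)
  tax <- read_taxonomy(file.path(d, "taxonomy.tsv"))
  expect_equal(tax$species, w$reference$taxonomy$species)
  cn <- read_copy_number_table(file.path(d, "copy_numbers.tsv"))
  expect_equal(cn$copy_number, w$reference$copy_numbers$copy_number)
  ann <- read_annotations(file.path(d, "annotations.tsv"))
  expect_equal(ann$genome_id, w$reference$annotations$genome_id)
  expect_equal(ann$GH1, w$reference$annotations$GH1)
  counts <- read_count_table(file.path(d, "counts.tsv"))
  expect_equal(sort(unique(counts$sample)),
               sort(read_metadata(file.path(d, "metadata.tsv"))$sample))
  voc <- read_vocabulary(file.path(d, "vocabulary.json"))
  expect_equal(phenotype_labels(voc), phenotype_labels(tiny_vocab))
})
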