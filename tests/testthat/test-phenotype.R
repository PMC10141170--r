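small_vocab <- phenotype_vocabulary(n_gh = 4, n_pl = 2)

toy_annotations <- function(species, calls) {
  # calls: matrix genomes x labels (counts for families, 0/1 for pathways)
  dplyr::bind_cols(
    tibble::tibble(genome_id = paste0("g", seq_along(species))),
    toy_taxonomy(seq_along(species), species)[, glycomod::taxonomic_ranks],
    tibble::as_tibble(calls))
}

test_that("family binarization is a >=1 indicator and idempotent", {
  expect_equal(binarize_families(c(GH13 = 12, GH2 = 0)), c(GH13 = 1, GH2 = 0),
               ignore_attr = "names")
  expect_equal(binarize_families(c(0, 0, 0)), c(0L, 0L, 0L))
  expect_equal(binarize_families(c(1)), 1L)
  x <- c(0, 1, 5, 2)
  expect_equal(binarize_families(binarize_families(x)), binarize_families(x))
  expect_error(binarize_families(c(-1, 2)), ">= 0")
})

test_that("BPM copies pathway calls, binarizes families, defaults absences", {
  calls <- cbind(GH1 = c(3L, 0L), acetate = c(1L, 0L), butyrate = c(0L, 1L))
  ann <- toy_annotations(c("Genus spA", "Genus spB"), calls)
  bpm <- build_bpm(ann, small_vocab)
  expect_setequal(setdiff(names(bpm), "genome_id"),
                  phenotype_labels(small_vocab))
  expect_equal(bpm$GH1, c(1L, 0L))
  expect_equal(bpm$acetate, c(1L, 0L))
  expect_equal(bpm$GH2, c(0L, 0L))  # absent from annotations -> 0
  expect_true(all(unlist(bpm[, -1]) %in% 0:1))

  expect_error(build_bpm(ann[c(1, 1), ], small_vocab), "duplicate")
  rogue <- toy_annotations("Genus spA", cbind(GH99 = 1L))
  expect_error(build_bpm(rogue, small_vocab), "GH99")

  # brute-force per-cell evaluation on a random 10-genome fixture
  withr::with_seed(21, {
    labs <- phenotype_labels(small_vocab)
    fam <- family_labels(small_vocab)
    raw <- matrix(rpois(10 * length(labs), 0.8), nrow = 10,
                  dimnames = list(NULL, labs))
    raw[, setdiff(labs, fam)] <- rbinom(10 * (length(labs) - length(fam)), 1, 0.5)
    ann10 <- toy_annotations(paste("Genus", letters[1:10]), raw)
    bpm10 <- build_bpm(ann10, small_vocab)
    for (j in labs) {
      expect_equal(bpm10[[j]], as.integer(raw[, j] >= 1))
    }
  })
})

test_that("taxon values average BPM rows over member genomes", {
  calls <- cbind(GH1 = c(2L, 0L), acetate = c(1L, 0L))
  ann <- toy_annotations(c("Genus spA", "Genus spB"), calls)
  bpm <- build_bpm(ann, small_vocab)
  tv <- taxon_phenotype_values(c("Genus spA", "Genus spA/Genus spB"), bpm)
  v <- function(p, ph) tv$value[tv$phylotype == p & tv$phenotype == ph]
  expect_equal(v("Genus spA", "acetate"), 1)
  expect_equal(v("Genus spA/Genus spB", "acetate"), 0.5)
  expect_equal(v("Genus spA/Genus spB", "GH1"), 0.5)

  expect_message(
    tv2 <- taxon_phenotype_values(c("Genus spA", "unclassified"), bpm),
    "no genome mapping")
  expect_equal(attr(tv2, "unmapped"), "unclassified")

  # random mapping equals flatten-and-average
  withr::with_seed(13, {
    sp <- paste("Genus", letters[1:6])
    labs <- phenotype_labels(small_vocab)
    raw <- matrix(rbinom(6 * length(labs), 1, 0.4), nrow = 6,
                  dimnames = list(NULL, labs))
    bpm6 <- build_bpm(toy_annotations(sp, raw), small_vocab)
    name <- paste(sort(sp[c(2, 5, 6)]), collapse = "/")
    tv6 <- taxon_phenotype_values(name, bpm6)
    expect_equal(tv6$value,
                 unname(colMeans(raw[c(2, 5, 6),
                                     phenotype_labels(small_vocab)])))
  })
})

test_that("CPI is the mapped-mass-weighted dot product, bounded in [0,1]", {
  calls <- cbind(acetate = c(1L, 0L))
  ann <- toy_annotations(c("Genus spA", "Genus spB"), calls)
  bpm <- build_bpm(ann, small_vocab)
  tv <- taxon_phenotype_values(c("Genus spA", "Genus spB"), bpm)
  rel <- tibble::tibble(phylotype = c("Genus spA", "Genus spB"),
                        sample = "s1", rel_abundance = c(0.5, 0.5))
  cpi <- community_phenotype_index(rel, tv)
  expect_equal(cpi$cpi[cpi$phenotype == "acetate"], 0.5)
  # phenotype carried by no genome is exactly 0; all-positive phenotype 1
  expect_equal(cpi$cpi[cpi$phenotype == "GH3"], 0)
  tv_all1 <- dplyr::mutate(tv, value = 1)
  expect_equal(unique(community_phenotype_index(rel, tv_all1)$cpi), 1)

  # unmapped mass is re-closed and reported
  rel2 <- tibble::tibble(phylotype = c("Genus spA", "Genus spB", "unclassified"),
                         sample = "s1", rel_abundance = c(0.25, 0.25, 0.5))
  cpi2 <- community_phenotype_index(rel2, tv)
  expect_equal(cpi2$cpi[cpi2$phenotype == "acetate"], 0.5)
  expect_equal(attr(cpi2, "mapped_fraction")$mapped_fraction, 0.5)
  expect_error(community_phenotype_index(
    tibble::tibble(phylotype = "unclassified", sample = "s1",
                   rel_abundance = 1), tv), "mapped")

  # mixture linearity: a 50/50 pooled sample's CPI is the mean of the parts
  relA <- c(0.7, 0.2, 0.1); relB <- c(0.1, 0.6, 0.3)
  sp3 <- c("Genus spA", "Genus spB", "Genus spC")
  raw3 <- cbind(acetate = c(1L, 0L, 1L))
  bpm3 <- build_bpm(toy_annotations(sp3, raw3), small_vocab)
  tv3 <- taxon_phenotype_values(sp3, bpm3)
  rel3 <- tibble::tibble(
    phylotype = rep(sp3, 3),
    sample = rep(c("A", "B", "mix"), each = 3),
    rel_abundance = c(relA, relB, (relA + relB) / 2))
  cpi3 <- community_phenotype_index(rel3, tv3) |>
    dplyr::filter(phenotype == "acetate")
  expect_equal(cpi3$cpi[cpi3$sample == "mix"],
               mean(cpi3$cpi[cpi3$sample != "mix"]))
  # moving mass from a v=0 taxon to a v=1 taxon strictly raises CPI
  rel_shift <- tibble::tibble(phylotype = sp3, sample = "s",
                              rel_abundance = c(0.8, 0.1, 0.1))
  cpi_lo <- community_phenotype_index(
    tibble::tibble(phylotype = sp3, sample = "s",
                   rel_abundance = c(0.7, 0.2, 0.1)), tv3)
  cpi_hi <- community_phenotype_index(rel_shift, tv3)
  expect_gt(cpi_hi$cpi[cpi_hi$phenotype == "acetate"],
            cpi_lo$cpi[cpi_lo$phenotype == "acetate"])
})

test_that("percent change and net family shift follow the printed arithmetic", {
  md <- tibble::tibble(sample = c("c1", "c2", "t1", "t2"),
                       condition = c("control", "control", "trt", "trt"))
  cpi <- tidyr::expand_grid(sample = md$sample,
                            phenotype = c("GH1", "GH2", "B1")) |>
    dplyr::mutate(cpi = dplyr::case_when(
      phenotype == "GH1" & grepl("^t", sample) ~ 0.4,
      phenotype == "GH1" ~ 0.2,              # +100%
      phenotype == "GH2" & grepl("^t", sample) ~ 0.1,
      phenotype == "GH2" ~ 0.2,              # -50%
      TRUE ~ 0.3))                            # 0%
  ch <- phenotype_change_stats(cpi, md, control = "control")
  pc <- function(p) ch$percent_change[ch$phenotype == p]
  expect_equal(pc("GH1"), 100)
  expect_equal(pc("GH2"), -50)
  expect_equal(pc("B1"), 0)

  ns <- net_family_shift(ch, small_vocab)
  expect_equal(ns$net_shift, 50)   # +100 - 50, B1 not a family
  expect_equal(ns$n_families, 2L)
  expect_equal(net_family_shift(dplyr::mutate(ch, percent_change = c(10, -10, 5)[
    match(phenotype, c("GH1", "GH2", "B1"))]), small_vocab)$net_shift, 0)

  # zero control mean is flagged undefined, not computed
  cpi0 <- dplyr::mutate(cpi, cpi = ifelse(phenotype == "B1" &
                                            grepl("^c", sample), 0, cpi))
  ch0 <- phenotype_change_stats(cpi0, md, control = "control")
  expect_true(ch0$undefined_change[ch0$phenotype == "B1"])
  expect_true(is.na(ch0$percent_change[ch0$phenotype == "B1"]))
})
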