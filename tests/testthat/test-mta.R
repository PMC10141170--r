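test_that("identity window follows M - (1-M)/4 and closes as M -> 1", {
  expect_equal(mta_threshold(1), 1)
  expect_equal(mta_threshold(0.96), 0.95)
  expect_equal(mta_threshold(0.90), 0.875)
  grid <- seq(0.80, 1, by = 0.005)
  expect_equal(mta_threshold(grid), grid - (1 - grid) / 4)
  # monotone in M, window width shrinks to zero
  expect_true(all(diff(mta_threshold(grid)) > 0))
  width <- grid - mta_threshold(grid)
  expect_true(all(diff(width) < 0))
  expect_equal(width[length(width)], 0)
  expect_error(mta_threshold(0), "0, 1")
  expect_error(mta_threshold(1.2), "0, 1")
})

test_that("admission keeps hits strictly above threshold plus the maximum", {
  tax <- toy_taxonomy(c("refA", "refB", "refC"),
                      c("Bacteroides faecis", "Bacteroides thetaiotaomicron",
                        "Bacteroides fragilis"))
  hits <- tibble::tibble(asv_id = "asv1",
                         ref_id = c("refA", "refB", "refC"),
                         identity = c(0.98, 0.976, 0.970))
  asg <- assign_taxonomy(hits, tax)
  # M = 0.98, t = 0.975: refB admitted (0.976 > t), refC excluded (0.970)
  expect_equal(asg$max_identity, 0.98)
  expect_equal(asg$threshold, 0.975)
  expect_equal(asg$n_members, 2L)
  expect_equal(asg$display_name,
               "Bacteroides faecis/Bacteroides thetaiotaomicron")

  single <- assign_taxonomy(
    tibble::tibble(asv_id = "a", ref_id = "refA", identity = 0.99), tax)
  expect_equal(single$n_members, 1L)
  expect_equal(single$display_name, "Bacteroides faecis")

  # two refs at identical M with the same lineage collapse to one member
  tax2 <- toy_taxonomy(c("r1", "r2"), c("Escherichia coli", "Escherichia coli"))
  dup <- assign_taxonomy(
    tibble::tibble(asv_id = "a", ref_id = c("r1", "r2"),
                   identity = c(0.99, 0.99)), tax2)
  expect_equal(dup$n_members, 1L)

  expect_error(
    assign_taxonomy(tibble::tibble(asv_id = "a", ref_id = "ghost",
                                   identity = 0.9), tax),
    "ghost")
})

test_that("assignment agrees with the exhaustive filter-and-dedupe oracle", {
  withr::with_seed(42, {
    species_pool <- paste("Genus", letters[1:8])
    tax <- toy_taxonomy(sprintf("ref%02d", 1:20),
                        sample(species_pool, 20, replace = TRUE))
    for (i in 1:30) {
      n <- sample(1:20, 1)
      refs <- sample(tax$ref_id, n)
      hits <- tibble::tibble(asv_id = "a", ref_id = refs,
                             identity = round(runif(n, 0.85, 1), 3))
      asg <- assign_taxonomy(hits, tax)
      expected <- oracle_assign_members(hits, tax)
      got <- asg$members[[1]][, taxonomic_ranks]
      expect_equal(nrow(got), nrow(expected))
      expect_setequal(got$species, expected$species)
      # the top-identity lineage is always a member
      top <- tax$species[match(hits$ref_id[which.max(round(hits$identity, 6))],
                               tax$ref_id)]
      expect_true(top %in% got$species)
    }
  })
})

test_that("phylotype collapse conserves counts and builds multi-names", {
  tax <- toy_taxonomy(c("rA", "rB", "rC"),
                      c("Bacteroides faecis", "Bacteroides thetaiotaomicron",
                        "Bacteroides fragilis"))
  hits <- tibble::tibble(
    asv_id = c("asv1", "asv1", "asv2", "asv3"),
    ref_id = c("rA", "rB", "rC", "rC"),
    identity = c(0.99, 0.99, 0.98, 0.97))
  asg <- assign_taxonomy(hits, tax)
  m <- matrix(c(10, 5, 3, 2, 0, 7), nrow = 3, byrow = TRUE,
              dimnames = list(c("asv1", "asv2", "asv3"), c("s1", "s2")))
  counts <- long_counts(m)

  sp <- collapse_phylotypes(counts, asg, rank = "species")
  expect_true("Bacteroides faecis/Bacteroides thetaiotaomicron" %in%
                sp$phylotype)
  # conservation per sample, exact
  tot <- dplyr::count(sp, sample, wt = count)
  expect_equal(tot$n[tot$sample == "s1"], 13)
  expect_equal(tot$n[tot$sample == "s2"], 14)
  # asv2 + asv3 share the fragilis phylotype
  frag <- dplyr::filter(sp, phylotype == "Bacteroides fragilis")
  expect_equal(frag$count[frag$sample == "s2"], 9)

  # all members share the family -> single name, never a multi-name
  fam <- collapse_phylotypes(counts, asg, rank = "family")
  expect_equal(unique(fam$phylotype), "FamilyX")
  # collapsing higher never increases the number of phylotypes
  expect_lte(dplyr::n_distinct(fam$phylotype), dplyr::n_distinct(sp$phylotype))

  # ASV with no assignment lands in "unclassified", counts still conserved
  m2 <- rbind(m, asv9 = c(4, 4))
  sp2 <- collapse_phylotypes(long_counts(m2), asg, rank = "species")
  expect_true("unclassified" %in% sp2$phylotype)
  expect_equal(sum(sp2$count), sum(m2))

  expect_error(collapse_phylotypes(counts, asg, rank = "kingdom"), "rank")
})

test_that("phylotype census matches brute-force set arithmetic", {
  md <- tibble::tibble(sample = c("a1", "a2", "b1", "b2"),
                       condition = c("A", "A", "B", "B"))
  # identical 50-phylotype sets in both conditions
  m <- matrix(1, nrow = 50, ncol = 4,
              dimnames = list(paste0("p", 1:50), md$sample))
  cen <- count_phylotypes(long_counts(m, "phylotype"), md)
  expect_equal(cen$total_unique, 50)
  expect_equal(cen$mean_per_condition, 50)

  # disjoint 30 + 20
  m2 <- matrix(0, nrow = 50, ncol = 4,
               dimnames = list(paste0("p", 1:50), md$sample))
  m2[1:30, 1:2] <- 5
  m2[31:50, 3:4] <- 5
  cen2 <- count_phylotypes(long_counts(m2, "phylotype"), md)
  expect_equal(cen2$total_unique, 50)
  expect_equal(cen2$per_condition$n_phylotypes[order(cen2$per_condition$condition)],
               c(30, 20))
  expect_equal(cen2$mean_per_condition, 25)

  # random membership vs brute force, with a presence floor
  withr::with_seed(7, {
    m3 <- matrix(rpois(200, 1), nrow = 50,
                 dimnames = list(paste0("p", 1:50), md$sample))
    cen3 <- count_phylotypes(long_counts(m3, "phylotype"), md,
                             presence_floor = 2)
    in_a <- rownames(m3)[apply(m3[, 1:2] >= 2, 1, any)]
    in_b <- rownames(m3)[apply(m3[, 3:4] >= 2, 1, any)]
    expect_equal(cen3$total_unique, length(union(in_a, in_b)))
    expect_equal(cen3$mean_per_condition,
                 mean(c(length(in_a), length(in_b))))
  })
})
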