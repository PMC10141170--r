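# Independent brute-force oracles, deliberately written with different
# machinery than the package implementations.

# Exact two-sided Mann-Whitney p by enumerating every split of the pooled
# values and counting pairwise wins (U with 0.5 per tie), no ranks involved.
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_stat(x, y)
  u_null <- apply(idx, 2, function(i) u_stat(pooled[i], pooled[-i]))
  eps <- 1e-9
  lo <- mean(u_null <= u_obs + eps)
  hi <- mean(u_null >= u_obs - eps)
  min(1, 2 * min(lo, hi))
}

# Filter-and-dedupe reference for the multi-taxonomy rule, one ASV at a time.
oracle_assign_members <- function(hits, taxonomy, digits = 6) {
  id <- round(hits$identity, digits)
  M <- max(id)
  t <- round(M - (1 - M) / 4, digits)
  keep <- hits$ref_id[id > t | id == M]
  lin <- taxonomy[match(keep, taxonomy$ref_id), glycomod::taxonomic_ranks]
  unique(lin)
}

# Tiny taxonomy builder: species strings "Genus species", ranks filled upward.
toy_taxonomy <- function(ref_ids, species, genus = sub(" .*", "", species),
                         family = "FamilyX") {
  tibble::tibble(
    ref_id = ref_ids, domain = "Bacteria", phylum = "PhylumX",
    class = "ClassX", order = "OrderX", family = family,
    genus = genus, species = species
  )
}

# Long counts from a named matrix (phylotypes/ASVs x samples)
long_counts <- function(m, feature = "asv_id") {
  out <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(!!feature := rownames(m)),
                     tibble::as_tibble(m)),
    -1, names_to = "sample", values_to = "count")
  out
}
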