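test_that("MOLPRINT2D environments match hand enumeration for ethanol", {
  # ethanol heavy atoms C1-C2-O3; environments to depth 2:
  #   C1: self C, d1 {C}, d2 {O};  C2: self C, d1 {C,O};  O3: self O, d1 {C}, d2 {C}
  eth <- smiles_to_mol("CCO", "ethanol")
  fp <- molprint2d(eth)
  manual <- c("C|1:Cx1|2:Ox1", "C|1:Cx1,Ox1|2:", "O|1:Cx1|2:Cx1")
  expect_setequal(fp$hashes, vapply(manual, phytophore:::hash32, 0))
  # methane: a single heavy atom, one environment
  expect_length(molprint2d(smiles_to_mol("C", "methane"))$hashes, 1L)
})

test_that("fingerprints are canonical across input atom orderings", {
  a <- molprint2d(smiles_to_mol("c1ccccc1CCO", "m1"))
  b <- molprint2d(smiles_to_mol("OCCc1ccccc1", "m2"))
  expect_identical(a$hashes, b$hashes)
  expect_equal(fp_tanimoto(a, b), 1)
})

test_that("Tanimoto follows direct set arithmetic", {
  fp <- function(h) structure(list(molecule_id = "x", hashes = h),
                              class = "phyto_fp")
  expect_equal(fp_tanimoto(fp(c(1, 2, 3)), fp(c(2, 3, 4))), 0.5)
  expect_equal(fp_tanimoto(fp(1:3), fp(1:3)), 1)
  expect_equal(fp_tanimoto(fp(1:3), fp(4:6)), 0)
  expect_warning(z <- fp_tanimoto(fp(numeric()), fp(numeric())), "empty")
  expect_equal(z, 0)
})

test_that("agglomeration equals a naive O(n^3) oracle and ignores input order", {
  fps <- random_fingerprints(8, seed = 10)
  dend <- hierarchical_cluster(fps)
  expect_false(has_distance_ties(dend$dist))  # merge order is unambiguous
  oracle <- naive_average_agglomeration(dend$dist)
  expect_equal(sort(dend$hclust$height), sort(oracle$heights),
               tolerance = 1e-12)
  n <- length(fps)
  for (k in 2:(n - 1)) {
    ours <- cutree(dend$hclust, k = k)
    theirs <- oracle$partitions[[n - k]]
    expect_identical(partition_key(ours), partition_key(theirs),
                     label = sprintf("partition at k=%d", k))
  }
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  dend2 <- hierarchical_cluster(fps[perm])
  for (k in 2:(n - 1)) {
    expect_identical(partition_key(cutree(dend$hclust, k)[dend$ids]),
                     partition_key(cutree(dend2$hclust, k)[dend2$ids]))
  }
})

test_that("Kelley level selection minimizes the penalty over all levels", {
  col <- make_scaffold_collection(3, seed = 9, members_per_family = 4)
  dend <- hierarchical_cluster(col$fingerprints)
  lev <- kelley_select(dend)
  pen <- lev$penalties
  chosen <- pen$penalty[pen$k == lev$k]
  expect_true(all(chosen <= pen$penalty[!is.na(pen$penalty)] + 1e-12))
  # independent exhaustive re-scan of the penalty definition
  n <- length(dend$ids)
  ks <- 2:(n - 1)
  spread <- vapply(ks, function(k) {
    part <- cutree(dend$hclust, k)
    sizes <- table(part)
    multi <- as.integer(names(sizes)[sizes >= 2])
    if (!length(multi)) return(NA_real_)
    mean(vapply(multi, function(cl) {
      ix <- which(part == cl)
      mean(dend$dist[ix, ix][upper.tri(diag(length(ix)))])
    }, 0))
  }, 0)
  ok <- !is.na(spread)
  rng <- range(spread[ok])
  norm <- 1 + (sum(ok) - 1) * (spread - rng[1]) / diff(rng)
  penalty <- norm + ks
  expect_identical(lev$k, ks[which.min(replace(penalty, !ok, Inf))])
})

test_that("two tight planted families select exactly two clusters", {
  col <- make_scaffold_collection(2, seed = 7, members_per_family = 5)
  lev <- kelley_select(hierarchical_cluster(col$fingerprints))
  expect_identical(lev$k, 2L)
  expect_equal(adjusted_rand(lev$partition[col$ids], col$family), 1)
})

test_that("novelty clusters are exactly the reference-free ones", {
  col <- make_scaffold_collection(3, seed = 13, members_per_family = 4)
  hits <- col$molecules[col$family == 1]
  knowns <- col$molecules[col$family != 1]
  sol <- cluster_with_reference(hits, knowns)
  nov <- novelty_clusters(sol)
  expect_length(nov, 1L)
  expect_setequal(names(sol$clusters)[sol$clusters == nov],
                  vapply(hits, `[[`, "", "id"))
  # all ids in the reference set: nothing is novel
  all_ref <- cluster_with_reference(list(), col$molecules)
  expect_length(novelty_clusters(all_ref), 0L)
  # empty reference set: every cluster is novel
  no_ref <- cluster_with_reference(col$molecules, list())
  expect_identical(novelty_clusters(no_ref),
                   sort(unique(as.integer(no_ref$clusters))))
  tab <- cluster_membership_table(sol)
  expect_identical(nrow(tab), length(sol$clusters))
  expect_identical(tab$cluster_is_novel, tab$cluster_index %in% nov)
})

test_that("flat spread profiles resolve toward fewer clusters", {
  fp <- function(id, h) structure(list(molecule_id = id, hashes = h),
                                  class = "phyto_fp")
  # mutually disjoint fingerprints: every pairwise distance is 1, so
  # every level has the same spread and the tie goes to the 2-cluster cut
  fps <- list(fp("a", 1:3), fp("b", 4:6), fp("c", 7:9), fp("d", 10:12))
  lev <- kelley_select(hierarchical_cluster(fps))
  expect_identical(lev$k, 2L)
  expect_error(kelley_select(hierarchical_cluster(fps[1:2])), "at least 3")
})
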