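# Shared helpers: tiny hand-built poses and naive oracles kept
# independent of the implementation paths they cross-check.

make_test_pose <- function(id, elements, coords, pcharge = NULL,
                           frame = "test-frame") {
  as_pose(phyto_mol(id, elements, coords = coords, pcharge = pcharge),
          frame_tag = frame)
}

# 5-atom bent fragment used across the field tests
fragment_pose <- function(id = "frag", frame = "test-frame", shift = c(0, 0, 0)) {
  xyz <- rbind(c(0, 0, 0), c(1.45, 0.2, 0), c(2.2, 1.4, 0.3),
               c(-0.8, 1.1, -0.4), c(0.4, -1.3, 0.5))
  make_test_pose(id, c("C", "C", "N", "O", "C"), sweep(xyz, 2, shift, "+"),
                 pcharge = c(0.12, -0.05, -0.42, -0.3, 0.65), frame = frame)
}

# numeric 3D quadrature of the product of two atom-Gaussian densities
quadrature_overlap <- function(elements_a, xyz_a, elements_b, xyz_b,
                               h = 0.15, pad = 5.5) {
  p <- 2.7
  alpha <- function(r) pi * (3 * p / (4 * pi * r^3))^(2 / 3)
  ra <- phytophore:::vdw_radius(elements_a)
  rb <- phytophore:::vdw_radius(elements_b)
  all_xyz <- rbind(xyz_a, xyz_b)
  lo <- apply(all_xyz, 2, min) - pad
  hi <- apply(all_xyz, 2, max) + pad
  gx <- seq(lo[1], hi[1], by = h)
  gy <- seq(lo[2], hi[2], by = h)
  gz <- seq(lo[3], hi[3], by = h)
  pts <- as.matrix(expand.grid(gx, gy, gz))
  dens <- function(el_r, xyz) {
    d <- numeric(nrow(pts))
    for (i in seq_len(nrow(xyz))) {
      a <- alpha(el_r[i])
      d <- d + p * exp(-a * rowSums(sweep(pts, 2, xyz[i, ])^2))
    }
    d
  }
  sum(dens(ra, xyz_a) * dens(rb, xyz_b)) * h^3
}

# naive O(n^3) average-linkage agglomeration on a distance matrix;
# returns the merge heights and the partitions after each merge
naive_average_agglomeration <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  partitions <- list()
  heights <- numeric()
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    bestd <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < bestd - 1e-12) { bestd <- d; best <- c(i, j) }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
    heights <- c(heights, bestd)
    memb <- integer(n)
    for (k in seq_along(clusters)) memb[clusters[[k]]] <- k
    partitions[[length(partitions) + 1L]] <- memb
  }
  list(heights = heights, partitions = partitions)
}

# canonical key of a partition (invariant to label permutation)
partition_key <- function(memb) {
  groups <- vapply(split(seq_along(memb), memb), function(ix)
    paste(sort(ix), collapse = ","), "")
  paste(sort(groups), collapse = "|")
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# fingerprints with generic (tie-free) pairwise distances, for oracle
# comparisons where the merge order must be unambiguous
random_fingerprints <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    structure(list(molecule_id = sprintf("R%02d", i),
                   hashes = sort(sample(1:200, sample(10:40, 1)))),
              class = "phyto_fp")
  })
}

has_distance_ties <- function(D) {
  d <- round(D[upper.tri(D)], 12)
  anyDuplicated(d) > 0
}
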