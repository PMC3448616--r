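# Scaffold-novelty analysis: MOLPRINT2D atom-environment fingerprints
# (32-bit hashed), Tanimoto similarities, average-linkage hierarchical
# clustering, Kelley-criterion level selection, and novelty flags for
# clusters that contain no known-inhibitor reference member.

# FNV-1a 32-bit string hash, done in doubles to stay exact mod 2^32
hash32 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    lo <- bitwXor(as.integer(lo), as.integer(b %% 256))
    h <- hi * 65536 + lo
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
    h <- h %% 4294967296
  }
  h
}

#' MOLPRINT2D atom-environment fingerprint
#'
#' For every heavy atom, an environment string encodes the atom's type
#' (element plus aromaticity flag) together with the sorted counts of
#' neighbour atom types at topological distances 1 and 2; each
#' environment is hashed to 32 bits and the fingerprint is the set of
#' hashes.
#'
#' @param mol a `phyto_mol`.
#' @return object of class `phyto_fp`: `molecule_id` and sorted numeric
#'   vector `hashes`.
#' @export
molprint2d <- function(mol) {
  heavy <- which(mol$elements != "H")
  if (!length(heavy)) stop("fingerprint needs at least one heavy atom")
  arom <- aromatic_atoms(mol)
  atype <- paste0(mol$elements, ifelse(arom, ":ar", ""))
  g <- mol_igraph(mol)
  td <- igraph::distances(g)
  envs <- vapply(heavy, function(a) {
    shell <- function(d) {
      nb <- heavy[td[a, heavy] == d]
      if (!length(nb)) return("")
      tab <- table(atype[nb])
      paste(paste0(names(tab), "x", as.integer(tab)), collapse = ",")
    }
    paste0(atype[a], "|1:", shell(1), "|2:", shell(2))
  }, "")
  structure(list(molecule_id = mol$id,
                 hashes = sort(unique(vapply(unique(envs), hash32, 0)))),
            class = "phyto_fp")
}

#' Tanimoto similarity of two fingerprints
#'
#' Set Tanimoto `|A & B| / |A | B|`; two empty fingerprints compare as 0
#' with a warning.
#'
#' @param a,b `phyto_fp` objects.
#' @return similarity in `[0, 1]`.
#' @export
fp_tanimoto <- function(a, b) {
  ha <- a$hashes; hb <- b$hashes
  if (!length(ha) && !length(hb)) {
    warning("both fingerprints empty; Tanimoto defined as 0")
    return(0)
  }
  ni <- length(intersect(ha, hb))
  ni / (length(ha) + length(hb) - ni)
}

fp_distance_matrix <- function(fps) {
  n <- length(fps)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- 1 - fp_tanimoto(fps[[i]], fps[[j]])
    }
  }
  dimnames(D) <- list(vapply(fps, `[[`, "", "molecule_id"),
                      vapply(fps, `[[`, "", "molecule_id"))
  D
}

#' Hierarchical clustering of fingerprints
#'
#' Agglomerative clustering on distance `1 - Tanimoto`. Input order
#' does not matter: fingerprints are sorted by molecule id before
#' agglomeration so ties break deterministically.
#'
#' @param fps list of at least two `phyto_fp`.
#' @param linkage agglomeration method (default group average).
#' @return object of class `phyto_dendrogram`: `hclust`, `dist`
#'   (matrix), `ids`.
#' @export
hierarchical_cluster <- function(fps, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (length(fps) < 2L) stop("clustering needs at least two fingerprints")
  ids <- vapply(fps, `[[`, "", "molecule_id")
  if (anyDuplicated(ids)) stop("duplicate molecule ids")
  fps <- fps[order(ids)]
  D <- fp_distance_matrix(fps)
  hc <- hclust(as.dist(D), method = linkage)
  structure(list(hclust = hc, dist = D, ids = sort(ids)),
            class = "phyto_dendrogram")
}

#' Kelley-criterion level selection
#'
#' For each cut level with `k` clusters, the spread is the mean over
#' multi-member clusters of their mean pairwise distance; spreads are
#' min-max normalized onto `[1, N_levels]` and the penalty
#' `normalized_spread + k` is minimized (ties toward fewer clusters).
#' Levels scanned are `k = 2 .. n-1`; if no level has a multi-member
#' cluster spread to compare (degenerate dendrogram), the 2-cluster
#' level is returned with a warning.
#'
#' @param dendrogram a `phyto_dendrogram` from at least 3 items.
#' @return list of class `kelley_level`: `k`, `partition` (named id ->
#'   cluster index), `penalties` (data.frame over levels).
#' @export
kelley_select <- function(dendrogram) {
  hc <- dendrogram$hclust
  D <- dendrogram$dist
  n <- length(dendrogram$ids)
  if (n < 3L) stop("Kelley selection needs at least 3 clustered items")
  ks <- 2:(n - 1)
  spreads <- rep(NA_real_, length(ks))
  parts <- vector("list", length(ks))
  for (t in seq_along(ks)) {
    part <- cutree(hc, k = ks[t])
    parts[[t]] <- part
    sizes <- table(part)
    multi <- as.integer(names(sizes)[sizes >= 2])
    if (!length(multi)) next
    sp <- vapply(multi, function(cl) {
      idx <- which(part == cl)
      mean(D[idx, idx][upper.tri(diag(length(idx)))])
    }, 0)
    spreads[t] <- mean(sp)
  }
  ok <- !is.na(spreads)
  if (!any(ok)) {
    warning("all levels degenerate; returning the 2-cluster level")
    sel <- 1L
    pen <- data.frame(k = ks, spread = spreads, penalty = NA_real_)
  } else {
    nl <- sum(ok)
    rng <- range(spreads[ok])
    norm <- rep(NA_real_, length(ks))
    norm[ok] <- if (diff(rng) < 1e-15) 1 else
      1 + (nl - 1) * (spreads[ok] - rng[1]) / diff(rng)
    penalty <- norm + ks
    pen <- data.frame(k = ks, spread = spreads, normalized = norm,
                      penalty = penalty)
    cand <- which(ok)
    sel <- cand[order(penalty[cand], ks[cand])][1]
  }
  structure(list(k = ks[sel], partition = parts[[sel]], penalties = pen),
            class = "kelley_level")
}

#' Cluster screening hits together with known inhibitors
#'
#' Fingerprints the merged set, clusters it, picks the level by the
#' Kelley criterion and flags clusters containing no reference member
#' as novel scaffolds.
#'
#' @param hits list of `phyto_mol` (screening hits).
#' @param reference list of `phyto_mol` (known inhibitors).
#' @param linkage agglomeration method.
#' @return object of class `cluster_solution`: `dendrogram`, `level`,
#'   `clusters` (named membership vector), `novelty_flags` (per-cluster
#'   logical), `reference_ids`.
#' @export
cluster_with_reference <- function(hits, reference,
                                   linkage = "average") {
  mols <- c(hits, reference)
  fps <- lapply(mols, molprint2d)
  dend <- hierarchical_cluster(fps, linkage = linkage)
  level <- kelley_select(dend)
  ref_ids <- vapply(reference, `[[`, "", "id")
  nov <- novelty_flags(level$partition, ref_ids)
  structure(list(dendrogram = dend, level = level,
                 clusters = level$partition, novelty_flags = nov,
                 reference_ids = ref_ids),
            class = "cluster_solution")
}

novelty_flags <- function(partition, reference_ids) {
  vapply(sort(unique(partition)), function(cl) {
    !any(names(partition)[partition == cl] %in% reference_ids)
  }, TRUE)
}

#' Clusters containing no known-inhibitor member
#'
#' @param solution a `cluster_solution` (or named membership vector).
#' @param reference_ids ids of the known-inhibitor reference set.
#' @return integer vector of novel cluster indices.
#' @export
novelty_clusters <- function(solution, reference_ids = NULL) {
  part <- if (inherits(solution, "cluster_solution")) solution$clusters else solution
  if (is.null(reference_ids)) reference_ids <- solution$reference_ids
  cls <- sort(unique(part))
  cls[vapply(cls, function(cl)
    !any(names(part)[part == cl] %in% reference_ids), TRUE)]
}

#' Cluster membership table
#' @param solution a `cluster_solution`.
#' @return data.frame: `molecule_id`, `cluster_index`, `is_reference`,
#'   `cluster_is_novel`.
#' @export
cluster_membership_table <- function(solution) {
  part <- solution$clusters
  novel <- novelty_clusters(solution)
  data.frame(molecule_id = names(part),
             cluster_index = as.integer(part),
             is_reference = names(part) %in% solution$reference_ids,
             cluster_is_novel = as.integer(part) %in% novel,
             row.names = NULL)
}

#' Newick-like text rendering of a dendrogram
#' @param dendrogram a `phyto_dendrogram`.
#' @return single Newick string (branch lengths from merge heights).
#' @export
dendrogram_newick <- function(dendrogram) {
  hc <- dendrogram$hclust
  lab <- hc$labels
  node <- function(i, parent_h) {
    if (i < 0) return(sprintf("%s:%.6f", lab[-i], parent_h))
    sprintf("(%s,%s):%.6f", node(hc$merge[i, 1], hc$height[i]),
            node(hc$merge[i, 2], hc$height[i]),
            parent_h - hc$height[i])
  }
  top <- nrow(hc$merge)
  sprintf("(%s,%s);", node(hc$merge[top, 1], hc$height[top]),
          node(hc$merge[top, 2], hc$height[top]))
}
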