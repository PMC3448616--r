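# Deterministic rule-based 3D construction and conformer enumeration.
#
# Geometry is built from internal coordinates (covalent bond lengths,
# hybridization-ideal angles, planar ring polygons) so that identical
# input always yields identical coordinates; conformers come from a
# systematic torsion driver over rotatable bonds ranked by a simple
# steric-repulsion score. The goal is reproducible, sterically sane
# geometry for screening and testing, not force-field-quality structures.

.cov_radius <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                 P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39)

.vdw_radius <- c(H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                 P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)

vdw_radius <- function(elements) {
  r <- .vdw_radius[elements]
  r[is.na(r)] <- 1.7
  unname(r)
}

bond_length_rule <- function(e1, e2, order, aromatic = FALSE) {
  r1 <- .cov_radius[e1]; r2 <- .cov_radius[e2]
  if (is.na(r1)) r1 <- 0.76
  if (is.na(r2)) r2 <- 0.76
  f <- if (aromatic || order == 4L) 0.93 else if (order == 2L) 0.87 else
    if (order >= 3L) 0.78 else 1.0
  unname((r1 + r2) * f)
}

# sp hybridization proxy per atom from explicit bond orders
atom_hybrid <- function(mol) {
  n <- n_atoms(mol)
  ndouble <- integer(n); ntriple <- integer(n); narom <- integer(n)
  for (k in seq_len(nrow(mol$bonds))) {
    o <- mol$bonds$order[k]
    for (a in c(mol$bonds$i[k], mol$bonds$j[k])) {
      if (o == 2L) ndouble[a] <- ndouble[a] + 1L
      if (o >= 3L && o != 4L) ntriple[a] <- ntriple[a] + 1L
      if (o == 4L) narom[a] <- narom[a] + 1L
    }
  }
  hy <- rep(3L, n)
  hy[ndouble > 0L | narom > 0L] <- 2L
  hy[ntriple > 0L | ndouble >= 2L] <- 1L
  hy
}

# direction for one more substituent on atom p given unit vectors to the
# already-placed neighbours; deterministic
substituent_direction <- function(evecs, hybrid, slot = 0L) {
  m <- length(evecs)
  theta <- if (hybrid == 3L) 109.47 * pi / 180 else if (hybrid == 2L)
    120 * pi / 180 else pi
  if (m == 0L) return(c(1, 0, 0))
  if (m == 1L) {
    e1 <- evecs[[1]]
    w <- perp_vector(e1)
    az <- slot * 2 * pi / 3
    w2 <- cos(az) * w + sin(az) * unitv(cross3(e1, w))
    return(unitv(cos(theta) * e1 + sin(theta) * w2))
  }
  if (m == 2L) {
    b <- -(evecs[[1]] + evecs[[2]])
    if (vnorm(b) < 1e-8) b <- perp_vector(evecs[[1]])
    b <- unitv(b)
    if (hybrid == 3L) {
      w <- cross3(evecs[[1]], evecs[[2]])
      if (vnorm(w) < 1e-8) w <- perp_vector(b)
      w <- unitv(w)
      half <- 54.73 * pi / 180
      sgn <- if (slot %% 2L == 0L) 1 else -1
      return(unitv(cos(half) * b + sgn * sin(half) * w))
    }
    return(b)
  }
  b <- -Reduce(`+`, evecs)
  if (vnorm(b) < 1e-8) b <- perp_vector(evecs[[1]])
  unitv(b)
}

# regular m-gon through the directed edge p1 -> p2, on the side away
# from `away` (a point); returns m x 3 coordinates starting at p1
polygon_through_edge <- function(p1, p2, m, away) {
  L <- vnorm(p2 - p1)
  mid <- (p1 + p2) / 2
  # ring plane: plane containing the edge and the `away` point
  nrm <- cross3(p2 - p1, away - p1)
  if (vnorm(nrm) < 1e-8) nrm <- cross3(p2 - p1, perp_vector(p2 - p1))
  nrm <- unitv(nrm)
  inplane <- unitv(cross3(nrm, p2 - p1))
  if (sum(inplane * (away - mid)) > 0) inplane <- -inplane
  h <- L / (2 * tan(pi / m))
  ctr <- mid + h * inplane
  step <- 2 * pi / m
  # rotation direction that carries p1 to p2 in one step
  cand1 <- drop(rotate_about_axis(rbind(p1), ctr, nrm, step))
  dir <- if (vnorm(cand1 - p2) < 1e-6 * max(1, L)) 1 else -1
  out <- matrix(NA_real_, m, 3)
  for (k in 0:(m - 1)) {
    out[k + 1, ] <- drop(rotate_about_axis(rbind(p1), ctr, nrm, dir * k * step))
  }
  out
}

# planar layout (z = 0) of one fused-ring system; bridged/spiro systems
# are rejected
layout_ring_system <- function(mol, rings) {
  arom <- aromatic_rings(mol)
  arom_keys <- vapply(arom, function(r) paste(sort(r), collapse = "-"), "")
  placed <- list()  # atom index -> coordinate
  pending <- rings
  first <- pending[[1]]
  pending <- pending[-1]
  m <- length(first)
  is_ar <- paste(sort(first), collapse = "-") %in% arom_keys
  L <- bond_length_rule(mol$elements[first[1]], mol$elements[first[2]],
                        1L, aromatic = is_ar)
  R <- L / (2 * sin(pi / m))
  for (k in seq_len(m)) {
    ang <- 2 * pi * (k - 1) / m
    placed[[as.character(first[k])]] <- c(R * cos(ang), R * sin(ang), 0)
  }
  while (length(pending)) {
    progressed <- FALSE
    for (q in seq_along(pending)) {
      ring <- pending[[q]]
      shared <- ring[as.character(ring) %in% names(placed)]
      if (length(shared) < 2L) next
      if (length(shared) > 2L) {
        # ring fully or over-determined already (ortho-fused chains)
        if (all(as.character(ring) %in% names(placed))) {
          pending <- pending[-q]; progressed <- TRUE; break
        }
        stop("unsupported ring fusion (bridged/spiro) in ", mol$id)
      }
      # rotate cycle so it runs shared[1], shared[2], rest
      pos <- match(shared, ring)
      if (!(abs(diff(pos)) == 1L || abs(diff(pos)) == length(ring) - 1L))
        stop("unsupported ring fusion (non-adjacent sharing) in ", mol$id)
      idx <- match(shared[1], ring)
      ord <- c(ring[idx:length(ring)], ring[seq_len(idx - 1L)])
      if (ord[2] != shared[2]) ord <- c(ord[1], rev(ord[-1]))
      p1 <- placed[[as.character(ord[1])]]
      p2 <- placed[[as.character(ord[2])]]
      away <- Reduce(`+`, placed) / length(placed)
      poly <- polygon_through_edge(p1, p2, length(ring), away)
      for (k in seq_along(ord)) {
        key <- as.character(ord[k])
        if (is.null(placed[[key]])) placed[[key]] <- poly[k, ]
      }
      pending <- pending[-q]
      progressed <- TRUE
      break
    }
    if (!progressed) stop("disconnected ring system layout in ", mol$id)
  }
  atoms <- as.integer(names(placed))
  coords <- do.call(rbind, placed)
  list(atoms = atoms, coords = coords)
}

#' Deterministic base 3D coordinates for a molecular graph
#'
#' Rings are laid out as planar regular polygons (fused rings share
#' edges in-plane); acyclic atoms are grown outward with
#' hybridization-ideal angles. Identical input gives identical output.
#'
#' @param mol a `phyto_mol` (explicit atoms only are placed).
#' @return n x 3 coordinate matrix in angstrom.
#' @export
build_base_coords <- function(mol) {
  n <- n_atoms(mol)
  coords <- matrix(NA_real_, n, 3)
  if (n == 1L) return(matrix(0, 1, 3))
  rings <- find_rings(mol)
  ring_id <- integer(n)
  systems <- list()
  for (r in rings) {
    hit <- unique(ring_id[r][ring_id[r] > 0L])
    if (!length(hit)) {
      systems[[length(systems) + 1L]] <- list(r)
      ring_id[r] <- length(systems)
    } else {
      tgt <- min(hit)
      for (h in setdiff(hit, tgt)) {
        systems[[tgt]] <- c(systems[[tgt]], systems[[h]])
        for (rr in systems[[h]]) ring_id[rr] <- tgt
        systems[[h]] <- list()
      }
      systems[[tgt]] <- c(systems[[tgt]], list(r))
      ring_id[r] <- tgt
    }
  }
  adj <- mol_adjacency(mol)
  hybrid <- atom_hybrid(mol)
  arom <- aromatic_atoms(mol)
  placed <- logical(n)
  slots_used <- integer(n)

  blen <- function(a, b) {
    k <- which((mol$bonds$i == a & mol$bonds$j == b) |
                 (mol$bonds$i == b & mol$bonds$j == a))[1]
    bond_length_rule(mol$elements[a], mol$elements[b], mol$bonds$order[k],
                     aromatic = arom[a] && arom[b])
  }
  place_system <- function(sys_id, attach = NULL, anchor_pos = NULL) {
    lay <- layout_ring_system(mol, systems[[sys_id]])
    loc <- lay$coords
    if (is.null(attach)) {
      for (k in seq_along(lay$atoms)) coords[lay$atoms[k], ] <<- loc[k, ]
    } else {
      ai <- match(attach, lay$atoms)
      la <- loc[ai, ]
      lcent <- colMeans(loc)
      xl <- unitv(lcent - la)
      zl <- c(0, 0, 1)
      yl <- unitv(cross3(zl, xl))
      u <- unitv(anchor_pos$dir)
      zg <- perp_vector(u)
      yg <- unitv(cross3(zg, u))
      Lf <- cbind(xl, yl, zl)
      Gf <- cbind(u, yg, zg)
      M <- Gf %*% t(Lf)
      moved <- sweep(loc, 2, la) %*% t(M)
      moved <- sweep(moved, 2, anchor_pos$pos, "+")
      for (k in seq_along(lay$atoms)) {
        if (!placed[lay$atoms[k]]) coords[lay$atoms[k], ] <<- moved[k, ]
      }
    }
    placed[lay$atoms] <<- TRUE
  }
  place_one <- function(a, p) {
    nb <- adj[[p]]
    done <- nb[placed[nb[, 1]], 1]
    evecs <- lapply(done, function(q) unitv(coords[q, ] - coords[p, ]))
    d <- substituent_direction(evecs, hybrid[p], slots_used[p])
    slots_used[p] <<- slots_used[p] + 1L
    coords[a, ] <<- coords[p, ] + blen(a, p) * d
    placed[a] <<- TRUE
  }

  start <- 1L
  if (ring_id[start] > 0L) {
    place_system(ring_id[start])
  } else {
    coords[start, ] <- c(0, 0, 0)
    placed[start] <- TRUE
  }
  repeat {
    frontier <- NULL
    for (p in which(placed)) {
      nb <- adj[[p]]
      if (is.null(nb)) next
      un <- nb[!placed[nb[, 1]], 1]
      if (length(un)) { frontier <- c(p, min(un)); break }
    }
    if (is.null(frontier)) break
    p <- frontier[1]; a <- frontier[2]
    if (ring_id[a] > 0L) {
      nb <- adj[[p]]
      done <- nb[placed[nb[, 1]], 1]
      evecs <- lapply(done, function(q) unitv(coords[q, ] - coords[p, ]))
      d <- substituent_direction(evecs, hybrid[p], slots_used[p])
      slots_used[p] <- slots_used[p] + 1L
      pos_a <- coords[p, ] + blen(a, p) * d
      place_system(ring_id[a], attach = a,
                   anchor_pos = list(pos = pos_a, dir = d))
    } else {
      place_one(a, p)
    }
  }
  if (anyNA(coords)) stop("failed to place all atoms of ", mol$id)
  coords
}

#' Expand implicit hydrogens with generated coordinates
#'
#' Appends explicit H atoms (bond order 1 to their parent) positioned
#' deterministically from the parent's existing substituent directions.
#' Planted partial charges are preserved; new hydrogens get charge 0.
#'
#' @param mol a `phyto_mol` with coordinates.
#' @return a `phyto_mol` with all hydrogens explicit.
#' @export
add_hydrogens <- function(mol) {
  if (is.null(mol$coords)) stop("add_hydrogens requires coordinates")
  hc <- implicit_h_counts(mol)
  if (!any(hc > 0L)) return(mol)
  elements <- mol$elements
  coords <- mol$coords
  bonds <- mol$bonds
  hybrid <- atom_hybrid(mol)
  adj <- mol_adjacency(mol)
  hlen <- c(C = 1.09, N = 1.01, O = 0.96, S = 1.34)
  for (p in which(hc > 0L)) {
    nbrs <- if (is.null(adj[[p]])) integer() else adj[[p]][, 1]
    evecs <- lapply(nbrs, function(q) unitv(mol$coords[q, ] - mol$coords[p, ]))
    r <- hlen[mol$elements[p]]
    if (is.na(r)) r <- 1.05
    hy <- hybrid[p]
    if (length(nbrs) == 0L && hc[p] >= 1L) {
      # isolated heavy atom (e.g. methane): fixed tetrahedral cage
      tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
      for (k in seq_len(hc[p])) {
        elements <- c(elements, "H")
        coords <- rbind(coords, mol$coords[p, ] + r * tet[k, ])
        bonds <- rbind(bonds, data.frame(i = p, j = length(elements), order = 1L))
      }
      next
    }
    slot <- 0L
    for (k in seq_len(hc[p])) {
      d <- substituent_direction(evecs, hy, slot)
      slot <- slot + 1L
      pos <- mol$coords[p, ] + 0 # anchor
      pos <- mol$coords[p, ] + r * d
      elements <- c(elements, "H")
      coords <- rbind(coords, pos)
      bonds <- rbind(bonds, data.frame(i = p, j = length(elements), order = 1L))
      evecs <- c(evecs, list(d))
    }
  }
  nH <- length(elements) - n_atoms(mol)
  phyto_mol(id = mol$id, elements = elements,
            fcharge = c(mol$fcharge, integer(nH)), bonds = bonds,
            coords = coords,
            pcharge = if (is.null(mol$pcharge)) NULL else
              c(mol$pcharge, numeric(nH)),
            smiles = mol$smiles, data = mol$data)
}

with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  expr
}

#' Enumerate low-clash conformers of a molecule
#'
#' Rotatable bonds (acyclic single bonds with non-terminal ends) are
#' driven over a 120-degree grid starting from the deterministic base
#' geometry; candidates are ranked by a pairwise steric-repulsion score
#' and the best `max_confs` are returned. Reproducible for a fixed seed
#' (the seed only matters when the torsion grid must be subsampled).
#'
#' @param mol a `phyto_mol`.
#' @param max_confs maximum number of conformers returned (the screening
#'   default mirrors common practice of raising the cap to 200).
#' @param seed integer seed controlling grid subsampling.
#' @return list of [new_conformer()] objects, energy_rank ascending.
#' @export
embed_conformers <- function(mol, max_confs = 200L, seed = 1L) {
  stopifnot(n_atoms(mol) >= 1L, max_confs >= 1L)
  base <- if (!is.null(mol$coords)) mol$coords else build_base_coords(mol)
  ring_atoms <- unique(unlist(find_rings(mol)))
  deg <- integer(n_atoms(mol))
  for (k in seq_len(nrow(mol$bonds))) {
    deg[mol$bonds$i[k]] <- deg[mol$bonds$i[k]] + 1L
    deg[mol$bonds$j[k]] <- deg[mol$bonds$j[k]] + 1L
  }
  in_ring_bond <- function(i, j) (i %in% ring_atoms) && (j %in% ring_atoms) &&
    any(vapply(find_rings(mol), function(r) all(c(i, j) %in% r), TRUE))
  rotors <- list()
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    if (mol$bonds$order[k] == 1L && deg[i] >= 2L && deg[j] >= 2L &&
        mol$elements[i] != "H" && mol$elements[j] != "H" &&
        !in_ring_bond(i, j)) {
      rotors[[length(rotors) + 1L]] <- c(i, j)
    }
  }
  g <- mol_igraph(mol)
  side_of <- lapply(rotors, function(b) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, b))
    comp <- igraph::components(g2)$membership
    as.integer(names(comp)[comp == comp[as.character(b[2])]])
  })
  nr <- length(rotors)
  deltas <- c(0, 2 * pi / 3, 4 * pi / 3)
  cap <- 729L
  if (nr == 0L) {
    combos <- matrix(0, 1, 0)
  } else if (3^nr <= cap) {
    combos <- as.matrix(expand.grid(rep(list(deltas), nr)))
  } else {
    combos <- with_preserved_rng({
      set.seed(seed)
      rbind(rep(0, nr),
            matrix(sample(deltas, (cap - 1L) * nr, replace = TRUE),
                   ncol = nr))
    })
  }
  topo_dist <- igraph::distances(g)
  rv <- vdw_radius(mol$elements)
  far <- which(upper.tri(topo_dist) & topo_dist >= 3, arr.ind = TRUE)
  energy_of <- function(xyz) {
    if (!nrow(far)) return(0)
    d <- sqrt(rowSums((xyz[far[, 1], , drop = FALSE] -
                         xyz[far[, 2], , drop = FALSE])^2))
    e <- (0.7 * (rv[far[, 1]] + rv[far[, 2]]) / pmax(d, 0.05))^12
    sum(pmin(e, 1e6))
  }
  seen <- character()
  confs <- list()
  energies <- numeric()
  for (ci in seq_len(nrow(combos))) {
    xyz <- base
    for (rk in seq_len(nr)) {
      dl <- combos[ci, rk]
      if (dl == 0) next
      b <- rotors[[rk]]
      xyz[side_of[[rk]], ] <- rotate_about_axis(
        xyz[side_of[[rk]], , drop = FALSE], xyz[b[1], ],
        xyz[b[2], ] - xyz[b[1], ], dl)
    }
    key <- paste(sprintf("%.3f", xyz), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    confs[[length(confs) + 1L]] <- xyz
    energies <- c(energies, energy_of(xyz))
  }
  ord <- order(energies, seq_along(energies))
  ord <- head(ord, max_confs)
  out <- vector("list", length(ord))
  for (k in seq_along(ord)) {
    m2 <- mol
    m2$coords <- confs[[ord[k]]]
    out[[k]] <- new_conformer(m2, confs[[ord[k]]], energy_rank = k - 1L)
  }
  out
}
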