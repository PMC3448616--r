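#' Molecular graph container
#'
#' Lightweight molecule representation used throughout the screening
#' engine: element list, integer formal charges, a bond table, optional
#' 3D coordinates (angstrom) and optional per-atom partial charges
#' (elementary-charge units). Hydrogens may be implicit; [add_hydrogens()]
#' expands them before any field computation.
#'
#' @param id molecule identifier (string).
#' @param elements character vector of element symbols.
#' @param fcharge integer vector of formal charges (default all 0).
#' @param bonds data.frame with columns `i`, `j`, `order` (1, 2, 3; 4 is
#'   accepted for aromatic bonds as found in some CTAB files).
#' @param coords optional numeric matrix (n x 3) of coordinates in angstrom.
#' @param pcharge optional numeric vector of partial charges.
#' @param smiles optional canonical SMILES (computed lazily elsewhere).
#' @param data optional named list of record-level data fields.
#' @return An object of class `phyto_mol`.
#' @export
phyto_mol <- function(id, elements, fcharge = NULL, bonds = NULL,
                      coords = NULL, pcharge = NULL, smiles = NA_character_,
                      data = list()) {
  n <- length(elements)
  stopifnot(is.character(id), length(id) == 1L, n >= 1L)
  if (is.null(fcharge)) fcharge <- integer(n)
  fcharge <- as.integer(fcharge)
  stopifnot(length(fcharge) == n, !anyNA(fcharge))
  if (is.null(bonds)) {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  }
  bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                      order = as.integer(bonds$order))
  if (nrow(bonds) > 0L) {
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stop("bond references an atom index outside the molecule")
    if (any(bonds$i == bonds$j)) stop("self-bond in bond table")
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 3L)
      stop("coords must be an n x 3 matrix matching the atom count")
    if (!all(is.finite(coords))) stop("non-finite coordinates")
    dimnames(coords) <- NULL
  }
  if (!is.null(pcharge)) {
    pcharge <- as.numeric(pcharge)
    stopifnot(length(pcharge) == n, all(is.finite(pcharge)))
  }
  structure(list(id = id, elements = elements, fcharge = fcharge,
                 bonds = bonds, coords = coords, pcharge = pcharge,
                 smiles = smiles, data = data),
            class = "phyto_mol")
}

#' @export
print.phyto_mol <- function(x, ...) {
  cat(sprintf("<phyto_mol> %s: %d atoms, %d bonds, net charge %+d%s%s\n",
              x$id, length(x$elements), nrow(x$bonds), sum(x$fcharge),
              if (!is.null(x$coords)) ", 3D" else "",
              if (!is.null(x$pcharge)) ", charged" else ""))
  invisible(x)
}

n_atoms <- function(mol) length(mol$elements)

is_heavy <- function(mol) mol$elements != "H"

#' Number of heavy (non-hydrogen) atoms
#' @param mol a `phyto_mol`.
#' @return integer count.
#' @export
n_heavy_atoms <- function(mol) sum(is_heavy(mol))

# adjacency list: for each atom, data.frame of (nbr, order)
mol_adjacency <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]; o <- mol$bonds$order[k]
    adj[[i]] <- rbind(adj[[i]], c(j, o))
    adj[[j]] <- rbind(adj[[j]], c(i, o))
  }
  adj
}

mol_igraph <- function(mol) {
  igraph::graph_from_data_frame(
    d = if (nrow(mol$bonds)) mol$bonds[, c("i", "j")] else
      data.frame(i = integer(), j = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(mol))))
}

# default valences used for implicit-hydrogen accounting
.default_valence <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, P = 3,
                      S = 2, Cl = 1, Br = 1, I = 1)

# bond-order sum per atom; aromatic (order 4) bonds count 1.5
bond_order_sums <- function(mol) {
  n <- n_atoms(mol)
  s <- numeric(n)
  if (nrow(mol$bonds) == 0L) return(s)
  o <- ifelse(mol$bonds$order == 4L, 1.5, mol$bonds$order)
  for (k in seq_len(nrow(mol$bonds))) {
    s[mol$bonds$i[k]] <- s[mol$bonds$i[k]] + o[k]
    s[mol$bonds$j[k]] <- s[mol$bonds$j[k]] + o[k]
  }
  s
}

#' Implicit hydrogen counts
#'
#' Computed from default valences adjusted by formal charge (N+ carries 4
#' bonds, O- carries 1, and so on), minus the explicit bond-order sum.
#'
#' @param mol a `phyto_mol`.
#' @return integer vector, one entry per atom.
#' @export
implicit_h_counts <- function(mol) {
  val <- .default_valence[mol$elements]
  val[is.na(val)] <- 0
  ch <- mol$fcharge
  adj <- val
  nlike <- mol$elements %in% c("N", "P")
  olike <- mol$elements %in% c("O", "S")
  adj[nlike] <- val[nlike] + ch[nlike]
  adj[olike] <- val[olike] + ch[olike]
  clike <- mol$elements == "C"
  adj[clike] <- val[clike] - abs(ch[clike])
  h <- floor(adj - bond_order_sums(mol) + 1e-9)
  h[h < 0] <- 0L
  as.integer(h)
}

#' Smallest rings of a molecule
#'
#' Fundamental cycles (up to size `max_size`) found by removing each
#' ring bond and taking the shortest remaining path between its ends.
#'
#' @param mol a `phyto_mol`.
#' @param max_size largest ring size reported.
#' @return list of integer atom-index vectors, deduplicated, in a
#'   deterministic order (by size then lowest member index).
#' @export
find_rings <- function(mol, max_size = 8L) {
  if (nrow(mol$bonds) == 0L) return(list())
  g <- mol_igraph(mol)
  rings <- list()
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
    sp <- suppressWarnings(igraph::shortest_paths(
      g2, from = as.character(i), to = as.character(j)))$vpath[[1]]
    if (length(sp) >= 2L && length(sp) <= max_size) {
      ring <- as.integer(igraph::V(g2)$name[as.integer(sp)])
      rings[[length(rings) + 1L]] <- ring
    }
  }
  if (!length(rings)) return(list())
  keys <- vapply(rings, function(r) paste(sort(r), collapse = "-"), "")
  rings <- rings[!duplicated(keys)]
  ord <- order(vapply(rings, length, 1L), vapply(rings, min, 1L))
  rings[ord]
}

#' Aromatic ring perception
#'
#' A 5- or 6-membered ring of C/N/O/S atoms is called aromatic when its
#' Hueckel-style pi-electron count reaches 6: an atom engaged in any
#' double/triple or explicitly aromatic bond contributes one electron, a
#' ring heteroatom without one contributes its lone pair (two).
#'
#' @param mol a `phyto_mol`.
#' @return list of integer atom-index vectors (aromatic rings only).
#' @export
aromatic_rings <- function(mol) {
  rings <- find_rings(mol, max_size = 6L)
  if (!length(rings)) return(list())
  n <- n_atoms(mol)
  in_multiple <- logical(n)
  for (k in seq_len(nrow(mol$bonds))) {
    if (mol$bonds$order[k] >= 2L) {
      in_multiple[mol$bonds$i[k]] <- TRUE
      in_multiple[mol$bonds$j[k]] <- TRUE
    }
  }
  Filter(function(ring) {
    if (!(length(ring) %in% c(5L, 6L))) return(FALSE)
    el <- mol$elements[ring]
    if (!all(el %in% c("C", "N", "O", "S"))) return(FALSE)
    pi_e <- 0L
    for (a in ring) {
      if (in_multiple[a]) pi_e <- pi_e + 1L
      else if (mol$elements[a] %in% c("N", "O", "S")) pi_e <- pi_e + 2L
      else return(FALSE)  # sp3 carbon breaks conjugation
    }
    pi_e == 6L
  }, rings)
}

#' Aromatic-atom flags
#' @param mol a `phyto_mol`.
#' @return logical vector, one per atom.
#' @export
aromatic_atoms <- function(mol) {
  fl <- logical(n_atoms(mol))
  for (r in aromatic_rings(mol)) fl[r] <- TRUE
  fl
}

# CTAB (V2000) text for one molecule; pcharge carried in a data field so
# fixture poses round-trip their planted charges
mol_to_ctab <- function(mol) {
  n <- n_atoms(mol)
  xyz <- if (is.null(mol$coords)) matrix(0, n, 3) else mol$coords
  lines <- c(mol$id, "  phytophor", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     n, nrow(mol$bonds)))
  for (a in seq_len(n)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              xyz[a, 1], xyz[a, 2], xyz[a, 3], mol$elements[a]))
  }
  for (k in seq_len(nrow(mol$bonds))) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              mol$bonds$i[k], mol$bonds$j[k], mol$bonds$order[k]))
  }
  chg <- which(mol$fcharge != 0L)
  if (length(chg)) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      lines <- c(lines, paste0(sprintf("M  CHG%3d", length(grp)),
                               paste(sprintf("%4d%4d", grp, mol$fcharge[grp]),
                                     collapse = "")))
    }
  }
  lines <- c(lines, "M  END")
  dat <- mol$data
  if (!is.null(mol$pcharge))
    dat$PHYTOPHORE_PCHARGE <- paste(sprintf("%.6f", mol$pcharge), collapse = " ")
  for (tag in names(dat)) {
    lines <- c(lines, sprintf(">  <%s>", tag), as.character(dat[[tag]]), "")
  }
  c(lines, "$$$$")
}

# parse one V2000 record (character vector of lines, without "$$$$")
ctab_to_mol <- function(lines, default_id = "MOL") {
  if (length(lines) < 4L) stop("truncated SDF record")
  title <- trimws(lines[1])
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || is.na(nb) || length(lines) < 4L + na + nb)
    stop("malformed counts line or truncated record")
  atoms <- lines[4L + seq_len(na)]
  elements <- trimws(substr(atoms, 32, 34))
  coords <- cbind(as.numeric(substr(atoms, 1, 10)),
                  as.numeric(substr(atoms, 11, 20)),
                  as.numeric(substr(atoms, 21, 30)))
  if (anyNA(coords) || !all(elements != ""))
    stop("malformed atom block")
  fcharge <- integer(na)
  # old-style atom-block charge codes (used when no M CHG present)
  oldchg <- suppressWarnings(as.integer(substr(atoms, 37, 39)))
  oldmap <- c(3L, 2L, 1L, 0L, -1L, -2L, -3L)
  has_mchg <- FALSE
  bonds <- data.frame(i = integer(), j = integer(), order = integer())
  if (nb > 0L) {
    bl <- lines[4L + na + seq_len(nb)]
    bonds <- data.frame(i = as.integer(substr(bl, 1, 3)),
                        j = as.integer(substr(bl, 4, 6)),
                        order = as.integer(substr(bl, 7, 9)))
    if (anyNA(bonds)) stop("malformed bond block")
  }
  rest <- if (length(lines) > 4L + na + nb) lines[(5L + na + nb):length(lines)] else character()
  for (ln in grep("^M  CHG", rest, value = TRUE)) {
    has_mchg <- TRUE
    nums <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    cnt <- nums[1]
    for (q in seq_len(cnt)) fcharge[nums[2 * q]] <- nums[2 * q + 1]
  }
  if (!has_mchg && !anyNA(oldchg)) {
    idx <- which(oldchg >= 1L & oldchg <= 7L & oldchg != 4L)
    fcharge[idx] <- oldmap[oldchg[idx]]
  }
  # data fields
  data <- list()
  tag_at <- grep("^>", rest)
  for (t in tag_at) {
    tag <- sub(".*<([^>]+)>.*", "\\1", rest[t])
    val <- character()
    k <- t + 1L
    while (k <= length(rest) && nzchar(trimws(rest[k])) &&
           !startsWith(rest[k], ">")) {
      val <- c(val, rest[k]); k <- k + 1L
    }
    data[[tag]] <- paste(val, collapse = "\n")
  }
  pch <- NULL
  if (!is.null(data$PHYTOPHORE_PCHARGE)) {
    pch <- as.numeric(strsplit(trimws(data$PHYTOPHORE_PCHARGE), "\\s+")[[1]])
    if (length(pch) != na) pch <- NULL
    data$PHYTOPHORE_PCHARGE <- NULL
  }
  if (all(coords == 0)) coords <- NULL
  phyto_mol(id = if (nzchar(title)) title else default_id,
            elements = elements, fcharge = fcharge, bonds = bonds,
            coords = coords, pcharge = pch, data = data)
}

#' Canonical SMILES of a molecule
#'
#' Canonicalization is delegated to Open Babel.
#'
#' @param x a `phyto_mol` or a SMILES string.
#' @return canonical SMILES string.
#' @export
canonical_smiles <- function(x) {
  if (inherits(x, "phyto_mol")) {
    ctab <- paste(mol_to_ctab(x), collapse = "\n")
    out <- ChemmineOB::convertFormat("SDF", "CAN", ctab)
  } else {
    out <- ChemmineOB::convertFormat("SMI", "CAN", as.character(x))
  }
  smi <- strsplit(trimws(out), "[\t ]")[[1]][1]
  if (is.na(smi) || !nzchar(smi)) stop("canonicalization failed")
  smi
}

#' Parse a single SMILES string into a molecule
#'
#' Structure interpretation is delegated to Open Babel; the result
#' carries no coordinates until embedded.
#'
#' @param smiles SMILES string.
#' @param id molecule identifier.
#' @return a [phyto_mol()] with canonical `smiles` filled in.
#' @export
smiles_to_mol <- function(smiles, id = "MOL") {
  sdf <- ChemmineOB::convertFormat("SMI", "SDF", smiles)
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  lines <- lines[!grepl("^\\$\\$\\$\\$", lines)]
  mol <- ctab_to_mol(lines, default_id = id)
  mol$id <- id
  mol$coords <- NULL
  mol$smiles <- canonical_smiles(smiles)
  mol
}
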