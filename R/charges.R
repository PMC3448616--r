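# Protonation-state assignment and partial charges.
#
# Input preparation reduces ionization handling to the dominant state at
# physiological pH by rule: protonate aliphatic amines and
# amidine/guanidine nitrogens, deprotonate carboxylic and sulfonic
# acids. No tautomer enumeration. Partial charges default to the
# Gasteiger scheme as implemented by Open Babel.

#' Assign the dominant protonation state at pH 7
#'
#' Rule-based: aliphatic (sp3, non-amide, non-aromatic) amine nitrogens
#' and the imine nitrogen of amidine/guanidine groups gain a formal +1;
#' hydroxyls of carboxylic and sulfonic acids lose their proton (formal
#' -1 on the oxygen). Implicit hydrogen counts follow the new formal
#' charges automatically.
#'
#' @param mol a `phyto_mol`.
#' @return the molecule with adjusted formal charges.
#' @export
protonate_ph7 <- function(mol) {
  adj <- mol_adjacency(mol)
  arom <- aromatic_atoms(mol)
  el <- mol$elements
  fc <- mol$fcharge
  has_double_O <- function(a) {
    nb <- adj[[a]]
    if (is.null(nb)) return(FALSE)
    any(el[nb[, 1]] == "O" & nb[, 2] == 2L)
  }
  for (a in seq_along(el)) {
    if (fc[a] != 0L) next
    nb <- adj[[a]]
    if (is.null(nb)) next
    if (el[a] == "N" && !arom[a]) {
      orders <- nb[, 2]
      nbrs <- nb[, 1]
      amide <- any(el[nbrs] %in% c("C", "S") & vapply(nbrs, has_double_O, TRUE))
      # anilines and amidine/guanidine NH2 groups are not basic amines
      conj <- any(arom[nbrs]) ||
        any(el[nbrs] == "C" & vapply(nbrs, function(cc) {
          cnb <- adj[[cc]]
          any(el[cnb[, 1]] == "N" & cnb[, 2] == 2L)
        }, TRUE))
      if (all(orders == 1L) && !amide && !conj) {
        fc[a] <- 1L                             # aliphatic amine
      } else if (any(orders == 2L & el[nbrs] == "C")) {
        cc <- nbrs[orders == 2L & el[nbrs] == "C"][1]
        cnb <- adj[[cc]]
        other_n <- cnb[, 1] != a & el[cnb[, 1]] == "N" & cnb[, 2] == 1L
        if (any(other_n)) fc[a] <- 1L           # amidine / guanidine
      }
    }
    if (el[a] == "O" && nrow(nb) == 1L && nb[1, 2] == 1L) {
      parent <- nb[1, 1]
      if (el[parent] %in% c("C", "S") && has_double_O(parent)) {
        # acidic hydroxyl (the O currently carries an implicit H)
        hs <- implicit_h_counts(mol)[a]
        if (hs >= 1L) fc[a] <- -1L
      }
    }
  }
  mol$fcharge <- fc
  mol
}

#' Assign per-atom partial charges
#'
#' Hydrogens are expanded explicitly, charges are computed with Open
#' Babel's implementation of the requested scheme, and the charge vector
#' is attached to the expanded molecule. When the molecule carries no
#' coordinates, charges of the (topologically placed) hydrogens are
#' folded onto their parent heavy atoms and the original implicit-H
#' molecule is returned. The charge sum always equals the net formal
#' charge of the molecule.
#'
#' Charges are uniformly renormalized so their sum equals the net formal
#' charge exactly (the MMFF94 and EEM models already conserve it to
#' rounding; the sigma-only Gasteiger model does not for ions, so the
#' default is MMFF94).
#'
#' @param mol a `phyto_mol`.
#' @param scheme charge model passed to Open Babel.
#' @return a `phyto_mol` with `pcharge` populated.
#' @export
assign_partial_charges <- function(mol, scheme = c("mmff94", "gasteiger", "eem")) {
  scheme <- match.arg(scheme)
  had_coords <- !is.null(mol$coords)
  work <- mol
  if (!had_coords) work$coords <- build_base_coords(mol)
  workh <- add_hydrogens(work)
  sdf_in <- tempfile(fileext = ".sdf")
  mol2_out <- tempfile(fileext = ".mol2")
  on.exit(unlink(c(sdf_in, mol2_out)))
  wh <- workh
  wh$pcharge <- NULL
  write_molecules(list(wh), sdf_in, "sdf")
  status <- suppressWarnings(system2(
    "obabel", c("-isdf", sdf_in, "-omol2", "-O", mol2_out,
                "--partialcharge", scheme),
    stdout = FALSE, stderr = FALSE))
  if (!identical(status, 0L) || !file.exists(mol2_out))
    stop("partial-charge assignment failed for ", mol$id)
  lines <- readLines(mol2_out, warn = FALSE)
  a0 <- grep("^@<TRIPOS>ATOM", lines)[1]
  a1 <- grep("^@<TRIPOS>", lines)
  a1 <- min(a1[a1 > a0], length(lines) + 1L)
  atom_lines <- lines[(a0 + 1L):(a1 - 1L)]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  fields <- strsplit(trimws(atom_lines), "\\s+")
  if (length(fields) != n_atoms(workh))
    stop("charge backend returned unexpected atom count for ", mol$id)
  q <- vapply(fields, function(f) as.numeric(f[9]), 0)
  if (anyNA(q)) stop("could not parse partial charges for ", mol$id)
  net <- sum(mol$fcharge)
  q <- q - (sum(q) - net) / length(q)  # enforce exact charge conservation
  if (had_coords) {
    workh$pcharge <- q
    return(workh)
  }
  nheavy <- n_atoms(mol)
  out <- mol
  qq <- q[seq_len(nheavy)]
  if (length(q) > nheavy) {
    for (k in (nheavy + 1L):length(q)) {
      parent <- workh$bonds$i[workh$bonds$j == k][1]
      qq[parent] <- qq[parent] + q[k]
    }
  }
  out$pcharge <- qq
  out
}
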