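# Synthetic structure fixtures: ideal alpha-helix bundles with C_n symmetry,
# caller-controlled side-chain chi1 angles, and pseudo-atom ligands.  These
# stand in for deposited channel structures in tests: every geometric claim
# made of them (symmetry, dihedrals, contact distances) is true by
# construction.

# bond lengths / angles (Engh-Huber-like ideal values)
.bb <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
            a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
            a_ca_c_o = 120.5, phi = -57, psi = -47, omega = 180)

# Side-chain internal-coordinate templates.  Each row places one atom from
# three previously placed atoms; dihedrals written "chi1" / "chi2" (with an
# optional +/- offset) are resolved per residue at build time.
.sidechain_templates <- list(
  GLY = NULL,
  ALA = list(),
  LEU = list(
    list("CG", "C", c("N", "CA", "CB"), 1.530, 116.3, "chi1"),
    list("CD1", "C", c("CA", "CB", "CG"), 1.521, 110.7, "chi2"),
    list("CD2", "C", c("CA", "CB", "CG"), 1.521, 110.7, "chi2-120")),
  VAL = list(
    list("CG1", "C", c("N", "CA", "CB"), 1.521, 110.5, "chi1"),
    list("CG2", "C", c("N", "CA", "CB"), 1.521, 110.5, "chi1-122")),
  ILE = list(
    list("CG1", "C", c("N", "CA", "CB"), 1.530, 110.4, "chi1"),
    list("CG2", "C", c("N", "CA", "CB"), 1.521, 110.5, "chi1-122"),
    list("CD1", "C", c("CA", "CB", "CG1"), 1.513, 113.9, "chi2")),
  SER = list(
    list("OG", "O", c("N", "CA", "CB"), 1.417, 110.8, "chi1")),
  THR = list(
    list("OG1", "O", c("N", "CA", "CB"), 1.433, 109.6, "chi1"),
    list("CG2", "C", c("N", "CA", "CB"), 1.521, 110.5, "chi1-122")),
  CYS = list(
    list("SG", "S", c("N", "CA", "CB"), 1.808, 113.8, "chi1")),
  PHE = list(
    list("CG", "C", c("N", "CA", "CB"), 1.502, 113.8, "chi1"),
    list("CD1", "C", c("CA", "CB", "CG"), 1.384, 120.8, "chi2"),
    list("CD2", "C", c("CA", "CB", "CG"), 1.384, 120.8, "chi2+180"),
    list("CE1", "C", c("CB", "CG", "CD1"), 1.382, 120.8, "180"),
    list("CE2", "C", c("CB", "CG", "CD2"), 1.382, 120.8, "180"),
    list("CZ", "C", c("CG", "CD1", "CE1"), 1.382, 120.0, "0")),
  TRP = list(
    list("CG", "C", c("N", "CA", "CB"), 1.498, 113.6, "chi1"),
    list("CD1", "C", c("CA", "CB", "CG"), 1.365, 127.0, "chi2"),
    list("CD2", "C", c("CA", "CB", "CG"), 1.433, 126.6, "chi2+180"))
)

resolve_dihedral <- function(spec, chi1, chi2) {
  if (grepl("^-?[0-9.]+$", spec)) return(as.numeric(spec))
  base <- if (startsWith(spec, "chi1")) chi1 else chi2
  off <- sub("^chi[12]", "", spec)
  if (nzchar(off)) base + as.numeric(off) else base
}

# Build one ideal residue chain (backbone via NeRF at ideal phi/psi; side
# chains at the requested chi angles), helix axis aligned to +z through the
# origin.  Returns an atom tibble.
build_helix_chain <- function(chain, n_res, sequence, chi1, chi2, start_resi = 1L) {
  sequence <- toupper(rep_len(sequence, n_res))
  chi1 <- rep_len(chi1, n_res)
  chi2 <- rep_len(chi2, n_res)
  bad <- setdiff(unique(sequence), names(.sidechain_templates))
  if (length(bad) > 0)
    abort(paste0("unsupported residue code(s): ", paste(bad, collapse = ", ")))

  # backbone trace
  bb <- .bb
  pos <- list()          # named "i/NAME" -> xyz
  pos[["1/N"]] <- c(0, 0, 0)
  pos[["1/CA"]] <- c(bb$b_n_ca, 0, 0)
  pos[["1/C"]] <- place_atom(c(0, 1, 0), pos[["1/N"]], pos[["1/CA"]],
                             bb$b_ca_c, bb$a_n_ca_c, 60)
  for (i in seq_len(n_res)) {
    ni <- paste0(i, "/")
    if (i > 1) {
      pv <- paste0(i - 1, "/")
      pos[[paste0(ni, "N")]] <- place_atom(pos[[paste0(pv, "N")]],
                                           pos[[paste0(pv, "CA")]],
                                           pos[[paste0(pv, "C")]],
                                           bb$b_c_n, bb$a_ca_c_n, bb$psi)
      pos[[paste0(ni, "CA")]] <- place_atom(pos[[paste0(pv, "CA")]],
                                            pos[[paste0(pv, "C")]],
                                            pos[[paste0(ni, "N")]],
                                            bb$b_n_ca, bb$a_c_n_ca, bb$omega)
      pos[[paste0(ni, "C")]] <- place_atom(pos[[paste0(pv, "C")]],
                                           pos[[paste0(ni, "N")]],
                                           pos[[paste0(ni, "CA")]],
                                           bb$b_ca_c, bb$a_n_ca_c, bb$phi)
    }
    pos[[paste0(ni, "O")]] <- place_atom(pos[[paste0(ni, "N")]],
                                         pos[[paste0(ni, "CA")]],
                                         pos[[paste0(ni, "C")]],
                                         bb$b_c_o, bb$a_ca_c_o, bb$psi + 180)
  }
  # side chains
  rows <- list()
  for (i in seq_len(n_res)) {
    ni <- paste0(i, "/")
    resn <- sequence[i]
    local_pos <- list(N = pos[[paste0(ni, "N")]], CA = pos[[paste0(ni, "CA")]],
                      C = pos[[paste0(ni, "C")]], O = pos[[paste0(ni, "O")]])
    if (!is.null(.sidechain_templates[[resn]])) {
      # CB from an improper about CA (L-chirality)
      local_pos$CB <- place_atom(local_pos$C, local_pos$N, local_pos$CA,
                                 1.530, 110.5, -122.0)
      for (tpl in .sidechain_templates[[resn]]) {
        refs <- tpl[[3]]
        local_pos[[tpl[[1]]]] <- place_atom(local_pos[[refs[1]]],
                                            local_pos[[refs[2]]],
                                            local_pos[[refs[3]]],
                                            tpl[[4]], tpl[[5]],
                                            resolve_dihedral(tpl[[6]],
                                                             chi1[i], chi2[i]))
      }
    }
    elems <- unname(vapply(names(local_pos), function(a)
      if (startsWith(a, "O")) "O" else if (startsWith(a, "N")) "N"
      else if (startsWith(a, "S")) "S" else "C", character(1)))
    xyz <- do.call(rbind, local_pos)
    rows[[i]] <- tibble(chain = chain, resi = start_resi + i - 1L, icode = "",
                        resn = resn, atom = names(local_pos), element = elems,
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        occ = 1, b = 0, het = FALSE)
  }
  atoms <- bind_rows(rows)

  # align the helix axis (principal component of the CA trace) to +z
  ca <- coords(filter(atoms, .data$atom == "CA"))
  ctr <- colMeans(ca)
  ax <- svd(sweep(ca, 2, ctr))$v[, 1]
  if (sum(ax * (ca[nrow(ca), ] - ca[1, ])) < 0) ax <- -ax
  R <- rotation_between(ax, c(0, 0, 1))
  xyz <- transform_xyz(sweep(coords(atoms), 2, ctr), R)
  set_coords(atoms, xyz)
}

# Rotation taking unit vector a onto unit vector b.
rotation_between <- function(a, b) {
  a <- unit(a); b <- unit(b)
  v <- pracma_cross(a, b)
  s <- vnorm(v)
  if (s < 1e-12) {
    if (sum(a * b) > 0) return(diag(3))
    # opposite: rotate 180 about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) pracma_cross(a, c(1, 0, 0)) else pracma_cross(a, c(0, 1, 0))
    return(rotation_about(p, 180))
  }
  rotation_about(v, rad2deg(atan2(s, sum(a * b))))
}

#' Build a synthetic C_n helix-bundle structure
#'
#' Generates `n_helices` copies of an ideal alpha-helix (1.5 A rise and 100
#' degrees of turn per residue emerge from ideal phi/psi), arranged with
#' exact C_n symmetry about the z axis at the given bundle radius.  Side
#' chains are built at caller-specified chi1 (and chi2) angles, so the
#' measured dihedrals of the fixture are known inputs.  An optional ligand
#' is placed as pseudo-atoms at caller-specified coordinates.
#'
#' @param n_helices Number of chains (>= 1).
#' @param radius Bundle radius in Angstrom (helix axis distance from z).
#' @param residues_per_helix Residues per chain.
#' @param sequence 3-letter residue codes, recycled along the helix.
#' @param chi1,chi2 Side-chain dihedrals in degrees, recycled along the helix.
#' @param ligand Optional data frame of ligand pseudo-atoms with columns
#'   `atom`, `element`, `x`, `y`, `z` (absolute coordinates), placed as a
#'   hetero-residue `LIG` in chain `"X"`.
#' @param start_resi First author residue number.
#' @param id Structure identifier.
#' @return A [new_structure()] tibble.
#' @export
#' @examples
#' b <- build_helix_bundle(4, radius = 10, residues_per_helix = 8)
#' print(b)
build_helix_bundle <- function(n_helices = 4, radius = 10,
                               residues_per_helix = 18, sequence = "LEU",
                               chi1 = -60, chi2 = 180, ligand = NULL,
                               start_resi = 1L, id = "bundle") {
  if (n_helices < 1 || radius < 0 || residues_per_helix < 1)
    abort("geometry parameters must be positive")
  base <- build_helix_chain("A", residues_per_helix, sequence, chi1, chi2,
                            start_resi = as.integer(start_resi))
  base_xyz <- coords(base)
  base_xyz[, 1] <- base_xyz[, 1] + radius
  chains <- lapply(seq_len(n_helices), function(i) {
    Rz <- rotation_about(c(0, 0, 1), (i - 1) * 360 / n_helices)
    ch <- base
    ch$chain <- LETTERS[i]
    set_coords(ch, transform_xyz(base_xyz, Rz))
  })
  atoms <- bind_rows(chains)
  if (!is.null(ligand)) {
    lig <- as_tibble(ligand)
    atoms <- bind_rows(atoms, tibble(
      chain = "X", resi = 1L, icode = "", resn = "LIG",
      atom = lig$atom, element = lig$element,
      x = lig$x, y = lig$y, z = lig$z, occ = 1, b = 0, het = TRUE))
  }
  new_structure(atoms, id = id, source_format = "synthetic")
}

#' Build a single ideal residue
#'
#' Convenience wrapper around the bundle builder's residue templates; useful
#' for construction/measurement inverse tests of chi1.
#'
#' @param resn 3-letter residue code.
#' @param chi1,chi2 Side-chain dihedrals (degrees).
#' @return Atom tibble (chain `"A"`, residue 1).
#' @export
build_residue <- function(resn, chi1 = -60, chi2 = 180) {
  ch <- build_helix_chain("A", 1L, resn, chi1, chi2)
  ch
}
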