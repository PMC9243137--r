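# Shared fixture helpers: random rigid transforms and small atom tables.

random_rotation <- function() {
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(atoms, R, t = c(0, 0, 0)) {
  xyz <- coords(atoms)
  xyz <- sweep(xyz %*% t(R), 2, t, FUN = "+")
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

transform_structure <- function(structure, R, t = c(0, 0, 0)) {
  new_structure(apply_rigid(tibble::as_tibble(structure), R, t),
                id = attr(structure, "id"), source_format = "synthetic")
}

random_atoms <- function(n, box = 30, chain = "E", element = "C") {
  tibble::tibble(chain = chain, resi = seq_len(n), icode = "", resn = "UNK",
                 atom = "C", element = element,
                 x = runif(n, 0, box), y = runif(n, 0, box),
                 z = runif(n, 0, box), occ = 1, b = 0, het = FALSE)
}

# small two-chain bundle with a ligand wedged between chains A and B
ligand_bundle <- function(radius = 9, n_res = 12) {
  b <- build_helix_bundle(4, radius = radius, residues_per_helix = n_res,
                          sequence = "LEU", chi1 = -60)
  ca <- select_atoms(b, "chain A and resi 6 and name CB")
  cb <- select_atoms(b, "chain B and resi 6 and name CB")
  mid <- (coords(ca) + coords(cb)) / 2
  lig <- tibble::tibble(atom = c("C1", "C2"), element = "C",
                        x = mid[1], y = mid[2], z = mid[3] + c(0, 1.5))
  build_helix_bundle(4, radius = radius, residues_per_helix = n_res,
                     sequence = "LEU", chi1 = -60, ligand = lig,
                     id = "ligand_bundle")
}
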