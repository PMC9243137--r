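test_that("a minimal PDB file round-trips with identity preserved", {
  pdb <- c(
    "ATOM      1  N   GLY A  42      11.104  13.207   9.002  1.00 20.00           N",
    "ATOM      2  CA  GLY A  42      12.560  13.300   9.100  1.00 20.00           C",
    "ATOM      3  C   GLY A  42      13.100  14.700   9.300  1.00 20.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  s <- read_structure(f)
  expect_equal(nrow(s), 3)
  expect_equal(unique(s$chain), "A")
  expect_equal(unique(s$resi), 42L)
  expect_equal(s$atom, c("N", "CA", "C"))
  expect_equal(s$x, c(11.104, 12.560, 13.100))
})

test_that("write_pdb/read_structure round-trip preserves coordinates and numbering", {
  b <- build_helix_bundle(2, radius = 8, residues_per_helix = 6,
                          sequence = c("LEU", "PHE", "SER"), start_resi = 101L)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(b, f)
  s <- read_structure(f)
  expect_equal(nrow(s), nrow(b))
  expect_lt(max(abs(coords(s) - coords(b))), 1e-3)  # PDB precision
  expect_equal(s$resi, b$resi)
  expect_equal(s$atom, b$atom)
  expect_equal(s$element, b$element)
})

test_that("mmCIF atom_site parsing resolves alternate conformers to highest occupancy", {
  cif <- c(
    "data_test", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id", "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "ATOM 1 N N . LEU A 5 ? 1.000 2.000 3.000 1.00 10.0",
    "ATOM 2 C CA A LEU A 5 ? 2.000 2.500 3.000 0.40 10.0",
    "ATOM 3 C CA B LEU A 5 ? 2.100 2.500 3.000 0.60 10.0",
    "ATOM 4 C CB A LEU A 5 ? 3.000 2.500 3.000 0.50 10.0",
    "ATOM 5 C CB B LEU A 5 ? 3.200 2.500 3.000 0.50 10.0",
    "HETATM 6 C C1 . LIG X 1 ? 5.000 5.000 5.000 1.00 20.0", "#")
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(cif, f)
  s <- read_structure(f)
  expect_equal(nrow(s), 4)                   # one copy per atom
  expect_equal(s$x[s$atom == "CA"], 2.1)     # highest occupancy wins
  expect_equal(s$x[s$atom == "CB"], 3.0)     # tie -> first listed
  expect_true(s$het[s$resn == "LIG"])
  expect_error(read_structure(withr::local_tempfile(fileext = ".cif")),
               "not found")
})

test_that("unknown elements are inferred from atom names with a warning", {
  pdb <- c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00",
    "ATOM      3  C   GLY A   1       2.000   1.400   0.000  1.00  0.00",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  expect_warning(s <- read_structure(f), "inferring")
  expect_equal(s$element, c("N", "C", "C"))
})

test_that("selection language counts, empty results, heavy filter and stability", {
  b <- build_helix_bundle(2, radius = 8, residues_per_helix = 10)
  sel <- select_atoms(b, "chain A and resi 2-9 and name CA")
  expect_equal(nrow(sel), 8)
  expect_equal(nrow(select_atoms(b, "chain Z")), 0)
  expect_error(select_atoms(b, "bogus clause here"), "malformed")
  # heavy-only excludes hydrogens
  a <- tibble::as_tibble(b)[1:4, ]
  a$atom[4] <- "H"; a$element[4] <- "H"
  s2 <- new_structure(a)
  expect_equal(nrow(select_atoms(s2, "heavy")), 3)
  # idempotent and order-stable; disjoint union == disjunction
  s_a <- select_atoms(b, "chain A")
  expect_identical(select_atoms(s_a, "chain A")$x, s_a$x)
  u <- dplyr::bind_rows(select_atoms(b, "resi 1-3"), select_atoms(b, "resi 7-9"))
  v <- select_atoms(b, "resi 1-3,7-9")
  expect_setequal(paste(u$chain, u$resi, u$atom), paste(v$chain, v$resi, v$atom))
})

test_that("numbering maps: offset, explicit pairs, inversion, no silent pass-through", {
  xmap <- xkcnq1_to_hkcnq1()
  expect_equal(map_residue(xmap, 262L), 272L)          # Gly262 -> G272
  expect_equal(map_residue(xmap, 256L), 266L)
  expect_equal(map_residue(identity_map(), 99L), 99L)
  # explicit pairs: xKCNQ1 Leu256 corresponds to the KCNQ4 Trp at 242
  q4 <- numbering_map("xKCNQ1", "hKCNQ4",
                      pairs = data.frame(source = c(256, 262, 325),
                                         target = c(242, 248, 306)))
  expect_equal(map_residue(q4, 256L), 242L)
  expect_true(is.na(map_residue(q4, 999L)))            # explicit no-correspondence
  # inverse composition is the identity on the domain
  expect_equal(map_residue(invert_map(q4), map_residue(q4, c(256L, 325L))),
               c(256L, 325L))
  expect_equal(map_residue(invert_map(xmap), map_residue(xmap, 100:110)),
               100:110)
  expect_error(numbering_map("a", "b",
                             pairs = data.frame(source = c(1, 2), target = c(3, 3))),
               "injective")
})

test_that("helix bundles have exact C_n symmetry and requested chi1", {
  for (n in c(3, 4)) {
    b <- build_helix_bundle(n, radius = 10, residues_per_helix = 8)
    tb <- tibble::as_tibble(b)
    A <- coords(dplyr::filter(tb, chain == "A"))
    B <- coords(dplyr::filter(tb, chain == "B"))
    th <- 2 * pi / n
    Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    expect_lt(sqrt(mean(rowSums((A %*% t(Rz) - B)^2))), 1e-6)
  }
  r <- get_residue(build_helix_bundle(1, 0, 5, sequence = "LEU", chi1 = 60),
                   "A", 3)
  expect_equal(chi1(r), 60, tolerance = 1e-9)
  expect_error(build_helix_bundle(2, 8, 4, sequence = "XXX"), "unsupported")
})

test_that("adjacent_protomer identifies the two pocket chains deterministically", {
  b <- ligand_bundle()
  lig <- ligand_instances(b)
  pair <- adjacent_protomer(b, lig[1, ], cutoff = 5)
  expect_setequal(c(pair$principal, pair$primed), c("A", "B"))
  expect_identical(adjacent_protomer(b, lig[1, ], cutoff = 5), pair)
  # ligand far from everything -> degenerate
  far <- tibble::as_tibble(b)
  far[far$het, c("x", "y", "z")] <- list(500, 500, 500)
  sfar <- new_structure(far)
  expect_error(adjacent_protomer(sfar, ligand_instances(sfar)[1, ],
                                 cutoff = 5), "contacts only 0")
  # ligand only near one chain
  one <- tibble::as_tibble(b)
  ca <- coords(select_atoms(b, "chain A and resi 6 and name CB"))
  one[one$het, c("x", "y", "z")] <-
    list(ca[1] , ca[2], ca[3] + 1.5)
  sone <- new_structure(one)
  expect_error(adjacent_protomer(sone, ligand_instances(sone)[1, ],
                                 cutoff = 3), "only 1 chain")
})
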