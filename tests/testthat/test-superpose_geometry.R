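test_that("kabsch: identity, exact recovery, reflection correction, degeneracy", {
  set.seed(101)
  P <- matrix(rnorm(30), 10, 3)
  tf <- kabsch(P, P)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-9)
  expect_equal(tf$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(tf$rmsd, 0, tolerance = 1e-9)

  R <- random_rotation(); t <- c(4, -7, 2)
  Q <- sweep(P %*% t(R), 2, t, FUN = "+")
  tf2 <- kabsch(P, Q)
  expect_lt(max(abs(tf2$rotation - R)), 1e-6)
  expect_lt(max(abs(tf2$translation - t)), 1e-6)
  expect_lt(tf2$rmsd, 1e-6)
  expect_equal(det(tf2$rotation), 1, tolerance = 1e-9)

  expect_error(kabsch(P[1:2, ], Q[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch(line, line + 1), "collinear")
})

test_that("kabsch rmsd beats 1,000 random rigid placements and is invariant to pre-transforms", {
  set.seed(202)
  P <- matrix(rnorm(24), 8, 3)
  Q <- P + matrix(rnorm(24, sd = 0.3), 8, 3)   # noisy pairing
  best <- kabsch(P, Q)$rmsd
  rand_rmsd <- replicate(1000, {
    R <- random_rotation(); t <- rnorm(3, sd = 5)
    sqrt(mean(rowSums((sweep(P %*% t(R), 2, t, FUN = "+") - Q)^2)))
  })
  expect_true(all(best <= rand_rmsd + 1e-12))
  # invariance of the fitted rmsd under rigid pre-transforms of the mobile set
  rmsds <- replicate(100, {
    R <- random_rotation(); t <- rnorm(3, sd = 10)
    kabsch(sweep(P %*% t(R), 2, t, FUN = "+"), Q)$rmsd
  })
  expect_lt(max(abs(rmsds - best)), 1e-6)
})

test_that("displacement_map: zero self-displacement, constructed offsets, missing atoms flagged", {
  b <- build_helix_bundle(2, radius = 9, residues_per_helix = 12)
  dm0 <- displacement_map(b, b, anchor = "resi 1-12")
  expect_true(all(dm0$displacement[dm0$flag == ""] < 1e-9))

  shifted <- tibble::as_tibble(b)
  idx <- shifted$chain == "A" & shifted$resi == 10
  shifted$x[idx] <- shifted$x[idx] + 2
  dm <- displacement_map(b, new_structure(shifted), anchor = "resi 1-6",
                         atom_rule = "CA")
  hit <- dplyr::filter(dm, chain == "A", resi == 10)
  expect_equal(hit$displacement, 2, tolerance = 1e-9)
  rest <- dplyr::filter(dm, !(chain == "A" & resi == 10))
  expect_lt(max(rest$displacement), 1e-9)

  # residue missing in B is flagged, not dropped
  gone <- dplyr::filter(tibble::as_tibble(b), !(chain == "A" & resi == 12))
  dmg <- displacement_map(b, new_structure(gone), anchor = "resi 1-6",
                          atom_rule = "CA")
  expect_equal(dplyr::filter(dmg, chain == "A", resi == 12)$flag, "unpaired")
  expect_error(displacement_map(b, b, anchor = "resi 500"), "empty anchor")
})

test_that("chi1 measures what the builder sets, for every supported gamma convention", {
  for (case in list(c("LEU", -72), c("LEU", 173), c("PHE", 60), c("VAL", -60),
                    c("ILE", 55), c("SER", 180), c("THR", -65), c("CYS", 65),
                    c("TRP", -90))) {
    r <- build_residue(case[1], chi1 = as.numeric(case[2]))
    expect_equal(chi1(r), as.numeric(case[2]), tolerance = 1e-6,
                 label = paste("chi1 of", case[1]))
  }
  expect_true(is.na(chi1(build_residue("GLY"))))
  expect_true(is.na(chi1(build_residue("ALA"))))
  incomplete <- dplyr::filter(build_residue("LEU", -60), atom != "CG")
  expect_error(chi1(incomplete), "CG")
})

test_that("chi1 is invariant under 1,000 random rigid transforms", {
  set.seed(7)
  r <- build_residue("LEU", chi1 = -72)
  base <- chi1(r)
  devs <- replicate(1000, {
    rr <- apply_rigid(r, random_rotation(), rnorm(3, sd = 30))
    abs(chi1(rr) - base)
  })
  expect_lt(max(devs), 1e-6)
})

test_that("rotate_chi1: identity, periodicity, exact round trip, rigid side chain", {
  r <- build_residue("LEU", chi1 = 173)
  expect_lt(max(abs(coords(rotate_chi1(r, 173)) - coords(r))), 1e-9)
  expect_lt(max(abs(coords(rotate_chi1(r, 173 + 360)) - coords(r))), 1e-9)
  r2 <- rotate_chi1(r, -72)
  expect_equal(chi1(r2), -72, tolerance = 1e-6)
  back <- rotate_chi1(r2, 173)
  expect_lt(max(abs(coords(back) - coords(r))), 1e-6)
  # backbone + CB untouched; intra-side-chain distances preserved
  fixed <- c("N", "CA", "C", "O", "CB")
  expect_lt(max(abs(coords(dplyr::filter(r2, atom %in% fixed)) -
                    coords(dplyr::filter(r, atom %in% fixed)))), 1e-12)
  side <- c("CG", "CD1", "CD2")
  d0 <- dist(coords(dplyr::filter(r, atom %in% side)))
  d2 <- dist(coords(dplyr::filter(r2, atom %in% side)))
  expect_equal(as.numeric(d2), as.numeric(d0), tolerance = 1e-9)
})

test_that("clash_check arithmetic and brute-force/grid agreement", {
  mk <- function(x, chain, resi) tibble::tibble(
    chain = chain, resi = resi, icode = "", resn = "UNK", atom = "C",
    element = "C", x = x, y = 0, z = 0, occ = 1, b = 0, het = FALSE)
  crit <- clash_criterion(tolerance = 0.4)   # C+C limit = 3.0
  expect_equal(nrow(clash_check(mk(0, "M", 1), mk(3.5, "E", 2), crit)), 0)
  hit <- clash_check(mk(0, "M", 1), mk(2.5, "E", 2), crit)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$overlap, 0.5, tolerance = 1e-9)
  expect_equal(nrow(clash_check(mk(0, "M", 1), mk(3.5, "E", 2)[0, ], crit)), 0)
  expect_error(clash_check(mk(0, "M", 1),
                           dplyr::mutate(mk(2, "E", 2), element = "Xx"), crit),
               "no vdW radius")

  set.seed(33)
  mv <- random_atoms(25, chain = "M")
  env <- random_atoms(500)
  g <- clash_check(mv, env, crit, method = "grid")
  b <- clash_check(mv, env, crit, method = "brute")
  expect_equal(as.data.frame(g), as.data.frame(b))
  expect_gt(nrow(g), 0)
})

test_that("chi1 clash scan matches the closed-form circle-sphere onsets", {
  r <- build_residue("CYS", chi1 = 0)
  # orbit of the gamma atom about the CA-CB axis
  n_at <- coords(dplyr::filter(r, atom == "N"))[1, ]
  ca <- coords(dplyr::filter(r, atom == "CA"))[1, ]
  cb <- coords(dplyr::filter(r, atom == "CB"))[1, ]
  sg <- coords(dplyr::filter(r, atom == "SG"))[1, ]
  u <- (cb - ca) / sqrt(sum((cb - ca)^2))
  c0 <- cb + u * sum((sg - cb) * u)
  rho <- sqrt(sum((sg - c0)^2))
  v1 <- (sg - c0) / rho                      # direction of chi1 = 0
  # environment carbon on the chi1 = 0 ray, just outside the orbit
  e <- c0 + (rho + 2) * v1
  env <- tibble::tibble(chain = "E", resi = 99L, icode = "", resn = "UNK",
                        atom = "C", element = "C", x = e[1], y = e[2],
                        z = e[3], occ = 1, b = 0, het = FALSE)
  s <- new_structure(dplyr::bind_rows(r, env), id = "orbit")
  crit <- clash_criterion(tolerance = 0.4)   # S+C limit = 3.1
  d_clash <- 1.80 + 1.70 - 0.4
  # law of cosines in the orbit plane: clash iff |chi1| < theta_star
  cth <- ((rho + 2)^2 + rho^2 - d_clash^2) / (2 * rho * (rho + 2))
  theta_star <- acos(cth) * 180 / pi
  scan <- chi1_clash_scan(s, "A", 1L, environment = "chain E", crit, step = 1)
  expect_equal(sort(scan$onsets), sort(c(-ceiling(theta_star), ceiling(theta_star))),
               tolerance = 1.5)              # within one grid step
  forb <- scan$angles[!scan$allowed]
  expect_true(all(abs(forb) < theta_star + 1 + 1e-9))
  # clash partner named at a forbidden angle
  k <- which(!scan$allowed)[1]
  expect_equal(scan$clash[[k]]$resi, 99L)
})

test_that("scan properties: empty environment, tolerance monotonicity, grid refinement", {
  b <- ligand_bundle()
  # isolated residue: whole circle allowed
  iso <- new_structure(get_residue(b, "A", 6))
  scan0 <- chi1_clash_scan(iso, "A", 6L, environment = "chain Z",
                           step = 5)
  expect_true(all(scan0$allowed))
  expect_equal(nrow(scan0$allowed_intervals), 1)

  scans <- lapply(c(0.0, 0.2, 0.4, 0.6), function(tol)
    chi1_clash_scan(b, "A", 6L, environment = "hetero",
                    clash_criterion(tolerance = tol), step = 5))
  allowed_n <- vapply(scans, function(s) sum(s$allowed), integer(1))
  expect_true(all(diff(allowed_n) >= 0))     # larger tolerance, more allowed
  # smaller tolerance gives a superset of clashes angle by angle
  for (k in seq_along(scans[[1]]$angles)) {
    strict <- scans[[1]]$clash[[k]]$resi
    loose <- scans[[4]]$clash[[k]]$resi
    expect_true(all(loose %in% strict))
  }
  # coarse grid is the fine grid restricted to shared angles
  fine <- chi1_clash_scan(b, "A", 6L, environment = "hetero", step = 5)
  coarse <- chi1_clash_scan(b, "A", 6L, environment = "hetero", step = 10)
  shared <- match(coarse$angles, fine$angles)
  expect_equal(coarse$allowed, fine$allowed[shared])
})
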