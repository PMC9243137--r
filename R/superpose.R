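#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation + translation taking `mobile` onto `reference`,
#' with atoms paired by order.  A proper rotation (det = +1) is enforced;
#' reflections are corrected in the standard way.
#'
#' @param mobile,reference Atom tibbles or n x 3 coordinate matrices with
#'   equal atom counts (>= 3), paired by row order.
#' @return A `rigid_transform`: list with `rotation` (3 x 3), `translation`
#'   (length-3, Angstrom), `rmsd` over the pairing, and `n_atoms`.
#' @export
kabsch <- function(mobile, reference) {
  P <- if (is.matrix(mobile)) mobile else coords(mobile)
  Q <- if (is.matrix(reference)) reference else coords(reference)
  if (nrow(P) != nrow(Q)) abort("kabsch: atom counts differ")
  if (nrow(P) < 3) abort("kabsch: need at least 3 paired atoms")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  if (min(svd(P0)$d) < 1e-9 * max(svd(P0)$d, 1))
    abort("kabsch: degenerate (collinear) anchor atoms")
  H <- t(P0) %*% Q0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t_vec <- as.numeric(cq - R %*% cp)
  res <- transform_xyz(P, R, t_vec) - Q
  out <- list(rotation = R, translation = t_vec,
              rmsd = sqrt(mean(rowSums(res^2))), n_atoms = nrow(P))
  class(out) <- "rigid_transform"
  out
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform: %d atoms, rmsd %.4f A>\n", x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to a structure or atom table
#'
#' @param x A `chan_structure`, atom tibble or n x 3 matrix.
#' @param transform A `rigid_transform` (or list with `rotation`,
#'   `translation`).
#' @return Same type as `x`, transformed.
#' @export
apply_transform <- function(x, transform) {
  R <- transform$rotation; t_vec <- transform$translation
  if (is.matrix(x)) return(transform_xyz(x, R, t_vec))
  set_coords(x, transform_xyz(coords(x), R, t_vec))
}

#' Superpose one structure onto another via an anchor selection
#'
#' Anchors default to the CA atoms of the named selection; residues are
#' paired across structures through `pairing`.
#'
#' @param mobile,reference `chan_structure` objects.
#' @param anchor Selection string resolved in the *reference* numbering
#'   (e.g. `"chain A and resi 10-40"`); CA atoms are used.
#' @param pairing A [numbering_map()] from reference numbering to mobile
#'   numbering (default: identity).
#' @return List with the fitted `transform` and the transformed `mobile`
#'   structure.
#' @export
superpose <- function(mobile, reference, anchor, pairing = identity_map()) {
  ref_ca <- select_atoms(reference, paste(anchor, "and name CA and protein"))
  if (nrow(ref_ca) == 0) abort("empty anchor selection")
  mob <- as_tibble(mobile)
  mob_resi <- map_residue(pairing, ref_ca$resi)
  key_ref <- paste(ref_ca$chain, mob_resi)
  mob_ca <- mob |> filter(.data$atom == "CA", !.data$het)
  idx <- match(key_ref, paste(mob_ca$chain, mob_ca$resi))
  ok <- !is.na(idx)
  if (sum(ok) < 3) abort("fewer than 3 anchor residues shared across structures")
  tf <- kabsch(coords(mob_ca[idx[ok], ]), coords(ref_ca[ok, ]))
  list(transform = tf, mobile = apply_transform(mobile, tf),
       n_anchor = sum(ok))
}

#' Per-residue displacement map after anchored superposition
#'
#' Superposes `structB` onto `structA` using the CA atoms of `anchor`, then
#' reports the displacement of every paired residue under one or more atom
#' rules: `"CA"` (CA-atom distance), `"backbone_mean"` (distance between
#' backbone-atom centroids), `"sidechain_centroid"` (distance between heavy
#' side-chain centroids; falls back to CA for Gly, flagged), `"max_heavy"`
#' (maximum over shared heavy atoms).  Residues missing the rule's atoms are
#' flagged, never dropped.
#'
#' @param structA,structB `chan_structure` objects (A is the reference).
#' @param anchor Anchor selection string (reference numbering).
#' @param pairing [numbering_map()] from A numbering to B numbering.
#' @param atom_rule Character vector of rules (see above).
#' @param scope Optional selection string restricting which A residues are
#'   reported (default: all protein residues).
#' @return Tibble: chain, resi, resn, atom_rule, displacement (Angstrom),
#'   flag.
#' @export
displacement_map <- function(structA, structB, anchor,
                             pairing = identity_map(),
                             atom_rule = c("CA", "sidechain_centroid"),
                             scope = "protein") {
  fit <- superpose(structB, structA, anchor, pairing)
  B <- as_tibble(fit$mobile) |> filter(!.data$het, .data$element != "H")
  A <- select_atoms(structA, paste(scope, "and heavy and protein"))
  resA <- residues(A)
  bb_names <- c("N", "CA", "C", "O")
  rows <- list()
  for (i in seq_len(nrow(resA))) {
    ra <- resA$atoms[[i]]
    resi_b <- map_residue(pairing, resA$resi[i])
    rb <- B |> filter(.data$chain == resA$chain[i], .data$resi == resi_b)
    for (rule in atom_rule) {
      flag <- ""
      d <- NA_real_
      if (is.na(resi_b) || nrow(rb) == 0) {
        flag <- "unpaired"
      } else if (rule == "CA") {
        pa <- ra |> filter(.data$atom == "CA")
        pb <- rb |> filter(.data$atom == "CA")
        if (nrow(pa) == 1 && nrow(pb) == 1)
          d <- vnorm(as.numeric(coords(pa) - coords(pb)))
        else flag <- "missing CA"
      } else if (rule == "backbone_mean") {
        pa <- ra |> filter(.data$atom %in% bb_names)
        pb <- rb |> filter(.data$atom %in% bb_names)
        if (nrow(pa) > 0 && nrow(pb) > 0)
          d <- vnorm(colMeans(coords(pa)) - colMeans(coords(pb)))
        else flag <- "missing backbone"
      } else if (rule == "sidechain_centroid") {
        pa <- ra |> filter(!.data$atom %in% bb_names)
        pb <- rb |> filter(!.data$atom %in% bb_names)
        if (nrow(pa) > 0 && nrow(pb) > 0) {
          d <- vnorm(colMeans(coords(pa)) - colMeans(coords(pb)))
        } else {
          pa <- ra |> filter(.data$atom == "CA")
          pb <- rb |> filter(.data$atom == "CA")
          if (nrow(pa) == 1 && nrow(pb) == 1) {
            d <- vnorm(as.numeric(coords(pa) - coords(pb)))
            flag <- "no sidechain: CA used"
          } else flag <- "missing atoms"
        }
      } else if (rule == "max_heavy") {
        shared <- intersect(ra$atom, rb$atom)
        if (length(shared) > 0) {
          pa <- coords(ra[match(shared, ra$atom), ])
          pb <- coords(rb[match(shared, rb$atom), ])
          d <- max(sqrt(rowSums((pa - pb)^2)))
        } else flag <- "no shared atoms"
      } else abort(paste0("unknown atom_rule: ", rule))
      rows[[length(rows) + 1]] <- tibble(
        chain = resA$chain[i], resi = resA$resi[i], resi_b = resi_b,
        resn = resA$resn[i], atom_rule = rule, displacement = d, flag = flag)
    }
  }
  out <- bind_rows(rows)
  attr(out, "anchor") <- anchor
  attr(out, "anchor_rmsd") <- fit$transform$rmsd
  out
}
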