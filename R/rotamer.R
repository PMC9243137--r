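# chi1 dihedrals, side-chain rotation about CA-CB, and van der Waals clash
# scanning over the chi1 circle.

# gamma atom defining chi1, by residue type (standard convention)
.gamma_atom <- c(ILE = "CG1", VAL = "CG1", SER = "OG", CYS = "SG", THR = "OG1")

gamma_atom_for <- function(resn) {
  if (resn %in% c("GLY", "ALA")) return(NA_character_)
  if (resn %in% names(.gamma_atom)) unname(.gamma_atom[[resn]]) else "CG"
}

residue_chi1_frame <- function(res) {
  resn <- res$resn[1]
  g <- gamma_atom_for(resn)
  if (is.na(g)) return(NULL)
  need <- c("N", "CA", "CB", g)
  missing <- setdiff(need, res$atom)
  if (length(missing) > 0)
    abort(sprintf("residue %s %s/%d lacks chi1-defining atom(s): %s",
                  resn, res$chain[1], res$resi[1],
                  paste(missing, collapse = ", ")))
  lapply(setNames(need, c("N", "CA", "CB", "G")), function(a)
    as.numeric(coords(res[match(a, res$atom), ])))
}

#' chi1 side-chain dihedral of a residue
#'
#' Signed N-CA-CB-gamma dihedral in (-180, 180] (IUPAC convention).  The
#' gamma atom follows the standard table (CG; CG1 for Ile/Val; OG for Ser;
#' SG for Cys; OG1 for Thr).  Gly/Ala have no chi1 and return `NA`.
#'
#' @param residue Atom tibble of one residue (e.g. from [get_residue()]).
#' @return chi1 in degrees, or `NA` for Gly/Ala.
#' @export
chi1 <- function(residue) {
  fr <- residue_chi1_frame(as_tibble(residue))
  if (is.null(fr)) return(NA_real_)
  dihedral_angle(fr$N, fr$CA, fr$CB, fr$G)
}

#' chi1 for every residue of a structure
#'
#' @param structure A `chan_structure`.
#' @return Tibble: chain, resi, resn, chi1 (degrees; `NA` for Gly/Ala).
#' @export
chi1_table <- function(structure) {
  rs <- residues(select_atoms(structure, "protein and heavy"))
  rs$chi1 <- vapply(seq_len(nrow(rs)), function(i) {
    res <- rs$atoms[[i]]
    res$chain <- rs$chain[i]; res$resi <- rs$resi[i]; res$resn <- rs$resn[i]
    g <- gamma_atom_for(rs$resn[i])
    if (is.na(g) || !all(c("N", "CA", "CB", g) %in% res$atom)) return(NA_real_)
    chi1(res)
  }, numeric(1))
  rs[, c("chain", "resi", "resn", "chi1")]
}

#' Rotate a side chain to a target chi1
#'
#' Atoms distal to CB are rotated rigidly about the CA-CB axis so that the
#' returned residue has exactly the requested chi1; backbone, CB and all
#' bonded geometry are untouched.
#'
#' @param residue Atom tibble of one residue.
#' @param target_angle Target chi1 in degrees.
#' @return The rotated residue tibble.
#' @export
rotate_chi1 <- function(residue, target_angle) {
  res <- as_tibble(residue)
  fr <- residue_chi1_frame(res)
  if (is.null(fr)) abort("residue has no chi1 (Gly/Ala)")
  cur <- dihedral_angle(fr$N, fr$CA, fr$CB, fr$G)
  delta <- target_angle - cur
  axis <- fr$CB - fr$CA
  R <- rotation_about(axis, delta)
  distal <- !res$atom %in% c("N", "CA", "C", "O", "CB", "H", "HA", "OXT")
  if (any(distal)) {
    xyz <- coords(res[distal, ])
    xyz <- transform_xyz(sweep(xyz, 2, fr$CA), R)
    xyz <- sweep(xyz, 2, fr$CA, FUN = "+")
    res[distal, c("x", "y", "z")] <- as.data.frame(xyz)
  }
  res
}

#' van der Waals clash criterion
#'
#' Two heavy atoms clash when their distance is below the sum of their
#' element radii minus `tolerance`.  Default radii are the Bondi set;
#' the paper-style clash bounds are screened over a documented tolerance
#' sweep because the printed figures give no numeric criterion.
#'
#' @param radii Named vector of per-element radii (Angstrom).
#' @param tolerance Overlap allowance subtracted from the radius sum
#'   (Angstrom, >= 0).
#' @return A `clash_criterion` list.
#' @export
clash_criterion <- function(radii = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                                      P = 1.80, F = 1.47, Cl = 1.75,
                                      Br = 1.85, I = 1.98),
                            tolerance = 0.4) {
  if (any(radii <= 0) || tolerance < 0)
    abort("clash_criterion: radii must be positive, tolerance >= 0")
  structure(list(radii = radii, tolerance = tolerance),
            class = "clash_criterion")
}

atom_radii <- function(elements, criterion) {
  r <- criterion$radii[elements]
  if (any(is.na(r)))
    abort(paste0("no vdW radius for element(s): ",
                 paste(unique(elements[is.na(r)]), collapse = ", ")))
  unname(r)
}

#' Steric clashes between a rotated side chain and its environment
#'
#' All-pairs check of `rotated` heavy atoms against `environment` heavy
#' atoms; a pair clashes when dist < r_i + r_j - tolerance.  A grid (cell
#' list) accelerates large environments and returns exactly the brute-force
#' pair set.
#'
#' @param rotated Atom tibble (the moving atoms; heavy atoms only are used).
#' @param environment Atom tibble, must exclude the rotated residue itself.
#' @param criterion A [clash_criterion()].
#' @param method `"grid"` or `"brute"` (identical results).
#' @return Tibble of clash partners: one row per environment *residue* with
#'   the worst overlap (Angstrom) and the closest atom pair.  Zero rows
#'   means no clash.
#' @export
clash_check <- function(rotated, environment, criterion = clash_criterion(),
                        method = c("grid", "brute")) {
  method <- match.arg(method)
  mv <- as_tibble(rotated) |> filter(.data$element != "H")
  env <- as_tibble(environment) |> filter(.data$element != "H")
  empty <- tibble(chain = character(), resi = integer(), resn = character(),
                  overlap = numeric(), atom = character(),
                  partner_atom = character(), dist = numeric())
  if (nrow(mv) == 0 || nrow(env) == 0) return(empty)
  rm_ <- atom_radii(mv$element, criterion)
  re_ <- atom_radii(env$element, criterion)
  cutmax <- max(rm_) + max(re_) - criterion$tolerance
  P <- coords(mv); E <- coords(env)

  pairs <- if (method == "brute" || nrow(env) <= 64) {
    all_pairs_clashes(P, E, rm_, re_, criterion$tolerance)
  } else {
    grid_clashes(P, E, rm_, re_, criterion$tolerance, cell = cutmax)
  }
  if (nrow(pairs) == 0) return(empty)
  pairs$chain <- env$chain[pairs$j]
  pairs$resi <- env$resi[pairs$j]
  pairs$resn <- env$resn[pairs$j]
  pairs$atom <- mv$atom[pairs$i]
  pairs$partner_atom <- env$atom[pairs$j]
  pairs |>
    group_by(.data$chain, .data$resi, .data$resn) |>
    slice(which.max(.data$overlap)) |>
    ungroup() |>
    arrange(.data$chain, .data$resi) |>
    select("chain", "resi", "resn", "overlap", "atom", "partner_atom", "dist")
}

all_pairs_clashes <- function(P, E, rm_, re_, tol) {
  d2 <- outer(rowSums(P^2), rowSums(E^2), "+") - 2 * P %*% t(E)
  d2[d2 < 0] <- 0
  lim <- outer(rm_, re_, "+") - tol
  hit <- which(d2 < lim^2, arr.ind = TRUE)
  if (length(hit) == 0)
    return(tibble(i = integer(), j = integer(), dist = numeric(),
                  overlap = numeric()))
  d <- sqrt(d2[hit])
  tibble(i = hit[, 1], j = hit[, 2], dist = d,
         overlap = lim[hit] - d)
}

grid_clashes <- function(P, E, rm_, re_, tol, cell) {
  key <- function(M) floor(sweep(M, 2, c(0, 0, 0)) / cell)
  ek <- key(E)
  ek_id <- paste(ek[, 1], ek[, 2], ek[, 3])
  buckets <- split(seq_len(nrow(E)), ek_id)
  out <- list()
  pk <- key(P)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(nrow(P))) {
    nb <- sweep(offs, 2, pk[i, ], FUN = "+")
    ids <- paste(nb[, 1], nb[, 2], nb[, 3])
    j <- unlist(buckets[ids], use.names = FALSE)
    if (length(j) == 0) next
    d <- sqrt(rowSums((E[j, , drop = FALSE] -
                         matrix(P[i, ], length(j), 3, byrow = TRUE))^2))
    lim <- rm_[i] + re_[j] - tol
    hit <- d < lim
    if (any(hit))
      out[[length(out) + 1]] <- tibble(i = i, j = j[hit], dist = d[hit],
                                       overlap = (lim - d)[hit])
  }
  if (length(out) == 0)
    return(tibble(i = integer(), j = integer(), dist = numeric(),
                  overlap = numeric()))
  bind_rows(out)
}

#' Scan chi1 for steric clashes around the full circle
#'
#' Rotates the side chain of one residue over a chi1 grid and records, at
#' each angle, the clashing environment residues.  Reports the sterically
#' allowed intervals and the onset angles where allowed turns forbidden
#' (onsets are reported at the allowed-side boundary grid point).
#'
#' @param structure A `chan_structure`.
#' @param chain,resi Residue to scan.
#' @param environment Selection string for the environment (the scanned
#'   residue is always excluded).
#' @param criterion A [clash_criterion()].
#' @param step Grid step in degrees; must divide 360.
#' @return A `rotamer_scan` list: `angles`, `clash` (list of clash tables
#'   per angle), `allowed` (logical), `allowed_intervals` tibble (lo, hi),
#'   `onsets` (degrees), plus the scanned residue id.
#' @export
chi1_clash_scan <- function(structure, chain, resi, environment,
                            criterion = clash_criterion(), step = 1) {
  if (abs(360 / step - round(360 / step)) > 1e-9)
    abort("step must divide 360 evenly")
  res <- get_residue(structure, chain, resi) |> filter(.data$element != "H")
  env <- select_atoms(structure, paste(environment, "and heavy"))
  env <- env |> filter(!(.data$chain == !!chain & .data$resi == !!resi))
  angles <- seq(-180 + step, 180, by = step)
  scans <- lapply(angles, function(a) {
    rot <- rotate_chi1(res, a)
    distal <- rot |> filter(!.data$atom %in% c("N", "CA", "C", "O", "CB"))
    clash_check(distal, env, criterion)
  })
  allowed <- vapply(scans, function(s) nrow(s) == 0, logical(1))
  iv <- allowed_intervals(angles, allowed, step)
  out <- list(chain = chain, resi = resi, resn = res$resn[1],
              angles = angles, clash = scans, allowed = allowed,
              allowed_intervals = iv$intervals, onsets = iv$onsets,
              step = step, tolerance = criterion$tolerance)
  class(out) <- "rotamer_scan"
  out
}

# Runs of the allowed mask as disjoint intervals within (-180, 180].
# Because the grid is circular, an allowed region spanning the +/-180
# boundary is reported as two intervals; onset angles are recorded only at
# true circular allowed/forbidden transitions, at the allowed-side grid
# point.
allowed_intervals <- function(angles, allowed, step) {
  n <- length(allowed)
  if (all(allowed))
    return(list(intervals = tibble(lo = -180 + step, hi = 180),
                onsets = numeric()))
  if (!any(allowed))
    return(list(intervals = tibble(lo = numeric(), hi = numeric()),
                onsets = numeric()))
  r <- rle(allowed)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1
  iv <- list(); onsets <- numeric()
  prev_circ <- function(i) if (i == 1) n else i - 1
  next_circ <- function(i) if (i == n) 1 else i + 1
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    lo_i <- begins[k]; hi_i <- ends[k]
    iv[[length(iv) + 1]] <- tibble(lo = angles[lo_i], hi = angles[hi_i])
    if (!allowed[prev_circ(lo_i)]) onsets <- c(onsets, angles[lo_i])
    if (!allowed[next_circ(hi_i)]) onsets <- c(onsets, angles[hi_i])
  }
  list(intervals = bind_rows(iv) |> arrange(.data$lo),
       onsets = sort(unique(onsets)))
}

#' @export
print.rotamer_scan <- function(x, ...) {
  cat(sprintf("<rotamer_scan %s %s/%d: step %g deg, tolerance %.2f A>\n",
              x$resn, x$chain, x$resi, x$step, x$tolerance))
  if (nrow(x$allowed_intervals) == 0) {
    cat("  no sterically allowed chi1\n")
  } else {
    for (i in seq_len(nrow(x$allowed_intervals)))
      cat(sprintf("  allowed: [%g, %g] deg\n",
                  x$allowed_intervals$lo[i], x$allowed_intervals$hi[i]))
  }
  invisible(x)
}

#' Tidy per-angle summary of a rotamer scan
#'
#' @param x A `rotamer_scan`.
#' @param ... Unused.
#' @return Tibble: angle, allowed, n_clash, partners (comma list).
#' @export
tidy.rotamer_scan <- function(x, ...) {
  tibble(angle = x$angles, allowed = x$allowed,
         n_clash = vapply(x$clash, nrow, integer(1)),
         partners = vapply(x$clash, function(s)
           paste(sprintf("%s/%d", s$chain, s$resi), collapse = ","),
           character(1)))
}
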