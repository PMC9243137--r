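#' Symmetry axis of a multi-chain channel
#'
#' For a C_n arrangement the chain centroids lie in a plane perpendicular
#' to the pore axis, so the axis is taken as the normal of the best-fit
#' plane through the chain centroids (smallest principal component),
#' through their common centroid.  The direction is sign-normalized to a
#' positive z component (tie: positive x).
#'
#' @param structure A `chan_structure`.
#' @param chains Chain ids to use (default: all protein chains).
#' @return List with `origin` and unit `direction`.
#' @export
channel_axis <- function(structure, chains = NULL) {
  prot <- select_atoms(structure, "protein and heavy")
  if (!is.null(chains)) prot <- filter(prot, .data$chain %in% chains)
  cent <- prot |>
    group_by(.data$chain) |>
    summarise(x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
              .groups = "drop")
  if (nrow(cent) < 3)
    abort("channel_axis needs >= 3 chains for a defined symmetry axis")
  M <- as.matrix(cent[, c("x", "y", "z")])
  ctr <- colMeans(M)
  s <- svd(sweep(M, 2, ctr))
  if (s$d[2] < 1e-9)
    abort("degenerate chain-centroid geometry (collinear centroids)")
  dir <- s$v[, 3]
  if (dir[3] < 0 || (dir[3] == 0 && dir[1] < 0)) dir <- -dir
  list(origin = ctr, direction = unit(dir))
}

#' Pore-radius profile along a channel axis
#'
#' At each position z along the axis the pore radius is the radius of the
#' largest sphere centred in the axis-normal plane that touches no atom:
#' max over candidate centres of min_i(|centre - atom_i| - r_i).  With
#' `optimize_center = FALSE` the candidate is the on-axis point; otherwise
#' a deterministic Nelder-Mead search in the plane starts from the axis
#' point (fixed iteration budget, no randomness).  Where no atoms are near
#' a slice, the radius is capped at `max_radius` and flagged.
#'
#' @param structure A `chan_structure`.
#' @param axis A [channel_axis()] result (default: computed from all
#'   protein chains).
#' @param chains Chains to profile against (default all protein).
#' @param z_range Length-2 numeric, Angstrom along the axis relative to the
#'   axis origin; default spans the selection's extent +/- 5.
#' @param step Sampling step along the axis (Angstrom).
#' @param criterion A [clash_criterion()] supplying the vdW radii.
#' @param optimize_center Search the plane for the widest sphere.
#' @param max_radius Cap for unbounded slices (Angstrom).
#' @return A `pore_profile` tibble: z, radius, limiting atom columns,
#'   capped flag; attributes hold the axis.
#' @export
pore_profile <- function(structure, axis = NULL, chains = NULL,
                         z_range = NULL, step = 0.5,
                         criterion = clash_criterion(),
                         optimize_center = TRUE, max_radius = 15) {
  if (step <= 0) abort("step must be > 0")
  prot <- select_atoms(structure, "protein and heavy")
  if (!is.null(chains)) prot <- filter(prot, .data$chain %in% chains)
  if (is.null(axis)) axis <- channel_axis(structure, chains)
  r_at <- atom_radii(prot$element, criterion)
  # axis frame: u along axis, (e1, e2) spanning the normal plane
  u <- unit(axis$direction)
  e1 <- if (abs(u[1]) < 0.9) unit(pracma_cross(u, c(1, 0, 0))) else
    unit(pracma_cross(u, c(0, 1, 0)))
  e2 <- pracma_cross(u, e1)
  rel <- sweep(coords(prot), 2, axis$origin)
  za <- as.numeric(rel %*% u)
  if (is.null(z_range)) z_range <- range(za) + c(-5, 5)
  zs <- seq(z_range[1], z_range[2], by = step)

  clearance <- function(center3d, idx) {
    d <- sqrt(rowSums(sweep(rel[idx, , drop = FALSE], 2, center3d)^2))
    d - r_at[idx]
  }
  rows <- vector("list", length(zs))
  for (k in seq_along(zs)) {
    z <- zs[k]
    idx <- which(abs(za - z) <= max_radius + max(r_at))
    if (length(idx) == 0) {
      rows[[k]] <- tibble(z = z, radius = max_radius, capped = TRUE,
                          limiting_chain = NA_character_,
                          limiting_resi = NA_integer_,
                          limiting_atom = NA_character_)
      next
    }
    center_of <- function(p) z * u + p[1] * e1 + p[2] * e2
    objective <- function(p) -min(clearance(center_of(p), idx))
    p_best <- c(0, 0)
    if (optimize_center) {
      fit <- optim(c(0, 0), objective, method = "Nelder-Mead",
                   control = list(maxit = 200, reltol = 1e-8))
      # keep the on-axis point if the search did not improve
      if (-fit$value >= -objective(c(0, 0))) p_best <- fit$par
    }
    cl <- clearance(center_of(p_best), idx)
    j <- idx[which.min(cl)]
    radius <- max(0, min(cl))
    capped <- radius >= max_radius
    rows[[k]] <- tibble(z = z, radius = min(radius, max_radius),
                        capped = capped,
                        limiting_chain = prot$chain[j],
                        limiting_resi = prot$resi[j],
                        limiting_atom = prot$atom[j])
  }
  out <- bind_rows(rows)
  attr(out, "axis") <- axis
  attr(out, "optimize_center") <- optimize_center
  class(out) <- c("pore_profile", class(out))
  out
}

#' Minimum pore radius over a z window
#'
#' @param profile A [pore_profile()] tibble.
#' @param z_window Optional length-2 numeric restricting z.
#' @return One-row tibble: min_radius, min_z, and the limiting atom.
#' @export
min_pore_radius <- function(profile, z_window = NULL) {
  p <- as_tibble(profile)
  if (!is.null(z_window))
    p <- filter(p, .data$z >= z_window[1], .data$z <= z_window[2])
  p |> slice(which.min(.data$radius)) |>
    select(min_z = "z", min_radius = "radius", "limiting_chain",
           "limiting_resi", "limiting_atom")
}

#' Open/closed gate call from a pore profile
#'
#' A gate window whose minimum radius falls below `threshold` (default
#' 1.4 Angstrom, too narrow for a dehydrated K+ ion) is called closed.
#'
#' @param profile A [pore_profile()].
#' @param z_window Gate window along the axis.
#' @param threshold Radius threshold (Angstrom).
#' @return `"closed"` or `"open"`.
#' @export
gate_state <- function(profile, z_window = NULL, threshold = 1.4) {
  m <- min_pore_radius(profile, z_window)
  if (m$min_radius < threshold) "closed" else "open"
}
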