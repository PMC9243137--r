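#' Identify the two protomers forming a ligand pocket
#'
#' In a domain-swapped tetramer the activator pocket is lined by one
#' "principal" protomer (S4-S5 linker, S5, S6) and one "primed" adjacent
#' protomer (S5', S6').  The principal chain is the one contributing the
#' S4-S5 linker contacts when a linker residue range is supplied; otherwise
#' it is the chain with the most ligand-contacting atoms (tie: closest
#' atom).
#'
#' @param structure A `chan_structure`.
#' @param ligand One row of [ligand_instances()] (or an atom tibble of
#'   ligand heavy atoms).
#' @param cutoff Contact cutoff in Angstrom (the pocket cutoff).
#' @param s4s5_range Optional integer residue numbers of the S4-S5 linker
#'   used to call the principal chain.
#' @return List with `principal` and `primed` chain ids.
#' @export
adjacent_protomer <- function(structure, ligand, cutoff = 5,
                              s4s5_range = NULL) {
  lig <- ligand_atoms(ligand)
  prot <- select_atoms(structure, "protein and heavy")
  if (length(unique(prot$chain)) < 2)
    abort("adjacent_protomer needs at least 2 protein chains")
  d <- min_dist_to(prot, lig)
  contact <- prot[d <= cutoff, , drop = FALSE]
  contact$dist <- d[d <= cutoff]
  chains <- unique(contact$chain)
  if (length(chains) > 2)
    abort(paste0("ligand contacts more than 2 chains: ",
                 paste(sort(chains), collapse = ", ")))
  if (length(chains) < 2)
    abort(paste0("ligand contacts only ", length(chains),
                 " chain(s); pocket is degenerate"))
  by_chain <- contact |>
    group_by(.data$chain) |>
    summarise(n = dplyr::n(), dmin = min(.data$dist),
              linker = if (!is.null(s4s5_range))
                sum(.data$resi %in% s4s5_range) else 0L)
  by_chain <- arrange(by_chain, dplyr::desc(.data$linker),
                      dplyr::desc(.data$n), .data$dmin)
  list(principal = by_chain$chain[1], primed = by_chain$chain[2])
}

ligand_atoms <- function(ligand) {
  if (is_tibble(ligand) && "atoms" %in% names(ligand))
    return(ligand$atoms[[1]])
  as_tibble(ligand)
}

# min distance from each row of `atoms` to any atom of `ref`
min_dist_to <- function(atoms, ref) {
  A <- coords(atoms); B <- coords(ref)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  sqrt(apply(d2, 1, min))
}

#' Ligand-lining residues at a distance cutoff
#'
#' All protein residues with at least one heavy atom within `cutoff` of any
#' ligand heavy atom (the binding-site rule used for docking-site
#' selection, default 5 Angstrom), with per-residue minimum distances,
#' principal/primed role, and optional structural-element labels.
#'
#' @param structure A `chan_structure`.
#' @param ligand One row of [ligand_instances()] or ligand atom tibble.
#' @param cutoff Angstrom (> 0); default 5.
#' @param elements Optional named list of integer residue ranges labelling
#'   structural elements (e.g. `list("S4-S5L" = 235:247, S5 = 248:270)`).
#' @param s4s5_range Passed to [adjacent_protomer()].
#' @return A `pocket_definition` tibble: chain, resi, resn, role, min_dist,
#'   element; attributes record ligand and cutoff.
#' @export
lining_residues <- function(structure, ligand, cutoff = 5, elements = NULL,
                            s4s5_range = NULL) {
  if (cutoff <= 0) abort("cutoff must be > 0")
  lig <- ligand_atoms(ligand)
  if (nrow(lig) == 0) abort("no ligand atoms")
  prot <- select_atoms(structure, "protein and heavy")
  d <- min_dist_to(prot, lig)
  prot$dist <- d
  within <- filter(prot, .data$dist <= cutoff)
  if (nrow(within) == 0) {
    out <- tibble(chain = character(), resi = integer(), resn = character(),
                  role = character(), min_dist = numeric(),
                  element = character())
    attr(out, "cutoff") <- cutoff
    class(out) <- c("pocket_definition", class(out))
    return(out)
  }
  lining <- within |>
    group_by(.data$chain, .data$resi, .data$resn) |>
    summarise(min_dist = min(.data$dist), .groups = "drop") |>
    arrange(.data$chain, .data$resi)
  role <- rep(NA_character_, nrow(lining))
  if (nrow(lining) > 0 && length(unique(lining$chain)) >= 2) {
    prot_chains <- try(adjacent_protomer(structure, lig, cutoff, s4s5_range),
                       silent = TRUE)
    if (!inherits(prot_chains, "try-error")) {
      role[lining$chain == prot_chains$principal] <- "principal"
      role[lining$chain == prot_chains$primed] <- "primed"
    }
  }
  lining$role <- role
  lining$element <- "other"
  if (!is.null(elements)) {
    for (nm in names(elements))
      lining$element[lining$resi %in% elements[[nm]]] <- nm
  }
  out <- lining[, c("chain", "resi", "resn", "role", "min_dist", "element")]
  attr(out, "cutoff") <- cutoff
  attr(out, "ligand") <- if ("resn" %in% names(lig)) lig$resn[1] else "LIG"
  class(out) <- c("pocket_definition", class(out))
  out
}

# side-chain-relevant residue volumes (A^3), standard literature mean
# residue volumes (Zamyatnin); deltas between them drive the bulkier /
# smaller calls with a +/- 10 A^3 threshold.
.residue_volume <- c(ALA = 88.6, ARG = 173.4, ASN = 114.1, ASP = 111.1,
                     CYS = 108.5, GLN = 143.8, GLU = 138.4, GLY = 60.1,
                     HIS = 153.2, ILE = 166.7, LEU = 166.7, LYS = 168.6,
                     MET = 162.9, PHE = 189.9, PRO = 112.7, SER = 89.0,
                     THR = 116.1, TRP = 227.8, TYR = 193.6, VAL = 140.0)

aa1to3 <- function(x) names(.aa3)[match(toupper(x), .aa3)]

#' Compare a binding pocket across channel isoforms
#'
#' For each lining residue, looks up the residue identity at the
#' corresponding position in each isoform (from a curated identity table
#' such as [kcnq_isoform_table()]), flags conservation, and annotates
#' side-chain volume changes: a volume delta above `threshold` is
#' "bulkier", below `-threshold` "smaller".  Positions without a curated
#' correspondence are reported as unknown, never dropped.
#'
#' @param pocket A [lining_residues()] result (or tibble with resi, resn).
#' @param table Identity table with a `<source>_resi` column and one column
#'   per isoform holding single-letter identities (position suffix
#'   allowed, e.g. `"W236"`); `NA` = unknown.
#' @param source_col Name of the residue-number column in `table`.
#' @param isoforms Columns of `table` to compare against.
#' @param threshold Volume-delta threshold in cubic Angstrom.
#' @return Tibble: resi, resn, isoform, target (identity or `"—"`),
#'   conserved, volume_delta, call (`"bulkier"`, `"smaller"`,
#'   `"comparable"`, `"unknown"`).
#' @export
isoform_compare <- function(pocket, table = kcnq_isoform_table(),
                            source_col = "xKCNQ1_resi",
                            isoforms = c("hKCNQ1", "hKCNQ2", "hKCNQ3",
                                         "hKCNQ4", "hKCNQ5"),
                            threshold = 10) {
  pk <- as_tibble(pocket) |> distinct(.data$resi, .data$resn)
  rows <- list()
  for (i in seq_len(nrow(pk))) {
    j <- match(pk$resi[i], table[[source_col]])
    for (iso in isoforms) {
      tgt <- if (!is.na(j)) table[[iso]][j] else NA_character_
      if (is.na(tgt)) {
        rows[[length(rows) + 1]] <- tibble(
          resi = pk$resi[i], resn = pk$resn[i], isoform = iso,
          target = "—", conserved = NA, volume_delta = NA_real_,
          call = "unknown")
        next
      }
      letter <- substr(tgt, 1, 1)
      tgt3 <- aa1to3(letter)
      dv <- unname(.residue_volume[tgt3] - .residue_volume[pk$resn[i]])
      call <- if (is.na(dv)) "unknown"
        else if (dv > threshold) "bulkier"
        else if (dv < -threshold) "smaller"
        else "comparable"
      rows[[length(rows) + 1]] <- tibble(
        resi = pk$resi[i], resn = pk$resn[i], isoform = iso, target = tgt,
        conserved = identical(tgt3, pk$resn[i]), volume_delta = dv,
        call = call)
    }
  }
  bind_rows(rows)
}

#' Overlap between two binding pockets
#'
#' Set algebra over residue identifiers after mapping pocket B into pocket
#' A's numbering; unmapped residues are counted as unique and flagged.
#'
#' @param defA,defB [lining_residues()] results.
#' @param pairing [numbering_map()] from B numbering to A numbering.
#' @return List: `shared`, `only_a`, `only_b` (residue ids), `unmapped_b`,
#'   and `jaccard` in \[0, 1\].
#' @export
pocket_overlap <- function(defA, defB, pairing = identity_map()) {
  a <- unique(as_tibble(defA)$resi)
  b_src <- unique(as_tibble(defB)$resi)
  b_map <- map_residue(pairing, b_src)
  unmapped <- b_src[is.na(b_map)]
  b <- b_map[!is.na(b_map)]
  shared <- intersect(a, b)
  uni <- union(a, b)
  list(shared = sort(shared), only_a = sort(setdiff(a, b)),
       only_b = sort(setdiff(b, a)), unmapped_b = sort(unmapped),
       jaccard = if (length(uni) == 0) NA_real_ else length(shared) / length(uni))
}
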