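#' Select atoms with a compact query string
#'
#' The query is a set of clauses joined by `and`; each clause is one of
#' `chain A` (or `chain A+B`), `resi 238-245` (ranges and comma lists),
#' `resn LEU` (or `LEU+PHE`), `name CA` (or `CA+CB`), `elem C`,
#' `heavy` (exclude hydrogens), `protein`, `hetero`.  Matching rows are
#' returned in stable (chain, resi, atom-order) order; an empty result is
#' not an error.
#'
#' @param structure A `chan_structure` or atom tibble.
#' @param query Selection string, e.g. `"chain A and resi 238-245 and name CA"`.
#' @return Atom tibble (possibly empty).
#' @export
select_atoms <- function(structure, query) {
  a <- as_tibble(structure)
  a$.ord <- seq_len(nrow(a))
  keepers <- rep(TRUE, nrow(a))
  clauses <- trimws(strsplit(query, "\\band\\b")[[1]])
  clauses <- clauses[nzchar(clauses)]
  if (length(clauses) == 0) abort(paste0("malformed selection query: '", query, "'"))
  for (cl in clauses) {
    toks <- strsplit(cl, "[ \t]+")[[1]]
    key <- tolower(toks[1])
    arg <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else ""
    keepers <- keepers & switch(
      key,
      chain = a$chain %in% strsplit(arg, "\\+")[[1]],
      resi = a$resi %in% parse_resi_ranges(arg),
      resn = a$resn %in% toupper(strsplit(arg, "\\+")[[1]]),
      name = a$atom %in% toupper(strsplit(arg, "\\+")[[1]]),
      elem = a$element %in% normalize_element(strsplit(arg, "\\+")[[1]]),
      heavy = a$element != "H",
      protein = !a$het,
      hetero = a$het,
      abort(paste0("malformed selection clause: '", cl, "'"))
    )
  }
  out <- a[keepers, , drop = FALSE] |>
    arrange(.data$chain, .data$resi, .data$icode, .data$.ord)
  out$.ord <- NULL
  out
}

parse_resi_ranges <- function(arg) {
  if (!grepl("^[-0-9, ]+$", arg))
    abort(paste0("malformed residue range: '", arg, "'"))
  parts <- strsplit(gsub(" ", "", arg), ",")[[1]]
  unlist(lapply(parts, function(p) {
    if (grepl("-", p)) {
      ab <- as.integer(strsplit(p, "-")[[1]])
      seq(ab[1], ab[2])
    } else as.integer(p)
  }))
}

#' Coordinates of an atom selection as a matrix
#'
#' @param atoms Atom tibble.
#' @return Numeric matrix with columns x, y, z.
#' @export
coords <- function(atoms) {
  as.matrix(as_tibble(atoms)[, c("x", "y", "z")])
}

set_coords <- function(atoms, xyz) {
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}
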