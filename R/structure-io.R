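#' Tidy atomic structures
#'
#' A structure is a tibble with one row per atom and columns
#' `chain`, `resi` (author residue number, kept exactly as deposited),
#' `icode` (insertion code, `""` if none), `resn` (3-letter residue name),
#' `atom` (atom name), `element`, `x`, `y`, `z` (Angstrom), `occ`, `b`,
#' and `het` (`TRUE` for HETATM records).  Attributes `id` and
#' `source_format` record provenance.  All tidyverse verbs work on it
#' directly; the class `chan_structure` only adds printing and validation.
#'
#' @param atoms A data frame with at least chain, resi, resn, atom,
#'   element, x, y, z columns.
#' @param id Identifier for the structure.
#' @param source_format `"mmCIF"`, `"PDB"` or `"synthetic"`.
#' @return A `chan_structure` tibble.
#' @export
new_structure <- function(atoms, id = "structure", source_format = "synthetic") {
  atoms <- as_tibble(atoms)
  if (!"icode" %in% names(atoms)) atoms$icode <- ""
  if (!"occ" %in% names(atoms)) atoms$occ <- 1
  if (!"b" %in% names(atoms)) atoms$b <- 0
  if (!"het" %in% names(atoms)) atoms$het <- !atoms$resn %in% names(.aa3)
  atoms <- atoms[, c("chain", "resi", "icode", "resn", "atom", "element",
                     "x", "y", "z", "occ", "b", "het")]
  atoms$resi <- as.integer(atoms$resi)
  validate_structure(atoms)
  structure(atoms,
            class = c("chan_structure", class(tibble())),
            id = id, source_format = source_format)
}

validate_structure <- function(atoms) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) abort("non-finite atomic coordinates")
  if (any(!nzchar(atoms$element))) abort("atoms with empty element")
  invisible(atoms)
}

#' @export
print.chan_structure <- function(x, ...) {
  nres <- nrow(dplyr::distinct(as_tibble(x), .data$chain, .data$resi, .data$icode))
  cat(sprintf("# structure '%s' (%s): %d chains, %d residues, %d atoms\n",
              attr(x, "id"), attr(x, "source_format"),
              length(unique(x$chain)), nres, nrow(x)))
  NextMethod()
}

.aa3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V")

#' Read an atomic structure from a PDB or mmCIF file
#'
#' Author chain identifiers and residue numbers are preserved exactly as
#' deposited.  Alternate conformers are resolved to the highest-occupancy
#' copy (ties: first listed).  Elements missing from the file are inferred
#' from the atom name with a warning.
#'
#' @param path Path to the coordinate file.
#' @param format `"auto"` (by extension/content), `"mmCIF"` or `"PDB"`.
#' @return A [new_structure()] tibble.
#' @export
read_structure <- function(path, format = c("auto", "mmCIF", "PDB")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE) ||
                  any(startsWith(head(lines, 50), "data_"))) "mmCIF" else "PDB"
  }
  atoms <- if (format == "mmCIF") parse_mmcif(lines) else parse_pdb(lines)
  if (nrow(atoms) == 0) abort(paste0("no atom records parsed from ", path))
  atoms <- resolve_altloc(atoms)
  new_structure(atoms,
                id = sub("\\.(pdb|cif|ent)$", "", basename(path), ignore.case = TRUE),
                source_format = format)
}

# PDB fixed-column format (ATOM/HETATM records only).
parse_pdb <- function(lines) {
  rec <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")]
  if (length(rec) == 0) return(tibble())
  f <- function(a, b) trimws(substr(rec, a, b))
  xyz <- suppressWarnings(cbind(as.numeric(substr(rec, 31, 38)),
                                as.numeric(substr(rec, 39, 46)),
                                as.numeric(substr(rec, 47, 54))))
  if (any(!is.finite(xyz))) {
    bad <- which(!stats::complete.cases(xyz))[1]
    abort(sprintf("unparseable PDB coordinate record at line: %s", rec[bad]))
  }
  elem <- f(77, 78)
  name <- f(13, 16)
  miss <- !nzchar(elem)
  if (any(miss)) {
    warn(sprintf("%d atoms lack an element field; inferring from atom names",
                 sum(miss)))
    elem[miss] <- infer_element(name[miss])
  }
  occ <- suppressWarnings(as.numeric(substr(rec, 55, 60)))
  occ[!is.finite(occ)] <- 1
  b <- suppressWarnings(as.numeric(substr(rec, 61, 66)))
  b[!is.finite(b)] <- 0
  tibble(chain = f(22, 22), resi = as.integer(f(23, 26)), icode = f(27, 27),
         resn = f(18, 20), atom = name, altloc = f(17, 17),
         element = normalize_element(elem),
         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = occ, b = b,
         het = startsWith(rec, "HETATM"))
}

# Minimal mmCIF reader for the _atom_site loop (whitespace-separated values,
# as written by the PDB).
parse_mmcif <- function(lines) {
  i <- which(trimws(lines) == "loop_")
  start <- NA_integer_
  for (k in i) {
    if (k < length(lines) && startsWith(trimws(lines[k + 1]), "_atom_site.")) {
      start <- k; break
    }
  }
  if (is.na(start)) abort("mmCIF file has no _atom_site loop")
  j <- start + 1
  fields <- character()
  while (j <= length(lines) && startsWith(trimws(lines[j]), "_atom_site.")) {
    fields <- c(fields, sub("^_atom_site\\.", "", trimws(lines[j])))
    j <- j + 1
  }
  rows <- character()
  while (j <= length(lines)) {
    ln <- trimws(lines[j])
    if (ln %in% c("#", "loop_") || startsWith(ln, "_") || startsWith(ln, "data_")) break
    if (nzchar(ln)) rows <- c(rows, ln)
    j <- j + 1
  }
  mat <- do.call(rbind, strsplit(rows, "[ \t]+"))
  if (ncol(mat) != length(fields))
    abort(sprintf("mmCIF _atom_site loop: %d fields declared, %d values per row",
                  length(fields), ncol(mat)))
  colnames(mat) <- fields
  get <- function(nms, default = NA_character_) {
    for (nm in nms) if (nm %in% fields) return(mat[, nm])
    rep(default, nrow(mat))
  }
  dot <- function(v, default) ifelse(v %in% c(".", "?", NA), default, v)
  elem <- dot(get("type_symbol"), "")
  name <- dot(get(c("auth_atom_id", "label_atom_id")), "")
  name <- gsub('"', "", name)
  miss <- !nzchar(elem)
  if (any(miss)) {
    warn(sprintf("%d atoms lack type_symbol; inferring from atom names", sum(miss)))
    elem[miss] <- infer_element(name[miss])
  }
  tibble(
    chain = dot(get(c("auth_asym_id", "label_asym_id")), ""),
    resi = as.integer(dot(get(c("auth_seq_id", "label_seq_id")), NA)),
    icode = dot(get("pdbx_PDB_ins_code"), ""),
    resn = dot(get(c("auth_comp_id", "label_comp_id")), ""),
    atom = name,
    altloc = dot(get("label_alt_id"), ""),
    element = normalize_element(elem),
    x = as.numeric(get("Cartn_x")), y = as.numeric(get("Cartn_y")),
    z = as.numeric(get("Cartn_z")),
    occ = as.numeric(dot(get("occupancy"), "1")),
    b = as.numeric(dot(get("B_iso_or_equiv"), "0")),
    het = get("group_PDB", "ATOM") == "HETATM")
}

normalize_element <- function(e) {
  e <- trimws(e)
  paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, 2)))
}

infer_element <- function(name) {
  nm <- gsub("[0-9']", "", name)
  two <- c("CL", "BR", "FE", "ZN", "MG", "NA", "MN", "SE")
  out <- substr(nm, 1, 1)
  hit <- toupper(substr(nm, 1, 2)) %in% two & nchar(name) >= 2
  out[hit] <- substr(nm[hit], 1, 2)
  out[!nzchar(out)] <- "C"
  out
}

resolve_altloc <- function(atoms) {
  if (!"altloc" %in% names(atoms)) return(atoms)
  if (all(atoms$altloc %in% c("", ".", "?"))) {
    atoms$altloc <- NULL
    return(atoms)
  }
  atoms$.ord <- seq_len(nrow(atoms))
  atoms <- atoms |>
    group_by(.data$chain, .data$resi, .data$icode, .data$resn, .data$atom) |>
    slice(which.max(.data$occ)) |>   # ties: which.max takes the first listed
    ungroup() |>
    arrange(.data$.ord)
  atoms$.ord <- NULL
  atoms$altloc <- NULL
  atoms
}

#' Write a structure as a PDB file
#'
#' @param structure A `chan_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  a <- as_tibble(structure)
  rec <- sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 ifelse(a$het, "HETATM", "ATOM"),
                 (seq_len(nrow(a)) - 1L) %% 99999L + 1L,
                 ifelse(nchar(a$atom) >= 4, a$atom, paste0(" ", a$atom)),
                 " ", a$resn, a$chain, a$resi, ifelse(nzchar(a$icode), a$icode, " "),
                 a$x, a$y, a$z, a$occ, a$b, toupper(a$element))
  writeLines(c(rec, "END"), path)
  invisible(path)
}

#' Split a structure into residues
#'
#' @param structure A `chan_structure` or atom tibble.
#' @return Tibble with one row per residue and a list-column `atoms`.
#' @export
residues <- function(structure) {
  as_tibble(structure) |>
    tidyr::nest(atoms = -c("chain", "resi", "icode", "resn", "het")) |>
    arrange(.data$chain, .data$resi, .data$icode)
}

#' Extract one residue's atoms
#'
#' @param structure A `chan_structure`.
#' @param chain Chain identifier.
#' @param resi Author residue number.
#' @return Atom tibble for that residue.
#' @export
get_residue <- function(structure, chain, resi) {
  out <- as_tibble(structure) |>
    filter(.data$chain == !!chain, .data$resi == !!resi)
  if (nrow(out) == 0)
    abort(sprintf("no residue %s/%s in structure", chain, resi))
  out
}

#' Ligand (hetero-residue) instances in a structure
#'
#' @param structure A `chan_structure`.
#' @param resn Optional residue-name filter (e.g. the ligand code).
#' @param exclude Residue names never treated as ligands (waters, ions).
#' @return Tibble of ligand instances with a list-column `atoms`
#'   (heavy atoms only).
#' @export
ligand_instances <- function(structure, resn = NULL,
                             exclude = c("HOH", "WAT", "K", "NA", "CL", "CA")) {
  lig <- as_tibble(structure) |>
    filter(.data$het, !.data$resn %in% exclude, .data$element != "H")
  if (!is.null(resn)) lig <- filter(lig, .data$resn == !!resn)
  if (nrow(lig) == 0) abort("no ligand instances found")
  tidyr::nest(lig, atoms = -c("chain", "resi", "icode", "resn"))
}
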