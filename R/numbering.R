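#' Residue-numbering correspondence between two numbering schemes
#'
#' Either a constant integer offset (e.g. +10 from *Xenopus* KCNQ1 to human
#' KCNQ1 numbering) or an explicit injective table of residue-number pairs.
#'
#' @param source,target Labels for the two schemes (e.g. "xKCNQ1", "hKCNQ1").
#' @param offset Constant integer offset applied to source numbers, or `NULL`.
#' @param pairs Two-column data frame (`source`, `target`) of residue numbers
#'   when the correspondence is not a constant offset.
#' @return A `numbering_map` object.
#' @export
numbering_map <- function(source, target, offset = NULL, pairs = NULL) {
  if (is.null(offset) && is.null(pairs))
    abort("numbering_map needs an offset or an explicit pair table")
  if (!is.null(pairs)) {
    pairs <- as_tibble(pairs)
    names(pairs)[1:2] <- c("source", "target")
    pairs$source <- as.integer(pairs$source)
    pairs$target <- as.integer(pairs$target)
    if (anyDuplicated(pairs$source) || anyDuplicated(pairs$target))
      abort("numbering_map pairs must be injective")
  }
  structure(list(source = source, target = target,
                 offset = if (!is.null(offset)) as.integer(offset),
                 pairs = pairs),
            class = "numbering_map")
}

#' @export
print.numbering_map <- function(x, ...) {
  kind <- if (!is.null(x$offset)) sprintf("offset %+d", x$offset)
          else sprintf("%d explicit pairs", nrow(x$pairs))
  cat(sprintf("<numbering_map %s -> %s: %s>\n", x$source, x$target, kind))
  invisible(x)
}

#' Map residue numbers across numbering schemes
#'
#' Residues without a correspondence map to `NA` (an explicit "no
#' correspondence", never a silent pass-through).
#'
#' @param map A [numbering_map()].
#' @param resi Integer vector of source residue numbers.
#' @return Integer vector of target residue numbers (`NA` where unmapped).
#' @export
map_residue <- function(map, resi) {
  stopifnot(inherits(map, "numbering_map"))
  resi <- as.integer(resi)
  if (!is.null(map$offset)) return(resi + map$offset)
  map$pairs$target[match(resi, map$pairs$source)]
}

#' Invert a numbering map
#'
#' @param map A [numbering_map()].
#' @return The inverse `numbering_map`.
#' @export
invert_map <- function(map) {
  if (!is.null(map$offset))
    numbering_map(map$target, map$source, offset = -map$offset)
  else
    numbering_map(map$target, map$source,
                  pairs = map$pairs[, c("target", "source")])
}

#' Identity numbering map
#' @param label Scheme label.
#' @return A `numbering_map` with offset 0.
#' @export
identity_map <- function(label = "self") numbering_map(label, label, offset = 0L)

#' Built-in map: Xenopus KCNQ1 to human KCNQ1 numbering (+10)
#' @return A `numbering_map`.
#' @export
xkcnq1_to_hkcnq1 <- function() numbering_map("xKCNQ1", "hKCNQ1", offset = 10L)

#' Curated pocket-residue identity table across KCNQ isoforms
#'
#' Residue identities of the activator pocket in *Xenopus* KCNQ1 numbering
#' with the corresponding human KCNQ1 position (+10) and, where documented
#' in the literature, the residue found in other KCNQ isoforms.  Unknown
#' correspondences are `NA` and are reported as em-dashes, never dropped.
#'
#' @return Tibble with columns `xKCNQ1_resi`, `xKCNQ1_resn`, `hKCNQ1`,
#'   `hKCNQ2`, `hKCNQ3`, `hKCNQ4`, `hKCNQ5` (single-letter codes, position
#'   appended where known, e.g. `"W236"`).
#' @export
kcnq_isoform_table <- function() {
  path <- system.file("extdata", "kcnq_isoform_pocket.tsv", package = "chanalyze")
  tb <- utils::read.delim(path, sep = "\t", na.strings = "-",
                          check.names = FALSE)
  as_tibble(tb)
}
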