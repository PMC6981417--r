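# Glycan head-group structures for the supported ganglioside species.
#
# Each species is a rooted tree growing from the ceramide through the
# Glc-Gal lactosyl core. The oligo-Neu5Ac chain sits on the inner Gal;
# GalNAc/Gal (and for LacNAcGM1 a further GlcNAc-Gal unit) extend the core.
# Node ids: parent 0 is the ceramide.

.species_nodes <- function(name) {
  core <- tibble::tibble(
    node = 1:2, residue = c("Hex", "Hex"),
    parent = c(0L, 1L), label = c("Glc", "Gal")
  )
  sia <- function(n) tibble::tibble(
    node = 2L + seq_len(n), residue = "Neu5Ac",
    parent = c(2L, 2L + seq_len(n - 1))[seq_len(n)],
    label = paste0("Neu5Ac", seq_len(n))
  )
  galnac  <- function(id) tibble::tibble(node = id, residue = "HexNAc",
                                         parent = 2L, label = "GalNAc")
  gal2    <- function(id) tibble::tibble(node = id, residue = "Hex",
                                         parent = id - 1L, label = "GalII")
  lacnac <- function(id) tibble::tibble(
    node = c(id, id + 1L), residue = c("HexNAc", "Hex"),
    parent = c(id - 1L, id), label = c("GlcNAc", "GalIII")
  )
  switch(name,
    GM3       = dplyr::bind_rows(core, sia(1)),
    GM2       = dplyr::bind_rows(core, sia(1), galnac(4L)),
    GM1       = dplyr::bind_rows(core, sia(1), galnac(4L), gal2(5L)),
    LacNAcGM1 = dplyr::bind_rows(core, sia(1), galnac(4L), gal2(5L), lacnac(6L)),
    GD3       = dplyr::bind_rows(core, sia(2)),
    GD2       = dplyr::bind_rows(core, sia(2), galnac(5L)),
    GD1b      = dplyr::bind_rows(core, sia(2), galnac(5L), gal2(6L)),
    GT3       = dplyr::bind_rows(core, sia(3)),
    GT2       = dplyr::bind_rows(core, sia(3), galnac(6L)),
    stop("unreachable")
  )
}

.SUPPORTED_SPECIES <- c("GM3", "GM2", "GM1", "LacNAcGM1", "GD3",
                        "GD2", "GD1b", "GT3", "GT2")

.SPECIES_SERIES <- c(
  GM3 = "a", GM2 = "a", GM1 = "a", LacNAcGM1 = "a",
  GD3 = "b", GD2 = "b", GD1b = "b", GT3 = "c", GT2 = "c"
)

#' Supported ganglioside species names
#'
#' @return Character vector of Svennerholm symbols the package models.
#' @export
supported_species <- function() .SUPPORTED_SPECIES

#' Composition and topology of a named ganglioside
#'
#' Resolves a Svennerholm symbol (optionally with an `OAc` prefix) to its
#' residue composition and rooted glycan topology. The sialic-acid chain on
#' the inner galactose is labelled inner-to-terminal (`Neu5Ac1` innermost).
#'
#' @param name Species symbol, e.g. `"GD2"` or `"OAcGD3"`.
#' @return A list of class `ganglioside_species`: `name`, `base_name` (symbol
#'   without the OAc prefix), `o_acetylated` flag, `series` (0/a/b/c),
#'   `composition` (named counts of Hex/HexNAc/Neu5Ac), `topology` (node
#'   tibble: node, residue, parent, label) and `neu5ac_positions` (labels,
#'   inner to terminal).
#' @examples
#' composition_of("GD2")$composition
#' composition_of("OAcGD3")$neu5ac_positions
#' @export
composition_of <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  oac <- grepl("^OAc", name)
  base_name <- sub("^OAc", "", name)
  if (!base_name %in% .SUPPORTED_SPECIES) {
    stop("Unsupported species '", name, "'. Supported: ",
         paste(.SUPPORTED_SPECIES, collapse = ", "),
         " (each optionally OAc-prefixed).", call. = FALSE)
  }
  nodes <- .species_nodes(base_name)
  comp <- c(
    Hex = sum(nodes$residue == "Hex"),
    HexNAc = sum(nodes$residue == "HexNAc"),
    Neu5Ac = sum(nodes$residue == "Neu5Ac")
  )
  if (oac && comp[["Neu5Ac"]] == 0) {
    stop("'", name, "' has no sialic acid to O-acetylate.", call. = FALSE)
  }
  structure(
    list(
      name = name, base_name = base_name, o_acetylated = oac,
      series = unname(.SPECIES_SERIES[base_name]),
      composition = comp, topology = nodes,
      neu5ac_positions = nodes$label[nodes$residue == "Neu5Ac"]
    ),
    class = "ganglioside_species"
  )
}

#' @export
print.ganglioside_species <- function(x, ...) {
  cat("<ganglioside ", x$name, "> series ", x$series, "; ",
      paste0(names(x$composition), x$composition, collapse = " "),
      "; Neu5Ac chain: ",
      paste(x$neu5ac_positions, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

# Maximum sialo-lactone count: one fewer than the oligosialyl chain length,
# capped at 2 (mono-sialylated species cannot lactonize).
.max_dehydrations <- function(species) {
  min(2L, max(0L, length(species$neu5ac_positions) - 1L))
}

.glycan_mass <- function(species) {
  sum(species$composition * unlist(.MASS[names(species$composition)]))
}
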