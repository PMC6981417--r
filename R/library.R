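# Theoretical [M-H]- ion library: every (species, ceramide, adduct state)
# combination used for MS1 annotation.

#' m/z of a deprotonated ganglioside ion
#'
#' Computes the monoisotopic m/z of the singly deprotonated ion
#' `[M - n_dehydrations*H2O - H]-`, with an optional O-acetyl increment.
#' Lactonization (intramolecular esterification between adjacent sialic
#' acids) removes one water per lactone, so oligosialylated species are
#' typically observed at `[M-H2O-H]-` or `[M-2H2O-H]-`.
#'
#' @param species A `ganglioside_species` (or symbol passed to
#'   [composition_of()]).
#' @param cer A `ceramide_spec` (or acyl shorthand passed to
#'   [ceramide_spec()]).
#' @param n_dehydrations Lactone count, 0-2, at most one fewer than the
#'   species' sialic-acid chain length.
#' @param n_acetyl 0 or 1 O-acetyl groups. An `OAc`-prefixed species name
#'   implies `n_acetyl = 1`.
#' @param acetyl_position Optional Neu5Ac label carrying the acetyl (metadata
#'   only; the acetylated carbon and residue are not mass-resolvable at MS1).
#' @return m/z in Th, full precision.
#' @examples
#' ion_mz("GM3", "16:0")                       # 1151.706
#' ion_mz("GD3", "16:0", n_dehydrations = 1)   # 1424.791
#' ion_mz("OAcGD3", "16:0", n_dehydrations = 1)
#' @export
ion_mz <- function(species, cer, n_dehydrations = 0L, n_acetyl = NULL,
                   acetyl_position = NULL) {
  if (is.character(species)) species <- composition_of(species)
  if (is.character(cer)) cer <- ceramide_spec(cer)
  stopifnot(inherits(species, "ganglioside_species"),
            inherits(cer, "ceramide_spec"))
  if (is.null(n_acetyl)) n_acetyl <- as.integer(species$o_acetylated)
  n_acetyl <- as.integer(n_acetyl)
  n_dehydrations <- as.integer(n_dehydrations)
  if (n_acetyl < 0 || n_acetyl > 1) {
    stop("n_acetyl must be 0 or 1.", call. = FALSE)
  }
  max_deh <- .max_dehydrations(species)
  if (n_dehydrations < 0 || n_dehydrations > max_deh) {
    stop(species$name, " admits at most ", max_deh,
         " lactone dehydration(s); got ", n_dehydrations, ".", call. = FALSE)
  }
  if (!is.null(acetyl_position) &&
      !acetyl_position %in% species$neu5ac_positions) {
    stop("acetyl_position '", acetyl_position, "' is not a Neu5Ac of ",
         species$name, ".", call. = FALSE)
  }
  ceramide_mass(cer) + .glycan_mass(species) +
    n_acetyl * .MASS$acetyl -
    n_dehydrations * .MASS$water -
    .MASS$proton
}

.adduct_label <- function(n_dehydrations) {
  if (n_dehydrations == 0) "[M-H]-"
  else if (n_dehydrations == 1) "[M-H2O-H]-"
  else paste0("[M-", n_dehydrations, "H2O-H]-")
}

#' Default ion-library configuration
#'
#' The default enumeration grid: the nine supported species, d18:1 sphingosine
#' with the fatty acids reported for these cell lines (C16 and C24 dominant;
#' C14, C18, C22 minor; C24 both saturated and 24:1), up to one O-acetyl per
#' species and lactone counts up to the per-species cap.
#'
#' @param path Optional path to a YAML config overriding the defaults
#'   (keys: `species`, `bases`, `acyls`, `max_dehydrations`, `max_acetyl`).
#'   The built-in defaults are also shipped as
#'   `system.file("extdata", "default_library.yaml", package = "gangliotools")`.
#' @return A list with those five fields.
#' @export
library_config <- function(path = NULL) {
  cfg <- list(
    species = .SUPPORTED_SPECIES,
    bases = "d18:1",
    acyls = .SUPPORTED_ACYLS,
    max_dehydrations = 2L,
    max_acetyl = 1L
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) {
      stop("Unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    cfg[names(user)] <- user
  }
  cfg$max_dehydrations <- as.integer(cfg$max_dehydrations)
  cfg$max_acetyl <- as.integer(cfg$max_acetyl)
  cfg
}

#' Enumerate the theoretical ion library
#'
#' Builds all valid (species, ceramide, adduct-state) ions for a configuration
#' grid, deduplicated and sorted ascending by m/z. O-acetyl positional isomers
#' are mass-identical and collapse to one MS1 entry (position is resolved
#' later by MS/MS).
#'
#' @param config A configuration list from [library_config()].
#' @return A tibble with one row per ion: `species` (OAc-prefixed when
#'   acetylated), `base_species`, `base`, `acyl`, `n_dehydrations`,
#'   `n_acetyl`, `adduct`, `mz`, `n_residues`, `label`.
#' @examples
#' lib <- enumerate_library()
#' nrow(lib)
#' @export
enumerate_library <- function(config = library_config()) {
  if (length(config$species) == 0) {
    stop("Library config lists no species.", call. = FALSE)
  }
  rows <- purrr::map_dfr(config$species, function(nm) {
    sp <- composition_of(nm)
    max_deh <- min(config$max_dehydrations, .max_dehydrations(sp))
    grid <- tidyr::expand_grid(
      base = config$bases,
      acyl = config$acyls,
      n_dehydrations = 0:max_deh,
      n_acetyl = 0:config$max_acetyl
    )
    if (length(sp$neu5ac_positions) == 0) {
      grid <- dplyr::filter(grid, .data$n_acetyl == 0L)
    }
    purrr::pmap_dfr(grid, function(base, acyl, n_dehydrations, n_acetyl) {
      cer <- ceramide_spec(acyl, base = base)
      tibble::tibble(
        species = if (n_acetyl > 0) paste0("OAc", sp$base_name) else sp$base_name,
        base_species = sp$base_name,
        base = base, acyl = acyl,
        n_dehydrations = as.integer(n_dehydrations),
        n_acetyl = as.integer(n_acetyl),
        adduct = .adduct_label(n_dehydrations),
        mz = ion_mz(sp, cer, n_dehydrations, n_acetyl),
        n_residues = sum(sp$composition) + n_acetyl
      )
    })
  })
  rows <- dplyr::distinct(rows)
  rows <- dplyr::arrange(rows, .data$mz, .data$species, .data$acyl)
  dplyr::mutate(
    rows,
    label = paste0(.data$species, " ", .data$base, "/", .data$acyl,
                   " ", .data$adduct)
  )
}
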