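# Monoisotopic mass bookkeeping for the glycan head-group and the ceramide
# anchor. All masses in Da. Residue masses are free monosaccharide minus water.

.MASS <- list(
  Hex      = 162.05282,
  HexNAc   = 203.07937,
  Neu5Ac   = 291.09542,
  water    = 18.01056,
  acetyl   = 42.01057,   # O-acetyl increment, C2H2O
  proton   = 1.00728,    # deprotonation convention for [M-H]-
  ch2      = 14.01565,   # per acyl carbon beyond the anchor
  h2       = 2.01565,    # per double bond
  hydroxyl = 15.99491,   # per extra hydroxyl on the ceramide
  cer_d181_160 = 537.51210  # intact ceramide d18:1/16:0 (C34H67NO3)
)

#' Monoisotopic residue masses and mass constants
#'
#' Returns the residue-mass table used throughout the package: monoisotopic
#' masses of the glycan residues (free monosaccharide minus one water) and the
#' increments for water loss (sialo-lactonization), O-acetylation and
#' deprotonation.
#'
#' @return A tibble with columns `name`, `mass_da` and `role`
#'   (`"residue"` or `"constant"`).
#' @examples
#' monomer_table()
#' @export
monomer_table <- function() {
  tibble::tibble(
    name = c("Hex", "HexNAc", "Neu5Ac", "water", "acetyl", "proton"),
    mass_da = unlist(.MASS[c("Hex", "HexNAc", "Neu5Ac", "water", "acetyl", "proton")],
                     use.names = FALSE),
    role = c(rep("residue", 3), rep("constant", 3))
  )
}

.SUPPORTED_ACYLS <- c("14:0", "16:0", "18:0", "22:0", "24:0", "24:1")

#' Specify a ceramide
#'
#' Builds a ceramide specification from the sphingoid base and the amide-linked
#' fatty acid, using lipidomics shorthand (e.g. base `"d18:1"`, acyl `"24:1"`).
#'
#' @param acyl Fatty-acid shorthand `"<carbons>:<double bonds>"`. Supported by
#'   default: 14:0, 16:0, 18:0, 22:0, 24:0, 24:1.
#' @param base Sphingoid base code; only `"d18:1"` (sphingosine) is supported.
#' @param hydroxylation Count of extra hydroxyl groups on the ceramide
#'   (0 by default; each adds 15.99491 Da).
#' @return A list of class `ceramide_spec` with fields `base`, `acyl_carbons`,
#'   `acyl_unsaturation`, `hydroxylation` and `label`.
#' @examples
#' ceramide_spec("16:0")
#' ceramide_mass(ceramide_spec("24:1"))
#' @export
ceramide_spec <- function(acyl = "16:0", base = "d18:1", hydroxylation = 0L) {
  if (!identical(base, "d18:1")) {
    stop("Unsupported sphingoid base '", base, "'; only d18:1 is supported.",
         call. = FALSE)
  }
  parts <- strsplit(acyl, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2 || anyNA(suppressWarnings(as.integer(parts)))) {
    stop("Malformed acyl shorthand '", acyl, "'; expected e.g. \"16:0\".",
         call. = FALSE)
  }
  carbons <- as.integer(parts[1])
  unsat <- as.integer(parts[2])
  if (!acyl %in% .SUPPORTED_ACYLS) {
    stop("Unsupported fatty acid '", acyl, "'. Supported: ",
         paste(.SUPPORTED_ACYLS, collapse = ", "), ".", call. = FALSE)
  }
  if (hydroxylation < 0) stop("hydroxylation must be >= 0", call. = FALSE)
  structure(
    list(base = base, acyl_carbons = carbons, acyl_unsaturation = unsat,
         hydroxylation = as.integer(hydroxylation),
         label = paste0(base, "/", acyl)),
    class = "ceramide_spec"
  )
}

#' @export
print.ceramide_spec <- function(x, ...) {
  cat("<ceramide ", x$label,
      if (x$hydroxylation > 0) paste0(" +", x$hydroxylation, "OH"),
      ">  ", format(ceramide_mass(x), nsmall = 5), " Da\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of an intact ceramide
#'
#' Mass of the amide of the sphingoid base and the fatty acid (one water lost
#' in condensation), anchored at d18:1/16:0 = 537.51210 Da; each additional
#' two acyl carbons add 28.03130 Da, each double bond subtracts 2.01565 Da,
#' each extra hydroxyl adds 15.99491 Da.
#'
#' @param cer A `ceramide_spec`.
#' @return Monoisotopic mass in Da.
#' @examples
#' ceramide_mass(ceramide_spec("16:0"))  # 537.5121
#' @export
ceramide_mass <- function(cer) {
  stopifnot(inherits(cer, "ceramide_spec"))
  .MASS$cer_d181_160 +
    (cer$acyl_carbons - 16L) * .MASS$ch2 -
    cer$acyl_unsaturation * .MASS$h2 +
    cer$hydroxylation * .MASS$hydroxyl
}

# Round half away from zero, matching how one-decimal m/z values are reported.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
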