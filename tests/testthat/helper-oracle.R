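# Independent brute-force oracle: assemble the full atomic composition
# (C/H/N/O counts) of an ion from monomer formulas and sum monoisotopic
# atomic masses. Used to cross-check the residue-mass arithmetic; shares no
# code with the package implementation.

.ATOM <- c(C = 12, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196)

.FORMULAS <- list(
  Hex    = c(C = 6, H = 10, N = 0, O = 5),
  HexNAc = c(C = 8, H = 13, N = 1, O = 5),
  Neu5Ac = c(C = 11, H = 17, N = 1, O = 8),
  water  = c(C = 0, H = 2, N = 0, O = 1),
  acetyl = c(C = 2, H = 2, N = 0, O = 1)
)

# Intact ceramide: sphingosine (C18H37NO2) + fatty acid CnH(2n-2u)O2, minus
# one water in amide condensation.
oracle_ceramide_formula <- function(acyl_carbons, acyl_unsat, hydroxylation = 0) {
  c(C = 18 + acyl_carbons,
    H = 37 + 2 * acyl_carbons - 2 * acyl_unsat - 2,
    N = 1,
    O = 2 + 2 - 1 + hydroxylation)
}

oracle_formula_mass <- function(formula) sum(formula * .ATOM[names(formula)])

# Composition counts (Hex/HexNAc/Neu5Ac) straight from the Svennerholm name,
# independent of the package's topology tables.
oracle_composition <- function(name) {
  base <- sub("^OAc", "", name)
  comp <- switch(base,
    GM3 = c(2, 0, 1), GM2 = c(2, 1, 1), GM1 = c(3, 1, 1),
    LacNAcGM1 = c(4, 2, 1),
    GD3 = c(2, 0, 2), GD2 = c(2, 1, 2), GD1b = c(3, 1, 2),
    GT3 = c(2, 0, 3), GT2 = c(2, 1, 3),
    stop("oracle has no composition for ", name)
  )
  setNames(comp, c("Hex", "HexNAc", "Neu5Ac"))
}

# m/z of the singly deprotonated ion by full atomic sum. Uses the same
# deprotonation constant as the contract (1.00728 Da).
oracle_ion_mz <- function(name, acyl, n_dehydrations = 0, n_acetyl = NA) {
  if (is.na(n_acetyl)) n_acetyl <- as.integer(grepl("^OAc", name))
  parts <- as.integer(strsplit(acyl, ":")[[1]])
  comp <- oracle_composition(name)
  formula <- oracle_ceramide_formula(parts[1], parts[2])
  for (res in names(comp)) {
    formula <- formula + comp[[res]] * .FORMULAS[[res]]
  }
  formula <- formula + n_acetyl * .FORMULAS$acetyl -
    n_dehydrations * .FORMULAS$water
  oracle_formula_mass(formula) - 1.00728
}

# B-type fragment: sum of residue formulas minus a proton (the glycosidic
# oxygen stays with the reducing side).
oracle_b_mz <- function(residues, n_acetyl = 0) {
  formula <- c(C = 0, H = 0, N = 0, O = 0)
  for (res in residues) formula <- formula + .FORMULAS[[res]]
  formula <- formula + n_acetyl * .FORMULAS$acetyl
  oracle_formula_mass(formula) - 1.00728
}
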