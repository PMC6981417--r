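---
title: "Compositional profiling of O-acetylated gangliosides: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional profiling of O-acetylated gangliosides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gangliotools)
```

## The problem

Negative-mode MALDI-QIT-TOF spectra of acidic glycosphingolipid extracts show
gangliosides as singly deprotonated ions. Three features make their
interpretation non-trivial:

1. **Ceramide heterogeneity.** The same glycan head-group appears on several
   ceramides (sphingosine d18:1 with C14–C24 fatty acids), spreading one
   species over many peaks.
2. **Sialo-lactonization.** Adjacent sialic acids form intramolecular esters
   during ionization/work-up, so di- and trisialylated species are observed
   mostly as `[M-H2O-H]-` and `[M-2H2O-H]-` rather than `[M-H]-`.
3. **O-acetylation.** A +42.01057 Da ester on a sialic-acid hydroxyl marks
   biologically distinct species (e.g. OAcGD2 vs GD2) but is mass-silent about
   *which* sialic acid carries it, and it creates isobars with unrelated
   compositions.

The package turns these rules into an explicit calculus, annotates observed
peak lists against it, and uses MS/MS fragmentation to resolve what MS1 mass
alone cannot.

## The mass model

All masses are monoisotopic. Residue masses (free monosaccharide minus water)
are Hex 162.05282, HexNAc 203.07937, Neu5Ac 291.09542 Da. The ceramide is
anchored at d18:1/16:0 = 537.51210 Da (C34H67NO3), with exact increments of
+28.03130 per two acyl carbons, −2.01565 per double bond and +15.99491 per
extra hydroxyl (the optional `hydroxylation` field accommodates cell lines
with highly hydroxylated ceramides; default 0). An ion's m/z is

$$ m/z = m_\mathrm{Cer} + \sum_r n_r m_r + a\,(42.01057) - d\,(18.01056) - 1.00728 $$

with $a \in \{0,1\}$ acetyl groups and $d$ lactone dehydrations. Two
conventions are fixed deliberately:

* **Deprotonation subtracts the proton mass 1.00728 Da** (not the hydrogen
  atom mass). At one-decimal reporting precision the two conventions are
  indistinguishable; the contract fixes one so that fragment complementarity
  identities hold exactly.
* **Lactone cap**: $d \le \min(2,\, s-1)$ for $s$ sialic acids.
  Monosialylated species cannot lactonize; disialylated species admit one
  lactone, trisialylated species two. This matches the adduct states under
  which the di-/trisialylated species are reported.

Every library ion is cross-checked in the test suite against an independent
brute-force oracle that assembles the full C/H/N/O atomic composition from
monomer formulas and sums atomic masses; agreement is required to 1e-4 Da.

The supported species are GM3, GM2, GM1, LacNAcGM1 (a-series), GD3, GD2, GD1b
(b-series) and GT3, GT2 (c-series), each optionally mono-O-acetylated. Their
topologies are rooted trees through the Glc–Gal core with the oligosialyl
chain on the inner galactose, labelled `Neu5Ac1` (inner) outwards. The
acetylated *carbon* (7 vs 9) is not mass-resolvable and is never modelled;
the acetylated *residue* is carried as metadata and resolved by MS/MS.

O-acetyl positional isomers are mass-identical, so the MS1 library collapses
them to one entry per (species, ceramide, lactone, acetyl-count) state; the
default grid (9 species × 6 ceramides × adduct states) yields 192 ions.

## Annotation

`match_peaks()` is a total function: every peak receives exactly one row with
status `unique`, `isobaric` or `unassigned`; nothing is dropped, and isobaric
peaks report *all* candidates rather than auto-selecting one — resolution is
delegated to MS/MS, mirroring how mixed signals are handled in practice.
Candidate order is deterministic: |Δm/z|, then residue count, then name.

* **MS1 tolerance ±0.3 Da** (default). One-decimal peak lists from a
  QIT-TOF in mid mode justify a few-tenths window; the value is configurable
  and the candidate count is monotone in it.
* **Isolation-window matching at ±1.0 Da** is appropriate when the precursor
  is quoted at integer precision, as for the classic mixed signal at m/z
  1670: lactonized OAcGD2 (d18:1/16:0) computes to 1669.88 and OAcGM1
  (d18:1/24:0) to 1670.97, so only a window of about ±1 Da captures both
  reported structures. The default grid also offers a third, non-acetylated
  reading of that mass (GT3 d18:1/14:0 with two lactones, 1669.84) that a
  C24-dominant GT3 ceramide distribution makes biologically implausible but
  that honest mass arithmetic must report; MS/MS fragment evidence is what
  separates these, via `split_isobaric_intensity()`.
* **Presence tables** assign each peak to its best candidate (ties keep all)
  and call a species `trace` when its strongest supporting peak is below
  `trace_threshold` (default 1%) of the base peak. Low peaks are flagged,
  never discarded.

## MS/MS: fragments, localization, isobar splitting

`predict_fragments()` enumerates all single glycosidic cleavages as singly
deprotonated B/C/Y/Z ions (B/C keep the non-reducing end; Y/Z keep the
ceramide; C = B + 18.01056, Y = Z + 18.01056). Design choices:

* Charge fixed at 1−; no internal (double-cleavage) or cross-ring A/X ions —
  glycosidic ions carry the positional information used here.
* Lactones are opened before prediction: fragment masses come from the
  non-dehydrated form, with optional `-H2O` satellites on sialylated
  fragments (`include_water_loss = TRUE`), since dehydration behaves as a
  satellite feature of sialylated fragments rather than a fixed modification.
* Exactly one fragment of each complementary pair inherits the acetyl
  increment (the one containing the acetylated residue); the suite checks
  this conservation and the complementarity identity
  `mz(B) + mz(Y) = mz(precursor) − 1.00728` for every edge.

**Localization** scores each possible acetyl position by the summed observed
intensity of its *diagnostic* fragments — those whose predicted m/z differs
between positional isomers by at least twice the MS2 tolerance (default
±0.5 Da). For a disialylated species the only diagnostic cleavage is the one
between the two sialic acids (four fragments, shifted by exactly 42.01057
between the inner and terminal hypotheses). The call is the argmax position;
it is `ambiguous` when the best/second score ratio is below 2.0 or when no
diagnostic fragment is matched, with an explanatory status either way.

**Isobar splitting** apportions a shared precursor's intensity
proportionally to the summed intensity of candidate-unique fragments
(predicted m/z not shared with any other candidate within tolerance). Shares
sum to 1 and are equivariant in candidate order; with no unique evidence the
split falls back to equal shares with an explicit `equal split` flag. Note
the estimator weights a candidate by (amount × number of its unique
fragments matched), so for candidates with different unique-fragment counts
it is mildly biased toward the fragment-richer structure; at realistic
fragment coverage this stays within a few percent for binary mixtures.

## Quantification

The statistic is the **peak apex intensity**, summed per species over all its
ceramide variants and adduct states, then normalized to 100 per sample. The
O-acetylated fraction is the summed percentage of `OAc`-prefixed species and
is invariant to how intensity distributes across a species' ceramide
variants. Isobaric peaks use MS/MS shares when available; otherwise the
fallback is either `"equal"` (default, flagged in the output — appropriate
when nothing is known) or `"best"` (nearest-mass candidate — appropriate for
well-calibrated spectra, and the choice used in the simulation studies where
m/z jitter is zero and the nearest candidate is correct by construction).
Species below 0.1% of the total are flagged as trace but remain in the
total, mirroring the practice of reporting weak species without letting them
vanish; species seen only in MS/MS with signals too weak for quantification
are simply absent from the intensity table rather than imputed.

## Pathway mapping

`ganglio_pathway()` hard-codes the ganglio-series biosynthesis topology:
GlcCer → LacCer (B4GALT6), the sialylation backbone LacCer → GM3 → GD3 → GT3
(ST3GAL5, ST8SIA1, ST8SIA5), and four parallel elongation lanes (0/a/b/c)
each via B4GALNT1 → B3GALT4 → ST3GAL2 → ST8SIA5. O-acetylated species hang
off their parent ganglioside as leaf nodes via CASD1 (the only known human
sialate O-acetyltransferase); SLC33A1 (the Golgi acetyl-CoA transporter) is
a gene node without edges, present so its expression can be mapped. The
GD3 → GT3 step is labelled ST8SIA5, which has reported GT3-synthase
activity and is the only ST8-family gene in the modelled set besides the
GD3 synthase ST8SIA1; the assignment is a display choice, not a claim about
enzymology, and the topology is fully replaceable by any igraph with the
same attributes.

qPCR expression ratios use the comparative-Ct method with replicate wells
averaged per (condition, gene); the reference gene is a **required argument**
with no default, since a silently assumed housekeeping gene is a classic
error source. Differential colors interpolate linearly in RGB from white at
0 to pure endpoints at the clamp bounds — blue/red at ±2 for gene log2
ratios, green/fuchsia at ±8 percentage points for metabolite deltas, grey
for no data. The named endpoint colors are realized as pure RGB
red/blue/green/magenta; no hex values are prescribed by the convention being
followed, so the saturated primaries are used.

## The simulators

The generators define the study conditions under which the pipeline is
validated:

* **Profiles.** Three presets span the observed qualitative patterns:
  `parental` (a-series only: GM3/GM2/GM1 at 40/30/30), `bseries_oac`
  (b-series with OAcGD3 terminal-acetylated and OAcGD2 inner-acetylated,
  30% O-acetylated total) and `gd3s_plus` (a GD3-synthase-overexpressing
  pattern with GT3/GT2 and four O-acetylated species, 30% O-acetylated).
  Abundances sum to 100 by contract. The ceramide mixture defaults to
  C16:0 0.45, C24:0 0.28, C24:1 0.12, C18:0 0.08, C22:0 0.05, C14:0 0.02 —
  C16/C24 dominant with minor C14/C18/C22, C24 in both saturated and
  monounsaturated form. Adduct-state weights put 80% of di-/trisialylated
  signal in the maximally lactonized state, matching the reported
  predominance of dehydrated adducts.
* **MS1 spectra.** One peak per (species, ceramide, adduct) with intensity
  ∝ abundance × mixture weight × adduct weight under multiplicative
  log-normal noise (MALDI shot-to-shot variation; `intensity_cv` on mean-1
  scale), Gaussian m/z jitter, and uniform contaminant peaks over the
  1000–3000 scan range. Ground truth is attached to every spectrum.
* **MS/MS spectra.** A hypergeometric subset (`coverage` fraction) of the
  predicted fragments with log-normal intensity noise.
* **qPCR tables.** Triplicate wells per (condition, gene) constructed so the
  comparative-Ct analysis recovers the true log2 ratios exactly at zero
  noise, with Gaussian per-well Ct noise otherwise.

What the simulators do **not** emulate: profile-mode (continuous) peak
shapes, isotope envelopes, detector saturation, baseline drift, mass-axis
miscalibration (jitter is unbiased), and the merging of near-isobaric peaks
into a single centroid. Passing the round-trip tests therefore demonstrates
the correctness of the calculus and the estimators under the stated noise
model, not robustness to raw-spectrum artefacts — peak picking is explicitly
out of scope, and peak lists are assumed centroided.

All generators are deterministic under a fixed seed, and every zero-noise
limit is an exact inverse of the corresponding analysis stage; the test
suite leans on this for its round-trip checks.

## Validation problem sizes

The simulation studies in the test suite use sizes chosen to make sampling
error negligible relative to the tolerances being checked: 100 seeded
replicates for annotation recall under m/z jitter of 0.1 Da (a third of the
matching tolerance), 50 replicates for abundance recovery under 5% intensity
noise, 200 replicates per coverage level for the localization-accuracy
curve, and 200 replicates for qPCR unbiasedness at 0.2 Ct noise.

## Numerical and formatting choices

* Report rounding is half-up to one decimal, matching how the reference m/z
  values are printed; internal computation always carries full precision and
  rounding is the caller's concern.
* Candidate ordering ties (identical |Δm/z|) break by ascending residue
  count, then lexicographic species name — output is reproducible across
  platforms.
* Library enumeration is deterministic and sorted by m/z; identical configs
  yield byte-identical libraries.
* Degenerate inputs fail loudly: empty peak lists, zero total intensity,
  lactone counts above the cap, unknown species symbols, missing reference
  Ct values and out-of-range thresholds all raise descriptive errors rather
  than propagating NAs.

## Known limitations

* Average (non-monoisotopic) masses, positive-mode adducts and multiply
  charged ions are unsupported; the species set is extensible through the
  library config but only the nine named species are tested.
* Peak lists are read from CSV/TSV only; conversion from vendor or mzML
  formats is left to upstream tooling.
* The measured percentages of any particular cell line cannot be reproduced
  without its raw spectra; validation is therefore property-based
  (round-trips and recovery under the stated noise model).
* Localization assumes one acetyl group; di-O-acetylated species would need
  a larger hypothesis space.
* The isobar-splitting estimator is exactly proportional only when competing
  candidates match similar numbers of unique fragments (see above).
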