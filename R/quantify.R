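# Relative quantification of ganglioside species from annotated apex
# intensities, normalized to 100 per sample, with the O-acetylated fraction.

#' Sum apex intensity per species
#'
#' Aggregates an annotated spectrum into per-species apex intensity: each
#' species receives the summed intensity of its supporting peaks over all
#' ceramide variants and adduct (lactone/acetyl) states. Unassigned peaks are
#' excluded. Isobaric peaks use MS/MS-derived shares when supplied; otherwise
#' the fallback policy applies: `"equal"` splits the peak evenly across
#' candidates (flagged), `"best"` assigns it to the smallest-|delta m/z|
#' candidate.
#'
#' @param annotation A `ganglio_annotation` from [match_peaks()].
#' @param shares Optional tibble (`peak_mz`, `species`, `share`) from
#'   [split_isobaric_intensity()] runs, keyed by precursor peak m/z.
#' @param fallback Isobar policy when no share is available: `"equal"`
#'   (default) or `"best"`.
#' @return A tibble: `species`, `intensity`, `n_peaks`, `shared` (TRUE when
#'   any contribution came from an equal split).
#' @export
aggregate_species <- function(annotation, shares = NULL,
                              fallback = c("equal", "best")) {
  fallback <- match.arg(fallback)
  assigned <- dplyr::filter(annotation, .data$status != "unassigned")
  if (nrow(assigned) == 0) {
    stop("All peaks unassigned; nothing to quantify.", call. = FALSE)
  }
  contrib <- purrr::map_dfr(seq_len(nrow(assigned)), function(i) {
    cand <- assigned$candidates[[i]]
    pk <- assigned$peak_mz[i]
    int <- assigned$intensity[i]
    sp <- unique(cand$species)
    if (length(sp) == 1) {
      return(tibble::tibble(species = sp, intensity = int, shared = FALSE))
    }
    if (!is.null(shares)) {
      sh <- dplyr::filter(shares, abs(.data$peak_mz - pk) < 1e-9)
      if (nrow(sh) > 0) {
        return(tibble::tibble(species = sh$species,
                              intensity = int * sh$share, shared = FALSE))
      }
    }
    if (fallback == "best") {
      best <- cand$species[abs(cand$delta_mz) <= min(abs(cand$delta_mz)) + 1e-12]
      best <- unique(best)
      return(tibble::tibble(species = best, intensity = int / length(best),
                            shared = length(best) > 1))
    }
    tibble::tibble(species = sp, intensity = int / length(sp), shared = TRUE)
  })
  dplyr::summarise(
    dplyr::group_by(contrib, .data$species),
    intensity = sum(.data$intensity),
    n_peaks = dplyr::n(),
    shared = any(.data$shared),
    .groups = "drop"
  )
}

#' Relative abundance table
#'
#' Normalizes per-species intensities to percentages of total ganglioside
#' content (summing to 100) and computes the O-acetylated fraction: the
#' summed percentage of species carrying the `OAc` prefix. Species below
#' `trace_floor` percent are flagged as trace but stay in the total.
#'
#' @param intensities Tibble with `species` and `intensity` (from
#'   [aggregate_species()] or elsewhere).
#' @param sample_id Sample label (default `"sample"`).
#' @param trace_floor Relative floor in percent below which a species is
#'   flagged trace (default 0.1).
#' @return A tibble of class `abundance_table`: `sample`, `species`,
#'   `abundance_pct`, `is_oac`, `trace`; attribute `oac_fraction`.
#'   `glance()` returns the per-sample summary.
#' @examples
#' relative_abundance(data.frame(
#'   species = c("GM3", "GD3", "OAcGD3"), intensity = c(50, 30, 20)))
#' @export
relative_abundance <- function(intensities, sample_id = "sample",
                               trace_floor = 0.1) {
  if (any(intensities$intensity < 0)) {
    stop("Negative intensities.", call. = FALSE)
  }
  total <- sum(intensities$intensity)
  if (total <= 0) {
    stop("Total intensity is zero; relative abundance undefined.",
         call. = FALSE)
  }
  out <- tibble::tibble(
    sample = sample_id,
    species = intensities$species,
    abundance_pct = 100 * intensities$intensity / total
  )
  out <- dplyr::mutate(out,
                       is_oac = grepl("^OAc", .data$species),
                       trace = .data$abundance_pct < trace_floor)
  attr(out, "oac_fraction") <- sum(out$abundance_pct[out$is_oac])
  class(out) <- c("abundance_table", class(out))
  out
}

#' O-acetylated fraction of an abundance table
#'
#' @param x An `abundance_table`.
#' @return Percentage of total ganglioside content that is O-acetylated.
#' @export
oac_fraction <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  attr(x, "oac_fraction")
}

#' @export
glance.abundance_table <- function(x, ...) {
  tibble::tibble(
    sample = x$sample[1],
    n_species = nrow(x),
    oac_fraction = attr(x, "oac_fraction"),
    non_oac_fraction = 100 - attr(x, "oac_fraction")
  )
}

#' Difference in relative abundance between two conditions
#'
#' @param table_a,table_b `abundance_table`s for the two conditions.
#' @param species Optional subset of species; defaults to the union.
#' @return A tibble: `species`, `delta_pct` (a minus b, percentage points;
#'   NA when the species is absent from both), `imputed_a`, `imputed_b`
#'   (TRUE where a missing value was treated as 0).
#' @export
delta_abundance <- function(table_a, table_b, species = NULL) {
  if (is.null(species)) {
    species <- sort(union(table_a$species, table_b$species))
  }
  val <- function(tab, sp) {
    i <- match(sp, tab$species)
    tab$abundance_pct[i]
  }
  a <- val(table_a, species)
  b <- val(table_b, species)
  both_missing <- is.na(a) & is.na(b)
  tibble::tibble(
    species = species,
    delta_pct = ifelse(both_missing, NA_real_,
                       dplyr::coalesce(a, 0) - dplyr::coalesce(b, 0)),
    imputed_a = is.na(a) & !both_missing,
    imputed_b = is.na(b) & !both_missing
  )
}
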