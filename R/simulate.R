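# Seeded simulators: ground-truthed MS1 spectra, MS/MS fragment spectra and
# qPCR Ct tables with the statistical structure the analysis assumes.
# Intensity noise is multiplicative log-normal (MALDI shot-to-shot
# variation), m/z jitter is Gaussian, contaminant peaks are uniform over the
# scan range.

.DEFAULT_CERAMIDE_WEIGHTS <- c(
  "16:0" = 0.45, "24:0" = 0.28, "24:1" = 0.12,
  "18:0" = 0.08, "22:0" = 0.05, "14:0" = 0.02
)

# Adduct-state weights by sialyl chain length: oligosialylated species are
# observed mostly lactonized ([M-H2O-H]- for di-, [M-2H2O-H]- for
# trisialylated species).
.adduct_weights <- function(n_sia) {
  if (n_sia <= 1) c(`0` = 1)
  else if (n_sia == 2) c(`0` = 0.2, `1` = 0.8)
  else c(`0` = 0.05, `1` = 0.15, `2` = 0.8)
}

.PROFILE_PRESETS <- list(
  parental = list(
    abundance = c(GM3 = 40, GM2 = 30, GM1 = 30),
    acetyl = character()
  ),
  bseries_oac = list(
    abundance = c(GM3 = 15, GD3 = 30, GD2 = 20, GD1b = 5,
                  OAcGD3 = 20, OAcGD2 = 10),
    acetyl = c(OAcGD3 = "Neu5Ac2", OAcGD2 = "Neu5Ac1")
  ),
  gd3s_plus = list(
    abundance = c(GM3 = 8, GM2 = 7, GD3 = 20, GD2 = 15, GT3 = 12, GT2 = 8,
                  OAcGD3 = 15, OAcGD2 = 7, OAcGT3 = 5, OAcGT2 = 3),
    acetyl = c(OAcGD3 = "Neu5Ac2", OAcGD2 = "Neu5Ac1",
               OAcGT3 = "Neu5Ac3", OAcGT2 = "Neu5Ac1")
  )
)

#' Ground-truth ganglioside profile
#'
#' Builds a reproducible ground-truth profile for the simulators: per-species
#' relative abundances summing to 100, a ceramide mixture, per-species adduct
#' weights and the acetyl position of each O-acetylated species. Presets:
#' `"parental"` (a-series only), `"bseries_oac"` (b-series with OAcGD3 and
#' OAcGD2), `"gd3s_plus"` (GD3-synthase-overexpressing pattern with c-series
#' species and four O-acetylated forms).
#'
#' @param scenario Preset name, ignored when `spec` is given.
#' @param seed Stored with the profile and used as the default seed of
#'   downstream simulators.
#' @param spec Optional explicit named abundance vector (must sum to 100);
#'   OAc species default to a terminal acetyl unless named in
#'   `acetyl_positions`.
#' @param acetyl_positions Optional named vector of Neu5Ac labels for OAc
#'   species in `spec`.
#' @param ceramide_weights Named acyl mixture weights (sum to 1).
#' @return A list of class `ganglio_profile`.
#' @examples
#' simulate_profile("gd3s_plus", seed = 7)
#' @export
simulate_profile <- function(scenario = c("parental", "bseries_oac", "gd3s_plus"),
                             seed = 1L, spec = NULL, acetyl_positions = NULL,
                             ceramide_weights = .DEFAULT_CERAMIDE_WEIGHTS) {
  if (is.null(spec)) {
    scenario <- match.arg(scenario)
    preset <- .PROFILE_PRESETS[[scenario]]
    abundance <- preset$abundance
    acetyl <- preset$acetyl
  } else {
    scenario <- "explicit"
    abundance <- spec
    oac <- grep("^OAc", names(spec), value = TRUE)
    acetyl <- setNames(
      purrr::map_chr(oac, function(nm) {
        utils::tail(composition_of(nm)$neu5ac_positions, 1)
      }), oac)
    if (!is.null(acetyl_positions)) acetyl[names(acetyl_positions)] <- acetyl_positions
  }
  if (abs(sum(abundance) - 100) > 1e-6) {
    stop("Profile abundances must sum to 100; got ", sum(abundance), ".",
         call. = FALSE)
  }
  if (any(abundance < 0)) stop("Abundances must be >= 0.", call. = FALSE)
  if (abs(sum(ceramide_weights) - 1) > 1e-9) {
    stop("Ceramide mixture weights must sum to 1.", call. = FALSE)
  }
  purrr::walk(names(abundance), composition_of)  # validates names
  structure(
    list(scenario = scenario, seed = seed,
         abundance = tibble::tibble(
           species = names(abundance),
           abundance = unname(abundance),
           acetyl_position = unname(acetyl[species])
         ),
         ceramide_weights = tibble::tibble(
           acyl = names(ceramide_weights),
           weight = unname(ceramide_weights)
         )),
    class = "ganglio_profile"
  )
}

#' @export
print.ganglio_profile <- function(x, ...) {
  cat("<ganglio_profile '", x$scenario, "'> seed ", x$seed, "\n", sep = "")
  print(x$abundance)
  invisible(x)
}

# All (species, acyl, adduct) ions a profile generates, with true intensity.
.profile_ions <- function(profile) {
  weights <- profile$ceramide_weights
  purrr::pmap_dfr(profile$abundance, function(species, abundance, acetyl_position) {
    sp <- composition_of(species)
    adw <- .adduct_weights(length(sp$neu5ac_positions))
    grid <- tidyr::expand_grid(acyl = weights$acyl,
                               n_dehydrations = as.integer(names(adw)))
    grid$cer_w <- weights$weight[match(grid$acyl, weights$acyl)]
    grid$ad_w <- unname(adw[as.character(grid$n_dehydrations)])
    grid <- dplyr::filter(grid, .data$cer_w > 0, .data$ad_w > 0)
    tibble::tibble(
      species = species,
      acyl = grid$acyl,
      n_dehydrations = grid$n_dehydrations,
      n_acetyl = as.integer(sp$o_acetylated),
      acetyl_position = acetyl_position,
      true_mz = purrr::map2_dbl(grid$acyl, grid$n_dehydrations,
                                function(a, d) ion_mz(sp, ceramide_spec(a), d)),
      true_intensity = abundance * grid$cer_w * grid$ad_w
    )
  })
}

#' Simulate a negative-mode MS1 spectrum
#'
#' Generates one peak per (species, ceramide variant, adduct state) of the
#' profile, with apex intensity proportional to abundance x mixture weight x
#' adduct weight under multiplicative log-normal noise, Gaussian m/z jitter,
#' and uniform contaminant peaks over the scan range. The generating ions are
#' attached as ground truth.
#'
#' @param profile A `ganglio_profile`.
#' @param jitter_sd Gaussian m/z jitter SD in Da (default 0).
#' @param noise_peaks Number of contaminant peaks (default 0); uniform m/z in
#'   `scan_range`, intensity uniform up to 5 percent of the base peak.
#' @param intensity_cv Coefficient of variation of multiplicative intensity
#'   noise (default 0).
#' @param seed RNG seed; the profile's seed by default.
#' @param scan_range m/z window, default `c(1000, 3000)`.
#' @return An `ms_spectrum` with attributes `ground_truth` (the generating
#'   ion table) and `profile`.
#' @export
simulate_ms1 <- function(profile, jitter_sd = 0, noise_peaks = 0,
                         intensity_cv = 0, seed = profile$seed,
                         scan_range = c(1000, 3000)) {
  stopifnot(inherits(profile, "ganglio_profile"), jitter_sd >= 0,
            intensity_cv >= 0, noise_peaks >= 0)
  if (!is.null(seed)) set.seed(seed)
  ions <- .profile_ions(profile)
  sdlog <- sqrt(log(1 + intensity_cv^2))
  noise_mult <- if (sdlog > 0) {
    rlnorm(nrow(ions), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else rep(1, nrow(ions))
  peaks <- tibble::tibble(
    mz = ions$true_mz + rnorm(nrow(ions), 0, jitter_sd),
    intensity = ions$true_intensity * noise_mult
  )
  if (noise_peaks > 0) {
    peaks <- dplyr::bind_rows(peaks, tibble::tibble(
      mz = runif(noise_peaks, scan_range[1], scan_range[2]),
      intensity = runif(noise_peaks, 0, 0.05 * max(peaks$intensity))
    ))
  }
  out <- as_spectrum(peaks, sample_id = paste0(profile$scenario, "_", seed))
  attr(out, "ground_truth") <- ions
  attr(out, "profile") <- profile
  out
}

#' Simulate an MS/MS fragment spectrum
#'
#' Draws a random subset (a `coverage` fraction) of the predicted glycosidic
#' fragments of an ion with log-normal intensity noise. The retained fragment
#' table, with the position-diagnostic flag, is attached as ground truth.
#'
#' @param species Acetylated or plain species symbol.
#' @param cer Acyl shorthand or `ceramide_spec`.
#' @param acetyl_position Neu5Ac label carrying the acetyl (required meaning
#'   for OAc species; terminal by default).
#' @param coverage Fraction of predicted fragments observed, in (0, 1].
#' @param noise_sd Log-scale SD of multiplicative intensity noise.
#' @param seed RNG seed.
#' @param base_intensity Noise-free fragment intensity (default 100).
#' @return An `ms_spectrum` with attribute `ground_truth`.
#' @export
simulate_msms <- function(species, cer, acetyl_position = NULL, coverage = 1,
                          noise_sd = 0, seed = 1L, base_intensity = 100) {
  stopifnot(coverage > 0, coverage <= 1, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.character(species)) species <- composition_of(species)
  pred <- predict_fragments(species, cer, acetyl_position = acetyl_position)
  n_keep <- max(1L, round(coverage * nrow(pred)))
  keep <- sort(sample.int(nrow(pred), n_keep))
  obs <- pred[keep, ]
  mult <- if (noise_sd > 0) {
    rlnorm(nrow(obs), meanlog = -noise_sd^2 / 2, sdlog = noise_sd)
  } else rep(1, nrow(obs))
  out <- as_spectrum(
    tibble::tibble(mz = obs$mz, intensity = base_intensity * mult),
    sample_id = paste0("msms_", species$name)
  )
  truth <- dplyr::mutate(pred, retained = dplyr::row_number() %in% keep)
  attr(out, "ground_truth") <- truth
  out
}

#' Simulate qPCR Ct tables for two conditions
#'
#' Constructs Ct values so that [log2_ratio_from_ct()] recovers the supplied
#' true log2 ratios exactly at zero noise. Wells are generated in triplicate
#' per (condition, gene) with Gaussian Ct noise.
#'
#' @param true_log2_ratios Named numeric vector: true expression log2 ratio
#'   (condition A over B) per gene.
#' @param ref_gene Reference gene name added to both conditions.
#' @param ct_noise_sd Per-well Ct noise SD (default 0).
#' @param seed RNG seed.
#' @param n_replicates Wells per (condition, gene) (default 3).
#' @param base_ct Noise-free target-gene Ct in condition B (default 24);
#'   reference Ct is 18 in both conditions.
#' @return A tidy Ct tibble: `condition` (`"A"`/`"B"`), `gene`, `replicate`,
#'   `ct`.
#' @export
simulate_qpcr <- function(true_log2_ratios, ref_gene = "RPLP0",
                          ct_noise_sd = 0, seed = 1L, n_replicates = 3L,
                          base_ct = 24) {
  stopifnot(ct_noise_sd >= 0, n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  genes <- names(true_log2_ratios)
  if (is.null(genes) || any(!nzchar(genes))) {
    stop("true_log2_ratios must be a named vector.", call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    condition = c("A", "B"),
    gene = c(genes, ref_gene),
    replicate = seq_len(n_replicates)
  )
  true_ct <- function(cond, gene) {
    if (gene == ref_gene) return(18)
    base_ct - if (cond == "A") true_log2_ratios[[gene]] else 0
  }
  ct0 <- purrr::map2_dbl(grid$condition, grid$gene, true_ct)
  dplyr::mutate(grid, ct = ct0 + rnorm(nrow(grid), 0, ct_noise_sd))
}
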