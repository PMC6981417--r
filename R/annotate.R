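# MS1 peak-list reading and compositional annotation against the ion library.

#' Read a peak list
#'
#' Reads a two-column (m/z, intensity) CSV or TSV peak list. A header row is
#' auto-detected; rows are sorted ascending by m/z on load. Malformed rows
#' are reported with their line numbers.
#'
#' @param path File path.
#' @param format `"csv"` or `"tsv"`; guessed from the extension by default.
#' @param sample_id Sample identifier attached to the result; the file stem
#'   by default.
#' @return A tibble of class `ms_spectrum` with columns `mz`, `intensity`
#'   and attribute `sample_id`.
#' @export
read_peaklist <- function(path, format = c("auto", "csv", "tsv"),
                          sample_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("Empty peak list: ", path, call. = FALSE)
  sep <- if (format == "csv") "," else "\t"
  fields <- strsplit(lines, sep, fixed = TRUE)
  parse_row <- function(f) suppressWarnings(as.numeric(f[1:2]))
  first <- parse_row(fields[[1]])
  has_header <- anyNA(first)
  data_idx <- seq_along(fields)
  if (has_header) data_idx <- data_idx[-1]
  if (length(data_idx) == 0) stop("Peak list has a header but no data rows: ",
                                  path, call. = FALSE)
  vals <- vapply(fields[data_idx], parse_row, numeric(2))
  bad <- data_idx[apply(is.na(vals), 2, any)]
  if (length(bad)) {
    stop("Non-numeric peak values at line(s) ", paste(bad, collapse = ", "),
         " of ", path, call. = FALSE)
  }
  spec <- tibble::tibble(mz = vals[1, ], intensity = vals[2, ])
  if (any(spec$intensity < 0)) {
    stop("Negative intensities in ", path, call. = FALSE)
  }
  spec <- dplyr::arrange(spec, .data$mz)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  as_spectrum(spec, sample_id = sample_id)
}

#' @rdname read_peaklist
#' @param x A data frame with columns `mz` and `intensity`.
#' @export
as_spectrum <- function(x, sample_id = "sample") {
  stopifnot(all(c("mz", "intensity") %in% names(x)))
  out <- dplyr::arrange(tibble::as_tibble(x[c("mz", "intensity")]), .data$mz)
  attr(out, "sample_id") <- sample_id
  class(out) <- c("ms_spectrum", class(out))
  out
}

#' Annotate MS1 peaks against a theoretical library
#'
#' Matches every peak of a spectrum against the ion library within an m/z
#' tolerance. Every peak receives exactly one annotation row: `unique` (one
#' candidate), `isobaric` (several candidates within tolerance) or
#' `unassigned`; no peak is dropped. Candidates are ordered by |delta m/z|,
#' ties broken by ascending residue count then species name, so output is
#' deterministic.
#'
#' @param spectrum An `ms_spectrum` (or any tibble with `mz`, `intensity`).
#' @param library An ion library from [enumerate_library()].
#' @param tolerance Match tolerance in Da (default 0.3, suited to
#'   one-decimal MALDI-QIT-TOF mid-mode peak lists).
#' @return A tibble of class `ganglio_annotation`: one row per peak with
#'   `peak_mz`, `intensity`, `rel_intensity`, `status`, `n_candidates` and a
#'   `candidates` list-column of library rows augmented with `delta_mz`.
#'   Attribute `sample_id` is carried over.
#' @examples
#' lib <- enumerate_library()
#' s <- as_spectrum(data.frame(mz = 1151.7, intensity = 100))
#' match_peaks(s, lib)
#' @export
match_peaks <- function(spectrum, library, tolerance = 0.3) {
  if (tolerance <= 0) stop("tolerance must be > 0.", call. = FALSE)
  if (nrow(library) == 0) stop("Empty ion library.", call. = FALSE)
  base_int <- max(spectrum$intensity, 0)
  lib_mz <- library$mz
  empty <- library[0, ]
  empty$delta_mz <- numeric()
  n <- nrow(spectrum)
  cand <- vector("list", n)
  n_cand <- integer(n)
  for (i in seq_len(n)) {
    pk <- spectrum$mz[i]
    idx <- which(abs(lib_mz - pk) <= tolerance)
    if (length(idx) == 0) {
      cand[[i]] <- empty
    } else {
      hits <- library[idx, ]
      hits$delta_mz <- hits$mz - pk
      hits <- hits[order(abs(hits$delta_mz), hits$n_residues, hits$species), ]
      cand[[i]] <- hits
    }
    n_cand[i] <- length(idx)
  }
  ann <- tibble::tibble(
    peak_mz = spectrum$mz,
    intensity = spectrum$intensity,
    rel_intensity = if (base_int > 0) spectrum$intensity / base_int else 0,
    status = dplyr::case_when(n_cand == 0 ~ "unassigned",
                              n_cand == 1 ~ "unique",
                              TRUE ~ "isobaric"),
    n_candidates = n_cand,
    candidates = cand
  )
  attr(ann, "sample_id") <- attr(spectrum, "sample_id") %||% "sample"
  attr(ann, "tolerance") <- tolerance
  class(ann) <- c("ganglio_annotation", class(ann))
  ann
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Long-format view of an annotation table
#'
#' @param x A `ganglio_annotation`.
#' @param ... Unused.
#' @return One row per (peak, candidate); unassigned peaks keep one row with
#'   NA candidate fields.
#' @export
tidy.ganglio_annotation <- function(x, ...) {
  out <- tidyr::unnest(
    dplyr::select(x, "peak_mz", "intensity", "status", "candidates"),
    "candidates", keep_empty = TRUE
  )
  dplyr::rename(out, theo_mz = "mz")
}

#' Per-peak best candidate (smallest |delta m/z|)
#'
#' @param annotation A `ganglio_annotation`.
#' @return Assigned peaks only, one row each, with the top candidate's fields.
#' @export
best_candidates <- function(annotation) {
  assigned <- dplyr::filter(annotation, .data$status != "unassigned")
  tops <- dplyr::bind_rows(purrr::map(assigned$candidates, function(x) x[1, ]))
  dplyr::bind_cols(
    assigned[, c("peak_mz", "intensity", "rel_intensity", "status")],
    tops
  )
}

#' Sample-by-species presence table
#'
#' Reconstructs a presence/trace/absence table from one or more annotated
#' samples. A species is supported by a peak when it is that peak's best
#' candidate (smallest |delta m/z|; ties keep all tied species). It is scored
#' `trace` when its strongest supporting peak falls below `trace_threshold`
#' as a fraction of the sample's base-peak intensity.
#'
#' @param annotations A `ganglio_annotation` or a (possibly named) list of
#'   them, one per sample.
#' @param trace_threshold Relative-intensity fraction in (0, 1) separating
#'   `trace` from `present` (default 0.01).
#' @return A tibble: `sample`, then one column per library species with
#'   values `"present"`, `"trace"` or `"absent"`.
#' @export
presence_table <- function(annotations, trace_threshold = 0.01) {
  if (trace_threshold <= 0 || trace_threshold >= 1) {
    stop("trace_threshold must lie in (0, 1).", call. = FALSE)
  }
  if (inherits(annotations, "ganglio_annotation")) {
    annotations <- list(annotations)
  }
  if (length(annotations) == 0) stop("No annotated samples.", call. = FALSE)
  per_sample <- purrr::imap_dfr(annotations, function(ann, idx) {
    sid <- attr(ann, "sample_id") %||% as.character(idx)
    assigned <- dplyr::filter(ann, .data$status != "unassigned")
    if (nrow(assigned) == 0) {
      return(tibble::tibble(sample = sid, species = character(),
                            rel = numeric()))
    }
    sup <- purrr::map_dfr(seq_len(nrow(assigned)), function(i) {
      cand <- assigned$candidates[[i]]
      best <- abs(cand$delta_mz) <= min(abs(cand$delta_mz)) + 1e-12
      tibble::tibble(species = unique(cand$species[best]),
                     rel = assigned$rel_intensity[i])
    })
    dplyr::summarise(dplyr::group_by(sup, .data$species),
                     rel = max(.data$rel), .groups = "drop") |>
      dplyr::mutate(sample = sid, .before = 1)
  })
  all_species <- sort(unique(unlist(
    purrr::map(annotations, function(a) {
      unique(unlist(purrr::map(a$candidates, function(cc) cc$species)))
    })
  )))
  samples <- purrr::imap_chr(annotations,
                             function(a, i) attr(a, "sample_id") %||% as.character(i))
  grid <- tidyr::expand_grid(sample = samples, species = all_species)
  out <- dplyr::left_join(grid, per_sample, by = c("sample", "species"))
  out <- dplyr::mutate(out, call = dplyr::case_when(
    is.na(.data$rel) ~ "absent",
    .data$rel < trace_threshold ~ "trace",
    TRUE ~ "present"
  ))
  tidyr::pivot_wider(dplyr::select(out, -"rel"),
                     names_from = "species", values_from = "call")
}
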