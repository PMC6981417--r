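# Negative-mode glycosidic fragment prediction (Domon-Costello B/C/Y/Z ions)
# and MS/MS-based reasoning: O-acetyl localization and isobar splitting.

# Descendants of a node (including itself) in the topology tibble.
.subtree <- function(topology, node) {
  members <- node
  repeat {
    kids <- topology$node[topology$parent %in% members &
                            !topology$node %in% members]
    if (length(kids) == 0) break
    members <- c(members, kids)
  }
  members
}

#' Predict glycosidic fragment ions
#'
#' Enumerates all singly deprotonated B/C/Y/Z ions from single glycosidic
#' cleavages of a ganglioside. B/C ions retain the non-reducing end; Y/Z
#' ions retain the ceramide. C = B + 18.01056; Y = Z + 18.01056. The
#' O-acetyl increment is inherited by exactly the fragment that contains the
#' acetylated sialic acid. Lactones are opened before prediction; water-loss
#' satellites of sialylated fragments can be added optionally.
#'
#' @param species Species symbol or `ganglioside_species`. An `OAc` prefix
#'   implies one acetyl group.
#' @param cer Acyl shorthand or `ceramide_spec`.
#' @param acetyl_position Neu5Ac label carrying the acetyl; defaults to the
#'   terminal residue of the chain for acetylated species.
#' @param include_water_loss Add `-H2O` satellites for fragments containing
#'   at least one sialic acid (default FALSE).
#' @return A tibble: `kind` (B/C/Y/Z, with `-H2O` suffix for satellites),
#'   `label`, `edge` (label of the node below the cleaved bond),
#'   `n_residues`, `contains_acetyl`, `mz`.
#' @examples
#' predict_fragments("GD3", "16:0")
#' predict_fragments("OAcGD3", "16:0", acetyl_position = "Neu5Ac2")
#' @export
predict_fragments <- function(species, cer, acetyl_position = NULL,
                              include_water_loss = FALSE) {
  if (is.character(species)) species <- composition_of(species)
  if (is.character(cer)) cer <- ceramide_spec(cer)
  n_acetyl <- as.integer(species$o_acetylated)
  topo <- species$topology
  if (n_acetyl == 1 && is.null(acetyl_position)) {
    acetyl_position <- utils::tail(species$neu5ac_positions, 1)
  }
  if (!is.null(acetyl_position) &&
      !acetyl_position %in% species$neu5ac_positions) {
    stop("acetyl_position '", acetyl_position, "' is not a Neu5Ac of ",
         species$name, ".", call. = FALSE)
  }
  res_mass <- unlist(.MASS[c("Hex", "HexNAc", "Neu5Ac")])
  cer_m <- ceramide_mass(cer)

  frags <- purrr::map_dfr(topo$node, function(nd) {
    sub <- .subtree(topo, nd)
    sub_rows <- topo[topo$node %in% sub, ]
    red_rows <- topo[!topo$node %in% sub, ]
    sub_mass <- sum(res_mass[sub_rows$residue])
    red_mass <- sum(res_mass[red_rows$residue])
    ac_nonred <- n_acetyl == 1 &&
      acetyl_position %in% sub_rows$label
    ac_inc <- n_acetyl * .MASS$acetyl
    b_mz <- sub_mass + (if (ac_nonred) ac_inc else 0) - .MASS$proton
    y_mz <- cer_m + red_mass + (if (ac_nonred) 0 else ac_inc) - .MASS$proton
    nb <- nrow(sub_rows)
    ny <- nrow(red_rows)
    edge_lab <- topo$label[topo$node == nd]
    tibble::tibble(
      kind = c("B", "C", "Y", "Z"),
      label = c(paste0("B", nb), paste0("C", nb),
                paste0("Y", ny), paste0("Z", ny)),
      edge = edge_lab,
      n_residues = c(nb, nb, ny, ny),
      contains_acetyl = c(ac_nonred, ac_nonred, !ac_nonred & n_acetyl == 1,
                          !ac_nonred & n_acetyl == 1),
      mz = c(b_mz, b_mz + .MASS$water, y_mz, y_mz - .MASS$water),
      sialylated = c(rep(any(sub_rows$residue == "Neu5Ac"), 2),
                     rep(any(red_rows$residue == "Neu5Ac"), 2))
    )
  })
  if (include_water_loss) {
    sat <- dplyr::filter(frags, .data$sialylated)
    sat <- dplyr::mutate(sat,
                         kind = paste0(.data$kind, "-H2O"),
                         label = paste0(.data$label, "-H2O"),
                         mz = .data$mz - .MASS$water)
    frags <- dplyr::bind_rows(frags, sat)
  }
  dplyr::arrange(dplyr::select(frags, -"sialylated"), .data$mz)
}

# Fragment keys whose m/z depends on the acetyl position: the diagnostic set.
.diagnostic_keys <- function(pred_by_pos, tolerance) {
  all_pred <- dplyr::bind_rows(pred_by_pos, .id = "position")
  keys <- dplyr::summarise(
    dplyr::group_by(all_pred, .data$kind, .data$edge),
    spread = max(.data$mz) - min(.data$mz), .groups = "drop"
  )
  dplyr::filter(keys, .data$spread >= 2 * tolerance)
}

#' Localize the O-acetylated sialic acid from an MS/MS spectrum
#'
#' Scores each possible acetyl position (sialic acids of the chain, inner to
#' terminal) by the summed intensity of matched position-diagnostic fragments
#' - those whose predicted m/z differs between positional isomers by at least
#' twice the MS2 tolerance. The call is the argmax; it is reported ambiguous
#' when the best-to-second score ratio falls below `margin_threshold` or when
#' no diagnostic fragment is matched.
#'
#' @param fragments An `ms_spectrum` of MS/MS peaks (or tibble with `mz`,
#'   `intensity`).
#' @param species Acetylated species symbol (e.g. `"OAcGD3"`) or
#'   `ganglioside_species`.
#' @param cer Acyl shorthand or `ceramide_spec` of the precursor.
#' @param tolerance MS2 match tolerance in Da (default 0.5).
#' @param margin_threshold Minimum best/second score ratio for an unambiguous
#'   call (default 2).
#' @return An object of class `oac_localization`: fields `species`,
#'   `ceramide`, `scores` (tibble: position, score), `call`, `margin`,
#'   `status`. `tidy()` returns the score table; `glance()` a one-row summary.
#' @export
localize_acetyl <- function(fragments, species, cer, tolerance = 0.5,
                            margin_threshold = 2) {
  if (is.character(species)) species <- composition_of(species)
  if (!species$o_acetylated) {
    stop("localize_acetyl() needs an O-acetylated candidate; got ",
         species$name, ".", call. = FALSE)
  }
  if (nrow(fragments) == 0) stop("Empty fragment spectrum.", call. = FALSE)
  positions <- species$neu5ac_positions
  pred_by_pos <- setNames(
    purrr::map(positions,
               function(p) predict_fragments(species, cer, acetyl_position = p)),
    positions
  )
  diag <- .diagnostic_keys(pred_by_pos, tolerance)
  scores <- purrr::map_dbl(positions, function(p) {
    pred <- dplyr::inner_join(pred_by_pos[[p]], diag,
                              by = c("kind", "edge"))
    if (nrow(pred) == 0) return(0)
    sum(purrr::map_dbl(pred$mz, function(m) {
      sum(fragments$intensity[abs(fragments$mz - m) <= tolerance])
    }))
  })
  score_tbl <- tibble::tibble(position = positions, score = scores)
  ord <- order(scores, decreasing = TRUE)
  status <- "ok"
  if (nrow(diag) == 0) {
    call <- "ambiguous"; margin <- NA_real_
    status <- "no diagnostic fragments predicted"
  } else if (max(scores) == 0) {
    call <- "ambiguous"; margin <- NA_real_
    status <- "no diagnostic fragments matched"
  } else if (length(positions) == 1) {
    call <- positions; margin <- Inf
  } else {
    best <- scores[ord[1]]; second <- scores[ord[2]]
    margin <- if (second == 0) Inf else best / second
    call <- if (margin >= margin_threshold) positions[ord[1]] else "ambiguous"
  }
  structure(
    list(species = species$name, ceramide = if (is.character(cer)) cer else cer$label,
         scores = score_tbl, call = call, margin = margin, status = status,
         n_diagnostic = nrow(diag)),
    class = "oac_localization"
  )
}

#' @export
print.oac_localization <- function(x, ...) {
  cat("<O-acetyl localization> ", x$species, " (", x$ceramide, ")\n", sep = "")
  cat("  call: ", x$call,
      if (is.finite(x$margin)) paste0("  (margin ", signif(x$margin, 3), ")"),
      "\n", sep = "")
  print(x$scores)
  invisible(x)
}

#' @export
tidy.oac_localization <- function(x, ...) {
  dplyr::mutate(x$scores, call = .data$position == x$call)
}

#' @export
glance.oac_localization <- function(x, ...) {
  tibble::tibble(species = x$species, call = x$call, margin = x$margin,
                 n_positions = nrow(x$scores), n_diagnostic = x$n_diagnostic,
                 status = x$status)
}

#' Apportion an isobaric precursor's intensity across candidates
#'
#' For each candidate structure of an isobaric MS1 peak, sums the MS/MS
#' intensity matched by that candidate's unique fragments (predicted m/z not
#' shared, within tolerance, with any other candidate) and returns
#' proportional shares. If no candidate matches any unique fragment the
#' intensity is split equally and flagged.
#'
#' @param fragments MS/MS spectrum of the shared precursor.
#' @param candidates A tibble of candidate ions (library rows: `species`,
#'   `acyl`, optionally `base`), at least two.
#' @param tolerance MS2 match tolerance in Da (default 0.5).
#' @return `candidates` with added `unique_intensity`, `share` (sums to 1)
#'   and `note` (`"equal split"` when the fallback was used).
#' @export
split_isobaric_intensity <- function(fragments, candidates, tolerance = 0.5) {
  if (nrow(candidates) < 2) {
    stop("Need at least two isobaric candidates.", call. = FALSE)
  }
  preds <- purrr::map(seq_len(nrow(candidates)), function(i) {
    predict_fragments(candidates$species[i], candidates$acyl[i])
  })
  uniq_int <- purrr::map_dbl(seq_len(nrow(candidates)), function(i) {
    others <- unlist(purrr::map(preds[-i], "mz"))
    mine <- preds[[i]]$mz
    is_unique <- purrr::map_lgl(mine, function(m) all(abs(others - m) > tolerance))
    mz_u <- unique(mine[is_unique])
    if (length(mz_u) == 0) return(0)
    sum(purrr::map_dbl(mz_u, function(m) {
      sum(fragments$intensity[abs(fragments$mz - m) <= tolerance])
    }))
  })
  total <- sum(uniq_int)
  if (total == 0) {
    warning("No candidate-unique fragments matched; splitting equally.",
            call. = FALSE)
    shares <- rep(1 / nrow(candidates), nrow(candidates))
    note <- "equal split"
  } else {
    shares <- uniq_int / total
    note <- "ms2"
  }
  dplyr::mutate(candidates, unique_intensity = uniq_int, share = shares,
                note = note)
}
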