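# Ganglioside biosynthesis pathway graph: default topology, qPCR log2
# ratios on gene nodes, abundance deltas on metabolite nodes, and the
# two-sided color scales used to render differential maps.

.PATHWAY_GENES <- c("B4GALT6", "ST3GAL5", "ST8SIA1", "B4GALNT1", "B3GALT4",
                    "ST3GAL2", "ST8SIA5", "SLC33A1", "CASD1")

.pathway_edges <- function() {
  lane <- function(from, members) {
    tibble::tibble(
      from = c(from, members[-length(members)]),
      to = members,
      gene = c("B4GALNT1", "B3GALT4", "ST3GAL2", "ST8SIA5")
    )
  }
  dplyr::bind_rows(
    tibble::tibble(
      from = c("GlcCer", "LacCer", "GM3", "GD3"),
      to = c("LacCer", "GM3", "GD3", "GT3"),
      gene = c("B4GALT6", "ST3GAL5", "ST8SIA1", "ST8SIA5")
    ),
    lane("LacCer", c("GA2", "GA1", "GM1b", "GD1c")),
    lane("GM3", c("GM2", "GM1", "GD1a", "GT1a")),
    lane("GD3", c("GD2", "GD1b", "GT1b", "GQ1b")),
    lane("GT3", c("GT2", "GT1c", "GQ1c", "GP1c")),
    tibble::tibble(
      from = c("GM1", "GD3", "GD2", "GT3", "GT2"),
      to = c("OAcGM1", "OAcGD3", "OAcGD2", "OAcGT3", "OAcGT2"),
      gene = "CASD1"
    )
  )
}

#' Default ganglioside biosynthesis pathway graph
#'
#' Builds the ganglio-series biosynthesis topology: GlcCer to LacCer, the
#' series precursors (LacCer, GM3, GD3, GT3) made by successive
#' sialylation (ST3GAL5, ST8SIA1, ST8SIA5), four parallel elongation lanes
#' via B4GALNT1 -> B3GALT4 -> ST3GAL2 -> ST8SIA5, and O-acetylated leaf
#' metabolites attached to their parent ganglioside via CASD1. Gene nodes
#' (including SLC33A1, the Golgi acetyl-CoA transporter, which catalyzes no
#' edge) are included so that expression ratios can be mapped onto them.
#'
#' @return An `igraph` graph with vertex attributes `type`
#'   (`"metabolite"`/`"gene"`), `value` (NA until set) and `color`
#'   (grey = no data), and edge attribute `gene`.
#' @export
ganglio_pathway <- function() {
  edges <- .pathway_edges()
  stopifnot(all(edges$gene %in% .PATHWAY_GENES))
  metabolites <- unique(c(edges$from, edges$to))
  nodes <- tibble::tibble(
    name = c(metabolites, .PATHWAY_GENES),
    type = c(rep("metabolite", length(metabolites)),
             rep("gene", length(.PATHWAY_GENES))),
    value = NA_real_,
    color = .NO_DATA_GREY
  )
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}

.NO_DATA_GREY <- "#BEBEBE"

#' Two-sided differential color scales
#'
#' Linear interpolation in RGB between white at 0 and a saturated endpoint at
#' the clamp bound: the gene scale runs blue (<= -2) to white (0) to red
#' (>= 2); the metabolite scale runs green (<= -8) to white (0) to fuchsia
#' (>= 8). Missing values map to grey (no data).
#'
#' @param value Numeric vector (gene log2 ratios or abundance deltas in
#'   percentage points).
#' @param scale `"gene"` or `"metabolite"`.
#' @return Hex color strings.
#' @examples
#' colorize(0, "gene")      # "#FFFFFF"
#' colorize(2.5, "gene")    # "#FF0000" (clamped)
#' colorize(-8, "metabolite")
#' @export
colorize <- function(value, scale = c("gene", "metabolite")) {
  scale <- match.arg(scale)
  bound <- if (scale == "gene") 2 else 8
  pos_end <- if (scale == "gene") c(255, 0, 0) else c(255, 0, 255)
  neg_end <- if (scale == "gene") c(0, 0, 255) else c(0, 255, 0)
  vapply(value, function(v) {
    if (is.na(v)) return(.NO_DATA_GREY)
    f <- min(abs(v), bound) / bound
    endpoint <- if (v >= 0) pos_end else neg_end
    rgb_vals <- round((1 - f) * c(255, 255, 255) + f * endpoint)
    grDevices::rgb(rgb_vals[1], rgb_vals[2], rgb_vals[3], maxColorValue = 255)
  }, character(1))
}

#' Expression log2 ratio from qPCR Ct values
#'
#' Computes the relative-expression log2 ratio of `condition_a` over
#' `condition_b` by the comparative-Ct method: the ratio equals minus the
#' delta-delta-Ct, where delta-Ct is the gene's Ct minus the reference
#' gene's Ct within each condition. Replicate wells are averaged per
#' (condition, gene) before differencing.
#'
#' @param ct Tidy Ct table: columns `condition`, `gene`, `ct` (one row per
#'   well; replicates allowed). Ct values must lie in (0, 45).
#' @param gene Target gene.
#' @param ref_gene Reference (housekeeping) gene; required, no default.
#' @param condition_a,condition_b The two conditions to compare.
#' @return The log2 expression ratio (a over b).
#' @examples
#' ct <- data.frame(
#'   condition = rep(c("A", "B"), each = 2),
#'   gene = rep(c("ST8SIA1", "REF"), 2),
#'   ct = c(20, 18, 22, 18))
#' log2_ratio_from_ct(ct, "ST8SIA1", "REF", "A", "B")  # +2
#' @export
log2_ratio_from_ct <- function(ct, gene, ref_gene, condition_a, condition_b) {
  stopifnot(all(c("condition", "gene", "ct") %in% names(ct)))
  if (any(ct$ct <= 0 | ct$ct >= 45)) {
    stop("Ct values must lie in (0, 45).", call. = FALSE)
  }
  mean_ct <- function(cond, g) {
    v <- ct$ct[ct$condition == cond & ct$gene == g]
    if (length(v) == 0) {
      stop("No Ct for gene '", g, "' in condition '", cond, "'.",
           call. = FALSE)
    }
    mean(v)
  }
  dct_a <- mean_ct(condition_a, gene) - mean_ct(condition_a, ref_gene)
  dct_b <- mean_ct(condition_b, gene) - mean_ct(condition_b, ref_gene)
  -(dct_a - dct_b)
}

#' Color a pathway graph with differential values
#'
#' Assigns log2 expression ratios to gene nodes and abundance deltas to
#' metabolite nodes, then colors every node on its scale; nodes without a
#' value stay grey (no data).
#'
#' @param graph A pathway graph from [ganglio_pathway()].
#' @param gene_ratios Named numeric vector or tibble (`gene`, `log2_ratio`).
#' @param metabolite_deltas Named numeric vector or tibble (`species`,
#'   `delta_pct`), e.g. from [delta_abundance()].
#' @return The graph with `value` and `color` vertex attributes filled in.
#' @export
map_differential <- function(graph, gene_ratios = NULL,
                             metabolite_deltas = NULL) {
  as_named <- function(x, key, val) {
    if (is.null(x)) return(numeric())
    if (is.data.frame(x)) setNames(x[[val]], x[[key]]) else x
  }
  genes <- as_named(gene_ratios, "gene", "log2_ratio")
  mets <- as_named(metabolite_deltas, "species", "delta_pct")
  nm <- igraph::V(graph)$name
  type <- igraph::V(graph)$type
  value <- igraph::V(graph)$value
  for (i in seq_along(nm)) {
    v <- if (type[i] == "gene") genes[nm[i]] else mets[nm[i]]
    if (length(v) == 1 && !is.na(v)) value[i] <- unname(v)
  }
  color <- ifelse(type == "gene", colorize(value, "gene"),
                  colorize(value, "metabolite"))
  graph <- igraph::set_vertex_attr(graph, "value", value = value)
  igraph::set_vertex_attr(graph, "color", value = color)
}

#' Export / import a pathway graph
#'
#' Writes the colored graph to GraphML, JSON (node-link lists) or SIF.
#' GraphML and JSON round-trip all node and edge attributes; SIF is a plain
#' edge list (`from  gene  to`).
#'
#' @param graph A pathway graph.
#' @param path Output file.
#' @param format `"graphml"`, `"json"` or `"sif"`; guessed from the
#'   extension by default.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("auto", "graphml", "json", "sif")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    if (!ext %in% c("graphml", "json", "sif")) {
      stop("Unsupported export format '.", ext, "'.", call. = FALSE)
    }
    format <- ext
  }
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else if (format == "json") {
    nodes <- igraph::as_data_frame(graph, what = "vertices")
    edges <- igraph::as_data_frame(graph, what = "edges")
    jsonlite::write_json(list(nodes = nodes, edges = edges), path,
                         dataframe = "rows", na = "null", auto_unbox = TRUE,
                         digits = NA)
  } else {
    edges <- igraph::as_data_frame(graph, what = "edges")
    writeLines(paste(edges$from, edges$gene, edges$to, sep = "\t"), path)
  }
  invisible(path)
}

#' @rdname export_graph
#' @export
import_graph <- function(path, format = c("auto", "graphml", "json")) {
  format <- match.arg(format)
  if (format == "auto") format <- tolower(sub(".*\\.", "", path))
  if (format == "graphml") {
    igraph::read_graph(path, format = "graphml")
  } else if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    nodes <- tibble::as_tibble(obj$nodes)
    if (!"value" %in% names(nodes)) nodes$value <- NA_real_
    nodes$value <- suppressWarnings(as.numeric(nodes$value))
    igraph::graph_from_data_frame(obj$edges, directed = TRUE,
                                  vertices = nodes)
  } else {
    stop("SIF files carry no attributes and are export-only.", call. = FALSE)
  }
}
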