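test_that("default pathway reproduces the four-lane topology", {
  g <- ganglio_pathway()
  edges <- igraph::as_data_frame(g, what = "edges")
  expect_true(igraph::is_dag(g))
  # every edge's catalyzing gene is a gene node
  genes <- igraph::V(g)$name[igraph::V(g)$type == "gene"]
  expect_true(all(edges$gene %in% genes))
  expect_true("SLC33A1" %in% genes)
  # series precursors each start an elongation lane with the same gene order
  lane_genes <- c("B4GALNT1", "B3GALT4", "ST3GAL2", "ST8SIA5")
  lanes <- list(c("LacCer", "GA2", "GA1", "GM1b", "GD1c"),
                c("GM3", "GM2", "GM1", "GD1a", "GT1a"),
                c("GD3", "GD2", "GD1b", "GT1b", "GQ1b"),
                c("GT3", "GT2", "GT1c", "GQ1c", "GP1c"))
  for (lane in lanes) {
    for (i in 1:4) {
      e <- edges[edges$from == lane[i] & edges$to == lane[i + 1], ]
      expect_equal(e$gene, lane_genes[i])
    }
  }
  # sialylation backbone and OAc leaves
  expect_equal(edges$gene[edges$from == "GM3" & edges$to == "GD3"], "ST8SIA1")
  oac <- edges[grepl("^OAc", edges$to), ]
  expect_equal(nrow(oac), 5)
  expect_true(all(oac$gene == "CASD1"))
  expect_equal(sub("^OAc", "", oac$to), oac$from)
})

test_that("comparative-Ct log2 ratios recover constructed values", {
  ct <- data.frame(
    condition = rep(c("A", "B"), each = 2),
    gene = rep(c("ST8SIA1", "REF"), 2),
    ct = c(20, 18, 22, 18))
  expect_equal(log2_ratio_from_ct(ct, "ST8SIA1", "REF", "A", "B"), 2)
  expect_equal(log2_ratio_from_ct(ct, "ST8SIA1", "REF", "A", "A"), 0)
  # antisymmetry
  expect_equal(log2_ratio_from_ct(ct, "ST8SIA1", "REF", "B", "A"),
               -log2_ratio_from_ct(ct, "ST8SIA1", "REF", "A", "B"),
               tolerance = 1e-12)
  expect_error(log2_ratio_from_ct(ct, "CASD1", "REF", "A", "B"), "No Ct")
  expect_error(log2_ratio_from_ct(ct, "ST8SIA1", "GAPDH", "A", "B"), "No Ct")
  bad <- ct; bad$ct[1] <- 50
  expect_error(log2_ratio_from_ct(bad, "ST8SIA1", "REF", "A", "B"), "0, 45")
})

test_that("color scales hit the stated endpoints and clamp", {
  expect_equal(colorize(0, "gene"), "#FFFFFF")
  expect_equal(colorize(2, "gene"), "#FF0000")
  expect_equal(colorize(2.5, "gene"), "#FF0000")   # clamped
  expect_equal(colorize(-2, "gene"), "#0000FF")
  expect_equal(colorize(-3, "gene"), "#0000FF")
  expect_equal(colorize(0, "metabolite"), "#FFFFFF")
  expect_equal(colorize(8, "metabolite"), "#FF00FF")
  expect_equal(colorize(-8, "metabolite"), "#00FF00")
  expect_equal(colorize(NA, "gene"), "#BEBEBE")    # no data -> grey
})

test_that("colorize is odd-symmetric around zero on each scale", {
  # v and -v interpolate the same fraction of the way from white toward
  # their respective endpoint colors
  implied_fraction <- function(hex) max(255 - grDevices::col2rgb(hex)[, 1]) / 255
  for (scale in c("gene", "metabolite")) {
    bound <- if (scale == "gene") 2 else 8
    for (v in c(0.3, 1, 1.7, 5)) {
      expect_equal(implied_fraction(colorize(v, scale)),
                   implied_fraction(colorize(-v, scale)))
      # 8-bit channels quantize the fraction to steps of 1/255
      expect_lt(abs(implied_fraction(colorize(v, scale)) -
                      min(v, bound) / bound), 1 / 255 + 1e-9)
    }
  }
  # idempotent under clamping
  expect_equal(colorize(100, "gene"), colorize(2, "gene"))
  expect_equal(colorize(-100, "metabolite"), colorize(-8, "metabolite"))
})

test_that("differential values map onto nodes with grey for no data", {
  g <- ganglio_pathway()
  g2 <- map_differential(
    g,
    gene_ratios = c(ST8SIA1 = 2, CASD1 = -1),
    metabolite_deltas = c(GD3 = 8, OAcGD3 = -4)
  )
  v <- igraph::V(g2)
  col <- setNames(v$color, v$name)
  expect_equal(unname(col["ST8SIA1"]), "#FF0000")
  expect_equal(unname(col["GD3"]), "#FF00FF")
  expect_equal(unname(col["GM3"]), "#BEBEBE")  # unquantified metabolite
  expect_equal(unname(col["B4GALT6"]), "#BEBEBE")
  expect_equal(unname(setNames(v$value, v$name)["CASD1"]), -1)
})

test_that("graph exports round-trip through GraphML and JSON", {
  g <- map_differential(ganglio_pathway(),
                        gene_ratios = c(ST8SIA1 = 1.5),
                        metabolite_deltas = c(GD3 = -3))
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, gml)
  g_rt <- import_graph(gml)
  expect_true(igraph::isomorphic(g, g_rt))
  expect_setequal(igraph::V(g_rt)$name, igraph::V(g)$name)
  col_rt <- setNames(igraph::V(g_rt)$color, igraph::V(g_rt)$name)
  expect_equal(unname(col_rt["GM3"]), "#BEBEBE")  # grey preserved

  js <- withr::local_tempfile(fileext = ".json")
  export_graph(g, js)
  g_js <- import_graph(js)
  expect_setequal(igraph::V(g_js)$name, igraph::V(g)$name)
  val <- setNames(igraph::V(g_js)$value, igraph::V(g_js)$name)
  expect_equal(unname(val["ST8SIA1"]), 1.5)
  ed1 <- igraph::as_data_frame(g, what = "edges")
  ed2 <- igraph::as_data_frame(g_js, what = "edges")
  expect_equal(ed1[order(ed1$from, ed1$to), ],
               ed2[order(ed2$from, ed2$to), ], ignore_attr = TRUE)

  sif <- withr::local_tempfile(fileext = ".sif")
  export_graph(g, sif)
  lines <- readLines(sif)
  expect_length(lines, igraph::ecount(g))
  expect_error(export_graph(g, "out.xyz"), "Unsupported export")
})
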