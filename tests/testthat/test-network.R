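test_that("Spearman candidates exclude self pairs and constant features, keep monotone transforms", {
  set.seed(2)
  x <- runif(12)
  vals <- data.frame(x = x, mono = exp(3 * x), flat = rep(1, 12),
                     noise = runif(12), row.names = sprintf("s%02d", 1:12))
  ft <- feature_table(vals, "metabolite")
  ca <- correlate_all(ft, rho_cut = 0.6)
  expect_false(any(ca$from == ca$to))
  hit <- ca[ca$from == "x" & ca$to == "mono", ]
  expect_equal(hit$rho, 1)
  expect_equal(hit$sign, "positive")
  expect_equal(attr(ca, "excluded"), "flat")
  expect_error(correlate_all(ft[1:2, ]), "3 samples")
})

test_that("the |rho| >= 0.6 edge rule is inclusive at the boundary", {
  # ranks chosen so Spearman rho is exactly 0.6 (sum d^2 = 8, n = 5)
  x <- 1:5
  y_at <- c(2, 3, 1, 5, 4)     # rho = 1 - 6*8/120  = 0.6  -> included
  y_below <- c(2, 4, 1, 3, 5)  # rho = 1 - 6*10/120 = 0.5  -> excluded
  expect_equal(cor(x, y_at, method = "spearman"), 0.6, tolerance = 1e-12)
  ft <- feature_table(data.frame(x = x, at = y_at, below = y_below,
                                 row.names = paste0("s", 1:5)), "metabolite")
  ca <- correlate_all(ft, rho_cut = 0.6)
  keys <- paste(ca$from, ca$to)
  expect_true("x at" %in% keys)
  expect_false("x below" %in% keys)
})

test_that("two-level extraction keeps primary and secondary edges only", {
  edges <- data.frame(from = c("B", "A", "X"), to = c("A", "X", "Y"),
                      rho = c(0.9, 0.8, 0.7),
                      sign = "positive", stringsAsFactors = FALSE)
  attr(edges, "features") <- data.frame(name = c("B", "A", "X", "Y"),
                                        class = "taxon", mean_abundance = 0.1,
                                        stringsAsFactors = FALSE)
  g <- extract_two_level(edges, "B")
  expect_setequal(igraph::V(g)$name, c("B", "A", "X"))
  el <- igraph::as_edgelist(g)
  expect_setequal(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])),
                  c("A B", "A X"))
  expect_error(extract_two_level(edges, "ZZ"), "absent")
  expect_error(extract_two_level(edges, character(0)), "empty")
  # isolated biomarker: omitted from the graph but flagged
  g2 <- extract_two_level(edges, c("B", "Y"))
  expect_true("Y" %in% igraph::V(g2)$name)  # Y has the X-Y edge: not isolated
  lone <- edges[1, , drop = FALSE]
  attr(lone, "features") <- attr(edges, "features")
  g3 <- extract_two_level(lone, c("B", "Y"))
  expect_equal(attr(g3, "isolated_biomarkers"), "Y")
  expect_false("Y" %in% igraph::V(g3)$name)
})

test_that("two-level extraction matches brute-force set construction on a random graph", {
  set.seed(30)
  nodes <- sprintf("n%02d", 1:30)
  pairs <- t(utils::combn(nodes, 2))
  keep <- runif(nrow(pairs)) < 0.08
  edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                      rho = runif(sum(keep), 0.6, 1) *
                        sample(c(-1, 1), sum(keep), TRUE),
                      stringsAsFactors = FALSE)
  edges$sign <- ifelse(edges$rho >= 0, "positive", "negative")
  attr(edges, "features") <- data.frame(name = nodes, class = "taxon",
                                        mean_abundance = 0.1,
                                        stringsAsFactors = FALSE)
  bios <- c("n03", "n17", "n25")
  g <- extract_two_level(edges, bios)
  el <- igraph::as_edgelist(g)
  got <- sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  expect_identical(got, bruteforce_two_level_edges(edges, bios))
  # the extracted graph is a subgraph of the full threshold graph
  full <- igraph::graph_from_data_frame(edges, directed = FALSE)
  expect_true(all(got %in% {
    fel <- igraph::as_edgelist(full)
    paste(pmin(fel[, 1], fel[, 2]), pmax(fel[, 1], fel[, 2]))
  }))
})

test_that("network metrics follow the E/N and 2E/(N(N-1)) conventions", {
  k3 <- igraph::make_full_graph(3)
  m3 <- network_metrics(k3)
  expect_equal(m3$density, 1)
  expect_equal(m3$avg_clustering, 1)
  expect_equal(m3$avg_degree, 1)  # 3 edges / 3 nodes
  # two disjoint triangles: the optimal partition has modularity 0.5
  two_tri <- igraph::disjoint_union(igraph::make_full_graph(3),
                                    igraph::make_full_graph(3))
  mt <- network_metrics(two_tri, seed = 7)
  expect_equal(mt$modularity, 0.5, tolerance = 1e-12)
  expect_equal(mt$modularity, bruteforce_max_modularity(two_tri),
               tolerance = 1e-12)
  # metrics are invariant to node relabeling
  perm <- igraph::permute(two_tri, sample(6))
  expect_equal(network_metrics(perm, seed = 7)[c("avg_degree", "density",
                                                 "avg_clustering", "modularity")],
               mt[c("avg_degree", "density", "avg_clustering", "modularity")])
  # degenerate graphs are flagged
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  me <- network_metrics(empty)
  expect_true(me$degenerate)
  expect_equal(me$avg_degree, 0)
})

test_that("GraphML export round-trips the graph with its attributes", {
  co <- mini_cohort()
  ca <- correlate_all(co$table, rho_cut = 0.5)
  bios <- unique(c(ca$from, ca$to))[1:2]
  g <- extract_two_level(ca, bios)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_network(g, path)
  g2 <- read_network(path)
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  expect_setequal(igraph::E(g2)$sign, igraph::E(g)$sign)
  expect_equal(sort(igraph::E(g2)$rho), sort(igraph::E(g)$rho),
               tolerance = 1e-9)
  expect_setequal(igraph::V(g2)$biomarker[match(bios, igraph::V(g2)$name)], TRUE)
})

test_that("GEXF export writes valid XML including the empty graph", {
  g <- igraph::make_graph(~ a - b, b - c)
  igraph::E(g)$rho <- c(0.8, -0.7)
  igraph::E(g)$sign <- c("positive", "negative")
  path <- withr::local_tempfile(fileext = ".gexf")
  export_network(g, path, format = "gexf")
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  expect_length(xml2::xml_find_all(doc, "//d1:node", ns), 3)
  expect_length(xml2::xml_find_all(doc, "//d1:edge", ns), 2)
  expect_setequal(
    xml2::xml_attr(xml2::xml_find_all(doc, "//d1:attvalue[@for='sign']", ns),
                   "value"),
    c("positive", "negative"))
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  p2 <- withr::local_tempfile(fileext = ".gexf")
  export_network(empty, p2, format = "gexf")
  expect_length(xml2::xml_find_all(xml2::read_xml(p2), "//d1:node",
                                   xml2::xml_ns(xml2::read_xml(p2))), 0)
})
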