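#' All-pairs Spearman correlation edge candidates
#'
#' Spearman's rank correlation over every pair of features on the raw
#' (untransformed) table: taxa as relative abundance, metabolites as
#' measured, categorical clinical covariates as 0/1 indicators per level.
#' Pairs with `|rho|` at or above the threshold become candidate edges; the
#' sign is retained. Constant features have an undefined correlation and are
#' excluded with a log entry.
#'
#' @param table a [feature_table()] with raw values (not CLR).
#' @param rho_cut inclusive absolute-correlation threshold (default 0.6).
#' @return data.frame of candidate edges (`from`, `to`, `rho`, `sign`) with
#'   attributes `"features"` (data.frame of usable features: name, class,
#'   mean abundance) and `"excluded"` (constant features).
#' @export
correlate_all <- function(table, rho_cut = 0.6) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$values) < 3L) stop("need at least 3 samples to correlate")
  m <- build_model_matrix(table)
  fc <- table$feature_class
  cls <- vapply(colnames(m), function(f) {
    if (f %in% names(fc)) unname(fc[f]) else "clinical"  # indicator columns
  }, character(1))
  const <- colnames(m)[apply(m, 2, stats::sd) == 0]
  use <- setdiff(colnames(m), const)
  m <- m[, use, drop = FALSE]
  rho <- stats::cor(m, method = "spearman")
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  vals <- rho[ut]
  hit <- abs(vals) >= rho_cut - 1e-12  # roundoff guard on the inclusive rule
  edges <- data.frame(from = colnames(m)[ut[hit, 1]],
                      to = colnames(m)[ut[hit, 2]],
                      rho = vals[hit],
                      sign = ifelse(vals[hit] >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  feats <- data.frame(name = use, class = unname(cls[use]),
                      mean_abundance = colMeans(m), stringsAsFactors = FALSE)
  structure(edges, features = feats, excluded = const, rho_cut = rho_cut)
}

#' Two-level biomarker neighborhood extraction
#'
#' Keeps the primary connection level (edges incident to a biomarker) and
#' the secondary level (edges incident to a biomarker's direct neighbor),
#' discarding anything further out. Equivalently: an edge survives iff one
#' of its endpoints is a biomarker or a direct neighbor of a biomarker in
#' the thresholded graph. Node attributes carry the feature class, the mean
#' abundance and the biomarker flag; edges keep rho and its sign.
#'
#' @param candidates edge candidates from [correlate_all()].
#' @param biomarkers a [select_biomarkers()] result or a character vector of
#'   feature names (non-empty). Clinical biomarkers match their indicator
#'   columns by prefix.
#' @return an undirected simple `igraph` graph; attribute
#'   `"isolated_biomarkers"` lists biomarkers with no qualifying edge (they
#'   are omitted from the graph).
#' @export
extract_two_level <- function(candidates, biomarkers) {
  if (inherits(biomarkers, "biomarker_set")) biomarkers <- biomarkers$features
  biomarkers <- as.character(biomarkers)
  if (!length(biomarkers)) stop("biomarker list is empty")
  feats <- attr(candidates, "features")
  known <- feats$name
  missing <- setdiff(biomarkers, known)
  if (length(missing))
    stop("biomarkers absent from the feature set: ",
         paste(missing, collapse = ", "))
  if (nrow(candidates) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(g, isolated_biomarkers = biomarkers))
  }
  inc_bio <- candidates$from %in% biomarkers | candidates$to %in% biomarkers
  neighbors <- setdiff(unique(c(candidates$from[inc_bio],
                                candidates$to[inc_bio])), biomarkers)
  lvl2 <- candidates$from %in% neighbors | candidates$to %in% neighbors
  kept <- candidates[inc_bio | lvl2, , drop = FALSE]
  isolated <- setdiff(biomarkers, unique(c(kept$from, kept$to)))
  nodes <- unique(c(kept$from, kept$to))
  vdf <- feats[match(nodes, feats$name), , drop = FALSE]
  vdf$biomarker <- vdf$name %in% biomarkers
  g <- igraph::graph_from_data_frame(kept, directed = FALSE, vertices = vdf)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = "first")
  structure(g, isolated_biomarkers = isolated)
}

#' Network summary metrics
#'
#' Conventions follow the reporting of the source graph tool: average degree
#' is `E / N` (single-count), density is `2E / (N(N-1))`, the average
#' clustering coefficient is the mean of local clustering with degree < 2
#' nodes contributing 0, and modularity is the quality of a seeded Louvain
#' partition (resolution 1, unweighted). Graphs with fewer than 2 nodes are
#' flagged degenerate and report zeros.
#'
#' @param net an undirected `igraph` graph.
#' @param seed seed for the Louvain partition (default 1).
#' @return list: `n_nodes`, `n_edges`, `avg_degree`, `density`,
#'   `avg_clustering`, `modularity`, `degenerate`.
#' @export
network_metrics <- function(net, seed = 1) {
  stopifnot(inherits(net, "igraph"))
  n <- igraph::vcount(net); e <- igraph::ecount(net)
  if (n < 2L) {
    return(list(n_nodes = n, n_edges = e, avg_degree = 0, density = 0,
                avg_clustering = 0, modularity = 0, degenerate = TRUE))
  }
  local <- igraph::transitivity(net, type = "local", isolates = "zero")
  local[!is.finite(local)] <- 0
  set.seed(seed)
  mod <- if (e == 0L) 0 else {
    comm <- igraph::cluster_louvain(net, weights = NA, resolution = 1)
    igraph::modularity(net, igraph::membership(comm))
  }
  list(n_nodes = n, n_edges = e,
       avg_degree = e / n,
       density = 2 * e / (n * (n - 1)),
       avg_clustering = mean(local),
       modularity = mod,
       degenerate = FALSE)
}

#' Export a correlation network for external visualization
#'
#' GraphML (via igraph, round-trippable with [read_network()]) or GEXF 1.2
#' for direct use in Gephi. Node attributes: feature class, biomarker flag,
#' mean abundance; edge attributes: rho and its sign.
#'
#' @param net an `igraph` graph, e.g. from [extract_two_level()].
#' @param path output file.
#' @param format `"graphml"` or `"gexf"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "gexf")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "igraph"))
  if (format == "graphml") {
    ok <- try(igraph::write_graph(net, path, format = "graphml"), silent = TRUE)
    if (inherits(ok, "try-error")) stop("failed to write ", path)
    return(invisible(path))
  }
  write_gexf(net, path)
}

#' Read a GraphML network back
#'
#' @param path a GraphML file written by [export_network()].
#' @return an `igraph` graph.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  igraph::read_graph(path, format = "graphml")
}

# Minimal GEXF 1.2 writer (igraph has no GEXF backend).
write_gexf <- function(net, path) {
  doc <- xml2::xml_new_root("gexf",
                            xmlns = "http://www.gexf.net/1.2draft",
                            version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  vattrs <- setdiff(igraph::vertex_attr_names(net), "name")
  attnode <- xml2::xml_add_child(graph, "attributes", class = "node")
  for (i in seq_along(vattrs)) {
    type <- if (is.numeric(igraph::vertex_attr(net, vattrs[i]))) "double" else "string"
    xml2::xml_add_child(attnode, "attribute", id = as.character(i - 1L),
                        title = vattrs[i], type = type)
  }
  nodes <- xml2::xml_add_child(graph, "nodes")
  vnames <- if ("name" %in% igraph::vertex_attr_names(net))
    igraph::V(net)$name else as.character(seq_len(igraph::vcount(net)))
  for (v in seq_len(igraph::vcount(net))) {
    nd <- xml2::xml_add_child(nodes, "node", id = vnames[v], label = vnames[v])
    if (length(vattrs)) {
      av <- xml2::xml_add_child(nd, "attvalues")
      for (i in seq_along(vattrs)) {
        xml2::xml_add_child(av, "attvalue", `for` = as.character(i - 1L),
                            value = as.character(igraph::vertex_attr(net, vattrs[i], v)))
      }
    }
  }
  edges <- xml2::xml_add_child(graph, "edges")
  if (igraph::ecount(net) > 0) {
    el <- igraph::as_edgelist(net, names = TRUE)
    w <- if ("rho" %in% igraph::edge_attr_names(net))
      igraph::E(net)$rho else rep(1, nrow(el))
    sgn <- if ("sign" %in% igraph::edge_attr_names(net))
      igraph::E(net)$sign else ifelse(w >= 0, "positive", "negative")
    for (k in seq_len(nrow(el))) {
      ed <- xml2::xml_add_child(edges, "edge", id = as.character(k - 1L),
                                source = el[k, 1], target = el[k, 2],
                                weight = as.character(abs(w[k])))
      av <- xml2::xml_add_child(ed, "attvalues")
      xml2::xml_add_child(av, "attvalue", `for` = "sign", value = sgn[k])
    }
  }
  ok <- try(xml2::write_xml(doc, path), silent = TRUE)
  if (inherits(ok, "try-error")) stop("failed to write ", path)
  invisible(path)
}
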