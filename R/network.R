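## Collapse fitted parameters to a signed weighted network, extract
## first-order neighborhoods, and import/export standard graph formats.

#' Collapse MGM parameters to an edge network
#'
#' Each nonzero parameter block becomes one undirected edge with a scalar
#' signed weight: \code{beta_st} itself for continuous-continuous edges, the
#' single free entry \code{rho_sj[2]} for continuous-binary edges,
#' \code{phi_rj[2,2]} for binary-binary edges, and the signed
#' maximum-magnitude free entry for blocks with more than two levels. The L2
#' norm of the free block is kept alongside so no information is lost for
#' multi-level edges. Blocks that are exactly zero produce no edge.
#'
#' @param params an \code{\linkS4class{MGMParameters}}.
#' @param layers optional named character vector of layer labels per
#'   variable (default "other").
#' @return an \code{\linkS4class{EdgeNetwork}}.
#' @export
collapseEdges <- function(params, layers = NULL) {
  cn <- params@contNames; qn <- params@catNames
  nodes <- data.frame(
    name = c(cn, qn),
    kind = c(rep("continuous", length(cn)), rep("categorical", length(qn))),
    stringsAsFactors = FALSE)
  nodes$layer <- if (is.null(layers)) "other" else unname(layers[nodes$name])
  nodes$layer[is.na(nodes$layer)] <- "other"
  src <- tgt <- blk <- character(0)
  wt <- nrm <- numeric(0)
  addEdge <- function(a, b, block, free) {
    if (all(free == 0)) return()
    w <- free[which.max(abs(free))]
    src <<- c(src, a); tgt <<- c(tgt, b); blk <<- c(blk, block)
    wt <<- c(wt, w); nrm <<- c(nrm, sqrt(sum(free^2)))
  }
  p <- length(cn)
  if (p > 1) {
    for (s in 1:(p - 1)) for (t in (s + 1):p)
      addEdge(cn[s], cn[t], "beta", params@beta[s, t])
  }
  for (j in seq_along(qn)) {
    for (s in seq_len(p))
      addEdge(cn[s], qn[j], "rho", params@rho[[j]][s, -1])
  }
  for (key in names(params@phi)) {
    rj <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
    addEdge(qn[rj[1]], qn[rj[2]], "phi", params@phi[[key]][-1, -1])
  }
  edges <- data.frame(source = src, target = tgt, weight = wt, norm = nrm,
                      block = blk, stringsAsFactors = FALSE)
  new("EdgeNetwork", nodes = nodes, edges = edges)
}

#' First-order neighborhood of a node
#'
#' All nodes directly connected to the center by exactly one edge, ordered by
#' decreasing absolute collapsed weight with ties broken by node name. The
#' center's own node potentials are attached so the neighborhood is usable as
#' a linear/logistic predictor via \code{\link{predictFromNeighborhood}}.
#'
#' @param net an \code{\linkS4class{EdgeNetwork}}.
#' @param center node name.
#' @param params optional \code{\linkS4class{MGMParameters}} from which the
#'   center's intercept terms are extracted.
#' @return a \code{\linkS4class{NeighborhoodModel}}.
#' @export
firstOrderNeighborhood <- function(net, center, params = NULL) {
  if (!center %in% net@nodes$name) {
    near <- agrep(center, net@nodes$name, max.distance = 0.3, value = TRUE)
    stop(sprintf("unknown node '%s'%s", center,
                 if (length(near)) paste0("; did you mean: ",
                                          paste(head(near, 5), collapse = ", "))
                 else ""))
  }
  e <- net@edges
  hit <- e$source == center | e$target == center
  nb <- data.frame(
    node = ifelse(e$source[hit] == center, e$target[hit], e$source[hit]),
    weight = e$weight[hit], norm = e$norm[hit], block = e$block[hit],
    stringsAsFactors = FALSE)
  nb <- nb[order(-abs(nb$weight), nb$node), , drop = FALSE]
  rownames(nb) <- NULL
  kind <- net@nodes$kind[match(center, net@nodes$name)]
  intercept <- list()
  if (!is.null(params)) {
    if (kind == "continuous") {
      s <- match(center, params@contNames)
      intercept <- list(alpha = unname(params@alpha[s]),
                        tau = -params@beta[s, s])
    } else {
      j <- match(center, params@catNames)
      intercept <- list(theta = params@theta[[j]])
    }
  }
  new("NeighborhoodModel", center = center, centerKind = kind,
      neighbors = nb, intercept = intercept)
}

#' Export a network to GraphML or an edge-list TSV
#'
#' GraphML carries node attributes \code{kind} and \code{layer} (plus
#' renderer hints \code{colorHint} by layer and \code{shapeHint}:
#' circle for continuous, rectangle for categorical) and edge attributes
#' \code{weight}, \code{norm} and \code{block}, written with full double
#' precision (17 significant digits) so round-trip import reproduces the
#' network exactly. The TSV has columns source, target, weight, norm, block.
#'
#' @param net an \code{\linkS4class{EdgeNetwork}}.
#' @param path output file.
#' @param format \code{"graphml"} or \code{"edge_tsv"}.
#' @return \code{path}, invisibly.
#' @export
exportNetwork <- function(net, path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    e <- net@edges
    e$weight <- sprintf("%.17g", e$weight)
    e$norm <- sprintf("%.17g", e$norm)
    write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  layerColors <- c(clinical_chemistry = "blue", demographic = "orange",
                   drug = "cyan", nmr = "red", other = "grey")
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keyDefs <- list(
    c("d_kind", "node", "kind", "string"),
    c("d_layer", "node", "layer", "string"),
    c("d_color", "node", "colorHint", "string"),
    c("d_shape", "node", "shapeHint", "string"),
    c("d_weight", "edge", "weight", "double"),
    c("d_norm", "edge", "norm", "double"),
    c("d_block", "edge", "block", "string"))
  for (k in keyDefs)
    xml2::xml_add_child(doc, "key", id = k[1], `for` = k[2],
                        attr.name = k[3], attr.type = k[4])
  g <- xml2::xml_add_child(doc, "graph", id = "mgm", edgedefault = "undirected")
  addData <- function(parent, key, value) {
    d <- xml2::xml_add_child(parent, "data", key = key)
    xml2::xml_text(d) <- value
  }
  for (i in seq_len(nrow(net@nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = net@nodes$name[i])
    addData(nd, "d_kind", net@nodes$kind[i])
    addData(nd, "d_layer", net@nodes$layer[i])
    col <- layerColors[net@nodes$layer[i]]
    addData(nd, "d_color", if (is.na(col)) "grey" else unname(col))
    addData(nd, "d_shape",
            if (net@nodes$kind[i] == "continuous") "circle" else "rectangle")
  }
  for (i in seq_len(nrow(net@edges))) {
    ed <- xml2::xml_add_child(g, "edge",
                              source = net@edges$source[i],
                              target = net@edges$target[i])
    addData(ed, "d_weight", sprintf("%.17g", net@edges$weight[i]))
    addData(ed, "d_norm", sprintf("%.17g", net@edges$norm[i]))
    addData(ed, "d_block", net@edges$block[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a network written by \code{\link{exportNetwork}}
#'
#' GraphML is read through igraph; the edge TSV is read directly.
#'
#' @param path input file.
#' @param format \code{"graphml"} or \code{"edge_tsv"}.
#' @return an \code{\linkS4class{EdgeNetwork}}. For \code{"edge_tsv"} the node
#'   table only lists the edge endpoints (kind/layer are not stored in a TSV).
#' @export
importNetwork <- function(path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    e <- read.delim(path, stringsAsFactors = FALSE)
    nodes <- data.frame(name = unique(c(e$source, e$target)),
                        kind = NA_character_, layer = NA_character_,
                        stringsAsFactors = FALSE)
    return(new("EdgeNetwork", nodes = nodes, edges = e))
  }
  ig <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(name = igraph::V(ig)$id,
                      kind = igraph::V(ig)$kind,
                      layer = igraph::V(ig)$layer,
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(ig, names = FALSE)
  edges <- data.frame(
    source = nodes$name[el[, 1]], target = nodes$name[el[, 2]],
    weight = if (igraph::ecount(ig)) igraph::E(ig)$weight else numeric(0),
    norm = if (igraph::ecount(ig)) igraph::E(ig)$norm else numeric(0),
    block = if (igraph::ecount(ig)) igraph::E(ig)$block else character(0),
    stringsAsFactors = FALSE)
  new("EdgeNetwork", nodes = nodes, edges = edges)
}
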