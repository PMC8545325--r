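#' Write a PathVisio-importable data file
#'
#' Tab-separated file with one row per gene: the mapped identifier, the
#' BridgeDb system code ("L" for entrez, "En" for ensembl) and one value
#' column per time point named `<result>_<tp>` in time-course order. Genes
#' lacking an identifier in the chosen namespace are omitted and counted in
#' the returned summary. Output is deterministic: rows sorted by gene
#' label, floats at 10 significant digits.
#'
#' @param de a `TimeCourseDE`.
#' @param ids an `IDMap`.
#' @param result which result to export: "log2fc" or "padj".
#' @param namespace "entrez" or "ensembl".
#' @param out output file path.
#' @param syscode override the system code string.
#' @return invisibly, list(path, n_written, n_omitted).
#' @export
write_pathvisio_data <- function(de, ids, result = c("log2fc", "padj"),
                                 namespace = c("entrez", "ensembl"), out,
                                 syscode = NULL) {
  result <- match.arg(result)
  namespace <- match.arg(namespace)
  syscode <- syscode %||% c(entrez = "L", ensembl = "En")[[namespace]]
  tps <- de_time_points(de)

  uniq <- unique(as.data.frame(de)[, c("gene", "gene_type")])
  idx <- match(paste(uniq$gene, uniq$gene_type),
               paste(ids$input_label, ids$gene_type))
  uniq$id <- ids[[namespace]][idx]
  omitted <- sum(is.na(uniq$id))
  uniq <- uniq[!is.na(uniq$id), , drop = FALSE]
  if (!nrow(uniq)) stop("no gene has a ", namespace, " identifier")
  uniq <- uniq[order(uniq$gene), , drop = FALSE]

  df <- data.frame(ID = uniq$id, SysCode = syscode,
                   stringsAsFactors = FALSE)
  for (tp in tps) {
    at <- de[de$time_point == tp, , drop = FALSE]
    m <- match(paste(uniq$gene, uniq$gene_type),
               paste(at$gene, at$gene_type))
    df[[paste0(result, "_", tp)]] <- at[[result]][m]
  }
  write_tsv_det(df, out, digits = 10)
  invisible(list(path = out, n_written = nrow(df), n_omitted = omitted))
}

#' Write the filtered-miRNA list for MAPPbuilder
#'
#' Three tab-separated columns per miRNA node of the filtered network:
#' adjusted label, mapped identifier (falling back to the label when the
#' namespace ID is absent) and the system code. Rows in lexicographic
#' order; byte-deterministic.
#'
#' @param network filtered interaction network (igraph).
#' @param ids an `IDMap`.
#' @param out output file path.
#' @param namespace "entrez" or "ensembl".
#' @return invisibly, list(path, n_written).
#' @export
write_filtered_mirnas <- function(network, ids, out,
                                  namespace = c("entrez", "ensembl")) {
  namespace <- match.arg(namespace)
  syscode <- c(entrez = "L", ensembl = "En")[[namespace]]
  mir <- sort(igraph::V(network)$name[igraph::V(network)$node_type == "miRNA"])
  if (!length(mir)) warning("empty network; writing an empty miRNA file")
  idx <- match(mir, ids$input_label)
  mapped <- ids[[namespace]][idx]
  adj <- ids$adjusted_label[idx]
  adj[is.na(adj)] <- mir[is.na(adj)]
  df <- data.frame(adjusted_label = adj,
                   mapped_id = ifelse(is.na(mapped), mir, mapped),
                   system_code = rep(syscode, length.out = length(mir)),
                   stringsAsFactors = FALSE)
  write_tsv_det(df, out)
  invisible(list(path = out, n_written = nrow(df)))
}

#' Export the filtered network for Cytoscape
#'
#' GraphML (open XML standard Cytoscape imports natively) carries the node
#' attribute `type` and edge attributes `corr` (full precision), `votes`
#' and one 0/1 attribute per database. SIF emits one
#' `mirna<TAB>targets<TAB>mrna` line per edge plus a sidecar
#' `<out>_edges.tsv` with the edge attributes.
#'
#' @param network filtered interaction network (igraph).
#' @param format "graphml" or "sif".
#' @param out output file path.
#' @return invisibly, character vector of file(s) written.
#' @export
write_network <- function(network, format = c("graphml", "sif"), out) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- network
    # export the character node type under the attribute name "type"
    if ("type" %in% igraph::vertex_attr_names(g)) {
      g <- igraph::delete_vertex_attr(g, "type")
    }
    g <- igraph::set_vertex_attr(g, "type",
                                 value = igraph::V(network)$node_type)
    igraph::write_graph(g, out, format = "graphml")
    return(invisible(out))
  }
  edges <- network_edges(network)
  sif <- sprintf("%s\ttargets\t%s", edges$mirna, edges$mrna)
  writeLines(sif, out, sep = "\n")
  side <- paste0(file_path_sans_ext(out), "_edges.tsv")
  write_tsv_det(edges, side)
  invisible(c(out, side))
}

#' Read a GraphML network back (round-trip helper)
#' @param path GraphML file.
#' @return igraph with `node_type` restored from the `type` attribute.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  igraph::set_vertex_attr(g, "node_type", value = igraph::V(g)$type)
}

#' Render the bipartite interaction network
#'
#' Draws the network with miRNA nodes in one color class (pink), mRNA
#' nodes in another (light blue) and edge colors mapped from the
#' correlation (the most negative correlation gets the extreme of the
#' colormap). The node-position/color table and edge-color table are
#' returned so the mapping is testable without image inspection.
#'
#' @param network filtered interaction network (igraph).
#' @param out optional PNG path.
#' @param seed layout seed (fixed seed gives a reproducible layout).
#' @return list(nodes = data.frame(name, node_type, color, x, y),
#'   edges = data.frame(mirna, mrna, corr, color)), or NULL for an empty
#'   network (with a warning).
#' @export
render_network <- function(network, out = NULL, seed = 1) {
  if (igraph::vcount(network) == 0) {
    warning("empty network; nothing to render")
    return(NULL)
  }
  node_cols <- ifelse(igraph::V(network)$node_type == "miRNA",
                      "pink", "lightblue")
  pal <- colorRampPalette(c("#08306B", "#9ECAE1", "#FDD0A2"))(100)
  corr <- igraph::E(network)$corr
  if (length(corr) && diff(range(corr)) > 0) {
    bins <- 1 + floor(99 * (corr - min(corr)) / diff(range(corr)))
  } else {
    bins <- rep(1, length(corr))
  }
  edge_cols <- pal[bins]
  layout <- with_seed(seed,
                      igraph::layout_with_fr(network))
  if (!is.null(out)) {
    png(out, width = 640, height = 640)
    on.exit(dev.off())
    igraph::plot.igraph(network, layout = layout,
                        vertex.color = node_cols,
                        vertex.label.cex = 0.7,
                        edge.color = edge_cols, edge.width = 2)
  }
  if (igraph::ecount(network) > 0) {
    ends <- igraph::as_edgelist(network)
    tp1 <- igraph::V(network)$node_type[match(ends[, 1],
                                              igraph::V(network)$name)]
    edf <- data.frame(mirna = ifelse(tp1 == "miRNA", ends[, 1], ends[, 2]),
                      mrna = ifelse(tp1 == "miRNA", ends[, 2], ends[, 1]),
                      corr = corr, color = edge_cols,
                      stringsAsFactors = FALSE)
    edf <- edf[order(edf$mirna, edf$mrna), , drop = FALSE]
    rownames(edf) <- NULL
  } else {
    edf <- data.frame(mirna = character(), mrna = character(),
                      corr = numeric(), color = character(),
                      stringsAsFactors = FALSE)
  }
  list(nodes = data.frame(name = igraph::V(network)$name,
                          node_type = igraph::V(network)$node_type,
                          color = node_cols,
                          x = layout[, 1], y = layout[, 2],
                          stringsAsFactors = FALSE),
       edges = edf)
}
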