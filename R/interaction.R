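#' mRNAs shared between a pathway and the input data
#'
#' Extracts the input mRNA labels whose mapped identifier (in the pathway's
#' namespace) is a member of the chosen pathway. Labels mapping to the same
#' pathway member are de-duplicated (first label in lexicographic order
#' wins) and the result is returned in lexicographic order.
#'
#' @param pathway_id pathway to intersect with.
#' @param pathways a `PathwaySet`.
#' @param de a `TimeCourseDE` (supplies the input mRNA labels).
#' @param ids optional `IDMap` (NULL: labels already are namespace IDs).
#' @return character vector of mRNA labels.
#' @export
pathway_mrnas <- function(pathway_id, pathways, de, ids = NULL) {
  if (!pathway_id %in% pathways$id) stop("unknown pathway_id: ", pathway_id)
  members <- pathways$members[[pathway_id]]
  labels <- sort(unique(de$gene[de$gene_type == "mRNA"]))
  if (is.null(ids)) {
    mapped <- labels
  } else {
    mapped <- ids[[pathways$namespace]][match(labels, ids$input_label)]
  }
  hit <- !is.na(mapped) & mapped %in% members
  labels <- labels[hit]
  mapped <- mapped[hit]
  labels <- labels[!duplicated(mapped)]
  if (!length(labels)) {
    stop("no input mRNA maps into pathway ", pathway_id,
         "; consider selecting another pathway")
  }
  sort(labels)
}

# gene x time matrix of values pulled from the DE table (or a user matrix)
value_matrix <- function(de, genes, gene_type, value = "log2fc",
                         expression = NULL) {
  tps <- de_time_points(de)
  if (value == "avg_expression") {
    if (is.null(expression)) {
      stop("value = 'avg_expression' needs a per-time-point expression matrix")
    }
    miss <- setdiff(genes, rownames(expression))
    if (length(miss)) {
      stop("expression matrix lacks gene(s): ", paste(miss, collapse = ", "))
    }
    return(as.matrix(expression[genes, tps, drop = FALSE]))
  }
  mat <- matrix(NA_real_, length(genes), length(tps),
                dimnames = list(genes, tps))
  sub <- de[de$gene_type == gene_type & de$gene %in% genes, , drop = FALSE]
  mat[cbind(match(sub$gene, genes), match(sub$time_point, tps))] <- sub$log2fc
  mat
}

#' All-pairs miRNA-mRNA trajectory correlations
#'
#' Builds the interaction matrix between candidate miRNA regulators and
#' pathway mRNAs: for every pair, the chosen correlation coefficient
#' between the two per-time-point value trajectories (log2 fold changes by
#' default, or a user-supplied mean-expression matrix). Kendall is the
#' tie-corrected tau-b. Pairs where either trajectory has fewer than two
#' finite values or zero variance are marked unavailable (NA) with a
#' warning; such pairs can never pass the downstream filter.
#'
#' @param de a `TimeCourseDE` (needs at least 3 time points).
#' @param mirnas candidate miRNA labels.
#' @param mrnas pathway mRNA labels (e.g. from [pathway_mrnas()]).
#' @param value "log2fc" (default) or "avg_expression".
#' @param method "pearson" (default), "spearman" or "kendall".
#' @param expression optional gene x time-point matrix for
#'   `avg_expression` mode (rows must cover both gene lists).
#' @return object of class `InteractionMatrix`: list with `mirnas`,
#'   `mrnas`, `corr` (miRNA x mRNA), `available` (logical), `flags` (per-
#'   database 0/1 matrices, filled by [apply_db_flags()]), `votes`,
#'   `traj` (the two value matrices), `method`, `value`, `time_points`.
#' @export
pair_correlations <- function(de, mirnas, mrnas,
                              value = c("log2fc", "avg_expression"),
                              method = c("pearson", "spearman", "kendall"),
                              expression = NULL) {
  value <- match.arg(value)
  method <- match.arg(method)
  tps <- de_time_points(de)
  if (length(tps) < 3) {
    stop("fewer than three time points: correlation analysis aborted")
  }
  mirnas <- as.character(mirnas)
  mrnas <- as.character(mrnas)
  X <- value_matrix(de, mirnas, "miRNA", value, expression)
  Y <- value_matrix(de, mrnas, "mRNA", value, expression)

  usable <- function(v) sum(is.finite(v)) >= 2 && sd(v[is.finite(v)]) > 0
  x_ok <- apply(X, 1, usable)
  y_ok <- apply(Y, 1, usable)
  corr <- matrix(NA_real_, length(mirnas), length(mrnas),
                 dimnames = list(mirnas, mrnas))
  for (i in seq_along(mirnas)) {
    if (!x_ok[i]) next
    for (j in seq_along(mrnas)) {
      if (!y_ok[j]) next
      corr[i, j] <- cor(X[i, ], Y[j, ], method = method,
                        use = "pairwise.complete.obs")
    }
  }
  available <- is.finite(corr)
  if (any(!x_ok) || any(!y_ok)) {
    warning("zero-variance or short trajectory for: ",
            paste(c(mirnas[!x_ok], mrnas[!y_ok]), collapse = ", "),
            " (pairs marked unavailable)")
  }
  structure(list(mirnas = mirnas, mrnas = mrnas, corr = corr,
                 available = available, flags = list(), votes = NULL,
                 selected_dbs = character(),
                 traj = list(mirna = X, mrna = Y),
                 method = method, value = value, time_points = tps),
            class = "InteractionMatrix")
}

#' @export
print.InteractionMatrix <- function(x, ...) {
  cat("InteractionMatrix: ", length(x$mirnas), " miRNAs x ",
      length(x$mrnas), " mRNAs (", x$method, " on ", x$value, "); ",
      length(x$flags), " database flag layer(s)\n", sep = "")
  invisible(x)
}

#' Annotate the interaction matrix with database evidence
#'
#' For every loaded database, flags each (miRNA, mRNA) pair 1 if the pair
#' is present in the database and 0 otherwise; the vote count is the sum of
#' flags over the user-selected databases only.
#'
#' @param mat an `InteractionMatrix`.
#' @param dbs list of `TargetDB` objects.
#' @param selected database names contributing to the vote (default: all
#'   loaded ones). A name not among the loaded databases is an error.
#' @return the `InteractionMatrix` with `flags`, `votes` and
#'   `selected_dbs` filled in.
#' @export
apply_db_flags <- function(mat, dbs, selected = NULL) {
  names(dbs) <- vapply(dbs, function(d) d$name, character(1))
  if (is.null(selected)) selected <- names(dbs)
  unknown <- setdiff(selected, names(dbs))
  if (length(unknown)) {
    stop("selected database(s) not loaded: ", paste(unknown, collapse = ", "))
  }
  flags <- lapply(dbs, function(db) {
    f <- matrix(0L, length(mat$mirnas), length(mat$mrnas),
                dimnames = dimnames(mat$corr))
    if (nrow(db$pairs)) {
      key <- paste(db$pairs$mirna, db$pairs$target, sep = "\r")
      grid <- expand.grid(mirna = mat$mirnas, mrna = mat$mrnas,
                          stringsAsFactors = FALSE)
      hit <- paste(grid$mirna, grid$mrna, sep = "\r") %in% key
      f[cbind(match(grid$mirna, mat$mirnas),
              match(grid$mrna, mat$mrnas))] <- as.integer(hit)
    }
    f
  })
  votes <- Reduce(`+`, flags[selected])
  mat$flags <- flags
  mat$votes <- votes
  mat$selected_dbs <- selected
  mat
}

#' Filter interactions by correlation and database votes
#'
#' Keeps a pair iff its correlation is at most `max_corr` (inclusive
#' boundary: a pair at exactly the threshold is kept) AND its database vote
#' count is at least `min_dbs`, then assembles the kept pairs into a
#' bipartite miRNA/mRNA graph. Pairs with unavailable correlation never
#' pass. Isolated nodes are excluded; an empty network is allowed (with a
#' warning).
#'
#' @param mat an `InteractionMatrix` with database flags applied (only
#'   optional when `min_dbs = 0`).
#' @param max_corr maximum correlation; default -0.5 (miRNAs repress their
#'   targets, so candidate interactions anticorrelate).
#' @param min_dbs minimum number of supporting databases; default 1.
#' @return an `igraph` bipartite graph: vertex attributes `name` and
#'   `node_type` ("miRNA"/"mRNA"), edge attributes `corr`, `votes` and one
#'   `flag_<db>` per loaded database.
#' @export
filter_interactions <- function(mat, max_corr = -0.5, min_dbs = 1) {
  if (is.null(mat$votes)) {
    if (min_dbs > 0) {
      stop("database flags not applied; run apply_db_flags() first ",
           "or set min_dbs = 0")
    }
    votes <- matrix(0L, length(mat$mirnas), length(mat$mrnas),
                    dimnames = dimnames(mat$corr))
  } else {
    votes <- mat$votes
  }
  keep <- mat$available & (mat$corr <= max_corr) & (votes >= min_dbs)
  keep[is.na(keep)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(mirna = mat$mirnas[idx[, 1]],
                      mrna = mat$mrnas[idx[, 2]],
                      corr = mat$corr[idx],
                      votes = as.integer(votes[idx]),
                      stringsAsFactors = FALSE)
  for (db in names(mat$flags)) {
    edges[[paste0("flag_", db)]] <- as.integer(mat$flags[[db]][idx])
  }
  edges <- edges[order(edges$mirna, edges$mrna), , drop = FALSE]
  if (!nrow(edges)) warning("no interaction passes the filter; empty network")

  nodes <- data.frame(
    name = c(sort(unique(edges$mirna)), sort(unique(edges$mrna))),
    node_type = rep(c("miRNA", "mRNA"),
                    c(length(unique(edges$mirna)),
                      length(unique(edges$mrna)))),
    stringsAsFactors = FALSE)
  nodes$type <- nodes$node_type == "miRNA"  # igraph bipartite marker
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  g <- igraph::set_graph_attr(g, "databases", names(mat$flags))
  g <- igraph::set_graph_attr(g, "max_corr", max_corr)
  g <- igraph::set_graph_attr(g, "min_dbs", min_dbs)
  g
}

# edge table of a filtered network, deterministically ordered
network_edges <- function(network) {
  if (igraph::ecount(network) == 0) {
    return(data.frame(mirna = character(), mrna = character(),
                      corr = numeric(), votes = integer(),
                      stringsAsFactors = FALSE))
  }
  ends <- igraph::as_edgelist(network)
  tp <- igraph::V(network)$node_type[match(ends[, 1],
                                           igraph::V(network)$name)]
  df <- data.frame(mirna = ifelse(tp == "miRNA", ends[, 1], ends[, 2]),
                   mrna = ifelse(tp == "miRNA", ends[, 2], ends[, 1]),
                   stringsAsFactors = FALSE)
  for (a in igraph::edge_attr_names(network)) {
    df[[a]] <- igraph::edge_attr(network, a)
  }
  df <- df[order(df$mirna, df$mrna), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Per-gene trends across the network's time course
#'
#' Returns the value trajectory of every gene in the filtered network plus
#' a highlight flag: a gene is highlighted iff any of its values exceeds
#' the (signed) threshold. Optionally draws a line plot with highlighted
#' genes emphasized.
#'
#' @param de a `TimeCourseDE`.
#' @param network a filtered interaction network (igraph).
#' @param highlight_threshold signed threshold; a gene is highlighted iff
#'   any value > threshold.
#' @param value "log2fc" or "avg_expression".
#' @param expression optional expression matrix for `avg_expression`.
#' @param out optional PNG path.
#' @return data.frame: `gene`, `node_type`, one column per time point,
#'   `highlighted`.
#' @export
gene_trends <- function(de, network, highlight_threshold, value = "log2fc",
                        expression = NULL, out = NULL) {
  if (!is.finite(highlight_threshold)) {
    stop("highlight_threshold must be finite")
  }
  tps <- de_time_points(de)
  if (igraph::vcount(network) == 0) {
    warning("empty network; no gene trends to report")
    out_df <- data.frame(gene = character(), node_type = character(),
                         stringsAsFactors = FALSE)
    for (tp in tps) out_df[[tp]] <- numeric(0)
    out_df$highlighted <- logical(0)
    return(out_df)
  }
  genes <- igraph::V(network)$name
  types <- igraph::V(network)$node_type
  ord <- order(genes)
  genes <- genes[ord]; types <- types[ord]
  mat <- matrix(NA_real_, length(genes), length(tps),
                dimnames = list(genes, tps))
  for (gt in c("miRNA", "mRNA")) {
    sel <- types == gt
    if (any(sel)) {
      mat[sel, ] <- value_matrix(de, genes[sel], gt, value, expression)
    }
  }
  highlighted <- apply(mat, 1, function(v) any(v > highlight_threshold,
                                               na.rm = TRUE))
  df <- data.frame(gene = genes, node_type = types, mat,
                   highlighted = highlighted,
                   check.names = FALSE, stringsAsFactors = FALSE,
                   row.names = NULL)
  if (!is.null(out)) {
    png(out, width = 720, height = 480)
    on.exit(dev.off())
    matplot(seq_along(tps), t(mat), type = "l", lty = 1,
            col = ifelse(highlighted, "red", "grey60"),
            xaxt = "n", xlab = "time point", ylab = value,
            main = paste0("Network gene trends (highlight > ",
                          highlight_threshold, ")"))
    axis(1, at = seq_along(tps), labels = tps)
  }
  df
}

#' Hierarchical clustering of network gene trajectories
#'
#' Agglomerative clustering (Euclidean distance on row-standardized
#' trajectories, average linkage by default) of the genes in the filtered
#' network, cut into `k` clusters. Returns the dendrogram leaf order
#' (shared by the heatmap rows), the cluster labels, per-cluster mean
#' trajectories with a smoothing-spline overlay, and the standardized
#' matrix in leaf order as heatmap data.
#'
#' @param de a `TimeCourseDE`.
#' @param network a filtered interaction network with >= 2 genes.
#' @param k number of clusters (<= number of genes).
#' @param linkage hclust agglomeration method; "average" by default.
#' @param value "log2fc" or "avg_expression".
#' @param expression optional expression matrix.
#' @param out_prefix optional path prefix; writes `<prefix>_clusterN.png`
#'   per cluster and `<prefix>_heatmap.png`.
#' @return list with `order` (leaf-ordered gene names), `labels` (named
#'   cluster vector), `hclust`, `heatmap` (standardized matrix in leaf
#'   order), `cluster_trends` (per cluster: data.frame of time, mean,
#'   spline grid and fit).
#' @export
cluster_network_genes <- function(de, network, k, linkage = "average",
                                  value = "log2fc", expression = NULL,
                                  out_prefix = NULL) {
  genes <- sort(igraph::V(network)$name)
  if (length(genes) < 2) stop("need at least 2 genes in the network")
  if (k > length(genes)) stop("k (", k, ") exceeds gene count (",
                              length(genes), ")")
  tps <- de_time_points(de)
  types <- igraph::V(network)$node_type[match(genes,
                                              igraph::V(network)$name)]
  mat <- matrix(NA_real_, length(genes), length(tps),
                dimnames = list(genes, tps))
  for (gt in c("miRNA", "mRNA")) {
    sel <- types == gt
    if (any(sel)) {
      mat[sel, ] <- value_matrix(de, genes[sel], gt, value, expression)
    }
  }
  std <- standardize(trajectory_matrix(mat, tps))
  h <- hclust(dist(std, method = "euclidean"), method = linkage)
  labels <- cutree(h, k = k)
  leaf_order <- rownames(std)[h$order]

  tidx <- seq_along(tps)
  grid <- seq(1, length(tps), length.out = 100)
  cluster_trends <- lapply(sort(unique(labels)), function(ci) {
    sub <- std[names(labels)[labels == ci], , drop = FALSE]
    mu <- colMeans(sub)
    fit <- tryCatch(
      predict(smooth.spline(tidx, mu), grid)$y,
      error = function(e) spline(tidx, mu, xout = grid,
                                 method = "natural")$y)
    list(cluster = ci, genes = rownames(sub),
         mean = data.frame(time_point = tps, mean = mu,
                           stringsAsFactors = FALSE),
         smooth = data.frame(x = grid, y = fit))
  })

  if (!is.null(out_prefix)) {
    for (tr in cluster_trends) {
      png(paste0(out_prefix, "_cluster", tr$cluster, ".png"),
          width = 540, height = 400)
      sub <- std[tr$genes, , drop = FALSE]
      matplot(tidx, t(sub), type = "l", lty = 1, col = "grey60",
              xaxt = "n", xlab = "time point", ylab = "standardized value",
              main = paste("Cluster", tr$cluster))
      lines(tr$smooth$x, tr$smooth$y, col = "red", lwd = 2)
      axis(1, at = tidx, labels = tps)
      dev.off()
    }
    png(paste0(out_prefix, "_heatmap.png"), width = 540, height = 540)
    hm <- std[leaf_order, , drop = FALSE]
    image(t(hm[rev(seq_len(nrow(hm))), , drop = FALSE]),
          axes = FALSE, main = "Network gene heatmap")
    dev.off()
  }
  list(order = leaf_order, labels = labels, hclust = h,
       heatmap = std[leaf_order, , drop = FALSE],
       cluster_trends = cluster_trends)
}
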