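#' Upper-tail hypergeometric probability for overrepresentation
#'
#' P(X >= k) where X ~ Hypergeometric(N, K, n): drawing n genes from a
#' universe of N containing K pathway members, the probability of seeing at
#' least the observed overlap k. One-sided upper tail including the
#' observed k, the standard overrepresentation-analysis convention.
#'
#' @param k observed overlap count.
#' @param K pathway size within the universe.
#' @param n significant-set size within the universe.
#' @param N universe size.
#' @return tail probability in \[0, 1\].
#' @export
hypergeom_tail <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (any(!is.finite(vals)) || any(vals != round(vals)) || any(vals < 0)) {
    stop("k, K, n, N must be non-negative integers")
  }
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k > min(n, K)) stop("k must not exceed min(n, K)")
  if (k == 0) return(1)
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Per-context pathway overrepresentation analysis
#'
#' One hypergeometric upper-tail test per (context, pathway), where a
#' context is a time point (combined mode), a (time point, gene type) pair
#' (separate mode) or a temporal cluster. Significant sets and pathway
#' members are intersected with the universe before counting, and
#' Benjamini-Hochberg adjustment is applied within each context across its
#' pathways.
#'
#' @param sig a `SignificantSets` object, or a plain named list of gene-ID
#'   vectors (one entry per context).
#' @param pathways a `PathwaySet`.
#' @param universe character vector of gene IDs in the pathway namespace, or
#'   "auto" to use every mapped ID in `ids` (the union of all genes present
#'   in the input DE data after ID mapping).
#' @param ids optional `IDMap` used to translate significant gene labels to
#'   the pathway namespace; NULL means labels are already namespace IDs.
#' @param keep_zero keep rows with zero overlap (p = 1)? Default drops them.
#' @return object of class `EnrichmentTable`: data.frame with columns
#'   `context`, `time_point`, `gene_type`, `pathway_id`, `pathway_name`,
#'   `k`, `n`, `K`, `N`, `p_raw`, `p_adj`.
#' @export
enrich_per_context <- function(sig, pathways, universe = "auto", ids = NULL,
                               keep_zero = FALSE) {
  ns <- pathways$namespace
  if (inherits(sig, "SignificantSets")) {
    sets <- sig$sets
    keys <- sig$keys
  } else {
    stopifnot(is.list(sig), !is.null(names(sig)))
    sets <- sig
    keys <- data.frame(key = names(sig), time_point = NA_character_,
                       gene_type = NA_character_, stringsAsFactors = FALSE)
  }
  if (identical(universe, "auto")) {
    if (is.null(ids)) {
      stop("universe = 'auto' requires an IDMap (ids); ",
           "otherwise pass the universe explicitly")
    }
    universe <- unique(ids[[ns]][!is.na(ids[[ns]])])
  }
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("universe is empty")

  rows <- list()
  for (ki in seq_len(nrow(keys))) {
    key <- keys$key[ki]
    sig_ids <- translate_labels(sets[[key]], ids, ns)
    sig_u <- intersect(sig_ids, universe)
    n <- length(sig_u)
    ctx <- list()
    for (pi in seq_along(pathways$id)) {
      mem_u <- intersect(pathways$members[[pi]], universe)
      K <- length(mem_u)
      if (K == 0) next
      k <- length(intersect(sig_u, mem_u))
      if (k == 0 && !keep_zero) next
      p <- hypergeom_tail(k, K, n, length(universe))
      ctx[[length(ctx) + 1]] <- data.frame(
        context = key, time_point = keys$time_point[ki],
        gene_type = keys$gene_type[ki],
        pathway_id = pathways$id[pi], pathway_name = pathways$name[pi],
        k = k, n = n, K = K, N = length(universe),
        p_raw = p, stringsAsFactors = FALSE)
    }
    if (!length(ctx)) next
    ctab <- do.call(rbind, ctx)
    ctab$p_adj <- p.adjust(ctab$p_raw, method = "BH")
    rows[[length(rows) + 1]] <- ctab
  }
  if (!length(rows)) {
    stop("no pathway overlaps the universe in any context")
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$context, out$p_adj, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("EnrichmentTable", "data.frame"))
}

#' Rank enriched pathways in one context and draw a bar plot
#'
#' Orders a context's pathways by adjusted p-value (most significant first)
#' and draws a horizontal bar plot of -log10(p_adj) for the top entries.
#' The plotted (pathway, p_adj) table is returned so the ordering is
#' testable without reading the image.
#'
#' @param tab an `EnrichmentTable`.
#' @param context context key to plot (e.g. a time point).
#' @param top number of pathways to keep (clamped to the table).
#' @param out optional PNG path; NULL skips rendering.
#' @return data.frame `pathway_id`, `pathway_name`, `p_adj`, ordered by
#'   increasing `p_adj`.
#' @export
rank_and_barplot <- function(tab, context, top = 10, out = NULL) {
  if (!context %in% tab$context) stop("unknown context: ", context)
  sub <- tab[tab$context == context, , drop = FALSE]
  sub <- sub[order(sub$p_adj, sub$pathway_id), , drop = FALSE]
  sub <- head(sub, top)
  res <- data.frame(pathway_id = sub$pathway_id,
                    pathway_name = sub$pathway_name,
                    p_adj = sub$p_adj, stringsAsFactors = FALSE)
  if (!nrow(res)) warning("no enriched pathway to plot for context ", context)
  if (!is.null(out)) {
    png(out, width = 720, height = 480)
    on.exit(dev.off())
    if (nrow(res)) {
      old <- par(mar = c(5, 12, 3, 2))
      on.exit(par(old), add = TRUE, after = FALSE)
      # reverse so the most significant pathway sits on top
      barplot(rev(-log10(pmax(res$p_adj, 1e-300))),
              names.arg = rev(res$pathway_id), horiz = TRUE, las = 1,
              xlab = "-log10 adjusted p", col = "steelblue",
              main = paste("Enriched pathways:", context))
    } else {
      plot.new()
    }
  }
  res
}
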