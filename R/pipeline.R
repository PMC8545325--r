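#' Build a pipeline run configuration
#'
#' Collects every tunable of the end-to-end pipeline with the package
#' defaults: combined mode, alpha 0.05, automatic universe, Pearson
#' correlation on log2 fold changes, maximum correlation -0.5, minimum
#' database votes 1, all three databases selected. A configuration
#' round-trips to a YAML file via [write_run_config()] /
#' [read_run_config()].
#'
#' @param paths named list of input paths: `mirna_de`, `mrna_de`, `gmt`,
#'   `targetscan`, `mirdb`, `mirtarbase`, `id_map`, `out_dir`.
#' @param time_points ordered time-point labels.
#' @param mode "combined" or "separate".
#' @param alpha significance threshold.
#' @param universe "auto" or explicit gene-ID vector.
#' @param namespace pathway namespace ("entrez"/"ensembl").
#' @param pathway pathway ID to analyze; NULL selects the pathway with the
#'   smallest adjusted p summed over contexts.
#' @param clustering list(c, m, seed, tol, max_iter) for pathway-trajectory
#'   soft clustering; `c = 0` disables the clustering stage.
#' @param filter list(max_corr, min_dbs, method, databases).
#' @param export character subset of c("graphml", "sif", "pathvisio").
#' @param highlight_threshold gene-trend highlight threshold.
#' @param log_level "info" or "quiet".
#' @return object of class `RunConfig` (a named list).
#' @export
run_config <- function(paths, time_points,
                       mode = "combined", alpha = 0.05,
                       universe = "auto", namespace = "entrez",
                       pathway = NULL,
                       clustering = list(),
                       filter = list(),
                       export = c("graphml", "sif", "pathvisio"),
                       highlight_threshold = 1.5,
                       log_level = "info") {
  cl_def <- list(c = 2, m = 2, seed = 1, tol = 1e-6, max_iter = 200)
  fl_def <- list(max_corr = -0.5, min_dbs = 1, method = "pearson",
                 databases = c("targetscan", "mirdb", "mirtarbase"))
  clustering <- utils::modifyList(cl_def, clustering)
  filter <- utils::modifyList(fl_def, filter)
  need <- c("mirna_de", "mrna_de", "gmt", "targetscan", "mirdb",
            "mirtarbase", "id_map", "out_dir")
  miss <- setdiff(need, names(paths))
  if (length(miss)) stop("paths lacks: ", paste(miss, collapse = ", "))
  structure(list(paths = paths, time_points = time_points, mode = mode,
                 alpha = alpha, universe = universe, namespace = namespace,
                 pathway = pathway, clustering = clustering,
                 filter = filter, export = export,
                 highlight_threshold = highlight_threshold,
                 log_level = log_level),
            class = "RunConfig")
}

#' @rdname run_config
#' @param config a `RunConfig`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  run_config(paths = raw$paths, time_points = raw$time_points,
             mode = raw$mode %||% "combined",
             alpha = raw$alpha %||% 0.05,
             universe = raw$universe %||% "auto",
             namespace = raw$namespace %||% "entrez",
             pathway = raw$pathway,
             clustering = raw$clustering %||% list(),
             filter = raw$filter %||% list(),
             export = raw$export %||% c("graphml", "sif", "pathvisio"),
             highlight_threshold = raw$highlight_threshold %||% 1.5,
             log_level = raw$log_level %||% "info")
}

pipe_log <- function(config, ...) {
  if (!identical(config$log_level, "quiet")) {
    message("[chronomiR] ", ...)
  }
}

#' Run the pipeline end to end
#'
#' Ingest -> significance filtering -> per-time-point enrichment (and,
#' optionally, pathway-trajectory soft clustering) -> pathway selection ->
#' interaction matrix, correlation + database-vote filtering -> pair
#' statistics on every kept pair -> exports. A manifest recording the
#' package version, parameters, seeds, input checksums and output
#' checksums is written to the run directory; reruns on identical inputs
#' produce identical manifests. A failing stage aborts with a
#' stage-labeled error and retains partial outputs under `failed/`.
#'
#' @param config a [run_config()].
#' @return invisibly, list with `dir`, `manifest`, `de`, `ids`,
#'   `enrichment`, `clustering`, `pathway`, `matrix`, `network`, `pairs`.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character()
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      fail_dir <- file.path(out_dir, "failed")
      dir.create(fail_dir, showWarnings = FALSE, recursive = TRUE)
      keep <- setdiff(list.files(out_dir, full.names = TRUE), fail_dir)
      file.copy(keep, fail_dir, recursive = TRUE)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
    stages[[name]] <<- "ok"
    res
  }

  # ingest -------------------------------------------------------------
  de <- run_stage("ingest", {
    mir <- read_de_table(config$paths$mirna_de, "miRNA", config$time_points)
    mrna <- read_de_table(config$paths$mrna_de, "mRNA", config$time_points)
    bind_de(mir, mrna)
  })
  ids <- run_stage("id_mapping", map_ids(de, config$paths$id_map))
  pathways <- run_stage("pathways",
                        read_gmt(config$paths$gmt, config$namespace))
  dbs <- run_stage("databases", list(
    read_target_db(config$paths$targetscan, "targetscan"),
    read_target_db(config$paths$mirdb, "mirdb"),
    read_target_db(config$paths$mirtarbase, "mirtarbase")))

  # significance + functional analysis ---------------------------------
  sig <- run_stage("significance",
                   filter_significant(de, config$mode, config$alpha))
  enr <- run_stage("enrichment",
                   enrich_per_context(sig, pathways,
                                      universe = config$universe,
                                      ids = ids))
  clust <- NULL
  if (config$clustering$c >= 2) {
    clust <- run_stage("clustering", {
      traj <- build_pathway_trajectories(
        sig, pathways, ids = ids,
        gene_type = if (config$mode == "separate") "mRNA" else NULL)
      std <- standardize(traj)
      if (config$clustering$c < nrow(std)) {
        fuzzy_cmeans(std, c = config$clustering$c,
                     m = config$clustering$m,
                     seed = config$clustering$seed,
                     tol = config$clustering$tol,
                     max_iter = config$clustering$max_iter)
      } else {
        pipe_log(config, "too few pathway trajectories to cluster; skipped")
        NULL
      }
    })
  }

  # pathway selection ---------------------------------------------------
  pathway_id <- run_stage("pathway_selection", {
    if (!is.null(config$pathway)) {
      config$pathway
    } else {
      agg <- tapply(enr$p_adj, enr$pathway_id, sum)
      names(agg)[order(unname(agg), names(agg))][1]
    }
  })
  pipe_log(config, "selected pathway: ", pathway_id)

  # interaction filtering ------------------------------------------------
  network <- NULL
  mat <- run_stage("interaction", {
    mrnas <- pathway_mrnas(pathway_id, pathways, de, ids)
    sig_mir <- sort(unique(unlist(lapply(names(sig$sets), function(k) {
      gt <- sig$keys$gene_type[sig$keys$key == k]
      labs <- sig$sets[[k]]
      if (is.na(gt)) labs[labs %in% de$gene[de$gene_type == "miRNA"]]
      else if (gt == "miRNA") labs else character()
    }))))
    if (!length(sig_mir)) stop("no miRNA is significant at any time point")
    m <- pair_correlations(de, sig_mir, mrnas,
                           method = config$filter$method)
    apply_db_flags(m, dbs, selected = config$filter$databases)
  })
  network <- run_stage("filtering",
                       filter_interactions(mat,
                                           max_corr = config$filter$max_corr,
                                           min_dbs = config$filter$min_dbs))

  # pair statistics ------------------------------------------------------
  pairs <- run_stage("pair_analysis", {
    edges <- network_edges(network)
    if (!nrow(edges)) {
      data.frame(mirna = character(), mrna = character(), corr = numeric(),
                 slope = numeric(), odds_ratio = numeric(),
                 ci_low = numeric(), ci_high = numeric(),
                 r_squared = numeric(), p_value = numeric(),
                 stringsAsFactors = FALSE)
    } else {
      rows <- lapply(seq_len(nrow(edges)), function(i) {
        ps <- pair_series_from_de(de, edges$mirna[i], edges$mrna[i])
        fit <- suppressWarnings(pair_odds_ratio(ps))
        data.frame(mirna = edges$mirna[i], mrna = edges$mrna[i],
                   corr = edges$corr[i], slope = fit$slope,
                   odds_ratio = fit$odds_ratio,
                   ci_low = fit$ci95[1], ci_high = fit$ci95[2],
                   r_squared = fit$r_squared, p_value = fit$p_value,
                   stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, rows)
      out[order(-out$corr, out$mirna, out$mrna), , drop = FALSE]
    }
  })

  # exports ---------------------------------------------------------------
  outputs <- run_stage("export", {
    written <- character()
    enr_path <- file.path(out_dir, "enrichment.tsv")
    write_tsv_det(as.data.frame(enr), enr_path, digits = 15)
    written <- c(written, enr_path)
    if (!is.null(clust)) {
      mem_path <- file.path(out_dir, "membership.tsv")
      write_membership(clust, mem_path)
      written <- c(written, mem_path)
    }
    pair_path <- file.path(out_dir, "pair_stats.tsv")
    write_tsv_det(pairs, pair_path, digits = 15)
    written <- c(written, pair_path)
    if ("pathvisio" %in% config$export) {
      pv <- file.path(out_dir, "pathvisio_log2fc.tsv")
      write_pathvisio_data(de, ids, "log2fc", config$namespace, pv)
      fm <- file.path(out_dir, "filtered_mirnas.tsv")
      suppressWarnings(write_filtered_mirnas(network, ids, fm,
                                             config$namespace))
      written <- c(written, pv, fm)
    }
    if ("graphml" %in% config$export && igraph::ecount(network) > 0) {
      gp <- file.path(out_dir, "network.graphml")
      write_network(network, "graphml", gp)
      written <- c(written, gp)
    }
    if ("sif" %in% config$export && igraph::ecount(network) > 0) {
      sp <- file.path(out_dir, "network.sif")
      written <- c(written, write_network(network, "sif", sp))
    }
    written
  })

  manifest <- list(
    package = "chronomiR",
    version = as.character(utils::packageVersion("chronomiR")),
    parameters = unclass(config)[c("mode", "alpha", "namespace",
                                   "clustering", "filter",
                                   "highlight_threshold")],
    pathway = pathway_id,
    input_md5 = {
      p <- unlist(config$paths[c("mirna_de", "mrna_de", "gmt", "targetscan",
                                 "mirdb", "mirtarbase", "id_map")])
      as.list(stats::setNames(unname(md5sum(p)), basename(p)))
    },
    stages = as.list(stages),
    outputs = as.list(stats::setNames(unname(md5sum(outputs)),
                                      basename(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(dir = out_dir, manifest = manifest, de = de, ids = ids,
                 enrichment = enr, clustering = clust,
                 pathway = pathway_id, matrix = mat, network = network,
                 pairs = pairs))
}
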