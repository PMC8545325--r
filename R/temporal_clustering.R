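#' Build per-pathway trajectories of significant-gene counts
#'
#' For each pathway and each time point, counts how many genes significant
#' at that time point are members of the pathway. In separate mode the count
#' is computed for one declared gene type.
#'
#' @param sig a `SignificantSets`.
#' @param pathways a `PathwaySet`.
#' @param ids optional `IDMap` translating gene labels to the pathway
#'   namespace (NULL: labels already are namespace IDs).
#' @param gene_type for separate-mode sets, which gene type to count.
#' @return object of class `TrajectoryMatrix`: numeric matrix, one row per
#'   pathway, one column per time point, with attributes `time_points` and
#'   `standardized = FALSE`.
#' @export
build_pathway_trajectories <- function(sig, pathways, ids = NULL,
                                       gene_type = NULL) {
  tps <- sig$time_points
  if (length(tps) < 2) stop("at least 2 time points are required")
  ns <- pathways$namespace
  mat <- matrix(0, nrow = length(pathways$id), ncol = length(tps),
                dimnames = list(pathways$id, tps))
  for (tp in tps) {
    if (sig$mode == "combined") {
      key <- tp
    } else {
      if (is.null(gene_type)) {
        stop("separate-mode sets need gene_type ('miRNA' or 'mRNA')")
      }
      key <- paste(tp, gene_type, sep = "|")
    }
    sig_ids <- translate_labels(sig$sets[[key]], ids, ns)
    for (pi in seq_along(pathways$id)) {
      mat[pi, tp] <- length(intersect(sig_ids, pathways$members[[pi]]))
    }
  }
  if (all(mat == 0)) stop("no pathway overlaps any time point")
  trajectory_matrix(mat, tps, standardized = FALSE)
}

trajectory_matrix <- function(mat, time_points, standardized = FALSE,
                              dropped = character()) {
  structure(mat, time_points = time_points, standardized = standardized,
            dropped = dropped, class = c("TrajectoryMatrix", "matrix", "array"))
}

#' Row-standardize a trajectory matrix
#'
#' Transforms each row to (x - mean) / sd using the sample (n - 1) standard
#' deviation, the convention of soft-clustering preprocessing for expression
#' time courses. Zero-variance rows cannot be standardized; they are dropped
#' and listed in the `dropped` attribute (with a warning).
#'
#' @param traj a `TrajectoryMatrix`.
#' @return standardized `TrajectoryMatrix` (rows mean 0, sd 1).
#' @export
standardize <- function(traj) {
  mat <- unclass(traj)
  attributes(mat) <- attributes(mat)[c("dim", "dimnames")]
  sds <- apply(mat, 1, sd)
  keep <- sds > 0
  if (!any(keep)) stop("every row has zero variance; nothing to standardize")
  dropped <- rownames(mat)[!keep]
  if (length(dropped)) {
    warning("dropped zero-variance row(s): ", paste(dropped, collapse = ", "))
  }
  mat <- mat[keep, , drop = FALSE]
  out <- t(apply(mat, 1, function(x) (x - mean(x)) / sd(x)))
  dimnames(out) <- dimnames(mat)
  trajectory_matrix(out, attr(traj, "time_points"), standardized = TRUE,
                    dropped = c(attr(traj, "dropped"), dropped))
}

#' Fuzzy c-means soft clustering of trajectories
#'
#' Alternating-update fuzzy c-means on row-standardized trajectories.
#' Memberships follow u_ic = 1 / sum_c' (d_ic / d_ic')^(2/(m-1)) with d the
#' Euclidean distance to the cluster center; centers are the u^m-weighted
#' row means. A row coincident with a center (d = 0) receives membership 1
#' there. Centers are initialized as `c` distinct rows sampled without
#' replacement under `seed`, and iteration stops when the largest center
#' coordinate change falls below `tol` or after `max_iter` iterations (in
#' which case `converged = FALSE` with a warning). The per-iteration
#' objective sum_i sum_c u_ic^m d_ic^2 is recorded and is non-increasing.
#'
#' @param traj standardized `TrajectoryMatrix`.
#' @param c number of clusters (2 <= c < rows).
#' @param m fuzzifier > 1; 2 by default. Smaller m sharpens memberships
#'   towards hard clustering.
#' @param seed integer seed for center initialization.
#' @param tol convergence tolerance on center movement.
#' @param max_iter iteration cap.
#' @return object of class `SoftClustering`: list with `centers` (c x T),
#'   `membership` (rows x c, rows summing to 1), `m`, `seed`, `iterations`,
#'   `converged`, `objective` (per-iteration values), `time_points`.
#' @export
fuzzy_cmeans <- function(traj, c, m = 2, seed = 1, tol = 1e-6,
                         max_iter = 200) {
  if (!isTRUE(attr(traj, "standardized"))) {
    stop("fuzzy_cmeans expects a standardized TrajectoryMatrix")
  }
  x <- unclass(traj)
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  n <- nrow(x)
  if (!(c >= 2 && c < n)) stop("need 2 <= c < number of rows (", n, ")")
  if (!(m > 1)) stop("fuzzifier m must be > 1")

  centers <- x[with_seed(seed, sample.int(n, c)), , drop = FALSE]
  rownames(centers) <- paste0("cluster_", seq_len(c))

  sq_dist <- function(x, v) {
    # n x c matrix of squared Euclidean distances
    outer(rowSums(x^2), rep(1, nrow(v))) +
      outer(rep(1, nrow(x)), rowSums(v^2)) - 2 * x %*% t(v)
  }
  memberships <- function(d2) {
    u <- matrix(0, nrow(d2), ncol(d2))
    pw <- 1 / (m - 1)
    for (i in seq_len(nrow(d2))) {
      zero <- which(d2[i, ] <= 0)
      if (length(zero)) {
        u[i, zero[1]] <- 1
      } else {
        w <- d2[i, ]^(-pw)
        u[i, ] <- w / sum(w)
      }
    }
    u
  }

  objective <- numeric(0)
  converged <- FALSE
  iter <- 0
  u <- NULL
  while (iter < max_iter) {
    iter <- iter + 1
    d2 <- pmax(sq_dist(x, centers), 0)
    u <- memberships(d2)
    objective <- c(objective, sum(u^m * d2))
    um <- u^m
    new_centers <- (t(um) %*% x) / colSums(um)
    delta <- max(abs(new_centers - centers))
    rownames(new_centers) <- rownames(centers)
    centers <- new_centers
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("fuzzy c-means did not converge in ", max_iter, " iterations")
  }
  dimnames(u) <- list(rownames(x), rownames(centers))
  colnames(centers) <- colnames(x)
  structure(list(centers = centers, membership = u, c = c, m = m,
                 seed = seed, iterations = iter, converged = converged,
                 objective = objective,
                 time_points = attr(traj, "time_points")),
            class = "SoftClustering")
}

#' @export
print.SoftClustering <- function(x, ...) {
  cat("SoftClustering: ", nrow(x$membership), " rows x ", x$c,
      " clusters (m = ", x$m, ", ", x$iterations, " iterations, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  invisible(x)
}

#' Filter rows by cluster membership
#'
#' Returns the row IDs whose membership in the chosen cluster is at least
#' `min_membership`, sorted by decreasing membership with ties broken by
#' lexicographic row ID.
#'
#' @param clust a `SoftClustering`.
#' @param cluster_id cluster index or name (e.g. "cluster_1").
#' @param min_membership threshold in \[0, 1\].
#' @return character vector of row IDs.
#' @export
filter_by_membership <- function(clust, cluster_id, min_membership) {
  if (!(is.numeric(min_membership) && length(min_membership) == 1 &&
        min_membership >= 0 && min_membership <= 1)) {
    stop("min_membership must be in [0, 1]")
  }
  u <- clust$membership[, cluster_id]
  ids <- rownames(clust$membership)
  keep <- u >= min_membership
  ids <- ids[keep]
  u <- u[keep]
  ids[order(-u, ids)]
}

#' Cluster gene trajectories, then enrich per cluster
#'
#' For whole-course (non-pairwise) differential-expression input: genes
#' already filtered for significance over the course are soft-clustered on
#' their standardized trajectories, hard-assigned to their maximum-
#' membership cluster (ties go to the lower-indexed cluster, with a
#' message), and each cluster's gene set is tested for pathway
#' overrepresentation.
#'
#' @param gene_traj `TrajectoryMatrix` of gene-level trajectories (rows are
#'   gene IDs; averaged counts or expression).
#' @param pathways a `PathwaySet`.
#' @param c number of clusters; `c = 1` skips clustering and enriches the
#'   whole gene list as one context.
#' @param m fuzzifier.
#' @param seed integer seed.
#' @param universe universe gene IDs (or "auto" with `ids`).
#' @param ids optional `IDMap`.
#' @return an `EnrichmentTable` with cluster IDs as contexts; the
#'   `SoftClustering` (or NULL when c = 1) is attached as attribute
#'   `clustering`.
#' @export
cluster_genes_then_enrich <- function(gene_traj, pathways, c, m = 2,
                                      seed = 1, universe = "auto",
                                      ids = NULL) {
  if (c == 1) {
    sets <- list(cluster_1 = rownames(gene_traj))
    tab <- enrich_per_context(sets, pathways, universe = universe, ids = ids)
    attr(tab, "clustering") <- NULL
    return(tab)
  }
  std <- if (isTRUE(attr(gene_traj, "standardized"))) gene_traj else
    standardize(gene_traj)
  cl <- fuzzy_cmeans(std, c = c, m = m, seed = seed)
  u <- cl$membership
  assign <- apply(u, 1, which.max)  # ties resolve to the lower index
  tie <- apply(u, 1, function(r) sum(r == max(r)) > 1)
  if (any(tie)) {
    message("tied maximum membership for: ",
            paste(rownames(u)[tie], collapse = ", "),
            " (assigned to the lower-indexed cluster)")
  }
  sets <- lapply(seq_len(c), function(ci) sort(rownames(u)[assign == ci]))
  names(sets) <- colnames(u)
  sets <- sets[lengths(sets) > 0]
  tab <- enrich_per_context(sets, pathways, universe = universe, ids = ids)
  attr(tab, "clustering") <- cl
  tab
}

#' Write / read trajectory and membership matrices as TSV
#'
#' Row-ID first column, one column per time point (trajectories) or per
#' cluster (memberships); values at 15 significant digits so matrices
#' round-trip.
#'
#' @param traj a `TrajectoryMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  df <- data.frame(id = rownames(traj), as.data.frame(unclass(traj)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_det(df, path, digits = 15)
}

#' @rdname write_trajectories
#' @param standardized flag recorded on the read-back matrix.
#' @export
read_trajectories <- function(path, standardized = FALSE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  trajectory_matrix(mat, colnames(mat), standardized = standardized)
}

#' @rdname write_trajectories
#' @param clust a `SoftClustering`.
#' @export
write_membership <- function(clust, path) {
  df <- data.frame(id = rownames(clust$membership),
                   as.data.frame(clust$membership),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_det(df, path, digits = 15)
}
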