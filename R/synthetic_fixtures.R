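#' Specification of a synthetic longitudinal miRNA-mRNA fixture
#'
#' Defines a toy dataset with planted, recorded truth at every stage:
#' a known enriched pathway at chosen time points, known temporal shapes of
#' the per-pathway significant-gene counts, and known true miRNA-mRNA
#' interactions with strongly negative trajectory correlation and database
#' support. The defaults emulate a five-day mouse kidney-injury style time
#' course at desk scale: 30 miRNAs x 60 mRNAs over D1, D2, D3, D7, D14,
#' with 10 disjoint pathways of 6 mRNAs each, the planted pathway enriched
#' at D3/D7/D14, five planted interactions supported by two databases each,
#' and Gaussian noise (sd 0.2) on the anticorrelated target trajectories so
#' planted pairs sit near correlation -0.9.
#'
#' @param seed integer seed; regeneration with the same spec is
#'   byte-identical.
#' @param n_mirna,n_mrna gene counts.
#' @param time_points ordered time-point labels.
#' @param n_pathways,pathway_size pathway layout (pathways are disjoint
#'   blocks of mRNAs, so `n_pathways * pathway_size <= n_mrna`).
#' @param planted_enriched list(pathway = index, time_points = labels):
#'   which pathway is stuffed with significant genes, and when.
#' @param planted_clusters character vector of per-pathway temporal shapes
#'   ("up", "down", "pulse"); default: first half "up", second half "down".
#' @param planted_interactions data.frame(mirna = index, mrna = index) of
#'   true interactions; default: miRNAs 1..5 paired with the first five
#'   members of the planted pathway.
#' @param noise_sd Gaussian noise sd on planted target trajectories;
#'   0 makes planted pairs exactly linear (correlation -1).
#' @param alpha significance level the padj values are planted around.
#' @return object of class `FixtureSpec`.
#' @export
fixture_spec <- function(seed = 101, n_mirna = 30, n_mrna = 60,
                         time_points = c("D1", "D2", "D3", "D7", "D14"),
                         n_pathways = 10, pathway_size = 6,
                         planted_enriched = NULL, planted_clusters = NULL,
                         planted_interactions = NULL, noise_sd = 0.2,
                         alpha = 0.05) {
  counts <- c(n_mirna = n_mirna, n_mrna = n_mrna, n_pathways = n_pathways,
              pathway_size = pathway_size)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (n_pathways * pathway_size > n_mrna) {
    stop("n_pathways * pathway_size must not exceed n_mrna")
  }
  if (length(time_points) < 2) stop("need at least 2 time points")
  planted_enriched <- planted_enriched %||%
    list(pathway = 1L, time_points = intersect(c("D3", "D7", "D14"),
                                               time_points))
  if (!all(planted_enriched$time_points %in% time_points)) {
    stop("planted_enriched time points must be on the axis")
  }
  if (planted_enriched$pathway > n_pathways) {
    stop("planted_enriched pathway index out of range")
  }
  planted_clusters <- planted_clusters %||%
    rep(c("up", "down"), c(ceiling(n_pathways / 2), floor(n_pathways / 2)))
  if (length(planted_clusters) != n_pathways ||
      !all(planted_clusters %in% c("up", "down", "pulse"))) {
    stop("planted_clusters must give one of up/down/pulse per pathway")
  }
  if (is.null(planted_interactions)) {
    npair <- min(5L, n_mirna, pathway_size)
    first_member <- (planted_enriched$pathway - 1L) * pathway_size
    planted_interactions <- data.frame(mirna = seq_len(npair),
                                       mrna = first_member + seq_len(npair))
  }
  if (any(planted_interactions$mirna > n_mirna) ||
      any(planted_interactions$mrna > n_mrna)) {
    stop("planted interaction references a nonexistent gene")
  }
  structure(list(seed = seed, n_mirna = n_mirna, n_mrna = n_mrna,
                 time_points = time_points, n_pathways = n_pathways,
                 pathway_size = pathway_size,
                 planted_enriched = planted_enriched,
                 planted_clusters = planted_clusters,
                 planted_interactions = planted_interactions,
                 noise_sd = noise_sd, alpha = alpha),
            class = "FixtureSpec")
}

# per-pathway significant-member counts over time, from the planted shape
shape_counts <- function(shape, T_, size, planted_tps_idx = integer()) {
  frac <- switch(shape,
                 up = seq(0.1, 0.9, length.out = T_),
                 down = seq(0.9, 0.1, length.out = T_),
                 pulse = {
                   mid <- (T_ + 1) / 2
                   0.1 + 0.8 * exp(-(seq_len(T_) - mid)^2 / 2)
                 })
  counts <- round(frac * 0.5 * size)
  counts[planted_tps_idx] <- pmax(counts[planted_tps_idx],
                                  round(0.8 * size))
  counts
}

#' Generate the synthetic fixture files with recorded truth
#'
#' Writes, under `out_dir`: wide DE tables (`mirna_de.tsv`,
#' `mrna_de.tsv`), `pathways.gmt` (entrez namespace), three target-
#' database tables (`targetscan.tsv`, `mirdb.tsv`, `mirtarbase.tsv`, the
#' latter with evidence strings including some "Functional MTI (Weak)"
#' rows), `id_map.tsv`, and a machine-readable `truth.json`. Planted
#' interactions get anticorrelated log2fc trajectories (mRNA = -0.8 x
#' miRNA + noise); decoy database entries are restricted to pairs whose
#' generated correlation is above -0.3, so with default thresholds the
#' filtered network recovers exactly the planted pairs.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, list(dir, files, truth) where `truth` mirrors
#'   `truth.json`.
#' @export
make_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tps <- spec$time_points
  T_ <- length(tps)

  # gene labels; miRNAs 1 and 2 are the -5p/-3p arms of one gene, sharing
  # entrez/ensembl, to exercise the adjusted-label rule
  mir_base <- 100 + c(0, 0, seq_len(max(spec$n_mirna - 2, 0)))
  arm <- c("-5p", "-3p", rep("-5p", max(spec$n_mirna - 2, 0)))
  mirnas <- sprintf("mmu-miR-%d%s", mir_base[seq_len(spec$n_mirna)],
                    arm[seq_len(spec$n_mirna)])
  mrnas <- sprintf("Gene%03d", seq_len(spec$n_mrna))

  path_ids <- sprintf("WPS%03d", seq_len(spec$n_pathways))
  path_names <- sprintf("Synthetic pathway %d", seq_len(spec$n_pathways))
  member_idx <- lapply(seq_len(spec$n_pathways), function(p) {
    (p - 1L) * spec$pathway_size + seq_len(spec$pathway_size)
  })

  mir_entrez <- as.character(20000 + mir_base[seq_len(spec$n_mirna)])
  mrna_entrez <- as.character(10000 + seq_len(spec$n_mrna))
  id_map <- data.frame(
    input_label = c(mirnas, mrnas),
    entrez = c(mir_entrez, mrna_entrez),
    ensembl = c(sprintf("ENSMUSG%011d", 20000 + mir_base[seq_len(spec$n_mirna)]),
                sprintf("ENSMUSG%011d", 10000 + seq_len(spec$n_mrna))),
    stringsAsFactors = FALSE)

  planted_p <- spec$planted_enriched$pathway
  planted_tp_idx <- match(spec$planted_enriched$time_points, tps)
  counts <- matrix(0L, spec$n_pathways, T_, dimnames = list(path_ids, tps))
  for (p in seq_len(spec$n_pathways)) {
    counts[p, ] <- shape_counts(spec$planted_clusters[p], T_,
                                spec$pathway_size,
                                if (p == planted_p) planted_tp_idx else
                                  integer())
  }

  pi_tab <- spec$planted_interactions
  planted_pairs <- data.frame(mirna = mirnas[pi_tab$mirna],
                              mrna = mrnas[pi_tab$mrna],
                              stringsAsFactors = FALSE)

  res <- with_seed(spec$seed, {
    # trajectories
    mir_traj <- matrix(rnorm(spec$n_mirna * T_, 0, 1.2), spec$n_mirna, T_,
                       dimnames = list(mirnas, tps))
    mrna_traj <- matrix(rnorm(spec$n_mrna * T_, 0, 1.2), spec$n_mrna, T_,
                        dimnames = list(mrnas, tps))
    for (r in seq_len(nrow(pi_tab))) {
      x <- mir_traj[pi_tab$mirna[r], ]
      mrna_traj[pi_tab$mrna[r], ] <- -0.8 * x +
        rnorm(T_, 0, spec$noise_sd)
    }

    # significance structure: pathway membership counts drive mRNA padj,
    # nested so counts realize exactly
    mrna_sig <- matrix(FALSE, spec$n_mrna, T_, dimnames = list(mrnas, tps))
    for (p in seq_len(spec$n_pathways)) {
      for (t in seq_len(T_)) {
        k <- counts[p, t]
        if (k > 0) mrna_sig[member_idx[[p]][seq_len(k)], t] <- TRUE
      }
    }
    mir_sig <- matrix(runif(spec$n_mirna * T_) < 0.25, spec$n_mirna, T_,
                      dimnames = list(mirnas, tps))
    mir_sig[unique(pi_tab$mirna), ] <- TRUE  # planted regulators stay on

    draw_padj <- function(sig, alpha) {
      p <- matrix(round(runif(length(sig), 0.2, 1), 6), nrow(sig), ncol(sig),
                  dimnames = dimnames(sig))
      ns <- sum(sig)
      p[sig] <- round(runif(ns, 0.001, 0.8 * alpha), 6)
      p
    }
    mir_padj <- draw_padj(mir_sig, spec$alpha)
    mrna_padj <- draw_padj(mrna_sig, spec$alpha)

    # decoy database entries only among clearly non-anticorrelated pairs
    planted_key <- paste(planted_pairs$mirna, planted_pairs$mrna)
    cor_all <- cor(t(mir_traj), t(mrna_traj))
    safe <- which(cor_all > -0.3, arr.ind = TRUE)
    safe_key <- paste(mirnas[safe[, 1]], mrnas[safe[, 2]])
    safe <- safe[!safe_key %in% planted_key, , drop = FALSE]
    n_decoy <- min(40L, nrow(safe))
    decoy <- safe[sample.int(nrow(safe), n_decoy), , drop = FALSE]
    decoy_pairs <- data.frame(mirna = mirnas[decoy[, 1]],
                              mrna = mrnas[decoy[, 2]],
                              stringsAsFactors = FALSE)
    dsplit <- sample(rep(1:3, length.out = n_decoy))
    list(mir_traj = mir_traj, mrna_traj = mrna_traj,
         mir_padj = mir_padj, mrna_padj = mrna_padj,
         mir_sig = mir_sig, mrna_sig = mrna_sig,
         decoy_pairs = decoy_pairs, dsplit = dsplit)
  })

  # --- write files ---------------------------------------------------
  de_wide <- function(genes, traj, padj) {
    df <- data.frame(gene = genes, stringsAsFactors = FALSE)
    for (t in seq_len(T_)) {
      df[[paste0("log2fc_", tps[t])]] <- traj[, t]
      df[[paste0("padj_", tps[t])]] <- padj[, t]
    }
    df
  }
  f <- list(
    mirna_de = file.path(out_dir, "mirna_de.tsv"),
    mrna_de = file.path(out_dir, "mrna_de.tsv"),
    gmt = file.path(out_dir, "pathways.gmt"),
    targetscan = file.path(out_dir, "targetscan.tsv"),
    mirdb = file.path(out_dir, "mirdb.tsv"),
    mirtarbase = file.path(out_dir, "mirtarbase.tsv"),
    id_map = file.path(out_dir, "id_map.tsv"),
    truth = file.path(out_dir, "truth.json"))

  write_tsv_det(de_wide(mirnas, res$mir_traj, res$mir_padj),
                f$mirna_de, digits = 15)
  write_tsv_det(de_wide(mrnas, res$mrna_traj, res$mrna_padj),
                f$mrna_de, digits = 15)

  gmt_lines <- vapply(seq_len(spec$n_pathways), function(p) {
    paste(c(path_names[p], path_ids[p], mrna_entrez[member_idx[[p]]]),
          collapse = "\t")
  }, character(1))
  writeLines(gmt_lines, f$gmt, sep = "\n")
  write_tsv_det(id_map, f$id_map)

  # database tables: every planted pair is in targetscan and mirtarbase
  # (two supporting databases); odd planted pairs also in mirdb
  dec <- res$decoy_pairs
  ts_pairs <- rbind(planted_pairs, dec[res$dsplit == 1, , drop = FALSE])
  mirdb_pairs <- rbind(planted_pairs[seq(1, nrow(planted_pairs), by = 2),
                                     , drop = FALSE],
                       dec[res$dsplit == 2, , drop = FALSE])
  mtb_strong <- planted_pairs
  mtb_weak <- dec[res$dsplit == 3, , drop = FALSE]
  order_pairs <- function(d) {
    names(d)[names(d) == "mrna"] <- "target"
    d <- d[order(d$mirna, d$target), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  write_tsv_det(order_pairs(ts_pairs), f$targetscan)
  write_tsv_det(order_pairs(mirdb_pairs), f$mirdb)
  mtb <- rbind(data.frame(mtb_strong, evidence = "Functional MTI",
                          stringsAsFactors = FALSE),
               data.frame(mtb_weak, evidence = "Functional MTI (Weak)",
                          stringsAsFactors = FALSE))
  write_tsv_det(order_pairs(mtb), f$mirtarbase)

  truth <- list(
    seed = spec$seed,
    time_points = tps,
    alpha = spec$alpha,
    noise_sd = spec$noise_sd,
    planted_pathway = path_ids[planted_p],
    planted_time_points = spec$planted_enriched$time_points,
    shapes = stats::setNames(as.list(spec$planted_clusters), path_ids),
    counts = counts,
    planted_pairs = planted_pairs,
    planted_pair_dbs = list(targetscan = nrow(planted_pairs),
                            mirdb = nrow(planted_pairs[seq(1,
                              nrow(planted_pairs), by = 2), , drop = FALSE]),
                            mirtarbase = nrow(planted_pairs)),
    significant_mirnas = apply(res$mir_sig, 2, function(s) mirnas[s],
                               simplify = FALSE),
    significant_mrnas = apply(res$mrna_sig, 2, function(s) mrnas[s],
                              simplify = FALSE))
  jsonlite::write_json(truth, f$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(dir = out_dir, files = f, truth = truth))
}

#' Compare pipeline results against the planted truth
#'
#' Computes: recall and precision of the filtered network's edges against
#' the planted interactions; the rank of the planted pathway in each
#' planted time point's enrichment; and the agreement between top-
#' membership cluster assignments and the planted shape groups, maximized
#' over cluster label permutations.
#'
#' @param results list with any of `network` (igraph), `enrichment`
#'   (`EnrichmentTable`), `clustering` (`SoftClustering`).
#' @param truth the truth record from [make_fixture()] (or read from
#'   `truth.json`).
#' @return list report with `interaction` (recall, precision, counts),
#'   `enrichment_rank` (named vector over planted time points),
#'   `cluster_agreement` (fraction in \[0, 1\]).
#' @export
truth_check <- function(results, truth) {
  need <- c("planted_pairs", "planted_pathway", "planted_time_points",
            "shapes")
  miss <- setdiff(need, names(truth))
  if (length(miss)) stop("truth record lacks field(s): ",
                         paste(miss, collapse = ", "))
  report <- list()

  if (!is.null(results$network)) {
    kept <- network_edges(results$network)
    kept_key <- paste(kept$mirna, kept$mrna)
    truth_pairs <- as.data.frame(truth$planted_pairs)
    true_key <- paste(truth_pairs$mirna, truth_pairs$mrna)
    tp_hits <- sum(kept_key %in% true_key)
    report$interaction <- list(
      recall = if (length(true_key)) tp_hits / length(true_key) else NA_real_,
      precision = if (length(kept_key)) tp_hits / length(kept_key)
                  else NA_real_,
      n_kept = length(kept_key), n_planted = length(true_key))
  }

  if (!is.null(results$enrichment)) {
    tab <- results$enrichment
    ranks <- vapply(unlist(truth$planted_time_points), function(tp) {
      sub <- tab[tab$time_point %in% tp | tab$context == tp, , drop = FALSE]
      if (!nrow(sub)) return(NA_real_)
      sub <- sub[order(sub$p_adj, sub$pathway_id), , drop = FALSE]
      pos <- match(truth$planted_pathway, sub$pathway_id)
      as.numeric(pos)
    }, numeric(1))
    report$enrichment_rank <- ranks
  }

  if (!is.null(results$clustering)) {
    u <- results$clustering$membership
    assign <- apply(u, 1, which.max)
    shapes <- unlist(truth$shapes)[rownames(u)]
    groups <- as.integer(factor(shapes))
    k <- max(results$clustering$c, max(groups))
    perms <- all_permutations(seq_len(k))
    agree <- max(vapply(perms, function(pm) {
      mean(pm[assign] == groups)
    }, numeric(1)))
    report$cluster_agreement <- agree
  }
  report
}

# all permutations of a small vector (used for label-invariant matching)
all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_permutations(v[-i])) {
      out[[length(out) + 1]] <- c(v[i], rest)
    }
  }
  out
}
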