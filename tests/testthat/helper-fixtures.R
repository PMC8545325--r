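# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately written from first principles (enumeration,
# direct formulas, brute-force scans) so they never share code with the
# implementation paths they check.

FIXTURE_TPS <- c("D1", "D2", "D3", "D7", "D14")

.fixture_cache <- new.env(parent = emptyenv())

# generate (once per session) a synthetic fixture directory
get_fixture <- function(noise_sd = 0.2, seed = 101) {
  key <- paste0("fx_", gsub("[.]", "p", noise_sd), "_", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  dir <- file.path(tempdir(), paste0("chronomir_", key))
  fx <- make_fixture(fixture_spec(seed = seed, noise_sd = noise_sd), dir)
  .fixture_cache[[key]] <- fx
  fx
}

# load the full input stack from a fixture directory
load_stack <- function(fx, mode = "combined", alpha = 0.05) {
  key <- paste0(fx$dir, "_", mode, "_", alpha)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  de <- bind_de(read_de_table(fx$files$mirna_de, "miRNA", FIXTURE_TPS),
                read_de_table(fx$files$mrna_de, "mRNA", FIXTURE_TPS))
  ids <- map_ids(de, fx$files$id_map)
  pathways <- read_gmt(fx$files$gmt, "entrez")
  dbs <- list(read_target_db(fx$files$targetscan, "targetscan"),
              read_target_db(fx$files$mirdb, "mirdb"),
              read_target_db(fx$files$mirtarbase, "mirtarbase"))
  sig <- filter_significant(de, mode, alpha)
  out <- list(de = de, ids = ids, pathways = pathways, dbs = dbs, sig = sig)
  .fixture_cache[[key]] <- out
  out
}

# build the default filtered network from a fixture stack
build_network <- function(stack, max_corr = -0.5, min_dbs = 1) {
  mrnas <- pathway_mrnas("WPS001", stack$pathways, stack$de, stack$ids)
  sig_mir <- sort(unique(unlist(stack$sig$sets)))
  sig_mir <- sig_mir[sig_mir %in% stack$de$gene[stack$de$gene_type == "miRNA"]]
  mat <- pair_correlations(stack$de, sig_mir, mrnas)
  mat <- apply_db_flags(mat, stack$dbs)
  list(mat = mat,
       network = suppressWarnings(
         filter_interactions(mat, max_corr = max_corr, min_dbs = min_dbs)))
}

# small in-code DE table builder (long form)
make_de <- function(genes, gene_type, tps, log2fc, padj) {
  rec <- expand.grid(gene = genes, time_point = tps,
                     stringsAsFactors = FALSE)
  rec$gene_type <- gene_type
  rec$log2fc <- as.vector(log2fc)   # genes x tps, column-major
  rec$padj <- as.vector(padj)
  time_course_de(rec, tps)
}

# --- independent oracles -------------------------------------------------

# exhaustive hypergeometric upper tail: enumerate all C(N, n) draws from a
# universe whose first K elements are pathway members
enum_hyper_tail <- function(k, K, n, N) {
  if (n == 0 || N == 0) return(if (k == 0) 1 else 0)
  draws <- combn(N, n)
  overlaps <- colSums(draws <= K)
  mean(overlaps >= k)
}

# direct Benjamini-Hochberg step-up formula
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, p[o] * m / seq_len(m))
  for (i in rev(seq_len(m - 1))) adj[i] <- min(adj[i], adj[i + 1])
  adj[order(o)]
}

# direct cross-correlation formula: full-series means, population sds,
# divisor T; positive lag shifts y later than x
ccf_oracle <- function(x, y, lag) {
  T_ <- length(x)
  sx <- sqrt(mean((x - mean(x))^2))
  sy <- sqrt(mean((y - mean(y))^2))
  t_idx <- seq(max(1, 1 - lag), min(T_, T_ - lag))
  sum((x[t_idx] - mean(x)) * (y[t_idx + lag] - mean(y))) / (T_ * sx * sy)
}

# brute-force interaction filter over the raw matrix entries
brute_filter <- function(mat, max_corr, min_dbs) {
  kept <- data.frame(mirna = character(), mrna = character(),
                     stringsAsFactors = FALSE)
  for (i in seq_along(mat$mirnas)) {
    for (j in seq_along(mat$mrnas)) {
      corr <- mat$corr[i, j]
      votes <- if (is.null(mat$votes)) 0L else mat$votes[i, j]
      if (!is.na(corr) && corr <= max_corr && votes >= min_dbs) {
        kept <- rbind(kept, data.frame(mirna = mat$mirnas[i],
                                       mrna = mat$mrnas[j],
                                       stringsAsFactors = FALSE))
      }
    }
  }
  kept[order(kept$mirna, kept$mrna), , drop = FALSE]
}

# membership update recomputed from centers with an independent formula
membership_oracle <- function(x, centers, m) {
  u <- matrix(0, nrow(x), nrow(centers))
  for (i in seq_len(nrow(x))) {
    d <- sqrt(colSums((t(centers) - x[i, ])^2))
    if (any(d == 0)) {
      u[i, which(d == 0)[1]] <- 1
    } else {
      for (ci in seq_len(nrow(centers))) {
        u[i, ci] <- 1 / sum((d[ci] / d)^(2 / (m - 1)))
      }
    }
  }
  u
}

# find a seed under which fuzzy_cmeans samples `target` as init centers
find_init_seed <- function(n, c, target) {
  for (s in 1:2000) {
    set.seed(s)
    if (identical(sort(sample.int(n, c)), as.integer(sort(target)))) return(s)
  }
  stop("no init seed found")
}

edge_table <- function(network) chronomiR:::network_edges(network)
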