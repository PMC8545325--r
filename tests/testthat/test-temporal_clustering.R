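# helper: a significant-sets object realizing given per-time-point gene sets
sets_from_lists <- function(sets, tps) {
  genes <- unique(unlist(sets))
  padj <- matrix(1, length(genes), length(tps),
                 dimnames = list(genes, tps))
  for (t in seq_along(tps)) padj[genes %in% sets[[t]], t] <- 0.01
  de <- make_de(genes, "mRNA", tps, matrix(0, length(genes), length(tps)),
                padj)
  filter_significant(de, "combined", 0.05)
}

test_that("pathway trajectories count significant members per time point", {
  tps <- c("D1", "D2", "D3")
  sig <- sets_from_lists(list("G1", c("G1", "G2"), c("G1", "G2", "G3")), tps)
  f <- tempfile(fileext = ".gmt")
  writeLines(c("P\tWP1\tG1\tG2\tG3", "Q\tWP2\tZ1\tZ2"), f)
  ps <- read_gmt(f, "entrez")
  traj <- build_pathway_trajectories(sig, ps)
  expect_equal(unname(traj["WP1", ]), c(1, 2, 3))
  # disjoint pathway stays all-zero, then drops at standardization
  expect_equal(unname(traj["WP2", ]), c(0, 0, 0))
  std <- suppressWarnings(standardize(traj))
  expect_false("WP2" %in% rownames(std))
  expect_true("WP2" %in% attr(std, "dropped"))
})

test_that("fixture trajectories equal the planted counts exactly", {
  fx <- get_fixture()
  stack <- load_stack(fx)
  traj <- build_pathway_trajectories(stack$sig, stack$pathways,
                                     ids = stack$ids)
  expect_equal(unclass(traj)[rownames(fx$truth$counts), ],
               fx$truth$counts + 0, ignore_attr = TRUE)
})

test_that("standardization gives mean-0 sd-1 rows and is idempotent", {
  tps <- c("T1", "T2", "T3")
  sig <- sets_from_lists(list("G1", c("G1", "G2"), c("G1", "G2", "G3")), tps)
  f <- tempfile(fileext = ".gmt")
  writeLines(c("P\tWP1\tG1\tG2\tG3", "C\tWP3\tG1"), f)
  traj <- build_pathway_trajectories(sig, read_gmt(f, "entrez"))
  # (1,2,3) -> (-1,0,1) under the sample-sd convention
  std <- suppressWarnings(standardize(traj))
  expect_equal(unname(std["WP1", ]), c(-1, 0, 1))
  # constant row (1,1,1) for the singleton pathway is dropped and reported
  expect_warning(standardize(traj), "WP3")
  expect_equal(apply(std, 1, mean), rep(0, nrow(std)), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(apply(std, 1, sd), rep(1, nrow(std)), ignore_attr = TRUE,
               tolerance = 1e-9)
  # idempotence
  again <- standardize(std)
  expect_equal(unclass(again), unclass(std), tolerance = 1e-9)

  const <- make_de(c("A", "B"), "mRNA", tps, matrix(0, 2, 3),
                   matrix(0.01, 2, 3))
  sig_const <- filter_significant(const, "combined", 0.05)
  f2 <- tempfile(fileext = ".gmt")
  writeLines("P\tWPC\tA\tB", f2)
  traj_const <- build_pathway_trajectories(sig_const, read_gmt(f2, "entrez"))
  expect_error(suppressWarnings(standardize(traj_const)), "zero variance")
})

test_that("membership rules: coincident rows and equidistant rows", {
  rows <- rbind(A = c(1, 2, 3), B = c(3, 2, 1), C = c(1, 3, 1),
                D = c(1, 2, 10))
  std <- standardize(chronomiR:::trajectory_matrix(rows, c("T1", "T2", "T3")))
  seed <- find_init_seed(4, 2, c(1, 2))
  res <- suppressWarnings(fuzzy_cmeans(std, c = 2, m = 2, seed = seed,
                                       max_iter = 1))
  # rows A and B coincide with the initial centers: membership exactly 1
  expect_equal(max(res$membership["A", ]), 1)
  expect_equal(max(res$membership["B", ]), 1)
  # C is equidistant from the two centers by symmetry: (0.5, 0.5)
  expect_equal(unname(res$membership["C", ]), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("soft clustering recovers planted shapes and behaves numerically", {
  fx <- get_fixture()
  stack <- load_stack(fx)
  traj <- build_pathway_trajectories(stack$sig, stack$pathways,
                                     ids = stack$ids)
  std <- standardize(traj)
  cl <- fuzzy_cmeans(std, c = 2, m = 2, seed = 5)
  expect_true(cl$converged)
  # memberships are proper: rows sum to 1, all in [0,1]
  expect_equal(unname(rowSums(cl$membership)),
               rep(1, nrow(cl$membership)), tolerance = 1e-9)
  expect_true(all(cl$membership >= 0 & cl$membership <= 1))
  # the objective never increases across iterations
  expect_true(all(diff(cl$objective) <= 1e-12))
  # top-membership clusters match the planted up/down shape groups
  rep <- truth_check(list(clustering = cl), fx$truth)
  expect_equal(rep$cluster_agreement, 1.0)
  # converged memberships agree with an independent single-step update
  x <- unclass(std); attributes(x) <- attributes(x)[c("dim", "dimnames")]
  expect_equal(unname(cl$membership),
               unname(membership_oracle(x, cl$centers, 2)),
               tolerance = 1e-3)
  # seeded runs are bit-reproducible; other seeds give the same partition
  expect_identical(cl, fuzzy_cmeans(std, c = 2, m = 2, seed = 5))
  cl2 <- fuzzy_cmeans(std, c = 2, m = 2, seed = 42)
  a1 <- apply(cl$membership, 1, which.max)
  a2 <- apply(cl2$membership, 1, which.max)
  expect_true(all(a1 == a2) || all(a1 == 3 - a2))
  # m -> 1+ sharpens memberships towards hard clustering
  ent <- function(u) -mean(rowSums(u * log(pmax(u, 1e-300))))
  sharp <- fuzzy_cmeans(std, c = 2, m = 1.05, seed = 5)
  soft <- fuzzy_cmeans(std, c = 2, m = 3, seed = 5)
  expect_lt(ent(sharp$membership), ent(soft$membership))

  expect_error(fuzzy_cmeans(std, c = nrow(std), m = 2, seed = 1), "c <")
  expect_error(fuzzy_cmeans(traj, c = 2, m = 2, seed = 1), "standardized")
  expect_error(fuzzy_cmeans(std, c = 2, m = 1, seed = 1), "m must be")
})

test_that("fuzzy c-means agrees with an independent library implementation", {
  set.seed(1)
  mat <- rbind(matrix(rep(c(0, 1, 2, 3, 4), 5), 5, byrow = TRUE) +
                 rnorm(25, 0, 0.1),
               matrix(rep(c(4, 3, 2, 1, 0), 5), 5, byrow = TRUE) +
                 rnorm(25, 0, 0.1))
  rownames(mat) <- paste0("r", 1:10)
  std <- standardize(chronomiR:::trajectory_matrix(mat, paste0("T", 1:5)))
  cl <- fuzzy_cmeans(std, c = 2, m = 2, seed = 3, tol = 1e-9)
  x <- unclass(std)
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  set.seed(3)
  init <- x[sample.int(10, 2), ]
  em <- e1071::cmeans(x, centers = init, m = 2, iter.max = 500,
                      method = "cmeans")
  d <- as.matrix(dist(rbind(cl$centers, em$centers)))[1:2, 3:4]
  perm <- apply(d, 1, which.min)
  expect_equal(sort(unname(perm)), 1:2)  # centers pair off one-to-one
  expect_equal(unname(cl$membership), unname(em$membership[, perm]),
               tolerance = 1e-6)
})

test_that("membership filtering sorts and respects bounds", {
  u <- rbind(A = c(0.9, 0.1), B = c(0.6, 0.4), C = c(0.3, 0.7))
  colnames(u) <- c("cluster_1", "cluster_2")
  cl <- structure(list(membership = u, c = 2), class = "SoftClustering")
  expect_equal(filter_by_membership(cl, "cluster_1", 0.5), c("A", "B"))
  expect_equal(filter_by_membership(cl, "cluster_1", 0), c("A", "B", "C"))
  expect_equal(filter_by_membership(cl, "cluster_1", 1), character(0))
  # ties break lexicographically
  u2 <- rbind(Z = c(0.8, 0.2), A = c(0.8, 0.2))
  colnames(u2) <- colnames(u)
  cl2 <- structure(list(membership = u2, c = 2), class = "SoftClustering")
  expect_equal(filter_by_membership(cl2, "cluster_1", 0.5), c("A", "Z"))
  expect_error(filter_by_membership(cl, "cluster_1", 1.5), "\\[0, 1\\]")
})

test_that("gene-level clustering feeds per-cluster enrichment", {
  # genes of pathway WP1 rise, genes of WP2 fall; two clean clusters
  tps <- c("T1", "T2", "T3", "T4")
  up <- t(sapply(1:4, function(i) c(0, 1, 2, 3) + i * 0.01))
  down <- t(sapply(1:4, function(i) c(3, 2, 1, 0) + i * 0.01))
  mat <- rbind(up, down)
  rownames(mat) <- c(paste0("U", 1:4), paste0("Dn", 1:4))
  traj <- chronomiR:::trajectory_matrix(mat, tps)
  f <- tempfile(fileext = ".gmt")
  writeLines(c("Up set\tWP1\tU1\tU2\tU3\tU4",
               "Down set\tWP2\tDn1\tDn2\tDn3\tDn4"), f)
  ps <- read_gmt(f, "entrez")
  uni <- rownames(mat)
  tab <- cluster_genes_then_enrich(traj, ps, c = 2, seed = 3, universe = uni)
  # each cluster's top pathway is the one it was built from
  for (ctx in unique(tab$context)) {
    sub <- tab[tab$context == ctx, ]
    top <- sub$pathway_id[which.min(sub$p_adj)]
    expect_equal(sub$k[sub$pathway_id == top], 4)
  }
  expect_setequal(
    vapply(unique(tab$context),
           function(ctx) tab$pathway_id[tab$context == ctx][
             which.min(tab$p_adj[tab$context == ctx])],
           character(1)),
    c("WP1", "WP2"))

  # c = 1 degenerates to whole-course enrichment
  tab1 <- cluster_genes_then_enrich(traj, ps, c = 1, universe = uni)
  whole <- enrich_per_context(list(cluster_1 = rownames(mat)), ps,
                              universe = uni)
  expect_equal(as.data.frame(tab1), as.data.frame(whole))
})

test_that("trajectory matrices round-trip through TSV", {
  fx <- get_fixture()
  stack <- load_stack(fx)
  traj <- build_pathway_trajectories(stack$sig, stack$pathways,
                                     ids = stack$ids)
  f <- tempfile(fileext = ".tsv")
  write_trajectories(traj, f)
  back <- read_trajectories(f)
  expect_equal(unclass(back), unclass(traj), ignore_attr = TRUE)

  cl <- fuzzy_cmeans(standardize(traj), c = 2, m = 2, seed = 5)
  f2 <- tempfile(fileext = ".tsv")
  write_membership(cl, f2)
  mem <- read.delim(f2, check.names = FALSE)
  expect_equal(as.matrix(mem[, -1]), cl$membership, ignore_attr = TRUE,
               tolerance = 1e-12)
})
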