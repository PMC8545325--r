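# small 3-time-point world used by several blocks
tiny_world <- function() {
  tps <- c("T1", "T2", "T3")
  de <- bind_de(
    make_de(c("miR-a", "miR-b"), "miRNA", tps,
            rbind(c(1, 2, 3), c(0.5, 0.1, 0.9)),
            matrix(0.01, 2, 3)),
    make_de(c("Gapdh", "Igf1", "Plau"), "mRNA", tps,
            rbind(c(2, 2, 2), c(-1, -2, -3), c(3, 1, 2)),
            matrix(0.01, 3, 3)))
  f <- tempfile(fileext = ".gmt")
  writeLines("Fibrosis-like\tWPX\tPlau\tIgf1\tTnf", f)
  list(de = de, pathways = read_gmt(f, "entrez"), tps = tps)
}

test_that("pathway mRNAs are the sorted intersection with input data", {
  w <- tiny_world()
  expect_equal(pathway_mrnas("WPX", w$pathways, w$de), c("Igf1", "Plau"))
  expect_error(pathway_mrnas("nope", w$pathways, w$de), "unknown pathway")

  # namespace mismatch leaves an empty intersection -> hard error
  f <- tempfile(fileext = ".tsv")
  writeLines(c("input_label\tentrez\tensembl",
               "Igf1\t16000\tENSMUSG00000020053",
               "Plau\t18792\tENSMUSG00000021822"), f)
  ids <- map_ids(w$de, f)
  expect_error(pathway_mrnas("WPX", w$pathways, w$de, ids),
               "another pathway")
})

test_that("pair correlations match the closed-form coefficients", {
  w <- tiny_world()
  # miR-a = (1,2,3); Igf1 = (-1,-2,-3): perfect anticorrelation
  mat <- suppressWarnings(
    pair_correlations(w$de, c("miR-a", "miR-b"), c("Gapdh", "Igf1", "Plau")))
  expect_equal(mat$corr["miR-a", "Igf1"], -1.0)
  # Kendall on x=(1,2,3), y=(3,1,2): one concordant, two discordant pairs
  matk <- suppressWarnings(
    pair_correlations(w$de, "miR-a", "Plau", method = "kendall"))
  expect_equal(matk$corr["miR-a", "Plau"], -1 / 3, tolerance = 1e-12)
  # zero-variance trajectory (Gapdh) is marked unavailable with a warning
  expect_warning(pair_correlations(w$de, "miR-a", "Gapdh"), "Gapdh")
  expect_true(is.na(mat$corr["miR-a", "Gapdh"]))
  expect_false(mat$available["miR-a", "Gapdh"])

  # Spearman is 1 on a monotone map, and equals Pearson on ranks
  tps4 <- c("T1", "T2", "T3", "T4")
  de4 <- bind_de(
    make_de("miR-x", "miRNA", tps4, matrix(c(1, 2, 3, 4), 1), matrix(0.01, 1, 4)),
    make_de("Gy", "mRNA", tps4, matrix(c(1, 4, 9, 16), 1), matrix(0.01, 1, 4)))
  ms <- suppressWarnings(
    pair_correlations(de4, "miR-x", "Gy", method = "spearman"))
  expect_equal(ms$corr["miR-x", "Gy"], 1.0)
  expect_equal(ms$corr["miR-x", "Gy"],
               cor(rank(c(1, 2, 3, 4)), rank(c(1, 4, 9, 16))))

  # all coefficients stay within [-1, 1]
  fx <- get_fixture()
  stack <- load_stack(fx)
  net <- build_network(stack)
  expect_true(all(abs(net$mat$corr[net$mat$available]) <= 1 + 1e-9))

  # fewer than three time points is a hard error
  tps2 <- c("T1", "T2")
  de2 <- bind_de(
    make_de("miR-x", "miRNA", tps2, matrix(1:2, 1), matrix(0.01, 1, 2)),
    make_de("Gy", "mRNA", tps2, matrix(2:1, 1), matrix(0.01, 1, 2)))
  expect_error(pair_correlations(de2, "miR-x", "Gy"),
               "fewer than three time points")
})

test_that("database flags and votes follow the selection", {
  w <- tiny_world()
  mat <- suppressWarnings(
    pair_correlations(w$de, c("miR-a", "miR-b"), c("Igf1", "Plau")))
  mk_db <- function(name, rows, evidence = FALSE) {
    f <- tempfile(fileext = ".tsv")
    if (evidence) {
      writeLines(c("mirna\ttarget\tevidence",
                   vapply(rows, function(r) paste(c(r, "Functional MTI"),
                                                  collapse = "\t"),
                          character(1))), f)
    } else {
      writeLines(c("mirna\ttarget",
                   vapply(rows, paste, character(1), collapse = "\t")), f)
    }
    read_target_db(f, name)
  }
  dbs <- list(mk_db("targetscan", list(c("miR-a", "Igf1"))),
              mk_db("mirdb", list()),
              mk_db("mirtarbase", list(c("miR-a", "Igf1")), evidence = TRUE))

  all3 <- apply_db_flags(mat, dbs)
  expect_equal(all3$votes["miR-a", "Igf1"], 2)
  expect_equal(unname(vapply(all3$flags, function(f) f["miR-a", "Igf1"],
                             integer(1))),
               c(1L, 0L, 1L))
  # selection restricts the vote even when other flags are set
  only_mirdb <- apply_db_flags(mat, dbs, selected = "mirdb")
  expect_equal(only_mirdb$votes["miR-a", "Igf1"], 0)
  # empty database contributes all-zero flags
  expect_true(all(all3$flags$mirdb == 0))
  expect_error(apply_db_flags(mat, dbs, selected = "starbase"), "not loaded")
})

test_that("interaction filtering applies both thresholds inclusively", {
  # hand-built matrix: three pairs with (corr, votes) =
  # (-0.9, 2), (-0.4, 3), (-0.8, 0)
  mat <- structure(list(
    mirnas = c("m1", "m2", "m3"), mrnas = c("g1"),
    corr = matrix(c(-0.9, -0.4, -0.8), 3, 1,
                  dimnames = list(c("m1", "m2", "m3"), "g1")),
    available = matrix(TRUE, 3, 1),
    flags = list(dbA = matrix(c(1L, 1L, 0L), 3, 1),
                 dbB = matrix(c(1L, 1L, 0L), 3, 1),
                 dbC = matrix(c(0L, 1L, 0L), 3, 1)),
    votes = matrix(c(2L, 3L, 0L), 3, 1,
                   dimnames = list(c("m1", "m2", "m3"), "g1")),
    selected_dbs = c("dbA", "dbB", "dbC"),
    traj = NULL, method = "pearson", value = "log2fc",
    time_points = c("T1", "T2", "T3")), class = "InteractionMatrix")

  net <- filter_interactions(mat)  # defaults: max_corr -0.5, min_dbs 1
  ed <- edge_table(net)
  expect_equal(nrow(ed), 1)
  expect_equal(ed$mirna, "m1")
  expect_equal(ed$corr, -0.9)
  expect_equal(ed$votes, 2L)
  # matches the independent brute-force scan
  expect_equal(ed[, c("mirna", "mrna")], brute_filter(mat, -0.5, 1),
               ignore_attr = TRUE)

  # vacuous filter keeps every available pair
  net_all <- filter_interactions(mat, max_corr = 1.0, min_dbs = 0)
  expect_equal(nrow(edge_table(net_all)), 3)

  # the correlation boundary is inclusive
  mat$corr["m2", "g1"] <- -0.5
  net_b <- filter_interactions(mat)
  expect_true("m2" %in% edge_table(net_b)$mirna)
})

test_that("filtering is anti-monotone in both thresholds and bipartite", {
  fx <- get_fixture()
  stack <- load_stack(fx)
  nets <- build_network(stack)
  key <- function(net) {
    ed <- edge_table(net)
    paste(ed$mirna, ed$mrna)
  }
  base <- key(nets$network)
  stricter_corr <- key(suppressWarnings(
    filter_interactions(nets$mat, max_corr = -0.95, min_dbs = 1)))
  stricter_dbs <- key(suppressWarnings(
    filter_interactions(nets$mat, max_corr = -0.5, min_dbs = 2)))
  looser <- key(suppressWarnings(
    filter_interactions(nets$mat, max_corr = -0.2, min_dbs = 0)))
  expect_true(all(stricter_corr %in% base))
  expect_true(all(stricter_dbs %in% base))
  expect_true(all(base %in% looser))
  # bipartite by construction
  expect_true(igraph::bipartite_mapping(nets$network)$res)
  ed <- edge_table(nets$network)
  vt <- igraph::V(nets$network)$node_type
  names(vt) <- igraph::V(nets$network)$name
  expect_true(all(vt[ed$mirna] == "miRNA" & vt[ed$mrna] == "mRNA"))
})

test_that("gene trends highlight threshold crossings", {
  tps <- c("T1", "T2", "T3")
  de <- bind_de(
    make_de("miR-a", "miRNA", tps, matrix(c(0.2, 1.6, 0.4), 1),
            matrix(0.01, 1, 3)),
    make_de("Plau", "mRNA", tps, matrix(c(-0.2, -1.6, -0.4), 1),
            matrix(0.01, 1, 3)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = "miR-a", to = "Plau", corr = -1, votes = 1L),
    directed = FALSE,
    vertices = data.frame(name = c("miR-a", "Plau"),
                          node_type = c("miRNA", "mRNA")))
  tr <- gene_trends(de, g, highlight_threshold = 1.5)
  # (0.2, 1.6, 0.4) crosses 1.5; the signed rule ignores -1.6
  expect_true(tr$highlighted[tr$gene == "miR-a"])
  expect_false(tr$highlighted[tr$gene == "Plau"])
  tr2 <- gene_trends(de, g, highlight_threshold = 2)
  expect_false(any(tr2$highlighted))
  expect_error(gene_trends(de, g, highlight_threshold = NA), "finite")
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_warning(tr3 <- gene_trends(de, empty, 1.5), "empty")
  expect_equal(nrow(tr3), 0)
})

test_that("network gene clustering recovers shapes and edge cases", {
  fx <- get_fixture()
  stack <- load_stack(fx)
  net <- build_network(stack)$network
  genes <- sort(igraph::V(net)$name)
  k <- 2
  res <- cluster_network_genes(stack$de, net, k = k)
  expect_setequal(res$order, genes)
  expect_setequal(names(res$labels), genes)
  expect_equal(sort(unique(res$labels)), 1:2)
  # planted pairs anticorrelate, so each miRNA and its target split across
  # the two clusters
  truth_pairs <- as.data.frame(fx$truth$planted_pairs)
  in_net <- truth_pairs[truth_pairs$mirna %in% genes &
                          truth_pairs$mrna %in% genes, ]
  expect_true(all(res$labels[in_net$mirna] != res$labels[in_net$mrna]))
  # heatmap rows follow the dendrogram leaf order
  expect_equal(rownames(res$heatmap), res$order)

  # identical trajectories merge first (height 0)
  tps <- c("T1", "T2", "T3")
  de <- bind_de(
    make_de(c("miR-a", "miR-b"), "miRNA", tps,
            rbind(c(1, 2, 3), c(1, 2, 3)), matrix(0.01, 2, 3)),
    make_de("Plau", "mRNA", tps, matrix(c(3, 1, 0), 1), matrix(0.01, 1, 3)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("miR-a", "miR-b"), to = "Plau",
               corr = -0.9, votes = 1L),
    directed = FALSE,
    vertices = data.frame(name = c("miR-a", "miR-b", "Plau"),
                          node_type = c("miRNA", "miRNA", "mRNA")))
  r2 <- cluster_network_genes(de, g, k = 2)
  expect_equal(r2$hclust$height[1], 0)
  expect_equal(r2$labels[["miR-a"]], r2$labels[["miR-b"]])
  # k = number of genes gives singletons; k beyond that errors
  r3 <- cluster_network_genes(de, g, k = 3)
  expect_equal(length(unique(r3$labels)), 3)
  expect_error(cluster_network_genes(de, g, k = 4), "exceeds")
})
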