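fake_de <- function(features, adj, raw = adj) {
  structure(data.frame(feature = features, logFC = 1, FC_magnitude = 2,
                       direction = "up", t = 1, P.Value = raw,
                       adj.P.Val = adj, df.total = 10, n.obs = 10,
                       skipped = FALSE, stringsAsFactors = FALSE),
            class = c("DEResult", "data.frame"))
}

test_that("top-N selection ranks by adjusted then raw p then feature ID", {
  de <- fake_de(c("B", "A", "C", "D"), adj = c(0.2, 0.2, 0.01, 0.2),
                raw = c(0.05, 0.2, 0.001, 0.05))
  expect_identical(select_top_n(de, 3), c("C", "B", "D"))
  # all ties -> lexicographic, deterministic
  de2 <- fake_de(c("Z", "Y", "X"), adj = 0.5)
  expect_identical(select_top_n(de2, 2), c("X", "Y"))
  expect_identical(select_top_n(de2, 3), c("X", "Y", "Z"))
  expect_error(select_top_n(de2, 4), "exceeds")
  expect_error(select_top_n(de2, 1), ">= 2")
})

test_that("correlation graphs carry |r| weights and 1/|r| distances", {
  set.seed(61)
  x <- rnorm(20)
  v <- rbind(A = x, B = 2 * x + 3, C = -x, D = rnorm(20))
  colnames(v) <- paste0("S", 1:20)
  g <- correlation_graph(omics_matrix(v, "proteomics"), c("A", "B", "C", "D"))
  expect_equal(g$r["A", "B"], 1, tolerance = 1e-12)
  expect_equal(g$r["A", "C"], -1, tolerance = 1e-12)
  ed <- graph_edges(g)
  ab <- ed[ed$node1 == "A" & ed$node2 == "B", ]
  ac <- ed[ed$node1 == "A" & ed$node2 == "C", ]
  expect_equal(ab$weight, 1); expect_equal(ab$distance, 1)
  expect_equal(ac$weight, 1); expect_equal(ac$distance, 1)

  # low pairwise overlap drops the edge and warns about isolation
  v2 <- v
  v2["D", 1:17] <- NA
  expect_warning(
    g2 <- correlation_graph(omics_matrix(v2, "proteomics"), rownames(v2),
                            min_overlap = 5),
    "isolated")
  expect_true(all(is.na(g2$r["D", c("A", "B", "C")])))
})

test_that("null correlations match the expected |r| magnitude", {
  set.seed(62)
  means <- replicate(10, {
    v <- matrix(rnorm(40 * 30), 40, 30,
                dimnames = list(sprintf("F%02d", 1:40), sprintf("S%02d", 1:30)))
    g <- correlation_graph(omics_matrix(v, "proteomics"), rownames(v))
    mean(abs(g$r[upper.tri(g$r)]))
  })
  expected <- sqrt(2 / (pi * 29))
  expect_lt(abs(mean(means) - expected), 3 * sd(means) / sqrt(10))
})

test_that("MST-kNN edge set follows the hand-computed construction", {
  # d(a,b)=1, d(b,c)=2, d(a,c)=3 encoded through correlations 1/d
  r <- matrix(c(1, 1/1, 1/3,
                1/1, 1, 1/2,
                1/3, 1/2, 1), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  g <- structure(list(nodes = c("a", "b", "c"), r = r,
                      overlap = matrix(99, 3, 3), min_overlap = 5),
                 class = "CorrelationGraph")
  cm <- mst_knn_cluster(g, k = 1)
  ed <- cm$edges[order(cm$edges$distance), ]
  expect_equal(nrow(ed), 2L)
  expect_setequal(paste(ed$node1, ed$node2), c("a b", "b c"))
  expect_equal(sort(unique(cm$membership)), 1L)

  # fewer than 3 nodes: single cluster with a warning
  r2 <- r[1:2, 1:2]
  g2 <- structure(list(nodes = c("a", "b"), r = r2,
                       overlap = matrix(99, 2, 2), min_overlap = 5),
                  class = "CorrelationGraph")
  expect_warning(cm2 <- mst_knn_cluster(g2), "single cluster")
  expect_equal(unname(cm2$membership), c(1L, 1L))
})

test_that("MST agrees with exhaustive enumeration and an independent Prim oracle", {
  set.seed(63)
  for (n in c(4, 5, 6)) {
    for (rep_i in 1:3) {
      D <- as.matrix(dist(matrix(rnorm(n * 3), n, 3)))
      ij <- which(upper.tri(D), arr.ind = TRUE)
      full <- igraph::graph_from_data_frame(
        data.frame(from = ij[, 1], to = ij[, 2]), directed = FALSE,
        vertices = data.frame(name = seq_len(n)))
      igraph::E(full)$weight <- D[ij]
      mst_total <- sum(igraph::E(igraph::mst(full))$weight)
      expect_equal(mst_total, exhaustive_mst_total(D), tolerance = 1e-10)
    }
  }
  for (rep_i in 1:5) {
    n <- 8
    D <- as.matrix(dist(matrix(rnorm(n * 3), n, 3)))
    ij <- which(upper.tri(D), arr.ind = TRUE)
    full <- igraph::graph_from_data_frame(
      data.frame(from = ij[, 1], to = ij[, 2]), directed = FALSE,
      vertices = data.frame(name = seq_len(n)))
    igraph::E(full)$weight <- D[ij]
    expect_equal(sum(igraph::E(igraph::mst(full))$weight),
                 prim_mst_total(D), tolerance = 1e-10)
  }
})

test_that("two tight planted modules split into exactly two components", {
  ok <- 0; n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    set.seed(800 + s)
    f1 <- rnorm(30); f2 <- rnorm(30)
    v <- rbind(
      matrix(f1, 12, 30, byrow = TRUE) + matrix(rnorm(12 * 30, 0, 0.3), 12, 30),
      matrix(f2, 12, 30, byrow = TRUE) + matrix(rnorm(12 * 30, 0, 0.3), 12, 30))
    dimnames(v) <- list(sprintf("F%02d", 1:24), sprintf("S%02d", 1:30))
    g <- correlation_graph(omics_matrix(v, "proteomics"), rownames(v))
    cm <- mst_knn_cluster(g, k = "auto")
    comp <- split(names(cm$membership), cm$membership)
    two_clean <- length(comp) == 2L &&
      (setequal(comp[[1]], rownames(v)[1:12]) ||
       setequal(comp[[1]], rownames(v)[13:24]))
    if (two_clean) ok <- ok + 1
  }
  expect_gte(ok / n_seeds, 0.95)
})

test_that("walktrap recovers bridged cliques and handles degenerate graphs", {
  # two 8-cliques joined by one edge
  g <- igraph::make_full_graph(8) +  igraph::make_full_graph(8)
  g <- igraph::add_edges(g, c(1, 9))
  igraph::V(g)$name <- sprintf("N%02d", 1:16)
  igraph::E(g)$weight <- 1
  model <- structure(list(graph = g,
                          membership = setNames(rep(1L, 16), igraph::V(g)$name),
                          k = 2, edges = NULL), class = "ClusterModel")
  wt <- walktrap_communities(model)
  expect_equal(length(unique(wt$membership)), 2L)
  expect_equal(length(unique(wt$membership[1:8])), 1L)
  expect_equal(length(unique(wt$membership[9:16])), 1L)
  expect_gt(wt$modularity, 0.3)

  # edgeless graph: singleton communities, Q = 0
  g0 <- igraph::make_empty_graph(5, directed = FALSE)
  igraph::V(g0)$name <- paste0("I", 1:5)
  m0 <- structure(list(graph = g0, membership = NULL, k = 1, edges = NULL),
                  class = "ClusterModel")
  wt0 <- walktrap_communities(m0)
  expect_equal(length(unique(wt0$membership)), 5L)
  expect_equal(wt0$modularity, 0)

  # a single clique is one community
  g1 <- igraph::make_full_graph(6)
  igraph::V(g1)$name <- paste0("C", 1:6)
  igraph::E(g1)$weight <- 1
  m1 <- structure(list(graph = g1, membership = NULL, k = 1, edges = NULL),
                  class = "ClusterModel")
  expect_equal(length(unique(walktrap_communities(m1)$membership)), 1L)
})

test_that("community structure is invariant to node relabelling", {
  set.seed(64)
  f1 <- rnorm(25); f2 <- rnorm(25)
  v <- rbind(
    matrix(f1, 6, 25, byrow = TRUE) + matrix(rnorm(150, 0, 0.3), 6, 25),
    matrix(f2, 6, 25, byrow = TRUE) + matrix(rnorm(150, 0, 0.3), 6, 25))
  dimnames(v) <- list(sprintf("F%02d", 1:12), sprintf("S%02d", 1:25))
  m <- omics_matrix(v, "proteomics")
  run <- function(mm) {
    g <- correlation_graph(mm, feature_ids(mm))
    walktrap_communities(mst_knn_cluster(g, k = 2))$membership
  }
  memb1 <- run(m)
  perm <- sample(nrow(v))
  memb2 <- run(omics_matrix(v[perm, ], "proteomics"))
  # same partition up to label permutation
  pairs1 <- outer(memb1, memb1, "==")
  pairs2 <- outer(memb2[names(memb1)], memb2[names(memb1)], "==")
  expect_identical(pairs1, pairs2)
})

test_that("MDS coordinates reflect observed-cell top-difference distances", {
  set.seed(65)
  v <- matrix(rnorm(200 * 8, 10), 200, 8,
              dimnames = list(sprintf("F%03d", 1:200), sprintf("S%d", 1:8)))
  v[, 2] <- v[, 1]                          # duplicated sample
  v[sample(length(v), 100)] <- NA
  v[, 2] <- v[, 1]                          # keep duplication after masking
  m <- omics_matrix(v, "proteomics")
  xy <- mds_coordinates(m, top = 50)
  D <- attr(xy, "distances")
  expect_equal(D["S1", "S2"], 0)
  expect_equal(unname(xy["S1", ]), unname(xy["S2", ]), tolerance = 1e-8)

  # independent brute-force oracle for every pair
  for (i in 1:7) for (j in (i + 1):8) {
    common <- which(!is.na(v[, i]) & !is.na(v[, j]))
    d2 <- sort((v[common, i] - v[common, j])^2, decreasing = TRUE)
    k <- min(50, length(d2))
    expect_equal(D[i, j], sqrt(mean(d2[1:k])), tolerance = 1e-10)
  }

  # two well-separated groups are separated on coordinate 1
  grp <- rep(c(0, 6), each = 6)
  v2 <- matrix(rnorm(100 * 12), 100, 12) +
    matrix(grp, 100, 12, byrow = TRUE) * matrix(runif(100) > 0.5, 100, 12)
  dimnames(v2) <- list(sprintf("G%03d", 1:100), sprintf("T%02d", 1:12))
  xy2 <- mds_coordinates(omics_matrix(v2, "proteomics"), top = 100)
  sep <- split(xy2[, 1], rep(1:2, each = 6))
  expect_true(max(sep[[1]]) < min(sep[[2]]) || max(sep[[2]]) < min(sep[[1]]))
  expect_gte(xy2[1, 1], 0)   # sign convention
})
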