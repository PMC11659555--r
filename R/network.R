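#' Select the top-N features of a differential-expression result
#'
#' Ranks by BH-adjusted p-value, breaking ties by raw p-value and then
#' feature ID, so the selection is deterministic. The study convention is
#' N = 200 for donor and ICM networks and N = 4 for DCM (the number of DE
#' proteins found there).
#'
#' @param de A `DEResult` (see [moderate()]).
#' @param n Number of features, >= 2.
#' @return Character vector of `n` feature IDs in rank order.
#' @export
select_top_n <- function(de, n) {
  stopifnot(inherits(de, "data.frame"))
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  ok <- de[!de$skipped, , drop = FALSE]
  if (n > nrow(ok)) {
    stop(sprintf("n = %d exceeds the %d fitted features", n, nrow(ok)))
  }
  ord <- order(ok$adj.P.Val, ok$P.Value, ok$feature)
  ok$feature[ord][seq_len(n)]
}

#' Pairwise-correlation graph over selected features
#'
#' Pearson correlations over pairwise-complete observations across the
#' samples in scope (both ventricles of the condition pooled). Edges carry
#' weight `|r|` and distance `1/|r|`; pairs with fewer than `min_overlap`
#' shared observations or `r = 0` have no edge.
#'
#' @param m An `OmicsMatrix` (normalised).
#' @param nodes Feature IDs (e.g. from [select_top_n()]).
#' @param samples Sample IDs in scope; default all samples of `m`.
#' @param min_overlap Minimum paired observations per correlation.
#' @return A `CorrelationGraph`: list with `nodes`, `r` (correlation matrix,
#'   `NA` where undefined or under-supported), `overlap` (paired-observation
#'   counts) and `min_overlap`.
#' @export
correlation_graph <- function(m, nodes, samples = sample_ids(m),
                              min_overlap = 5L) {
  stopifnot_omics(m)
  v <- m$values[nodes, samples, drop = FALSE]
  r <- suppressWarnings(cor(t(v), use = "pairwise.complete.obs"))
  overlap <- tcrossprod((!is.na(v)) * 1)
  low <- overlap < min_overlap
  diag(low) <- FALSE
  r[low] <- NA_real_
  diag(r) <- 1
  deg <- rowSums(!is.na(r) & r != 0) - 1L
  if (any(deg == 0L)) {
    warning("isolated nodes (no supported correlation): ",
            paste(nodes[deg == 0L], collapse = ", "))
  }
  structure(list(nodes = nodes, r = r, overlap = overlap,
                 min_overlap = min_overlap),
            class = "CorrelationGraph")
}

#' Edge list of a correlation graph
#'
#' @param g A `CorrelationGraph`.
#' @return Data frame `node1`, `node2`, `r`, `weight` (`|r|`), `distance`
#'   (`1/|r|`) for every defined, nonzero pair.
#' @export
graph_edges <- function(g) {
  stopifnot(inherits(g, "CorrelationGraph"))
  idx <- which(upper.tri(g$r) & !is.na(g$r) & g$r != 0, arr.ind = TRUE)
  data.frame(node1 = g$nodes[idx[, 1L]], node2 = g$nodes[idx[, 2L]],
             r = g$r[idx], weight = abs(g$r[idx]), distance = 1 / abs(g$r[idx]),
             stringsAsFactors = FALSE)
}

#' MST-kNN graph clustering
#'
#' Builds the minimal spanning tree of the `1/|r|` distances, intersects its
#' edge set with the union-direction k-nearest-neighbour graph (an edge
#' survives if it is in the MST and either endpoint lists the other among
#' its k nearest), and takes connected components as structural clusters.
#' `k = "auto"` uses `max(1, floor(ln(number of nodes)))`. A single pass is
#' performed (no recursion) unless `recursive = TRUE`, which re-applies the
#' construction inside each component until the component count stabilises.
#'
#' @param g A `CorrelationGraph`.
#' @param k Neighbourhood size or `"auto"`.
#' @param recursive Recurse within components (off by default).
#' @return A `ClusterModel`: list with `graph` (igraph, `weight` = `|r|`,
#'   `distance` attributes), `membership` (named integer cluster labels),
#'   `k`, `edges` (data frame).
#' @export
mst_knn_cluster <- function(g, k = "auto", recursive = FALSE) {
  stopifnot(inherits(g, "CorrelationGraph"))
  nodes <- g$nodes
  if (length(nodes) < 3L) {
    warning("fewer than 3 nodes; returning a single cluster")
    memb <- setNames(rep(1L, length(nodes)), nodes)
    gr <- igraph::make_full_graph(length(nodes))
    igraph::V(gr)$name <- nodes
    return(structure(list(graph = gr, membership = memb,
                          k = 1L, edges = graph_edges(g)),
                     class = "ClusterModel"))
  }
  if (identical(k, "auto")) k <- max(1L, floor(log(length(nodes))))
  k <- as.integer(k)
  D <- 1 / abs(g$r)
  D[is.na(g$r) | g$r == 0] <- Inf
  diag(D) <- 0
  edge_set <- mst_knn_edges(D, k)
  keep <- edge_set$mst & edge_set$knn
  ii <- which(keep, arr.ind = TRUE)
  gr <- igraph::graph_from_data_frame(
    data.frame(from = nodes[ii[, 1L]], to = nodes[ii[, 2L]]),
    directed = FALSE,
    vertices = data.frame(name = nodes))
  igraph::E(gr)$distance <- D[ii]
  igraph::E(gr)$weight <- abs(g$r)[ii]
  memb <- igraph::components(gr)$membership[nodes]
  if (recursive) {
    repeat {
      new_memb <- memb
      changed <- FALSE
      for (cl in unique(memb)) {
        sub <- nodes[memb == cl]
        if (length(sub) < 3L) next
        gs <- structure(list(nodes = sub,
                             r = g$r[sub, sub, drop = FALSE],
                             overlap = g$overlap[sub, sub, drop = FALSE],
                             min_overlap = g$min_overlap),
                        class = "CorrelationGraph")
        sub_fit <- mst_knn_cluster(gs, k = "auto", recursive = FALSE)
        if (max(sub_fit$membership) > 1L) {
          new_memb[sub] <- max(new_memb) + sub_fit$membership
          changed <- TRUE
        }
      }
      if (!changed) break
      memb <- as.integer(factor(new_memb)); names(memb) <- nodes
    }
  }
  structure(list(graph = gr, membership = memb, k = k,
                 edges = data.frame(node1 = nodes[ii[, 1L]],
                                    node2 = nodes[ii[, 2L]],
                                    r = g$r[ii], weight = abs(g$r)[ii],
                                    distance = D[ii],
                                    stringsAsFactors = FALSE)),
            class = "ClusterModel")
}

# MST (via igraph) and union-direction kNN adjacency on a distance matrix;
# returns upper-triangular logical matrices
mst_knn_edges <- function(D, k) {
  n <- nrow(D)
  finite <- is.finite(D) & upper.tri(D)
  ij <- which(finite, arr.ind = TRUE)
  full <- igraph::graph_from_data_frame(
    data.frame(from = ij[, 1L], to = ij[, 2L]), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  igraph::E(full)$weight <- D[ij]
  mst_g <- igraph::mst(full)
  mst_m <- matrix(FALSE, n, n)
  me <- igraph::as_edgelist(mst_g)
  mi <- cbind(as.integer(me[, 1L]), as.integer(me[, 2L]))
  mst_m[mi] <- TRUE; mst_m[mi[, 2:1, drop = FALSE]] <- TRUE
  knn_m <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    d <- D[i, ]; d[i] <- Inf
    nb <- order(d)[seq_len(min(k, sum(is.finite(d))))]
    knn_m[i, nb] <- TRUE
  }
  knn_m <- knn_m | t(knn_m)           # edge if either endpoint lists the other
  list(mst = mst_m & upper.tri(mst_m), knn = knn_m & upper.tri(knn_m))
}

#' Random-walk (walktrap) community detection
#'
#' Runs the short-random-walk agglomeration on the MST-kNN network (or, with
#' `use_full_graph = TRUE`, on the full weighted correlation graph), using
#' `|r|` edge weights and walk length `t`, and returns the
#' modularity-optimal partition along the merge sequence. Isolated nodes
#' become singleton communities.
#'
#' @param model A `ClusterModel` from [mst_knn_cluster()], or a
#'   `CorrelationGraph` when `use_full_graph = TRUE`.
#' @param t Walk length (steps).
#' @param use_full_graph Cluster the full correlation graph instead of the
#'   MST-kNN edge set.
#' @return List with `membership` (named integer) and `modularity` (Q; 0 for
#'   an edgeless graph).
#' @export
walktrap_communities <- function(model, t = 4L, use_full_graph = FALSE) {
  if (use_full_graph) {
    stopifnot(inherits(model, "CorrelationGraph"))
    ed <- graph_edges(model)
    gr <- igraph::graph_from_data_frame(ed[, c("node1", "node2")],
                                        directed = FALSE,
                                        vertices = data.frame(name = model$nodes))
    igraph::E(gr)$weight <- ed$weight
  } else {
    stopifnot(inherits(model, "ClusterModel"))
    gr <- model$graph
  }
  if (igraph::ecount(gr) == 0L) {
    memb <- setNames(seq_len(igraph::vcount(gr)), igraph::V(gr)$name)
    return(list(membership = memb, modularity = 0))
  }
  wt <- igraph::cluster_walktrap(gr, steps = t, weights = igraph::E(gr)$weight)
  memb <- igraph::membership(wt)
  q <- igraph::modularity(gr, memb, weights = igraph::E(gr)$weight)
  list(membership = setNames(as.integer(memb), names(memb)), modularity = q)
}

#' Classical multidimensional-scaling coordinates for samples
#'
#' The distance between two samples is the root-mean-square of the `top`
#' largest absolute log2 differences over their shared observed features
#' (pairwise gene selection). Coordinates come from classical metric scaling
#' to 2 dimensions, with the sign convention that the first sample's first
#' coordinate is non-negative.
#'
#' @param m An `OmicsMatrix`.
#' @param top Number of largest differences per pair.
#' @return Samples x 2 coordinate matrix, with the distance matrix in
#'   attribute `distances`.
#' @export
mds_coordinates <- function(m, top = 500L) {
  stopifnot_omics(m)
  if (ncol(m$values) < 3L) stop("need >= 3 samples")
  D <- pairwise_top_dist(m$values, top)
  xy <- cmdscale(stats::as.dist(D), k = 2L)
  for (j in 1:2) if (xy[1L, j] < 0) xy[, j] <- -xy[, j]
  colnames(xy) <- c("dim1", "dim2")
  attr(xy, "distances") <- D
  xy
}

pairwise_top_dist <- function(values, top) {
  n <- ncol(values)
  D <- matrix(0, n, n, dimnames = list(colnames(values), colnames(values)))
  obs <- !is.na(values)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      common <- obs[, i] & obs[, j]
      if (!any(common)) stop(sprintf(
        "samples %s and %s share no observed features",
        colnames(values)[i], colnames(values)[j]))
      d2 <- (values[common, i] - values[common, j])^2
      tk <- min(top, length(d2))
      D[i, j] <- D[j, i] <- sqrt(mean(sort(d2, decreasing = TRUE)[seq_len(tk)]))
    }
  }
  D
}
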