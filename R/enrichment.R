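#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of a differential-expression
#' set against the analysed universe (the detected, post-filter features -
#' not all annotated genes, which would import detection bias). The one-sided
#' p-value is `P(X >= overlap)` for `X` hypergeometric with the set's
#' universe overlap as successes and the DE-set size as draws. Up- and
#' down-regulated DE sets are tested in separate calls.
#'
#' @param de_ids Character vector of DE feature IDs (subset of `universe`).
#' @param universe Character vector: all features analysed in the layer.
#' @param sets A `GeneSetCollection`.
#' @param alpha Flagging threshold for the `enriched` column.
#' @param direction Optional label recorded in the output (e.g. `"up"`).
#' @return Data frame with one row per set overlapping the universe:
#'   `set`, `set_size` (in universe), `overlap`, `p`, `enriched`,
#'   `direction`; ordered by `p`.
#' @export
ora_hypergeometric <- function(de_ids, universe, sets, alpha = 0.05,
                               direction = NA_character_) {
  stopifnot(inherits(sets, "GeneSetCollection"))
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  if (!all(de_ids %in% universe)) {
    stop("DE features outside the universe: ",
         paste(head(setdiff(de_ids, universe), 5L), collapse = ", "))
  }
  de_ids <- unique(de_ids)
  N <- length(universe); n_de <- length(de_ids)
  rows <- lapply(names(sets$sets), function(nm) {
    members <- intersect(sets$sets[[nm]], universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    x <- length(intersect(members, de_ids))
    data.frame(set = nm, set_size = K, overlap = x,
               p = phyper(x - 1L, K, N - K, n_de, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no set overlaps the universe")
  out$enriched <- out$p <= alpha
  out$direction <- direction
  out[order(out$p, out$set), , drop = FALSE]
}

rank_sum_p_upper <- function(r, in_set) {
  # one-sided p that the set's ranks are high, given rank vector r
  nS <- sum(in_set); nC <- length(r) - nS
  if (nS <= 10L && nC <= 10L) {
    # exact enumeration over all subsets of the observed ranks
    W <- sum(r[in_set])
    sums <- combn(r, nS, sum)
    return(mean(sums >= W - 1e-9))
  }
  rank_sum_p_upper_normal(r, in_set)
}

# tie-corrected normal approximation with continuity correction
rank_sum_p_upper_normal <- function(r, in_set) {
  n <- length(r); nS <- sum(in_set); nC <- n - nS
  W <- sum(r[in_set])
  ties <- table(r)
  mu <- nS * (n + 1) / 2
  sigma2 <- nS * nC / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  pnorm((W - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
}

#' Mean-rank (Wilcoxon) gene set test
#'
#' Competitive set test on per-feature statistics (typically moderated
#' t-statistics from a differential-abundance analysis): ranks the set's
#' statistics against those of all other features. `"up"` asks whether the
#' set's statistics rank high, `"down"` whether they rank low (equivalently,
#' high on the negated statistics), and `"mixed"` ranks absolute values to
#' detect regulation in either direction. Uses a tie-corrected normal
#' approximation with continuity correction, or exact subset enumeration
#' when both groups have at most 10 members.
#'
#' @param stats Named numeric vector of per-feature statistics.
#' @param set Character vector of member feature IDs; must be a non-empty
#'   proper subset of `names(stats)`.
#' @param alternative `"up"`, `"down"` or `"mixed"`.
#' @return One-sided p-value.
#' @export
mean_rank_set_test <- function(stats, set, alternative = c("up", "down", "mixed")) {
  alternative <- match.arg(alternative)
  if (is.null(names(stats))) stop("'stats' must be named")
  set <- unique(set)
  if (!length(set)) stop("empty set")
  if (!all(set %in% names(stats))) {
    stop("set members missing from stats: ",
         paste(head(setdiff(set, names(stats)), 5L), collapse = ", "))
  }
  if (length(set) >= length(stats)) stop("set must be a proper subset of features")
  x <- switch(alternative, up = stats, down = -stats, mixed = abs(stats))
  r <- rank(x)
  rank_sum_p_upper(r, names(stats) %in% set)
}

#' Annotate network clusters with enriched set terms
#'
#' For each cluster of at least `min_size` nodes, ranks all network features
#' by a membership score - the cluster-membership indicator refined by the
#' correlation to the cluster medoid (the member with the smallest total
#' `1/|r|` distance to its co-members), so members always outrank
#' non-members and tightly correlated members rank highest - and applies
#' the competitive [mean_rank_set_test()] to every term of the collection.
#' Terms at `p <= alpha` are reported; the best one labels the cluster.
#' `method = "hypergeometric"` falls back to plain over-representation of
#' cluster membership.
#'
#' @param clusters Named vector: cluster label per network feature.
#' @param sets A `GeneSetCollection` (e.g. GO Molecular Function terms).
#' @param r Correlation matrix over the network features (see
#'   [correlation_graph()]).
#' @param alpha Reporting threshold.
#' @param min_size Smallest cluster that is tested; smaller clusters are
#'   labelled `"unannotated"`.
#' @param method `"meanrank"` (default) or `"hypergeometric"`.
#' @return List with `labels` (named character, one per cluster) and
#'   `tables` (per cluster, a data frame of enriched terms).
#' @export
annotate_clusters <- function(clusters, sets, r, alpha = 0.05, min_size = 3L,
                              method = c("meanrank", "hypergeometric")) {
  method <- match.arg(method)
  stopifnot(inherits(sets, "GeneSetCollection"))
  if (is.null(names(clusters))) stop("'clusters' must be named by feature")
  nodes <- names(clusters)
  labels <- character(0)
  tables <- list()
  for (cl in unique(clusters)) {
    members <- nodes[clusters == cl]
    lab <- "unannotated"
    tab <- NULL
    if (length(members) >= min_size) {
      if (method == "meanrank") {
        dsub <- 1 / pmax(abs(r[members, members, drop = FALSE]), 1e-12)
        medoid <- members[which.min(rowSums(dsub) - diag(dsub))]
        score <- 2 * as.numeric(nodes %in% members) + (r[, medoid] + 1) / 2
        names(score) <- nodes
        ps <- vapply(names(sets$sets), function(nm) {
          term <- intersect(sets$sets[[nm]], nodes)
          if (!length(term) || length(term) >= length(nodes)) return(NA_real_)
          mean_rank_set_test(score, term, "up")
        }, 1)
      } else {
        ora <- ora_hypergeometric(members, nodes, sets, alpha = alpha)
        ps <- setNames(ora$p, ora$set)
      }
      ps <- ps[!is.na(ps)]
      hits <- sort(ps[ps <= alpha])
      if (length(hits)) {
        lab <- names(hits)[1L]
        tab <- data.frame(term = names(hits), p = unname(hits),
                          stringsAsFactors = FALSE)
      }
    }
    labels[as.character(cl)] <- lab
    tables[[as.character(cl)]] <- tab
  }
  list(labels = labels, tables = tables)
}
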