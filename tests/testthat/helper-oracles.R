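# Independent oracles and small fixture builders shared across tests.
# Everything here is deliberately written with plain matrix algebra / loops,
# separate from the package's code paths.

# textbook RUV-III: projection + SVD formulas, complete data only
textbook_ruviii <- function(Y, M, ctl, k) {
  # Y: samples x features; M: samples x groups incidence; ctl: logical/index
  R <- diag(nrow(Y)) - M %*% solve(crossprod(M)) %*% t(M)
  Y0 <- R %*% Y
  U <- svd(Y0[, ctl, drop = FALSE])$u[, seq_len(k), drop = FALSE]
  alpha <- t(U) %*% Y
  ac <- alpha[, ctl, drop = FALSE]
  W <- Y[, ctl, drop = FALSE] %*% t(ac) %*% solve(ac %*% t(ac))
  Y - W %*% alpha
}

# brute-force BH: min over j >= i of p_(j) * n / j, mapped back
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# Prim's algorithm, hand-coded, as an MST oracle
prim_mst_total <- function(D) {
  n <- nrow(D)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  total <- 0
  for (step in seq_len(n - 1L)) {
    best <- Inf; bj <- NA
    for (i in which(in_tree)) for (j in which(!in_tree)) {
      if (D[i, j] < best) { best <- D[i, j]; bj <- j }
    }
    total <- total + best
    in_tree[bj] <- TRUE
  }
  total
}

# exhaustive minimum spanning tree by enumerating all (n-1)-edge subsets
exhaustive_mst_total <- function(D) {
  n <- nrow(D)
  edges <- which(upper.tri(D), arr.ind = TRUE)
  combs <- combn(nrow(edges), n - 1L)
  best <- Inf
  for (c_i in seq_len(ncol(combs))) {
    sel <- edges[combs[, c_i], , drop = FALSE]
    # connectivity check via union-find
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    acyclic <- TRUE
    for (e in seq_len(nrow(sel))) {
      a <- find(sel[e, 1L]); b <- find(sel[e, 2L])
      if (a == b) { acyclic <- FALSE; break }
      parent[a] <- b
    }
    if (!acyclic) next
    best <- min(best, sum(D[sel]))
  }
  best
}

# metadata for n_subj hearts, each with LV+RV in both batches (fully paired)
paired_meta <- function(n_subj, batches = c("2018", "2020"),
                        condition = "Donor") {
  rows <- expand.grid(subject = sprintf("H%02d", seq_len(n_subj)),
                      location = c("LV", "RV"), batch = batches,
                      stringsAsFactors = FALSE)
  data.frame(
    sample_id = paste(rows$subject, rows$location, rows$batch, sep = "_"),
    subject_id = rows$subject, condition = condition,
    location = rows$location,
    sex = c("M", "F")[1L + (as.integer(sub("H", "", rows$subject)) %% 2L)],
    age = 40 + 2 * as.integer(sub("H", "", rows$subject)),
    batch = rows$batch, stringsAsFactors = FALSE)
}

# random complete OmicsMatrix for the samples of a metadata table
random_omics <- function(meta, n_features = 50, sd = 1, mean = 10,
                         layer = "proteomics") {
  v <- matrix(rnorm(n_features * nrow(meta), mean, sd), n_features,
              dimnames = list(sprintf("P%03d", seq_len(n_features)),
                              meta$sample_id))
  omics_matrix(v, layer)
}

write_tmp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
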