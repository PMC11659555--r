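#' Filter features by per-batch missingness
#'
#' Drops features missing in more than `threshold` of the samples of either
#' batch; a feature missing in exactly `threshold` of a batch is retained
#' (the rule is strictly "more than"). Feature order is preserved.
#'
#' @param m An `OmicsMatrix`.
#' @param meta Validated metadata covering the samples of `m` (supplies the
#'   batch of every sample).
#' @param threshold Missing-fraction cut-off in (0, 1]; default 0.75.
#' @return The filtered `OmicsMatrix`.
#' @export
filter_by_missingness <- function(m, meta, threshold = 0.75) {
  stopifnot_omics(m)
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  meta <- validate_sample_meta(meta, m)
  keep <- rep(TRUE, nrow(m$values))
  for (b in unique(meta$batch)) {
    in_b <- meta$sample_id[meta$batch == b]
    miss_frac <- rowMeans(!m$mask[, in_b, drop = FALSE])
    keep <- keep & (miss_frac <= threshold)
  }
  subset_omics(m, features = which(keep))
}

#' Select negative-control features for normalisation
#'
#' Negative controls are assumed biologically invariant and anchor the
#' estimate of unwanted variation. Proteomics rule: observed-cell sample
#' variance strictly below the median of all feature variances AND no
#' missing cells in any sample. Metabolomics rule: variance strictly below
#' the median (the layer is complete by construction).
#'
#' With `variance_scope = "per_batch"` (requires `meta`), feature variances
#' are instead computed within each batch and a control must fall strictly
#' below the median in every batch. When batches are strongly shifted, the
#' merged-matrix variance is dominated by the batch loading, so the default
#' rule mostly selects features that happen to have small batch effects;
#' per-batch variances measure biological invariance directly and are much
#' less likely to admit genuinely regulated features into the control set.
#'
#' @param m An `OmicsMatrix` (already missingness-filtered for proteomics).
#' @param layer Overrides `m$layer` if given.
#' @param variance_scope `"merged"` (default) or `"per_batch"`.
#' @param meta Metadata, needed for `variance_scope = "per_batch"`.
#' @return Character vector of control feature IDs.
#' @export
select_negative_controls <- function(m, layer = m$layer,
                                     variance_scope = c("merged", "per_batch"),
                                     meta = NULL) {
  stopifnot_omics(m)
  variance_scope <- match.arg(variance_scope)
  if (variance_scope == "per_batch") {
    if (is.null(meta)) stop("per-batch variance scope needs 'meta'")
    meta <- validate_sample_meta(meta, m)
    low_var <- rep(TRUE, nrow(m$values))
    for (b in unique(meta$batch)) {
      ids <- meta$sample_id[meta$batch == b]
      vb <- apply(m$values[, ids, drop = FALSE], 1L,
                  function(y) var(y[!is.na(y)]))
      low_var <- low_var & !is.na(vb) & vb < median(vb, na.rm = TRUE)
    }
  } else {
    v <- apply(m$values, 1L, function(y) var(y[!is.na(y)]))
    med <- median(v, na.rm = TRUE)
    low_var <- !is.na(v) & v < med
  }
  if (layer == "proteomics") {
    complete <- rowSums(!m$mask) == 0L
    ctl <- low_var & complete
  } else {
    ctl <- low_var
  }
  if (!any(ctl)) {
    stop(sprintf(paste0("no negative controls: %d/%d features below the ",
                        "median variance, %d complete"),
                 sum(low_var), length(low_var),
                 sum(rowSums(!m$mask) == 0L)))
  }
  rownames(m$values)[ctl]
}

#' Generalised replicate-averaging residuals
#'
#' For every feature and every observed cell, subtracts the mean of the cell's
#' technical-replicate group computed over the samples observed for that
#' feature. A cell whose group has no other observed member gets residual 0;
#' missing cells stay missing. On complete data this equals the replicate
#' projection `(I - M (M'M)^-1 M') Y` exactly, which is what standard RUV-III
#' applies; the available-case group means extend it to incomplete data.
#'
#' @param m An `OmicsMatrix`.
#' @param rep A [build_replicate_map()] covering the samples of `m`.
#' @return An `OmicsMatrix` of residuals (same mask and layer).
#' @export
generalized_averaging_residuals <- function(m, rep) {
  stopifnot_omics(m)
  M <- rep$incidence[colnames(m$values), , drop = FALSE]
  Yt <- t(m$values)                      # samples x features
  obs <- !is.na(Yt)
  Y0 <- Yt; Y0[!obs] <- 0
  grp_sum <- crossprod(M, Y0)            # groups x features
  grp_n <- crossprod(M, obs * 1)
  grp_mean <- grp_sum / pmax(grp_n, 1)
  res <- Yt - (M %*% grp_mean)
  res[!obs] <- NA_real_
  omics_matrix(t(res), m$layer)
}

# number of singular values exceeding the strongest one seen in column-wise
# permutations of Z (fixed internal stream, so results are reproducible)
parallel_analysis_k <- function(Z, d, n_perm = 19L) {
  d_null <- with_substream(77003L, "parallel_analysis", {
    vapply(seq_len(n_perm), function(b) {
      Zp <- apply(Z, 2L, sample)
      svd(Zp, nu = 0L, nv = 0L)$d[1L]
    }, 1)
  })
  sum(d > max(d_null))
}

svd_sign_fix <- function(U) {
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  U
}

#' RUV-III normalisation generalised to missing values
#'
#' Estimates and removes unwanted (non-biological) variation using
#' negative-control features and technical replicates. Control residuals are
#' formed by [generalized_averaging_residuals()]; their left singular vectors
#' give `k` orthonormal unwanted-variation directions `U_k`; per-feature
#' loadings are available-case inner products rescaled by `m / |O_j|`
#' (total over observed samples for feature `j`); sample scores `W` are
#' recovered from the complete control block; and `W alpha` is subtracted
#' from observed cells. Missing cells are never imputed. On complete data the
#' procedure reproduces standard RUV-III exactly.
#'
#' `mode = "complete"` instead re-estimates the factor basis per feature on
#' that feature's observed samples only (the complete-cases-per-feature
#' strategy of RUV-III-C), for comparison; it is slower and discards the
#' information carried by partially observed rows.
#'
#' @param m An `OmicsMatrix` (filtered).
#' @param rep A [build_replicate_map()] for the samples of `m`.
#' @param controls Character vector of control feature IDs; must be complete
#'   (no missing cells) across all samples.
#' @param k Number of unwanted factors, or `"auto"` for the maximal
#'   estimable value, samples minus replicate groups.
#' @param mode `"generalized"` (default) or `"complete"`.
#' @return A `RuvFit`: list with `k`, `controls`, `U` (samples x k,
#'   orthonormal), `alpha` (k x features), `W` (samples x k), `normalized`
#'   (an `OmicsMatrix`, same mask as the input) and `raw` (the input).
#' @export
ruviii_generalized <- function(m, rep, controls, k = "auto",
                               mode = c("generalized", "complete")) {
  stopifnot_omics(m)
  mode <- match.arg(mode)
  if (!all(controls %in% rownames(m$values))) {
    stop("controls absent from the matrix: ",
         paste(head(setdiff(controls, rownames(m$values)), 5L), collapse = ", "))
  }
  if (any(!m$mask[controls, ])) {
    stop("control features must be complete across all samples")
  }
  n <- ncol(m$values)
  n_grp <- length(rep$groups)
  k_max <- n - n_grp
  auto_k <- identical(k, "auto")
  if (!auto_k) {
    k <- as.integer(k)
    if (k < 1L) stop("k must be >= 1 (no replicated samples -> nothing to estimate)")
    if (k > k_max) {
      stop(sprintf("k = %d exceeds samples - replicate groups = %d", k, k_max))
    }
  } else if (k_max < 1L) {
    stop("no replicated samples -> nothing to estimate")
  }

  res <- generalized_averaging_residuals(m, rep)
  Z <- t(res$values[controls, , drop = FALSE])       # samples x controls
  if (max(abs(Z)) < 1e-12) {
    # exact replicate agreement on controls: nothing to estimate or remove
    k0 <- if (auto_k) 1L else k
    U0 <- matrix(0, n, k0, dimnames = list(colnames(m$values), NULL))
    return(structure(list(k = k0, controls = controls, U = U0,
                          alpha = matrix(0, k0, nrow(m$values),
                                         dimnames = list(NULL, rownames(m$values))),
                          W = U0, normalized = m, raw = m, replicates = rep,
                          mode = mode),
                     class = "RuvFit"))
  }
  sv <- svd(Z)
  rank_z <- sum(sv$d > max(sv$d) * 1e-10)
  if (auto_k) {
    # parallel analysis: keep components whose singular value exceeds what
    # column-wise permutation (structure destroyed, margins kept) produces
    k <- min(parallel_analysis_k(Z, sv$d), k_max, rank_z)
    k <- max(k, 1L)
  } else if (k > rank_z) {
    stop(sprintf("k = %d exceeds the rank (%d) of the control residuals",
                 k, rank_z))
  }
  log_msg("RUV-III: k = %d (%d controls, %d replicate groups)", k,
          length(controls), n_grp)
  U <- svd_sign_fix(sv$u[, seq_len(k), drop = FALSE])
  rownames(U) <- colnames(m$values)

  # loadings from the replicate residuals of every feature (equal to U'Y on
  # complete data because U is orthogonal to the replicate-group space);
  # residuals are centred, so partial observation cannot leak feature means.
  # For incomplete features the loading is the available-case least-squares
  # projection (U[O]'U[O])^-1 U[O]' y0, which collapses to the plain inner
  # product on complete data (U orthonormal) and avoids the multiplicative
  # error of simply rescaling partial inner products by m/|O|.
  # Only samples whose replicate group retains >= 2 observed members carry
  # information about the unwanted factors for that feature (the residual-0
  # convention for broken groups is an output convention, not data); feeding
  # those zeros into the fit would shrink the loadings toward zero.
  Yt <- t(m$values)
  obs <- !is.na(Yt)
  n_obs <- colSums(obs)
  R0 <- t(res$values)
  R0[!obs] <- 0
  M <- rep$incidence[colnames(m$values), , drop = FALSE]
  grp_obs <- crossprod(M, obs * 1)                    # groups x features
  informative <- (M %*% grp_obs) >= 2 & obs           # samples x features
  alpha <- crossprod(U, R0)                           # k x features
  partial <- which(colSums(informative) < n)
  for (j in partial) {
    I <- informative[, j]
    if (!any(I)) { alpha[, j] <- alpha[, j] * n / n_obs[j]; next }
    Ui <- U[I, , drop = FALSE]
    aj <- tryCatch(solve(crossprod(Ui), crossprod(Ui, R0[I, j])),
                   error = function(e) NULL)
    alpha[, j] <- if (is.null(aj)) alpha[, j] * n / n_obs[j] else aj
  }
  ac <- alpha[, controls, drop = FALSE]
  gram <- tcrossprod(ac)
  W <- tryCatch(
    Yt[, controls, drop = FALSE] %*% t(ac) %*% solve(gram),
    error = function(e) stop("singular control loading matrix; try a smaller k"))
  colnames(W) <- paste0("W", seq_len(k))

  if (mode == "generalized") {
    corr <- W %*% alpha
    norm_t <- Yt - corr
  } else {
    norm_t <- Yt
    meta_like <- rep$incidence
    full <- n_obs == n
    Yc <- Yt[, controls, drop = FALSE]
    corr_full <- W %*% alpha
    for (j in seq_len(ncol(Yt))) {
      if (full[j]) {
        norm_t[, j] <- Yt[, j] - corr_full[, j]
        next
      }
      O <- which(obs[, j])
      Mo <- meta_like[O, colSums(meta_like[O, , drop = FALSE]) > 0, drop = FALSE]
      kj <- min(k, length(O) - ncol(Mo))
      if (kj < 1L) next                               # uncorrectable, left raw
      Ho <- Mo %*% solve(crossprod(Mo)) %*% t(Mo)
      Zo <- (diag(length(O)) - Ho) %*% Yc[O, , drop = FALSE]
      svo <- svd(Zo)
      kj <- min(kj, sum(svo$d > max(svo$d) * 1e-10))
      if (kj < 1L) next
      Uo <- svd_sign_fix(svo$u[, seq_len(kj), drop = FALSE])
      aj <- crossprod(Uo, Yt[O, j])
      aco <- crossprod(Uo, Yc[O, , drop = FALSE])
      Wo <- Yc[O, , drop = FALSE] %*% t(aco) %*% solve(tcrossprod(aco))
      norm_t[O, j] <- Yt[O, j] - Wo %*% aj
    }
  }
  norm_t[!obs] <- NA_real_
  structure(list(k = k, controls = controls, U = U, alpha = alpha, W = W,
                 normalized = omics_matrix(t(norm_t), m$layer),
                 raw = m, replicates = rep, mode = mode),
            class = "RuvFit")
}

#' @export
print.RuvFit <- function(x, ...) {
  cat(sprintf("RuvFit (%s): k = %d, %d controls, %d features x %d samples\n",
              x$mode, x$k, length(x$controls), nrow(x$normalized$values),
              ncol(x$normalized$values)))
  invisible(x)
}

# pairwise sample distances over shared observed cells (RMS difference)
observed_sample_dist <- function(values) {
  obs <- !is.na(values)
  n <- ncol(values)
  D <- matrix(0, n, n, dimnames = list(colnames(values), colnames(values)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      common <- obs[, i] & obs[, j]
      if (!any(common)) stop(sprintf(
        "samples %s and %s share no observed features",
        colnames(values)[i], colnames(values)[j]))
      d <- sqrt(mean((values[common, i] - values[common, j])^2))
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

batch_silhouette <- function(values, batch) {
  D <- observed_sample_dist(values)
  xy <- cmdscale(stats::as.dist(D), k = 2L)
  sil <- cluster::silhouette(as.integer(factor(batch)), dist(xy))
  mean(sil[, "sil_width"])
}

replicate_rms <- function(values, rep) {
  M <- rep$incidence[colnames(values), , drop = FALSE]
  Yt <- t(values)
  obs <- !is.na(Yt)
  Y0 <- Yt; Y0[!obs] <- 0
  grp_mean <- crossprod(M, Y0) / pmax(crossprod(M, obs * 1), 1)
  res <- Yt - M %*% grp_mean
  multi <- rownames(M) %in% unlist(rep$groups[lengths(rep$groups) > 1L])
  dev <- res[multi, , drop = FALSE]
  sqrt(mean(dev[!is.na(dev)]^2))
}

#' Normalisation diagnostics
#'
#' Quantifies how much batch structure the normalisation removed: mean
#' silhouette width of samples grouped by batch (on 2-D classical-scaling
#' coordinates of observed-cell RMS distances), mean negative-control
#' feature variance, and root-mean-square disagreement within technical
#' replicate groups - each before and after correction.
#'
#' @param fit A [ruviii_generalized()] fit.
#' @param meta Validated metadata for the fitted samples.
#' @return List of class `ruv_diagnostics` with elements
#'   `silhouette_batch`, `control_variance`, `replicate_rms`, each a named
#'   vector `c(before, after)`.
#' @export
normalization_diagnostics <- function(fit, meta) {
  stopifnot(inherits(fit, "RuvFit"))
  meta <- validate_sample_meta(meta, fit$raw)
  ctl_var <- function(v) mean(apply(v[fit$controls, , drop = FALSE], 1L,
                                    function(y) var(y[!is.na(y)])))
  out <- list(
    silhouette_batch = c(before = batch_silhouette(fit$raw$values, meta$batch),
                         after = batch_silhouette(fit$normalized$values, meta$batch)),
    control_variance = c(before = ctl_var(fit$raw$values),
                         after = ctl_var(fit$normalized$values)),
    replicate_rms = c(before = replicate_rms(fit$raw$values, fit$replicates),
                      after = replicate_rms(fit$normalized$values, fit$replicates)))
  class(out) <- "ruv_diagnostics"
  out
}

#' @export
print.ruv_diagnostics <- function(x, ...) {
  for (nm in names(x)) {
    cat(sprintf("%-18s before %8.4f  after %8.4f\n", nm, x[[nm]]["before"],
                x[[nm]]["after"]))
  }
  invisible(x)
}
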