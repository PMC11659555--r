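#' Build the design matrix for a ventricle or sex contrast
#'
#' `LVvsRV` fits intercept + location (LV = 1, reference RV) + sex (M = 1) +
#' log2(age), within the samples of the requested condition scope, so the
#' location coefficient is the covariate-adjusted log2(LV) - log2(RV)
#' difference. `MvsF` fits per-location means with per-location sex effects
#' plus log2(age), so each sex coefficient compares males with females at
#' the same ventricle.
#'
#' @param meta Validated metadata.
#' @param scope Condition or vector of conditions to keep (`"Donor"`,
#'   `"DCM"`, `"ICM"`, or e.g. `c("DCM", "ICM")` for pooled heart failure).
#' @param comparison `"LVvsRV"` or `"MvsF"`.
#' @return Numeric design matrix with sample-ID rownames and attributes
#'   `test_coefs` (coefficients of interest), `compared` (named list of
#'   per-sample factors whose levels must each keep >= 3 observed samples
#'   when fitting), and `meta` (the scoped metadata).
#' @export
build_design <- function(meta, scope, comparison = c("LVvsRV", "MvsF")) {
  comparison <- match.arg(comparison)
  meta <- validate_sample_meta(meta)
  meta <- meta[meta$condition %in% scope, , drop = FALSE]
  if (nrow(meta) < 4L) stop("scope selects fewer than 4 samples")
  lv <- as.numeric(meta$location == "LV")
  sexM <- as.numeric(meta$sex == "M")
  l2age <- log2(meta$age)
  if (comparison == "LVvsRV") {
    X <- cbind(`(Intercept)` = 1, locationLV = lv, sexM = sexM, log2age = l2age)
    test_coefs <- "locationLV"
    compared <- list(locationLV = factor(meta$location))
  } else {
    X <- cbind(locLV = lv, locRV = 1 - lv,
               sexM_LV = sexM * lv, sexM_RV = sexM * (1 - lv),
               log2age = l2age)
    test_coefs <- c("sexM_LV", "sexM_RV")
    sexf <- factor(meta$sex)
    cmp_lv <- sexf; cmp_lv[meta$location != "LV"] <- NA
    cmp_rv <- sexf; cmp_rv[meta$location != "RV"] <- NA
    compared <- list(sexM_LV = cmp_lv, sexM_RV = cmp_rv)
  }
  rownames(X) <- meta$sample_id
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  for (cf in test_coefs) {
    tab <- table(compared[[cf]])
    if (length(tab) < 2L || any(tab < 3L)) {
      stop(sprintf("fewer than 3 samples in a compared level for %s (%s)",
                   cf, paste(names(tab), tab, sep = "=", collapse = ", ")))
    }
  }
  structure(X, test_coefs = test_coefs, compared = compared, meta = meta)
}

# correlation matrix I + rho * same-block off-diagonal
block_sigma <- function(blocks, rho) {
  B <- outer(blocks, blocks, `==`) * 1
  diag(B) <- 0
  diag(length(blocks)) + rho * B
}

# REML criterion for a per-feature random-intercept model, profiled in rho
reml_crit <- function(rho, y, X, blocks) {
  S <- block_sigma(blocks, rho)
  C <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(C)) return(1e300)
  yw <- backsolve(C, y, transpose = TRUE)
  Xw <- backsolve(C, X, transpose = TRUE)
  qx <- qr(Xw)
  rss <- sum(qr.resid(qx, yw)^2)
  n <- length(y); p <- qx$rank
  if (!is.finite(rss) || rss <= 0) return(1e300)
  2 * sum(log(diag(C))) + 2 * sum(log(abs(diag(qr.R(qx))))) +
    (n - p) * log(rss / (n - p))
}

#' Estimate the consensus intra-subject correlation
#'
#' Paired LV/RV (and replicated) samples from one heart are correlated;
#' ignoring that correlation overstates the effective sample size. For every
#' feature, the within-block correlation of a random-intercept model is
#' estimated by restricted maximum likelihood on the feature's observed
#' cells; the consensus is the inverse Fisher-z of the 15%-trimmed mean of
#' the per-feature Fisher-z values, clipped to (-0.99, 0.99).
#'
#' @param m An `OmicsMatrix` (normalised).
#' @param design A [build_design()] matrix.
#' @param blocks Subject ID per design row; defaults to the scoped metadata.
#' @return The consensus correlation (scalar), with the per-feature values
#'   in attribute `per_feature`.
#' @export
estimate_consensus_correlation <- function(m, design,
                                           blocks = attr(design, "meta")$subject_id) {
  stopifnot_omics(m)
  ids <- rownames(design)
  v <- m$values[, ids, drop = FALSE]
  multi <- table(blocks)
  if (sum(multi >= 2L) < 2L) {
    stop("need >= 2 subjects with >= 2 samples to estimate a block ",
         "correlation; fit unblocked (rho = 0) instead")
  }
  rho_f <- rep(NA_real_, nrow(v))
  for (g in seq_len(nrow(v))) {
    o <- which(!is.na(v[g, ]))
    if (length(o) < ncol(design) + 2L) next
    bl <- blocks[o]
    if (sum(table(bl) >= 2L) < 2L) next
    X <- design[o, , drop = FALSE]
    if (qr(X)$rank < ncol(X)) next
    opt <- optimize(reml_crit, c(-0.95, 0.99), y = v[g, o], X = X, blocks = bl,
                    tol = 1e-4)
    rho_f[g] <- opt$minimum
  }
  rho_f <- rho_f[!is.na(rho_f)]
  if (!length(rho_f)) stop("no feature permitted a block-correlation fit")
  z <- atanh(pmax(pmin(rho_f, 0.99), -0.99))
  rho <- tanh(mean(z, trim = 0.15))
  rho <- pmax(pmin(rho, 0.99), -0.99)
  attr(rho, "per_feature") <- rho_f
  rho
}

#' Per-feature generalised-least-squares fits
#'
#' Fits every feature on its observed samples under the covariance
#' `I + rho * (same-subject indicator)`, i.e. ordinary least squares when
#' `rho = 0`. Features whose observed design is rank deficient, or with
#' fewer than 3 observed samples in a compared level, are flagged and
#' skipped rather than fitted.
#'
#' @param m An `OmicsMatrix`.
#' @param design A [build_design()] matrix.
#' @param blocks Subject IDs per design row.
#' @param rho Consensus within-block correlation.
#' @param coef Coefficient to report; default the design's first test
#'   coefficient.
#' @return Data frame with one row per feature: `feature`, `coef`,
#'   `se_unscaled`, `sigma` (residual sd), `df_residual`, `n_obs`,
#'   `skipped`, `reason`.
#' @export
fit_features <- function(m, design, blocks = attr(design, "meta")$subject_id,
                         rho = 0, coef = attr(design, "test_coefs")[1L]) {
  stopifnot_omics(m)
  ids <- rownames(design)
  v <- m$values[, ids, drop = FALSE]
  cmp <- attr(design, "compared")[[coef]]
  p <- ncol(design)
  out <- data.frame(feature = rownames(v), coef = NA_real_,
                    se_unscaled = NA_real_, sigma = NA_real_,
                    df_residual = NA_real_, n_obs = 0L,
                    skipped = TRUE, reason = "", stringsAsFactors = FALSE)
  # cache whitening for each distinct observation pattern (complete rows share one)
  whiten_cache <- new.env(parent = emptyenv())
  for (g in seq_len(nrow(v))) {
    o <- which(!is.na(v[g, ]))
    out$n_obs[g] <- length(o)
    if (!is.null(cmp)) {
      tab <- table(cmp[o])
      if (length(tab) < 2L || any(tab < 3L)) {
        out$reason[g] <- "fewer than 3 observed samples in a compared level"
        next
      }
    }
    if (length(o) <= p) { out$reason[g] <- "too few observed samples"; next }
    X <- design[o, , drop = FALSE]
    key <- paste(o, collapse = ",")
    ent <- whiten_cache[[key]]
    if (is.null(ent)) {
      qx0 <- qr(X)
      if (qx0$rank < p) {
        whiten_cache[[key]] <- list(bad = TRUE)
        out$reason[g] <- "rank-deficient observed design"
        next
      }
      C <- if (rho != 0) chol(block_sigma(blocks[o], rho)) else NULL
      Xw <- if (is.null(C)) X else backsolve(C, X, transpose = TRUE)
      qx <- qr(Xw)
      cov_u <- solve(crossprod(Xw))    # unscaled coefficient covariance
      whiten_cache[[key]] <- ent <- list(bad = FALSE, C = C, qx = qx,
                                         se_u = sqrt(diag(cov_u)))
    } else if (isTRUE(ent$bad)) {
      out$reason[g] <- "rank-deficient observed design"
      next
    }
    y <- v[g, o]
    yw <- if (is.null(ent$C)) y else backsolve(ent$C, y, transpose = TRUE)
    beta <- qr.coef(ent$qx, yw)
    rss <- sum(qr.resid(ent$qx, yw)^2)
    df <- length(o) - p
    ci <- match(coef, colnames(design))
    out$coef[g] <- beta[ci]
    out$se_unscaled[g] <- ent$se_u[ci]
    out$sigma[g] <- sqrt(rss / df)
    out$df_residual[g] <- df
    out$skipped[g] <- FALSE
  }
  attr(out, "rho") <- rho
  attr(out, "coef_name") <- coef
  out
}

#' Empirical-Bayes moderation and multiplicity adjustment
#'
#' Shrinks per-feature residual variances toward a common prior by fitting a
#' scaled-F distribution to the observed variances (moment matching on the
#' log scale), then forms moderated t-statistics
#' `t = coef / (s_post * se_unscaled)` with `d0 + df` degrees of freedom,
#' where `s_post^2 = (d0 s0^2 + df s^2) / (d0 + df)`. `d0 = Inf` collapses
#' every variance to the prior (normal reference); `d0 = 0` reproduces the
#' ordinary t-statistic.
#'
#' @param fits Output of [fit_features()].
#' @param d0,s02 Optional prior df and prior variance; estimated from the
#'   data when `NULL` (requires >= 10 fitted features).
#' @return A `DEResult` data frame: `feature`, `logFC`, `FC_magnitude`
#'   (`2^|logFC|`), `direction` (`"up"` = higher in the coefficient's
#'   reference-positive group), `t`, `P.Value`, `adj.P.Val`, `df.total`,
#'   `n.obs`, `skipped`; attributes `d0`, `s02`, `rho`.
#' @export
moderate <- function(fits, d0 = NULL, s02 = NULL) {
  ok <- !fits$skipped
  s2 <- fits$sigma[ok]^2
  df <- fits$df_residual[ok]
  if (!any(ok)) stop("no fitted features")
  if (all(s2 == 0)) stop("all residual variances are zero")
  if (is.null(d0) || is.null(s02)) {
    if (sum(ok) < 10L) stop("need >= 10 fitted features to estimate the prior")
    fd <- limma::fitFDist(s2, df1 = df)
    if (is.null(d0)) d0 <- fd$df2
    if (is.null(s02)) s02 <- fd$scale
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else {
    (d0 * s02 + df * s2) / (d0 + df)
  }
  tt <- fits$coef[ok] / (sqrt(s2_post) * fits$se_unscaled[ok])
  # total df capped at the pooled residual df, as in the standard
  # empirical-Bayes implementation (only binds for near-infinite d0)
  df_tot <- pmin(d0 + df, sum(df))
  pp <- 2 * pt(-abs(tt), df_tot)
  res <- data.frame(feature = fits$feature, logFC = NA_real_,
                    FC_magnitude = NA_real_, direction = NA_character_,
                    t = NA_real_, P.Value = NA_real_, adj.P.Val = NA_real_,
                    df.total = NA_real_, n.obs = fits$n_obs,
                    skipped = fits$skipped, stringsAsFactors = FALSE)
  res$logFC[ok] <- fits$coef[ok]
  res$FC_magnitude[ok] <- 2^abs(fits$coef[ok])
  res$direction[ok] <- ifelse(fits$coef[ok] > 0, "up", "down")
  res$t[ok] <- tt
  res$P.Value[ok] <- pp
  res$adj.P.Val[ok] <- adjust_bh(pp)
  res$df.total[ok] <- df_tot
  attr(res, "d0") <- d0
  attr(res, "s02") <- s02
  attr(res, "rho") <- attr(fits, "rho")
  attr(res, "coef_name") <- attr(fits, "coef_name")
  class(res) <- c("DEResult", "data.frame")
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false-discovery rate;
#' a thin validating wrapper around [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Append a log-ratio feature
#'
#' Adds `value(numerator) - value(denominator)` (a log-scale ratio, e.g.
#' glutamine / glutamate) as a new feature, observed only where both parents
#' are observed.
#'
#' @param m An `OmicsMatrix`.
#' @param numerator,denominator Existing feature IDs.
#' @param name New feature ID; must not collide.
#' @return The extended `OmicsMatrix`.
#' @export
derived_ratio_feature <- function(m, numerator, denominator, name) {
  stopifnot_omics(m)
  if (!all(c(numerator, denominator) %in% rownames(m$values))) {
    stop("numerator/denominator not present")
  }
  if (name %in% rownames(m$values)) stop("feature '", name, "' already exists")
  ratio <- m$values[numerator, ] - m$values[denominator, ]
  v <- rbind(m$values, ratio)
  rownames(v)[nrow(v)] <- name
  omics_matrix(v, m$layer)
}

#' One-call differential analysis for a scope and comparison
#'
#' Convenience wrapper chaining [build_design()],
#' [estimate_consensus_correlation()] (falling back to `rho = 0` when no
#' subject has multiple samples in scope), [fit_features()] and
#' [moderate()].
#'
#' @inheritParams build_design
#' @param m Normalised `OmicsMatrix`.
#' @param coef Coefficient to test; default the comparison's first.
#' @param rho Fixed correlation; estimated when `NULL`.
#' @return A `DEResult` (see [moderate()]).
#' @export
de_analysis <- function(m, meta, scope, comparison = "LVvsRV", coef = NULL,
                        rho = NULL) {
  design <- build_design(meta, scope, comparison)
  m_sc <- subset_omics(m, samples = rownames(design))
  if (is.null(rho)) {
    rho <- tryCatch(as.numeric(estimate_consensus_correlation(m_sc, design)),
                    error = function(e) 0)
  }
  if (is.null(coef)) coef <- attr(design, "test_coefs")[1L]
  fits <- fit_features(m_sc, design, rho = rho, coef = coef)
  moderate(fits)
}
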