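make_meta2batch <- function(n_subj) paired_meta(n_subj)

test_that("missingness filter applies the strict per-batch 75% rule", {
  meta <- paired_meta(5)                      # 10 samples per batch
  v <- matrix(rnorm(3 * 20, 10), 3, 20,
              dimnames = list(c("Pdrop", "Pedge", "Pok"), meta$sample_id))
  b2018 <- meta$sample_id[meta$batch == "2018"]
  v["Pdrop", b2018[1:8]] <- NA                # 80% missing in 2018
  v["Pedge", b2018[1:7]] <- NA
  v["Pedge", meta$sample_id[meta$batch == "2020"][1:3]] <- NA
  # Pedge: 7/10 in 2018, 3/10 in 2020 -> <= 0.75 in both, retained
  m <- omics_matrix(v, "proteomics")
  f <- filter_by_missingness(m, meta, 0.75)
  expect_identical(feature_ids(f), c("Pedge", "Pok"))

  # exactly 75% missing in each batch is retained (strict "more than")
  v2 <- matrix(rnorm(2 * 8, 10), 2, 8,
               dimnames = list(c("P75", "Pfull"), paired_meta(2)$sample_id))
  meta2 <- paired_meta(2)
  for (b in c("2018", "2020")) {
    v2["P75", meta2$sample_id[meta2$batch == b][1:3]] <- NA
  }
  f2 <- filter_by_missingness(omics_matrix(v2, "proteomics"), meta2, 0.75)
  expect_true("P75" %in% feature_ids(f2))

  m3 <- random_omics(meta, 4)
  expect_identical(filter_by_missingness(m3, meta)$values, m3$values)
  expect_error(filter_by_missingness(m3, meta, 0), "threshold")
  expect_error(filter_by_missingness(m3, meta, 1.2), "threshold")
})

test_that("negative-control selection follows the variance and completeness rules", {
  set.seed(21)
  meta <- paired_meta(3)
  # 10 features with strictly increasing variance -> metabolomics rule keeps
  # exactly the 5 lowest-variance ones (brute-force ranking oracle)
  v <- t(sapply(1:10, function(i) rnorm(12, 0, i / 4)))
  dimnames(v) <- list(sprintf("M%02d", 1:10), meta$sample_id)
  ctl <- select_negative_controls(omics_matrix(v, "metabolomics"))
  vars <- apply(v, 1, var)
  expect_setequal(ctl, names(sort(vars))[1:5])

  # proteomics: a tiny-variance feature with one missing cell is excluded
  vp <- v; vp["M01", 1] <- NA
  ctl_p <- select_negative_controls(omics_matrix(vp, "proteomics"))
  expect_false("M01" %in% ctl_p)

  # a constant feature is always selected (variance 0 < median)
  vc <- rbind(v, Pconst = rep(5, 12))
  expect_true("Pconst" %in%
    select_negative_controls(omics_matrix(vc, "metabolomics")))

  # all features missing somewhere -> proteomics rule finds nothing
  vbad <- v; vbad[, 1] <- NA
  expect_error(select_negative_controls(omics_matrix(vbad, "proteomics")),
               "no negative controls")
})

test_that("per-batch variance scope rejects features with planted effects", {
  co <- generate_cohort(cohort_spec(seed = 31, n_features = 600))
  m <- merge_batches(co$batches[["2018"]], co$batches[["2020"]])
  m <- inject_missingness(m, co$truth, 0.134, seed = 31)
  f <- filter_by_missingness(m, co$meta)
  ctl_pb <- select_negative_controls(f, variance_scope = "per_batch",
                                     meta = co$meta)
  expect_gt(length(ctl_pb), 10)
  expect_length(intersect(ctl_pb, co$truth$de_features), 0)
})

test_that("generalised averaging residuals centre within replicate groups", {
  meta <- data.frame(sample_id = c("a", "b", "c"), subject_id = c("H1", "H1", "H2"),
                     condition = "Donor", location = "LV", sex = "M", age = 50,
                     batch = c("2018", "2020", "2020"), stringsAsFactors = FALSE)
  rp <- build_replicate_map(meta)
  v <- matrix(c(5, 7, 3), 1, 3, dimnames = list("P1", c("a", "b", "c")))
  res <- generalized_averaging_residuals(omics_matrix(v, "proteomics"), rp)
  expect_equal(unname(res$values[1, ]), c(-1, 1, 0))

  # partner missing -> residual 0 at the remaining member
  v2 <- v; v2[1, "b"] <- NA
  res2 <- generalized_averaging_residuals(omics_matrix(v2, "proteomics"), rp)
  expect_equal(unname(res2$values[1, ]), c(0, NA, 0))
})

test_that("residuals equal the closed-form replicate projection on complete data", {
  set.seed(22)
  meta <- paired_meta(2)                       # 8 samples, 4 groups
  m <- random_omics(meta, 6)
  rp <- build_replicate_map(meta)
  res <- generalized_averaging_residuals(m, rp)
  M <- rp$incidence[colnames(m$values), ]
  P <- diag(nrow(M)) - M %*% solve(crossprod(M)) %*% t(M)
  expect_equal(t(res$values), P %*% t(m$values), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("generalised RUV-III reproduces textbook RUV-III on complete data", {
  set.seed(23)
  meta <- paired_meta(10)                      # 40 samples, 20 replicate pairs
  m <- random_omics(meta, 100)
  # add latent structure so the fit is non-trivial
  W <- matrix(rnorm(40 * 2), 40, 2)
  al <- matrix(rnorm(2 * 100), 2, 100)
  m$values <- m$values + t(W %*% al)
  rp <- build_replicate_map(meta)
  ctl <- feature_ids(m)[1:30]
  fit <- ruviii_generalized(m, rp, ctl, k = 2)
  M <- rp$incidence[colnames(m$values), ]
  oracle <- textbook_ruviii(t(m$values), M, feature_ids(m) %in% ctl, k = 2)
  expect_lt(max(abs(t(fit$normalized$values) - oracle)), 1e-8)
  # complete-cases mode agrees on complete data too
  fitc <- ruviii_generalized(m, rp, ctl, k = 2, mode = "complete")
  expect_lt(max(abs(fitc$normalized$values - fit$normalized$values)), 1e-8)
  # orthonormal scores, mask preserved
  expect_equal(crossprod(fit$U), diag(2), tolerance = 1e-10)
  expect_identical(fit$normalized$mask, m$mask)
})

test_that("RUV-III validates controls, k and degenerate input", {
  meta <- paired_meta(3)
  m <- random_omics(meta, 10)
  rp <- build_replicate_map(meta)
  expect_error(ruviii_generalized(m, rp, c("P001", "nope"), k = 1), "absent")
  v <- m$values; v["P001", 1] <- NA
  expect_error(ruviii_generalized(omics_matrix(v, "proteomics"), rp,
                                  c("P001", "P002"), k = 1), "complete")
  expect_error(ruviii_generalized(m, rp, feature_ids(m)[1:4], k = 99),
               "exceeds")
  # exact replicate agreement: residuals vanish, normalisation is identity
  dup <- m$values
  M <- rp$incidence[colnames(dup), ]
  grp <- apply(M, 1, which.max)
  base <- matrix(rnorm(nrow(dup) * max(grp), 10), nrow(dup))
  dup <- base[, grp] + 0
  dimnames(dup) <- dimnames(m$values)
  md <- omics_matrix(dup, "proteomics")
  fit0 <- ruviii_generalized(md, rp, feature_ids(md)[1:4], k = 1)
  expect_identical(fit0$normalized$values, md$values)
  expect_true(all(fit0$alpha == 0))
})

test_that("missing cells stay missing and a planted batch shift is removed", {
  set.seed(24)
  meta <- paired_meta(8)                      # 16 pairs across batches
  m <- random_omics(meta, 80, sd = 0.05)      # technical noise << batch shift
  shift <- ifelse(meta$batch == "2020", 2, 0) # delta = 2 on all features
  m$values <- m$values + matrix(shift, 80, nrow(meta), byrow = TRUE)
  v <- m$values
  v[cbind(sample(31:80, 200, TRUE), sample(ncol(v), 200, TRUE))] <- NA
  m <- omics_matrix(v, "proteomics")
  ctl <- feature_ids(m)[1:15]                 # complete by construction
  rp <- build_replicate_map(meta)
  fit <- ruviii_generalized(m, rp, ctl, k = 1)
  expect_identical(fit$normalized$mask, m$mask)
  dg <- normalization_diagnostics(fit, meta)
  expect_lt(dg$replicate_rms["after"], 0.1 * dg$replicate_rms["before"])
})

test_that("frozen-loading refit yields a null correction (projection property)", {
  set.seed(25)
  meta <- paired_meta(6)
  m <- random_omics(meta, 60)
  W <- matrix(rnorm(24), 24, 1); al <- matrix(rnorm(60), 1, 60)
  m$values <- m$values + t(W %*% al)
  rp <- build_replicate_map(meta)
  ctl <- feature_ids(m)[1:20]
  fit <- ruviii_generalized(m, rp, ctl, k = 1)
  # re-derive W from the normalised control block with alpha frozen
  Yc1 <- t(fit$normalized$values[ctl, ])
  ac <- fit$alpha[, ctl, drop = FALSE]
  W2 <- Yc1 %*% t(ac) %*% solve(ac %*% t(ac))
  corr2 <- W2 %*% fit$alpha
  corr1 <- t(m$values - fit$normalized$values)
  expect_lt(norm(corr2, "F"), 1e-8 * norm(corr1, "F"))
})

test_that("normalisation improves truth recovery and batch mixing on default cohorts", {
  wins <- 0; n_runs <- 12
  for (s in seq_len(n_runs)) {
    co <- generate_cohort(cohort_spec(seed = 500 + s, n_features = 300))
    m <- merge_batches(co$batches[["2018"]], co$batches[["2020"]])
    m <- inject_missingness(m, co$truth, 0.134, seed = 500 + s)
    f <- filter_by_missingness(m, co$meta)
    ctl <- select_negative_controls(f, variance_scope = "per_batch",
                                    meta = co$meta)
    rp <- build_replicate_map(co$meta)
    fit <- suppressMessages(ruviii_generalized(f, rp, ctl, k = "auto"))
    ts <- co$truth$true_signal[feature_ids(f), sample_ids(f)]
    ctr <- function(x) sweep(x, 1, rowMeans(x, na.rm = TRUE))
    rmse <- function(x) sqrt(mean(ctr(x - ts)^2, na.rm = TRUE))
    if (rmse(fit$normalized$values) < rmse(f$values)) wins <- wins + 1
  }
  expect_gte(wins / n_runs, 0.95)
})

test_that("control variance does not increase after correction (across seeds)", {
  worse <- 0
  for (s in 1:20) {
    co <- generate_cohort(cohort_spec(seed = 600 + s, n_features = 150))
    m <- merge_batches(co$batches[["2018"]], co$batches[["2020"]])
    m <- inject_missingness(m, co$truth, 0.134, seed = 600 + s)
    f <- filter_by_missingness(m, co$meta)
    ctl <- select_negative_controls(f, variance_scope = "per_batch",
                                    meta = co$meta)
    rp <- build_replicate_map(co$meta)
    fit <- suppressMessages(ruviii_generalized(f, rp, ctl, k = "auto"))
    dg <- normalization_diagnostics(fit, co$meta)
    if (dg$control_variance["after"] > dg$control_variance["before"]) {
      worse <- worse + 1
    }
  }
  expect_equal(worse, 0)
})

test_that("diagnostics show no change where there is no batch structure", {
  set.seed(26)
  meta <- paired_meta(6)
  m <- random_omics(meta, 60)
  rp <- build_replicate_map(meta)
  fit <- ruviii_generalized(m, rp, feature_ids(m)[1:20], k = 1)
  dg <- normalization_diagnostics(fit, meta)
  expect_lt(abs(dg$silhouette_batch["after"] - dg$silhouette_batch["before"]),
            0.15)
})
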