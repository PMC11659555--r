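#' Specification of a synthetic two-batch LV/RV cohort
#'
#' Default sample sizes reproduce the study design the pipeline targets:
#' per-condition merged sample counts of 27 LV / 13 RV (Donor),
#' 13 / 5 (DCM) and 19 / 11 (ICM), with about 40% of subject-ventricle
#' profiles measured in both the 2018 and 2020 batches as technical
#' replicates. Unwanted variation is a rank-`k_true` factor model whose
#' first factor is the batch indicator (loading scale `batch_shift`, in
#' log2 units per feature); additional factors model continuous
#' instrument drift. Biology contains per-subject random intercepts and
#' sex / log2(age) covariate effects so that covariate adjustment is
#' genuinely exercised downstream.
#'
#' @param n_samples Named list: per condition, a list with `LV` and `RV`
#'   merged sample counts.
#' @param frac_replicated Fraction of subject-ventricle profiles measured in
#'   both batches.
#' @param n_features Number of features.
#' @param frac_de Fraction of features with a planted LV-RV effect.
#' @param effect_range Magnitude range (log2) of planted effects; signs are
#'   random.
#' @param k_true Number of latent unwanted factors (0 disables all unwanted
#'   variation including the batch factor).
#' @param batch_shift Loading sd (log2) of the batch factor.
#' @param uv_sd Loading sd of the non-batch unwanted factors.
#' @param subject_sd Per-feature subject random-intercept sd.
#' @param sex_sd,sex_frac Sd of sex coefficients and fraction of
#'   biology-variable features carrying one.
#' @param age_sd Sd of log2(age) coefficients.
#' @param resid_sd Residual (technical) sd, log2 units.
#' @param frac_control_eligible Fraction of non-DE features simulated with no
#'   biological variation at all (ideal negative controls).
#' @param missing_rate,mnar_weight Defaults passed to [inject_missingness()]
#'   for the proteomics layer.
#' @param layer Omics layer to emulate.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `CohortSpec` list.
#' @export
cohort_spec <- function(n_samples = list(Donor = list(LV = 27, RV = 13),
                                         DCM = list(LV = 13, RV = 5),
                                         ICM = list(LV = 19, RV = 11)),
                        frac_replicated = 0.4,
                        n_features = 2000,
                        frac_de = 0.1,
                        effect_range = c(0.5, 2),
                        k_true = 1,
                        batch_shift = 2,
                        uv_sd = 1,
                        subject_sd = 0.3,
                        sex_sd = 0.3, sex_frac = 0.2,
                        age_sd = 0.05,
                        resid_sd = 0.15,
                        frac_control_eligible = 0.3,
                        missing_rate = 0.134,
                        mnar_weight = 1,
                        layer = c("proteomics", "metabolomics"),
                        seed = 1L) {
  layer <- match.arg(layer)
  spec <- list(n_samples = n_samples, frac_replicated = frac_replicated,
               n_features = n_features, frac_de = frac_de,
               effect_range = effect_range, k_true = k_true,
               batch_shift = batch_shift, uv_sd = uv_sd,
               subject_sd = subject_sd, sex_sd = sex_sd, sex_frac = sex_frac,
               age_sd = age_sd, resid_sd = resid_sd,
               frac_control_eligible = frac_control_eligible,
               missing_rate = missing_rate, mnar_weight = mnar_weight,
               layer = layer, seed = as.integer(seed))
  stopifnot(frac_replicated >= 0, frac_replicated <= 1,
            frac_de >= 0, frac_de <= 1, n_features > 0, k_true >= 0,
            missing_rate >= 0, missing_rate < 1)
  class(spec) <- "CohortSpec"
  spec
}

# deterministic sub-stream: one master seed, independent named streams
substream_seed <- function(seed, name) {
  (as.integer(seed) + sum(utf8ToInt(name)) * 7919L) %% 2147483629L
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(seed, name))
  expr
}

# lay out subjects and samples for one condition; returns meta rows
plan_condition <- function(cond, n_lv, n_rv, frac_rep, prefix) {
  # a replicated profile contributes two merged columns, a singleton one:
  # d replicated + s singleton with 2d + s = n and d/(d+s) = frac_rep
  plan_loc <- function(n) {
    d <- round(n * frac_rep / (1 + frac_rep))
    s <- n - 2L * d
    if (s < 0L) stop("replicated fraction too high for ", cond,
                     ": needs more replicated profiles than subjects")
    c(replicated = d, singleton = s)
  }
  lv <- plan_loc(n_lv); rv <- plan_loc(n_rv)
  n_subj <- lv[["replicated"]] + lv[["singleton"]]
  if (rv[["replicated"]] + rv[["singleton"]] > n_subj) {
    stop("more RV than LV subjects requested for ", cond)
  }
  subjects <- sprintf("%s%02d", prefix, seq_len(n_subj))
  # first subjects carry the replicated LV profiles; RV profiles are placed
  # on the same hearts first so cross-batch replication co-occurs per heart
  rows <- list()
  add <- function(subj, loc, batches) {
    for (b in batches) {
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = paste(subj, loc, b, sep = "_"), subject_id = subj,
        condition = cond, location = loc, batch = b,
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(n_subj)) {
    add(subjects[i], "LV", if (i <= lv[["replicated"]]) c("2018", "2020") else "2020")
  }
  n_rv_subj <- rv[["replicated"]] + rv[["singleton"]]
  for (i in seq_len(n_rv_subj)) {
    add(subjects[i], "RV", if (i <= rv[["replicated"]]) c("2018", "2020") else "2020")
  }
  do.call(rbind, rows)
}

#' Generate a synthetic two-batch cohort with known ground truth
#'
#' Builds per-batch abundance matrices, sample metadata and a `GroundTruth`
#' object. Shared subject profiles appear in both batches with identical
#' biology (`true_signal`) but batch-specific unwanted variation
#' `W alpha` plus residual noise. The proteomics layer is returned complete;
#' apply [inject_missingness()] to emulate intensity-dependent non-detection.
#'
#' @param spec A [cohort_spec()].
#' @return List with `batches` (named list of `OmicsMatrix`, one per batch),
#'   `meta` (metadata for all merged samples) and `truth` (list: `true_signal`
#'   features x samples, `W` samples x k, `alpha` k x features, `de_effects`
#'   named log2 effects, `control_eligible` feature IDs).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "CohortSpec"))
  meta <- do.call(rbind, lapply(names(spec$n_samples), function(cond) {
    prefix <- c(Donor = "D", DCM = "C", ICM = "I")[[cond]]
    plan_condition(cond, spec$n_samples[[cond]]$LV, spec$n_samples[[cond]]$RV,
                   spec$frac_replicated, prefix)
  }))
  subjects <- unique(meta$subject_id)
  covar <- with_substream(spec$seed, "covariates", {
    data.frame(subject_id = subjects,
               sex = rep(c("M", "F"), length.out = length(subjects)),
               age = round(runif(length(subjects), 30, 70), 1),
               stringsAsFactors = FALSE)
  })
  meta <- merge(meta, covar, by = "subject_id", sort = FALSE)
  meta <- meta[, c("sample_id", "subject_id", "condition", "location",
                   "sex", "age", "batch")]
  meta <- validate_sample_meta(meta)
  n_s <- nrow(meta)
  n_f <- spec$n_features
  fid_prefix <- if (spec$layer == "proteomics") "P" else "M"
  feats <- sprintf("%s%04d", fid_prefix, seq_len(n_f))

  # --- feature-level biology ------------------------------------------------
  fx <- with_substream(spec$seed, "features", {
    n_de <- round(spec$frac_de * n_f)
    de_idx <- if (n_de > 0) sample.int(n_f, n_de) else integer(0)
    de_eff <- setNames(numeric(n_f), feats)
    de_eff[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
      runif(n_de, spec$effect_range[1], spec$effect_range[2])
    non_de <- setdiff(seq_len(n_f), de_idx)
    ctl_idx <- sample(non_de, round(spec$frac_control_eligible * length(non_de)))
    bio <- setdiff(seq_len(n_f), ctl_idx)  # features with biological variation
    sex_coef <- numeric(n_f)
    carries_sex <- intersect(bio, sample.int(n_f, round(spec$sex_frac * n_f)))
    sex_coef[carries_sex] <- rnorm(length(carries_sex), 0, spec$sex_sd)
    age_coef <- numeric(n_f)
    age_coef[bio] <- rnorm(length(bio), 0, spec$age_sd)
    list(baseline = rnorm(n_f, 20, 2), de_idx = de_idx, de_eff = de_eff,
         ctl_idx = ctl_idx, bio = bio, sex_coef = sex_coef, age_coef = age_coef)
  })

  # --- true signal: biology only -------------------------------------------
  true_signal <- with_substream(spec$seed, "subjects", {
    b_subj <- matrix(0, n_f, length(subjects),
                     dimnames = list(feats, subjects))
    b_subj[fx$bio, ] <- rnorm(length(fx$bio) * length(subjects),
                              0, spec$subject_sd)
    ts <- matrix(fx$baseline, n_f, n_s, dimnames = list(feats, meta$sample_id))
    ts <- ts + b_subj[, meta$subject_id, drop = FALSE]
    ts <- ts + outer(fx$sex_coef, as.numeric(meta$sex == "M"))
    ts <- ts + outer(fx$age_coef, log2(meta$age))
    ts <- ts + outer(fx$de_eff, as.numeric(meta$location == "LV"))
    ts
  })

  # --- unwanted variation: batch factor + drift factors ---------------------
  kn <- if (spec$k_true > 0) paste0("W", seq_len(spec$k_true)) else NULL
  W <- matrix(0, n_s, spec$k_true, dimnames = list(meta$sample_id, kn))
  alpha <- matrix(0, spec$k_true, n_f, dimnames = list(kn, feats))
  if (spec$k_true >= 1) {
    wa <- with_substream(spec$seed, "unwanted", {
      W[, 1] <- ifelse(meta$batch == "2020", 1, -1)
      alpha[1, ] <- rnorm(n_f, 0, spec$batch_shift)
      if (spec$k_true >= 2) {
        for (j in 2:spec$k_true) {
          W[, j] <- rnorm(n_s)
          alpha[j, ] <- rnorm(n_f, 0, spec$uv_sd)
        }
      }
      list(W = W, alpha = alpha)
    })
    W <- wa$W; alpha <- wa$alpha
  }

  noise <- with_substream(spec$seed, "residuals", {
    matrix(rnorm(n_f * n_s, 0, spec$resid_sd), n_f, n_s)
  })
  Y <- true_signal + t(W %*% alpha) + noise

  batches <- lapply(split(meta$sample_id, meta$batch), function(ids) {
    omics_matrix(Y[, ids, drop = FALSE], spec$layer)
  })
  truth <- list(true_signal = true_signal, W = W, alpha = alpha,
                de_effects = fx$de_eff[fx$de_idx],
                de_features = feats[fx$de_idx],
                control_eligible = feats[fx$ctl_idx])
  list(batches = batches, meta = meta, truth = truth, spec = spec)
}

#' Inject intensity-dependent missingness
#'
#' Marks observed cells missing with probability that mixes a uniform
#' (missing-completely-at-random) component with a censoring-like component
#' that increases as the underlying true intensity decreases - the regime of
#' data-independent-acquisition proteomics, where low-abundance peptides drop
#' below detection. The mixture is rescaled so the expected overall missing
#' fraction equals `rate`.
#'
#' @param m An `OmicsMatrix` (proteomics; metabolomics layers must be called
#'   with `rate = 0`).
#' @param truth Ground truth from [generate_cohort()] (uses `true_signal`).
#' @param rate Target overall missing fraction in `[0, 1)`.
#' @param mnar_weight Weight of the intensity-dependent component in `[0, 1]`;
#'   0 gives pure MCAR, 1 pure censoring.
#' @param seed Integer seed.
#' @return The matrix with additional cells set missing.
#' @export
inject_missingness <- function(m, truth, rate, mnar_weight = 1, seed = 1L) {
  stopifnot_omics(m)
  if (rate >= 1) stop("missingness rate must be < 1")
  if (rate < 0) stop("missingness rate must be >= 0")
  if (rate == 0) return(m)
  if (m$layer == "metabolomics") {
    stop("metabolomics layers are complete; call with rate = 0")
  }
  ts <- truth$true_signal[rownames(m$values), colnames(m$values), drop = FALSE]
  z <- (ts - mean(ts)) / sd(ts)
  # steep censoring: dropout concentrates on dim features, so a substantial
  # fraction of bright features stays complete (as in DIA data, where the
  # complete low-variance proteins serve as negative controls)
  score <- plogis(-4 * z)
  score <- score / mean(score)         # unit mean, preserves overall rate
  p <- rate * ((1 - mnar_weight) + mnar_weight * score)
  p <- pmin(p, 0.99)
  drop <- with_substream(seed, "missingness", {
    matrix(runif(length(p)) < p, nrow(p), ncol(p))
  })
  v <- m$values
  v[drop & m$mask] <- NA_real_
  omics_matrix(v, m$layer)
}
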