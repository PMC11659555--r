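#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Defaults mirror the study
#' conventions: 0.75 per-batch missingness filter, BH FDR 0.05 for DE sets,
#' enrichment reporting at p <= 0.05, RUV `k = "auto"` (samples minus
#' replicate groups), network top-N of 200 for Donor and ICM and 4 for DCM,
#' walk length 4. When `simulate` is `TRUE` the input matrices come from
#' [generate_cohort()] under `cohort` / `cohort_metabolomics`; otherwise
#' `paths` must point at per-batch TSVs and a metadata CSV.
#'
#' @param seed Integer master seed; recorded in every output.
#' @param out_dir Output directory.
#' @param simulate Generate synthetic input data.
#' @param cohort [cohort_spec()] for the proteomics layer.
#' @param cohort_metabolomics [cohort_spec()] for the metabolomics layer.
#' @param missingness_threshold,de_fdr,enrichment_alpha Thresholds in [0,1].
#' @param ruv_k `"auto"` (parallel-analysis choice) or integer.
#' @param control_variance_scope `"per_batch"` (default; variances computed
#'   within each batch, robust to batch-loading dominance) or `"merged"`;
#'   see [select_negative_controls()].
#' @param top_n Named list of per-condition network sizes.
#' @param knn_k,walk_length,min_overlap Network stage parameters.
#' @param mds_top Pairwise gene count for MDS distances.
#' @param paths Named list of input files (`proteomics_2018`,
#'   `proteomics_2020`, `metabolomics_2018`, `metabolomics_2020`, `meta`,
#'   `kegg_gmt`, `gomf_gmt`); unused when simulating.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = tempfile("bivomics_run_"),
                            simulate = TRUE,
                            cohort = cohort_spec(seed = seed),
                            cohort_metabolomics = cohort_spec(
                              n_features = 100, frac_de = 0.25,
                              missing_rate = 0, layer = "metabolomics",
                              seed = seed + 101L),
                            missingness_threshold = 0.75,
                            de_fdr = 0.05,
                            enrichment_alpha = 0.05,
                            ruv_k = "auto",
                            control_variance_scope = "per_batch",
                            top_n = list(Donor = 200, DCM = 4, ICM = 200),
                            knn_k = "auto",
                            walk_length = 4,
                            min_overlap = 5,
                            mds_top = 500,
                            paths = list()) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir, simulate = simulate,
              cohort = cohort, cohort_metabolomics = cohort_metabolomics,
              missingness_threshold = missingness_threshold, de_fdr = de_fdr,
              enrichment_alpha = enrichment_alpha, ruv_k = ruv_k,
              control_variance_scope = control_variance_scope,
              top_n = top_n, knn_k = knn_k, walk_length = walk_length,
              min_overlap = min_overlap, mds_top = mds_top, paths = paths)
  stopifnot(missingness_threshold > 0, missingness_threshold <= 1,
            de_fdr >= 0, de_fdr <= 1, enrichment_alpha >= 0,
            enrichment_alpha <= 1, all(unlist(top_n) >= 2))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Fields absent from the file keep their [pipeline_config()] defaults;
#' `cohort:` entries override individual [cohort_spec()] arguments.
#'
#' @param path YAML file path.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- if (!is.null(y$seed)) as.integer(y$seed) else 1L
  cohort_args <- y$cohort %||% list()
  cohort_args$seed <- cohort_args$seed %||% seed
  met_args <- y$cohort_metabolomics %||% list()
  args <- y[setdiff(names(y), c("cohort", "cohort_metabolomics"))]
  args$seed <- seed
  args$cohort <- do.call(cohort_spec, cohort_args)
  if (length(met_args)) {
    met_args$layer <- "metabolomics"
    met_args$seed <- met_args$seed %||% (seed + 101L)
    args$cohort_metabolomics <- do.call(cohort_spec, met_args)
  }
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(...) message(sprintf("[bivomics] %s", sprintf(...)))

write_tsv <- function(df, path) {
  write.table(format(df, digits = 15, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  path
}

# random sets over the simulated feature space; used when no GMT is supplied.
# These are synthetic annotation stand-ins, not curated pathways.
make_synthetic_genesets <- function(features, n_sets, size_range = c(8, 40),
                                    source = "KEGG-like", seed = 1L,
                                    prefix = "SET") {
  with_substream(seed, paste0("genesets_", prefix), {
    sets <- lapply(seq_len(n_sets), function(i) {
      sample(features, min(length(features),
                           sample(size_range[1]:size_range[2], 1L)))
    })
    names(sets) <- sprintf("%s_%03d_synthetic", prefix, seq_len(n_sets))
    geneset_collection(sets, source = source)
  })
}

#' Run the full analysis pipeline
#'
#' Executes, per layer: batch merging (feature union for proteomics,
#' intersection for metabolomics), the per-batch missingness filter
#' (proteomics only), negative-control selection, generalised RUV-III,
#' differential analysis per scope (Donor, DCM, ICM and pooled heart
#' failure; ventricle contrast plus donor sex contrasts), pathway
#' over-representation of the up/down DE protein sets, mean-rank set tests
#' on the donor metabolite t-statistics, MDS coordinates, and the per-
#' condition DE-protein correlation networks with MST-kNN / walktrap
#' clustering and competitive term annotation. All outputs are written to
#' `config$out_dir`; a manifest records the seed, configuration, stage
#' timings, surviving feature counts and an MD5 hash of every file.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   config = config[setdiff(names(config), "cohort")],
                   stages = list(), counts = list(), outputs = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  log_msg("run starting, seed = %d, out = %s", config$seed, config$out_dir)

  # ---- inputs --------------------------------------------------------------
  inputs <- t_stage("input", {
    if (config$simulate) {
      prot <- generate_cohort(config$cohort)
      prot$batches <- lapply(prot$batches, function(b) {
        inject_missingness(b, prot$truth, config$cohort$missing_rate,
                           config$cohort$mnar_weight,
                           seed = config$cohort$seed)
      })
      met <- generate_cohort(config$cohort_metabolomics)
      list(prot = prot, met = met, meta = prot$meta, meta_met = met$meta)
    } else {
      p <- config$paths
      list(prot = list(batches = list(
             `2018` = read_matrix(p$proteomics_2018, "proteomics"),
             `2020` = read_matrix(p$proteomics_2020, "proteomics"))),
           met = list(batches = list(
             `2018` = read_matrix(p$metabolomics_2018, "metabolomics"),
             `2020` = read_matrix(p$metabolomics_2020, "metabolomics"))),
           meta = read_sample_meta(p$meta),
           meta_met = read_sample_meta(p$meta))
    }
  })
  meta <- inputs$meta

  gmt_kegg <- if (!is.null(config$paths$kegg_gmt)) {
    read_gmt(config$paths$kegg_gmt, "KEGG-like")
  } else {
    make_synthetic_genesets(rownames(inputs$prot$batches[[1]]$values), 25,
                            source = "KEGG-like", seed = config$seed,
                            prefix = "PWY")
  }
  gmt_gomf <- if (!is.null(config$paths$gomf_gmt)) {
    read_gmt(config$paths$gomf_gmt, "GO-MF-like")
  } else {
    make_synthetic_genesets(rownames(inputs$prot$batches[[1]]$values), 40,
                            source = "GO-MF-like", seed = config$seed,
                            prefix = "GOMF")
  }
  gmt_met <- make_synthetic_genesets(rownames(inputs$met$batches[[1]]$values),
                                     15, size_range = c(5, 15),
                                     source = "KEGG-like",
                                     seed = config$seed, prefix = "METPWY")

  out <- function(name, df) {
    path <- file.path(config$out_dir, name)
    write_tsv(df, path)
    manifest$outputs[[name]] <<- unname(tools::md5sum(path))
    path
  }

  # ---- proteomics ----------------------------------------------------------
  prot_norm <- t_stage("normalize_proteomics", {
    merged <- merge_batches(inputs$prot$batches[[1]], inputs$prot$batches[[2]])
    meta_p <- validate_sample_meta(meta, merged)
    filtered <- filter_by_missingness(merged, meta_p,
                                      config$missingness_threshold)
    ctl <- select_negative_controls(filtered,
                                    variance_scope = config$control_variance_scope,
                                    meta = meta_p)
    repmap <- build_replicate_map(meta_p)
    fit <- ruviii_generalized(filtered, repmap, ctl, k = config$ruv_k)
    manifest$counts$proteomics <- list(
      features_merged = nrow(merged$values),
      features_filtered = nrow(filtered$values),
      controls = length(ctl), k = fit$k,
      missing_fraction = round(mean(!filtered$mask), 4))
    write_matrix(merged, file.path(config$out_dir, "proteomics_merged.tsv"))
    write_matrix(fit$normalized,
                 file.path(config$out_dir, "proteomics_normalized.tsv"))
    log_msg("proteomics: %d features, %d controls, k = %d",
            nrow(filtered$values), length(ctl), fit$k)
    fit
  })
  meta_p <- validate_sample_meta(meta, prot_norm$normalized)

  scopes <- list(donor = "Donor", dcm = "DCM", icm = "ICM",
                 hf = c("DCM", "ICM"))
  de_prot <- t_stage("de_proteomics", {
    lapply(scopes, function(sc) {
      for (cond in sc) {
        for (loc in c("LV", "RV")) {
          n <- sum(meta_p$condition == cond & meta_p$location == loc)
          log_msg("n_%s,%s = %d", cond, loc, n)
        }
      }
      de_analysis(prot_norm$normalized, meta_p, sc, "LVvsRV")
    })
  })
  for (nm in names(de_prot)) out(sprintf("de_proteomics_%s.tsv", nm), de_prot[[nm]])

  t_stage("de_proteomics_sex", {
    for (cf in c("sexM_LV", "sexM_RV")) {
      res <- de_analysis(prot_norm$normalized, meta_p, "Donor", "MvsF",
                         coef = cf)
      out(sprintf("de_proteomics_donor_sex_%s.tsv", sub("sexM_", "", cf)), res)
    }
    NULL
  })

  t_stage("mds", {
    xy <- mds_coordinates(prot_norm$normalized, top = config$mds_top)
    out("mds_proteomics.tsv",
        data.frame(sample_id = rownames(xy), xy, check.names = FALSE))
    NULL
  })

  t_stage("enrichment_proteomics", {
    universe <- feature_ids(prot_norm$normalized)
    for (nm in c("donor", "icm", "hf")) {
      de <- de_prot[[nm]]
      sig <- de[!de$skipped & de$adj.P.Val <= config$de_fdr, , drop = FALSE]
      for (dir in c("up", "down")) {
        ids <- sig$feature[sig$direction == dir]
        if (!length(ids)) next
        enr <- ora_hypergeometric(ids, universe, gmt_kegg,
                                  alpha = config$enrichment_alpha,
                                  direction = dir)
        out(sprintf("enrichment_proteomics_%s_%s.tsv", nm, dir), enr)
      }
    }
    NULL
  })

  # ---- proteomics networks -------------------------------------------------
  t_stage("network", {
    for (cond in c("Donor", "DCM", "ICM")) {
      de <- de_prot[[tolower(cond)]]
      n_avail <- sum(!de$skipped)
      n_sig <- sum(!de$skipped & de$adj.P.Val <= config$de_fdr)
      n_req <- min(config$top_n[[cond]] %||% 200, n_avail)
      if (n_sig < n_req) {
        # mirror the study convention of sizing the network by the DE count
        warning(sprintf(
          "network %s: only %d significant features for top-N %d; using %d",
          cond, n_sig, n_req, max(n_sig, 2L)))
        n_req <- max(n_sig, 2L)
      }
      nodes <- select_top_n(de, n_req)
      in_scope <- meta_p$sample_id[meta_p$condition == cond]
      g <- correlation_graph(prot_norm$normalized, nodes, in_scope,
                             min_overlap = config$min_overlap)
      cm <- mst_knn_cluster(g, k = config$knn_k)
      wt <- walktrap_communities(cm, t = config$walk_length)
      ann <- annotate_clusters(wt$membership, gmt_gomf, g$r)
      out(sprintf("network_%s_edges.tsv", tolower(cond)), cm$edges)
      out(sprintf("network_%s_communities.tsv", tolower(cond)),
          data.frame(feature = names(wt$membership),
                     mstknn_cluster = unname(cm$membership[names(wt$membership)]),
                     community = unname(wt$membership),
                     annotation = unname(ann$labels[as.character(wt$membership)]),
                     stringsAsFactors = FALSE))
      log_msg("network %s: %d nodes, %d communities, Q = %.3f", cond,
              length(nodes), length(unique(wt$membership)), wt$modularity)
    }
    NULL
  })

  # ---- metabolomics --------------------------------------------------------
  met_norm <- t_stage("normalize_metabolomics", {
    merged <- merge_batches(inputs$met$batches[[1]], inputs$met$batches[[2]])
    meta_m <- validate_sample_meta(inputs$meta_met, merged)
    ctl <- select_negative_controls(merged,
                                    variance_scope = config$control_variance_scope,
                                    meta = meta_m)
    repmap <- build_replicate_map(meta_m)
    fit <- ruviii_generalized(merged, repmap, ctl, k = config$ruv_k)
    manifest$counts$metabolomics <- list(
      features_merged = nrow(merged$values), controls = length(ctl), k = fit$k)
    write_matrix(fit$normalized,
                 file.path(config$out_dir, "metabolomics_normalized.tsv"))
    fit
  })
  meta_m <- validate_sample_meta(inputs$meta_met, met_norm$normalized)

  da_met <- t_stage("da_metabolomics", {
    lapply(scopes, function(sc) {
      de_analysis(met_norm$normalized, meta_m, sc, "LVvsRV")
    })
  })
  for (nm in names(da_met)) out(sprintf("da_metabolomics_%s.tsv", nm), da_met[[nm]])

  t_stage("meanrank_metabolomics", {
    de <- da_met$donor
    tstats <- setNames(de$t[!de$skipped], de$feature[!de$skipped])
    rows <- do.call(rbind, lapply(names(gmt_met$sets), function(nm) {
      members <- intersect(gmt_met$sets[[nm]], names(tstats))
      if (length(members) < 2L || length(members) >= length(tstats)) return(NULL)
      data.frame(set = nm, n_members = length(members),
                 p_up = mean_rank_set_test(tstats, members, "up"),
                 p_down = mean_rank_set_test(tstats, members, "down"),
                 p_mixed = mean_rank_set_test(tstats, members, "mixed"),
                 stringsAsFactors = FALSE)
    }))
    out("meanrank_metabolomics_donor.tsv", rows)
    NULL
  })

  manifest_path <- file.path(config$out_dir, "manifest.json")
  manifest$config$cohort <- unclass(config$cohort)
  manifest$config$cohort_metabolomics <- unclass(config$cohort_metabolomics)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  log_msg("run complete: %d outputs", length(manifest$outputs))
  invisible(manifest)
}
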