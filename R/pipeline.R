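#' Pipeline configuration
#'
#' Collects paths and thresholds for a full run. Every analysis threshold
#' defaults to the study's stated setting: 80% presence, 3-SD outlier rule,
#' 1% explained-variance floor, q < 0.05 consensus, q < 0.01 graph nodes,
#' set sizes 5-300.
#'
#' @param matrices named character vector: tissue -> intensity TSV path.
#' @param metadata path to the metadata TSV.
#' @param gmt path to the gene-set GMT file.
#' @param out_dir output directory (created if needed).
#' @param identifier_lists optional path to an ordered-identifier TSV
#'   (columns `protein_id`, `ordered_ids` semicolon-delimited).
#' @param contrasts list of [contrast_spec()]s (default
#'   [default_contrasts()]).
#' @param candidate_covariates covariate columns screened for selection.
#' @param min_frac,outlier_sd,ev_threshold,alpha,node_q,set_size,edge_threshold
#'   analysis thresholds (see Description); `set_size` is `c(min, max)`.
#' @param n_perm GSEA permutations per set size (default 10000).
#' @param impute `"qrilc"`, `"halfmin"` or `"none"`.
#' @param fdr_method `"BH"` or `"storey"`.
#' @param seed integer master seed.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(matrices, metadata, gmt, out_dir,
                            identifier_lists = NULL,
                            contrasts = default_contrasts(),
                            candidate_covariates = c("BMI", "age", "CIT",
                                                     "ICU_days", "purity"),
                            min_frac = 0.8, outlier_sd = 3,
                            ev_threshold = 0.01, alpha = 0.05,
                            node_q = 0.01, set_size = c(5, 300),
                            edge_threshold = 0.5, n_perm = 10000,
                            impute = c("qrilc", "halfmin", "none"),
                            fdr_method = "BH", seed = 1L) {
  impute <- match.arg(impute)
  stopifnot(min_frac > 0, min_frac <= 1, outlier_sd > 0,
            ev_threshold >= 0, alpha > 0, alpha < 1, node_q > 0,
            node_q <= 1, length(set_size) == 2, set_size[1] <= set_size[2],
            n_perm >= 1)
  structure(list(matrices = matrices, metadata = metadata, gmt = gmt,
                 out_dir = out_dir, identifier_lists = identifier_lists,
                 contrasts = contrasts,
                 candidate_covariates = candidate_covariates,
                 min_frac = min_frac, outlier_sd = outlier_sd,
                 ev_threshold = ev_threshold, alpha = alpha,
                 node_q = node_q, set_size = set_size,
                 edge_threshold = edge_threshold, n_perm = n_perm,
                 impute = impute, fdr_method = fdr_method,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file; keys match the arguments of [pipeline_config()],
#'   with contrasts given as `name: {A: [...], B: [...]}` maps.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$contrasts))
    y$contrasts <- lapply(names(y$contrasts), function(nm)
      contrast_spec(nm, unlist(y$contrasts[[nm]]$A), unlist(y$contrasts[[nm]]$B)))
  y$matrices <- unlist(y$matrices)
  do.call(pipeline_config, y)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- lapply(cfg, function(x) if (inherits(x, "Contrast")) unclass(x) else x)
  plain$contrasts <- lapply(cfg$contrasts, unclass)
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full downstream analysis
#'
#' Stages: (1) QC — sample outlier exclusion by the consistent 3-SD rule,
#' presence filtering per tissue; (2) normalization and imputation —
#' median sweep then QRILC; (3) identifier resolution against the GMT
#' universe and gene-level aggregation; (4) covariate selection by median
#' explained variance; (5) differential analysis per tissue x contrast
#' with pi-value ranking; (6) dual enrichment (competitive parametric +
#' permutation GSEA) with the same-direction consensus rule; (7)
#' enrichment-map graph per tissue x contrast. All outputs are TSV/JSON
#' under `cfg$out_dir`; a manifest records the config hash and per-stage
#' row counts. Reruns with the same config are byte-identical.
#'
#' @param cfg a [pipeline_config()] or path to its YAML form.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "PipelineConfig"))
  for (p in c(cfg$matrices, cfg$metadata, cfg$gmt))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_counts <- list()
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
  }

  meta <- utils::read.delim(cfg$metadata, stringsAsFactors = FALSE)
  meta$group <- factor(meta$group, levels = c("CTRL", "PD", "T2D"))
  mats <- lapply(names(cfg$matrices), function(t)
    read_intensity_tsv(cfg$matrices[[t]], tissue = t, scale = "log2"))
  names(mats) <- names(cfg$matrices)
  sets <- read_gmt(cfg$gmt)

  # stage 1: QC
  qc_dir <- file.path(cfg$out_dir, "qc")
  dir.create(qc_dir, showWarnings = FALSE)
  step("qc", {
    reports <- lapply(mats, detect_outlier_samples, k = cfg$outlier_sd)
    excluded <- consistent_outliers(reports, meta)
    mats <- lapply(mats, function(m)
      drop_samples(m, meta$sample_id[meta$subject_id %in% excluded]))
    filtered <- lapply(mats, presence_filter, min_frac = cfg$min_frac)
    mats <- lapply(filtered, `[[`, "matrix")
    qc_json <- list(
      excluded_subjects = as.list(excluded),
      outlier_scores = lapply(reports, `[[`, "sample_scores"),
      presence = lapply(filtered, function(f)
        list(before = f$report$proteins_before,
             after = f$report$proteins_after)))
    jsonlite::write_json(qc_json, file.path(qc_dir, "qc_report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    stage_counts$qc <- vapply(mats, function(m) nrow(values(m)), 0L)
  })

  # stage 2: normalize + impute
  step("normalize_impute", {
    mats <- lapply(mats, median_sweep)
    if (cfg$impute == "qrilc") {
      mats <- lapply(mats, qrilc_impute,
                      params = impute_params(seed = cfg$seed))
    } else if (cfg$impute == "halfmin") {
      mats <- lapply(mats, halfmin_impute)
    }
    for (t in names(mats))
      write_intensity_tsv(mats[[t]],
                          file.path(cfg$out_dir, paste0("normalized_", t, ".tsv")))
    stage_counts$normalize_impute <- vapply(mats, function(m)
      sum(is.na(values(m))), 0L)
  })

  # stage 3: identifier resolution + gene aggregation + tissue overlap
  step("id_resolution", {
    universe <- build_universe(sets)
    for (t in names(mats)) {
      m <- mats[[t]]
      ids <- rownames(values(m))
      if (!is.null(cfg$identifier_lists)) {
        rec <- utils::read.delim(cfg$identifier_lists, stringsAsFactors = FALSE)
        rec <- rec[match(ids, rec$protein_id), , drop = FALSE]
        rec$ordered_ids[is.na(rec$ordered_ids)] <- ids[is.na(rec$ordered_ids)]
        gene_of <- stats::setNames(
          resolve_identifiers(rec, universe)$resolved, ids)
      } else {
        gene_of <- stats::setNames(ids, ids)
      }
      mats[[t]] <- aggregate_gene_duplicates(m, gene_of)
    }
    overlap <- compute_tissue_overlap(mats)
    jsonlite::write_json(overlap, file.path(cfg$out_dir, "tissue_overlap.json"),
                         auto_unbox = FALSE)
    stage_counts$id_resolution <- vapply(mats, function(m)
      nrow(values(m)), 0L)
  })

  # stage 4: covariate selection
  covariates <- character(0)
  step("covariates", {
    ev <- explained_variance_by_tissue(mats, meta, cfg$candidate_covariates)
    covariates <- select_covariates(ev, threshold = cfg$ev_threshold)
    write_tsv(ev, file.path(cfg$out_dir, "explained_variance.tsv"))
    jsonlite::write_json(list(selected = as.character(covariates)),
                         file.path(cfg$out_dir, "covariates.json"),
                         auto_unbox = FALSE)
    stage_counts$covariates <- length(covariates)
  })

  # stage 5: differential analysis per tissue x contrast
  diff_dir <- file.path(cfg$out_dir, "differential")
  dir.create(diff_dir, showWarnings = FALSE)
  diffs <- list()
  step("differential", {
    restricted <- attr(covariates, "tissue_restricted")
    for (t in names(mats)) {
      covs <- as.character(covariates)
      for (cv in names(restricted))
        if (!t %in% restricted[[cv]]) covs <- setdiff(covs, cv)
      for (ct in cfg$contrasts) {
        d <- run_differential(mats[[t]], meta, ct, covariates = covs,
                              fdr_method = cfg$fdr_method)
        diffs[[paste(t, ct$name, sep = ".")]] <- d
        write_tsv(d, file.path(diff_dir,
                               paste0(t, "_", ct$name, ".tsv")))
      }
    }
    stage_counts$differential <- length(diffs)
  })

  # stage 6: dual enrichment + consensus
  enr_dir <- file.path(cfg$out_dir, "enrichment")
  dir.create(enr_dir, showWarnings = FALSE)
  consensus_tables <- list()
  step("enrichment", {
    for (key in names(diffs)) {
      ranked <- pi_ranking(diffs[[key]])
      cam <- camera_pr(ranked, sets)
      gs <- gsea_preranked(ranked, sets, n_perm = cfg$n_perm,
                           min_size = cfg$set_size[1],
                           max_size = cfg$set_size[2], seed = cfg$seed)
      cons <- consensus_enrichment(cam, gs, alpha = cfg$alpha,
                                   fdr_method = cfg$fdr_method)
      consensus_tables[[key]] <- cons
      write_tsv(cons, file.path(enr_dir, paste0(key, ".tsv")))
    }
    stage_counts$enrichment <- vapply(consensus_tables, function(x)
      sum(x$consensus), 0L)
  })

  # stage 7: enrichment-map graphs
  graph_dir <- file.path(cfg$out_dir, "graphs")
  dir.create(graph_dir, showWarnings = FALSE)
  step("graph", {
    for (key in names(consensus_tables)) {
      g <- build_enrichment_graph(consensus_tables[[key]], sets,
                                  node_q = cfg$node_q,
                                  threshold = cfg$edge_threshold)
      write_graph_json(g, file.path(graph_dir, paste0(key, ".json")))
    }
    stage_counts$graph <- length(consensus_tables)
  })

  manifest <- list(package_version = as.character(utils::packageVersion("protflow")),
                   config_hash = config_hash(cfg), seed = cfg$seed,
                   stages = stage_counts)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Write a small ready-to-run synthetic workspace
#'
#' Generates a compact cohort (3 tissues, 43 subjects split 17/14/12, 500
#' proteins, 60 gene sets with 3 planted up-regulated sets in T2D vs CTRL),
#' applies left-censored missingness, and writes matrices, metadata, GMT,
#' ground truth and a pipeline YAML config into `dir`.
#'
#' @param dir workspace directory.
#' @param seed integer seed.
#' @param n_proteins,n_sets scale knobs for the demo.
#' @return Path to the written config file, invisibly; the ground truth is
#'   in `truth.json`.
#' @export
make_demo <- function(dir, seed = 1L, n_proteins = 500, n_sets = 60) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sets <- generate_gene_sets(n_sets, size_range = c(10, 30),
                             universe_size = n_proteins, seed = seed,
                             path = file.path(dir, "sets.gmt"))
  spec <- cohort_spec(tissues = c("islet", "liver", "muscle"), seed = seed)
  meta <- generate_cohort(spec)
  planted <- lapply(names(sets)[seq_len(3)], function(nm)
    list(set = nm, delta = 1,
         contrast = contrast_spec("T2D_vs_CTRL", "CTRL", "T2D")))
  sig <- signal_spec(planted_sets = planted,
                     covariate_effects = list(
                       list(covariate = "BMI", slope = 0.05, n_proteins = 50)))
  gen <- generate_proteome(meta, n_proteins, sig, sets, seed = seed)
  mats <- lapply(gen$matrices, apply_missingness, cspec = censor_spec(),
                 seed = seed)
  paths <- character(0)
  for (t in names(mats)) {
    p <- file.path(dir, paste0("intensities_", t, ".tsv"))
    write_intensity_tsv(mats[[t]], p)
    paths[t] <- p
  }
  write_tsv(meta, file.path(dir, "metadata.tsv"))
  truth <- gen$truth
  jsonlite::write_json(
    list(enriched_sets = truth$enriched_sets,
         group_offsets = as.data.frame(truth$group_offsets),
         covariate_slopes = as.data.frame(truth$covariate_slopes)),
    file.path(dir, "truth.json"), dataframe = "columns", digits = NA)
  cfg <- list(matrices = as.list(paths),
              metadata = file.path(dir, "metadata.tsv"),
              gmt = file.path(dir, "sets.gmt"),
              out_dir = file.path(dir, "results"),
              contrasts = list(T2D_vs_CTRL = list(A = "CTRL", B = "T2D"),
                               PD_vs_CTRL = list(A = "CTRL", B = "PD")),
              n_perm = 4000, seed = as.integer(seed))
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
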