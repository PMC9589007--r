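#' Cohort specification for the synthetic generator
#'
#' Describes a multi-tissue organ-donor cohort with three glycemic groups
#' (normoglycemic controls, prediabetes, type 2 diabetes). Defaults mirror
#' the study design the package targets: 17/14/12 subjects per group across
#' five metabolic tissues, with clinical covariates (BMI, age), technical
#' covariates (cold ischemic time in hours, days in intensive care,
#' islet-preparation purity — islet tissue only) and two glycemic traits
#' (HbA1c %, glucose-stimulated insulin secretion).
#'
#' @param n_per_group named integer vector `c(CTRL=, PD=, T2D=)`; all
#'   counts must be >= 2.
#' @param tissues character vector of unique tissue names.
#' @param covariate_params list of per-covariate distribution parameters;
#'   see Details. Unspecified covariates keep their defaults.
#' @param seed integer seed; a fixed seed makes generation byte-identical.
#'
#' @details Continuous covariates are normal (`mean`, `sd`, optional
#' truncation `min`); `ICU_days` is `1 + Poisson(lambda)`; `purity` is
#' uniform on `[min, max]` and only defined for the islet tissue. The traits
#' HbA1c and GSIS are drawn per group (`mean`/`sd` triples in group order
#' CTRL, PD, T2D) so that they separate the groups the way clinical markers
#' of glycemia do.
#' @return A `CohortSpec` list.
#' @export
cohort_spec <- function(n_per_group = c(CTRL = 17, PD = 14, T2D = 12),
                        tissues = c("islet", "liver", "muscle", "vat", "serum"),
                        covariate_params = list(),
                        seed = 1L) {
  groups <- c("CTRL", "PD", "T2D")
  if (is.null(names(n_per_group)) || !setequal(names(n_per_group), groups))
    stop("`n_per_group` must be named CTRL, PD, T2D")
  n_per_group <- n_per_group[groups]
  if (any(n_per_group < 2))
    stop("`n_per_group`: all group counts must be >= 2 (got ",
         paste(n_per_group, collapse = "/"), ")")
  if (anyDuplicated(tissues)) stop("`tissues` must be unique")
  defaults <- list(
    BMI      = list(mean = 26.5, sd = 4,  min = 16),
    age      = list(mean = 58,   sd = 11, min = 18),
    CIT      = list(mean = 11,   sd = 4,  min = 2),   # hours
    ICU_days = list(lambda = 3),
    purity   = list(min = 40, max = 90),               # %, islet only
    HbA1c    = list(mean = c(5.4, 6.2, 7.6), sd = c(0.25, 0.15, 1.0)),
    GSIS     = list(mean = c(25, 17, 8),     sd = c(6, 5, 3), min = 0.5)
  )
  covariate_params <- utils::modifyList(defaults, covariate_params)
  structure(list(n_per_group = n_per_group, tissues = tissues,
                 covariate_params = covariate_params, seed = as.integer(seed)),
            class = "CohortSpec")
}

rtrunc_norm <- function(n, mean, sd, min = -Inf) {
  x <- stats::rnorm(n, mean, sd)
  pmax(x, min)
}

#' Generate a synthetic cohort metadata table
#'
#' Draws one subject per row of the design implied by `spec` and replicates
#' each subject across tissues, producing one sample row per subject x
#' tissue. Covariates are subject-level (identical across that subject's
#' samples); islet purity is present only for islet samples.
#'
#' @param spec a [cohort_spec()].
#' @return A `data.frame` with columns `sample_id`, `subject_id`, `tissue`,
#'   `group` (factor CTRL/PD/T2D), `BMI`, `age`, `CIT`, `ICU_days`,
#'   `purity`, `HbA1c`, `GSIS`.
#' @examples
#' meta <- generate_cohort(cohort_spec(seed = 7))
#' nrow(meta)      # 43 subjects x 5 tissues = 215
#' table(meta$group) / length(unique(meta$tissue))
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  withr::with_seed(spec$seed, {
    n <- sum(spec$n_per_group)
    cp <- spec$covariate_params
    group <- factor(rep(names(spec$n_per_group), spec$n_per_group),
                    levels = c("CTRL", "PD", "T2D"))
    gi <- as.integer(group)
    subjects <- data.frame(
      subject_id = sprintf("p%02d", seq_len(n)),
      group = group,
      BMI = rtrunc_norm(n, cp$BMI$mean, cp$BMI$sd, cp$BMI$min),
      age = rtrunc_norm(n, cp$age$mean, cp$age$sd, cp$age$min),
      CIT = rtrunc_norm(n, cp$CIT$mean, cp$CIT$sd, cp$CIT$min),
      ICU_days = 1L + stats::rpois(n, cp$ICU_days$lambda),
      purity = stats::runif(n, cp$purity$min, cp$purity$max),
      HbA1c = stats::rnorm(n, cp$HbA1c$mean[gi], cp$HbA1c$sd[gi]),
      GSIS = rtrunc_norm(n, cp$GSIS$mean[gi], cp$GSIS$sd[gi], cp$GSIS$min),
      stringsAsFactors = FALSE
    )
    meta <- do.call(rbind, lapply(spec$tissues, function(t) {
      df <- subjects
      df$tissue <- t
      df$sample_id <- paste0(df$subject_id, ".", t)
      if (t != "islet") df$purity <- NA_real_
      df
    }))
    rownames(meta) <- NULL
    meta[, c("sample_id", "subject_id", "tissue", "group", "BMI", "age",
             "CIT", "ICU_days", "purity", "HbA1c", "GSIS")]
  })
}

#' Signal specification: planted effects for recovery experiments
#'
#' @param planted_sets list of entries `list(set =, delta =, contrast =)`
#'   where `set` names a gene set in the collection handed to
#'   [generate_proteome()], `delta` is the per-protein group effect in log2
#'   units, and `contrast` is a [contrast_spec()]: subjects in its B groups
#'   receive `+delta` on every member protein, so the true log-fold change
#'   of B vs A equals `delta`.
#' @param covariate_effects list of entries
#'   `list(covariate =, slope =, n_proteins =)` (or `proteins =` with
#'   explicit gene ids): the covariate, centered at its cohort mean,
#'   contributes `slope * (x - mean(x))` to the chosen proteins.
#' @param baseline_mu_range range of per-protein baseline means, log2 scale.
#' @param baseline_sd sd of the per-subject protein baseline (biological
#'   variation shared across tissues), log2 scale.
#' @param residual_sd sd of the per-sample residual noise, log2 scale; > 0.
#' @return A `SignalSpec` list.
#' @export
signal_spec <- function(planted_sets = list(), covariate_effects = list(),
                        baseline_mu_range = c(16, 28), baseline_sd = 0.5,
                        residual_sd = 0.6) {
  if (residual_sd <= 0) stop("`residual_sd` must be > 0")
  deltas <- vapply(planted_sets, function(p) p$delta, 0)
  if (length(deltas) && any(!is.finite(deltas))) stop("planted `delta` must be finite")
  structure(list(planted_sets = planted_sets,
                 covariate_effects = covariate_effects,
                 baseline_mu_range = baseline_mu_range,
                 baseline_sd = baseline_sd, residual_sd = residual_sd),
            class = "SignalSpec")
}

#' Generate complete multi-tissue intensity matrices with known truth
#'
#' The generative model on the log2 scale is
#' `y[p, s] = mu_p + b[p, subject] + group_offset[p, group] +
#'  sum_c slope_c * (x_c - mean(x_c)) + N(0, residual_sd)`,
#' with `mu_p ~ U(baseline_mu_range)` and subject baselines
#' `b ~ N(0, baseline_sd)` shared across tissues, while group and covariate
#' effects are applied within each tissue. Every planted quantity is
#' recorded in the returned truth object.
#'
#' @param meta cohort table from [generate_cohort()].
#' @param n_proteins number of proteins; must be at least the size of the
#'   largest set in `sets` so planted sets fit.
#' @param signal a [signal_spec()].
#' @param sets a `GeneSetCollection`; proteins are named after its gene
#'   universe (padded with filler genes), so enrichment sees them directly.
#' @param seed integer seed.
#' @return `list(matrices = named list of IntensityMatrix (one per tissue,
#'   scale log2, complete), truth = TruthRecord)`. The truth carries
#'   `group_offsets` (proteins x groups), `covariate_slopes`
#'   (proteins x covariates), `planted_sets`, and helper
#'   [true_logfc()] can read any contrast's true effect off it.
#' @export
generate_proteome <- function(meta, n_proteins, signal = signal_spec(),
                              sets = gene_set_collection(list()), seed = 1L) {
  stopifnot(inherits(signal, "SignalSpec"))
  universe <- unique(unlist(sets, use.names = FALSE))
  if (length(universe) > 0 && n_proteins < max(lengths(sets)))
    stop("`n_proteins` must be >= the largest gene set (",
         max(lengths(sets)), ")")
  for (p in signal$planted_sets)
    if (!p$set %in% names(sets))
      stop("planted set not in collection: ", p$set)

  genes <- if (length(universe) >= n_proteins) universe[seq_len(n_proteins)]
           else c(universe, sprintf("FILLER%05d", seq_len(n_proteins - length(universe))))
  subjects <- unique(meta[, c("subject_id", "group")])
  tissues <- unique(meta$tissue)
  n_sub <- nrow(subjects)
  groups <- c("CTRL", "PD", "T2D")

  withr::with_seed(seed, {
    mu <- stats::runif(n_proteins, signal$baseline_mu_range[1],
                       signal$baseline_mu_range[2])
    b <- matrix(stats::rnorm(n_proteins * n_sub, 0, signal$baseline_sd),
                n_proteins, n_sub,
                dimnames = list(genes, subjects$subject_id))

    group_offsets <- matrix(0, n_proteins, 3, dimnames = list(genes, groups))
    for (p in signal$planted_sets) {
      members <- intersect(sets[[p$set]], genes)
      group_offsets[members, p$contrast$B] <-
        group_offsets[members, p$contrast$B, drop = FALSE] + p$delta
    }

    cov_names <- unique(vapply(signal$covariate_effects,
                               function(e) e$covariate, ""))
    covariate_slopes <- matrix(0, n_proteins, length(cov_names),
                               dimnames = list(genes, cov_names))
    for (e in signal$covariate_effects) {
      prot <- if (!is.null(e$proteins)) e$proteins
              else sample(genes, e$n_proteins)
      covariate_slopes[prot, e$covariate] <-
        covariate_slopes[prot, e$covariate] + e$slope
    }

    matrices <- lapply(tissues, function(t) {
      mt <- meta[meta$tissue == t, , drop = FALSE]
      sub_idx <- match(mt$subject_id, subjects$subject_id)
      v <- mu + b[, sub_idx, drop = FALSE] +
        group_offsets[, as.character(mt$group), drop = FALSE]
      for (cv in cov_names) {
        x <- mt[[cv]]
        if (all(is.na(x))) next
        v <- v + covariate_slopes[, cv, drop = FALSE] %*%
          rbind(x - mean(x, na.rm = TRUE))
      }
      v <- v + matrix(stats::rnorm(length(v), 0, signal$residual_sd),
                      nrow(v), ncol(v))
      dimnames(v) <- list(genes, mt$sample_id)
      intensity_matrix(v, tissue = t, scale = "log2")
    })
    names(matrices) <- tissues

    truth <- structure(list(genes = genes, group_offsets = group_offsets,
                            covariate_slopes = covariate_slopes,
                            planted_sets = signal$planted_sets,
                            enriched_sets = vapply(signal$planted_sets,
                                                   function(p) p$set, ""),
                            censor_thresholds = list()),
                       class = "TruthRecord")
    list(matrices = matrices, truth = truth)
  })
}

#' True log-fold change of a contrast under the generative model
#'
#' @param truth a `TruthRecord` from [generate_proteome()].
#' @param contrast a [contrast_spec()].
#' @return Named numeric vector: mean group offset over the contrast's B
#'   groups minus the mean over its A groups, per protein.
#' @export
true_logfc <- function(truth, contrast) {
  go <- truth$group_offsets
  rowMeans(go[, contrast$B, drop = FALSE]) -
    rowMeans(go[, contrast$A, drop = FALSE])
}

#' Censoring specification for missing-not-at-random dropout
#'
#' Models the detection-limit dropout of label-free proteomics: values low
#' in a sample's intensity distribution are preferentially lost. The
#' missingness probability is probit in the value,
#' `P(missing | v) = pnorm((T_s - v) / kappa) + mcar_rate` (clipped to
#' `[0, 1]`), with `T_s` the `censor_quantile` quantile of sample `s` and
#' `kappa = censor_steepness` the probit scale in log2 units
#' (`kappa -> 0` gives a hard threshold).
#'
#' @param censor_quantile fraction of each sample's distribution around
#'   which censoring operates, in `[0, 1)`.
#' @param censor_steepness probit scale `kappa` (log2 units, >= 0).
#' @param mcar_rate additional missing-completely-at-random rate, `[0, 0.2]`.
#' @return A `CensorSpec` list.
#' @export
censor_spec <- function(censor_quantile = 0.15, censor_steepness = 0.3,
                        mcar_rate = 0) {
  if (censor_quantile < 0 || censor_quantile >= 1)
    stop("`censor_quantile` must be in [0, 1)")
  if (mcar_rate < 0 || mcar_rate > 0.2)
    stop("`mcar_rate` must be in [0, 0.2]")
  if (censor_steepness < 0) stop("`censor_steepness` must be >= 0")
  structure(list(censor_quantile = censor_quantile,
                 censor_steepness = censor_steepness, mcar_rate = mcar_rate),
            class = "CensorSpec")
}

#' Apply left-censored missingness to a complete matrix
#'
#' @param m a complete `IntensityMatrix`.
#' @param cspec a [censor_spec()].
#' @param seed integer seed.
#' @return The matrix with cells set to `NA` according to the censoring
#'   model; surviving cells are unchanged. The per-sample thresholds used
#'   are attached as attribute `"censor_thresholds"`.
#' @export
apply_missingness <- function(m, cspec = censor_spec(), seed = 1L) {
  stopifnot(inherits(cspec, "CensorSpec"))
  v <- values(m)
  if (anyNA(v)) stop("`apply_missingness` expects a complete matrix")
  withr::with_seed(seed, {
    thr <- apply(v, 2, stats::quantile, probs = cspec$censor_quantile,
                 names = FALSE)
    if (cspec$censor_quantile == 0) thr <- rep(-Inf, ncol(v))
    tmat <- matrix(thr, nrow(v), ncol(v), byrow = TRUE)
    p_miss <- if (cspec$censor_steepness == 0) as.numeric(v < tmat)
              else stats::pnorm((tmat - v) / cspec$censor_steepness)
    p_miss <- pmin(1, pmax(0, p_miss + cspec$mcar_rate))
    drop <- matrix(stats::runif(length(v)) < p_miss, nrow(v), ncol(v))
    v[drop] <- NA_real_
    out <- with_values(m, v)
    attr(out, "censor_thresholds") <- stats::setNames(thr, colnames(v))
    out
  })
}

#' Generate a random gene-set collection
#'
#' Stand-in for curated collections (GO / pathway GMT files): a universe of
#' synthetic gene symbols and sets sampled from it without replacement.
#'
#' @param n_sets number of sets.
#' @param size_range integer range of set sizes, within
#'   `[2, universe_size]`.
#' @param universe_size number of distinct gene symbols.
#' @param seed integer seed.
#' @param path optional path; when given the collection is also written as
#'   GMT.
#' @return A `GeneSetCollection`.
#' @export
generate_gene_sets <- function(n_sets, size_range = c(10, 50),
                               universe_size = 1000, seed = 1L, path = NULL) {
  if (size_range[1] < 2 || size_range[2] > universe_size)
    stop("`size_range` must lie within [2, universe_size]")
  withr::with_seed(seed, {
    universe <- sprintf("GENE%05d", seq_len(universe_size))
    size_pool <- seq(size_range[1], size_range[2])
    sizes <- if (n_sets == 0) integer(0)
             else if (length(size_pool) == 1) rep(size_pool, n_sets)
             else sample(size_pool, n_sets, replace = TRUE)
    sets <- lapply(sizes, function(k) sample(universe, k))
    names(sets) <- sprintf("SET%04d", seq_len(n_sets))
    coll <- gene_set_collection(sets, rep("synthetic", n_sets))
    if (!is.null(path)) write_gmt(coll, path)
    coll
  })
}

#' Generate ambiguous ordered identifier lists
#'
#' Emulates quantification output where each protein carries an ordered
#' list of candidate identifiers (accessions and gene names) ranked by
#' confidence. With probability `ambiguity_rate` the in-universe gene name
#' is pushed behind decoy accessions (position >= 2); otherwise it leads.
#'
#' @param proteins character vector of intended gene names.
#' @param ambiguity_rate fraction of records whose first identifier is a
#'   decoy, in `[0, 1]`.
#' @param universe gene-name universe the true names are checked against
#'   (used only for bookkeeping; resolution happens in
#'   [resolve_identifier()]).
#' @param seed integer seed.
#' @return `data.frame(protein_id, ordered_ids, true_gene, ambiguous)`;
#'   `ordered_ids` is a semicolon-delimited string.
#' @export
generate_identifier_lists <- function(proteins, ambiguity_rate = 0.1,
                                      universe = proteins, seed = 1L) {
  if (ambiguity_rate < 0 || ambiguity_rate > 1)
    stop("`ambiguity_rate` must be in [0, 1]")
  withr::with_seed(seed, {
    n <- length(proteins)
    decoy <- function(k) sprintf("X%06d", sample.int(999999, k))
    ambiguous <- stats::runif(n) < ambiguity_rate
    ids <- vapply(seq_len(n), function(i) {
      if (ambiguous[i]) paste(c(decoy(1), proteins[i], decoy(1)), collapse = ";")
      else paste(c(proteins[i], decoy(2)), collapse = ";")
    }, "")
    data.frame(protein_id = proteins, ordered_ids = ids,
               true_gene = proteins, ambiguous = ambiguous,
               stringsAsFactors = FALSE)
  })
}
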