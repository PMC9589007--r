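#' Log2-transform a raw intensity matrix
#'
#' @param m an `IntensityMatrix` on the raw scale; all observed values must
#'   be strictly positive.
#' @return The matrix with `values = log2(raw)` and `scale = "log2"`; the
#'   missingness mask is unchanged.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "IntensityMatrix"))
  if (m$scale != "raw")
    stop("`log2_transform` expects a raw-scale matrix (got scale=", m$scale, ")")
  v <- values(m)
  bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-positive observed value(s) at [protein, sample]: ",
         paste(sprintf("[%s, %s]", rownames(v)[bad[, 1]],
                       colnames(v)[bad[, 2]]), collapse = ", "))
  m$values <- log2(v)
  m$scale <- "log2"
  m
}

#' Flag outlier samples by deviation of their median abundance
#'
#' Scores each sample by how far its median observed log2 abundance lies
#' from the cohort: `d_s = (median_s - M) / SD`, where `M` is the median
#' of the per-sample medians within the tissue and `SD` their spread,
#' estimated robustly as `1.4826 * MAD` (the normal-consistent median
#' absolute deviation). A robust scale is essential here: with the plain
#' standard deviation a single gross outlier inflates `SD` so much that it
#' can never reach 3 SDs in a small cohort (at `n` samples the maximum
#' attainable score is about `(n-1)/sqrt(n)`) and would mask itself.
#' Samples with `|d_s| > k` are flagged. A degenerate tissue where all
#' medians coincide (`SD = 0`) has no outliers.
#'
#' @param m an `IntensityMatrix` (log2 scale) with at least 3 samples.
#' @param k flagging threshold in SD units (default 3).
#' @return A `QcReport` list with `sample_scores`
#'   (`data.frame(sample_id, sample_median, score, flagged)`), `tissue`,
#'   and `k`.
#' @export
detect_outlier_samples <- function(m, k = 3) {
  stopifnot(inherits(m, "IntensityMatrix"))
  v <- values(m)
  if (ncol(v) < 3)
    stop("outlier detection needs >= 3 samples (got ", ncol(v), ")")
  med <- apply(v, 2, stats::median, na.rm = TRUE)
  M <- stats::median(med)
  SD <- stats::mad(med, center = M)
  score <- if (SD == 0) rep(0, length(med)) else unname((med - M) / SD)
  structure(list(
    sample_scores = data.frame(sample_id = colnames(v),
                               sample_median = unname(med),
                               score = score, flagged = abs(score) > k,
                               row.names = NULL, stringsAsFactors = FALSE),
    tissue = m$tissue, k = k), class = "QcReport")
}

#' Subjects consistently flagged as outliers across tissues
#'
#' A subject is recommended for exclusion only when it is flagged in every
#' tissue in which it has a sample — a single-tissue deviation is not
#' treated as a subject-level problem.
#'
#' @param reports named list of `QcReport`s, one per tissue, from
#'   [detect_outlier_samples()].
#' @param meta cohort metadata mapping `sample_id` to `subject_id`.
#' @return Character vector of subject ids to exclude (possibly empty).
#' @export
consistent_outliers <- function(reports, meta) {
  scores <- do.call(rbind, lapply(reports, `[[`, "sample_scores"))
  scores$subject_id <- meta$subject_id[match(scores$sample_id, meta$sample_id)]
  if (anyNA(scores$subject_id))
    stop("sample ids in reports not found in `meta`")
  flagged_all <- tapply(scores$flagged, scores$subject_id, all)
  names(flagged_all)[flagged_all]
}

#' Drop samples from an intensity matrix
#' @param m an `IntensityMatrix`.
#' @param sample_ids samples to remove (ids absent from the matrix are
#'   ignored).
#' @return The matrix without those columns.
#' @export
drop_samples <- function(m, sample_ids) {
  v <- values(m)
  with_values(m, v[, !(colnames(v) %in% sample_ids), drop = FALSE])
}

#' Presence filter: keep proteins quantified in enough samples
#'
#' @param m an `IntensityMatrix`.
#' @param min_frac minimum fraction of samples in which a protein must be
#'   observed, in `(0, 1]`. The stated rule is inclusive: a protein seen in
#'   exactly `min_frac` of samples is kept.
#' @return `list(matrix =, report =)` where the report records counts
#'   before/after and the per-protein observed fraction of dropped rows.
#' @export
presence_filter <- function(m, min_frac = 0.8) {
  stopifnot(inherits(m, "IntensityMatrix"))
  if (min_frac <= 0 || min_frac > 1) stop("`min_frac` must be in (0, 1]")
  v <- values(m)
  if (nrow(v) == 0 || ncol(v) == 0) stop("empty matrix")
  frac <- rowMeans(!is.na(v))
  keep <- frac >= min_frac - 1e-12   # inclusive threshold, float-safe
  report <- structure(list(
    proteins_before = nrow(v), proteins_after = sum(keep),
    dropped = data.frame(protein_id = rownames(v)[!keep],
                         observed_frac = frac[!keep], row.names = NULL,
                         stringsAsFactors = FALSE),
    min_frac = min_frac, tissue = m$tissue), class = "QcReport")
  list(matrix = with_values(m, v[keep, , drop = FALSE]), report = report)
}

#' Average duplicate proteins mapping to the same gene
#'
#' Within each sample, rows whose proteins map to the same gene are
#' replaced by the mean of their observed values; a cell is missing only
#' when every contributing protein is missing in that sample. Averaging is
#' missing-aware precisely so that it can run before imputation without
#' fabricating values.
#'
#' @param m an `IntensityMatrix`.
#' @param gene_of named character vector mapping every protein id to a gene
#'   name.
#' @return An `IntensityMatrix` with one row per gene (first-appearance
#'   order).
#' @export
aggregate_gene_duplicates <- function(m, gene_of) {
  v <- values(m)
  unmapped <- setdiff(rownames(v), names(gene_of))
  if (length(unmapped) > 0)
    stop("unmapped protein id(s): ", paste(unmapped, collapse = ", "))
  genes <- unname(gene_of[rownames(v)])
  fac <- factor(genes, levels = unique(genes))
  obs <- !is.na(v)
  vv <- v
  vv[!obs] <- 0
  sums <- rowsum(vv, fac)
  counts <- rowsum(obs + 0, fac)
  out <- sums / counts
  out[counts == 0] <- NA_real_
  with_values(m, out)
}
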