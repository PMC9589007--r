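#' Variance explained by a single covariate, protein-wise
#'
#' For each protein, the R-squared of a one-covariate least-squares fit
#' (continuous covariates) or of the group-means model (categorical
#' covariates), on pairwise-complete cases. The median across proteins is
#' the quantity used for covariate screening.
#'
#' @param m an `IntensityMatrix`.
#' @param covariate numeric or factor/character vector, one value per
#'   sample; must take at least 2 distinct values.
#' @return `list(r2 = per-protein vector, median_r2 = scalar)`.
#' @export
explained_variance <- function(m, covariate) {
  v <- values(m)
  stopifnot(length(covariate) == ncol(v))
  cc_cov <- covariate[!is.na(covariate)]
  if (length(unique(cc_cov)) < 2) stop("constant covariate")
  r2 <- if (is.numeric(covariate)) {
    suppressWarnings(stats::cor(t(v), covariate,
                                use = "pairwise.complete.obs")[, 1])^2
  } else {
    fac <- factor(covariate)
    apply(v, 1, function(y) {
      ok <- !is.na(y) & !is.na(fac)
      y <- y[ok]; g <- droplevels(fac[ok])
      if (length(y) < 3 || nlevels(g) < 2) return(NA_real_)
      sst <- sum((y - mean(y))^2)
      if (sst == 0) return(NA_real_)
      gm <- tapply(y, g, mean)
      1 - sum((y - gm[g])^2) / sst
    })
  }
  list(r2 = r2, median_r2 = stats::median(r2, na.rm = TRUE))
}

#' Explained-variance screen across tissues
#'
#' @param matrices named list of per-tissue `IntensityMatrix`.
#' @param meta cohort metadata with a `sample_id` column and one column per
#'   candidate covariate.
#' @param candidates covariate column names to screen.
#' @return `data.frame(tissue, covariate, median_r2)`; covariates that are
#'   all-`NA` in a tissue (e.g. islet purity elsewhere) are skipped.
#' @export
explained_variance_by_tissue <- function(matrices, meta, candidates) {
  rows <- list()
  for (t in names(matrices)) {
    v <- values(matrices[[t]])
    mm <- meta[match(colnames(v), meta$sample_id), , drop = FALSE]
    for (cv in candidates) {
      x <- mm[[cv]]
      if (is.null(x)) stop("covariate not in `meta`: ", cv)
      if (all(is.na(x)) || length(unique(x[!is.na(x)])) < 2) next
      ev <- explained_variance(matrices[[t]], x)
      rows[[length(rows) + 1]] <- data.frame(tissue = t, covariate = cv,
                                             median_r2 = ev$median_r2,
                                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Select covariates explaining enough median variance
#'
#' A covariate is selected when its median explained variance reaches the
#' threshold in at least one tissue (default 1%). Islet purity is only
#' eligible in the islet tissue and is marked as tissue-restricted in the
#' result so designs for other tissues omit it.
#'
#' @param report output of [explained_variance_by_tissue()].
#' @param threshold minimum median R-squared (inclusive), default 0.01.
#' @param islet_tissue,purity_covariate names used for the
#'   eligibility restriction.
#' @return Character vector of selected covariates, with an attribute
#'   `"tissue_restricted"` (named list covariate -> tissues it applies to).
#' @export
select_covariates <- function(report, threshold = 0.01,
                              islet_tissue = "islet",
                              purity_covariate = "purity") {
  if (is.null(report) || nrow(report) == 0) stop("empty report")
  rep_ok <- report
  purity <- rep_ok$covariate == purity_covariate
  rep_ok <- rep_ok[!purity | rep_ok$tissue == islet_tissue, , drop = FALSE]
  hit <- rep_ok$median_r2 >= threshold - 1e-12
  selected <- unique(rep_ok$covariate[hit])
  restricted <- list()
  if (purity_covariate %in% selected)
    restricted[[purity_covariate]] <- islet_tissue
  structure(selected, tissue_restricted = restricted)
}

#' Rank correlation of each protein to a clinical trait
#'
#' Spearman correlation on pairwise-complete observations, two-sided
#' p-values, FDR-adjusted to q-values across proteins. Proteins with fewer
#' than `min_pairs` complete pairs are reported as `NA`.
#'
#' @param m an `IntensityMatrix`.
#' @param trait numeric vector, one value per sample, not constant.
#' @param method correlation method (default `"spearman"`).
#' @param min_pairs minimum complete pairs (default 5).
#' @param fdr_method passed to [fdr_adjust()].
#' @return `data.frame(protein_id, r, p, q, n)`.
#' @export
correlate_to_trait <- function(m, trait, method = "spearman", min_pairs = 5,
                               fdr_method = "BH") {
  v <- values(m)
  stopifnot(length(trait) == ncol(v))
  if (length(unique(trait[!is.na(trait)])) < 2) stop("constant trait")
  res <- t(apply(v, 1, function(y) {
    ok <- !is.na(y) & !is.na(trait)
    if (sum(ok) < min_pairs) return(c(NA_real_, NA_real_, sum(ok)))
    ct <- suppressWarnings(stats::cor.test(y[ok], trait[ok], method = method,
                                           exact = FALSE))
    c(unname(ct$estimate), ct$p.value, sum(ok))
  }))
  q <- rep(NA_real_, nrow(res))
  ok <- !is.na(res[, 2])
  if (any(ok)) q[ok] <- fdr_adjust(res[ok, 2], method = fdr_method)
  data.frame(protein_id = rownames(v), r = res[, 1], p = res[, 2], q = q,
             n = as.integer(res[, 3]), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Partial rank correlation of proteins to a trait given covariates
#'
#' Ranks are taken first (matching the Spearman choice of the marginal
#' correlations), then the covariates are removed from both the protein and
#' the trait by least squares, and the residuals are correlated. With an
#' empty covariate set this reduces to the marginal Spearman correlation.
#'
#' @param m an `IntensityMatrix` (complete, post-imputation).
#' @param trait numeric vector per sample.
#' @param covariates `data.frame` of covariate columns (may be empty); must
#'   be full rank after adding an intercept.
#' @param include named columns to drop, e.g. `include_bmi = FALSE` drops a
#'   column called `BMI` — convenience for the with/without-BMI comparison.
#' @param include_bmi when `FALSE`, the `BMI` column (if present) is
#'   excluded from the adjustment.
#' @return Named numeric vector of partial correlations per protein.
#' @export
partial_correlation <- function(m, trait, covariates = NULL,
                                include_bmi = TRUE) {
  v <- values(m)
  stopifnot(length(trait) == ncol(v))
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0) {
    X <- matrix(1, ncol(v), 1)
  } else {
    covariates <- as.data.frame(covariates)
    if (!include_bmi) covariates <- covariates[, setdiff(colnames(covariates), "BMI"),
                                               drop = FALSE]
    X <- stats::model.matrix(~ ., data = covariates)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("collinear covariate column(s): ", paste(bad, collapse = ", "))
  }
  rt <- rank(trait)
  res_t <- qr.resid(qx, rt)
  rv <- t(apply(v, 1, rank))
  res_v <- t(qr.resid(qx, t(rv)))
  r <- suppressWarnings(stats::cor(t(res_v), res_t)[, 1])
  stats::setNames(r, rownames(v))
}

#' Agreement between trait correlations and differential statistics
#'
#' Rank (Spearman) correlation, across proteins, between the per-protein
#' trait correlation `r` and the signed differential statistic
#' `logFC / SE`. Under a common driving effect the two landscapes agree.
#'
#' @param r named vector of trait correlations (e.g.
#'   `correlate_to_trait()$r` named by protein).
#' @param differential a `data.frame` with `gene`, `logFC`, `SE` columns
#'   (see [run_differential()]).
#' @return `list(rho =, p =, n_shared =)`.
#' @export
compare_r_to_teststat <- function(r, differential) {
  shared <- intersect(names(r), differential$gene)
  if (length(shared) < 10)
    stop("fewer than 10 shared proteins (got ", length(shared), ")")
  stat <- differential$logFC / differential$SE
  names(stat) <- differential$gene
  ct <- suppressWarnings(stats::cor.test(r[shared], stat[shared],
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n_shared = length(shared))
}
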