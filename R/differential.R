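#' Define a group contrast
#'
#' A contrast compares the union of groups `B` against the union of groups
#' `A` (logFC is B minus A). Groups are subsets of CTRL/PD/T2D; merged
#' groups such as CTRL+PD are expressed by listing both members.
#'
#' @param name label for output tables.
#' @param A,B character vectors of group levels; disjoint, both non-empty.
#' @return A `Contrast` list.
#' @export
contrast_spec <- function(name, A, B) {
  if (length(A) == 0 || length(B) == 0) stop("both contrast sides must be non-empty")
  if (length(intersect(A, B)) > 0)
    stop("contrast sides overlap: ", paste(intersect(A, B), collapse = ", "))
  structure(list(name = name, A = A, B = B), class = "Contrast")
}

#' The study's standard contrasts
#'
#' Pairwise comparisons among CTRL, PD and T2D plus the merged-group
#' comparisons T2D vs CTRL+PD and PD+T2D vs CTRL.
#'
#' @return Named list of [contrast_spec()] objects.
#' @export
default_contrasts <- function() {
  cs <- list(
    contrast_spec("PD_vs_CTRL", A = "CTRL", B = "PD"),
    contrast_spec("T2D_vs_CTRL", A = "CTRL", B = "T2D"),
    contrast_spec("T2D_vs_PD", A = "PD", B = "T2D"),
    contrast_spec("T2D_vs_CTRLPD", A = c("CTRL", "PD"), B = "T2D"),
    contrast_spec("PDT2D_vs_CTRL", A = "CTRL", B = c("PD", "T2D"))
  )
  stats::setNames(cs, vapply(cs, `[[`, "", "name"))
}

#' Build a design matrix for one contrast
#'
#' Subsets the metadata to samples belonging to either side of the
#' contrast and builds columns: intercept, group indicator (1 for the B
#' side), one centered column per continuous covariate and dummy columns
#' per categorical covariate. The fitted group coefficient is then directly
#' the covariate-adjusted log-fold change B vs A.
#'
#' @param meta metadata for the samples of one tissue (`sample_id`,
#'   `group`, covariate columns).
#' @param contrast a [contrast_spec()].
#' @param covariates character vector of covariate column names (possibly
#'   empty).
#' @return `list(design = matrix with rownames sample_id, coef = "group",
#'   samples = sample ids used)`.
#' @export
build_design <- function(meta, contrast, covariates = character(0)) {
  stopifnot(inherits(contrast, "Contrast"))
  keep <- meta$group %in% c(contrast$A, contrast$B)
  mt <- meta[keep, , drop = FALSE]
  in_b <- as.integer(mt$group %in% contrast$B)
  if (sum(in_b) < 2 || sum(1 - in_b) < 2)
    stop("each contrast side needs >= 2 samples (", contrast$name, ": ",
         sum(1 - in_b), " vs ", sum(in_b), ")")
  X <- cbind(`(Intercept)` = 1, group = in_b)
  for (cv in covariates) {
    x <- mt[[cv]]
    if (is.null(x)) stop("covariate not in `meta`: ", cv)
    if (anyNA(x)) stop("covariate with missing values: ", cv)
    if (is.numeric(x)) {
      xc <- cbind(x - mean(x))
      colnames(xc) <- cv
    } else {
      fac <- droplevels(factor(x))
      xc <- stats::model.matrix(~ fac)[, -1, drop = FALSE]
      colnames(xc) <- paste0(cv, levels(fac)[-1])
    }
    X <- cbind(X, xc)
  }
  rownames(X) <- mt$sample_id
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  list(design = X, coef = "group", samples = mt$sample_id)
}

#' Protein-wise ordinary least squares for one coefficient
#'
#' Fits `y = X beta + e` per protein and extracts the target coefficient,
#' the residual variance `s2` on `d = n - rank(X)` degrees of freedom, and
#' the unscaled variance factor `v` of the coefficient (its diagonal entry
#' of `(X'X)^-1`), so that `SE^2 = s2 * v`.
#'
#' @param m an `IntensityMatrix` whose columns cover the design rows
#'   (complete values; fit on the imputed matrix).
#' @param design output of [build_design()].
#' @return `data.frame(gene, beta, s2, d, v)`.
#' @export
fit_linear_models <- function(m, design) {
  X <- design$design
  v_all <- values(m)[, rownames(X), drop = FALSE]
  if (anyNA(v_all)) stop("fit requires a complete (imputed) matrix")
  n <- nrow(X)
  qx <- qr(X)
  rk <- qx$rank
  if (n <= rk) stop("not enough samples: n = ", n, ", rank = ", rk)
  Y <- t(v_all)
  B <- qr.coef(qx, Y)
  res <- qr.resid(qx, Y)
  s2 <- colSums(res^2) / (n - rk)
  XtXi <- chol2inv(chol(crossprod(X)))
  dimnames(XtXi) <- list(colnames(X), colnames(X))
  cidx <- design$coef
  data.frame(gene = rownames(v_all), beta = B[cidx, ], s2 = unname(s2),
             d = n - rk, v = XtXi[cidx, cidx], row.names = NULL,
             stringsAsFactors = FALSE)
}

# Newton inversion of the trigamma function (y = trigamma(x), y > 0).
trigamma_inverse <- function(y) {
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderation of protein-wise variances
#'
#' Shrinks each protein's residual variance toward a common prior
#' `s0^2` with prior degrees of freedom `d0`, estimated by method of
#' moments on `z = log(s2)`: with `s2 ~ s0^2 * F(d, d0)`,
#' `Var(z) = trigamma(d/2) + trigamma(d0/2)`, so `d0` solves
#' `trigamma(d0/2) = var(z) - trigamma(d/2)` and `s0^2` follows from
#' `mean(z)` via the matching digamma identity. When the observed spread of
#' `z` does not exceed what sampling alone produces
#' (`var(z) <= trigamma(d/2)`), `d0` is infinite and every posterior
#' variance equals `s0^2`. The posterior variance is
#' `s2_tilde = (d0 * s0^2 + d * s2) / (d0 + d)`; the moderated t is
#' `beta / sqrt(s2_tilde * v)` on `d0 + d` degrees of freedom.
#'
#' @param fits output of [fit_linear_models()] (>= 10 proteins with
#'   `d > 0`).
#' @return The input with columns `s2_post`, `t`, `p` appended and
#'   attributes `d0`, `s02`.
#' @export
ebayes_moderate <- function(fits) {
  ok <- fits$d > 0 & is.finite(fits$s2) & fits$s2 > 0
  if (sum(fits$d > 0) < 10)
    stop("need >= 10 proteins with positive residual df")
  if (all(fits$s2 == 0)) stop("all residual variances are zero")
  z <- log(fits$s2[ok])
  d <- fits$d[ok]
  varz <- stats::var(z)
  mean_tri <- mean(trigamma(d / 2))
  if (varz > mean_tri) {
    d0 <- 2 * trigamma_inverse(varz - mean_tri)
    s02 <- exp(mean(z) - mean(digamma(d / 2) - log(d / 2)) +
                 digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(mean(z) - mean(digamma(d / 2) - log(d / 2)))
  }
  s2_post <- if (is.infinite(d0)) rep(s02, nrow(fits))
             else (d0 * s02 + fits$d * fits$s2) / (d0 + fits$d)
  tstat <- fits$beta / sqrt(s2_post * fits$v)
  df_total <- d0 + fits$d
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- fits
  out$s2_post <- s2_post
  out$t <- tstat
  out$p <- p
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

#' False-discovery-rate adjustment
#'
#' Benjamini-Hochberg step-up by default; the Storey variant scales BH by
#' the null-proportion estimate `pi0 = min(1, mean(p > lambda)/(1 -
#' lambda))` at fixed `lambda = 0.5`.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param method `"BH"` or `"storey"`.
#' @return Vector of q-values.
#' @export
fdr_adjust <- function(p, method = c("BH", "storey")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  if (method == "storey") {
    lambda <- 0.5
    pi0 <- min(1, mean(p > lambda, na.rm = TRUE) / (1 - lambda))
    q <- pmin(1, q * pi0)
  }
  q
}

#' The pi ranking statistic
#'
#' `pi = logFC * (-log10 q)`: a signed score combining effect size and
#' significance, used to rank proteins for enrichment. Zero q-values are
#' clamped to the smallest positive double with a warning.
#'
#' @param logfc log-fold changes.
#' @param q q-values in `(0, 1]`.
#' @return Numeric vector of pi values; `sign(pi) == sign(logFC)`.
#' @examples
#' pi_value(2, 0.01)   # 4
#' @export
pi_value <- function(logfc, q) {
  if (any(q < 0 | q > 1, na.rm = TRUE)) stop("q-values must lie in [0, 1]")
  if (any(q == 0, na.rm = TRUE)) {
    warning("q-value(s) of 0 clamped to smallest positive double")
    q[q == 0] <- .Machine$double.xmin
  }
  logfc * (-log10(q))
}

#' Differential abundance for one tissue and contrast
#'
#' Convenience wrapper: build the design, fit protein-wise least squares,
#' moderate, adjust and rank. `SE` is the moderated standard error
#' `sqrt(s2_post * v)`, so `logFC / SE` equals the moderated t.
#'
#' @param m imputed `IntensityMatrix` of one tissue.
#' @param meta metadata covering the matrix's samples.
#' @param contrast a [contrast_spec()].
#' @param covariates covariate column names to adjust for.
#' @param fdr_method passed to [fdr_adjust()].
#' @return `data.frame(gene, logFC, SE, t, p, q, pi)` sorted as the input
#'   matrix; attributes `d0`, `s02`, `contrast`.
#' @export
run_differential <- function(m, meta, contrast, covariates = character(0),
                             fdr_method = "BH") {
  meta_t <- meta[match(colnames(values(m)), meta$sample_id), , drop = FALSE]
  des <- build_design(meta_t, contrast, covariates)
  fits <- ebayes_moderate(fit_linear_models(m, des))
  q <- fdr_adjust(fits$p, method = fdr_method)
  out <- data.frame(gene = fits$gene, logFC = fits$beta,
                    SE = sqrt(fits$s2_post * fits$v), t = fits$t,
                    p = fits$p, q = q,
                    pi = suppressWarnings(pi_value(fits$beta, pmax(q, .Machine$double.xmin))),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- attr(fits, "d0")
  attr(out, "s02") <- attr(fits, "s02")
  attr(out, "contrast") <- contrast$name
  out
}

#' Signed pi ranking for enrichment
#'
#' @param differential output of [run_differential()].
#' @return Named numeric vector of pi values sorted in decreasing order —
#'   the pre-ranked input for [camera_pr()] and [gsea_preranked()].
#' @export
pi_ranking <- function(differential) {
  sort(stats::setNames(differential$pi, differential$gene), decreasing = TRUE)
}
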