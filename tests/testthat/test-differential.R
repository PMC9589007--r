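test_that("design construction covers plain, merged and covariate cases", {
  meta <- two_group_meta(3, 3)
  des <- build_design(meta, contrast_spec("T2D_vs_CTRL", "CTRL", "T2D"))
  expect_equal(dim(des$design), c(6, 2))
  expect_equal(unname(des$design[, "group"]), rep(0:1, each = 3))

  # merged group pools CTRL and PD on the A side
  meta3 <- data.frame(sample_id = paste0("s", 1:9),
                      group = factor(rep(c("CTRL", "PD", "T2D"), each = 3),
                                     levels = c("CTRL", "PD", "T2D")))
  desm <- build_design(meta3, contrast_spec("T2D_vs_CTRLPD",
                                            A = c("CTRL", "PD"), B = "T2D"))
  expect_equal(unname(desm$design[, "group"]), rep(c(0, 1), c(6, 3)))

  # centered continuous covariate; duplicated covariate is rank-deficient
  meta$BMI <- rnorm(6)
  meta$BMI2 <- meta$BMI
  desc <- build_design(meta, contrast_spec("c", "CTRL", "T2D"), "BMI")
  expect_lt(abs(sum(desc$design[, "BMI"])), 1e-12)
  expect_error(build_design(meta, contrast_spec("c", "CTRL", "T2D"),
                            c("BMI", "BMI2")), "BMI2")
  expect_error(build_design(two_group_meta(1, 5),
                            contrast_spec("c", "CTRL", "T2D")), ">= 2")
})

test_that("protein-wise OLS matches the normal-equations oracle", {
  set.seed(61)
  n <- 14
  meta <- two_group_meta(7, 7)
  meta$BMI <- rnorm(n)
  des <- build_design(meta, contrast_spec("c", "CTRL", "T2D"), "BMI")
  v <- matrix(rnorm(50 * n), 50, n,
              dimnames = list(paste0("P", 1:50), meta$sample_id))
  fits <- fit_linear_models(intensity_matrix(v), des)

  X <- des$design
  XtXi <- solve(t(X) %*% X)
  for (i in c(1, 17, 50)) {
    beta <- XtXi %*% t(X) %*% v[i, ]
    res <- v[i, ] - X %*% beta
    expect_equal(fits$beta[i], unname(beta["group", 1]), tolerance = 1e-10)
    expect_equal(fits$s2[i], sum(res^2) / (n - ncol(X)), tolerance = 1e-10)
  }
  expect_equal(fits$v[1], XtXi["group", "group"], tolerance = 1e-12)
  expect_equal(fits$d[1], n - ncol(X))

  # two groups, no covariates: beta is the group mean difference
  des0 <- build_design(meta, contrast_spec("c", "CTRL", "T2D"))
  fits0 <- fit_linear_models(intensity_matrix(v), des0)
  expect_equal(fits0$beta,
               unname(rowMeans(v[, 8:14]) - rowMeans(v[, 1:7])),
               tolerance = 1e-12)
  # response identical to a design column: zero residual variance
  v1 <- matrix(rep(des$design[, "BMI"], each = 12), 12, n,
               dimnames = list(paste0("Q", 1:12), meta$sample_id))
  expect_equal(max(fit_linear_models(intensity_matrix(v1), des)$s2), 0,
               tolerance = 1e-20)

  # orthogonal covariate leaves beta unchanged (sums to zero within each
  # group, hence orthogonal to intercept and group indicator)
  meta$orth <- rep(c(-1, 1, -1, 1, -1, 1, 0), 2)
  deso <- build_design(meta, contrast_spec("c", "CTRL", "T2D"), "orth")
  fitso <- fit_linear_models(intensity_matrix(v), deso)
  expect_equal(fitso$beta, fits0$beta, tolerance = 1e-10)
})

test_that("moderation follows the closed-form empirical-Bayes scheme", {
  set.seed(62)
  # formula oracle on the moderated quantities; variances carry genuine
  # excess dispersion so the prior df is finite
  s2 <- (0.2 * 6 / rchisq(200, 6)) * rchisq(200, 10) / 10
  fits <- data.frame(gene = paste0("g", 1:200), beta = rnorm(200),
                     s2 = s2, d = 10, v = 0.25)
  mod <- ebayes_moderate(fits)
  expect_true(is.finite(attr(mod, "d0")))
  d0 <- attr(mod, "d0"); s02 <- attr(mod, "s02")
  s2_post <- (d0 * s02 + fits$d * fits$s2) / (d0 + fits$d)
  t_oracle <- fits$beta / sqrt(s2_post * fits$v)
  p_oracle <- 2 * pt(-abs(t_oracle), d0 + fits$d)
  expect_equal(mod$s2_post, s2_post, tolerance = 1e-12)
  expect_equal(mod$t, t_oracle, tolerance = 1e-8)
  expect_equal(mod$p, p_oracle, tolerance = 1e-8)

  # all variances equal: no excess dispersion, fully shrunk to the prior;
  # the moment estimator's digamma offset (exact for log chi-square
  # sampling) maps a degenerate constant input to s2 * exp(log(d/2) -
  # digamma(d/2)), matching the reference implementation
  fe <- data.frame(gene = paste0("g", 1:20), beta = rnorm(20), s2 = 0.3,
                   d = 8, v = 0.2)
  me <- ebayes_moderate(fe)
  expect_true(is.infinite(attr(me, "d0")))
  expect_equal(me$s2_post, rep(attr(me, "s02"), 20))
  expect_equal(attr(me, "s02"), 0.3 * exp(log(4) - digamma(4)),
               tolerance = 1e-10)

  expect_error(ebayes_moderate(data.frame(gene = "g", beta = 1, s2 = 1,
                                          d = 1, v = 1)), ">= 10")
})

test_that("prior df and variance are recovered on the generative model", {
  set.seed(63)
  d0 <- 6; s02 <- 0.25; d <- 20; G <- 5000
  sig2 <- s02 * d0 / rchisq(G, d0)
  s2 <- sig2 * rchisq(G, d) / d
  mod <- ebayes_moderate(data.frame(gene = paste0("g", 1:G), beta = 0,
                                    s2 = s2, d = d, v = 0.1))
  expect_lt(abs(attr(mod, "d0") - d0) / d0, 0.2)
  expect_lt(abs(attr(mod, "s02") - s02) / s02, 0.1)
})

test_that("moderated statistics agree with the reference implementation", {
  skip_if_not_installed("limma")
  set.seed(64)
  n <- 16; G <- 800
  meta <- two_group_meta(8, 8)
  v <- matrix(rnorm(G * n, sd = rep(sqrt(0.3 * 5 / rchisq(G, 5)), n)), G, n,
              dimnames = list(paste0("P", 1:G), meta$sample_id))
  des <- build_design(meta, contrast_spec("c", "CTRL", "T2D"))
  mod <- ebayes_moderate(fit_linear_models(intensity_matrix(v), des))
  eb <- limma::eBayes(limma::lmFit(v, des$design))
  expect_equal(attr(mod, "d0"), eb$df.prior, tolerance = 1e-6)
  expect_equal(attr(mod, "s02"), eb$s2.prior, tolerance = 1e-6)
  expect_equal(mod$t, unname(eb$t[, "group"]), tolerance = 1e-10)
  expect_equal(mod$p, unname(eb$p.value[, "group"]), tolerance = 1e-10)
})

test_that("BH adjustment and the pi statistic follow their stated forms", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  set.seed(65)
  p <- runif(100)
  q <- fdr_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))   # monotone in sorted p
  expect_true(all(q <= 1 & q >= p))
  qs <- fdr_adjust(p, method = "storey")
  expect_true(all(qs <= q + 1e-15))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  expect_equal(pi_value(2, 0.01), 4)
  expect_equal(pi_value(0, 0.5), 0)
  expect_equal(pi_value(3, 1), 0)
  expect_identical(sign(pi_value(c(-2, 2), c(0.1, 0.1))), c(-1, 1))
  expect_warning(pq <- pi_value(1, 0), "clamped")
  expect_true(is.finite(pq) && pq > 0)
})

test_that("type-I error is nominal on a null synthetic cohort", {
  meta <- generate_cohort(cohort_spec(tissues = "islet", seed = 66))
  gen <- generate_proteome(meta, 2500, signal_spec(),
                           gene_set_collection(list()), seed = 67)
  d <- run_differential(gen$matrices$islet, meta,
                        contrast_spec("T2D_vs_CTRL", "CTRL", "T2D"))
  rej <- mean(d$p < 0.05)
  ci <- 1.96 * sqrt(0.05 * 0.95 / 2500)
  expect_lt(abs(rej - 0.05), ci + 1e-12)
})

test_that("planted log-fold changes are recovered at cohort scale", {
  sets <- generate_gene_sets(3, c(100, 100), universe_size = 600, seed = 68)
  meta <- generate_cohort(cohort_spec(tissues = "islet", seed = 68))
  ctr <- contrast_spec("T2D_vs_CTRL", "CTRL", "T2D")
  sig <- signal_spec(planted_sets = list(list(set = "SET0001", delta = 1,
                                              contrast = ctr)))
  gen <- generate_proteome(meta, 600, sig, sets, seed = 69)
  d <- run_differential(gen$matrices$islet, meta, ctr)
  affected <- d$gene %in% sets$SET0001
  expect_lt(abs(mean(d$logFC[affected]) - 1), 0.05)
})
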