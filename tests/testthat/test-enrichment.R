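test_that("competitive test reduces to the pooled two-sample t at rho = 0", {
  set.seed(71)
  stat <- setNames(rnorm(300), paste0("G", 1:300))
  sets <- gene_set_collection(list(A = paste0("G", 1:40),
                                   B = paste0("G", sample(300, 25))))
  cam <- camera_pr(stat, sets, rho = 0)
  for (i in 1:2) {
    inset <- names(stat) %in% sets[[cam$set[i]]]
    tt <- t.test(stat[inset], stat[!inset], var.equal = TRUE)
    expect_equal(cam$p[i], tt$p.value, tolerance = 1e-10)
    expect_equal(cam$t[i], unname(tt$statistic), tolerance = 1e-10)
  }
  # equal means: t = 0, p = 1
  s0 <- setNames(rep(c(1, -1), 10), paste0("G", 1:20))
  c0 <- camera_pr(s0, gene_set_collection(list(S = paste0("G", 1:10))), rho = 0)
  expect_equal(c0$p, 1)
  expect_equal(c0$t, 0)
  # VIF enters as 1 + (m-1) rho: doubling at m = 101, rho = 0.01 halves t^2
  # relative to the rho = 0 variance share of the set term
  stat2 <- setNames(rnorm(400), paste0("G", 1:400))
  set101 <- gene_set_collection(list(S = paste0("G", 1:101)))
  t_rho <- camera_pr(stat2, set101, rho = 0.01)$t
  t_0 <- camera_pr(stat2, set101, rho = 0)$t
  ratio <- (1 / 101 + 1 / 299) / (2 / 101 + 1 / 299)   # VIF = 2 exactly
  expect_equal((t_rho / t_0)^2, ratio, tolerance = 1e-10)
})

test_that("competitive test matches the reference implementation", {
  skip_if_not_installed("limma")
  set.seed(72)
  stat <- setNames(rnorm(500), paste0("G", 1:500))
  sets <- lapply(1:10, function(i) paste0("G", sample(500, sample(5:80, 1))))
  names(sets) <- paste0("S", 1:10)
  cam <- camera_pr(stat, gene_set_collection(sets))
  ref <- limma::cameraPR(stat, lapply(sets, function(s)
    which(names(stat) %in% s)), sort = FALSE)
  expect_equal(cam$p, unname(ref$PValue), tolerance = 1e-10)
  expect_identical(cam$direction, tolower(ref$Direction))
})

test_that("competitive test is calibrated on null statistics", {
  set.seed(73)
  stat <- setNames(rnorm(1000), paste0("G", 1:1000))
  sets <- lapply(1:2000, function(i) sample(names(stat), sample(10, 1) + 9))
  names(sets) <- paste0("S", 1:2000)
  cam <- camera_pr(stat, gene_set_collection(sets), rho = 0)
  expect_gt(stats::ks.test(cam$p, "punif")$p.value, 0.01)
  ci <- 1.96 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(mean(cam$p < 0.05) - 0.05), ci)
})

test_that("enrichment score equals the brute-force running sum", {
  # hand-evaluated: stats (3,2,1,0.5), set = top gene -> ES = 1
  st <- setNames(c(3, 2, 1, 0.5), paste0("G", 1:4))
  gs <- gsea_preranked(st, gene_set_collection(list(S = "G1")),
                       n_perm = 10, min_size = 1, seed = 1)
  expect_equal(gs$ES, 1)
  # set = all genes: no miss steps, ES = 1 (internal scorer; the public
  # interface excludes sets covering the whole list)
  expect_equal(protflow:::running_es(1:4, abs(st), 4)$es, 1)

  # exhaustive oracle over every proper subset at G = 10
  set.seed(74)
  st10 <- sort(setNames(rnorm(10), paste0("G", 1:10)), decreasing = TRUE)
  w <- abs(st10)
  for (mask in 1:1022) {
    members <- names(st10)[bitwAnd(mask, 2^(0:9)) > 0]
    idx <- which(names(st10) %in% members)
    expect_equal(protflow:::running_es(idx, w, 10)$es,
                 oracle_es(st10, members))
  }
})

test_that("permutation p agrees with exhaustive same-size enumeration", {
  set.seed(75)
  st <- sort(setNames(rnorm(8), paste0("G", 1:8)), decreasing = TRUE)
  members <- names(st)[c(1, 2, 5)]
  gs <- gsea_preranked(st, gene_set_collection(list(S = members)),
                       n_perm = 20000, min_size = 1, seed = 2)
  # enumerate all C(8,3) = 56 same-size sets as the exact null
  all_es <- apply(combn(8, 3), 2, function(idx)
    protflow:::running_es(sort(idx), abs(st), 8)$es)
  es <- gs$ES
  same <- if (es >= 0) all_es[all_es >= 0] else all_es[all_es < 0]
  p_exact <- sum(abs(same) >= abs(es)) / length(same)
  expect_lt(abs(gs$p - p_exact), 0.02)
})

test_that("planted high-statistic sets are significant and seed-stable", {
  set.seed(76)
  stats <- c(rnorm(30, mean = 2), rnorm(470))
  names(stats) <- paste0("G", 1:500)
  ranked <- sort(stats, decreasing = TRUE)
  sets <- gene_set_collection(c(list(PLANT = paste0("G", 1:30)),
    setNames(lapply(1:20, function(i) paste0("G", sample(500, 30))),
             paste0("R", 1:20))))
  g1 <- gsea_preranked(ranked, sets, n_perm = 10000, seed = 3)
  g2 <- gsea_preranked(ranked, sets, n_perm = 10000, seed = 4)
  expect_lt(g1$p[g1$set == "PLANT"], 0.01)
  expect_lt(g2$p[g2$set == "PLANT"], 0.01)
  expect_identical(g1$ES, g2$ES)   # ES is permutation-free
  expect_gt(g1$NES[g1$set == "PLANT"], 1)
  # size filter: nothing survives -> empty result with warning
  expect_warning(
    empty <- gsea_preranked(ranked, sets, n_perm = 10, min_size = 100),
    "size filter")
  expect_equal(nrow(empty), 0)
})

test_that("consensus requires both methods significant in the same direction", {
  camera <- data.frame(set = c("A", "B", "C", "D"), size = 10,
                       delta = c(1, 1, -1, 1), t = 2,
                       direction = c("up", "up", "down", "up"),
                       p = c(1e-6, 1e-6, 1e-6, 0.9))
  gsea <- data.frame(set = c("A", "B", "C", "D"), size = 10,
                     ES = c(0.5, -0.5, -0.5, 0.5), NES = 1,
                     p = c(1e-5, 1e-5, 1e-5, 0.8),
                     direction = c("up", "down", "down", "up"))
  cons <- consensus_enrichment(camera, gsea, alpha = 0.05)
  got <- setNames(cons$consensus, cons$set)
  expect_true(got[["A"]])    # both significant, same direction
  expect_false(got[["B"]])   # directions disagree
  expect_true(got[["C"]])    # both down
  expect_false(got[["D"]])   # neither significant
  # consensus is a subset of each method's significant sets
  expect_true(all(cons$camera_q[cons$consensus] < 0.05))
  expect_true(all(cons$gsea_q[cons$consensus] < 0.05))
  # boundary: q above alpha in one method blocks consensus
  cam2 <- camera; cam2$p <- c(0.04, 0.04, 0.04, 0.04)
  gs2 <- gsea; gs2$p <- c(0.06, 0.06, 0.06, 0.06)
  cons2 <- consensus_enrichment(cam2, gs2, alpha = 0.05)
  expect_false(any(cons2$consensus))
})

test_that("hypergeometric ORA matches exhaustive enumeration", {
  sets <- gene_set_collection(list(S = paste0("G", 1:5)))
  bg <- paste0("G", 1:10)
  res <- hypergeom_ora(paste0("G", 1:5), sets, bg, min_size = 2)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)

  # enumeration oracle at N = 10: P(overlap >= k) over all C(10, n) draws
  set.seed(77)
  query <- paste0("G", c(1, 2, 3, 7, 9))
  draws <- combn(10, 5)
  k_obs <- length(intersect(query, paste0("G", 1:5)))
  tail_true <- mean(apply(draws, 2, function(d) sum(d <= 5)) >= k_obs)
  res2 <- hypergeom_ora(query, sets, bg, min_size = 2)
  expect_equal(res2$p, tail_true, tolerance = 1e-12)
  expect_equal(res2$overlap, k_obs)

  # k = 0 -> p = 1; sets below min size are excluded; query must be in bg
  res3 <- hypergeom_ora("G10", gene_set_collection(list(S = paste0("G", 1:5))),
                        bg, min_size = 2)
  expect_equal(res3$p, 1)
  expect_equal(nrow(hypergeom_ora("G1", sets, bg, min_size = 6)), 0)
  expect_error(hypergeom_ora("ZZZ", sets, bg), "ZZZ")
})

test_that("enrichment graph nodes and edges follow the overlap rule", {
  sets <- gene_set_collection(list(A = paste0("G", 1:10),
                                   B = paste0("G", 1:5),      # A superset of B
                                   C = paste0("G", 20:29),
                                   D = paste0("G", c(1, 25, 40:47))))
  cons <- data.frame(set = c("A", "B", "C", "D"), size = 10,
                     camera_p = 1e-6, camera_q = c(1e-5, 1e-5, 1e-5, 0.2),
                     camera_dir = "up", ES = 0.5, NES = 1, gsea_p = 1e-6,
                     gsea_q = c(1e-5, 1e-5, 1e-5, 0.2), gsea_dir = "up",
                     consensus = c(TRUE, TRUE, TRUE, FALSE),
                     direction = c("up", "up", "up", NA))
  g <- build_enrichment_graph(cons, sets, node_q = 0.01, threshold = 0.5)
  expect_setequal(g$nodes$set, c("A", "B", "C"))   # D fails node_q
  # B subset of A -> overlap coefficient 1; disjoint pairs get no edge
  expect_equal(nrow(g$edges), 1)
  expect_setequal(unlist(g$edges[1, c("from", "to")]), c("A", "B"))
  expect_equal(g$edges$similarity, 1)
  # threshold 0 connects every pair sharing >= 1 gene
  g0 <- build_enrichment_graph(cons, sets, node_q = 0.01, threshold = 0)
  expect_equal(nrow(g0$edges), 1)   # A-B share genes; C disjoint from both
})
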