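#' Competitive pre-ranked gene-set test with inter-gene correlation
#'
#' For a set of size `m` among `G` ranked statistics, tests whether the
#' set's mean statistic differs from the rest using a two-sample t-statistic
#' whose set-side variance is inflated by `VIF = 1 + (m - 1) * rho` to
#' account for inter-gene correlation `rho`:
#' `t = (mean_set - mean_rest) / (s_p * sqrt(VIF/m + 1/(G - m)))` on
#' `G - 2` degrees of freedom, with `s_p` the pooled standard deviation.
#' At `rho = 0` this is exactly the pooled two-sample t-test.
#'
#' @param ranked named numeric vector: gene -> signed statistic (order
#'   irrelevant for this test); >= 3 genes.
#' @param sets a `GeneSetCollection`.
#' @param rho inter-gene correlation (default 0.01, the conventional
#'   pre-ranked value).
#' @param min_size minimum set size after intersection with `ranked`
#'   (default 2).
#' @return `data.frame(set, size, delta, t, direction, p)`; sets smaller
#'   than `min_size` after intersection (or as large as the whole list)
#'   are dropped.
#' @export
camera_pr <- function(ranked, sets, rho = 0.01, min_size = 2) {
  G <- length(ranked)
  if (G < 3) stop("need >= 3 ranked genes")
  genes <- names(ranked)
  mean_all <- mean(ranked)
  ss_all <- sum((ranked - mean_all)^2)
  rows <- lapply(names(sets), function(nm) {
    idx <- genes %in% sets[[nm]]
    m <- sum(idx)
    if (m < min_size) return(NULL)
    if (m >= G) stop("set covers the whole ranked list: ", nm)
    x <- ranked[idx]; y <- ranked[!idx]
    delta <- mean(x) - mean(y)
    sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (G - 2)
    vif <- 1 + (m - 1) * rho
    tstat <- if (sp2 == 0) 0
             else delta / sqrt(sp2 * (vif / m + 1 / (G - m)))
    p <- if (sp2 == 0 && delta == 0) 1 else 2 * stats::pt(-abs(tstat), G - 2)
    data.frame(set = nm, size = m, delta = delta, t = tstat,
               direction = ifelse(delta >= 0, "up", "down"), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set = character(0), size = integer(0),
                      delta = numeric(0), t = numeric(0),
                      direction = character(0), p = numeric(0))
  rownames(out) <- NULL
  out
}

# Weighted running-sum enrichment score for hit positions `idx` (sorted
# increasing) among G ranks with weights w (|stat|^weight, full length G).
# Returns ES and the index (into idx) of the extremum.
running_es <- function(idx, w, G) {
  m <- length(idx)
  wh <- w[idx]
  NR <- sum(wh)
  if (NR == 0) wh <- rep(1, m) else wh <- wh / NR
  if (NR == 0) wh <- wh / m
  hit_cum <- cumsum(wh)
  miss_step <- if (G > m) 1 / (G - m) else 0
  miss_before <- (idx - seq_len(m)) * miss_step
  tops <- hit_cum - miss_before            # just after each hit
  bottoms <- c(0, hit_cum[-m]) - miss_before  # just before each hit
  max_p <- max(tops)
  min_n <- min(bottoms)
  # Exact positive/negative ties occur (both deviations can be integer
  # multiples of the miss step); compare with a tolerance so cumsum
  # rounding cannot flip the branch.
  if (max_p + min_n > 1e-10) list(es = max_p, at = which.max(tops), pos = TRUE)
  else if (max_p + min_n < -1e-10) list(es = min_n, at = which.min(bottoms),
                                        pos = FALSE)
  else list(es = 0, at = which.max(tops), pos = TRUE)
}

#' Pre-ranked gene-set enrichment by the weighted running-sum statistic
#'
#' Walks the ranked list top to bottom; a member gene ("hit") at rank `i`
#' advances the running sum by `|stat_i|^weight / sum_set |stat|^weight`, a
#' non-member retreats it by `1 / (G - m)`. The enrichment score ES is the
#' signed maximum deviation from zero. Significance comes from `n_perm`
#' random gene sets of the same size: `p = (1 + #{same-sign perm ES with
#' |ES_perm| >= |ES|}) / (1 + #{same-sign perm ES})`, and
#' `NES = ES / mean(|same-sign perm ES|)`. The leading edge contains the
#' member genes at or before the extremum (at or after it for negative ES).
#'
#' @param ranked named numeric vector of signed statistics sorted in
#'   decreasing order (e.g. [pi_ranking()]).
#' @param sets a `GeneSetCollection`.
#' @param n_perm number of permutations (default 10000).
#' @param weight exponent on `|stat|` (default 1).
#' @param min_size,max_size set-size bounds after intersection with the
#'   ranked list (defaults 5 and 300).
#' @param seed integer seed for the permutation null.
#' @return `data.frame(set, size, ES, NES, p, direction)` with a
#'   `leading_edge` list column; empty (with a warning) when no set
#'   survives the size filter. Null ES draws are shared across sets of
#'   equal size.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 10000, weight = 1,
                           min_size = 5, max_size = 300, seed = 1L) {
  if (is.unsorted(rev(ranked))) ranked <- sort(ranked, decreasing = TRUE)
  G <- length(ranked)
  genes <- names(ranked)
  w <- abs(ranked)^weight
  hits <- lapply(names(sets), function(nm) which(genes %in% sets[[nm]]))
  names(hits) <- names(sets)
  sizes <- lengths(hits)
  keep <- sizes >= min_size & sizes <= max_size & sizes < G
  if (!any(keep)) {
    warning("no gene set within the size filter [", min_size, ", ",
            max_size, "]")
    return(data.frame(set = character(0), size = integer(0), ES = numeric(0),
                      NES = numeric(0), p = numeric(0),
                      direction = character(0)))
  }
  hits <- hits[keep]
  sizes <- sizes[keep]
  withr::with_seed(seed, {
    null_es <- lapply(sort(unique(sizes)), function(ms) {
      vapply(seq_len(n_perm), function(i) {
        running_es(sort(sample.int(G, ms)), w, G)$es
      }, 0)
    })
    names(null_es) <- as.character(sort(unique(sizes)))
    rows <- lapply(seq_along(hits), function(i) {
      re <- running_es(hits[[i]], w, G)
      perm <- null_es[[as.character(sizes[i])]]
      same <- if (re$es >= 0) perm[perm >= 0] else perm[perm < 0]
      p <- (1 + sum(abs(same) >= abs(re$es))) / (1 + length(same))
      nes <- if (length(same) == 0) NA_real_ else re$es / mean(abs(same))
      lead <- if (re$pos) genes[hits[[i]][seq_len(re$at)]]
              else genes[hits[[i]][seq(re$at, length(hits[[i]]))]]
      data.frame(set = names(hits)[i], size = sizes[i], ES = re$es,
                 NES = nes, p = p,
                 direction = ifelse(re$es >= 0, "up", "down"),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out$leading_edge <- lapply(seq_along(hits), function(i) {
      re <- running_es(hits[[i]], w, G)
      if (re$pos) genes[hits[[i]][seq_len(re$at)]]
      else genes[hits[[i]][seq(re$at, length(hits[[i]]))]]
    })
    out
  })
}

#' Consensus of the two enrichment methods
#'
#' Each method's p-values are FDR-adjusted across its own sets; a set is
#' consensus-enriched when both q-values fall below `alpha` and both
#' methods agree on the direction of change.
#'
#' @param camera output of [camera_pr()].
#' @param gsea output of [gsea_preranked()].
#' @param alpha significance level on the q-values (default 0.05).
#' @param fdr_method passed to [fdr_adjust()].
#' @return Merged `data.frame` (one row per set present in both tables)
#'   with `camera_q`, `gsea_q`, both directions and a logical `consensus`.
#' @export
consensus_enrichment <- function(camera, gsea, alpha = 0.05,
                                 fdr_method = "BH") {
  camera$camera_q <- fdr_adjust(camera$p, method = fdr_method)
  gsea$gsea_q <- fdr_adjust(gsea$p, method = fdr_method)
  merged <- merge(
    data.frame(set = camera$set, size = camera$size, camera_p = camera$p,
               camera_q = camera$camera_q, camera_dir = camera$direction,
               stringsAsFactors = FALSE),
    data.frame(set = gsea$set, ES = gsea$ES, NES = gsea$NES,
               gsea_p = gsea$p, gsea_q = gsea$gsea_q,
               gsea_dir = gsea$direction, stringsAsFactors = FALSE),
    by = "set")
  merged$consensus <- merged$camera_q < alpha & merged$gsea_q < alpha &
    merged$camera_dir == merged$gsea_dir
  merged$direction <- ifelse(merged$consensus, merged$camera_dir, NA_character_)
  merged[order(pmax(merged$camera_q, merged$gsea_q)), , drop = FALSE]
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a query list and
#' each gene set, against an explicit background (universe) — e.g.
#' tissue-specific proteins against that tissue's identifications, or
#' tissue-shared proteins against the union across tissues. Sets are
#' intersected with the background before the size filter.
#'
#' @param query character vector of genes; must be contained in
#'   `background`.
#' @param sets a `GeneSetCollection`.
#' @param background character vector, the universe `N`.
#' @param min_size,max_size size filter on `|set & background|` (defaults
#'   5 and 300).
#' @param fdr_method passed to [fdr_adjust()].
#' @return `data.frame(set, set_size, overlap, p, q)`.
#' @export
hypergeom_ora <- function(query, sets, background, min_size = 5,
                          max_size = 300, fdr_method = "BH") {
  off <- setdiff(query, background)
  if (length(off) > 0)
    stop("query gene(s) not in background: ", paste(off, collapse = ", "))
  N <- length(unique(background))
  n <- length(unique(query))
  rows <- lapply(names(sets), function(nm) {
    K <- length(intersect(sets[[nm]], background))
    if (K < min_size || K > max_size) return(NULL)
    k <- length(intersect(query, intersect(sets[[nm]], background)))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set = character(0), set_size = integer(0),
                      overlap = integer(0), p = numeric(0), q = numeric(0)))
  out$q <- fdr_adjust(out$p, method = fdr_method)
  rownames(out) <- NULL
  out
}

#' Enrichment-map graph of consensus sets
#'
#' Nodes are consensus sets significant in both methods at `node_q`; edges
#' connect sets whose member overlap coefficient
#' `|A & B| / min(|A|, |B|)` reaches `threshold`.
#'
#' @param consensus output of [consensus_enrichment()].
#' @param sets the `GeneSetCollection` providing member lists.
#' @param node_q node inclusion threshold on both q-values (default 0.01).
#' @param threshold minimum overlap coefficient for an edge (default 0.5).
#' @return `list(nodes = data.frame(set, camera_q, gsea_q, direction,
#'   size), edges = data.frame(from, to, similarity))`.
#' @export
build_enrichment_graph <- function(consensus, sets, node_q = 0.01,
                                   threshold = 0.5) {
  nodes <- consensus[consensus$consensus & consensus$camera_q < node_q &
                       consensus$gsea_q < node_q, , drop = FALSE]
  nodes <- data.frame(set = nodes$set, camera_q = nodes$camera_q,
                      gsea_q = nodes$gsea_q, direction = nodes$direction,
                      size = nodes$size, stringsAsFactors = FALSE)
  edges <- data.frame(from = character(0), to = character(0),
                      similarity = numeric(0), stringsAsFactors = FALSE)
  if (nrow(nodes) >= 2) {
    combs <- utils::combn(nodes$set, 2)
    sim <- apply(combs, 2, function(ab) {
      a <- sets[[ab[1]]]; b <- sets[[ab[2]]]
      length(intersect(a, b)) / min(length(a), length(b))
    })
    keep <- sim >= threshold & sim > 0
    edges <- data.frame(from = combs[1, keep], to = combs[2, keep],
                        similarity = sim[keep], stringsAsFactors = FALSE)
  }
  list(nodes = nodes, edges = edges)
}

#' Write an enrichment graph as JSON node/edge lists
#' @param graph output of [build_enrichment_graph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  jsonlite::write_json(graph, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
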