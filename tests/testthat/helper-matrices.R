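# Small builders shared across test files.

mat_of <- function(values, nrow, tissue = "liver", scale = "log2",
                   proteins = NULL, samples = NULL) {
  v <- matrix(values, nrow = nrow)
  rownames(v) <- proteins %||% paste0("P", seq_len(nrow(v)))
  colnames(v) <- samples %||% paste0("s", seq_len(ncol(v)))
  intensity_matrix(v, tissue = tissue, scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-group metadata for n_a + n_b samples of one tissue.
two_group_meta <- function(n_a, n_b, groups = c("CTRL", "T2D"),
                           tissue = "liver") {
  n <- n_a + n_b
  data.frame(
    sample_id = paste0("s", seq_len(n)),
    subject_id = paste0("p", seq_len(n)),
    tissue = tissue,
    group = factor(rep(groups, c(n_a, n_b)), levels = c("CTRL", "PD", "T2D")),
    stringsAsFactors = FALSE)
}

# Full running-sum GSEA oracle: walks every rank, O(G) per set. Kept
# independent of the package's incremental implementation.
oracle_es <- function(ranked, members, weight = 1) {
  G <- length(ranked)
  hit <- names(ranked) %in% members
  w <- abs(ranked)^weight
  nr <- sum(w[hit])
  inc <- ifelse(hit, if (nr > 0) w / nr else 1 / sum(hit), 0)
  dec <- ifelse(hit, 0, if (G > sum(hit)) 1 / (G - sum(hit)) else 0)
  run <- cumsum(inc - dec)
  mx <- max(run, 0); mn <- min(run, 0)
  if (mx + mn > 1e-10) mx else if (mx + mn < -1e-10) mn else 0
}
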