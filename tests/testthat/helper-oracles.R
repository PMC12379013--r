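# Independent oracles used across the suite. These deliberately re-derive
# each quantity with naive loops / dense grids, not via the package's own
# code paths.

# empirical-CDF quantile rank with midrank ties, by explicit counting
quantile_rank_bruteforce <- function(values, idx) {
  v <- values[idx]
  others <- values[-idx]
  below <- 0; ties <- 0
  for (w in others) {
    if (w < v) below <- below + 1
    if (w == v) ties <- ties + 1
  }
  (below + 0.5 * ties) / length(values)
}

# ssGSEA enrichment score by direct position-by-position enumeration
ssgsea_bruteforce <- function(expr_col, gene_ids, set_genes, alpha) {
  ord <- order(-expr_col, gene_ids, method = "radix")
  genes <- gene_ids[ord]
  N <- length(genes)
  in_set <- genes %in% set_genes
  m <- sum(in_set)
  denom <- 0
  for (p in seq_len(N)) if (in_set[p]) denom <- denom + (N - p + 1)^alpha
  ecdf_in <- 0; ecdf_out <- 0; es <- 0
  for (p in seq_len(N)) {
    if (in_set[p]) ecdf_in <- ecdf_in + (N - p + 1)^alpha / denom
    else ecdf_out <- ecdf_out + 1 / (N - m)
    es <- es + (ecdf_in - ecdf_out)
  }
  es
}

# dense trapezoid integration of the thresholded inhibition area
dss_trapezoid <- function(curve, window, t = 10, n = 2000) {
  lx <- seq(window[1], window[2], length.out = n)
  i <- 100 * (1 - fivepl(10^lx, curve$L, curve$U, curve$ec50, curve$h,
                         curve$s))
  g <- pmax(pmin(i, 100) - t, 0)
  area <- sum((g[-1] + g[-n]) / 2) * diff(window) / (n - 1)
  100 * area / ((100 - t) * diff(window))
}

# greedy one-to-one matching of detected to ground-truth puncta within a
# pixel tolerance; returns recall and precision
match_puncta <- function(truth, detected, tol = 2) {
  if (nrow(truth) == 0 || nrow(detected) == 0)
    return(list(recall = as.numeric(nrow(truth) == 0),
                precision = as.numeric(nrow(detected) == 0)))
  d <- sqrt(outer(truth$x, detected$x, "-")^2 +
            outer(truth$y, detected$y, "-")^2)
  used <- rep(FALSE, nrow(detected))
  matched <- 0
  for (i in order(apply(d, 1, min))) {
    j <- which.min(ifelse(used, Inf, d[i, ]))
    if (d[i, j] <= tol) { matched <- matched + 1; used[j] <- TRUE }
  }
  list(recall = matched / nrow(truth), precision = matched / nrow(detected))
}

# weak-effect monotherapy curve pair whose ZIP expectation stays far enough
# below 1 that an added interaction delta is never clipped
weak_curve_pair <- function() {
  list(c1 = list(L = 0.6, U = 1, ec50 = 100, h = 1, s = 1),
       c2 = list(L = 0.7, U = 1, ec50 = 1000, h = 1, s = 1))
}

random_small_expr <- function(N, n_samples = 1, gene_prefix = "g") {
  matrix(rnorm(N * n_samples), N, n_samples,
         dimnames = list(sprintf("%s%02d", gene_prefix, seq_len(N)),
                         sprintf("smp%d", seq_len(n_samples))))
}
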