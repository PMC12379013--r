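#' Cohort quantile rank of one cell line's drug sensitivity
#'
#' Empirical-CDF rank with midrank tie handling:
#' `q = (#\{j: dss_j < dss_line\} + 0.5 #\{j != line: dss_j = dss_line\}) / n`
#' over the lines with a non-missing DSS for the drug (missing values are
#' excluded from `n`).
#'
#' @param dss named numeric vector of DSS values for one drug (names = lines);
#'   may contain `NA`.
#' @param line the line of interest (name present in `dss`).
#' @return quantile rank in \[0, 1).
#' @export
quantile_rank <- function(dss, line) {
  stop_if_not(line %in% names(dss), "line '", line, "' not in the cohort")
  v <- dss[[line]]
  if (is.na(v)) stop("line '", line, "' has no DSS for this drug",
                     call. = FALSE)
  x <- dss[!is.na(dss)]
  stop_if_not(length(x) >= 2, "need >= 2 non-missing values to rank")
  (sum(x < v) + 0.5 * (sum(x == v) - 1)) / length(x)
}

hit_call <- function(q, hit_q = 0.75, top_q = 0.95) {
  ifelse(is.na(q), NA_character_,
         ifelse(q > top_q, "top_hit", ifelse(q > hit_q, "hit", "none")))
}

#' Quantile-rank matrix of a cohort sensitivity matrix
#'
#' @param dss lines x drugs numeric matrix (dimnames required; NAs allowed).
#' @return matrix of quantile ranks, same shape; NA where DSS missing.
#' @export
quantile_matrix <- function(dss) {
  stop_if_not(!is.null(rownames(dss)) && !is.null(colnames(dss)),
              "dss matrix needs line rownames and drug colnames")
  stop_if_not(!anyDuplicated(rownames(dss)) && !anyDuplicated(colnames(dss)),
              "line and drug names must be unique")
  q <- dss
  for (j in seq_len(ncol(dss))) {
    col <- dss[, j]
    ok <- !is.na(col)
    q[, j] <- NA_real_
    if (sum(ok) >= 2)
      q[ok, j] <- vapply(rownames(dss)[ok],
                         function(ln) quantile_rank(col, ln), numeric(1))
  }
  q
}

#' Call hits and top hits across a cohort
#'
#' A drug effect is a hit for a line when its cohort quantile rank is strictly
#' above `hit_q` (default 0.75) and a top hit strictly above `top_q`
#' (default 0.95).
#'
#' @param dss lines x drugs DSS matrix.
#' @param hit_q,top_q quantile thresholds (strict inequalities).
#' @return long data.frame: `line`, `drug`, `dss`, `q`, `call`.
#' @export
call_hits <- function(dss, hit_q = 0.75, top_q = 0.95) {
  q <- quantile_matrix(dss)
  out <- data.frame(
    line = rep(rownames(dss), times = ncol(dss)),
    drug = rep(colnames(dss), each = nrow(dss)),
    dss = as.vector(dss),
    q = as.vector(q),
    call = hit_call(as.vector(q), hit_q, top_q),
    stringsAsFactors = FALSE)
  out
}

#' Per-drug z-scores of quantile ranks (display scaling)
#'
#' Columns with zero variance map to all zeros.
#'
#' @param dss lines x drugs DSS matrix.
#' @return z-scored quantile matrix.
#' @export
zscore_matrix <- function(dss) {
  q <- quantile_matrix(dss)
  apply(q, 2, function(col) {
    s <- sd(col, na.rm = TRUE)
    if (is.na(s) || s == 0) return(ifelse(is.na(col), NA_real_, 0))
    (col - mean(col, na.rm = TRUE)) / s
  })
}

#' Compare subtype groups on mean DSS over a drug subset
#'
#' Two-sided Wilcoxon rank-sum test on per-line mean DSS over the selected
#' drugs; exact null distribution when both groups have <= 10 lines and there
#' are no ties, otherwise the tie-corrected normal approximation.
#'
#' @param dss lines x drugs DSS matrix.
#' @param groups named character vector mapping line -> group label (exactly
#'   two labels used).
#' @param drug_subset drugs to average over (default all columns).
#' @return list with `statistic` (rank-sum U), `p_value`, `group_means`, `n`.
#' @export
compare_groups <- function(dss, groups, drug_subset = colnames(dss)) {
  stop_if_not(all(drug_subset %in% colnames(dss)),
              "unknown drugs in drug_subset")
  lines <- intersect(rownames(dss), names(groups))
  g <- factor(groups[lines])
  stop_if_not(nlevels(g) == 2, "groups must contain exactly two labels")
  m <- rowMeans(dss[lines, drug_subset, drop = FALSE], na.rm = TRUE)
  x <- m[g == levels(g)[1]]; y <- m[g == levels(g)[2]]
  stop_if_not(length(x) >= 2 && length(y) >= 2,
              "each group needs >= 2 lines")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- max(length(x), length(y)) <= 10 && !ties
  wt <- wilcox.test(x, y, exact = exact, correct = !exact)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       group_means = setNames(c(mean(x), mean(y)), levels(g)),
       n = setNames(c(length(x), length(y)), levels(g)),
       exact = exact)
}
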