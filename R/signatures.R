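#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return named list of character vectors (whitespace-trimmed, deduplicated).
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, function(g) unique(trimws(g)))
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(gene_sets, path) {
  stop_if_not(!is.null(names(gene_sets)), "gene_sets must be named")
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

check_expr <- function(expr) {
  stop_if_not(is.matrix(expr) && !is.null(rownames(expr)),
              "expr must be a genes x samples matrix with gene rownames")
  rownames(expr) <- trimws(rownames(expr))
  stop_if_not(!anyDuplicated(rownames(expr)), "duplicate gene identifiers")
  stop_if_not(all(is.finite(expr)), "expression values must be finite")
  expr
}

#' Single-sample GSEA enrichment score
#'
#' Per sample, genes are ranked by decreasing expression (ties broken by gene
#' identifier). Walking down the ranked list, in-set genes step by their rank
#' weight `r^alpha` (r = N for the top gene, 1 for the bottom) normalized to
#' sum to one over the in-set genes; out-of-set genes step uniformly by
#' `1/(N - m)`. The enrichment score is the integrated (summed) difference of
#' the two running ECDFs over all N positions — the single-sample variant,
#' not the max-deviation statistic.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param gene_set character vector of gene identifiers.
#' @param alpha rank weighting exponent (default 0.25).
#' @param set_name label used in error messages.
#' @return named numeric vector of enrichment scores, one per sample.
#' @export
ssgsea <- function(expr, gene_set, alpha = 0.25, set_name = "gene set") {
  expr <- check_expr(expr)
  gene_set <- unique(trimws(gene_set))
  in_set <- rownames(expr) %in% gene_set
  if (!any(in_set))
    stop("no genes of '", set_name, "' present in the expression matrix",
         call. = FALSE)
  stop_if_not(sum(!in_set) >= 1, "gene set covers the whole matrix")
  N <- nrow(expr)
  vapply(seq_len(ncol(expr)), function(j) {
    # decreasing expression; gene id as deterministic tie-break
    ord <- order(-expr[, j], rownames(expr), method = "radix")
    inz <- in_set[ord]
    r <- (N:1)^alpha
    w_in <- r * inz
    w_in <- w_in / sum(w_in)
    w_out <- (!inz) / (N - sum(inz))
    sum(cumsum(w_in) - cumsum(w_out))
  }, numeric(1), USE.NAMES = FALSE) |>
    setNames(colnames(expr))
}

#' Score several gene sets per sample, with cohort rescaling
#'
#' @param expr genes x samples matrix.
#' @param gene_sets named list of gene identifier vectors.
#' @param alpha ssGSEA rank exponent.
#' @param normalize min-max rescale each set's scores to \[0, 1\] across
#'   samples (requires >= 2 samples).
#' @return data.frame: `sample`, `set`, `es`, `normalized`.
#' @export
score_gene_sets <- function(expr, gene_sets, alpha = 0.25, normalize = TRUE) {
  rows <- lapply(names(gene_sets), function(nm) {
    es <- ssgsea(expr, gene_sets[[nm]], alpha = alpha, set_name = nm)
    norm <- if (normalize && length(es) >= 2 && diff(range(es)) > 0)
      (es - min(es)) / diff(range(es)) else rep(NA_real_, length(es))
    data.frame(sample = names(es), set = nm, es = unname(es),
               normalized = unname(norm), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mesenchymal/adrenergic identity score
#'
#' ssGSEA enrichment of a mesenchymal super-enhancer signature, min-max
#' normalized across the cohort to \[0, 1\]; higher = more mesenchymal.
#'
#' @param expr genes x samples matrix.
#' @param mes_set mesenchymal signature genes.
#' @param alpha ssGSEA rank exponent.
#' @return named numeric vector in \[0, 1\], one score per sample.
#' @export
mes_adr_score <- function(expr, mes_set, alpha = 0.25) {
  es <- ssgsea(expr, mes_set, alpha = alpha, set_name = "MES")
  stop_if_not(length(es) >= 2, "need >= 2 samples to normalize the score")
  rng <- range(es)
  if (diff(rng) == 0) return(setNames(rep(0.5, length(es)), names(es)))
  (es - rng[1]) / diff(rng)
}

#' MAPK pathway activity score (MPAS)
#'
#' Each signature gene's expression is z-scored across samples; the score is
#' the sum of the z-scores divided by the square root of the number of
#' signature genes present. Genes absent from the matrix are dropped with a
#' warning.
#'
#' @param expr genes x samples matrix.
#' @param mpas_genes signature gene identifiers.
#' @return named numeric vector, one score per sample.
#' @export
mpas <- function(expr, mpas_genes) {
  expr <- check_expr(expr)
  mpas_genes <- unique(trimws(mpas_genes))
  present <- intersect(mpas_genes, rownames(expr))
  if (length(present) == 0)
    stop("no MPAS genes present in the expression matrix", call. = FALSE)
  n_drop <- length(mpas_genes) - length(present)
  if (n_drop > 0)
    warning(n_drop, " MPAS gene(s) absent from the matrix were dropped")
  z <- t(apply(expr[present, , drop = FALSE], 1, function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  setNames(colSums(z) / sqrt(length(present)), colnames(expr))
}

#' Correlate two per-sample score vectors
#'
#' Pearson (or Spearman) correlation over pairwise-complete samples, with the
#' two-sided test p-value.
#'
#' @param x,y numeric vectors; if named, matched by name.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r`, `p_value`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!is.null(names(x)) && !is.null(names(y))) {
    common <- intersect(names(x), names(y))
    x <- x[common]; y <- y[common]
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  stop_if_not(length(x) >= 3, "need >= 3 complete pairs to correlate")
  ct <- suppressWarnings(cor.test(x, y, method = method))
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
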