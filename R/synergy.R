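#' Construct a combination-response surface
#'
#' The inhibition matrix is `(K1 + 1) x (K2 + 1)`: row 1 and column 1 are the
#' monotherapy edges (dose 0 of the partner), the remaining cells the
#' combination wells. `NA` inhibition marks unmeasured wells.
#'
#' @param doses1,doses2 strictly increasing positive dose grids (nM).
#' @param inhibition numeric matrix of inhibition fractions in \[0, 1\]
#'   (NAs allowed); `inhibition[1, 1]` is the untreated well (0).
#' @param mask optional character matrix (`"measured"`, `"imputed"`,
#'   `"missing"`); defaults to measured where inhibition is present.
#' @param drug1,drug2 labels.
#' @return object of class `combination_surface`.
#' @export
combination_surface <- function(doses1, doses2, inhibition, mask = NULL,
                                drug1 = "drug1", drug2 = "drug2") {
  stop_if_not(all(doses1 > 0) && all(diff(doses1) > 0) &&
              all(doses2 > 0) && all(diff(doses2) > 0),
              "doses must be strictly increasing positives")
  stop_if_not(nrow(inhibition) == length(doses1) + 1 &&
              ncol(inhibition) == length(doses2) + 1,
              "inhibition must be (K1+1) x (K2+1) including dose-0 edges")
  meas <- inhibition[!is.na(inhibition)]
  stop_if_not(all(meas >= 0 & meas <= 1),
              "measured inhibition must lie in [0, 1]")
  if (is.null(mask)) {
    mask <- matrix(ifelse(is.na(inhibition), "missing", "measured"),
                   nrow(inhibition))
  }
  dimnames(inhibition) <- dimnames(mask) <-
    list(c("0", format(doses1, trim = TRUE)),
         c("0", format(doses2, trim = TRUE)))
  structure(list(drug1 = drug1, drug2 = drug2, doses1 = doses1,
                 doses2 = doses2, inhibition = inhibition, mask = mask),
            class = "combination_surface")
}

#' @export
print.combination_surface <- function(x, ...) {
  cat(sprintf("combination surface: %s x %s (%d x %d doses), %d imputed\n",
              x$drug1, x$drug2, length(x$doses1), length(x$doses2),
              sum(x$mask == "imputed")))
  invisible(x)
}

#' @export
as.data.frame.combination_surface <- function(x, ...) {
  d1 <- c(0, x$doses1); d2 <- c(0, x$doses2)
  df <- expand.grid(dose1_nM = d1, dose2_nM = d2)
  df$drug1 <- x$drug1; df$drug2 <- x$drug2
  df$inhibition <- as.vector(x$inhibition)
  df$mask <- as.vector(x$mask)
  df[, c("drug1", "drug2", "dose1_nM", "dose2_nM", "inhibition", "mask")]
}

#' Zero-interaction-potency expected combination effect
#'
#' Bliss-independence expectation `y1 + y2 - y1 y2` of two single-agent
#' inhibition fractions.
#'
#' @param y1,y2 inhibition fractions in \[0, 1\].
#' @return expected combined inhibition fraction.
#' @export
zip_expected <- function(y1, y2) {
  stop_if_not(all(y1 >= 0 & y1 <= 1) && all(y2 >= 0 & y2 <= 1),
              "inhibition fractions must lie in [0, 1]")
  y1 + y2 - y1 * y2
}

# fit 4PL curves to the two monotherapy edges; returns fitted inhibition
# vectors along each axis plus the viability-curve fits
fit_edges <- function(surface) {
  inh1 <- surface$inhibition[-1, 1]
  inh2 <- surface$inhibition[1, -1]
  if (anyNA(inh1) || anyNA(inh2) ||
      any(surface$mask[-1, 1] == "missing") ||
      any(surface$mask[1, -1] == "missing"))
    stop("monotherapy edges must be measured (edges cannot be imputed)",
         call. = FALSE)
  fit1 <- fit_curve(doses = surface$doses1, viability = 1 - inh1,
                    symmetric = TRUE)
  fit2 <- fit_curve(doses = surface$doses2, viability = 1 - inh2,
                    symmetric = TRUE)
  list(fit1 = fit1, fit2 = fit2,
       y1 = pmin(pmax(1 - predict(fit1, surface$doses1), 0), 1),
       y2 = pmin(pmax(1 - predict(fit2, surface$doses2), 0), 1))
}

#' ZIP delta matrix and mean synergy score
#'
#' Fits a symmetric logistic to each monotherapy edge; for every interior
#' (combination) well the delta is the observed (or imputed) inhibition minus
#' the ZIP expectation of the fitted single-agent effects. The summary score
#' is 100 times the mean interior delta; classification uses the +-
#' `threshold` boundary (default 10 on the x100 scale): `synergy` at or above
#' it, `antagonism-trend` at or below its negative, else `additive`.
#'
#' @param surface a [combination_surface()] with measured edges and measured
#'   or imputed interior.
#' @param threshold classification boundary on the x100 scale.
#' @return list of class `zip_result`: `delta` (interior matrix), `expected`,
#'   `mean_zip`, `classification`, `edge_fits`.
#' @export
zip_delta_matrix <- function(surface, threshold = 10) {
  ed <- fit_edges(surface)
  obs <- surface$inhibition[-1, -1, drop = FALSE]
  if (anyNA(obs))
    stop("interior wells unmeasured; impute the design first ",
         "(impute_diagonal_design)", call. = FALSE)
  expected <- outer(ed$y1, ed$y2, function(a, b) a + b - a * b)
  delta <- obs - expected
  mean_zip <- 100 * mean(delta)
  cls <- if (mean_zip >= threshold) "synergy"
         else if (mean_zip <= -threshold) "antagonism-trend" else "additive"
  structure(list(delta = delta, expected = expected, mean_zip = mean_zip,
                 classification = cls, edge_fits = ed[c("fit1", "fit2")]),
            class = "zip_result")
}

#' @export
print.zip_result <- function(x, ...) {
  cat(sprintf("ZIP: mean score %.2f (%s)\n", x$mean_zip, x$classification))
  invisible(x)
}

#' Impute a diagonal minimal-sampling design to a full surface
#'
#' For a reduced design measuring only the monotherapy edges and the main
#' diagonal (equal dose-rank pairs), the observed diagonal deltas
#' `d_k = observed(k, k) - ZIP(k, k)` are linearly interpolated over the dose
#' rank at `k* = (i + j) / 2` (clamped to \[1, K\]) to fill each interior
#' well: `inhibition = clip(ZIP expectation + interpolated delta, 0, 1)`.
#' Imputed wells are marked in the mask; measured wells are untouched.
#'
#' @param surface a `combination_surface` with equal-length dose grids,
#'   measured edges and complete measured diagonal.
#' @return the fully populated `combination_surface`.
#' @export
impute_diagonal_design <- function(surface) {
  K <- length(surface$doses1)
  stop_if_not(length(surface$doses2) == K,
              "diagonal design requires equally long dose grids")
  inner <- surface$inhibition[-1, -1, drop = FALSE]
  diag_missing <- which(is.na(diag(inner)))
  if (length(diag_missing))
    stop("diagonal incomplete; missing wells at dose rank(s): ",
         paste(diag_missing, collapse = ", "), call. = FALSE)
  ed <- fit_edges(surface)
  expected <- outer(ed$y1, ed$y2, function(a, b) a + b - a * b)
  d <- diag(inner) - diag(expected)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (!is.na(inner[i, j])) next
    kstar <- min(max((i + j) / 2, 1), K)
    dstar <- if (K == 1) d else stats::approx(seq_len(K), d, xout = kstar)$y
    inner[i, j] <- min(max(expected[i, j] + dstar, 0), 1)
    surface$mask[i + 1, j + 1] <- "imputed"
  }
  surface$inhibition[-1, -1] <- inner
  surface
}

#' Combination sensitivity score (CSS)
#'
#' For each direction, the partner drug is fixed at the tested dose closest
#' (on the log scale) to its fitted relative IC50; the resulting combination
#' dose-response of the other drug is fitted with a symmetric logistic and
#' summarized as the normalized area under its inhibition curve (the DSS
#' integral with threshold 0, on the 0-100 scale). The CSS is the mean of the
#' two directional scores; combinations with CSS above `high_threshold`
#' (default 40) are classed as high-effect.
#'
#' @param surface a fully populated `combination_surface`.
#' @param high_threshold effect-class boundary.
#' @return list of class `css_result`: `css_1at2`, `css_2at1`, `css`,
#'   `effect_class`, `fixed_dose` (per direction), `ic50_outside_range`
#'   flags.
#' @export
css <- function(surface, high_threshold = 40) {
  ed <- fit_edges(surface)
  pick <- function(doses, ec50) {
    j <- which.min(abs(log(doses) - log(ec50)))
    list(j = j, outside = ec50 < min(doses) || ec50 > max(doses))
  }
  p2 <- pick(surface$doses2, ed$fit2$ec50)
  p1 <- pick(surface$doses1, ed$fit1$ec50)
  if (p1$outside || p2$outside)
    warning("fitted IC50 outside the tested range; nearest edge dose used")
  dir_score <- function(doses, inh_vec) {
    stop_if_not(!anyNA(inh_vec),
                "combination response at the IC50 dose is unmeasured")
    fit <- fit_curve(doses = doses, viability = 1 - inh_vec,
                     symmetric = TRUE)
    compute_dss(fit, log10(range(doses)), t = 0)$dss
  }
  css_1at2 <- dir_score(surface$doses1,
                        surface$inhibition[-1, p2$j + 1])
  css_2at1 <- dir_score(surface$doses2,
                        surface$inhibition[p1$j + 1, -1])
  val <- mean(c(css_1at2, css_2at1))
  structure(list(css_1at2 = css_1at2, css_2at1 = css_2at1, css = val,
                 effect_class = if (val > high_threshold) "high" else "low",
                 fixed_dose = c(dose2 = surface$doses2[p2$j],
                                dose1 = surface$doses1[p1$j]),
                 ic50_outside_range = c(drug1 = p1$outside,
                                        drug2 = p2$outside)),
            class = "css_result")
}

#' @export
print.css_result <- function(x, ...) {
  cat(sprintf("CSS: %.1f (1at2 %.1f, 2at1 %.1f; %s effect)\n",
              x$css, x$css_1at2, x$css_2at1, x$effect_class))
  invisible(x)
}

#' Compare co-treatment against sequential-treatment score tables
#'
#' Pairs the two tables on their shared identifier columns and summarizes
#' per-pair differences (sequential minus co-treatment) of `css` and
#' `mean_zip` with paired Wilcoxon signed-rank tests; reports per-group
#' medians when a `group` column is present. Unpaired rows are dropped with a
#' warning.
#'
#' @param co,sequential data.frames with identifier columns (e.g. `line`,
#'   `drug1`, `drug2`) plus `css` and/or `mean_zip`.
#' @return list with per-score summaries (`median_diff`, `p_value`, `n`) and
#'   `group_medians` when grouping is available.
#' @export
compare_schedules <- function(co, sequential) {
  score_cols <- intersect(c("css", "mean_zip"),
                          intersect(names(co), names(sequential)))
  stop_if_not(length(score_cols) >= 1,
              "tables must share a 'css' and/or 'mean_zip' column")
  id_cols <- setdiff(intersect(names(co), names(sequential)),
                     c(score_cols, "group"))
  stop_if_not(length(id_cols) >= 1, "no shared identifier columns to pair on")
  merged <- merge(co, sequential, by = id_cols,
                  suffixes = c("_co", "_seq"))
  dropped <- nrow(co) + nrow(sequential) - 2 * nrow(merged)
  if (dropped > 0)
    warning(dropped, " unpaired entr(ies) dropped")
  stop_if_not(nrow(merged) >= 1, "no paired entries")
  res <- lapply(score_cols, function(sc) {
    d <- merged[[paste0(sc, "_seq")]] - merged[[paste0(sc, "_co")]]
    p <- if (all(d == 0)) 1 else
      suppressWarnings(wilcox.test(d, exact = FALSE)$p.value)
    out <- list(median_diff = median(d), p_value = p, n = length(d))
    gcol <- intersect(c("group_co", "group"), names(merged))[1]
    if (!is.na(gcol))
      out$group_medians <- tapply(d, merged[[gcol]], median)
    out
  })
  setNames(res, score_cols)
}
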