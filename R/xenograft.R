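#' RECIST-style response classification of xenograft volume changes
#'
#' Percent tumor-volume change between the baseline (24 hpi) and follow-up
#' (72 hpi) measurement, classified with the zebrafish-adapted RECIST2.0
#' thresholds: partial response (PR) at 30% or more below baseline,
#' progressive disease (PD) at 20% or more above, stable disease (SD)
#' otherwise. Both boundaries are inclusive. The call is invariant to the
#' volume unit.
#'
#' @param records data.frame with columns `v24` and `v72` (positive volumes),
#'   or two numeric vectors via `v24`/`v72`.
#' @param v24,v72 alternative vector interface.
#' @param pr_bound,pd_bound percent-change boundaries (defaults -30 / +20).
#' @return the records with added `pct_change` and `call` columns (factor
#'   PR/SD/PD).
#' @export
classify_response <- function(records = NULL, v24 = NULL, v72 = NULL,
                              pr_bound = -30, pd_bound = 20) {
  if (!is.null(records)) { v24 <- records$v24; v72 <- records$v72 }
  stop_if_not(all(v24 > 0) && all(v72 > 0), "volumes must be positive")
  stop_if_not(pr_bound < 0 && pd_bound > 0,
              "PR bound must be negative and PD bound positive")
  pct <- 100 * (v72 - v24) / v24
  call <- factor(ifelse(pct <= pr_bound, "PR",
                        ifelse(pct >= pd_bound, "PD", "SD")),
                 levels = c("PR", "SD", "PD"))
  if (is.null(records)) records <- data.frame(v24 = v24, v72 = v72)
  records$pct_change <- pct
  records$call <- call
  records
}

#' Per-group response rates
#'
#' @param records classified records (see [classify_response()]; classified
#'   on the fly if the `call` column is absent) with a `group` column.
#' @return data.frame per group: `n`, `n_PR`, `PR_pct`, `n_SD`, `n_PD`,
#'   `PD_pct`.
#' @export
response_rates <- function(records) {
  stop_if_not("group" %in% names(records), "records need a 'group' column")
  stop_if_not(nrow(records) > 0, "no records")
  if (!"call" %in% names(records)) records <- classify_response(records)
  groups <- split(records, records$group, drop = TRUE)
  stop_if_not(all(vapply(groups, nrow, integer(1)) > 0), "empty group")
  out <- do.call(rbind, lapply(names(groups), function(g) {
    r <- groups[[g]]
    data.frame(group = g, n = nrow(r),
               n_PR = sum(r$call == "PR"),
               PR_pct = 100 * mean(r$call == "PR"),
               n_SD = sum(r$call == "SD"),
               n_PD = sum(r$call == "PD"),
               PD_pct = 100 * mean(r$call == "PD"))
  }))
  rownames(out) <- NULL
  out
}

#' Mann-Whitney comparison of control vs treated volume changes
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on the percent volume
#' change; exact null distribution when the smaller arm has at most 8 embryos
#' and there are no ties, otherwise the tie-corrected normal approximation.
#'
#' @param control,treated data.frames with `v24`/`v72` (classified on the
#'   fly) or numeric vectors of percent changes.
#' @return list with `statistic` (U), `p_value`, `n`, `exact`.
#' @export
compare_volume_change <- function(control, treated) {
  as_pct <- function(x) {
    if (is.data.frame(x)) {
      if (!"pct_change" %in% names(x)) x <- classify_response(x)
      x$pct_change
    } else x
  }
  x <- as_pct(control); y <- as_pct(treated)
  stop_if_not(length(x) >= 1 && length(y) >= 1, "both arms need records")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !ties
  wt <- wilcox.test(x, y, exact = exact, correct = !exact)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n = c(control = length(x), treated = length(y)), exact = exact)
}
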