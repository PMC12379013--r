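#' Five-parameter asymmetric logistic viability model
#'
#' `y(x) = L + (U - L) / (1 + (x / ec50)^h)^s`, evaluated at dose `x` (nM).
#' With `h > 0` the curve decreases monotonically from the upper plateau `U`
#' (untreated viability) towards the lower plateau `L` (residual viability at
#' saturating dose); `s` controls the asymmetry around the inflection, with
#' `s = 1` recovering the symmetric four-parameter logistic.
#'
#' @param x dose vector (nM, positive).
#' @param L,U lower and upper viability asymptotes.
#' @param ec50 dose of half-maximal effect when `s = 1` (nM).
#' @param h Hill slope (> 0).
#' @param s asymmetry exponent (> 0).
#' @return predicted viability fractions.
#' @export
fivepl <- function(x, L, U, ec50, h, s = 1) {
  L + (U - L) / (1 + (x / ec50)^h)^s
}

#' Normalize raw plate signals to solvent controls
#'
#' Converts raw luminescence to viability fractions by dividing each well by
#' the median of the solvent-control wells on the same plate, then clipping to
#' \[0, 2\] to bound the leverage of outlier wells.
#'
#' @param plate a data.frame with columns `plate`, `well`, `line`, `drug`,
#'   `dose_nM`, `signal`, `is_control` (logical; `line`, `drug`, `dose_nM` may
#'   be `NA` for control wells).
#' @return the non-control rows with an added `viability` column.
#' @export
normalize_signals <- function(plate) {
  need <- c("plate", "signal", "is_control")
  stop_if_not(all(need %in% names(plate)),
              "plate table must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(plate, plate$plate), function(pl) {
    ctrl <- pl$signal[pl$is_control]
    if (length(ctrl) == 0)
      stop("no solvent-control wells on plate '", pl$plate[1], "'",
           call. = FALSE)
    if (length(ctrl) < 3)
      warning("plate '", pl$plate[1], "' has fewer than 3 control wells")
    wells <- pl[!pl$is_control, , drop = FALSE]
    wells$viability <- pmin(pmax(wells$signal / median(ctrl), 0), 2)
    wells
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit a five-parameter asymmetric dose-response curve
#'
#' Least-squares fit of [fivepl()] on log10 dose, with multi-start
#' initialization: a grid over `ec50` spanning the observed dose range, Hill
#' slopes \{0.5, 1, 2\} and asymmetry \{0.5, 1, 2\}; the start with the best
#' residual sum of squares wins. Box constraints `L` in \[0, 1\], `U` in
#' \[0.5, 1.5\], `s` in \[0.1, 10\]. Near-constant data (or total failure of
#' all starts) returns a flat fallback curve with `converged = FALSE` rather
#' than raising.
#'
#' @param series data.frame with columns `dose_nM` and `viability`, or a pair
#'   of vectors via `doses`/`viability`.
#' @param doses,viability alternative vector interface.
#' @param symmetric if `TRUE`, fixes `s = 1` (four-parameter logistic).
#' @return an object of class `fitted_curve`: list with `L`, `U`, `ec50`, `h`,
#'   `s`, `rss`, `converged`, `n`.
#' @export
fit_curve <- function(series = NULL, doses = NULL, viability = NULL,
                      symmetric = FALSE) {
  if (!is.null(series)) {
    doses <- series$dose_nM %||% series$dose
    viability <- series$viability
  }
  ok <- is.finite(doses) & is.finite(viability) & doses > 0
  doses <- doses[ok]; viability <- viability[ok]
  stop_if_not(length(unique(doses)) >= 4,
              "need >= 4 distinct positive doses to fit a curve")

  flat <- function() {
    m <- mean(viability)
    structure(list(L = m, U = m, ec50 = exp(mean(log(doses))), h = 1, s = 1,
                   rss = sum((viability - m)^2), converged = FALSE,
                   n = length(doses)),
              class = "fitted_curve")
  }
  if (sd(viability) < 1e-6) return(flat())

  lt <- log10(doses)
  dat <- data.frame(lt = lt, y = viability)
  lower <- c(L = 0,   U = 0.5, e = min(lt) - 2, h = 0.05, s = 0.1)
  upper <- c(L = 1,   U = 1.5, e = max(lt) + 2, h = 20,   s = 10)
  L0 <- min(1, max(0, min(viability)))
  U0 <- min(1.5, max(0.5, max(viability)))
  e_grid <- seq(min(lt), max(lt), length.out = 4)
  s_grid <- if (symmetric) 1 else c(0.5, 1, 2)
  if (symmetric) { lower["s"] <- 1; upper["s"] <- 1 }

  best <- NULL
  for (e0 in e_grid) for (h0 in c(0.5, 1, 2)) for (s0 in s_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ L + (U - L) / (1 + 10^((lt - e) * h))^s,
        data = dat,
        start = list(L = L0, U = U0, e = e0, h = h0, s = s0),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      p <- as.list(stats::coef(fit))
      best <- list(L = p$L, U = p$U, ec50 = 10^p$e, h = p$h, s = p$s,
                   rss = rss, converged = TRUE, n = length(doses))
    }
  }
  if (is.null(best)) return(flat())
  structure(best, class = "fitted_curve")
}

#' @export
predict.fitted_curve <- function(object, newdata = NULL, ...) {
  x <- if (is.data.frame(newdata)) (newdata$dose_nM %||% newdata$dose)
       else newdata
  fivepl(x, object$L, object$U, object$ec50, object$h, object$s)
}

#' @export
print.fitted_curve <- function(x, ...) {
  cat(sprintf(
    "5PL fit: L=%.3f U=%.3f EC50=%.3g nM h=%.3f s=%.3f (rss=%.2e, %s)\n",
    x$L, x$U, x$ec50, x$h, x$s, x$rss,
    if (x$converged) "converged" else "fallback"))
  invisible(x)
}

#' Drug sensitivity score from a fitted curve
#'
#' Normalized thresholded area under the inhibition curve on log10 dose:
#' with inhibition `i(x) = 100 (1 - y(x))`,
#' `DSS = 100 * int max(i(x) - t, 0) dx / ((100 - t) (x_max - x_min))`
#' over the log10-dose window, by adaptive quadrature. Bounded in \[0, 100\];
#' 0 when fitted inhibition never exceeds the activity threshold `t`, 100 for
#' complete inhibition across the whole window. Computed here on the
#' asymmetric five-parameter fit (the `DSS_asym` flavour).
#'
#' @param curve a `fitted_curve`.
#' @param dose_window numeric length-2, window in log10 nM; defaults should be
#'   the tested dose range.
#' @param t activity threshold in percent inhibition (default 10).
#' @return object of class `dss_result`: list with `dss`, `threshold`,
#'   `dose_window`.
#' @export
compute_dss <- function(curve, dose_window, t = 10) {
  stop_if_not(length(dose_window) == 2 && dose_window[1] < dose_window[2],
              "dose_window must be (x_min, x_max) with x_min < x_max")
  stop_if_not(t >= 0 && t < 100, "threshold t must be in [0, 100)")
  f <- function(lx) {
    i <- 100 * (1 - fivepl(10^lx, curve$L, curve$U, curve$ec50,
                           curve$h, curve$s))
    pmax(pmin(i, 100) - t, 0)
  }
  w <- diff(dose_window)
  int <- integrate(f, dose_window[1], dose_window[2],
                   subdivisions = 500L, rel.tol = 1e-8, abs.tol = 1e-10)
  dss <- 100 * int$value / ((100 - t) * w)
  structure(list(dss = min(max(dss, 0), 100), threshold = t,
                 dose_window = dose_window),
            class = "dss_result")
}

#' Fit curves and score every line-drug series of a normalized plate table
#'
#' Convenience wrapper running [fit_curve()] and [compute_dss()] per
#' (line, drug) group of a [normalize_signals()] output.
#'
#' @param norm normalized long table (columns `line`, `drug`, `dose_nM`,
#'   `viability`).
#' @param t DSS activity threshold (percent inhibition).
#' @param dose_window optional fixed log10-nM window for cross-drug
#'   comparability; default is each series' tested range.
#' @return data.frame with one row per (line, drug): curve parameters,
#'   convergence flag and `dss`.
#' @export
dss_table <- function(norm, t = 10, dose_window = NULL) {
  groups <- split(norm, list(norm$line, norm$drug), drop = TRUE)
  rows <- lapply(groups, function(g) {
    cv <- fit_curve(g)
    win <- dose_window %||% log10(range(g$dose_nM))
    d <- compute_dss(cv, win, t = t)
    data.frame(line = g$line[1], drug = g$drug[1],
               L = cv$L, U = cv$U, ec50 = cv$ec50, h = cv$h, s = cv$s,
               rss = cv$rss, converged = cv$converged, dss = d$dss)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
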