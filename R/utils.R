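#' @keywords internal
"_PACKAGE"

#' @importFrom stats median mad sd cor cor.test wilcox.test rnorm rlnorm rpois
#'   runif integrate setNames complete.cases quantile
#' @importFrom utils write.csv read.csv head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed
#'
#' All generators draw from named substreams derived from one base seed, so
#' that adding a new table to the cohort never perturbs the draws of another.
#' The derived seed is a deterministic hash of the base seed and the stream
#' name, kept below 2^31.
#'
#' @param seed integer base seed.
#' @param name character stream name.
#' @return an integer seed.
#' @keywords internal
substream_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483629L
  as.integer((as.numeric(seed) %% 2147483629 * 7919 + h) %% 2147483629)
}

# evaluate expr under a local RNG state seeded from (seed, name); the caller's
# .Random.seed is restored afterwards
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}

# log-normal multiplicative noise with unit mean and given coefficient of
# variation (cv = 0 returns exact ones)
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

stop_if_not <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)

# Otsu threshold of a numeric vector (maximizes between-class variance over a
# histogram of the values); used for per-cell intensity classification
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) return(NA_real_)
  br <- seq(r[1], r[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, br, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}
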