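as_norm_matrix <- function(img) {
  m <- if (inherits(img, "Image")) EBImage::imageData(img) else as.matrix(img)
  storage.mode(m) <- "double"
  m
}

rescale01 <- function(m) {
  r <- range(m)
  if (diff(r) == 0) return(m * 0)
  (m - r[1]) / diff(r)
}

relabel <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (length(u) == 0) return(lab)
  map <- integer(max(u)); map[u] <- seq_along(u)
  lab[lab > 0] <- map[lab[lab > 0]]
  lab
}

#' Segment nuclei from the Hoechst channel
#'
#' Gaussian smoothing, global Otsu threshold, hole filling, then watershed on
#' the distance transform to split touching nuclei; objects below `min_area`
#' pixels are discarded. Fully deterministic.
#'
#' @param nuclei_channel numeric matrix (or EBImage Image) of the nuclear
#'   stain.
#' @param sigma Gaussian smoothing sigma in pixels.
#' @param min_area minimum object area in pixels.
#' @return integer label matrix (0 = background); an empty or flat channel
#'   yields zero labels without error.
#' @export
segment_nuclei <- function(nuclei_channel, sigma = 2, min_area = 30) {
  m <- as_norm_matrix(nuclei_channel)
  lab0 <- matrix(0L, nrow(m), ncol(m))
  if (diff(range(m)) == 0) return(lab0)
  sm <- EBImage::gblur(EBImage::Image(rescale01(m)), sigma = sigma)
  th <- EBImage::otsu(sm, range = c(0, 1))
  mask <- EBImage::fillHull(sm > th)
  if (sum(mask) == 0) return(lab0)
  dm <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  lab <- as_norm_matrix(lab)
  areas <- tabulate(lab[lab > 0])
  small <- which(areas > 0 & areas < min_area)
  if (length(small)) lab[lab %in% small] <- 0
  relabel(matrix(as.integer(lab), nrow(m), ncol(m)))
}

#' Segment cells from the cell-mask channel, seeded by nuclei
#'
#' Voronoi-style watershed propagation of the nucleus seeds over the
#' cell-mask intensity, restricted to the Otsu foreground — one cell per
#' nucleus, each cell containing its seed.
#'
#' @param cellmask_channel numeric matrix of the whole-cell stain.
#' @param nucleus_labels label matrix from [segment_nuclei()].
#' @param sigma Gaussian smoothing sigma.
#' @return integer cell label matrix with labels matching the nuclei.
#' @export
segment_cells <- function(cellmask_channel, nucleus_labels, sigma = 2) {
  m <- as_norm_matrix(cellmask_channel)
  if (max(nucleus_labels) == 0 || diff(range(m)) == 0)
    return(matrix(0L, nrow(m), ncol(m)))
  sm <- EBImage::gblur(EBImage::Image(rescale01(m)), sigma = sigma)
  th <- EBImage::otsu(sm, range = c(0, 1))
  fg <- (sm > th) | (nucleus_labels > 0)
  cells <- EBImage::propagate(sm, seeds = EBImage::Image(nucleus_labels),
                              mask = fg)
  matrix(as.integer(as_norm_matrix(cells)), nrow(m), ncol(m))
}

log_kernel <- function(sigma) {
  n <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  c0 <- (n + 1) / 2
  d2 <- outer(seq_len(n), seq_len(n),
              function(i, j) (i - c0)^2 + (j - c0)^2)
  k <- (d2 - 2 * sigma^2) / sigma^4 * exp(-d2 / (2 * sigma^2))
  k - mean(k)
}

# 3x3 grayscale maximum filter (border pixels compared to available
# neighbours only)
max_filter3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  out <- matrix(-Inf, nr, nc)
  for (di in 0:2) for (dj in 0:2)
    out <- pmax(out, pad[(1 + di):(nr + di), (1 + dj):(nc + dj)])
  out
}

#' Detect lysosomal puncta in the lysosome channel
#'
#' Laplacian-of-Gaussian blob response at the configured spot scale, local
#' maxima, and an amplitude threshold of `k` times the robust (MAD-based)
#' background SD of the response. The threshold is relative to the image's
#' own background, so a global multiplicative intensity change does not alter
#' the detected count. Each punctum is assigned to the cell label at its
#' coordinate; puncta falling on background are dropped when `cell_labels`
#' is given.
#'
#' @param lyso_channel numeric matrix of the lysosomal stain.
#' @param cell_labels optional cell label matrix.
#' @param sigma spot scale in pixels (default 1.5, matched to the synthetic
#'   renderer).
#' @param k amplitude threshold multiplier (default 5).
#' @return list with `coords` (data.frame `x`, `y`, `cell`), `n_foci`, and
#'   `per_cell` (named counts per cell label) when labels are supplied.
#' @export
detect_foci <- function(lyso_channel, cell_labels = NULL, sigma = 1.5, k = 5) {
  m <- as_norm_matrix(lyso_channel)
  empty <- list(coords = data.frame(x = integer(), y = integer(),
                                    cell = integer()),
                n_foci = 0L, per_cell = NULL)
  if (diff(range(m)) == 0) return(empty)
  resp <- as_norm_matrix(
    EBImage::filter2(EBImage::Image(m), -log_kernel(sigma)))
  bg_sd <- mad(resp)
  if (bg_sd == 0) bg_sd <- sd(resp)
  peaks <- which(resp >= max_filter3(resp) & resp > k * bg_sd, arr.ind = TRUE)
  coords <- data.frame(x = peaks[, 1], y = peaks[, 2])
  if (!is.null(cell_labels)) {
    coords$cell <- cell_labels[peaks]
    coords <- coords[coords$cell > 0, , drop = FALSE]
    n_cells <- max(cell_labels)
    per_cell <- tabulate(coords$cell, nbins = n_cells)
    names(per_cell) <- seq_len(n_cells)
  } else {
    coords$cell <- NA_integer_
    per_cell <- NULL
  }
  rownames(coords) <- NULL
  list(coords = coords, n_foci = nrow(coords), per_cell = per_cell)
}

#' Quantify one multi-channel image
#'
#' Runs nucleus and cell segmentation plus puncta detection and aggregates to
#' the per-image statistic used throughout: `foci_per_cell = n_foci /
#' n_nuclei`.
#'
#' @param channels list with elements `nuclei`, `cellmask`, `lyso` (numeric
#'   matrices).
#' @param sigma_spot,k puncta detection parameters, see [detect_foci()].
#' @return list with `n_nuclei`, `n_cells`, `n_foci`, `foci_per_cell`,
#'   `per_cell_counts`, and the label matrices.
#' @export
quantify_image <- function(channels, sigma_spot = 1.5, k = 5) {
  nuc <- segment_nuclei(channels$nuclei)
  cells <- segment_cells(channels$cellmask, nuc)
  foci <- detect_foci(channels$lyso, cells, sigma = sigma_spot, k = k)
  n_nuclei <- max(nuc)
  list(n_nuclei = n_nuclei, n_cells = max(cells), n_foci = foci$n_foci,
       foci_per_cell = if (n_nuclei > 0) foci$n_foci / n_nuclei else NA_real_,
       per_cell_counts = foci$per_cell,
       nucleus_labels = nuc, cell_labels = cells, foci = foci$coords)
}

#' Combined basal lysosomal score
#'
#' For each plate and stain, the foci-per-cell value of every line is
#' normalized to the reference line on the same plate (correcting plate
#' effects); the per-stain normalized values are then averaged across
#' plates/replicates and the stain means summed into the combined score. The
#' reference line scores 1 per stain, hence `combined = number of stains`
#' (3 for LAMP1/LAMP2/LT).
#'
#' @param foci data.frame with columns `line`, `stain`, `plate` and either
#'   `foci_per_cell` or both `n_foci` and `n_nuclei`.
#' @param reference_line reference line name (default `"GI-M-EN"`).
#' @return data.frame: one row per line, one column per stain (normalized
#'   mean) plus `combined`.
#' @export
basal_lysoscore <- function(foci, reference_line = "GI-M-EN") {
  if (!"foci_per_cell" %in% names(foci))
    foci$foci_per_cell <- foci$n_foci / foci$n_nuclei
  stop_if_not(all(c("line", "stain", "plate") %in% names(foci)),
              "foci table needs columns line, stain, plate")
  parts <- split(foci, list(foci$plate, foci$stain), drop = TRUE)
  norm <- do.call(rbind, lapply(parts, function(g) {
    ref <- g$foci_per_cell[g$line == reference_line]
    if (length(ref) == 0)
      stop("reference line '", reference_line, "' missing on plate '",
           g$plate[1], "' for stain '", g$stain[1], "'", call. = FALSE)
    ref <- mean(ref)
    if (ref == 0)
      stop("reference line has zero foci per cell on plate '", g$plate[1],
           "', stain '", g$stain[1], "'", call. = FALSE)
    data.frame(line = g$line, stain = g$stain,
               value = g$foci_per_cell / ref)
  }))
  stains <- unique(foci$stain)
  lines <- unique(foci$line)
  per_stain <- sapply(stains, function(s) {
    sapply(lines, function(ln)
      mean(norm$value[norm$line == ln & norm$stain == s]))
  })
  per_stain <- matrix(per_stain, nrow = length(lines),
                      dimnames = list(lines, stains))
  out <- data.frame(line = lines, per_stain, combined = rowSums(per_stain),
                    row.names = NULL, check.names = FALSE)
  out
}

#' Lysosomal adaptation score of a treatment series
#'
#' Foci-per-cell at each tested concentration is divided by the DMSO control
#' value; the score sums the differences from 1 over the concentrations
#' (target design: five doses):
#' `score = sum_c (ratio_c - 1)`.
#'
#' @param treated numeric vector of foci-per-cell values at increasing doses
#'   (or a data.frame with a `foci_per_cell` column).
#' @param dmso DMSO-control foci-per-cell (single value > 0).
#' @return list with `score`, `per_dose_ratio`, `n_doses`.
#' @export
adaptation_score <- function(treated, dmso) {
  if (is.data.frame(treated)) treated <- treated$foci_per_cell
  stop_if_not(length(dmso) == 1 && is.finite(dmso),
              "dmso must be a single finite value")
  if (dmso == 0) stop("DMSO control has zero foci per cell", call. = FALSE)
  stop_if_not(length(treated) >= 1, "need at least one treated dose")
  if (length(treated) < 5)
    warning("adaptation score computed over ", length(treated),
            " dose(s); design targets 5")
  ratio <- treated / dmso
  list(score = sum(ratio - 1), per_dose_ratio = ratio,
       n_doses = length(treated))
}

#' Threshold classification of marker-positive cells
#'
#' Mean nuclear marker intensity per segmented nucleus, classified positive
#' above an Otsu threshold of the per-cell intensity distribution (or a fixed
#' threshold). A deterministic replacement for interactive machine-learning
#' nucleus classification; the policy is explicit and reproducible.
#'
#' @param nucleus_labels label matrix from [segment_nuclei()].
#' @param marker_channel numeric matrix of the marker stain.
#' @param threshold optional fixed intensity threshold; default derives one by
#'   Otsu from the per-cell intensities.
#' @return data.frame `cell`, `intensity`, `positive`; attributes `threshold`
#'   and `degenerate` (TRUE when the intensity distribution had no spread, in
#'   which case all cells are classified negative).
#' @export
classify_marker_cells <- function(nucleus_labels, marker_channel,
                                  threshold = NULL) {
  m <- as_norm_matrix(marker_channel)
  n <- max(nucleus_labels)
  stop_if_not(n >= 1, "no nuclei to classify")
  intensity <- vapply(seq_len(n),
                      function(i) mean(m[nucleus_labels == i]), numeric(1))
  degenerate <- FALSE
  if (is.null(threshold)) {
    threshold <- otsu_threshold(intensity)
    if (is.na(threshold)) {
      degenerate <- TRUE
      warning("degenerate marker intensity distribution; all cells one class")
      threshold <- Inf
    }
  }
  out <- data.frame(cell = seq_len(n), intensity = intensity,
                    positive = intensity > threshold)
  attr(out, "threshold") <- threshold
  attr(out, "degenerate") <- degenerate
  out
}

#' Write a multi-channel image to a multi-page TIFF
#'
#' One page per channel, in the order nuclei, cell mask, lysosome (plus any
#' extra channels); values are clipped to \[0, 1\].
#'
#' @param channels named list of numeric matrices.
#' @param path output file.
#' @export
write_image_tiff <- function(channels, path) {
  pages <- lapply(channels, function(m) pmin(pmax(as_norm_matrix(m), 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_image_tiff()]
#'
#' @param path TIFF file.
#' @param channel_names names for the pages (default nuclei/cellmask/lyso).
#' @return named list of numeric matrices.
#' @export
read_image_tiff <- function(path,
                            channel_names = c("nuclei", "cellmask", "lyso")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  names(pages) <- channel_names[seq_along(pages)]
  pages
}
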