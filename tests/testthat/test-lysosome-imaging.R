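small_img <- function(seed = 1, n_cells = 12, rate = 10, noise = 0.02)
  generate_lysosome_image(n_cells, rate, c(256, 256), seed = seed,
                          noise_sd = noise)

test_that("the renderer is deterministic and honors the zero-rate limit", {
  a <- small_img(seed = 5)
  b <- small_img(seed = 5)
  expect_identical(a, b)
  expect_equal(sum(a$truth$n_per_cell), nrow(a$truth$puncta))

  z <- generate_lysosome_image(5, 0, c(128, 128), seed = 1, noise_sd = 0)
  expect_equal(max(z$channels$lyso), 0)
  expect_equal(detect_foci(z$channels$lyso)$n_foci, 0)
})

test_that("placement fails loudly when the image cannot hold the cells", {
  expect_error(generate_lysosome_image(30, 5, c(96, 96), seed = 1),
               "too small")
})

test_that("nucleus segmentation counts match ground truth on clean images", {
  img <- small_img(seed = 9, noise = 0)
  nuc <- segment_nuclei(img$channels$nuclei)
  expect_equal(max(nuc), 12)
  expect_equal(max(segment_nuclei(matrix(0, 64, 64))), 0)
})

test_that("cell segmentation keeps one cell per nucleus with good overlap", {
  img <- small_img(seed = 9, noise = 0)
  nuc <- segment_nuclei(img$channels$nuclei)
  cells <- segment_cells(img$channels$cellmask, nuc)
  expect_equal(max(cells), max(nuc))
  # every cell contains its seed nucleus
  for (i in seq_len(max(nuc)))
    expect_true(all(cells[nuc == i] == i))
  # per-cell Jaccard against the truth masks (labels may be permuted; match
  # cells via the truth label at the nucleus centroid)
  truth_lab <- img$truth$cell_labels
  for (i in seq_len(max(nuc))) {
    tl <- as.integer(names(which.max(table(truth_lab[nuc == i]))))
    inter <- sum(cells == i & truth_lab == tl)
    uni <- sum(cells == i | truth_lab == tl)
    expect_gte(inter / uni, 0.8)
  }
})

test_that("puncta detection is accurate and intensity-scale invariant", {
  img <- small_img(seed = 3, noise = 0)
  nuc <- segment_nuclei(img$channels$nuclei)
  cells <- segment_cells(img$channels$cellmask, nuc)
  foci <- detect_foci(img$channels$lyso, cells)
  m <- match_puncta(img$truth$puncta, foci$coords)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
  # threshold is background-relative: doubling intensity changes nothing
  foci2 <- detect_foci(2 * img$channels$lyso, cells)
  expect_equal(foci2$n_foci, foci$n_foci)
  expect_equal(foci2$coords$x, foci$coords$x)
})

test_that("identical image bytes give identical quantification", {
  img <- small_img(seed = 4)
  q1 <- quantify_image(img$channels)
  q2 <- quantify_image(lapply(img$channels, identity))
  expect_identical(q1[c("n_nuclei", "n_cells", "n_foci", "foci_per_cell")],
                   q2[c("n_nuclei", "n_cells", "n_foci", "foci_per_cell")])
})

test_that("multi-channel TIFF round-trip preserves the channels", {
  img <- generate_lysosome_image(4, 6, c(96, 96), seed = 2, cell_radius = 12)
  p <- withr::local_tempfile(fileext = ".tiff")
  write_image_tiff(img$channels, p)
  back <- read_image_tiff(p)
  expect_equal(names(back), c("nuclei", "cellmask", "lyso"))
  # 16-bit quantization: compare with an absolute bound
  expect_lt(max(abs(back$lyso - pmin(img$channels$lyso, 1))), 2e-4)
})

test_that("basal lysoscore normalizes per plate and sums the stain means", {
  foci <- expand.grid(line = c("GI-M-EN", "X", "Y"),
                      stain = c("LAMP1", "LAMP2", "LT"),
                      plate = c("P1", "P2"), stringsAsFactors = FALSE)
  fpc <- c("GI-M-EN" = 10, X = 20, Y = 5)
  foci$foci_per_cell <- fpc[foci$line]
  ls <- basal_lysoscore(foci)
  expect_equal(ls$combined[ls$line == "GI-M-EN"], 3)  # self-normalization
  expect_equal(ls$combined[ls$line == "X"], 6)        # 2x in all stains
  expect_equal(ls$combined[ls$line == "Y"], 1.5)
  # invariant to a plate-wide multiplicative staining change
  foci2 <- foci
  scale2 <- ifelse(foci2$plate == "P2", 3.7, 1)
  foci2$foci_per_cell <- foci2$foci_per_cell * scale2
  expect_equal(basal_lysoscore(foci2), ls)
  expect_error(basal_lysoscore(foci[foci$line != "GI-M-EN", ]), "GI-M-EN")
})

test_that("adaptation score is the exact sum of ratio differences", {
  r <- adaptation_score(c(1.2, 1.4, 1.6, 1.8, 2.0) * 8, dmso = 8)
  expect_equal(r$score, 3.0)
  expect_equal(adaptation_score(rep(4, 5), dmso = 8)$score, -2.5)
  expect_equal(adaptation_score(rep(6, 5), dmso = 6)$score, 0)
  set.seed(8)
  for (rep in 1:50) {
    ratios <- runif(5, 0.2, 3)
    expect_equal(adaptation_score(ratios * 2, dmso = 2)$score,
                 sum(ratios - 1), tolerance = 1e-12)
  }
  expect_warning(adaptation_score(c(1, 2), dmso = 1), "design targets 5")
  expect_error(adaptation_score(1:5, dmso = 0), "zero")
})

test_that("marker classification splits well-separated populations", {
  img <- small_img(seed = 6, noise = 0)
  nuc <- segment_nuclei(img$channels$nuclei)
  n <- max(nuc)
  truth_pos <- seq_len(n) > n / 2
  marker <- matrix(0, 256, 256)
  set.seed(1)
  for (i in seq_len(n))
    marker[nuc == i] <- rnorm(sum(nuc == i),
                              mean = ifelse(truth_pos[i], 0.9, 0.3),
                              sd = 0.1)
  cls <- classify_marker_cells(nuc, marker)
  expect_lte(mean(cls$positive != truth_pos), 0.02)
  # fixed threshold respected exactly
  cls2 <- classify_marker_cells(nuc, marker, threshold = 0.6)
  expect_equal(cls2$positive, cls2$intensity > 0.6)
  # degenerate distribution flagged, single class
  expect_warning(
    cls3 <- classify_marker_cells(nuc, matrix(0.5, 256, 256)),
    "degenerate")
  expect_true(all(!cls3$positive))
})
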