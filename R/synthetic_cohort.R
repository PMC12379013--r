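#' Configuration for a synthetic screening cohort
#'
#' Bundles every knob of the generator. Defaults encode the statistical
#' structure the analysis assumes: MEK-inhibitor potency increases and
#' chemotherapy potency decreases with the latent mesenchymal score, lysosome
#' puncta rates rise with it, signature genes shift with it, and one
#' mid-spectrum line is designated the plate-normalization reference.
#'
#' @param n_lines number of cell lines (>= 2).
#' @param n_drugs_per_class named integer vector of drugs per class; classes
#'   `MEKi` and `chemo` carry the identity-linked potency structure.
#' @param doses dose grid in nM, strictly increasing (default 5 log-spaced
#'   concentrations, 1 nM to 10 uM).
#' @param noise_cv coefficient of variation of the multiplicative log-normal
#'   viability noise.
#' @param effect_size log2 expression shift of signature genes per unit
#'   mesenchymal score.
#' @param expr_noise_sd SD of the iid expression noise.
#' @param seed base seed; all tables draw from named substreams derived from
#'   it.
#' @param reference_line_name name given to the reference line (the line with
#'   mid-range mesenchymal score and hence mid-range lysosome rate).
#' @param n_signature_genes,n_background_genes gene counts for the expression
#'   generator.
#' @param xeno list of xenograft generator settings (`n_control`, `n_treated`,
#'   `growth_log`, `effect_log_fold`, `sd_log`).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_lines = 20,
                          n_drugs_per_class = c(MEKi = 3, chemo = 3,
                                                other = 2),
                          doses = 10^seq(0, 4, length.out = 5),
                          noise_cv = 0.05,
                          effect_size = 2,
                          expr_noise_sd = 0.5,
                          seed = 1,
                          reference_line_name = "GI-M-EN",
                          n_signature_genes = 10,
                          n_background_genes = 170,
                          xeno = list(n_control = 40, n_treated = 40,
                                      growth_log = 0.22,
                                      effect_log_fold = 0.34,
                                      sd_log = 0.35)) {
  stop_if_not(n_lines >= 2, "invalid config: n_lines must be >= 2")
  stop_if_not(all(doses > 0) && all(diff(doses) > 0),
              "invalid config: doses must be strictly increasing positives")
  stop_if_not(noise_cv >= 0, "invalid config: noise_cv must be >= 0")
  structure(as.list(environment()), class = "cohort_config")
}

# monotone potency structure: MEKi EC50 shrinks with mes score, chemo EC50
# grows; 'other' drugs are identity-neutral
potency_multiplier <- function(class, mes) {
  switch(class,
         MEKi = 10^(1.5 * (0.5 - mes)),
         chemo = 10^(1.0 * (mes - 0.5)),
         1)
}

#' Generate cell-line specifications
#'
#' Latent mesenchymal scores span \[0, 1\] evenly; lysosome puncta rate is an
#' affine increasing function of the score (`4 + 12 * mes`, so the mid-range
#' reference sits near 10 puncta/cell and normalization never divides by a
#' near-zero rate).
#'
#' @param config a [cohort_config()].
#' @return data.frame: `name`, `mes_score_true`, `mycn_amplified`,
#'   `lyso_rate`, `is_reference`.
#' @export
generate_line_specs <- function(config) {
  n <- config$n_lines
  mes <- seq(0, 1, length.out = n)
  name <- sprintf("NB-%02d", seq_len(n))
  ref <- which.min(abs(mes - 0.5))
  name[ref] <- config$reference_line_name
  mycn <- with_substream(config$seed, "mycn", runif(n) < 0.3)
  data.frame(name = name, mes_score_true = mes, mycn_amplified = mycn,
             lyso_rate = 4 + 12 * mes, is_reference = seq_len(n) == ref,
             stringsAsFactors = FALSE)
}

generate_drug_specs <- function(config) {
  classes <- rep(names(config$n_drugs_per_class), config$n_drugs_per_class)
  drug <- unlist(lapply(names(config$n_drugs_per_class), function(cl)
    sprintf("%s-%d", cl, seq_len(config$n_drugs_per_class[[cl]]))))
  with_substream(config$seed, "drugs", {
    data.frame(drug = drug, class = classes,
               base_ec50 = 10^runif(length(drug), 1.5, 3),
               L = runif(length(drug), 0.05, 0.3),
               U = 1,
               h = 1,
               s = sample(c(0.7, 1, 1.4), length(drug), replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

#' Generate one viability dose series with solvent controls
#'
#' Values follow the five-parameter logistic truth multiplied by log-normal
#' noise of the given CV (unit mean); solvent controls have mean 1 before
#' noise.
#'
#' @param doses positive increasing dose grid (nM).
#' @param params list/row with `L`, `U`, `ec50`, `h`, `s`.
#' @param noise_cv log-normal noise CV (0 = exactly on the curve).
#' @param seed substream seed.
#' @param n_replicates replicate wells per dose.
#' @param n_controls number of solvent-control wells.
#' @return data.frame `dose_nM`, `replicate`, `viability`; attribute
#'   `controls` holds the control viabilities.
#' @export
generate_viability_series <- function(doses, params, noise_cv = 0, seed = 1,
                                      n_replicates = 1, n_controls = 8) {
  stop_if_not(all(doses > 0) && all(diff(doses) > 0),
              "doses must be positive and increasing")
  with_substream(seed, "series", {
    truth <- fivepl(doses, params$L, params$U, params$ec50, params$h,
                    params$s)
    out <- data.frame(
      dose_nM = rep(doses, each = n_replicates),
      replicate = rep(seq_len(n_replicates), times = length(doses)),
      viability = rep(truth, each = n_replicates) *
        rlnorm_cv(length(doses) * n_replicates, noise_cv))
    attr(out, "controls") <- rlnorm_cv(n_controls, noise_cv)
    out
  })
}

#' Generate signature-structured log2 expression
#'
#' Background genes are iid noise around per-gene baselines; signature genes
#' (mesenchymal super-enhancer targets, MAPK activity targets, SASP) have
#' their means shifted by `effect_size * mes_score_true` (scaled 1 / 0.8 /
#' 0.6 for MES / MPAS / SASP respectively, keeping all three identity-linked
#' but distinguishable).
#'
#' @param specs line specs (needs `name`, `mes_score_true`).
#' @param gene_sets named list with disjoint elements `MES`, `MPAS`, `SASP`,
#'   or `NULL` to auto-generate.
#' @param effect_size shift per unit mesenchymal score (log2 units).
#' @param noise_sd iid noise SD.
#' @param seed substream seed.
#' @param n_signature,n_background gene counts when auto-generating sets.
#' @return list with `expr` (genes x lines matrix) and `gene_sets`.
#' @export
generate_expression <- function(specs, gene_sets = NULL, effect_size = 2,
                                noise_sd = 0.5, seed = 1, n_signature = 10,
                                n_background = 170) {
  if (is.null(gene_sets))
    gene_sets <- list(MES = sprintf("MES_%03d", seq_len(n_signature)),
                      MPAS = sprintf("MPAS_%03d", seq_len(n_signature)),
                      SASP = sprintf("SASP_%03d", seq_len(n_signature)))
  sig_genes <- unlist(gene_sets, use.names = FALSE)
  stop_if_not(!anyDuplicated(sig_genes),
              "signature gene sets must be disjoint")
  bg <- setdiff(sprintf("BG_%04d", seq_len(n_background + length(sig_genes))),
                sig_genes)[seq_len(n_background)]
  genes <- c(sig_genes, bg)
  scale <- c(MES = 1, MPAS = 0.8, SASP = 0.6)
  with_substream(seed, "expression", {
    base <- rnorm(length(genes), mean = 7, sd = 1)
    names(base) <- genes
    mu <- matrix(base, nrow = length(genes), ncol = nrow(specs),
                 dimnames = list(genes, specs$name))
    for (set in names(gene_sets)) {
      sc <- if (set %in% names(scale)) scale[[set]] else 1
      mu[gene_sets[[set]], ] <- mu[gene_sets[[set]], , drop = FALSE] +
        rep(sc * effect_size * specs$mes_score_true,
            each = length(gene_sets[[set]]))
    }
    expr <- mu + matrix(rnorm(length(mu), sd = noise_sd), nrow = nrow(mu))
    list(expr = expr, gene_sets = gene_sets)
  })
}

#' Render a synthetic multi-channel lysosome image with ground truth
#'
#' Cells are non-overlapping disks placed by rejection sampling; each cell
#' carries a Poisson(`puncta_rate`) number of lysosomal puncta rendered as
#' isotropic Gaussian spots (sigma `spot_sigma`) inside the cell mask, with a
#' minimum separation so distinct puncta stay resolvable; additive Gaussian
#' background noise on every channel.
#'
#' @param n_cells number of cells to place.
#' @param puncta_rate expected puncta per cell (>= 0).
#' @param image_size integer length-2 (rows, cols).
#' @param seed substream seed.
#' @param cell_radius,nucleus_radius disk radii in px.
#' @param spot_sigma puncta Gaussian sigma in px.
#' @param noise_sd additive background noise SD (0 = noiseless).
#' @param spot_amp_mult puncta amplitude as a multiple of `noise_sd` (when
#'   `noise_sd` is 0 the reference SD 0.02 is used so the render is not
#'   degenerate).
#' @return list with `channels` (`nuclei`, `cellmask`, `lyso`) and `truth`
#'   (`centers`, `cell_labels`, `puncta`, `n_per_cell`).
#' @export
generate_lysosome_image <- function(n_cells, puncta_rate,
                                    image_size = c(512, 512), seed = 1,
                                    cell_radius = 20, nucleus_radius = 7,
                                    spot_sigma = 1.5, noise_sd = 0.02,
                                    spot_amp_mult = 6) {
  stop_if_not(puncta_rate >= 0, "puncta_rate must be >= 0")
  nr <- image_size[1]; nc <- image_size[2]
  amp <- spot_amp_mult * if (noise_sd > 0) noise_sd else 0.02
  with_substream(seed, "image", {
    # rejection placement of non-overlapping cells
    centers <- matrix(NA_real_, n_cells, 2)
    min_sep <- 2 * cell_radius + 2
    for (i in seq_len(n_cells)) {
      placed <- FALSE
      for (try in seq_len(2000)) {
        p <- c(runif(1, cell_radius + 1, nr - cell_radius),
               runif(1, cell_radius + 1, nc - cell_radius))
        if (i == 1 || all(sqrt(colSums((t(centers[seq_len(i - 1), ,
                                                  drop = FALSE]) - p)^2)) >=
                          min_sep)) {
          centers[i, ] <- p; placed <- TRUE; break
        }
      }
      if (!placed)
        stop("image too small to place ", n_cells,
             " non-overlapping cells", call. = FALSE)
    }

    nuclei <- matrix(0, nr, nc)
    cellmask <- matrix(0, nr, nc)
    lyso <- matrix(0, nr, nc)
    labels <- matrix(0L, nr, nc)
    add_disk <- function(ch, cx, cy, r, val) {
      xi <- max(1, floor(cx - r)):min(nr, ceiling(cx + r))
      yi <- max(1, floor(cy - r)):min(nc, ceiling(cy + r))
      d2 <- outer((xi - cx)^2, (yi - cy)^2, `+`)
      ch[xi, yi][d2 <= r^2] <- val
      ch
    }

    puncta <- list()
    n_per_cell <- integer(n_cells)
    for (i in seq_len(n_cells)) {
      cx <- centers[i, 1]; cy <- centers[i, 2]
      nuclei <- add_disk(nuclei, cx, cy, nucleus_radius, 1)
      cellmask <- add_disk(cellmask, cx, cy, cell_radius, 0.7)
      labels <- add_disk(labels, cx, cy, cell_radius, i)
      n_p <- rpois(1, puncta_rate)
      n_per_cell[i] <- n_p
      if (n_p == 0) next
      pts <- matrix(NA_real_, n_p, 2)
      for (pidx in seq_len(n_p)) {
        for (try in seq_len(200)) {
          ang <- runif(1, 0, 2 * pi)
          rad <- sqrt(runif(1)) * (cell_radius - 3)
          q <- c(cx + rad * cos(ang), cy + rad * sin(ang))
          if (pidx == 1 ||
              all(sqrt(colSums((t(pts[seq_len(pidx - 1), ,
                                      drop = FALSE]) - q)^2)) >= 4)) break
        }
        pts[pidx, ] <- q
        xi <- max(1, floor(q[1] - 5)):min(nr, ceiling(q[1] + 5))
        yi <- max(1, floor(q[2] - 5)):min(nc, ceiling(q[2] + 5))
        d2 <- outer((xi - q[1])^2, (yi - q[2])^2, `+`)
        lyso[xi, yi] <- lyso[xi, yi] + amp * exp(-d2 / (2 * spot_sigma^2))
      }
      puncta[[i]] <- data.frame(cell = i, x = pts[, 1], y = pts[, 2])
    }
    puncta <- if (length(puncta)) do.call(rbind, puncta)
              else data.frame(cell = integer(), x = numeric(), y = numeric())

    if (noise_sd > 0) {
      nuclei <- nuclei + matrix(rnorm(nr * nc, sd = noise_sd), nr, nc)
      cellmask <- cellmask + matrix(rnorm(nr * nc, sd = noise_sd), nr, nc)
      lyso <- lyso + matrix(rnorm(nr * nc, sd = noise_sd), nr, nc)
    }
    list(channels = list(nuclei = pmax(nuclei, 0),
                         cellmask = pmax(cellmask, 0),
                         lyso = pmax(lyso, 0)),
         truth = list(centers = data.frame(cell = seq_len(n_cells),
                                           x = centers[, 1],
                                           y = centers[, 2]),
                      cell_labels = labels, puncta = puncta,
                      n_per_cell = n_per_cell))
  })
}

#' Generate a combination-response surface with known interaction
#'
#' Monotherapy inhibitions follow the two supplied logistic curves; interior
#' wells follow the Bliss/ZIP expectation `y1 + y2 - y1 y2` plus the
#' ground-truth interaction `delta_profile(x1, x2)`, clipped to \[0, 1\] and
#' multiplied by log-normal noise. Monotherapy edges always have delta 0.
#'
#' @param curve1,curve2 parameter lists (`L`, `U`, `ec50`, `h`, `s`) of the
#'   two monotherapy viability curves.
#' @param delta_profile scalar or `function(x1, x2)` returning the
#'   interaction term in \[-1, 1\].
#' @param doses1,doses2 positive increasing dose grids.
#' @param noise_cv multiplicative noise CV.
#' @param seed substream seed.
#' @param drug1,drug2 labels.
#' @return a `combination_surface` (see [combination_surface()]) with
#'   attribute `truth_delta` (interior delta matrix before clipping/noise).
#' @export
generate_combination_surface <- function(curve1, curve2, delta_profile = 0,
                                         doses1, doses2, noise_cv = 0,
                                         seed = 1, drug1 = "drug1",
                                         drug2 = "drug2") {
  dp <- if (is.function(delta_profile)) delta_profile
        else function(x1, x2) delta_profile
  y1 <- 1 - fivepl(doses1, curve1$L, curve1$U, curve1$ec50, curve1$h,
                   curve1$s %||% 1)
  y2 <- 1 - fivepl(doses2, curve2$L, curve2$U, curve2$ec50, curve2$h,
                   curve2$s %||% 1)
  y1 <- pmin(pmax(y1, 0), 1); y2 <- pmin(pmax(y2, 0), 1)
  K1 <- length(doses1); K2 <- length(doses2)
  delta <- outer(seq_len(K1), seq_len(K2),
                 Vectorize(function(i, j) dp(doses1[i], doses2[j])))
  stop_if_not(all(abs(delta) <= 1), "delta_profile must lie in [-1, 1]")
  inh <- matrix(0, K1 + 1, K2 + 1)
  inh[-1, 1] <- y1
  inh[1, -1] <- y2
  inh[-1, -1] <- pmin(pmax(outer(y1, y2, function(a, b) a + b - a * b) +
                             delta, 0), 1)
  noisy <- with_substream(seed, "combo", {
    n <- inh * matrix(rlnorm_cv(length(inh), noise_cv), nrow(inh))
    pmin(pmax(n, 0), 1)
  })
  noisy[1, 1] <- 0
  surf <- combination_surface(doses1, doses2, noisy, drug1 = drug1,
                              drug2 = drug2)
  attr(surf, "truth_delta") <- delta
  surf
}

#' Generate xenograft tumor-volume records
#'
#' Baseline (24 hpi) volumes are log-normal; the 24-to-72 hpi log volume
#' ratio is Normal(`growth_log - group * effect_log_fold`, `sd_log`), so
#' volumes stay positive by construction.
#'
#' @param n_control,n_treated embryos per arm.
#' @param effect_log_fold treatment effect on the log volume ratio.
#' @param sd_log SD of the log volume ratio.
#' @param seed substream seed.
#' @param growth_log mean log growth of untreated tumors.
#' @return data.frame `embryo`, `group`, `v24`, `v72`.
#' @export
generate_xenograft_volumes <- function(n_control, n_treated,
                                       effect_log_fold, sd_log, seed = 1,
                                       growth_log = 0.22) {
  with_substream(seed, "xeno", {
    n <- n_control + n_treated
    group <- rep(c("control", "treated"), c(n_control, n_treated))
    v24 <- rlnorm(n, meanlog = log(100), sdlog = 0.3)
    lr <- rnorm(n, mean = growth_log - (group == "treated") * effect_log_fold,
                sd = sd_log)
    data.frame(embryo = sprintf("E%03d", seq_len(n)), group = group,
               v24 = v24, v72 = v24 * exp(lr), stringsAsFactors = FALSE)
  })
}

#' Generate a full synthetic cohort with ground truth
#'
#' Invokes every sub-generator consistently from one base seed: line specs,
#' plate-format viability tables, signature-structured expression, per-plate
#' lysosome foci-count tables, combination surfaces (interaction strength
#' increasing with mesenchymal score), and xenograft volumes. The `truth`
#' element records every generating parameter, sufficient to recompute all
#' expectations.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stop_if_not(inherits(config, "cohort_config"),
              "config must be built with cohort_config()")
  specs <- generate_line_specs(config)
  drugs <- generate_drug_specs(config)
  scale <- 1e5

  # plate-format viability: one plate per line, all drugs + controls
  curve_truth <- list(); plates <- list()
  for (i in seq_len(nrow(specs))) {
    ln <- specs$name[i]
    rows <- list(); well <- 1L
    ctrl_v <- with_substream(config$seed, paste0("controls:", ln),
                            rlnorm_cv(8, config$noise_cv))
    rows[[1]] <- data.frame(plate = ln, well = sprintf("C%02d", 1:8),
                            line = NA, drug = NA, dose_nM = NA,
                            signal = scale * ctrl_v, is_control = TRUE)
    for (k in seq_len(nrow(drugs))) {
      p <- drugs[k, ]
      ec50 <- p$base_ec50 * potency_multiplier(p$class,
                                               specs$mes_score_true[i])
      ser <- generate_viability_series(
        config$doses, list(L = p$L, U = p$U, ec50 = ec50, h = p$h, s = p$s),
        noise_cv = config$noise_cv,
        seed = substream_seed(config$seed, paste0("viab:", ln, ":", p$drug)),
        n_controls = 0)
      rows[[k + 1]] <- data.frame(
        plate = ln,
        well = sprintf("W%03d", well - 1L + seq_len(nrow(ser))),
        line = ln, drug = p$drug, dose_nM = ser$dose_nM,
        signal = scale * ser$viability, is_control = FALSE)
      well <- well + nrow(ser)
      curve_truth[[paste(ln, p$drug)]] <-
        data.frame(line = ln, drug = p$drug, class = p$class, L = p$L,
                   U = p$U, ec50 = ec50, h = p$h, s = p$s)
    }
    plates[[i]] <- do.call(rbind, rows)
  }
  viability <- do.call(rbind, plates)
  rownames(viability) <- NULL
  curve_truth <- do.call(rbind, curve_truth)
  rownames(curve_truth) <- NULL

  ex <- generate_expression(specs, effect_size = config$effect_size,
                            noise_sd = config$expr_noise_sd,
                            seed = config$seed,
                            n_signature = config$n_signature_genes,
                            n_background = config$n_background_genes)

  # foci-count tables: two replicate plates, all lines x three stains, with
  # a per-plate staining efficiency removed later by reference normalization
  stain_factor <- c(LAMP1 = 1, LAMP2 = 0.8, LT = 1.2)
  foci <- with_substream(config$seed, "foci", {
    rows <- list()
    for (pl in c("P1", "P2")) {
      plate_eff <- rlnorm_cv(3, 0.1)
      names(plate_eff) <- names(stain_factor)
      for (st in names(stain_factor)) for (i in seq_len(nrow(specs))) {
        n_nuc <- rpois(1, 200)
        rate <- specs$lyso_rate[i] * stain_factor[[st]] * plate_eff[[st]]
        rows[[length(rows) + 1]] <- data.frame(
          plate = pl, stain = st, line = specs$name[i], n_nuclei = n_nuc,
          n_foci = rpois(1, n_nuc * rate))
      }
    }
    do.call(rbind, rows)
  })
  foci$foci_per_cell <- foci$n_foci / foci$n_nuclei

  # one combination surface per line: first MEKi + a BCL2-family senolytic,
  # interaction strength growing with the mesenchymal score
  meki <- drugs[drugs$class == "MEKi", ][1, ]
  seno <- list(L = 0.15, U = 1, ec50 = 1000, h = 1, s = 1)
  surfaces <- lapply(seq_len(nrow(specs)), function(i) {
    ec50 <- meki$base_ec50 * potency_multiplier("MEKi",
                                                specs$mes_score_true[i])
    generate_combination_surface(
      curve1 = list(L = meki$L, U = 1, ec50 = ec50, h = 1, s = 1),
      curve2 = seno,
      delta_profile = 0.15 * specs$mes_score_true[i],
      doses1 = config$doses, doses2 = config$doses,
      noise_cv = min(config$noise_cv, 0.02),
      seed = substream_seed(config$seed, paste0("combo:", specs$name[i])),
      drug1 = meki$drug, drug2 = "senolytic-1")
  })
  names(surfaces) <- specs$name

  xeno <- generate_xenograft_volumes(
    config$xeno$n_control, config$xeno$n_treated,
    effect_log_fold = config$xeno$effect_log_fold,
    sd_log = config$xeno$sd_log,
    growth_log = config$xeno$growth_log,
    seed = substream_seed(config$seed, "xeno"))

  structure(list(
    config = config,
    specs = specs,
    drugs = drugs,
    viability = viability,
    expression = ex$expr,
    gene_sets = ex$gene_sets,
    foci = foci,
    combination_surfaces = surfaces,
    xenograft_volumes = xeno,
    truth = list(curves = curve_truth, specs = specs, drugs = drugs,
                 delta_per_line = setNames(0.15 * specs$mes_score_true,
                                           specs$name),
                 xeno = config$xeno)),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic cohort: %d lines x %d drugs, %d genes, %d foci rows, ",
    "%d combination surfaces, %d xenograft embryos (seed %d)\n"),
    nrow(x$specs), nrow(x$drugs), nrow(x$expression), nrow(x$foci),
    length(x$combination_surfaces), nrow(x$xenograft_volumes),
    x$config$seed))
  invisible(x)
}

#' Write a cohort's tables to a directory
#'
#' Emits the standard on-disk forms: long viability CSV, expression TSV
#' (genes as rows), gene sets GMT, foci CSV, combination CSVs, xenograft CSV
#' and a JSON truth record.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$viability, file.path(dir, "viability.csv"),
            row.names = FALSE)
  write.table(data.frame(gene = rownames(cohort$expression),
                         cohort$expression, check.names = FALSE),
              file.path(dir, "expression.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  write.csv(cohort$foci, file.path(dir, "foci.csv"), row.names = FALSE)
  combos <- do.call(rbind, lapply(names(cohort$combination_surfaces),
                                  function(ln) {
    s <- cohort$combination_surfaces[[ln]]
    df <- as.data.frame(s)
    df$line <- ln
    df
  }))
  write.csv(combos, file.path(dir, "combinations.csv"), row.names = FALSE)
  write.csv(cohort$xenograft_volumes, file.path(dir, "xenograft.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(seed = cohort$config$seed,
         specs = cohort$specs,
         drugs = cohort$drugs,
         delta_per_line = as.list(cohort$truth$delta_per_line),
         xeno = cohort$truth$xeno),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
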