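#' Pipeline run configuration
#'
#' Every threshold the analysis uses is a named key with its conventional
#' default: DSS activity threshold 10% inhibition, hit / top-hit quantiles
#' 0.75 / 0.95, ZIP classification boundary 10, CSS high-effect boundary 40,
#' RECIST PR / PD bounds -30 / +20 percent.
#'
#' @param out_dir run directory.
#' @param seed base seed for the simulate stage.
#' @param stages named logical vector of stage toggles.
#' @param thresholds named list of analysis thresholds.
#' @param cohort list of overrides passed to [cohort_config()].
#' @param resume if `TRUE`, stages whose outputs already exist are skipped.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1,
                            stages = c(simulate = TRUE, dss = TRUE,
                                       cobra = TRUE, signatures = TRUE,
                                       lyso = TRUE, synergy = TRUE,
                                       xeno = TRUE, report = TRUE),
                            thresholds = list(dss_t = 10, hit_q = 0.75,
                                              top_q = 0.95, zip = 10,
                                              css = 40, recist_pr = -30,
                                              recist_pd = 20),
                            cohort = list(),
                            resume = FALSE) {
  defaults <- list(dss_t = 10, hit_q = 0.75, top_q = 0.95, zip = 10,
                   css = 40, recist_pr = -30, recist_pd = 20)
  thresholds <- modifyList(defaults, thresholds)
  stop_if_not(thresholds$hit_q > 0 && thresholds$hit_q < 1 &&
              thresholds$top_q > 0 && thresholds$top_q < 1,
              "hit quantiles must lie in (0, 1)")
  stop_if_not(thresholds$recist_pr < 0 && thresholds$recist_pd > 0,
              "RECIST PR bound must be negative, PD bound positive")
  structure(list(out_dir = out_dir, seed = seed, stages = stages,
                 thresholds = thresholds, cohort = cohort, resume = resume),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file with any subset of the [pipeline_config()] fields.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    out_dir = y$out_dir %||% dirname(path),
    seed = y$seed %||% 1,
    stages = if (is.null(y$stages)) formals(pipeline_config)$stages |> eval()
             else unlist(y$stages),
    thresholds = y$thresholds %||% list(),
    cohort = y$cohort %||% list(),
    resume = isTRUE(y$resume))
}

# rebuild combination_surface objects from the long combinations.csv form
surfaces_from_df <- function(df) {
  lapply(split(df, df$line), function(g) {
    d1 <- sort(unique(g$dose1_nM[g$dose1_nM > 0]))
    d2 <- sort(unique(g$dose2_nM[g$dose2_nM > 0]))
    inh <- matrix(NA_real_, length(d1) + 1, length(d2) + 1)
    msk <- matrix("missing", length(d1) + 1, length(d2) + 1)
    i <- match(g$dose1_nM, c(0, d1))
    j <- match(g$dose2_nM, c(0, d2))
    inh[cbind(i, j)] <- g$inhibition
    msk[cbind(i, j)] <- g$mask
    combination_surface(d1, d2, inh, msk, drug1 = g$drug1[1],
                        drug2 = g$drug2[1])
  })
}

need_file <- function(dir, file, stage, producer) {
  p <- file.path(dir, file)
  if (!file.exists(p))
    stop("stage '", stage, "' is missing its input '", file,
         "' (produced by stage '", producer, "')", call. = FALSE)
  p
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order (simulate, dss, cobra,
#' signatures, lyso, synergy, xeno, report), writing each stage's tables into
#' the run directory plus a manifest recording the seed, configuration,
#' package version, warning count and an MD5 checksum of every produced
#' file. Re-running with an identical configuration reproduces identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the stage outputs and the manifest.
#' @export
run_pipeline <- function(config) {
  stop_if_not(inherits(config, "pipeline_config"),
              "config must come from pipeline_config()")
  dir <- config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  on_stage <- function(nm) isTRUE(config$stages[[nm]])
  done <- function(f) config$resume && file.exists(file.path(dir, f))
  n_warnings <- 0L
  catch_warn <- function(expr) withCallingHandlers(expr, warning = function(w) {
    n_warnings <<- n_warnings + 1L
    invokeRestart("muffleWarning")
  })
  out <- list()

  if (on_stage("simulate") && !done("viability.csv")) {
    cc <- do.call(cohort_config, modifyList(list(seed = config$seed),
                                            config$cohort))
    cohort <- catch_warn(generate_cohort(cc))
    write_cohort(cohort, dir)
    meta <- data.frame(line = cohort$specs$name,
                       mes_score = cohort$specs$mes_score_true,
                       group = ifelse(cohort$specs$mes_score_true >= 0.5,
                                      "mes", "adr"),
                       mycn = cohort$specs$mycn_amplified)
    write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
    out$cohort <- cohort
  }

  if (on_stage("dss") && !done("dss.csv")) {
    viab <- read.csv(need_file(dir, "viability.csv", "dss", "simulate"))
    norm <- catch_warn(normalize_signals(viab))
    dss <- catch_warn(dss_table(norm, t = th$dss_t))
    write.csv(dss, file.path(dir, "dss.csv"), row.names = FALSE)
    out$dss <- dss
  }

  if (on_stage("cobra") && !done("hits.csv")) {
    dss <- read.csv(need_file(dir, "dss.csv", "cobra", "dss"))
    mat <- tapply(dss$dss, list(dss$line, dss$drug), mean)
    hits <- call_hits(mat, hit_q = th$hit_q, top_q = th$top_q)
    write.csv(hits, file.path(dir, "hits.csv"), row.names = FALSE)
    z <- zscore_matrix(mat)
    write.table(data.frame(line = rownames(z), z, check.names = FALSE),
                file.path(dir, "zscores.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    out$hits <- hits
  }

  if (on_stage("signatures") && !done("scores.csv")) {
    ep <- need_file(dir, "expression.tsv", "signatures", "simulate")
    expr_df <- read.delim(ep, check.names = FALSE)
    expr <- as.matrix(expr_df[, -1])
    rownames(expr) <- expr_df$gene
    sets <- read_gmt(need_file(dir, "gene_sets.gmt", "signatures",
                               "simulate"))
    scores <- catch_warn(score_gene_sets(expr, sets))
    mes <- mes_adr_score(expr, sets$MES)
    mp <- catch_warn(mpas(expr, sets$MPAS))
    scores <- rbind(scores,
                    data.frame(sample = names(mes), set = "mes_adr",
                               es = unname(mes), normalized = unname(mes)),
                    data.frame(sample = names(mp), set = "MPAS_zsum",
                               es = unname(mp), normalized = NA_real_))
    write.csv(scores, file.path(dir, "scores.csv"), row.names = FALSE)
    out$scores <- scores
  }

  if (on_stage("lyso") && !done("lysoscore.csv")) {
    foci <- read.csv(need_file(dir, "foci.csv", "lyso", "simulate"))
    ref <- if (length(config$cohort$reference_line_name))
      config$cohort$reference_line_name else "GI-M-EN"
    ls <- catch_warn(basal_lysoscore(foci, reference_line = ref))
    write.csv(ls, file.path(dir, "lysoscore.csv"), row.names = FALSE)
    out$lysoscore <- ls
  }

  if (on_stage("synergy") && !done("synergy.csv")) {
    comb <- read.csv(need_file(dir, "combinations.csv", "synergy",
                               "simulate"))
    surfaces <- surfaces_from_df(comb)
    rows <- lapply(names(surfaces), function(ln) {
      s <- surfaces[[ln]]
      if (any(is.na(s$inhibition[-1, -1]))) s <- impute_diagonal_design(s)
      z <- zip_delta_matrix(s, threshold = th$zip)
      cs <- catch_warn(css(s, high_threshold = th$css))
      data.frame(line = ln, drug1 = s$drug1, drug2 = s$drug2,
                 mean_zip = z$mean_zip, zip_class = z$classification,
                 css = cs$css, effect_class = cs$effect_class)
    })
    syn <- do.call(rbind, rows)
    write.csv(syn, file.path(dir, "synergy.csv"), row.names = FALSE)
    out$synergy <- syn
  }

  if (on_stage("xeno") && !done("xeno_calls.csv")) {
    vol <- read.csv(need_file(dir, "xenograft.csv", "xeno", "simulate"))
    calls <- classify_response(vol, pr_bound = th$recist_pr,
                               pd_bound = th$recist_pd)
    write.csv(calls, file.path(dir, "xeno_calls.csv"), row.names = FALSE)
    rates <- response_rates(calls)
    mw <- compare_volume_change(calls[calls$group == "control", ],
                                calls[calls$group == "treated", ])
    write.csv(rates, file.path(dir, "xeno_rates.csv"), row.names = FALSE)
    out$xeno <- list(calls = calls, rates = rates, test = mw)
  }

  if (on_stage("report") && !done("report.md")) {
    lines <- c("# Screening pipeline report", "")
    hp <- file.path(dir, "hits.csv")
    if (file.exists(hp)) {
      hits <- read.csv(hp)
      called <- hits[!is.na(hits$call) & hits$call != "none", ]
      lines <- c(lines, sprintf("## Hits (%d)", nrow(called)), "",
                 "line | drug | q | call", "--- | --- | --- | ---",
                 sprintf("%s | %s | %.3f | %s", called$line, called$drug,
                         called$q, called$call), "")
    }
    sp <- file.path(dir, "synergy.csv")
    if (file.exists(sp)) {
      syn <- read.csv(sp)
      lines <- c(lines, "## Combination screen", "",
                 sprintf("mean ZIP %.2f, mean CSS %.1f over %d surfaces",
                         mean(syn$mean_zip), mean(syn$css), nrow(syn)), "")
    }
    xp <- file.path(dir, "xeno_rates.csv")
    if (file.exists(xp)) {
      rates <- read.csv(xp)
      lines <- c(lines, "## Xenograft response", "",
                 sprintf("%s: %d/%d PR (%.1f%%)", rates$group, rates$n_PR,
                         rates$n, rates$PR_pct), "")
    }
    writeLines(lines, file.path(dir, "report.md"))
  }

  files <- sort(setdiff(list.files(dir), "manifest.json"))
  manifest <- list(
    package = "senoscreen",
    version = as.character(utils::packageVersion("senoscreen")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    thresholds = th,
    stages = as.list(config$stages),
    n_warnings = n_warnings,
    files = as.list(tools::md5sum(file.path(dir, files))) |>
      setNames(files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}
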