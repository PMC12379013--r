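test_that("identical config and seed give a bitwise-identical cohort", {
  cfg <- cohort_config(n_lines = 5, seed = 3,
                       n_drugs_per_class = c(MEKi = 1, chemo = 1))
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- cohort_config(n_lines = 5, seed = 4,
                        n_drugs_per_class = c(MEKi = 1, chemo = 1))
  expect_false(identical(generate_cohort(cfg)$viability,
                         generate_cohort(cfg2)$viability))
})

test_that("configuration validation rejects degenerate cohorts", {
  expect_error(cohort_config(n_lines = 1), "n_lines")
  expect_error(cohort_config(doses = c(10, 5, 100)), "increasing")
  expect_error(cohort_config(noise_cv = -0.1), "noise_cv")
})

test_that("the zero-noise limit sits exactly on the generating curves", {
  params <- list(L = 0.2, U = 1, ec50 = 100, h = 1, s = 1)
  doses <- 10^seq(0, 6, length.out = 9)
  ser <- generate_viability_series(doses, params, noise_cv = 0, seed = 1)
  expect_equal(ser$viability, fivepl(doses, 0.2, 1, 100, 1, 1))
  # far asymptote: viability approaches L as dose grows
  expect_equal(ser$viability[9], 0.2, tolerance = 1e-3)
  # symmetric curve passes through (U + L) / 2 at its EC50
  mid <- generate_viability_series(c(10, 50, 100, 500, 1000), params,
                                   noise_cv = 0, seed = 1)
  expect_equal(mid$viability[mid$dose_nM == 100], (1 + 0.2) / 2)
  expect_equal(attr(ser, "controls"), rep(1, 8))
})

test_that("replicate noise has the configured coefficient of variation", {
  params <- list(L = 0.1, U = 1, ec50 = 100, h = 1, s = 1)
  ser <- generate_viability_series(c(10, 100, 1000, 1e4), params,
                                   noise_cv = 0.1, seed = 42,
                                   n_replicates = 6)
  cvs <- tapply(ser$viability, ser$dose_nM,
                function(v) sd(v) / mean(v))
  expect_true(all(cvs >= 0.02 & cvs <= 0.25))
  expect_true(mean(cvs) >= 0.05 && mean(cvs) <= 0.2)
})

test_that("latent structure is monotone across generated lines", {
  co <- generate_cohort(cohort_config(n_lines = 12, noise_cv = 0, seed = 5))
  sp <- co$specs
  expect_true(all(sp$mes_score_true >= 0 & sp$mes_score_true <= 1))
  expect_equal(range(sp$mes_score_true), c(0, 1))
  expect_equal(sum(sp$is_reference), 1)
  expect_true(co$config$reference_line_name %in% sp$name)
  expect_gte(cor(sp$mes_score_true, sp$lyso_rate, method = "spearman"), 0.9)
  meki_ec50 <- with(co$truth$curves[co$truth$curves$class == "MEKi", ],
                    tapply(ec50, line, mean))
  expect_gte(cor(sp$mes_score_true[match(names(meki_ec50), sp$name)],
                 -log(meki_ec50), method = "spearman"), 0.9)
  # chemotherapy potency runs the other way
  chemo_ec50 <- with(co$truth$curves[co$truth$curves$class == "chemo", ],
                     tapply(ec50, line, mean))
  expect_lte(cor(sp$mes_score_true[match(names(chemo_ec50), sp$name)],
                 -log(chemo_ec50), method = "spearman"), -0.9)
})

test_that("expression carries the identity signal only when asked to", {
  specs <- data.frame(name = sprintf("L%02d", 1:50),
                      mes_score_true = seq(0, 1, length.out = 50))
  null_ex <- generate_expression(specs, effect_size = 0, noise_sd = 0.5,
                                 seed = 9)
  sc0 <- ssgsea(null_ex$expr, null_ex$gene_sets$MES)
  expect_lt(abs(cor(sc0, specs$mes_score_true)), 0.35)
  # large effect, noiseless draw: rank order identical to the latent score
  strong <- generate_expression(specs, effect_size = 2, noise_sd = 0,
                                seed = 9)
  sc2 <- ssgsea(strong$expr, strong$gene_sets$MES)
  expect_equal(order(sc2), order(specs$mes_score_true))
  # identical mes scores on the same stream give identical signature means
  twin <- data.frame(name = c("A", "B"), mes_score_true = c(0.4, 0.4))
  tw <- generate_expression(twin, effect_size = 2, noise_sd = 0, seed = 1)
  expect_equal(tw$expr[tw$gene_sets$MES, "A"], tw$expr[tw$gene_sets$MES, "B"],
               ignore_attr = TRUE)
  expect_error(generate_expression(specs,
                                   gene_sets = list(MES = "g1", MPAS = "g1",
                                                    SASP = "g2")),
               "disjoint")
})

test_that("xenograft generator honors its deterministic and null limits", {
  # sd 0 with a -40% deterministic change: every treated embryo is PR
  det <- generate_xenograft_volumes(5, 5, effect_log_fold = log(1 / 0.6),
                                    sd_log = 0, growth_log = 0, seed = 1)
  calls <- classify_response(det)
  expect_true(all(calls$call[calls$group == "treated"] == "PR"))
  expect_true(all(calls$call[calls$group == "control"] == "SD"))
  expect_true(all(det$v24 > 0 & det$v72 > 0))
  # null effect: PR rates agree within binomial error
  nul <- generate_xenograft_volumes(300, 300, effect_log_fold = 0,
                                    sd_log = 0.35, growth_log = 0.22,
                                    seed = 2)
  rates <- response_rates(classify_response(nul))
  se <- sqrt(2 * 0.1 * 0.9 / 300)
  expect_lt(abs(diff(rates$PR_pct)) / 100, 4 * se)
})

test_that("treatment effect is detectable in most seeded repetitions", {
  hits <- 0
  for (s in 1:20) {
    v <- generate_xenograft_volumes(200, 200, effect_log_fold = 0.34,
                                    sd_log = 0.35, seed = s)
    cl <- classify_response(v)
    p <- compare_volume_change(cl[cl$group == "control", ],
                               cl[cl$group == "treated", ])$p_value
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.9)
})

test_that("combination generator reduces to Bliss at zero delta", {
  wp <- weak_curve_pair()
  doses <- 10^seq(0, 4, length.out = 5)
  s <- generate_combination_surface(wp$c1, wp$c2, 0, doses, doses, 0, 1)
  y1 <- 1 - fivepl(doses, wp$c1$L, wp$c1$U, wp$c1$ec50, wp$c1$h, 1)
  y2 <- 1 - fivepl(doses, wp$c2$L, wp$c2$U, wp$c2$ec50, wp$c2$h, 1)
  expect_equal(s$inhibition[-1, -1], outer(y1, y2, zip_expected),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unname(s$inhibition[-1, 1]), y1, tolerance = 1e-12)
  # constant delta shifts every interior cell before clipping
  s2 <- generate_combination_surface(wp$c1, wp$c2, 0.2, doses, doses, 0, 1)
  expect_equal(s2$inhibition[-1, -1] - s$inhibition[-1, -1],
               matrix(0.2, 5, 5), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("cohort tables reference only known lines and drugs", {
  co <- generate_cohort(cohort_config(n_lines = 4, seed = 6,
                                      n_drugs_per_class = c(MEKi = 2,
                                                            chemo = 1)))
  wells <- co$viability[!co$viability$is_control, ]
  expect_true(all(wells$line %in% co$specs$name))
  expect_true(all(wells$drug %in% co$drugs$drug))
  expect_true(all(co$foci$line %in% co$specs$name))
  expect_true(all(colnames(co$expression) %in% co$specs$name))
  expect_false(any(is.na(co$expression)))
  expect_setequal(names(co$combination_surfaces), co$specs$name)
})
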