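doses5 <- 10^seq(0, 4, length.out = 5)

test_that("the ZIP expectation has the Bliss properties", {
  expect_equal(zip_expected(0, 0.4), 0.4)
  expect_equal(zip_expected(1, 0.4), 1)
  expect_equal(zip_expected(0.5, 0.4), 0.7)
  set.seed(1)
  y <- matrix(runif(40), 20)
  expect_equal(zip_expected(y[, 1], y[, 2]), zip_expected(y[, 2], y[, 1]))
  expect_true(all(zip_expected(y[, 1], y[, 2]) >= pmax(y[, 1], y[, 2]) - 1e-12))
  expect_true(all(zip_expected(y[, 1], y[, 2]) <= 1))
  expect_error(zip_expected(1.2, 0.5), "\\[0, 1\\]")
})

test_that("Bliss-null surfaces score near zero, constant delta is recovered", {
  wp <- weak_curve_pair()
  null_surf <- generate_combination_surface(wp$c1, wp$c2, 0, doses5, doses5,
                                            noise_cv = 0, seed = 1)
  z0 <- zip_delta_matrix(null_surf)
  expect_lte(abs(z0$mean_zip), 1)
  expect_equal(z0$classification, "additive")

  s2 <- generate_combination_surface(wp$c1, wp$c2, 0.2, doses5, doses5,
                                     noise_cv = 0, seed = 1)
  z2 <- zip_delta_matrix(s2)
  expect_equal(z2$mean_zip, 20, tolerance = 1)
  expect_equal(z2$classification, "synergy")
  # every interior delta is the injected constant
  expect_equal(as.vector(z2$delta), rep(0.2, 25), tolerance = 0.01)
})

test_that("edges are mandatory and cannot be imputed", {
  wp <- weak_curve_pair()
  s <- generate_combination_surface(wp$c1, wp$c2, 0, doses5, doses5, 0, 1)
  s$inhibition[3, 1] <- NA
  s$mask[3, 1] <- "missing"
  expect_error(zip_delta_matrix(s), "edges")
})

diagonal_only <- function(surface) {
  K <- length(surface$doses1)
  inner <- surface$inhibition[-1, -1]
  keep <- diag(K) == 1
  inner[!keep] <- NA
  surface$inhibition[-1, -1] <- inner
  surface$mask[-1, -1][!keep] <- "missing"
  surface
}

test_that("diagonal imputation reproduces the exactly recoverable cases", {
  wp <- weak_curve_pair()
  # zero diagonal delta: imputed surface equals the ZIP expectation
  s0 <- diagonal_only(generate_combination_surface(wp$c1, wp$c2, 0, doses5,
                                                   doses5, 0, 1))
  f0 <- impute_diagonal_design(s0)
  z <- zip_delta_matrix(f0)
  expect_equal(max(abs(z$delta)), 0, tolerance = 0.01)
  expect_equal(sum(f0$mask == "imputed"), 20)
  # constant diagonal delta propagates unchanged to every interior cell
  s2 <- diagonal_only(generate_combination_surface(wp$c1, wp$c2, 0.2, doses5,
                                                   doses5, 0, 1))
  f2 <- impute_diagonal_design(s2)
  z2 <- zip_delta_matrix(f2)
  expect_equal(as.vector(z2$delta), rep(0.2, 25), tolerance = 0.01)
  # incomplete diagonal is a hard error naming the gap
  s3 <- s2
  s3$inhibition[3, 3] <- NA
  expect_error(impute_diagonal_design(s3), "rank\\(s\\): 2")
})

test_that("reduced-design scores track full-matrix scores on varying deltas", {
  set.seed(20)
  wp <- weak_curve_pair()
  n_ok <- 0; n_tot <- 40
  for (rep in seq_len(n_tot)) {
    a <- runif(1, -0.1, 0.1); b <- runif(1, -0.1, 0.1)
    dp <- function(x1, x2) a + b * (log10(x1) + log10(x2) - 4) / 4
    s <- generate_combination_surface(wp$c1, wp$c2, dp, doses5, doses5,
                                      noise_cv = 0.02, seed = rep)
    full <- zip_delta_matrix(s)$mean_zip
    red <- zip_delta_matrix(impute_diagonal_design(diagonal_only(s)))$mean_zip
    if (abs(full - red) <= 2) n_ok <- n_ok + 1
  }
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("CSS spans its limits and is label-exchange invariant", {
  # zero-inhibition surface
  z <- combination_surface(doses5, doses5, matrix(0, 6, 6))
  expect_equal(css(z)$css, 0, tolerance = 0.01)
  expect_equal(css(z)$effect_class, "low")
  # full-inhibition surface (untreated corner stays 0)
  f <- matrix(1, 6, 6); f[1, 1] <- 0
  cf <- css(combination_surface(doses5, doses5, f))
  expect_equal(cf$css, 100, tolerance = 0.01)
  expect_equal(cf$effect_class, "high")
  # exchanging drug labels flips the directions but not the mean
  wp <- weak_curve_pair()
  s <- generate_combination_surface(wp$c1, wp$c2, 0.1, doses5, doses5, 0, 3)
  st <- combination_surface(doses5, doses5, t(s$inhibition),
                            drug1 = s$drug2, drug2 = s$drug1)
  expect_equal(css(s)$css, css(st)$css, tolerance = 0.2)
  expect_equal(css(s)$css_1at2, css(st)$css_2at1, tolerance = 0.2)
})

test_that("CSS matches a dense-grid area oracle on a 4PL response row", {
  # surface whose combination rows are exact logistics of known area
  c1 <- list(L = 0.2, U = 1, ec50 = 100, h = 1, s = 1)
  c2 <- list(L = 0.5, U = 1, ec50 = 100, h = 1, s = 1)
  s <- generate_combination_surface(c1, c2, 0, doses5, doses5, 0, 1)
  cs <- css(s)
  j <- which.min(abs(log(doses5) - log(100)))
  y2fix <- 1 - fivepl(doses5[j], c2$L, c2$U, c2$ec50, c2$h, 1)
  # direction-1 response: zip of drug1 curve with fixed y2
  oracle_fit <- fit_curve(
    doses = doses5,
    viability = 1 - zip_expected(1 - fivepl(doses5, c1$L, c1$U, c1$ec50,
                                            c1$h, 1), y2fix),
    symmetric = TRUE)
  oracle <- dss_trapezoid(oracle_fit, log10(range(doses5)), t = 0)
  expect_equal(cs$css_1at2, oracle, tolerance = 1)
})

test_that("schedule comparison pairs tables and summarizes differences", {
  tab <- data.frame(line = sprintf("L%d", 1:6),
                    drug1 = "meki", drug2 = "seno",
                    css = c(40, 45, 50, 55, 60, 65),
                    mean_zip = c(0, 1, 2, 3, 4, 5))
  same <- compare_schedules(tab, tab)
  expect_equal(same$css$median_diff, 0)
  expect_equal(same$css$p_value, 1)
  boosted <- tab
  boosted$css <- tab$css + 5
  res <- compare_schedules(tab, boosted)
  expect_equal(res$css$median_diff, 5)
  expect_equal(res$mean_zip$median_diff, 0)
  expect_warning(compare_schedules(tab, boosted[-1, ]), "unpaired")
})
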