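test_that("partial correlation matches the closed-form single-covariate formula", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  z <- c(1, 1, 2, 2, 3)
  got <- partial_correlation(x, y, cbind(z = z))
  r_xy <- cor(x, y); r_xz <- cor(x, z); r_yz <- cor(y, z)
  expected <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  expect_equal(got$r, expected)
  expect_equal(got$k, 1)

  # intercept-only reduces to the plain Pearson correlation
  expect_equal(partial_correlation(x, y)$r, cor(x, y))

  # identical inputs with an orthogonal covariate: r = 1
  expect_equal(partial_correlation(x, x, cbind(c(1, -1, 0, 1, -1)))$r, 1)

  expect_error(partial_correlation(x, y[1:4]), "equal length")
  expect_warning(partial_correlation(x, y, cbind(k = rep(2, 5))),
                 "constant covariate")
  expect_error(
    suppressWarnings(partial_correlation(x, y, cbind(z, 2 * z))),
    "rank-deficient")
})

test_that("fisher_z is the atanh map with odd symmetry", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.6), log(1.6 / 0.4) / 2)
  r <- seq(-0.95, 0.95, by = 0.19)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_error(fisher_z(1), "\\|r\\| < 1")
  expect_error(fisher_z(-1.2), "\\|r\\| < 1")
})

test_that("the one-sided Fisher comparison evaluates its formula and is antisymmetric", {
  # worked example: rMZ = 0.8 (n 18), rDZ = 0.2 (n 25), k = 2
  got <- compare_correlations(0.8, 0.2, 18, 25, k = 2)
  expect_equal(got$Z, (atanh(0.8) - atanh(0.2)) / sqrt(1 / 13 + 1 / 20))
  expect_equal(got$Z, 2.5147, tolerance = 1e-4)
  expect_equal(got$p, 0.0060, tolerance = 1e-2)
  expect_equal(got$p, pnorm(got$Z, lower.tail = FALSE))

  # no difference: Z = 0, p = 0.5
  same <- compare_correlations(0.4, 0.4, 18, 25)
  expect_equal(same$Z, 0)
  expect_equal(same$p, 0.5)

  # swapping the groups negates Z and maps p to 1 - p
  fwd <- compare_correlations(0.7, 0.3, 20, 30)
  rev <- compare_correlations(0.3, 0.7, 30, 20)
  expect_equal(rev$Z, -fwd$Z)
  expect_equal(rev$p, 1 - fwd$p)

  expect_error(compare_correlations(0.5, 0.2, 5, 25, k = 2), "n - 3 - k")
})

test_that("scenario gating partitions the admissible region", {
  expect_equal(classify_scenario(0.5, 0.1), "EPISTASIS")   # 0.5 > 0.4
  expect_equal(classify_scenario(0.6, 0.2), "ADE")
  expect_equal(classify_scenario(0.35, 0.2), "ACE")
  expect_equal(classify_scenario(0.3, 0.4), "UNMODELED")   # rMZ <= rDZ
  expect_equal(classify_scenario(-0.2, -0.4), "UNMODELED")
  expect_equal(classify_scenario(0.5, 0), "UNMODELED")     # rDZ not positive

  # boundaries: rMZ = 2 rDZ -> ACE with C = 0; rMZ = 4 rDZ -> ADE with A = 0
  expect_equal(classify_scenario(0.4, 0.2), "ACE")
  expect_equal(ace_decompose(0.4, 0.2)$C, 0)
  expect_equal(classify_scenario(0.8, 0.2), "ADE")
  expect_equal(ade_decompose(0.8, 0.2)$A, 0)

  # dense grid over {0 < rDZ < rMZ < 1}: exactly one modelled label each,
  # and every point gets EPISTASIS, ADE or ACE
  grid <- expand.grid(rMZ = seq(0.01, 0.99, by = 0.02),
                      rDZ = seq(0.01, 0.99, by = 0.02))
  grid <- grid[grid$rDZ < grid$rMZ, ]
  lab <- classify_scenario(grid$rMZ, grid$rDZ)
  expect_true(all(lab %in% c("EPISTASIS", "ADE", "ACE")))
  in_epi <- grid$rMZ > 4 * grid$rDZ
  in_ade <- grid$rMZ <= 4 * grid$rDZ & grid$rMZ > 2 * grid$rDZ
  in_ace <- grid$rMZ <= 2 * grid$rDZ
  expect_identical(lab == "EPISTASIS", in_epi)
  expect_identical(lab == "ADE", in_ade)
  expect_identical(lab == "ACE", in_ace)
})

test_that("Falconer decompositions reproduce printed rows and sum to one", {
  # right gyrus rectus, strength of negative weights (ADE)
  ade <- ade_decompose(0.6191, 0.27025)
  expect_equal(round(100 * ade$A, 2), 46.19)
  expect_equal(round(100 * ade$D, 2), 15.72)
  expect_equal(round(100 * ade$E, 2), 38.09)
  expect_equal(round(100 * ade$H2, 2), 61.91)

  # right insula local efficiency (ACE): narrow-sense heritability 33.67%
  ace <- ace_decompose(0.3519, 0.18355)
  expect_equal(round(100 * ace$A, 2), 33.67)
  expect_equal(round(100 * ace$C, 2), 1.52)
  expect_equal(round(100 * ace$E, 2), 64.81)
  expect_equal(ace$h2, ace$A)

  # direct evaluations
  expect_equal(ade_decompose(0.6, 0.2),
               list(model = "ADE", A = 0.2, D = 0.4, E = 0.4, H2 = 0.6),
               tolerance = 1e-12)
  expect_equal(ace_decompose(0.4, 0.3),
               list(model = "ACE", A = 0.2, C = 0.2, E = 0.6, h2 = 0.2),
               tolerance = 1e-12)

  # scenario mismatch errors
  expect_error(ade_decompose(0.35, 0.2), "ADE")
  expect_error(ace_decompose(0.6, 0.2), "ACE")

  # over the whole gated grid: components non-negative, summing to 1
  grid <- expand.grid(rMZ = seq(0.005, 0.995, by = 0.01),
                      rDZ = seq(0.005, 0.995, by = 0.01))
  lab <- classify_scenario(grid$rMZ, grid$rDZ)
  g_ade <- grid[lab == "ADE", ]
  d <- ade_decompose(g_ade$rMZ, g_ade$rDZ)
  expect_true(all(d$A >= 0 & d$D >= 0 & d$E >= 0))
  expect_equal(d$A + d$D + d$E, rep(1, nrow(g_ade)), tolerance = 1e-12)
  expect_equal(d$H2, d$A + d$D, tolerance = 1e-12)
  g_ace <- grid[lab == "ACE", ]
  a <- ace_decompose(g_ace$rMZ, g_ace$rDZ)
  expect_true(all(a$A >= 0 & a$C >= 0 & a$E >= 0))
  expect_equal(a$A + a$C + a$E, rep(1, nrow(g_ace)), tolerance = 1e-12)
})

test_that("Bonferroni adjustment uses the explicit family size and caps at 1", {
  adj <- bonferroni_adjust(c(0.01, 0.2, 0.004), 10)
  expect_equal(adj$p_bonferroni, c(0.1, 1.0, 0.04))
  expect_equal(adj$significant_bonf, c(FALSE, FALSE, TRUE))
  expect_equal(adj$significant_unc, c(TRUE, FALSE, TRUE))
  expect_error(bonferroni_adjust(0.01, 0), ">= 1")
  expect_error(bonferroni_adjust(rep(0.01, 5), 3), "family size")
})

test_that("zygosity correlations handle duplication, covariates and ordering", {
  sim <- simulate_feature_cohort(variance_components(a2 = 0.5, e2 = 0.5),
                                 n_mz = 20, n_dz = 20, seed = 31)
  man <- sim$manifest
  # twin2 duplicates twin1: both correlations exactly 1
  dup <- sim$features
  dup[man$twin2_id, ] <- dup[man$twin1_id, ]
  zc <- zygosity_correlations(dup, man)
  expect_equal(zc$rMZ, 1)
  expect_equal(zc$rDZ, 1)

  # single-sex cohort: sex covariate dropped with a warning per zygosity
  # group, k reduced
  man_f <- man; man_f$sex <- "F"
  warns <- capture_warnings(
    zcf <- zygosity_correlations(sim$features, man_f))
  expect_length(warns, 2)
  expect_match(warns, "constant covariate", all = TRUE)
  expect_equal(zcf$kMZ, 1)
  expect_equal(zcf$kDZ, 1)

  # missing subject detected
  expect_error(zygosity_correlations(sim$features[-1, ], man), "missing")

  # double entry removes sensitivity to within-pair ordering
  swapped <- man
  swapped$twin1_id <- man$twin2_id
  swapped$twin2_id <- man$twin1_id
  de1 <- zygosity_correlations(sim$features, man, double_entry = TRUE)
  de2 <- zygosity_correlations(sim$features, swapped, double_entry = TRUE)
  expect_equal(de1$rMZ, de2$rMZ, tolerance = 1e-12)
  expect_equal(de1$rDZ, de2$rDZ, tolerance = 1e-12)
  expect_equal(de1$nMZ, 20)  # pair count, not row count
})

test_that("the full pipeline recovers known ACE variance components", {
  # spec (0.4, 0.2, 0.4) at 5000 + 5000 pairs. The per-seed sampling SD of
  # A = 2(rMZ - rDZ) is ~0.03 here, so recovery is asserted on the
  # scenario gate per seed and on the mean estimate across 20 seeds.
  est <- matrix(NA_real_, 20, 3, dimnames = list(NULL, c("A", "C", "E")))
  gated_ace <- 0L
  for (s in 1:20) {
    sim <- simulate_feature_cohort(
      variance_components(a2 = 0.4, c2 = 0.2, e2 = 0.4),
      n_mz = 5000, n_dz = 5000, seed = 1000 + s)
    fit <- twin_fc(sim$features, sim$manifest)
    r <- fit$results
    gated_ace <- gated_ace + (r$scenario == "ACE")
    if (r$scenario == "ACE") est[s, ] <- c(r$A, r$C, r$E)
  }
  expect_gte(gated_ace, 19)
  expect_lt(abs(mean(est[, "A"], na.rm = TRUE) - 0.4), 0.03)
  expect_lt(abs(mean(est[, "C"], na.rm = TRUE) - 0.2), 0.03)
  expect_lt(abs(mean(est[, "E"], na.rm = TRUE) - 0.4), 0.03)
})

test_that("the full pipeline recovers known ADE variance components", {
  est <- matrix(NA_real_, 20, 3, dimnames = list(NULL, c("A", "D", "E")))
  gated_ade <- 0L
  for (s in 1:20) {
    sim <- simulate_feature_cohort(
      variance_components(a2 = 0.3, d2 = 0.4, e2 = 0.3),
      n_mz = 5000, n_dz = 5000, seed = 2000 + s)
    fit <- twin_fc(sim$features, sim$manifest)
    r <- fit$results
    gated_ade <- gated_ade + (r$scenario == "ADE")
    if (r$scenario == "ADE") est[s, ] <- c(r$A, r$D, r$E)
  }
  expect_gte(gated_ade, 19)
  expect_lt(abs(mean(est[, "A"], na.rm = TRUE) - 0.3), 0.04)
  expect_lt(abs(mean(est[, "D"], na.rm = TRUE) - 0.4), 0.04)
  expect_lt(abs(mean(est[, "E"], na.rm = TRUE) - 0.3), 0.04)
})

test_that("under the global null the uncorrected type-I rate is close to 0.05", {
  rates <- vapply(1:20, function(s) {
    sim <- simulate_feature_cohort(variance_components(e2 = 1),
                                   n_mz = 18, n_dz = 25,
                                   n_features = 4550, seed = 3000 + s)
    fit <- twin_fc(sim$features, sim$manifest)
    mean(fit$results$p < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.01)
})

test_that("twin_fc assembles results, families and methods coherently", {
  sim <- simulate_feature_cohort(variance_components(a2 = 0.6, e2 = 0.4),
                                 n_mz = 200, n_dz = 200, n_features = 40,
                                 seed = 77)
  fit <- twin_fc(sim$features, sim$manifest)
  r <- fit$results
  expect_equal(nrow(r), 40)
  expect_true(all(r$scenario %in% c("EPISTASIS", "ADE", "ACE", "UNMODELED")))
  # components populated only for the applicable scenario
  expect_true(all(is.na(r$C[r$scenario == "ADE"])))
  expect_true(all(is.na(r$D[r$scenario == "ACE"])))
  expect_true(all(is.na(r$A[r$scenario %in% c("EPISTASIS", "UNMODELED")])))
  # Bonferroni: within each (scale, scenario) family, p_bonf = min(1, N p)
  fam <- split(seq_len(nrow(r)), paste(r$scale, r$scenario))
  for (idx in fam) {
    idx <- idx[!is.na(r$p[idx])]
    if (!length(idx)) next
    expect_equal(r$p_bonferroni[idx], pmin(1, length(idx) * r$p[idx]))
  }
  # S3 surface
  expect_output(print(fit), "Twin genetic/environmental")
  expect_output(print(summary(fit)), "Scenario counts")
  cf <- coef(fit)
  expect_equal(dim(cf), c(40, 6))
  expect_identical(as.data.frame(fit), fit$results)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))

  # pre-filter: with tiny samples nothing passes the significance screen
  sim2 <- simulate_feature_cohort(variance_components(a2 = 0.2, e2 = 0.8),
                                  n_mz = 8, n_dz = 8, n_features = 5,
                                  seed = 5)
  fit2 <- twin_fc(sim2$features, sim2$manifest,
                  require_significant_r = TRUE)
  fit2_off <- twin_fc(sim2$features, sim2$manifest)
  expect_gte(sum(fit2$results$scenario == "UNMODELED"),
             sum(fit2_off$results$scenario == "UNMODELED"))
})
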