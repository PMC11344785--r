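test_that("noise-free power-law data are identified exactly", {
  pts <- gen_allometric_taxa(alpha = log(0.5), beta = 0.72, noise_free = TRUE,
                             n_points = 42, seed = 1)
  m <- fit_glm(pts, "POC")
  expect_equal(m$volume_exponent, 0.72, tolerance = 1e-6)
  expect_equal(m$intercept, log(0.5), tolerance = 1e-6)
  # haploid multiplier of 0.2 -> offset ln(0.2)
  pts2 <- gen_allometric_taxa(alpha = log(0.5), beta = 0.72,
                              gamma_haploid = log(0.2), noise_free = TRUE,
                              n_points = 60, seed = 2)
  m2 <- fit_glm(pts2, "PIC")
  expect_equal(m2$ploidy_offset, log(0.2), tolerance = 1e-6)
  expect_equal(m2$volume_exponent, 0.72, tolerance = 1e-6)
})

test_that("training-point validation rejects bad inputs", {
  pts <- gen_allometric_taxa(n_points = 10, seed = 1)
  bad <- pts; bad$carbon_pg[3] <- -1
  expect_error(fit_glm(bad, "POC"), "non-positive")
  bad2 <- pts; bad2$volume_um3[1] <- NA
  expect_error(fit_glm(bad2, "POC"), "non-positive|non-finite")
  expect_error(fit_glm(pts[1:2, ], "POC"), "at least 3")
  expect_error(fit_glm(pts, "PIC"), "ploidy")
})

test_that("rescaling volumes moves only the intercept", {
  pts <- gen_allometric_taxa(n_points = 100, seed = 3)
  m1 <- fit_glm(pts, "POC")
  pts2 <- pts; pts2$volume_um3 <- pts2$volume_um3 * 1000
  m2 <- fit_glm(pts2, "POC")
  expect_equal(m1$volume_exponent, m2$volume_exponent, tolerance = 1e-6)
  expect_equal(m2$intercept, m1$intercept - m1$volume_exponent * log(1000),
               tolerance = 1e-5)
})

test_that("bootstrap ensembles behave under degeneracy and consistency", {
  # resampling exact power-law data gives identical coefficients every refit
  pts0 <- gen_allometric_taxa(noise_free = TRUE, n_points = 30, seed = 4)
  ens0 <- bootstrap_ensemble(pts0, "POC", B = 5, seed = 1)
  expect_lt(max(apply(ens0[, "volume_exponent", drop = FALSE], 2, sd)), 1e-6)
  # ensemble spread of the exponent shrinks with n (sqrt-n consistency)
  ens_small <- bootstrap_ensemble(gen_allometric_taxa(n_points = 42, seed = 5),
                                  "POC", B = 60, seed = 2)
  ens_large <- bootstrap_ensemble(gen_allometric_taxa(n_points = 420, seed = 5),
                                  "POC", B = 60, seed = 2)
  expect_lt(sd(ens_large[, "volume_exponent"]), sd(ens_small[, "volume_exponent"]))
  # reproducible by seed
  expect_identical(bootstrap_ensemble(pts0, "POC", B = 3, seed = 9),
                   bootstrap_ensemble(pts0, "POC", B = 3, seed = 9))
})

test_that("quota predictions are positive, seeded and mean-consistent", {
  pts <- gen_allometric_taxa(n_points = 200, seed = 6)
  m <- fit_glm(pts, "POC", B = 20, seed = 7)
  vols <- draw_truncated_normal(100, 20, R = 2000, seed = 8,
                                taxon = "A HET", variable = "volume_um3")
  q <- predict_quota(m, vols, R = 5000, seed = 9)
  expect_true(all(q$values > 0))
  expect_identical(q$variable, "poc_pg")
  expect_identical(predict_quota(m, vols, R = 100, seed = 9)$values,
                   predict_quota(m, vols, R = 100, seed = 9)$values)
  # degenerate model (dispersion -> 0, single-member ensemble, constant
  # volume) collapses to the conditional mean
  md <- m; md$ensemble <- NULL; md$dispersion <- 0
  qd <- predict_quota(md, const_set(100, R = 10), R = 50, seed = 1)
  expect_equal(qd$values,
               rep(exp(m$intercept + m$volume_exponent * log(100)), 50))
  # two-member ensemble with constant volume: mixture mean lies between the
  # two conditional means
  m2 <- m
  m2$ensemble <- rbind(c(intercept = log(0.5), volume_exponent = 0.6, dispersion = 0),
                       c(intercept = log(0.5), volume_exponent = 0.9, dispersion = 0))
  mu <- 0.5 * 100^c(0.6, 0.9)
  qm <- predict_quota(m2, const_set(100, R = 10), R = 4000, seed = 2)
  expect_gt(mean(qm$values), min(mu))
  expect_lt(mean(qm$values), max(mu))
  # predicted mean quota increases with volume for a positive exponent
  q_small <- mean(predict_quota(md, const_set(50, R = 10), R = 100, seed = 3)$values)
  q_big <- mean(predict_quota(md, const_set(500, R = 10), R = 100, seed = 3)$values)
  expect_gt(q_big, q_small)
})

test_that("haploid PIC predictions sit below diploid at equal volume", {
  pts <- gen_allometric_taxa(gamma_haploid = log(0.2), n_points = 400,
                             prop_haploid = 0.25, seed = 10)
  m <- fit_glm(pts, "PIC", B = 10, seed = 11)
  expect_lt(m$ploidy_offset, 0)
  vols <- const_set(150, R = 10)
  q_dip <- mean(predict_quota(m, vols, ploidy = "diploid", R = 4000, seed = 12)$values)
  q_hap <- mean(predict_quota(m, vols, ploidy = "haploid", R = 4000, seed = 12)$values)
  expect_lt(q_hap, q_dip)
  expect_error(predict_quota(m, vols, R = 10, seed = 1), "ploidy")
})

test_that("diagnostics report error metrics and pseudo-R2 on the training set", {
  pts <- gen_allometric_taxa(noise_free = TRUE, n_points = 30, seed = 13)
  m <- fit_glm(pts, "POC")
  expect_lt(m$diagnostics$MAE, 1e-6)
  expect_lt(m$diagnostics$RMSE, 1e-6)
  pts2 <- gen_allometric_taxa(n_points = 100, seed = 14)
  d <- fit_glm(pts2, "POC")$diagnostics
  expect_gte(d$RMSE, d$MAE)  # RMSE dominates MAE always
  expect_equal(d$relMAE, 100 * d$MAE / mean(pts2$carbon_pg))
  expect_gt(d$CoxSnellR2, 0)
  expect_lt(d$CoxSnellR2, 1)
})

test_that("family comparison prefers the Gamma fit on Gamma-generated data", {
  # AICs are put on a common (natural response) scale, so preference is a
  # fair likelihood comparison; majority vote over independent realisations
  wins <- vapply(1:11, function(s) {
    pts <- gen_allometric_taxa(n_points = 150, shape = 2, seed = 100 + s)
    compare_families(pts, "POC")$preferred == "gamma"
  }, logical(1))
  expect_gt(mean(wins), 0.5)
  cmp <- compare_families(gen_allometric_taxa(n_points = 150, shape = 2, seed = 101),
                          "POC")
  expect_true(all(c("AIC", "CoxSnellR2") %in% names(cmp$gamma)))
  expect_true(all(c("AIC", "CoxSnellR2") %in% names(cmp$gaussian)))
  expect_match(cmp$axis_convention[["gaussian"]], "log10")
})
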