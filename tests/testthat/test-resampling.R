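test_that("range rule and SD-to-SE conversion follow their closed forms", {
  expect_equal(sd_from_range(10, 14), 2)
  expect_equal(sd_from_range(5, 5), 0)
  expect_equal(sd_from_range(0.8, 3.0), 1.1)
  expect_error(sd_from_range(3, 1), ">=")
  expect_equal(se_from_sd(3), 3 / sqrt(3))
  expect_equal(se_from_sd(0), 0)
  expect_equal(se_from_sd(1.1), 0.6350853, tolerance = 1e-6)
  expect_equal(se_from_sd(2, n_assumed = 4), 1)
})

test_that("truncated-normal draws honour mean, truncation rule and seed", {
  # zero-variance degenerates to the mean
  expect_equal(draw_truncated_normal(10, 0, R = 5, seed = 1)$values, rep(10, 5))
  # rejection mode: sample mean near the untruncated expectation (mean/se = 5,
  # truncation bias negligible); bound is 3 MC standard errors
  rs <- draw_truncated_normal(10, 2, R = 1e5, seed = 42)
  expect_lt(abs(mean(rs$values) - 10), 3 * 2 / sqrt(1e5))
  expect_true(all(rs$values >= 0))
  # clip mode leaves a point mass exactly at zero when spread >> mean
  cl <- draw_truncated_normal(0.1, 5, R = 1e5, seed = 7, truncation = "clip")
  expect_gt(mean(cl$values == 0), 0.05)
  expect_true(all(cl$values >= 0))
  # identical seed => identical output; different seed differs
  expect_identical(draw_truncated_normal(10, 2, R = 100, seed = 3)$values,
                   draw_truncated_normal(10, 2, R = 100, seed = 3)$values)
  expect_false(identical(draw_truncated_normal(10, 2, R = 100, seed = 3)$values,
                         draw_truncated_normal(10, 2, R = 100, seed = 4)$values))
  expect_error(draw_truncated_normal(10, -1, R = 10, seed = 1), ">= 0")
})

test_that("Bayesian bootstrap keeps support and preserves the sample mean", {
  expect_equal(bayesian_bootstrap(7, R = 50, seed = 1)$values, rep(7, 50))
  rs <- bayesian_bootstrap(c(0, 10), R = 1e5, seed = 2)
  # E[replicate mean] over flat Dirichlet weights equals the sample mean;
  # replicate-mean MC spread is dominated by the weight draw (sd ~ range/sqrt(12))
  expect_lt(abs(mean(rs$values) - 5), 4 * 5 / sqrt(12))
  rs3 <- bayesian_bootstrap(c(1, 2, 3), R = 1e5, seed = 3)
  expect_gte(min(rs3$values), 1)
  expect_lte(max(rs3$values), 3)
  expect_true(all(rs3$values %in% c(1, 2, 3)))
  expect_error(bayesian_bootstrap(numeric(0), R = 10, seed = 1), "empty")
})

test_that("bootstrap replicate-mean expectation matches the input mean across cases", {
  # property check: average of replicate means over several weight draws
  # approaches the sample mean within Monte-Carlo error
  for (seed in 1:5) {
    set.seed(seed)
    vals <- exp(stats::rnorm(20, 2, 1))
    means <- vapply(1:40, function(k)
      mean(bayesian_bootstrap(vals, R = 500, seed = seed * 100 + k)$values),
      numeric(1))
    expect_lt(abs(mean(means) - mean(vals)), 4 * stats::sd(vals) / sqrt(40 * 20))
  }
})

test_that("SE imputation prefers the same-taxon pool and rescales by the target mean", {
  tgt <- measurement("A HET", "volume_um3", "mean_only", mean = 10,
                     method = "culture", source = "t")
  # singleton same-taxon pool with normalized SE 0.2 -> se = 2
  pool1 <- list(measurement("A HET", "volume_um3", "mean_se", mean = 5, se = 1,
                            method = "culture", source = "p"))
  expect_equal(impute_se(tgt, pool1, seed = 1), 2)
  # empty same-taxon pool: falls back to the global pool's support
  pool2 <- list(measurement("B HET", "volume_um3", "mean_se", mean = 10, se = 1,
                            method = "culture", source = "p1"),
                measurement("C HET", "volume_um3", "mean_se", mean = 10, se = 3,
                            method = "culture", source = "p2"))
  draws <- vapply(1:20, function(s) impute_se(tgt, pool2, seed = s), numeric(1))
  expect_true(all(draws %in% c(1, 3)))
  # all-zero normalized SEs give zero
  pool3 <- list(measurement("A HET", "volume_um3", "mean_se", mean = 4, se = 0,
                            method = "culture", source = "p"))
  expect_equal(impute_se(tgt, pool3, seed = 1), 0)
  expect_error(impute_se(tgt, list(), seed = 1), "cannot impute")
})

test_that("reconstruction dispatches by reporting mode", {
  # min_max chains range rule -> assumed-n SE -> truncated normal centred on
  # the midpoint; bitwise identical to the hand-built chain at equal seed
  m <- measurement("A HET", "diameter_um", "min_max", min = 10, max = 14,
                   method = "culture", source = "x")
  got <- reconstruct(m, R = 1000, seed = 5)
  want <- draw_truncated_normal(12, se_from_sd(sd_from_range(10, 14)), R = 1000,
                                seed = 5, taxon = "A HET",
                                variable = "diameter_um", source = "x")
  expect_identical(got$values, want$values)
  # a reported mean overrides the midpoint
  m2 <- measurement("A HET", "diameter_um", "min_max", min = 10, max = 14,
                    mean = 11, method = "culture", source = "x")
  expect_identical(reconstruct(m2, R = 100, seed = 5)$values,
                   draw_truncated_normal(11, se_from_sd(2), R = 100, seed = 5)$values)
  # raw singleton is constant
  raw1 <- measurement("A HET", "volume_um3", "raw", raw_values = 5,
                      method = "culture", source = "x")
  expect_equal(reconstruct(raw1, R = 100, seed = 1)$values, rep(5, 100))
  # mean_se reconstructions recover the mean within MC error
  ms <- measurement("A HET", "volume_um3", "mean_se", mean = 10, se = 2,
                    method = "culture", source = "x")
  expect_lt(abs(mean(reconstruct(ms, R = 1e5, seed = 2)$values) - 10),
            3 * 2 / sqrt(1e5))
  # mean_sd converts the SD under the assumed sample size before drawing
  msd <- measurement("A HET", "volume_um3", "mean_sd", mean = 10, sd = 3,
                     method = "culture", source = "x")
  expect_identical(reconstruct(msd, R = 200, seed = 9)$values,
                   draw_truncated_normal(10, 3 / sqrt(3), R = 200, seed = 9)$values)
  # mean_only requires an imputation pool
  mo <- measurement("A HET", "volume_um3", "mean_only", mean = 10,
                    method = "culture", source = "x")
  expect_error(reconstruct(mo, R = 10, seed = 1), "cannot impute")
})

test_that("merging concatenates study replicate sets before smoothing", {
  a <- replicate_set("Sp i HET", "diameter_um", c(11.6, 6.0, 9.7), "study_a")
  b <- replicate_set("Sp i HET", "diameter_um", c(7.6, 18.0, 16.9), "study_b")
  res <- merge_replicates(list(a, b), R_out = 2000, seed = 1)
  pool <- c(11.6, 6.0, 9.7, 7.6, 18.0, 16.9)
  expect_true(all(res$set$values %in% pool))
  expect_setequal(unique(res$set$values), pool)
  expect_equal(res$estimate$n_studies, 2)
  expect_true(res$estimate$ci_low <= res$estimate$mean &&
              res$estimate$mean <= res$estimate$ci_high)
  # mixed taxa refuse to merge
  c_set <- replicate_set("Other HET", "diameter_um", 1:3)
  expect_error(merge_replicates(list(a, c_set), R_out = 10, seed = 1), "mixed")
  # a constant set collapses to a point estimate with degenerate CI
  res1 <- merge_replicates(list(const_set(5)), R_out = 500, seed = 2)
  expect_equal(res1$estimate$mean, 5)
  expect_equal(res1$estimate$ci_low, 5)
  expect_equal(res1$estimate$ci_high, 5)
})

test_that("merging equal-size sets of zeros and tens centres near five", {
  z <- replicate_set("A HET", "volume_um3", rep(0, 500), "s1")
  t10 <- replicate_set("A HET", "volume_um3", rep(10, 500), "s2")
  res <- merge_replicates(list(z, t10), R_out = 1e5, seed = 3)
  # the Dirichlet weight draw dominates the spread of the pooled mean
  expect_lt(abs(res$estimate$mean - 5), 1)
})

test_that("merging identical sets reproduces the single-set mean within MC error", {
  s <- draw_truncated_normal(50, 5, R = 2000, seed = 11, taxon = "A HET")
  single <- merge_replicates(list(s), R_out = 1e4, seed = 12)
  triple <- merge_replicates(list(s, s, s), R_out = 1e4, seed = 13)
  expect_lt(abs(single$estimate$mean - triple$estimate$mean),
            4 * 5 / sqrt(1e4) + 4 * 5 / sqrt(2000))
})

test_that("reconstruction and merging are bitwise reproducible given seeds", {
  m <- measurement("A HET", "volume_um3", "mean_se", mean = 30, se = 6,
                   method = "LM", source = "x")
  r1 <- reconstruct(m, R = 500, seed = 77)
  r2 <- reconstruct(m, R = 500, seed = 77)
  expect_identical(r1$values, r2$values)
  mm1 <- merge_replicates(list(r1), R_out = 500, seed = 78)
  mm2 <- merge_replicates(list(r2), R_out = 500, seed = 78)
  expect_identical(mm1$set$values, mm2$set$values)
})

test_that("range-rule simulation matches order-statistic expectations", {
  # E[range]/2 at n=2 is sigma/sqrt(pi); at n=5 it is d5*sigma/2, d5 ~ 2.326
  res <- range_rule_simulation(c(2, 5), divisor = 2, reps = 2e5, seed = 1)
  expect_equal(res$mean_estimate[res$n == 2], 1 / sqrt(pi), tolerance = 0.01)
  expect_equal(res$mean_estimate[res$n == 5], 2.32593 / 2, tolerance = 0.01)
  # divisor 4 reuses the same draws: exactly half of divisor 2
  res4 <- range_rule_simulation(c(2, 5), divisor = 4, reps = 2e5, seed = 1)
  expect_identical(res$mean_estimate / 2, res4$mean_estimate)
  # signs: divisor 2 overestimates at n = 5, divisor 4 underestimates
  expect_gt(res$pct_error[res$n == 5], 0)
  expect_lt(res4$pct_error[res4$n == 5], 0)
  expect_error(range_rule_simulation(1, 2, reps = 10, seed = 1))
})
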