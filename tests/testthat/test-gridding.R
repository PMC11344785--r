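test_that("abundance converts to stocks with pg-to-ug unit arithmetic", {
  q10 <- const_set(10, R = 20, variable = "poc_pg")
  expect_equal(abundance_to_stock(1e6, q10), rep(10, 20))
  expect_equal(abundance_to_stock(0, q10), rep(0, 20))
  q2 <- replicate_set("A HET", "poc_pg", c(5, 15))
  s <- abundance_to_stock(1e6, q2)
  expect_equal(sort(unique(s)), c(5, 15))
  expect_equal(mean(s), 10)
  expect_error(abundance_to_stock(-1, q10), ">= 0")
  expect_error(abundance_to_stock(1, replicate_set("A HET", "poc_pg", c(0, 1))),
               "strictly positive")
})

test_that("record validation flags range, positivity and type violations", {
  clean <- mk_obs(10, 20, 10)
  expect_equal(nrow(validate_records(clean, "abundance")), 0)
  bad <- rbind(mk_obs(91, 20, 10), mk_obs(10, 20, 300),
               mk_obs(10, 20, 10, year = 1950),
               mk_obs(10, 20, 10, abundance = -5))
  rep <- validate_records(bad, "abundance")
  expect_setequal(rep$rule, c("range", "positivity"))
  expect_true(all(c("lat", "depth", "year", "abundance") %in% rep$column))
  trait_bad <- data.frame(taxon = "A HET", variable = "poc_pg", value = -3)
  expect_identical(validate_records(trait_bad, "trait")$rule, "positivity")
})

test_that("gridding bins half-open, averages within bins and conserves counts", {
  obs <- rbind(mk_obs(10.2, 20.3, 2, abundance = 100),
               mk_obs(10.8, 20.9, 3, abundance = 200),   # same 1-degree/5-m bin
               mk_obs(10.2, 20.3, 4.9, abundance = 50),  # still bin [0,5)... same cell
               mk_obs(10.2, 20.3, 5.0, abundance = 70))  # bin [5,10): new cell
  g <- grid_observations(obs)
  expect_equal(nrow(g), 2)
  shallow <- g[g$depth_bin == 0, ]
  expect_equal(shallow$mean_abundance, mean(c(100, 200, 50)))
  expect_equal(shallow$n_obs, 3)
  expect_equal(g[g$depth_bin == 5, ]$mean_abundance, 70)
  # count conservation over a larger random field
  ab <- gen_abundance_field(n_stations = 150, seed = 3)
  gg <- grid_observations(ab)
  expect_equal(sum(gg$n_obs), nrow(ab))
  expect_error(grid_observations(mk_obs(95, 0, 0)), "validation")
})

test_that("gridding is invariant to row order and idempotent at bin centroids", {
  ab <- gen_abundance_field(n_stations = 120, seed = 4)
  g1 <- grid_observations(ab)
  g2 <- grid_observations(ab[sample.int(nrow(ab)), ])
  expect_equal(g1, g2)
  # re-gridding the gridded cells (viewed as observations at bin lower
  # edges) reproduces the same cells and means
  as_obs <- data.frame(lat = g1$lat_bin + 0.5, lon = g1$lon_bin + 0.5,
                       depth = g1$depth_bin + 0.1, year = g1$year,
                       month = g1$month, taxon = g1$taxon,
                       abundance = g1$mean_abundance, method = "SEM",
                       stringsAsFactors = FALSE)
  g3 <- grid_observations(as_obs)
  expect_equal(g3[c("lat_bin", "lon_bin", "depth_bin", "year", "month",
                    "taxon", "mean_abundance")],
               g1[c("lat_bin", "lon_bin", "depth_bin", "year", "month",
                    "taxon", "mean_abundance")])
})

test_that("stock means scale linearly with abundance", {
  ab <- gen_abundance_field(n_stations = 60, seed = 5)
  quotas <- list()
  for (tx in unique(ab$taxon))
    quotas[[tx]] <- const_set(8, R = 200, taxon = tx, variable = "poc_pg")
  g1 <- grid_observations(ab, poc_quotas = quotas)
  ab2 <- ab; ab2$abundance <- ab2$abundance * 3
  g2 <- grid_observations(ab2, poc_quotas = quotas)
  expect_equal(g2$poc_stock_mean, 3 * g1$poc_stock_mean)
  expect_equal(g2$mean_abundance, 3 * g1$mean_abundance)
  # stock CI widths are non-negative and zero for constant quotas
  expect_true(all(g1$poc_stock_hi - g1$poc_stock_lo >= 0))
  expect_equal(g1$poc_stock_hi, g1$poc_stock_lo)
})

test_that("longitudes normalise onto [-180, 180) before binning", {
  obs <- rbind(mk_obs(0.5, 190.5, 1), mk_obs(0.5, -169.5, 1))
  g <- grid_observations(obs)
  expect_equal(nrow(g), 1)       # 190.5 wraps to -169.5
  expect_equal(g$lon_bin, -170)
  expect_equal(g$n_obs, 2)
})

test_that("LM-vs-SEM bias is a Bayesian-bootstrap mean of per-pair differences", {
  # identical counts: zero bias with degenerate interval
  same <- data.frame(count_LM = c(10, 20, 30), count_SEM = c(10, 20, 30))
  res <- lm_sem_bias(same, R = 500, seed = 1)
  expect_equal(res$mean_pct, 0)
  expect_equal(c(res$ci_low, res$ci_high), c(0, 0))
  # single pair under the (LM-SEM)/SEM convention
  one <- data.frame(count_LM = 80, count_SEM = 100)
  res1 <- lm_sem_bias(one, R = 500, seed = 2)
  expect_equal(res1$mean_pct, -20)
  expect_equal(c(res1$ci_low, res1$ci_high), c(-20, -20))
  expect_identical(res1$convention, "100*(LM-SEM)/SEM")
  # a systematic LM deficit is recovered with a covering interval
  set.seed(3)
  sem <- round(runif(40, 50, 500))
  pairs <- data.frame(count_LM = round(sem * 0.8 * exp(rnorm(40, 0, 0.1))),
                      count_SEM = sem)
  res2 <- lm_sem_bias(pairs, R = 4000, seed = 4)
  expect_lt(res2$mean_pct, 0)
  expect_true(res2$ci_low < -20 && -20 < res2$ci_high)
  # uninformative (0, 0) pairs are dropped and counted
  with0 <- rbind(pairs, data.frame(count_LM = 0, count_SEM = 0))
  expect_equal(lm_sem_bias(with0, R = 100, seed = 5)$n_dropped, 1)
  expect_error(lm_sem_bias(data.frame(count_LM = 5, count_SEM = 0), R = 10, seed = 1),
               "undefined")
})
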