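#' Abundance-to-stock conversion and spatiotemporal gridding
#'
#' Abundance observations (cells per litre at a station, depth and date)
#' are converted into water-column carbon stocks by multiplying the cellular
#' quota replicate distribution by the abundance, and aggregated onto a
#' 1-degree, 5-m, monthly grid. Bin intervals are half-open with the lower
#' edge inclusive; longitudes are normalised to `[-180, 180)`; grid labels
#' sit at the bin lower edge. Count uncertainty is not modelled: stock
#' confidence intervals carry only the trait (quota) uncertainty.
#'
#' @name stocks_gridding
NULL

PG_PER_UG <- 1e6

#' Convert an abundance into a carbon-stock distribution
#'
#' @param abundance cells per litre, `>= 0` (a single value).
#' @param quota_replicates a [replicate_set()] of cellular carbon quotas,
#'   pg C per cell, all `> 0`.
#' @return Numeric vector of stock replicates in ug C per litre
#'   (`abundance * quota / 1e6`); identically zero when `abundance` is 0.
#' @examples
#' q <- replicate_set("x HET", "poc_pg", c(5, 15))
#' abundance_to_stock(1e6, q)   # 5 and 15 ug C / L
#' @export
abundance_to_stock <- function(abundance, quota_replicates) {
  stopifnot(inherits(quota_replicates, "replicate_set"))
  if (!is.numeric(abundance) || length(abundance) != 1L || !is.finite(abundance))
    stop("'abundance' must be a single finite number", call. = FALSE)
  if (abundance < 0) stop("'abundance' must be >= 0", call. = FALSE)
  if (any(quota_replicates$values <= 0))
    stop("quota replicates must be strictly positive", call. = FALSE)
  abundance * quota_replicates$values / PG_PER_UG
}

normalize_lon <- function(lon) ((lon + 180) %% 360) - 180

#' Validate an observation table against the pipeline schema
#'
#' Checks types, coordinate and date ranges (latitude in `[-90, 90]`,
#' longitude in `[-180, 180)` after normalisation, depth in `[0, 275]` m,
#' year 1964-2019, month 1-12), non-negative finite abundances and, for
#' trait tables, strict positivity of size/POC/PIC values.
#'
#' @param table a data frame of observations.
#' @param schema `"abundance"` (columns lat, lon, depth, year, month,
#'   taxon, abundance, method) or `"trait"` (column value `> 0`).
#' @return A data frame report with columns `row`, `column`, `rule`,
#'   `value`; zero rows means the table is clean.
#' @export
validate_records <- function(table, schema = c("abundance", "trait")) {
  schema <- match.arg(schema)
  report <- data.frame(row = integer(), column = character(),
                       rule = character(), value = character(),
                       stringsAsFactors = FALSE)
  flag <- function(rows, column, rule, values) {
    if (length(rows) > 0L)
      report <<- rbind(report, data.frame(row = rows, column = column,
                                          rule = rule,
                                          value = as.character(values),
                                          stringsAsFactors = FALSE))
  }
  need <- if (schema == "abundance")
    c("lat", "lon", "depth", "year", "month", "taxon", "abundance", "method")
  else c("taxon", "variable", "value")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0L) {
    flag(0L, missing_cols, "missing_column", NA)
    return(report)
  }
  if (schema == "abundance") {
    num <- c("lat", "lon", "depth", "year", "month", "abundance")
    for (cn in num) {
      if (!is.numeric(table[[cn]])) { flag(0L, cn, "not_numeric", NA); next }
      flag(which(!is.finite(table[[cn]])), cn, "not_finite", table[[cn]][!is.finite(table[[cn]])])
    }
    ok <- function(cn) is.numeric(table[[cn]])
    if (ok("lat")) { i <- which(table$lat < -90 | table$lat > 90); flag(i, "lat", "range", table$lat[i]) }
    if (ok("lon")) { i <- which(table$lon < -360 | table$lon >= 360); flag(i, "lon", "range", table$lon[i]) }
    if (ok("depth")) { i <- which(table$depth < 0 | table$depth > 275); flag(i, "depth", "range", table$depth[i]) }
    if (ok("year")) { i <- which(table$year < 1964 | table$year > 2019); flag(i, "year", "range", table$year[i]) }
    if (ok("month")) { i <- which(!table$month %in% 1:12); flag(i, "month", "range", table$month[i]) }
    if (ok("abundance")) { i <- which(table$abundance < 0); flag(i, "abundance", "positivity", table$abundance[i]) }
    i <- which(!table$method %in% c("SEM", "LM")); flag(i, "method", "enum", table$method[i])
  } else {
    if (!is.numeric(table$value)) flag(0L, "value", "not_numeric", NA)
    else {
      i <- which(!is.finite(table$value) | table$value <= 0)
      flag(i, "value", "positivity", table$value[i])
    }
  }
  report
}

#' Grid abundance observations onto 1-degree, 5-m, monthly bins
#'
#' Bins observations by `floor(lat)`, `floor(lon)` (after normalising
#' longitude to `[-180, 180)`), 5-m depth level (`[0,5), [5,10), ...`),
#' year, month and taxon, and takes the arithmetic mean abundance per
#' occupied bin. When per-taxon quota replicate sets are supplied, each
#' cell also carries POC/PIC stock means and percentile CIs obtained by
#' scaling the quota distribution by the cell's mean abundance.
#'
#' @param observations data frame with columns `lat`, `lon`, `depth`,
#'   `year`, `month`, `taxon`, `abundance` (cells per litre), `method`.
#' @param poc_quotas,pic_quotas optional named lists, taxon ->
#'   [replicate_set()] of quotas (pg C per cell).
#' @param probs CI percentiles for the stock summaries.
#' @param validate abort on validation violations (default `TRUE`); set
#'   `FALSE` for report-only workflows that pre-validate.
#' @return A data frame with one row per occupied bin: `lat_bin`,
#'   `lon_bin`, `depth_bin` (bin lower edges), `year`, `month`, `taxon`,
#'   `mean_abundance`, `n_obs`, and when quotas are given
#'   `poc_stock_mean`/`_lo`/`_hi` and `pic_stock_mean`/`_lo`/`_hi`
#'   (ug C per litre). Rows are sorted on the bin keys, so output is
#'   invariant to input row order.
#' @export
grid_observations <- function(observations, poc_quotas = NULL, pic_quotas = NULL,
                              probs = c(0.025, 0.975), validate = TRUE) {
  if (validate) {
    vr <- validate_records(observations, "abundance")
    if (nrow(vr) > 0L)
      stop(sprintf("validation failed for %d record(s); first: row %s, %s (%s)",
                   nrow(vr), vr$row[1], vr$column[1], vr$rule[1]), call. = FALSE)
  }
  obs <- observations
  obs$lon <- normalize_lon(obs$lon)
  key <- data.frame(lat_bin = floor(obs$lat), lon_bin = floor(obs$lon),
                    depth_bin = 5 * floor(obs$depth / 5),
                    year = obs$year, month = obs$month, taxon = obs$taxon,
                    stringsAsFactors = FALSE)
  agg <- aggregate(obs$abundance, by = key, FUN = mean)
  names(agg)[ncol(agg)] <- "mean_abundance"
  cnt <- aggregate(rep.int(1L, nrow(obs)), by = key, FUN = sum)
  agg$n_obs <- cnt$x[match(do.call(paste, agg[seq_len(6)]),
                           do.call(paste, cnt[seq_len(6)]))]
  ord <- do.call(order, agg[c("taxon", "year", "month", "lat_bin", "lon_bin", "depth_bin")])
  agg <- agg[ord, , drop = FALSE]
  rownames(agg) <- NULL
  add_stock <- function(agg, quotas, prefix) {
    m <- lo <- hi <- rep(NA_real_, nrow(agg))
    for (i in seq_len(nrow(agg))) {
      q <- quotas[[agg$taxon[i]]]
      if (is.null(q)) next
      stock <- abundance_to_stock(agg$mean_abundance[i], q)
      m[i] <- mean(stock)
      qq <- quantile(stock, probs = probs, names = FALSE)
      lo[i] <- qq[1]; hi[i] <- qq[2]
    }
    agg[[paste0(prefix, "_stock_mean")]] <- m
    agg[[paste0(prefix, "_stock_lo")]] <- lo
    agg[[paste0(prefix, "_stock_hi")]] <- hi
    agg
  }
  if (!is.null(poc_quotas)) agg <- add_stock(agg, poc_quotas, "poc")
  if (!is.null(pic_quotas)) agg <- add_stock(agg, pic_quotas, "pic")
  agg
}

#' Method bias between paired light-microscopy and SEM counts
#'
#' Light microscopy tends to miss lightly calcified cells that SEM resolves.
#' Given taxon-specific counts of the same water samples by both methods,
#' computes the per-pair relative percentage difference
#' `100 * (LM - SEM) / SEM` (SEM as the reference method) and summarises it
#' by Bayesian bootstrap: flat-Dirichlet weights over the pairs, a weighted
#' mean per draw, and the mean with a 95 percent percentile interval over
#' draws. Pairs with both counts zero carry no information and are dropped
#' (their number is reported).
#'
#' @param paired_counts data frame with columns `count_LM` and `count_SEM`
#'   (same sample and taxon per row; sub-species merged and
#'   non-taxon-specific counts excluded upstream).
#' @param R number of bootstrap draws.
#' @param seed integer seed.
#' @param probs CI percentiles.
#' @return A list: `mean_pct`, `ci_low`, `ci_high`, `n_pairs`,
#'   `n_dropped`, and `convention = "100*(LM-SEM)/SEM"`.
#' @export
lm_sem_bias <- function(paired_counts, R = 10000, seed = 1L,
                        probs = c(0.025, 0.975)) {
  stopifnot(all(c("count_LM", "count_SEM") %in% names(paired_counts)), R >= 1)
  lm_n <- paired_counts$count_LM; sem_n <- paired_counts$count_SEM
  if (any(lm_n < 0 | sem_n < 0)) stop("counts must be >= 0", call. = FALSE)
  drop <- lm_n == 0 & sem_n == 0
  lm_n <- lm_n[!drop]; sem_n <- sem_n[!drop]
  if (length(lm_n) == 0L) stop("no informative pairs", call. = FALSE)
  if (any(sem_n == 0))
    stop("pairs with SEM count zero but LM nonzero have undefined relative difference",
         call. = FALSE)
  pct <- 100 * (lm_n - sem_n) / sem_n
  means <- with_seed(seed, {
    vapply(seq_len(R), function(i) sum(dirichlet_weights(length(pct)) * pct),
           numeric(1L))
  })
  qq <- quantile(means, probs = probs, names = FALSE)
  list(mean_pct = mean(means), ci_low = qq[1], ci_high = qq[2],
       n_pairs = length(pct), n_dropped = sum(drop),
       convention = "100*(LM-SEM)/SEM")
}
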