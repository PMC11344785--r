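#' Synthetic fixtures with the statistical structure the pipeline assumes
#'
#' Generators for the three input classes the pipeline consumes: per-study
#' size/carbon reports in any of the five summary modes, allometric
#' training sets following a power law with Gamma noise and a haploid
#' effect, and abundance fields with realistic spatial, depth and seasonal
#' structure. Every generator is seeded and returns (or embeds) the truth
#' used to generate the data, so recovery can be scored. Defaults mimic the
#' magnitudes of the real compilations: cell volumes of order 10-1000 um^3,
#' organic carbon quotas around 67 pg C, inorganic around 16 pg C.
#'
#' @name synthetic_data
NULL

#' Generate one study's report of a size (or carbon) measurement
#'
#' Draws `n_cells` positive values around a true mean (zero-truncated
#' normal by default, log-normal optionally to exercise robustness to the
#' normality assumption), then reports them in the requested mode,
#' discarding exactly the information that mode hides.
#'
#' @param taxon canonical taxon name for the report.
#' @param true_mean,true_sd truth of the generating distribution
#'   (`true_mean > 0`, `true_sd >= 0`).
#' @param n_cells number of cells "measured".
#' @param reporting_mode one of `"raw"`, `"mean_se"`, `"mean_sd"`,
#'   `"min_max"`, `"mean_only"`.
#' @param seed integer seed.
#' @param variable,method,source passed to [measurement()].
#' @param distribution `"truncnorm"` (matches the reconstruction
#'   assumption) or `"lognormal"` (violates it).
#' @return A [measurement()] in the requested mode.
#' @export
gen_size_study <- function(taxon, true_mean, true_sd, n_cells,
                           reporting_mode = c("raw", "mean_se", "mean_sd",
                                              "min_max", "mean_only"),
                           seed = 1L, variable = "volume_um3",
                           method = "culture", source = "synthetic",
                           distribution = c("truncnorm", "lognormal")) {
  reporting_mode <- match.arg(reporting_mode)
  distribution <- match.arg(distribution)
  stopifnot(true_mean > 0, true_sd >= 0, n_cells >= 1)
  x <- with_seed(seed, {
    if (true_sd == 0) rep(true_mean, n_cells)
    else if (distribution == "truncnorm") {
      v <- rnorm(n_cells, true_mean, true_sd)
      bad <- which(v <= 0)
      while (length(bad) > 0L) {
        v[bad] <- rnorm(length(bad), true_mean, true_sd)
        bad <- bad[v[bad] <= 0]
      }
      v
    } else {
      s2 <- log(1 + (true_sd / true_mean)^2)
      rlnorm(n_cells, meanlog = log(true_mean) - s2 / 2, sdlog = sqrt(s2))
    }
  })
  switch(reporting_mode,
    raw = measurement(taxon, variable, "raw", raw_values = x,
                      method = method, source = source),
    mean_se = measurement(taxon, variable, "mean_se", mean = mean(x),
                          se = if (n_cells > 1) sd(x) / sqrt(n_cells) else 0,
                          n = n_cells, method = method, source = source),
    mean_sd = measurement(taxon, variable, "mean_sd", mean = mean(x),
                          sd = if (n_cells > 1) sd(x) else 0,
                          n = n_cells, method = method, source = source),
    min_max = measurement(taxon, variable, "min_max", min = min(x), max = max(x),
                          n = n_cells, method = method, source = source),
    mean_only = measurement(taxon, variable, "mean_only", mean = mean(x),
                            n = n_cells, method = method, source = source))
}

#' Generate allometric training points from a known power law
#'
#' Volumes are drawn log-uniformly over `volume_range`; carbon follows
#' `Gamma(mean = exp(alpha + beta * ln(V) + gamma_haploid * haploid),
#' shape)`. When `include_ploidy` is `TRUE` roughly `prop_haploid` of the
#' points are haploid (the real inorganic-carbon training set is heavily
#' diploid-dominated, 925 of 961 points). `noise_free = TRUE` puts carbon
#' exactly on the power law, the identifiability limit of infinite shape.
#'
#' @param alpha,beta power-law intercept (natural-log scale) and exponent.
#' @param gamma_haploid log-scale haploid offset (0 disables the effect).
#' @param shape Gamma shape of the carbon noise (larger is tighter). The
#'   default of 1 (residual coefficient of variation 1) matches the order
#'   of the relative prediction errors seen in cross-study carbon
#'   compilations, where biological and methodological scatter is of the
#'   same magnitude as the quota itself.
#' @param n_points number of training points.
#' @param volume_range cell-volume range, um^3 (log-uniform sampling).
#' @param include_ploidy attach a `ploidy` column and the haploid effect.
#' @param prop_haploid expected haploid share when `include_ploidy`.
#' @param noise_free bypass the Gamma noise.
#' @param seed integer seed.
#' @return A data frame of training points (`taxon`, `volume_um3`,
#'   `carbon_pg`, `ploidy` if requested, `source`) with the generating
#'   truth attached as `attr(, "truth")`.
#' @examples
#' pts <- gen_allometric_taxa(n_points = 100, seed = 1)
#' attr(pts, "truth")$beta
#' @export
gen_allometric_taxa <- function(alpha = log(0.5), beta = 0.72, gamma_haploid = 0,
                                shape = 1, n_points = 42,
                                volume_range = c(10, 1000),
                                include_ploidy = gamma_haploid != 0,
                                prop_haploid = 0.3, noise_free = FALSE,
                                seed = 1L) {
  stopifnot(shape > 0, beta > 0, beta < 2, n_points >= 3,
            volume_range[1] > 0, volume_range[2] > volume_range[1])
  out <- with_seed(seed, {
    v <- exp(runif(n_points, log(volume_range[1]), log(volume_range[2])))
    hap <- if (include_ploidy) {
      h <- rbinom(n_points, 1, prop_haploid)
      # both classes must be represented for the one-hot fit to be defined
      if (all(h == 0)) h[1] <- 1L
      if (all(h == 1)) h[1] <- 0L
      h
    } else rep(0L, n_points)
    mu <- exp(alpha + beta * log(v) + gamma_haploid * hap)
    carbon <- if (noise_free) mu else rgamma(n_points, shape = shape, scale = mu / shape)
    data.frame(taxon = sprintf("Synthetic taxon %02d HET",
                               1 + (seq_len(n_points) - 1L) %% 10),
               volume_um3 = v, carbon_pg = carbon,
               ploidy = ifelse(hap == 1, "haploid", "diploid"),
               source = "synthetic", stringsAsFactors = FALSE)
  })
  if (!include_ploidy) out$ploidy <- NULL
  attr(out, "truth") <- list(alpha = alpha, beta = beta,
                             gamma_haploid = gamma_haploid, shape = shape,
                             seed = as.integer(seed))
  out
}

#' Generate an abundance field with realistic sampling structure
#'
#' Stations are placed with a northern-hemisphere bias, depths skewed
#' toward the upper 50 m, and months skewed toward summer, mirroring the
#' sampling biases of real compilations. A fraction of sampling events
#' revisit an earlier station's position, depth level and month, emulating
#' the time-series and repeat-transect structure of real datasets (which is
#' what makes gridding aggregate). Per taxon, abundance is log-normal with
#' structural zeros (absences); zero rows are retained so gridding sees
#' true absences.
#'
#' @param n_stations number of station/depth/date sampling events.
#' @param taxa character vector of taxon names to populate.
#' @param seed integer seed.
#' @param mean_log_abundance,sd_log_abundance log-normal abundance
#'   parameters (natural log, cells per litre).
#' @param p_present probability a taxon is present at a station.
#' @param depth_max maximum sampled depth, m.
#' @param p_revisit fraction of sampling events that re-occupy an earlier
#'   event's grid position (time-series / repeat-transect structure).
#' @return A data frame of abundance observations (`lat`, `lon`, `depth`,
#'   `year`, `month`, `taxon`, `abundance`, `method`, `source`) with the
#'   generation parameters attached as `attr(, "truth")`.
#' @export
gen_abundance_field <- function(n_stations = 100,
                                taxa = c("Emiliania huxleyi HET",
                                         "Rhabdosphaera clavigera HET",
                                         "Syracosphaera pulchra HOL"),
                                seed = 1L, mean_log_abundance = log(5000),
                                sd_log_abundance = 1.2, p_present = 0.7,
                                depth_max = 275, p_revisit = 0.3) {
  stopifnot(n_stations >= 1, length(taxa) >= 1,
            p_revisit >= 0, p_revisit < 1)
  out <- with_seed(seed, {
    lat <- pmin(89.99, pmax(-89.99, rnorm(n_stations, 25, 28)))
    lon <- runif(n_stations, -180, 180)
    # ~75% of casts in the upper 50 m, the remainder spread to depth_max
    shallow <- runif(n_stations) < 0.75
    depth <- ifelse(shallow, runif(n_stations, 0, 50),
                    runif(n_stations, 50, depth_max))
    year <- sample(1964:2019, n_stations, replace = TRUE)
    month <- sample(1:12, n_stations, replace = TRUE,
                    prob = c(2, 2, 3, 4, 6, 8, 9, 8, 6, 4, 3, 2))
    if (n_stations > 1 && p_revisit > 0) {
      revisit <- which(runif(n_stations) < p_revisit & seq_len(n_stations) > 1)
      src <- vapply(revisit, function(i) sample.int(i - 1L, 1L), integer(1L))
      lat[revisit] <- lat[src]; lon[revisit] <- lon[src]
      depth[revisit] <- depth[src]; year[revisit] <- year[src]
      month[revisit] <- month[src]
    }
    method <- sample(c("SEM", "LM"), n_stations, replace = TRUE, prob = c(0.7, 0.3))
    rows <- lapply(seq_along(taxa), function(k) {
      present <- runif(n_stations) < p_present
      ab <- ifelse(present,
                   rlnorm(n_stations, mean_log_abundance, sd_log_abundance), 0)
      data.frame(lat = lat, lon = lon, depth = depth, year = year,
                 month = month, taxon = taxa[k], abundance = ab,
                 method = method, source = "synthetic",
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  rownames(out) <- NULL
  attr(out, "truth") <- list(n_stations = n_stations, taxa = taxa,
                             mean_log_abundance = mean_log_abundance,
                             sd_log_abundance = sd_log_abundance,
                             p_present = p_present, seed = as.integer(seed))
  out
}
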