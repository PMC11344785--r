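#' Pipeline configuration
#'
#' Collects every tunable knob of the trait-synthesis pipeline in one
#' validated object that is serialised into output manifests.
#'
#' @param master_seed master seed; all per-task seeds derive from it via
#'   [derive_seed()], so results do not depend on processing order.
#' @param R replicates per reconstructed study report.
#' @param R_out replicates in merged per-taxon sets.
#' @param B bootstrap refits in allometric ensembles.
#' @param fold_threshold LM/SEM disagreement ratio above which SEM sizes
#'   are discarded (see [merge_lm_sem()]).
#' @param rarity_threshold minimum global occurrences for a taxon to be
#'   modelled (see [filter_rare()]).
#' @param truncation truncation rule for normal reconstruction
#'   (`"reject"` or `"clip"`).
#' @param n_assumed assumed sample size behind SD-only reports.
#' @param ci_probs percentile CI bounds.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(master_seed = 1L, R = 10000, R_out = 10000,
                            B = 1000, fold_threshold = 5,
                            rarity_threshold = 20,
                            truncation = c("reject", "clip"),
                            n_assumed = 3, ci_probs = c(0.025, 0.975)) {
  truncation <- match.arg(truncation)
  stopifnot(R >= 1, R_out >= 1, B >= 1, fold_threshold > 1,
            rarity_threshold >= 0, n_assumed >= 1,
            length(ci_probs) == 2L, ci_probs[1] < ci_probs[2],
            all(ci_probs > 0 & ci_probs < 1))
  structure(list(master_seed = as.integer(master_seed), R = R, R_out = R_out,
                 B = B, fold_threshold = fold_threshold,
                 rarity_threshold = rarity_threshold, truncation = truncation,
                 n_assumed = n_assumed, ci_probs = ci_probs),
            class = "pipeline_config")
}

reconstruct_and_merge <- function(msmts, variable, config, context_pool = list()) {
  taxon <- msmts[[1L]]$taxon
  sets <- lapply(msmts, function(m)
    reconstruct(m, R = config$R,
                seed = derive_seed(config$master_seed, "reconstruct",
                                   taxon, variable, m$source, m$method),
                context_pool = context_pool,
                truncation = config$truncation, n_assumed = config$n_assumed))
  merge_replicates(sets, R_out = config$R_out,
                   seed = derive_seed(config$master_seed, "merge", taxon, variable),
                   probs = config$ci_probs)
}

#' Run the trait-synthesis pipeline for a single taxon
#'
#' Produces the taxon's trait bundle: a merged cell-volume replicate set
#' (LM and SEM sources merged under the fold rule, or inherited from
#' associated HET phases for haploid-phase taxa without measurements), and
#' POC/PIC quota replicate sets from the direct branch when the taxon has
#' direct carbon measurements, else from the allometric branch. The two
#' branches are exclusive per trait and the bundle records which fired.
#'
#' @param taxon canonical name (already resolved, not excluded, not rare).
#' @param inputs a list with elements `size_measurements`,
#'   `poc_measurements`, `pic_measurements` (named lists, taxon -> list of
#'   [measurement()]), `poc_model` and `pic_model` (fitted
#'   `"allometric_model"` objects), and optionally `het_sizes` (named list
#'   taxon -> [replicate_set()]) and `registry` (a [taxon_registry()], for
#'   haploid-phase size fallback).
#' @param config a [pipeline_config()].
#' @return A list of class `"taxon_bundle"`: `taxon`, `ploidy`, `volume`,
#'   `poc`, `pic` (each a [replicate_set()] with a `"merged_estimate"` in
#'   the matching `*_estimate` slot) and `branches` (named character,
#'   `"direct"`/`"allometric"`/`"het_association"`).
#' @export
run_taxon <- function(taxon, inputs, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  ploidy <- assign_ploidy(phase_of(taxon))
  branches <- c(volume = NA_character_, poc = NA_character_, pic = NA_character_)

  size_ms <- inputs$size_measurements[[taxon]]
  pool <- unlist(lapply(inputs$size_measurements, identity), recursive = FALSE)
  if (!is.null(size_ms) && length(size_ms) > 0L) {
    by_lm <- Filter(function(m) m$method == "LM", size_ms)
    by_sem <- Filter(function(m) m$method == "SEM", size_ms)
    other <- Filter(function(m) !m$method %in% c("LM", "SEM"), size_ms)
    if (length(by_lm) > 0L && length(by_sem) > 0L) {
      lm_set <- reconstruct_and_merge(by_lm, "volume_um3", config, pool)$set
      sem_set <- reconstruct_and_merge(by_sem, "volume_um3", config, pool)$set
      vol_set <- merge_lm_sem(lm_set, sem_set,
                              fold_threshold = config$fold_threshold,
                              R_out = config$R_out,
                              seed = derive_seed(config$master_seed, "merge_lm_sem", taxon))
      if (length(other) > 0L) {
        rest <- reconstruct_and_merge(other, "volume_um3", config, pool)$set
        vol_set <- merge_replicates(list(vol_set, rest), R_out = config$R_out,
                                    seed = derive_seed(config$master_seed,
                                                       "merge_all_sizes", taxon),
                                    probs = config$ci_probs)$set
      }
    } else {
      vol_set <- reconstruct_and_merge(size_ms, "volume_um3", config, pool)$set
    }
    branches["volume"] <- "direct"
  } else if (ploidy == "haploid" && !is.null(inputs$registry)) {
    assoc <- het_associations(taxon, inputs$registry)
    vol_set <- hol_size_from_het(taxon, inputs$het_sizes, assoc)
    branches["volume"] <- "het_association"
  } else {
    stop(sprintf("no size estimate obtainable for '%s'", taxon), call. = FALSE)
  }
  vol_est <- summary(vol_set, probs = config$ci_probs)

  carbon_branch <- function(trait, variable, model, direct_ms) {
    if (!is.null(direct_ms) && length(direct_ms) > 0L) {
      mm <- reconstruct_and_merge(direct_ms, variable, config,
                                  unlist(lapply(inputs[[paste0(trait, "_measurements")]],
                                                identity), recursive = FALSE))
      list(set = mm$set, estimate = mm$estimate, branch = "direct")
    } else {
      if (is.null(model))
        stop(sprintf("no direct %s data and no allometric model for '%s'",
                     toupper(trait), taxon), call. = FALSE)
      qs <- predict_quota(model, vol_set,
                          ploidy = if (model$response == "PIC") ploidy else NULL,
                          R = config$R_out,
                          seed = derive_seed(config$master_seed, "predict", taxon, trait))
      list(set = qs, estimate = summary(qs, probs = config$ci_probs),
           branch = "allometric")
    }
  }
  poc <- carbon_branch("poc", "poc_pg", inputs$poc_model,
                       inputs$poc_measurements[[taxon]])
  pic <- carbon_branch("pic", "pic_pg", inputs$pic_model,
                       inputs$pic_measurements[[taxon]])
  branches["poc"] <- poc$branch
  branches["pic"] <- pic$branch

  structure(list(taxon = taxon, ploidy = ploidy,
                 volume = vol_set, volume_estimate = vol_est,
                 poc = poc$set, poc_estimate = poc$estimate,
                 pic = pic$set, pic_estimate = pic$estimate,
                 branches = branches,
                 flagged = isTRUE(attr(vol_set, "flagged"))),
            class = "taxon_bundle")
}

#' @export
print.taxon_bundle <- function(x, ...) {
  cat(sprintf("<taxon_bundle> %s (%s)\n", x$taxon, x$ploidy))
  cat(sprintf("  volume [%s]: %.4g um^3 [%.4g, %.4g]\n", x$branches["volume"],
              x$volume_estimate$mean, x$volume_estimate$ci_low, x$volume_estimate$ci_high))
  cat(sprintf("  POC [%s]: %.4g pg C [%.4g, %.4g]\n", x$branches["poc"],
              x$poc_estimate$mean, x$poc_estimate$ci_low, x$poc_estimate$ci_high))
  cat(sprintf("  PIC [%s]: %.4g pg C [%.4g, %.4g]\n", x$branches["pic"],
              x$pic_estimate$mean, x$pic_estimate$ci_low, x$pic_estimate$ci_high))
  invisible(x)
}

#' Run the full pipeline across taxa and grid the stocks
#'
#' Applies [run_taxon()] to every taxon in the common set, converts the
#' abundance table into stocks with the resulting quota sets, grids them,
#' and assembles a manifest recording configuration, branch choices,
#' flagged taxa and per-taxon failures (a failing taxon is logged and
#' skipped; the batch aborts only if every taxon fails).
#'
#' @param inputs as in [run_taxon()], plus `abundance` (observation data
#'   frame) and optionally `occurrence_counts` (named taxon counts for
#'   rarity filtering; taxa present in `abundance` are used otherwise).
#' @param config a [pipeline_config()].
#' @return A list: `bundles` (named list of `"taxon_bundle"`), `summary`
#'   (per-taxon trait summary data frame), `grid` (gridded stock data
#'   frame), `manifest` (list: config, branches, flagged, skipped).
#' @export
run_all <- function(inputs, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"), is.data.frame(inputs$abundance))
  vr <- validate_records(inputs$abundance, "abundance")
  if (nrow(vr) > 0L)
    stop(sprintf("abundance table failed validation (%d violations)", nrow(vr)),
         call. = FALSE)
  counts <- inputs$occurrence_counts
  if (is.null(counts)) counts <- table(inputs$abundance$taxon)
  common <- filter_rare(as.list(counts), threshold = config$rarity_threshold)$common
  excl <- if (!is.null(inputs$registry)) exclusion_list(inputs$registry)
          else exclusion_list()
  common <- setdiff(common, excl)
  if (length(common) == 0L) stop("no common taxa to process", call. = FALSE)

  bundles <- list(); skipped <- list()
  for (tx in common) {
    b <- tryCatch(run_taxon(tx, inputs, config), error = function(e) e)
    if (inherits(b, "error")) skipped[[tx]] <- conditionMessage(b)
    else bundles[[tx]] <- b
  }
  if (length(bundles) == 0L)
    stop("all taxa failed; first reason: ", skipped[[1L]], call. = FALSE)

  summary_df <- do.call(rbind, lapply(bundles, function(b) {
    data.frame(taxon = b$taxon, ploidy = b$ploidy,
               volume_mean = b$volume_estimate$mean,
               volume_lo = b$volume_estimate$ci_low,
               volume_hi = b$volume_estimate$ci_high,
               poc_mean = b$poc_estimate$mean,
               poc_lo = b$poc_estimate$ci_low, poc_hi = b$poc_estimate$ci_high,
               pic_mean = b$pic_estimate$mean,
               pic_lo = b$pic_estimate$ci_low, pic_hi = b$pic_estimate$ci_high,
               volume_branch = unname(b$branches["volume"]),
               poc_branch = unname(b$branches["poc"]),
               pic_branch = unname(b$branches["pic"]),
               flagged = b$flagged, stringsAsFactors = FALSE)
  }))
  rownames(summary_df) <- NULL
  summary_df <- summary_df[order(summary_df$taxon), , drop = FALSE]

  ab <- inputs$abundance[inputs$abundance$taxon %in% names(bundles), , drop = FALSE]
  gridded <- grid_observations(ab,
                               poc_quotas = lapply(bundles, `[[`, "poc"),
                               pic_quotas = lapply(bundles, `[[`, "pic"),
                               probs = config$ci_probs, validate = FALSE)
  manifest <- list(config = unclass(config),
                   n_taxa = length(bundles),
                   branches = lapply(bundles, function(b) as.list(b$branches)),
                   flagged = names(bundles)[vapply(bundles, `[[`, logical(1L), "flagged")],
                   skipped = skipped,
                   excluded = intersect(excl, names(counts)),
                   n_observations_in = nrow(ab),
                   n_gridded_rows = nrow(gridded))
  list(bundles = bundles, summary = summary_df, grid = gridded,
       manifest = manifest)
}
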