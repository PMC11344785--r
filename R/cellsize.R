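#' Cell-size geometry and LM/SEM merging
#'
#' Cell volumes are derived from linear measurements under simple solids:
#' most coccospheres are treated as spheres, a configured few (e.g.
#' *Syracosphaera aurisinae* HET, *Calciopappus caudatus* HET) as prolate
#' spheroids. Scanning-electron-microscopy (SEM) images show only the
#' coccosphere exterior, so SEM-derived cell sizes come from the coccosphere
#' either through a taxon-specific volume fraction (cell volume as a share
#' of coccosphere volume, calibrated against light microscopy) or by
#' subtracting twice the coccolith thickness from the coccosphere diameter.
#'
#' @name cellsize
NULL

#' Volume of a spherical cell
#'
#' @param d diameter, um, `> 0` (vectorised).
#' @return Volume in um^3, `pi * d^3 / 6`.
#' @export
volume_sphere <- function(d) {
  if (any(!is.finite(d) | d <= 0)) stop("'d' must be > 0", call. = FALSE)
  pi * d^3 / 6
}

#' Volume of a prolate-spheroid cell
#'
#' @param length long axis, um.
#' @param width short axis, um, `0 < width <= length`.
#' @return Volume in um^3, `pi * length * width^2 / 6`.
#' @export
volume_prolate <- function(length, width) {
  if (any(!is.finite(length) | !is.finite(width) | width <= 0))
    stop("dimensions must be positive", call. = FALSE)
  if (any(width > length)) stop("'width' must be <= 'length'", call. = FALSE)
  pi * length * width^2 / 6
}

#' Equivalent spherical diameter of a volume
#'
#' @param volume um^3, `> 0`.
#' @return Diameter of the sphere with the same volume, um.
#' @export
esd_from_volume <- function(volume) {
  if (any(!is.finite(volume) | volume <= 0)) stop("'volume' must be > 0", call. = FALSE)
  (6 * volume / pi)^(1 / 3)
}

#' Cell diameter from coccosphere diameter and coccolith thickness
#'
#' The cell sits inside its coccosphere; its diameter is estimated by
#' subtracting twice the coccolith thickness from the measured coccosphere
#' diameter.
#'
#' @param cocco_d coccosphere diameter, um.
#' @param coccolith_thickness coccolith thickness, um, `>= 0`.
#' @return `cocco_d - 2 * coccolith_thickness`; an error if the result is
#'   not positive (thickness inconsistent with the coccosphere).
#' @export
cell_diameter_from_coccosphere <- function(cocco_d, coccolith_thickness) {
  if (any(!is.finite(cocco_d) | cocco_d <= 0)) stop("'cocco_d' must be > 0", call. = FALSE)
  if (any(!is.finite(coccolith_thickness) | coccolith_thickness < 0))
    stop("'coccolith_thickness' must be >= 0", call. = FALSE)
  out <- cocco_d - 2 * coccolith_thickness
  if (any(out <= 0))
    stop("coccolith thickness inconsistent with coccosphere diameter", call. = FALSE)
  out
}

#' Cell volume as a fraction of coccosphere volume
#'
#' Taxon-specific fractions (calibrated from paired light-microscopy cell
#' and coccosphere measurements) range roughly from 0.3 to 0.9; a single
#' fixed ratio across taxa can be off several-fold.
#'
#' @param cocco_volume coccosphere volume, um^3, `> 0`.
#' @param fraction share of coccosphere volume occupied by the cell, in
#'   `(0, 1]`.
#' @return `fraction * cocco_volume`.
#' @export
cell_volume_from_fraction <- function(cocco_volume, fraction) {
  if (any(!is.finite(cocco_volume) | cocco_volume <= 0))
    stop("'cocco_volume' must be > 0", call. = FALSE)
  if (any(!is.finite(fraction) | fraction <= 0 | fraction > 1))
    stop("'fraction' must be in (0, 1]", call. = FALSE)
  fraction * cocco_volume
}

#' Merge light-microscopy and SEM cell-size replicate sets
#'
#' LM observes the cell directly and is the more accurate method; SEM sizes
#' are derived from the coccosphere. Both are merged to maximise coverage,
#' unless their median cell sizes disagree more than `fold_threshold`-fold,
#' in which case only the LM set is used and the taxon is flagged (attribute
#' `"flagged"` on the returned set).
#'
#' @param lm,sem [replicate_set()] objects for the same taxon and variable.
#' @param fold_threshold disagreement ratio above which SEM is discarded
#'   (default 5).
#' @param R_out,seed merge parameters passed to [merge_replicates()].
#' @return A [replicate_set()]; `attr(, "flagged")` is `TRUE` when the SEM
#'   set was discarded.
#' @export
merge_lm_sem <- function(lm, sem, fold_threshold = 5,
                         R_out = length(lm$values) + length(sem$values),
                         seed = 1L) {
  stopifnot(inherits(lm, "replicate_set"), inherits(sem, "replicate_set"))
  if (!identical(lm$taxon, sem$taxon) || !identical(lm$variable, sem$variable))
    stop("LM and SEM sets must share taxon and variable", call. = FALSE)
  med <- c(median(lm$values), median(sem$values))
  if (any(med == 0)) stop("zero median cell size", call. = FALSE)
  ratio <- max(med) / min(med)
  if (ratio > fold_threshold) {
    out <- lm
    attr(out, "flagged") <- TRUE
    attr(out, "fold_ratio") <- ratio
    return(out)
  }
  out <- merge_replicates(list(lm, sem), R_out = R_out, seed = seed)$set
  attr(out, "flagged") <- FALSE
  attr(out, "fold_ratio") <- ratio
  out
}

#' Impute a haploid-phase cell size from associated diploid phases
#'
#' Haploid and diploid life-cycle phases of a species tend to have similar
#' cell sizes, so a holococcolith-bearing (or other haploid-phase) taxon
#' without size measurements inherits the size distribution of its
#' associated HET phase(s): the single associated set is reused directly,
#' and with multiple associations the replicate-wise mean is taken (sets are
#' paired by replicate index, which is meaningful under the shared
#' derived-seed scheme and requires equal lengths).
#'
#' @param hol_taxon canonical haploid-phase name.
#' @param het_estimates named list, HET canonical -> [replicate_set()].
#' @param associations character vector of associated HET canonicals (e.g.
#'   from [het_associations()]).
#' @return A [replicate_set()] for `hol_taxon`.
#' @export
hol_size_from_het <- function(hol_taxon, het_estimates, associations) {
  avail <- associations[associations %in% names(het_estimates)]
  if (length(avail) == 0L)
    stop(sprintf("no associated diploid phase with a size estimate for '%s'",
                 hol_taxon), call. = FALSE)
  sets <- het_estimates[avail]
  lens <- vapply(sets, function(s) length(s$values), integer(1L))
  if (length(unique(lens)) != 1L)
    stop("associated replicate sets must have equal length for pairing", call. = FALSE)
  vals <- if (length(sets) == 1L) sets[[1L]]$values
  else rowMeans(do.call(cbind, lapply(sets, `[[`, "values")))
  replicate_set(hol_taxon, sets[[1L]]$variable, vals,
                provenance = unique(unlist(lapply(sets, `[[`, "provenance"))),
                seed = sets[[1L]]$seed)
}

#' Taxa treated as prolate spheroids
#'
#' All taxa are assumed spherical except a small configured list measured as
#' prolate spheroids.
#'
#' @return Character vector of canonical names.
#' @export
prolate_taxa <- function() {
  c("Syracosphaera aurisinae HET", "Calciopappus caudatus HET")
}
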