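#' Construct a single-study trait measurement
#'
#' A `measurement` records one study's report of one trait (cell volume,
#' cellular POC or PIC, or a linear dimension) for one taxonomic unit, in
#' whichever of five summary modes the source used: raw per-cell values, a
#' mean with standard error, a mean with standard deviation, a min-max
#' range, or a bare mean. Downstream reconstruction dispatches on `mode`.
#'
#' @param taxon canonical taxon name ("Genus species" plus life-cycle
#'   suffix, e.g. `"Rhabdosphaera clavigera HET"`).
#' @param variable one of `"volume_um3"`, `"poc_pg"`, `"pic_pg"`,
#'   `"diameter_um"`.
#' @param mode reporting mode: `"raw"`, `"mean_se"`, `"mean_sd"`,
#'   `"min_max"`, or `"mean_only"`.
#' @param raw_values numeric vector of strictly positive raw values
#'   (`mode = "raw"` only).
#' @param mean,sd,se,min,max summary statistics as reported; which are
#'   required depends on `mode`.
#' @param n sample size behind the summary, if reported.
#' @param method measurement method: `"LM"`, `"SEM"`, `"morphometric"`, or
#'   `"culture"`.
#' @param source citation key for provenance tracking.
#' @return An object of class `"measurement"`.
#' @examples
#' measurement("Gephyrocapsa oceanica HET", "volume_um3", "mean_se",
#'             mean = 100, se = 12, method = "culture", source = "a1990")
#' @export
measurement <- function(taxon, variable = c("volume_um3", "poc_pg", "pic_pg", "diameter_um"),
                        mode = c("raw", "mean_se", "mean_sd", "min_max", "mean_only"),
                        raw_values = NULL, mean = NULL, sd = NULL, se = NULL,
                        min = NULL, max = NULL, n = NULL,
                        method = c("LM", "SEM", "morphometric", "culture"),
                        source = "unknown") {
  variable <- match.arg(variable)
  mode <- match.arg(mode)
  method <- match.arg(method)
  chk_pos <- function(x, nm, strict = TRUE) {
    if (!is.null(x) && (!is.numeric(x) || any(!is.finite(x)) ||
                        any(if (strict) x <= 0 else x < 0)))
      stop(sprintf("'%s' must be finite and %s", nm,
                   if (strict) "strictly positive" else "non-negative"), call. = FALSE)
  }
  switch(mode,
    raw = if (is.null(raw_values) || length(raw_values) == 0L)
      stop("mode 'raw' requires non-empty 'raw_values'", call. = FALSE),
    mean_se = if (is.null(mean) || is.null(se))
      stop("mode 'mean_se' requires 'mean' and 'se'", call. = FALSE),
    mean_sd = if (is.null(mean) || is.null(sd))
      stop("mode 'mean_sd' requires 'mean' and 'sd'", call. = FALSE),
    min_max = if (is.null(min) || is.null(max))
      stop("mode 'min_max' requires 'min' and 'max'", call. = FALSE),
    mean_only = if (is.null(mean))
      stop("mode 'mean_only' requires 'mean'", call. = FALSE)
  )
  chk_pos(raw_values, "raw_values")
  chk_pos(mean, "mean")
  chk_pos(sd, "sd", strict = FALSE)
  chk_pos(se, "se", strict = FALSE)
  chk_pos(min, "min")
  chk_pos(max, "max")
  if (!is.null(min) && !is.null(max) && max < min)
    stop("'max' must be >= 'min'", call. = FALSE)
  if (!is.null(min) && !is.null(mean) && !is.null(max) &&
      (mean < min || mean > max))
    stop("'mean' must lie within [min, max]", call. = FALSE)
  if (!is.null(n) && (n < 1 || n != round(n)))
    stop("'n' must be a positive integer", call. = FALSE)
  structure(list(taxon = taxon, variable = variable, mode = mode,
                 raw_values = raw_values, mean = mean, sd = sd, se = se,
                 min = min, max = max, n = n, method = method, source = source),
            class = "measurement")
}

#' @export
print.measurement <- function(x, ...) {
  stat <- switch(x$mode,
    raw = sprintf("%d raw values", length(x$raw_values)),
    mean_se = sprintf("mean %.4g, SE %.4g", x$mean, x$se),
    mean_sd = sprintf("mean %.4g, SD %.4g", x$mean, x$sd),
    min_max = sprintf("range [%.4g, %.4g]", x$min, x$max),
    mean_only = sprintf("mean %.4g (no spread)", x$mean))
  cat(sprintf("<measurement> %s %s [%s/%s]: %s\n",
              x$taxon, x$variable, x$method, x$source, stat))
  invisible(x)
}

#' Construct a replicate set
#'
#' A replicate set is the pipeline's uncertainty currency: a sample of
#' possible values of a trait for one taxon, reconstructed from one or more
#' study reports. All values are constrained non-negative (trait values are
#' physical quantities) and the seed used to generate them is recorded so
#' that any set can be regenerated.
#'
#' @param taxon,variable as in [measurement()].
#' @param values numeric vector of non-negative replicate values.
#' @param provenance character vector of contributing source keys.
#' @param seed integer seed recorded for reproducibility (`NA` for
#'   deterministic constructions).
#' @return An object of class `"replicate_set"`.
#' @seealso [reconstruct()], [merge_replicates()]
#' @export
replicate_set <- function(taxon, variable, values, provenance = character(), seed = NA_integer_) {
  if (length(values) == 0L) stop("replicate set must be non-empty", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("replicate values must be finite and >= 0", call. = FALSE)
  structure(list(taxon = taxon, variable = variable, values = as.numeric(values),
                 provenance = as.character(provenance), seed = seed),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("<replicate_set> %s %s: R=%d, mean %.4g [%.4g, %.4g], %d source(s)\n",
              x$taxon, x$variable, length(x$values), mean(x$values),
              min(x$values), max(x$values), length(x$provenance)))
  invisible(x)
}

#' Summarise a replicate set as a merged estimate
#'
#' Computes the mean and a percentile confidence interval of a replicate
#' set, the form in which per-taxon traits are reported.
#'
#' @param object a [replicate_set()].
#' @param probs lower/upper percentile bounds (default the central 95%).
#' @param n_studies number of contributing studies recorded in the output
#'   (defaults to the number of provenance keys, or 1).
#' @param ... unused.
#' @return A `"merged_estimate"` list with fields `mean`, `ci_low`,
#'   `ci_high`, `n_replicates`, `n_studies`.
#' @export
summary.replicate_set <- function(object, probs = c(0.025, 0.975),
                                  n_studies = max(1L, length(object$provenance)), ...) {
  stopifnot(length(probs) == 2L, probs[1] < probs[2])
  q <- unname(quantile(object$values, probs = probs, names = FALSE, type = 7))
  structure(list(mean = mean(object$values), ci_low = q[1], ci_high = q[2],
                 n_replicates = length(object$values), n_studies = n_studies),
            class = "merged_estimate")
}

#' @export
print.merged_estimate <- function(x, ...) {
  cat(sprintf("<merged_estimate> mean %.4g, CI [%.4g, %.4g] (R=%d, %d studies)\n",
              x$mean, x$ci_low, x$ci_high, x$n_replicates, x$n_studies))
  invisible(x)
}
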