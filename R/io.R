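#' Readers and writers for the long-format interchange files
#'
#' Measurements travel as long-format CSV with a `mode` column; replicate
#' sets as long-format CSV (taxon, variable, replicate_id, value); trait
#' summaries and gridded stocks as flat CSV. All files are plain UTF-8
#' text.
#'
#' @name io
NULL

num_or_null <- function(x) if (is.na(x)) NULL else as.numeric(x)

#' Read measurements from long-format CSV
#'
#' Expected columns: `taxon`, `variable`, `mode`, `method`, `source`, plus
#' the statistics for each mode (`mean`, `sd`, `se`, `min`, `max`, `n`,
#' empty where inapplicable). Raw-value reports occupy several rows sharing
#' `taxon`/`variable`/`source` with mode `raw` and a `value` column.
#'
#' @param path CSV file path.
#' @param registry optional [taxon_registry()]; when supplied, taxon names
#'   are resolved to canonical form and unknown names are an error.
#' @return A named list, taxon -> list of [measurement()] objects.
#' @export
read_measurements <- function(path, registry = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon", "variable", "mode", "method", "source")
  if (!all(need %in% names(df)))
    stop(sprintf("measurement CSV must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  if (!is.null(registry))
    df$taxon <- vapply(df$taxon, resolve_name, character(1L), registry = registry)
  for (cn in c("mean", "sd", "se", "min", "max", "n", "value"))
    if (!cn %in% names(df)) df[[cn]] <- NA_real_
  key <- paste(df$taxon, df$variable, df$source, df$mode, df$method, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    rows <- df[key == k, , drop = FALSE]
    r1 <- rows[1L, ]
    m <- if (r1$mode == "raw")
      measurement(r1$taxon, r1$variable, "raw", raw_values = rows$value,
                  method = r1$method, source = r1$source)
    else
      measurement(r1$taxon, r1$variable, r1$mode,
                  mean = num_or_null(r1$mean), sd = num_or_null(r1$sd),
                  se = num_or_null(r1$se), min = num_or_null(r1$min),
                  max = num_or_null(r1$max),
                  n = if (is.na(r1$n)) NULL else as.integer(r1$n),
                  method = r1$method, source = r1$source)
    out[[r1$taxon]] <- c(out[[r1$taxon]], list(m))
  }
  out
}

#' Write replicate sets to long-format CSV
#'
#' @param sets list of [replicate_set()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_replicates <- function(sets, path) {
  if (inherits(sets, "replicate_set")) sets <- list(sets)
  df <- do.call(rbind, lapply(sets, function(s)
    data.frame(taxon = s$taxon, variable = s$variable,
               replicate_id = seq_along(s$values), value = s$values,
               stringsAsFactors = FALSE)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read replicate sets back from long-format CSV
#'
#' @param path CSV written by [write_replicates()].
#' @return A named list, "taxon|variable" -> [replicate_set()].
#' @export
read_replicates <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  key <- paste(df$taxon, df$variable, sep = "|")
  out <- list()
  for (k in unique(key)) {
    rows <- df[key == k, , drop = FALSE]
    rows <- rows[order(rows$replicate_id), , drop = FALSE]
    out[[k]] <- replicate_set(rows$taxon[1L], rows$variable[1L], rows$value)
  }
  out
}

#' Read abundance observations from long-format CSV
#'
#' Expected columns: `lat`, `lon`, `depth`, `date` (ISO `YYYY-MM-DD` or
#' `YYYY-MM`) or `year`+`month`, `taxon`, `abundance`, `method`, `source`.
#'
#' @param path CSV file path.
#' @param registry optional [taxon_registry()] for name resolution.
#' @return A validated observation data frame (see [validate_records()]).
#' @export
read_abundance <- function(path, registry = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("date" %in% names(df) && !all(c("year", "month") %in% names(df))) {
    df$year <- as.integer(substr(df$date, 1, 4))
    df$month <- as.integer(substr(df$date, 6, 7))
    df$date <- NULL
  }
  if (!is.null(registry))
    df$taxon <- vapply(df$taxon, resolve_name, character(1L), registry = registry)
  vr <- validate_records(df, "abundance")
  if (nrow(vr) > 0L)
    stop(sprintf("abundance file failed validation: %d violation(s); first: row %s %s (%s)",
                 nrow(vr), vr$row[1], vr$column[1], vr$rule[1]), call. = FALSE)
  df
}

#' Write a trait summary or gridded stock table to CSV
#'
#' @param df data frame (e.g. `run_all()$summary` or `run_all()$grid`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Literature morphometric size table
#'
#' Cell volumes for taxa whose size is known only from literature
#' morphometry (coccosphere dimensions minus twice the coccolith
#' thickness, converted to volume under a spherical or prolate-spheroid
#' shape). Rows without an SD carry only a mean and flow through the
#' SE-imputation path of [reconstruct()].
#'
#' @return Data frame with columns `taxon`, `vol_mean_um3`, `vol_sd_um3`
#'   (`NA` where unavailable), `shape`, `source`, `n_obs`.
#' @export
morphometric_size_table <- function() {
  read.csv(system.file("extdata", "morphometric_sizes.csv",
                       package = "coccotraits"),
           stringsAsFactors = FALSE)
}

#' Write a run manifest as JSON
#'
#' @param manifest the `manifest` element of [run_all()]'s result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
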