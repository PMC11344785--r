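#' Taxon registries: canonical names, synonyms, life-cycle associations
#'
#' Every downstream stage works on canonical taxonomic units: species-level
#' names carrying a coccolith-morphology suffix (HET, HOL, NANO, CER, POL)
#' that doubles as the life-cycle-phase label. The registry harmonises raw
#' names from heterogeneous sources against this canon: synonyms and known
#' misspellings map onto canonical names, sub-species and variety epithets
#' are stripped (no below-species resolution is attempted), and lookups are
#' case-insensitive and whitespace-normalised. Diacritics are not folded, so
#' genuinely foreign strings fail loudly rather than over-matching.
#'
#' @name taxonomy
NULL

PHASE_CODES <- c("HET", "HOL", "NANO", "CER", "POL")

normalize_name <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  # drop sub-species / variety / forma segments: epithet rank marker + name
  x <- gsub("\\b(subsp|ssp|var|f)\\.?\\s+\\S+\\s*", "", x)
  gsub("\\s+", " ", trimws(x))
}

#' Build a taxon registry
#'
#' @param synonyms named list `canonical -> character vector of synonyms`
#'   (misspellings included). A synonym mapping to two canonicals is a load
#'   error.
#' @param associations named list `haploid-phase canonical -> character
#'   vector of associated diploid-phase (HET) canonicals`, used for
#'   cell-size imputation of holococcolith-bearing phases.
#' @param families named list `family -> character vector of canonicals`.
#' @param exclusions character vector of canonicals excluded outright from
#'   all downstream stages (default: *Reticulofenestra sessilis* HET, which
#'   lives in obligate association with a diatom and whose carbon stocks
#'   cannot be attributed cleanly).
#' @return An object of class `"taxon_registry"`.
#' @seealso [load_registry()] to read the YAML interchange files,
#'   [resolve_name()], [exclusion_list()]
#' @export
taxon_registry <- function(synonyms = list(), associations = list(),
                           families = list(),
                           exclusions = "Reticulofenestra sessilis HET") {
  canonicals <- names(synonyms)
  if (anyDuplicated(canonicals))
    stop("duplicate canonical names in synonym map", call. = FALSE)
  syn_keys <- character(); syn_vals <- character()
  for (canon in canonicals) {
    for (s in synonyms[[canon]]) {
      k <- tolower(normalize_name(s))
      if (k %in% syn_keys && syn_vals[match(k, syn_keys)] != canon)
        stop(sprintf("synonym '%s' maps to both '%s' and '%s'",
                     s, syn_vals[match(k, syn_keys)], canon), call. = FALSE)
      syn_keys <- c(syn_keys, k); syn_vals <- c(syn_vals, canon)
    }
  }
  lookup <- c(setNames(canonicals, tolower(normalize_name(canonicals))),
              setNames(syn_vals, syn_keys))
  lookup <- lookup[!duplicated(names(lookup))]
  fam_of <- character()
  for (fam in names(families))
    fam_of[families[[fam]]] <- fam
  for (hap in names(associations)) {
    hets <- associations[[hap]]
    bad <- hets[vapply(hets, function(h) phase_of(h) %in% c("HOL", "CER", "POL"),
                       logical(1L))]
    if (length(bad) > 0L)
      stop(sprintf("association target(s) not diploid-phase: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(canonicals = canonicals, lookup = lookup,
                 associations = associations, family_of = fam_of,
                 exclusions = as.character(exclusions)),
            class = "taxon_registry")
}

#' @export
print.taxon_registry <- function(x, ...) {
  cat(sprintf("<taxon_registry> %d canonical units, %d lookup keys, %d associations, %d exclusions\n",
              length(x$canonicals), length(x$lookup), length(x$associations),
              length(x$exclusions)))
  invisible(x)
}

#' Load a taxon registry from YAML interchange files
#'
#' Reads the three classification files (each a UTF-8 YAML mapping of
#' lists): synonyms (`canonical: [synonym, ...]`), life-cycle associations
#' (`haploid canonical: [HET canonical, ...]`) and families
#' (`family: [canonical, ...]`).
#'
#' @param synonyms_file,associations_file,families_file paths;
#'   `associations_file` and `families_file` may be `NULL`.
#' @param exclusions passed through to [taxon_registry()].
#' @return A `"taxon_registry"`.
#' @examples
#' reg <- load_registry(
#'   system.file("extdata", "synonyms.yaml", package = "coccotraits"),
#'   system.file("extdata", "life_cycle_associations.yaml", package = "coccotraits"),
#'   system.file("extdata", "families.yaml", package = "coccotraits"))
#' resolve_name("Rhabdosphaera claviger HET", reg)
#' @export
load_registry <- function(synonyms_file, associations_file = NULL,
                          families_file = NULL,
                          exclusions = "Reticulofenestra sessilis HET") {
  syn <- yaml::read_yaml(synonyms_file)
  syn <- lapply(syn, function(x) as.character(unlist(x)))
  assoc <- if (!is.null(associations_file))
    lapply(yaml::read_yaml(associations_file), function(x) as.character(unlist(x)))
  else list()
  fam <- if (!is.null(families_file))
    lapply(yaml::read_yaml(families_file), function(x) as.character(unlist(x)))
  else list()
  taxon_registry(synonyms = syn, associations = assoc, families = fam,
                 exclusions = exclusions)
}

#' Resolve a raw taxon name to its canonical form
#'
#' @param raw_name non-empty string as it appears in a source table.
#' @param registry a [taxon_registry()].
#' @return The canonical name. Unknown names raise a condition of class
#'   `"coccotraits_unknown_name"` carrying the offending string in field
#'   `$name`, so callers can decide whether to extend the registry or reject
#'   the record.
#' @export
resolve_name <- function(raw_name, registry) {
  stopifnot(inherits(registry, "taxon_registry"))
  if (!is.character(raw_name) || length(raw_name) != 1L || !nzchar(trimws(raw_name)))
    stop("'raw_name' must be a non-empty string", call. = FALSE)
  key <- tolower(normalize_name(raw_name))
  hit <- registry$lookup[key]
  if (is.na(hit))
    stop(structure(class = c("coccotraits_unknown_name", "error", "condition"),
                   list(message = sprintf("unknown taxon name: '%s'", raw_name),
                        call = sys.call(-1), name = raw_name)))
  unname(hit)
}

#' Extract the coccolith-morphology phase code from a canonical name
#'
#' @param canonical_name canonical taxon name containing one of HET, HOL,
#'   NANO, CER, POL as a whole token (e.g. "Syracosphaera mediterranea HOL
#'   wettsteinii type").
#' @return The phase code string.
#' @export
phase_of <- function(canonical_name) {
  toks <- strsplit(canonical_name, "\\s+")[[1]]
  hit <- toks[toks %in% PHASE_CODES]
  if (length(hit) != 1L)
    stop(sprintf("cannot determine phase of '%s'", canonical_name), call. = FALSE)
  hit
}

#' Map a coccolith-morphology phase to a ploidy class
#'
#' Heterococcolith (HET) and nannolith (NANO) morphologies are treated as
#' diploid; ceratolith (CER), holococcolith (HOL) and polycrater (POL)
#' morphologies as haploid. Some cells deviate from this rule in nature, but
#' the label is what the inorganic-carbon allometry conditions on.
#'
#' @param phase one of `"HET"`, `"NANO"`, `"CER"`, `"HOL"`, `"POL"` (vectorised).
#' @return `"diploid"` or `"haploid"` per element.
#' @examples
#' assign_ploidy(c("HET", "POL"))
#' @export
assign_ploidy <- function(phase) {
  out <- ifelse(phase %in% c("HET", "NANO"), "diploid",
                ifelse(phase %in% c("CER", "HOL", "POL"), "haploid", NA_character_))
  if (anyNA(out))
    stop(sprintf("unrecognized phase code(s): %s",
                 paste(unique(phase[is.na(out)]), collapse = ", ")), call. = FALSE)
  out
}

#' Partition taxa into common and rare by global occurrence count
#'
#' Taxa observed fewer than `threshold` times globally are set aside: with
#' so few occurrences their trait estimates would be dominated by sampling
#' noise and their contribution to carbon stocks is negligible.
#'
#' @param occurrence_counts named integer vector or list, taxon -> count.
#' @param threshold minimum count to be kept (default 20; the cut is
#'   `count >= threshold`).
#' @return A list with character vectors `common` and `rare`; together they
#'   partition the input taxa.
#' @examples
#' filter_rare(c(A = 20, B = 19))
#' @export
filter_rare <- function(occurrence_counts, threshold = 20) {
  counts <- unlist(occurrence_counts)
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  list(common = names(counts)[counts >= threshold],
       rare = names(counts)[counts < threshold])
}

#' Hard-excluded taxa
#'
#' @param registry a [taxon_registry()]; `NULL` returns the default set.
#' @return Character vector of canonical names dropped before all
#'   downstream stages.
#' @export
exclusion_list <- function(registry = NULL) {
  if (is.null(registry)) return("Reticulofenestra sessilis HET")
  stopifnot(inherits(registry, "taxon_registry"))
  registry$exclusions
}

#' Associated diploid-phase units for a haploid-phase taxon
#'
#' @param taxon canonical haploid-phase (HOL/CER/POL) name.
#' @param registry a [taxon_registry()].
#' @return Character vector of associated HET canonicals (possibly empty).
#' @export
het_associations <- function(taxon, registry) {
  stopifnot(inherits(registry, "taxon_registry"))
  assoc <- registry$associations[[taxon]]
  if (is.null(assoc)) character() else assoc
}
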