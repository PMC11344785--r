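# Shared fixtures built in code: a small registry mirroring the packaged
# classification files, and convenience constructors.

make_registry <- function() {
  load_registry(
    system.file("extdata", "synonyms.yaml", package = "coccotraits"),
    system.file("extdata", "life_cycle_associations.yaml", package = "coccotraits"),
    system.file("extdata", "families.yaml", package = "coccotraits"))
}

const_set <- function(value, R = 100, taxon = "Test taxon HET",
                      variable = "volume_um3") {
  replicate_set(taxon, variable, rep(value, R), provenance = "fixture")
}

mk_obs <- function(lat, lon, depth, year = 2000, month = 6,
                   taxon = "Emiliania huxleyi HET", abundance = 100,
                   method = "SEM") {
  data.frame(lat = lat, lon = lon, depth = depth, year = year, month = month,
             taxon = taxon, abundance = abundance, method = method,
             source = "fixture", stringsAsFactors = FALSE)
}
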