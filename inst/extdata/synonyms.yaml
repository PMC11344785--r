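# Canonical taxonomic units (species + coccolith-morphology suffix) mapped
# to their synonyms and known misspellings. One synonym may map to only one
# canonical name; collisions are a load error.
"Emiliania huxleyi HET":
  - "Coccolithus huxleyi HET"
  - "Emiliana huxleyi HET"
"Gephyrocapsa oceanica HET":
  - "Gephyrocapsa oceanicus HET"
"Reticulofenestra sessilis HET": []
"Rhabdosphaera clavigera HET":
  - "Rhabdosphaera claviger HET"
  - "Rhabdosphaera stylifera HET"
"Algirosphaera robusta HET":
  - "Algirosphaera oryza HET"
"Calcidiscus leptoporus HET":
  - "Cyclococcolithus leptoporus HET"
  - "Calcidiscus quadriperforatus HET"
"Umbilicosphaera sibogae HET": []
"Coccolithus pelagicus HET":
  - "Coccolithus pelagicus ssp. pelagicus HET"
"Helicosphaera carteri HET":
  - "Helicosphaera carterii HET"
"Helicosphaera pavimentum HET": []
"Syracosphaera nodosa HET": []
"Syracosphaera noroitica HET": []
"Syracosphaera pulchra HET": []
"Syracosphaera pulchra HOL":
  - "Calyptrosphaera oblonga HOL"
"Syracosphaera mediterranea HOL wettsteinii type": []
"Helladosphaera cornifera HOL": []
"Sphaerocalyptra quadridentata HOL": []
"Ceratolithus cristatus CER":
  - "Ceratolithus cristatus HET telesmus type"
"Florisphaera profunda NANO": []
"Alisphaera gaudii POL": []
"Calciopappus caudatus HET": []
"Syracosphaera aurisinae HET": []
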