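# Family-level classification: family mapped to its canonical units.
Noelaerhabdaceae:
  - "Emiliania huxleyi HET"
  - "Gephyrocapsa oceanica HET"
  - "Reticulofenestra sessilis HET"
Rhabdosphaeraceae:
  - "Rhabdosphaera clavigera HET"
  - "Algirosphaera robusta HET"
  - "Sphaerocalyptra quadridentata HOL"
Calcidiscaceae:
  - "Calcidiscus leptoporus HET"
  - "Umbilicosphaera sibogae HET"
Coccolithaceae:
  - "Coccolithus pelagicus HET"
Helicosphaeraceae:
  - "Helicosphaera carteri HET"
  - "Helicosphaera pavimentum HET"
Syracosphaeraceae:
  - "Syracosphaera nodosa HET"
  - "Syracosphaera noroitica HET"
  - "Syracosphaera pulchra HET"
  - "Syracosphaera pulchra HOL"
  - "Syracosphaera mediterranea HOL wettsteinii type"
  - "Syracosphaera aurisinae HET"
  - "Calciopappus caudatus HET"
Ceratolithaceae:
  - "Ceratolithus cristatus CER"
Incertae sedis:
  - "Florisphaera profunda NANO"
  - "Alisphaera gaudii POL"
  - "Helladosphaera cornifera HOL"
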