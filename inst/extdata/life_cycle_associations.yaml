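# Haploid-phase taxonomic units mapped to their associated diploid (HET)
# life-cycle phases, used to impute cell sizes for haploid phases lacking
# direct measurements.
"Sphaerocalyptra quadridentata HOL":
  - "Algirosphaera robusta HET"
  - "Rhabdosphaera clavigera HET"
"Helladosphaera cornifera HOL":
  - "Syracosphaera nodosa HET"
  - "Syracosphaera noroitica HET"
"Syracosphaera pulchra HOL":
  - "Syracosphaera pulchra HET"
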