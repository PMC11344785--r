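taxon,vol_mean_um3,vol_sd_um3,shape,source,n_obs
Alisphaera gaudii POL,134.2,79.7,spherical,cros_fortuno_2002,26
Calciopappus caudatus HET,23.4,3.9,prolate_spheroid,gaarder_ramsfjell_1954,177
Calicasphaera blokii HOL,33.5,,spherical,cros_fortuno_2002,32
Calicasphaera concava HOL,20.6,,spherical,cros_fortuno_2002,27
Calyptrosphaera sphaeroidea HOL,346.4,186.2,spherical,cros_fortuno_2002,81
Helicosphaera HOL confusus type,472.3,181.0,spherical,cros_fortuno_2002,27
Helladosphaera pienaarii HOL,190.0,99.5,spherical,norris_1985,25
Ophiaster formosus HET,51.5,25.0,spherical,cros_fortuno_2002,187
Ophiaster hydroideus HET,44.7,3.0,spherical,cros_fortuno_2002,490
Pappomonas sp. type 5 HET,144.3,16.5,spherical,cros_fortuno_2002,31
Sphaerocalyptra adenensis HOL,70.0,31.0,spherical,cros_fortuno_2002,40
Syracosphaera aurisinae HET,942.7,150.0,prolate_spheroid,lecal_schlauder_1951,91
Syracosphaera borealis HET,81.7,19.3,spherical,okada_mcintyre_1977,45
Syracosphaera reniformis HET,59.8,19.0,spherical,kleijne_cros_2009,39
Syracosphaera squamosa HET,11.7,2.5,spherical,kleijne_cros_2009,48
Syracosphaera strigilis HET,91.7,37.1,spherical,cros_fortuno_2002,24
Wigwamma antarctica HET,65.4,,spherical,thomsen_1988,41
Zygosphaera marsilii HOL,174.4,37.6,spherical,borsetti_cati_1976,45
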