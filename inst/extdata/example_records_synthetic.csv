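species,thermoregulation,fertilization_mode,diluent,diluent_job,handling,concentration_sperm_per_ml,rate_ul_o2_per_h,reporting,std_concentration_sperm_per_ml,assay_volume_ml,n_replicates,source
Bos taurus,endotherm,internal,carbohydrate_containing,extender,fresh,3e8,4.02,actual,,1,4,synthetic example
Bos taurus,endotherm,internal,carbohydrate_containing,extender,fresh,5e7,1.1,standardized,1e8,1,4,synthetic example
Galeolaria caespitosa,ectotherm,external,carbohydrate_free,activator,fresh,1e7,0.12,actual,,0.75,6,synthetic example
Galeolaria caespitosa,ectotherm,external,carbohydrate_free,activator,fresh,1e8,0.95,actual,,0.75,6,synthetic example
Heliocidaris erythrogramma,ectotherm,external,carbohydrate_free,activator,fresh,1e6,0.02,actual,,0.75,5,synthetic example
Gallus gallus,endotherm,internal,carbohydrate_containing,extender,frozen_thawed,,2.4,standardized,1e8,,3,synthetic example
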