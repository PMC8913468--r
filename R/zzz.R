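.datatable.aware <- TRUE

utils::globalVariables(c("ed", "off", "allele", "pos", "read", "strand", "."))
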