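species_id	cutoff_percent
sp01	99.95
sp02	99.94
sp03	99.96
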