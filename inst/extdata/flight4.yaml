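# Miniaturized wireless system: 4-optode prefrontal band, 4 Hz.
n_optodes: 4
fs_hz: 4.0
wavelengths_nm: [730, 850]
separation_mm: 25
dpf: 5.97
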