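# Desktop continuous-wave system: 16-optode prefrontal headband, 2 Hz.
n_optodes: 16
fs_hz: 2.0
wavelengths_nm: [730, 850]
separation_mm: 25
dpf: 5.97
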