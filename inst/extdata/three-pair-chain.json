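{"n_pairs":3,"offsets_hz":[0,200,400],"j_intra_hz":[-13.5,-13.5,-13.5],"j_vicinal_hz":[{"i":1,"j":3,"J_hz":7},{"i":1,"j":4,"J_hz":6},{"i":2,"j":3,"J_hz":6},{"i":2,"j":4,"J_hz":7},{"i":3,"j":5,"J_hz":7},{"i":3,"j":6,"J_hz":6},{"i":4,"j":5,"J_hz":6},{"i":4,"j":6,"J_hz":7}],"labels":["AA'","MM'","XX'"]}
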