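# Example tracer panel: in-vivo effective diffusion coefficients in cm^2/s
tracers:
  - name: dextran-10kDa
    kDa: 10
    Rh_nm: 2
    D_cm2s: 5.1e-7
  - name: dextran-70kDa
    kDa: 70
    Rh_nm: 5
    D_cm2s: 0.75e-7
  - name: dextran-2000kDa
    kDa: 2000
    Rh_nm: 12
    D_cm2s: 0.1e-7
  - name: ovalbumin
    kDa: 45
    Rh_nm: 3
    D_cm2s: 1.6e-7
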