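# Worked-example scenario: a pre-measured reporter-DNA concentration of
# 2.41 +/- 0.48 nM run through the conversion chain (strands:antibody 3:1,
# antigen MW 29.1 kDa), yielding 0.80 +/- 0.16 nM antibody and
# 23.4 +/- 4.66 ng/mL antigen mass.
scenario: worked_example
measured:
  dna_conc: 2.41
  dna_sd: 0.48
qpcr:
  slope: 4.059
  intercept: 8.144
  conc_at_x0: 10.0
  noise_sd: 0.2
  max_cycles: 40
quantify:
  dna_per_ab: 3
  mw: 29.1
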