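# Worked example: feed the printed apparent ethyl acetate concentrations
# (10^-7.4 at sample dilution 10^-2; 10^-6.1 at 10^-1) through the
# co-dilution and aggregation stages. Reproduces the 10^-5.2 / 6 ppm /
# 0.0006% aggregate.
mode: worked_example
worked_example:
  - apparent_c: -7.4
    sample_dilution: -2
  - apparent_c: -6.1
    sample_dilution: -1
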