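# Continuous hydrogen peroxide treatment of the standard biofilm:
# every parameter omitted here keeps its standard value.
parameters:
  S_in_G: 100
dose:
  time1: 2
  time2: 6
  dose1: 500
  dose2: 500
scenario:
  case: B
  t_final: 100
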