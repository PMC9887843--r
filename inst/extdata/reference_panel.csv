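name,red_reflectance,nir_reflectance
White,92.69,87.62
Sand,63.59,60.85
Brown,16.29,16.13
Indian Burch,66.72,62.69
Forest Green,4.90,5.88
Burgundy,25.53,39.40
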