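component,wastewater,solvent,raffinate,extract
water,0.9948,0,0.9962,0.1283
acetic_acid,0.0037,0,0.0037,0.0028
butyric_acid,0.0002,0,0.0001,0.0010
octyl_acetate,0.0013,0,0.0000009,0.0692
tridecanol,0,1,0,0.7987
flow,9682,150,9644,187.6
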